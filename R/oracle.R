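#' Betti number of a super-level set, without persistence
#'
#' Computes the Betti number beta_dim of B(p), the union of closed
#' pixel/voxel cubes with value >= p, directly from its definition; no
#' persistence computation is involved, so this serves as an independent
#' oracle against which barcodes are checked.
#'
#' In 2D, beta_0 is found by union-find over included pixels (closed cubes
#' meeting in a corner are connected, i.e. 8-connectivity) and beta_1 from
#' the Euler characteristic of the closed cubical set:
#' chi = #vertices - #edges + #squares and beta_1 = beta_0 - chi.
#' In 3D, the ranks of the GF(2) boundary maps of the closed cubical set are
#' computed by Gaussian elimination (intended for small inputs only).
#'
#' @param field a scalar field.
#' @param p threshold in \[0, 1\].
#' @param dim homology dimension (0 or 1 in 2D; 0, 1 or 2 in 3D).
#' @return a non-negative integer.
#' @examples
#' ring <- matrix(0.1, 5, 5); ring[2:4, 2:4] <- 0.9; ring[3, 3] <- 0.1
#' betti_at_threshold(ring, 0.5, 0)  # 1 component
#' betti_at_threshold(ring, 0.5, 1)  # 1 loop
#' @export
betti_at_threshold <- function(field, p, dim) {
  field <- as_scalar_field(field)
  shape <- base::dim(field)
  d <- length(shape)
  if (dim > d - 1L || dim > 2L)
    stop("dim must be <= field dimension - 1 (and <= 2)")
  if (d == 2L) betti2d(field >= p, dim) else betti3d(field >= p, dim)
}

betti2d <- function(inc, dim) {
  n1 <- nrow(inc); n2 <- ncol(inc)
  if (!any(inc)) return(0L)
  if (dim == 0L) return(n_components_2d(inc))
  # closed cubical set cell counts
  pad <- matrix(FALSE, n1 + 2L, n2 + 2L)
  pad[2:(n1 + 1L), 2:(n2 + 1L)] <- inc
  # vertex (i, j), i in 0..n1, j in 0..n2: included iff any of the <= 4
  # pixels having it as a corner is included
  vert <- pad[1:(n1 + 1L), 1:(n2 + 1L)] | pad[2:(n1 + 2L), 1:(n2 + 1L)] |
    pad[1:(n1 + 1L), 2:(n2 + 2L)] | pad[2:(n1 + 2L), 2:(n2 + 2L)]
  # edges along axis 1 (span rows): at (i in 1..n1, j in 0..n2)
  e1 <- pad[2:(n1 + 1L), 1:(n2 + 1L)] | pad[2:(n1 + 1L), 2:(n2 + 2L)]
  # edges along axis 2 (span cols): at (i in 0..n1, j in 1..n2)
  e2 <- pad[1:(n1 + 1L), 2:(n2 + 1L)] | pad[2:(n1 + 2L), 2:(n2 + 1L)]
  chi <- sum(vert) - (sum(e1) + sum(e2)) + sum(inc)
  b0 <- n_components_2d(inc)
  b0 - chi
}

n_components_2d <- function(inc) {
  idx <- which(inc, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) return(0L)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  key <- idx[, 1] + (idx[, 2] - 1L) * (max(idx[, 1]) + 1L)
  lookup <- new.env(hash = TRUE)
  for (k in seq_len(n)) assign(as.character(key[k]), k, envir = lookup)
  for (k in seq_len(n)) {
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      nb <- (idx[k, 1] + di) + (idx[k, 2] + dj - 1L) * (max(idx[, 1]) + 1L)
      m <- mget(as.character(nb), envir = lookup, ifnotfound = list(NULL))[[1]]
      if (!is.null(m)) {
        ra <- find(k); rb <- find(m)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# --- 3D: GF(2) boundary-map ranks on the doubled grid ------------------

# cells of the closed cubical set as doubled-grid coordinates; a cell is
# included iff one of its cofacing voxels is
included_cells_3d <- function(inc) {
  n <- base::dim(inc)
  G <- 2L * n + 1L
  # voxel inclusion, padded so every grid cell can look up its cofaces
  pad <- array(FALSE, n + 2L)
  pad[2:(n[1] + 1L), 2:(n[2] + 1L), 2:(n[3] + 1L)] <- inc
  cells <- vector("list", 4L)
  gr <- expand.grid(g1 = 0:(G[1] - 1L), g2 = 0:(G[2] - 1L), g3 = 0:(G[3] - 1L))
  odd <- cbind(gr$g1 %% 2L, gr$g2 %% 2L, gr$g3 %% 2L)
  cdim <- rowSums(odd)
  # coface voxel ranges (in padded coords: voxel v -> pad index v + 1)
  lo <- hi <- matrix(0L, nrow(gr), 3L)
  for (ax in 1:3) {
    g <- gr[[ax]]
    lo[, ax] <- ifelse(odd[, ax] == 1L, (g - 1L) %/% 2L, pmax(0L, g %/% 2L - 1L))
    hi[, ax] <- ifelse(odd[, ax] == 1L, (g - 1L) %/% 2L, pmin(n[ax] - 1L, g %/% 2L))
  }
  keep <- logical(nrow(gr))
  for (r in seq_len(nrow(gr))) {
    sub <- pad[(lo[r, 1] + 2L):(hi[r, 1] + 2L),
               (lo[r, 2] + 2L):(hi[r, 2] + 2L),
               (lo[r, 3] + 2L):(hi[r, 3] + 2L)]
    keep[r] <- any(sub)
  }
  ids <- gr$g1 + G[1] * (gr$g2 + G[2] * gr$g3)
  for (k in 0:3) cells[[k + 1L]] <- ids[keep & cdim == k]
  attr(cells, "G") <- G
  cells
}

faces_of_cell_3d <- function(id, G) {
  g <- c(id %% G[1], (id %/% G[1]) %% G[2], id %/% (G[1] * G[2]))
  strides <- c(1L, G[1], G[1] * G[2])
  out <- integer(0)
  for (ax in 1:3) if (g[ax] %% 2L == 1L)
    out <- c(out, id - strides[ax], id + strides[ax])
  out
}

rank_gf2 <- function(M) {
  if (length(M) == 0L || nrow(M) == 0L || ncol(M) == 0L) return(0L)
  M <- M %% 2L
  r <- 0L
  nr <- nrow(M); nc <- ncol(M)
  row <- 1L
  for (col in seq_len(nc)) {
    piv <- which(M[row:nr, col] == 1L)
    if (length(piv) == 0L) next
    piv <- piv[1] + row - 1L
    if (piv != row) M[c(piv, row), ] <- M[c(row, piv), ]
    hits <- which(M[, col] == 1L)
    hits <- hits[hits != row]
    if (length(hits))
      M[hits, ] <- (M[hits, , drop = FALSE] + matrix(M[row, ], length(hits), nc, byrow = TRUE)) %% 2L
    r <- r + 1L
    row <- row + 1L
    if (row > nr) break
  }
  r
}

betti3d <- function(inc, dim) {
  if (!any(inc)) return(0L)
  cells <- included_cells_3d(inc)
  G <- attr(cells, "G")
  nk <- vapply(cells, length, integer(1))
  bmat <- function(k) { # boundary map from k-cells to (k-1)-cells
    if (nk[k + 1L] == 0L || nk[k]== 0L) return(matrix(0L, 0L, 0L))
    ridx <- seq_along(cells[[k]])
    names(ridx) <- as.character(cells[[k]])
    M <- matrix(0L, nk[k], nk[k + 1L])
    for (j in seq_len(nk[k + 1L])) {
      f <- faces_of_cell_3d(cells[[k + 1L]][j], G)
      M[ridx[as.character(f)], j] <- 1L
    }
    M
  }
  rk <- function(k) if (k < 1L || k > 3L) 0L else rank_gf2(bmat(k))
  nk[dim + 1L] - rk(dim) - rk(dim + 1L)
}

#' Brute-force reference barcode
#'
#' Full boundary-matrix reduction over GF(2) in filtration order, written
#' directly from the definitions in plain R with dense bookkeeping.  It is an
#' independent implementation used to validate [compute_barcode()] on small
#' inputs; the bar multisets (dim, birth, death) of the two must agree
#' exactly (critical cells may differ only within value ties).
#'
#' @param field a scalar field with at most 500 pixels/voxels.
#' @return a `"barcode"` object.
#' @export
reference_barcode_bruteforce <- function(field) {
  field <- as_scalar_field(field)
  n <- base::dim(field)
  if (prod(n) > 500) stop("brute-force oracle limited to fields with <= 500 cells")
  d <- length(n)
  if (d == 2L) n <- c(n, 1L)
  G <- ifelse(seq_len(3) <= d, 2L * n + 1L, 1L)
  ids <- 0:(prod(G) - 1L)
  g1 <- ids %% G[1]; g2 <- (ids %/% G[1]) %% G[2]; g3 <- ids %/% (G[1] * G[2])
  odd <- cbind(g1 %% 2L, g2 %% 2L, g3 %% 2L)
  cdim <- rowSums(odd)
  # value and source pixel: max over cofacing voxels, smallest index on ties
  val <- numeric(length(ids)); src <- integer(length(ids))
  gco <- cbind(g1, g2, g3)
  for (r in seq_along(ids)) {
    rng <- lapply(1:3, function(ax) {
      g <- gco[r, ax]
      if (ax > d) return(0L)
      if (g %% 2L == 1L) (g - 1L) %/% 2L
      else seq(max(0L, g %/% 2L - 1L), min(n[ax] - 1L, g %/% 2L))
    })
    pix <- as.matrix(expand.grid(rng))
    lin <- pix[, 1] + n[1] * (pix[, 2] + n[2] * pix[, 3]) + 1L
    v <- field[lin]
    best <- which(v == max(v))
    best <- best[which.min(lin[best])]
    val[r] <- v[best]; src[r] <- lin[best]
  }
  ord <- order(-val, cdim, ids)
  pos <- integer(length(ids)); pos[ord] <- seq_along(ids)
  strides <- c(1L, G[1], G[1] * G[2])
  C <- length(ids)
  cols <- vector("list", C)
  owner <- rep(NA_integer_, C)
  paired <- logical(C)
  pair_birth <- integer(0); pair_death <- integer(0)
  symdiff <- function(a, b) { u <- c(a, b); sort(u[!(duplicated(u) | duplicated(u, fromLast = TRUE))]) }
  for (j in seq_len(C)) {
    id <- ids[ord[j]]
    gc <- gco[ord[j], ]
    col <- integer(0)
    for (ax in seq_len(d)) if (gc[ax] %% 2L == 1L)
      col <- c(col, pos[match(c(id - strides[ax], id + strides[ax]), ids)])
    col <- sort(col)
    repeat {
      if (length(col) == 0L) break
      piv <- col[length(col)]
      if (is.na(owner[piv])) {
        owner[piv] <- j
        paired[piv] <- TRUE; paired[j] <- TRUE
        pair_birth <- c(pair_birth, piv); pair_death <- c(pair_death, j)
        cols[[j]] <- col
        break
      }
      col <- symdiff(col, cols[[owner[piv]]])
    }
  }
  bi <- ord[pair_birth]; de <- ord[pair_death]
  bars <- data.frame(dim = cdim[bi], birth = val[bi], death = val[de],
                     birth_cell = src[bi], death_cell = src[de],
                     essential = FALSE)
  bars <- bars[bars$birth > bars$death, , drop = FALSE]
  ess <- which(!paired)
  if (length(ess)) {
    ei <- ord[ess]
    keep <- val[ei] > 0
    if (any(keep)) {
      bars <- rbind(bars, data.frame(
        dim = cdim[ei[keep]], birth = val[ei[keep]], death = 0,
        birth_cell = src[ei[keep]], death_cell = NA_integer_,
        essential = TRUE))
    }
  }
  new_barcode(bars, base::dim(field))
}
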