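#' Build the filtered cubical complex of a scalar field
#'
#' Enumerates every cell of the cubical complex covering the pixel/voxel
#' grid — vertices, edges, squares (and cubes in 3D) — on the "doubled
#' grid", where a cell with integer coordinates `g` in `0..2n` spans an
#' interval in each coordinate where `g` is odd.  Pixel (i, j) (0-based)
#' corresponds to the closed square \[i, i+1\] x \[j, j+1\], the top cell at
#' doubled-grid coordinates (2i+1, 2j+1).
#'
#' Each top cell carries its pixel's value; every lower-dimensional face
#' carries the maximum value over the top cells containing it, so that a
#' face enters the super-level set B(p) exactly when its first top cell
#' does, and B(p) is the closed cubical set of Eq.-style unions of closed
#' cubes.  The pixel attaining that maximum (smallest linear index on ties)
#' is the cell's `source_cell`.
#'
#' @param field a scalar field (2D or 3D, finite values).
#' @return an object of class `"cubical_filtration"`: a data frame with one
#'   row per cell and columns `cell_dim`, `value`, `source_cell` (1-based
#'   pixel linear index) and the doubled-grid coordinates `g1`, `g2`
#'   (and `g3` in 3D); field shape in `attr(, "shape")`.
#' @examples
#' cx <- build_filtration(matrix(0.7, 1, 1))
#' table(cx$cell_dim)  # 4 vertices, 4 edges, 1 square
#' @export
build_filtration <- function(field) {
  field <- as_scalar_field(field)
  n <- dim(field)
  d <- length(n)
  G <- 2L * n + 1L
  grids <- lapply(G, function(g) 0:(g - 1L))
  gr <- as.matrix(do.call(expand.grid, grids))
  colnames(gr) <- paste0("g", seq_len(d))
  odd <- gr %% 2L
  cdim <- rowSums(odd)
  val <- numeric(nrow(gr)); src <- integer(nrow(gr))
  for (r in seq_len(nrow(gr))) {
    rng <- lapply(seq_len(d), function(ax) {
      g <- gr[r, ax]
      if (g %% 2L == 1L) (g - 1L) %/% 2L
      else seq(max(0L, g %/% 2L - 1L), min(n[ax] - 1L, g %/% 2L))
    })
    pix <- as.matrix(expand.grid(rng))
    lin <- if (d == 2L) pix[, 1] + n[1] * pix[, 2] + 1L
           else pix[, 1] + n[1] * (pix[, 2] + n[2] * pix[, 3]) + 1L
    v <- field[lin]
    best <- which(v == max(v))
    best <- best[which.min(lin[best])]
    val[r] <- v[best]; src[r] <- lin[best]
  }
  out <- data.frame(cell_dim = cdim, value = val, source_cell = src)
  out <- cbind(out, as.data.frame(gr))
  structure(out, shape = n, class = c("cubical_filtration", "data.frame"))
}

#' @export
print.cubical_filtration <- function(x, ...) {
  cat(sprintf("Filtered cubical complex, field %s: %s\n",
              paste(attr(x, "shape"), collapse = " x "),
              paste(sprintf("%d cells of dim %d", table(x$cell_dim),
                            sort(unique(x$cell_dim))), collapse = ", ")))
  invisible(x)
}

#' Super-level set of a filtration
#'
#' Returns the logical pixel mask of the super-level set B(p): the union of
#' closed pixel cubes with value >= p.  A cell of the complex belongs to
#' B(p) exactly when its filtration value is >= p.
#'
#' @param complex a [build_filtration()] result (or a scalar field, which is
#'   filtered first).
#' @param p threshold in \[0, 1\].
#' @return logical array over pixels: which closed cubes are present.
#' @export
super_level_set <- function(complex, p) {
  if (!inherits(complex, "cubical_filtration"))
    complex <- build_filtration(complex)
  n <- attr(complex, "shape")
  top <- complex[complex$cell_dim == length(n), , drop = FALSE]
  mask <- array(FALSE, n)
  idx <- if (length(n) == 2L) (top$g1 - 1L) %/% 2L + n[1] * ((top$g2 - 1L) %/% 2L) + 1L
         else (top$g1 - 1L) %/% 2L + n[1] * (((top$g2 - 1L) %/% 2L) +
                n[2] * ((top$g3 - 1L) %/% 2L)) + 1L
  mask[idx] <- top$value >= p
  mask
}
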