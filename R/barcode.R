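#' Persistence barcode of a super-level-set cubical filtration
#'
#' Treats each pixel/voxel of `field` as a closed unit cube carrying its
#' value, and sweeps the threshold p from 1 down to 0.  The super-level set
#' B(p) is the union of closed cubes with value >= p; as p falls, connected
#' components, loops and (in 3D) cavities appear and disappear.  Each such
#' feature is one bar (birth, death) with birth >= death.  Every birth and
#' death happens at the exact value of some pixel — that pixel is recorded as
#' the bar's critical cell, and is the conduit through which gradients of
#' barcode-based losses reach the probability map.
#'
#' The single component that never dies (the whole image is one component at
#' p = 0) is reported as an essential bar with death truncated to 0 and an
#' `NA` death cell.  Zero-length bars are dropped.
#'
#' @param field a scalar field (2D matrix or 3D array, values in \[0, 1\]);
#'   see [as_scalar_field()].
#' @param max_dim highest homology dimension to report (defaults to the field
#'   dimension minus one: 1 in 2D, 2 in 3D).
#' @return an object of class `"barcode"`: a data frame with columns
#'   `dim` (homology dimension), `ell` (rank of the bar within its dimension,
#'   longest first), `birth`, `death`, `birth_cell`, `death_cell` (1-based
#'   linear indices into `field`; `NA` death cell for the essential bar) and
#'   `essential`.  The field shape is kept in `attr(, "shape")`.
#' @seealso [betti_at_threshold()] for the persistence-free oracle,
#'   [topo_loss()] for the loss on barcodes, [plot.barcode()].
#' @examples
#' ring <- matrix(0.1, 5, 5); ring[2:4, 2:4] <- 0.9; ring[3, 3] <- 0.1
#' compute_barcode(ring)
#' @export
compute_barcode <- function(field, max_dim = NULL) {
  field <- as_scalar_field(field)
  shape <- dim(field)
  if (is.null(max_dim)) max_dim <- length(shape) - 1L
  if (max_dim > length(shape) - 1L)
    stop("max_dim must be <= field dimension - 1")
  raw <- .cubical_persistence_cpp(as.numeric(field), as.integer(shape))
  bars <- data.frame(dim = raw$dim, birth = raw$birth, death = raw$death,
                     birth_cell = raw$birth_cell, death_cell = raw$death_cell,
                     essential = as.logical(raw$essential))
  if (any(bars$essential & bars$dim > 0L))
    stop("internal error: essential bar in dimension > 0") # full grid is contractible
  bars <- bars[bars$dim <= max_dim, , drop = FALSE]
  new_barcode(bars, shape)
}

# canonical ordering + ell ranks; shared by the fast path and the brute-force
# oracle so the two are comparable row-by-row
new_barcode <- function(bars, shape) {
  stopifnot(all(bars$birth >= bars$death))
  len <- bars$birth - bars$death
  o <- order(bars$dim, -len, -bars$birth, bars$birth_cell)
  bars <- bars[o, , drop = FALSE]
  ell <- stats::ave(seq_len(nrow(bars)), bars$dim, FUN = seq_along)
  bars <- data.frame(dim = bars$dim, ell = as.integer(ell),
                     birth = bars$birth, death = bars$death,
                     birth_cell = bars$birth_cell,
                     death_cell = bars$death_cell,
                     essential = bars$essential,
                     row.names = NULL)
  structure(bars, shape = shape, class = c("barcode", "data.frame"))
}

#' Number of bars alive at a threshold
#'
#' Counts bars of dimension `dim` with `death < p <= birth`; by construction
#' this equals the Betti number of the super-level set B(p).
#'
#' @param barcode a [compute_barcode()] result.
#' @param p threshold in \[0, 1\].
#' @param dim homology dimension.
#' @return a non-negative integer.
#' @export
bars_alive <- function(barcode, p, dim) {
  stopifnot(inherits(barcode, "barcode"))
  sum(barcode$dim == dim & barcode$death < p & p <= barcode$birth)
}

#' @export
print.barcode <- function(x, ...) {
  shape <- attr(x, "shape")
  cat(sprintf("Persistence barcode (super-level sets), field %s\n",
              paste(shape, collapse = " x ")))
  if (nrow(x) == 0L) {
    cat("  <no bars>\n")
    return(invisible(x))
  }
  for (k in sort(unique(x$dim))) {
    cat(sprintf("  dim %d: %d bar(s)\n", k, sum(x$dim == k)))
  }
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @export
summary.barcode <- function(object, ...) {
  len <- object$birth - object$death
  out <- do.call(rbind, lapply(sort(unique(object$dim)), function(k) {
    sel <- object$dim == k
    data.frame(dim = k, n_bars = sum(sel), longest = max(len[sel]),
               total_persistence = sum(len[sel]))
  }))
  if (is.null(out))
    out <- data.frame(dim = integer(), n_bars = integer(),
                      longest = numeric(), total_persistence = numeric())
  out
}

#' Plot a barcode diagram
#'
#' Horizontal bars per feature, one colour per homology dimension
#' (components red, loops green, cavities blue), threshold on the x axis
#' running from 1 to 0 as the filtration grows.
#'
#' @param x a `"barcode"` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.barcode <- function(x, ...) {
  cols <- c("firebrick", "forestgreen", "steelblue")
  n <- nrow(x)
  graphics::plot(NA, xlim = c(1, 0), ylim = c(0, max(n, 1) + 1),
                 xlab = "filtration value p", ylab = "",
                 yaxt = "n", ...)
  if (n > 0L) {
    o <- order(x$dim, x$ell)
    for (i in seq_len(n)) {
      b <- x[o[i], ]
      graphics::segments(b$birth, n - i + 1, b$death, n - i + 1,
                         col = cols[b$dim + 1L], lwd = 3)
    }
  }
  graphics::legend("topright", bty = "n", lwd = 3, col = cols[seq_len(3)],
                   legend = paste0("dim ", 0:2))
  invisible(x)
}

#' Export a barcode to CSV or JSON
#'
#' @param barcode a `"barcode"` object.
#' @param path output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_barcode <- function(barcode, path) {
  stopifnot(inherits(barcode, "barcode"))
  df <- as.data.frame(barcode)
  if (grepl("\\.csv$", tolower(path))) {
    utils::write.csv(df, path, row.names = FALSE)
  } else if (grepl("\\.json$", tolower(path))) {
    jsonlite::write_json(list(shape = attr(barcode, "shape"), bars = df),
                         path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported barcode format for ", path)
  invisible(path)
}
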