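#' Dice overlap score
#'
#' `2|A n B| / (|A| + |B|)` between two binary masks; defined as 1 when both
#' masks are empty.
#'
#' @param a,b binary masks (logical or 0/1 arrays) of equal shape.
#' @return a number in \[0, 1\].
#' @examples
#' dice_score(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2))  # 0.5
#' @export
dice_score <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  a <- a != 0; b <- b != 0
  sab <- sum(a) + sum(b)
  if (sab == 0) return(1)
  2 * sum(a & b) / sab
}

#' Is a probability map topologically correct?
#'
#' `TRUE` iff the Betti numbers of the super-level set at `threshold` equal
#' the prior's desired Betti numbers in every dimension the prior covers.
#' By default the Betti numbers are counted from the persistence barcode
#' (fast, exact); `method = "oracle"` uses the persistence-free
#' [betti_at_threshold()] computation instead — the two always agree, which
#' the test suite verifies.
#'
#' @param field a scalar field.
#' @param prior a [topo_prior()].
#' @param threshold binarisation threshold (default 0.5).
#' @param method `"barcode"` or `"oracle"`.
#' @return logical.
#' @export
topological_correctness <- function(field, prior, threshold = 0.5,
                                    method = c("barcode", "oracle")) {
  method <- match.arg(method)
  stopifnot(inherits(prior, "topo_prior"))
  field <- as_scalar_field(field)
  dims <- seq_along(prior$desired) - 1L
  dims <- dims[dims <= length(dim(field)) - 1L]
  if (method == "oracle") {
    betti <- vapply(dims, function(k) betti_at_threshold(field, threshold, k),
                    integer(1))
  } else {
    bc <- compute_barcode(field, max_dim = max(dims))
    betti <- vapply(dims, function(k) bars_alive(bc, threshold, k), integer(1))
  }
  all(betti == prior$desired[dims + 1L])
}

#' Evaluate a predictor on a test set
#'
#' Computes, per item, the hard Dice score against the ground truth (where a
#' target is available) and the topological correctness of the prediction at
#' the threshold, plus their aggregates.
#'
#' @param pred a `"unet"`, or any function mapping an image to a
#'   probability map.
#' @param test non-empty list of samples.
#' @param prior_fn function(sample) returning a [topo_prior()]; default uses
#'   the sample's `betti` field.
#' @param threshold binarisation threshold.
#' @return an object of class `"eval_report"`: a data frame with one row per
#'   item (`dice`, `topo_correct`, per-dimension `betti_*` columns), with
#'   aggregates `mean_dice` and `prop_topo_correct` as attributes.
#' @export
evaluate <- function(pred, test, prior_fn = NULL, threshold = 0.5) {
  if (length(test) == 0L) stop("test set is empty")
  if (is.null(prior_fn)) prior_fn <- function(s) topo_prior(s$betti)
  fwd <- if (is.function(pred)) pred else function(img) predict(pred, img)
  rows <- lapply(seq_along(test), function(i) {
    it <- test[[i]]
    S <- fwd(it$image)
    prior <- prior_fn(it)
    dims <- seq_along(prior$desired) - 1L
    bc <- compute_barcode(S, max_dim = max(dims))
    betti <- vapply(dims, function(k) bars_alive(bc, threshold, k), integer(1))
    dice <- if (!is.null(it$target))
      dice_score(S >= threshold, it$target >= threshold) else NA_real_
    row <- data.frame(item = i, dice = dice,
                      topo_correct = all(betti == prior$desired[dims + 1L]))
    for (k in dims) row[[paste0("betti_", k)]] <- betti[k + 1L]
    row
  })
  df <- do.call(rbind, rows)
  structure(df,
            mean_dice = mean(df$dice, na.rm = TRUE),
            prop_topo_correct = mean(df$topo_correct),
            class = c("eval_report", "data.frame"))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "Evaluation: %d item(s); mean Dice %.4f; proportion topologically correct %.3f\n",
    nrow(x), attr(x, "mean_dice"), attr(x, "prop_topo_correct")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Write an evaluation report to JSON or CSV
#'
#' @param report an `"eval_report"`.
#' @param path output path ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  df <- as.data.frame(report)
  if (grepl("\\.csv$", tolower(path))) {
    utils::write.csv(df, path, row.names = FALSE)
  } else if (grepl("\\.json$", tolower(path))) {
    jsonlite::write_json(
      list(per_item = df,
           aggregate = list(mean_dice = attr(report, "mean_dice"),
                            prop_topo_correct = attr(report, "prop_topo_correct"))),
      path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported report format for ", path)
  invisible(path)
}
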