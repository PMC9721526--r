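#' Training configuration
#'
#' Collects the tunable parameters of all training entry points.
#'
#' @param lambda weight of the topological loss term (>= 0).
#' @param lr learning rate for supervised/semi-supervised training (Adam).
#' @param epochs maximum number of epochs (one full labelled batch per
#'   epoch; in semi-supervised training also one unlabelled batch).
#' @param val_interval validate every this many epochs.
#' @param patience stop after this many consecutive non-improving
#'   validations (>= 1).
#' @param warmup optimiser steps over which the learning rate ramps
#'   linearly from 0 to `lr` (0 disables).  A short warmup stabilises
#'   continued training of an already-converged network, whose restarted
#'   adaptive optimiser would otherwise take full-size first steps.
#' @param steps gradient steps for per-item post-processing adaptation.
#' @param post_lr learning rate for post-processing adaptation.
#' @param loss supervised loss: `"dice"` (soft Dice) or `"mse"` (mean
#'   squared error, for denoising-style targets).
#' @param threshold binarisation threshold used for validation Dice and
#'   topological correctness.
#' @param seed integer seed; every stochastic choice during training derives
#'   from it.
#' @return a list of class `"train_config"`.
#' @export
train_config <- function(lambda = 0.01, lr = 1e-3, epochs = 200L,
                         val_interval = 10L, patience = 5L, warmup = 0L,
                         steps = 200L, post_lr = 1e-2,
                         loss = c("dice", "mse"), threshold = 0.5,
                         seed = 1L) {
  loss <- match.arg(loss)
  if (lambda < 0) stop("lambda must be >= 0")
  if (patience < 1L) stop("patience must be >= 1")
  structure(list(lambda = lambda, lr = lr, epochs = as.integer(epochs),
                 val_interval = as.integer(val_interval),
                 patience = as.integer(patience), warmup = as.integer(warmup),
                 steps = as.integer(steps),
                 post_lr = post_lr, loss = loss, threshold = threshold,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)` with
#' `eps = 1e-6`; differentiable in the prediction `p`.
#'
#' @param pred,target scalar fields of equal shape.
#' @return a single number in \[0, 1\].
#' @export
soft_dice_loss <- function(pred, target) {
  if (!identical(dim(pred), dim(target))) stop("shape mismatch")
  eps <- 1e-6
  1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)
}

# loss value and gradient dL/dpred for the supervised objectives
supervised_loss_grad <- function(pred, target, kind) {
  if (kind == "dice") {
    eps <- 1e-6
    num <- 2 * sum(pred * target) + eps
    den <- sum(pred) + sum(target) + eps
    list(loss = 1 - num / den, grad = -(2 * target * den - num) / den^2)
  } else {
    v <- length(pred)
    list(loss = mean((pred - target)^2), grad = 2 * (pred - target) / v)
  }
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]]$W <- a[[nm]]$W + b[[nm]]$W
    a[[nm]]$b <- a[[nm]]$b + b[[nm]]$b
  }
  a
}

scale_grads <- function(g, s) {
  for (nm in names(g)) { g[[nm]]$W <- g[[nm]]$W * s; g[[nm]]$b <- g[[nm]]$b * s }
  g
}

# one full-batch supervised gradient; returns mean loss and mean grads
supervised_batch <- function(net, items, kind) {
  grads <- NULL; total <- 0
  for (it in items) {
    fw <- unet_forward(net, it$image, train = TRUE)
    lg <- supervised_loss_grad(fw$S, it$target, kind)
    total <- total + lg$loss
    grads <- add_grads(grads, unet_backward(net, fw$cache, lg$grad))
  }
  list(loss = total / length(items), grads = scale_grads(grads, 1 / length(items)))
}

val_dice <- function(net, val, threshold) {
  mean(vapply(val, function(it) {
    dice_score(predict(net, it$image) >= threshold, it$target >= threshold)
  }, numeric(1)))
}

#' Supervised training with early stopping
#'
#' Full-batch Adam minimisation of the soft Dice loss (or MSE in denoising
#' mode) on the labelled set.  Every `val_interval` epochs the hard Dice
#' score on the validation set is evaluated; training stops early when it
#' has not improved for `patience` consecutive evaluations, and the weights
#' from the best validation point are returned.
#'
#' @param pred a `"unet"` predictor (its weights are the starting point).
#' @param labelled non-empty list of samples (`$image`, `$target`).
#' @param val validation samples; may be `NULL` to disable early stopping.
#' @param cfg a [train_config()].
#' @return an object of class `"topo_fit"`: list with `predictor` (best
#'   weights), `history` (data frame: epoch, dice_loss, topo_loss, val_dice),
#'   `cfg` and `stopped_epoch`.
#' @export
train_supervised <- function(pred, labelled, val = NULL, cfg = train_config()) {
  stopifnot(inherits(pred, "unet"))
  if (length(labelled) == 0L) stop("labelled set is empty")
  run_training(pred, labelled, unlabelled = NULL, val = val, prior_fn = NULL,
               cfg = cfg, semi = FALSE)
}

#' Semi-supervised training with a topological prior
#'
#' Alternates, within each epoch, one full labelled batch back-propagating
#' the Dice (or MSE) loss and one full unlabelled batch back-propagating the
#' topological loss of the predicted probability maps, weighted by
#' `cfg$lambda` and averaged over the batch.  The unlabelled images need no
#' masks — only their desired Betti numbers, supplied per item by
#' `prior_fn`.  The topological gradient enters the network through each
#' bar's critical pixels.  With `lambda = 0` the unlabelled step is skipped
#' entirely, so the run coincides exactly with supervised training under the
#' same seed and schedule.
#'
#' The predictor should already be supervised-pretrained so that its
#' predictions are good enough for the topological signal to be useful; use
#' [train_supervised()] first.
#'
#' @param pred a `"unet"` (typically pretrained).
#' @param labelled,val as in [train_supervised()].
#' @param unlabelled list of samples whose `$target` may be absent; if the
#'   list is empty the call degenerates to supervised training with a
#'   warning.
#' @param prior_fn function(sample) returning a [topo_prior()]; default uses
#'   the sample's `betti` field.
#' @param cfg a [train_config()].
#' @return a `"topo_fit"`; its history carries both loss streams.
#' @export
train_semisupervised <- function(pred, labelled, unlabelled, val = NULL,
                                 prior_fn = NULL, cfg = train_config()) {
  stopifnot(inherits(pred, "unet"))
  if (length(labelled) == 0L) stop("labelled set is empty")
  if (length(unlabelled) == 0L) {
    warning("unlabelled set is empty; degenerating to supervised training")
    return(run_training(pred, labelled, NULL, val, NULL, cfg, semi = FALSE))
  }
  if (is.null(prior_fn)) prior_fn <- function(s) topo_prior(s$betti)
  run_training(pred, labelled, unlabelled, val, prior_fn, cfg, semi = TRUE)
}

run_training <- function(pred, labelled, unlabelled, val, prior_fn, cfg,
                         semi) {
  net <- clone_predictor(pred)
  opt <- adam_init(net$params)
  hist <- vector("list", cfg$epochs)
  # the starting weights compete in model selection: a continuation that
  # never beats its own starting point returns the start, not a worse net
  best <- list(metric = -Inf, net = clone_predictor(net), epoch = 0L)
  if (!is.null(val) && length(val)) {
    vd0 <- val_dice(net, val, cfg$threshold)
    best$metric <- if (semi && cfg$lambda > 0) {
      vt0 <- mean(vapply(val, function(it)
        topological_correctness(predict(net, it$image), prior_fn(it),
                                cfg$threshold), logical(1)))
      vt0 + vd0 / 1000
    } else vd0
  }
  bad <- 0L
  stopped <- cfg$epochs
  wu <- if (is.null(cfg$warmup)) 0L else cfg$warmup
  eff_lr <- function(state) if (wu > 0L) cfg$lr * min(1, (state$t + 1) / wu) else cfg$lr
  for (ep in seq_len(cfg$epochs)) {
    sb <- supervised_batch(net, labelled, cfg$loss)
    st <- adam_step(net$params, sb$grads, opt, eff_lr(opt))
    net$params <- st$params; opt <- st$state
    tl <- NA_real_
    if (semi && cfg$lambda > 0) {
      grads <- NULL; tl <- 0
      for (it in unlabelled) {
        fw <- unet_forward(net, it$image, train = TRUE)
        rep <- topo_loss_on_field(fw$S, prior_fn(it))
        tl <- tl + rep$total
        dS <- loss_gradient_field(rep)
        grads <- add_grads(grads, unet_backward(net, fw$cache, dS))
      }
      tl <- tl / length(unlabelled)
      # the semi-supervised objective sums the topological loss over the
      # unlabelled batch (lambda multiplies the sum, not the mean), so the
      # unlabelled gradient is scaled by lambda alone
      grads <- scale_grads(grads, cfg$lambda)
      st <- adam_step(net$params, grads, opt, eff_lr(opt))
      net$params <- st$params; opt <- st$state
    }
    vd <- NA_real_
    if (!is.null(val) && length(val) && ep %% cfg$val_interval == 0L) {
      vd <- val_dice(net, val, cfg$threshold)
      # supervised training selects on validation Dice; with the
      # topological loss active, validation topological correctness is the
      # quantity being optimised and takes precedence (Dice as tie-break)
      metric <- vd
      if (semi && cfg$lambda > 0) {
        vt <- mean(vapply(val, function(it)
          topological_correctness(predict(net, it$image), prior_fn(it),
                                  cfg$threshold), logical(1)))
        metric <- vt + vd / 1000
      }
      if (metric > best$metric) {
        best <- list(metric = metric, net = clone_predictor(net), epoch = ep)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= cfg$patience) { stopped <- ep; }
      }
    }
    hist[[ep]] <- data.frame(epoch = ep, dice_loss = sb$loss, topo_loss = tl,
                             val_dice = vd)
    if (bad >= cfg$patience) { stopped <- ep; break }
  }
  hist <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  out_net <- if (is.finite(best$metric)) best$net else net
  structure(list(predictor = out_net, final_predictor = net, history = hist,
                 cfg = cfg, stopped_epoch = stopped,
                 best_epoch = if (is.finite(best$metric)) best$epoch else stopped),
            class = "topo_fit")
}

#' @export
print.topo_fit <- function(x, ...) {
  cat(sprintf("topo_fit: %d epoch(s) run, best at epoch %d\n",
              x$stopped_epoch, x$best_epoch))
  tail_row <- x$history[nrow(x$history), ]
  cat(sprintf("  final training loss %.4f", tail_row$dice_loss))
  if (!is.na(tail_row$topo_loss))
    cat(sprintf(", topological loss %.4f", tail_row$topo_loss))
  vd <- x$history$val_dice[!is.na(x$history$val_dice)]
  if (length(vd)) cat(sprintf(", best val Dice %.4f", max(vd)))
  cat("\n")
  invisible(x)
}

#' @export
plot.topo_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$dice_loss, type = "l", xlab = "epoch",
                 ylab = "loss", col = "black", ...)
  if (any(!is.na(h$topo_loss)))
    graphics::lines(h$epoch, h$topo_loss, col = "firebrick")
  sel <- !is.na(h$val_dice)
  if (any(sel))
    graphics::lines(h$epoch[sel], 1 - h$val_dice[sel], col = "steelblue",
                    lty = 2)
  graphics::legend("topright", bty = "n", lty = c(1, 1, 2),
                   col = c("black", "firebrick", "steelblue"),
                   legend = c("supervised loss", "topological loss",
                              "1 - val Dice"))
  invisible(x)
}

#' Per-item topological post-processing
#'
#' Given a trained predictor and one test image with known desired topology
#' (but no ground-truth mask), adapts a copy of the weights to that single
#' item by minimising
#' `mean((anchor - S)^2) + lambda * L_topo(S)`,
#' where the anchor is the original prediction, held fixed.  This finds the
#' minimal change to the output segmentation that corrects its topology.
#' The original predictor is never modified.  Persistence is recomputed at
#' every step, since critical pixels migrate as the map changes.
#'
#' @param pred a trained `"unet"`.
#' @param item a scalar field (the input image) or a synthetic sample
#'   (its `$image` is used).
#' @param prior a [topo_prior()].
#' @param cfg a [train_config()]; uses `lambda`, `steps`, `post_lr`.
#' @return an object of class `"topo_adapt"`: list with `predictor` (the
#'   adapted clone), `adapted` (its probability map), `anchor` (the original
#'   prediction) and `trace` (objective per step: total, proximity, topo).
#' @export
postprocess_adapt <- function(pred, item, prior, cfg = train_config()) {
  stopifnot(inherits(pred, "unet"), inherits(prior, "topo_prior"))
  if (cfg$lambda < 0) stop("lambda must be >= 0")
  X <- if (inherits(item, "synthetic_sample")) item$image else as_scalar_field(item)
  anchor <- predict(pred, X)
  net <- clone_predictor(pred)
  opt <- adam_init(net$params)
  V <- length(anchor)
  trace <- vector("list", cfg$steps)
  best <- list(total = Inf, params = net$params)
  for (s in seq_len(cfg$steps)) {
    fw <- unet_forward(net, X, train = TRUE)
    S <- fw$S
    prox <- sum((anchor - S)^2) / V
    rep <- topo_loss_on_field(S, prior)
    total <- prox + cfg$lambda * rep$total
    if (total < best$total) best <- list(total = total, params = net$params)
    dS <- 2 * (S - anchor) / V + cfg$lambda * loss_gradient_field(rep)
    grads <- unet_backward(net, fw$cache, dS)
    st <- adam_step(net$params, grads, opt, cfg$post_lr)
    net$params <- st$params; opt <- st$state
    trace[[s]] <- data.frame(step = s, total = total,
                             proximity = prox, topo = rep$total)
  }
  # return the iterate that minimises the objective, not the last one
  net$params <- best$params
  structure(list(predictor = net, adapted = predict(net, X), anchor = anchor,
                 trace = do.call(rbind, trace), prior = prior, cfg = cfg),
            class = "topo_adapt")
}

#' @export
print.topo_adapt <- function(x, ...) {
  n <- nrow(x$trace)
  cat(sprintf(
    "Post-processing adaptation: %d step(s)\n  objective %.6f -> %.6f (topological term %.4f -> %.4f)\n",
    n, x$trace$total[1], x$trace$total[n], x$trace$topo[1], x$trace$topo[n]))
  invisible(x)
}
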