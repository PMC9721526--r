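#' Build a compact U-net predictor
#'
#' An encoder-decoder convolutional network with skip concatenations,
#' mapping an image/volume to a probability map of the same shape with
#' values in (0, 1) (terminal sigmoid).  Each encoder level applies two 3x3
#' (3x3x3 in 3D) convolutions with ReLU and halves the resolution by 2x max
#' pooling; channels double per level from `base_channels`.  Each decoder
#' level upsamples (nearest neighbour), concatenates the matching encoder
#' features, and applies two convolutions.  A 1x1 convolution plus sigmoid
#' produces the output.
#'
#' The forward and backward passes are implemented in base R on top of
#' BLAS-backed matrix products (im2col convolutions), so predictions and
#' gradients are exactly reproducible given the initialisation seed.
#'
#' @param spatial_dims 2 or 3.
#' @param depth number of pooling levels (>= 1); input spatial sizes must be
#'   divisible by `2^depth`.
#' @param base_channels channels at the first level.
#' @param seed integer seed for the (He-normal) weight initialisation.
#' @return an object of class `"unet"`.
#' @examples
#' net <- build_unet(2, depth = 2, base_channels = 4, seed = 1)
#' S <- predict(net, matrix(runif(32 * 32), 32, 32))
#' @export
build_unet <- function(spatial_dims = 2L, depth = 2L, base_channels = 8L,
                       seed = 1L) {
  if (!spatial_dims %in% c(2L, 3L)) stop("spatial_dims must be 2 or 3")
  if (depth < 1L) stop("depth must be >= 1")
  d <- as.integer(spatial_dims); depth <- as.integer(depth)
  base <- as.integer(base_channels)
  k <- 3L
  chans <- base * 2L^(0:(depth))     # level channels; last = bottleneck
  params <- list()
  init <- function(cin, cout, kk) {
    fan_in <- kk^d * cin
    list(W = matrix(stats::rnorm(cout * fan_in, sd = sqrt(2 / fan_in)),
                    cout, fan_in),
         b = numeric(cout))
  }
  with_seed(seed, {
    cin <- 1L
    for (i in seq_len(depth)) {
      params[[paste0("enc", i, "a")]] <- init(cin, chans[i], k)
      params[[paste0("enc", i, "b")]] <- init(chans[i], chans[i], k)
      cin <- chans[i]
    }
    params[["bota"]] <- init(chans[depth], chans[depth + 1L], k)
    params[["botb"]] <- init(chans[depth + 1L], chans[depth + 1L], k)
    for (i in rev(seq_len(depth))) {
      below <- if (i == depth) chans[depth + 1L] else chans[i + 1L]
      params[[paste0("dec", i, "a")]] <- init(chans[i] + below, chans[i], k)
      params[[paste0("dec", i, "b")]] <- init(chans[i], chans[i], k)
    }
    params[["out"]] <- init(chans[1], 1L, 1L)
  })
  structure(list(params = params, d = d, depth = depth, base = base, k = k),
            class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), numeric(1)))
  cat(sprintf("U-net: %dD, depth %d, base %d channels, %d parameters\n",
              x$d, x$depth, x$base, np))
  invisible(x)
}

#' Predict a probability map
#'
#' @param object a `"unet"`.
#' @param newdata input scalar field (2D or 3D matching the network).
#' @param ... unused.
#' @return a scalar field of the same shape with values in (0, 1).
#' @export
predict.unet <- function(object, newdata, ...) {
  unet_forward(object, as_scalar_field(newdata))$S
}

#' Deep-copy a predictor
#'
#' Returns an independent copy whose later mutation leaves the original's
#' predictions unchanged.  (Networks are plain R lists, so this is a
#' value-semantics copy.)
#'
#' @param p a `"unet"`.
#' @return a new `"unet"`.
#' @export
clone_predictor <- function(p) {
  stopifnot(inherits(p, "unet"))
  unserialize(serialize(p, NULL))
}

# ---- layer primitives (channels-last arrays) ---------------------------

pad_spatial <- function(x, p) {
  dm <- dim(x); d <- length(dm) - 1L
  out <- array(0, c(dm[seq_len(d)] + 2L * p, dm[d + 1L]))
  if (d == 2L) out[p + seq_len(dm[1]), p + seq_len(dm[2]), ] <- x
  else out[p + seq_len(dm[1]), p + seq_len(dm[2]), p + seq_len(dm[3]), ] <- x
  out
}

crop_spatial <- function(x, p, sp) {
  if (length(sp) == 2L) x[p + seq_len(sp[1]), p + seq_len(sp[2]), , drop = FALSE]
  else x[p + seq_len(sp[1]), p + seq_len(sp[2]), p + seq_len(sp[3]), , drop = FALSE]
}

conv_fwd <- function(x, par, k) {
  dm <- dim(x); d <- length(dm) - 1L
  sp <- dm[seq_len(d)]; cin <- dm[d + 1L]
  p <- (k - 1L) %/% 2L
  xp <- if (p > 0L) pad_spatial(x, p) else x
  offs <- as.matrix(expand.grid(rep(list(0:(k - 1L)), d)))
  n <- prod(sp)
  blocks <- vector("list", nrow(offs))
  for (t in seq_len(nrow(offs))) {
    sl <- if (d == 2L) xp[offs[t, 1] + seq_len(sp[1]),
                          offs[t, 2] + seq_len(sp[2]), , drop = FALSE]
          else xp[offs[t, 1] + seq_len(sp[1]), offs[t, 2] + seq_len(sp[2]),
                  offs[t, 3] + seq_len(sp[3]), , drop = FALSE]
    dim(sl) <- c(n, cin)
    blocks[[t]] <- sl
  }
  patches <- t(do.call(cbind, blocks))        # (k^d cin, n)
  out <- par$W %*% patches + par$b            # b recycles down columns
  y <- array(t(out), c(sp, nrow(par$W)))
  list(y = y, cache = list(patches = patches, sp = sp, cin = cin, k = k,
                           offs = offs))
}

conv_bwd <- function(dy, cache, par) {
  sp <- cache$sp; d <- length(sp); cin <- cache$cin
  n <- prod(sp); cout <- nrow(par$W)
  dmat <- t(matrix(dy, n, cout))              # (cout, n)
  dW <- dmat %*% t(cache$patches)
  db <- rowSums(dmat)
  dp <- crossprod(par$W, dmat)                # (k^d cin, n)
  p <- (cache$k - 1L) %/% 2L
  padsp <- sp + 2L * p
  dxp <- array(0, c(padsp, cin))
  for (t in seq_len(nrow(cache$offs))) {
    blk <- array(t(dp[(t - 1L) * cin + seq_len(cin), , drop = FALSE]),
                 c(sp, cin))
    if (d == 2L) {
      i1 <- cache$offs[t, 1] + seq_len(sp[1]); i2 <- cache$offs[t, 2] + seq_len(sp[2])
      dxp[i1, i2, ] <- dxp[i1, i2, , drop = FALSE] + blk
    } else {
      i1 <- cache$offs[t, 1] + seq_len(sp[1]); i2 <- cache$offs[t, 2] + seq_len(sp[2])
      i3 <- cache$offs[t, 3] + seq_len(sp[3])
      dxp[i1, i2, i3, ] <- dxp[i1, i2, i3, , drop = FALSE] + blk
    }
  }
  dx <- if (p > 0L) crop_spatial(dxp, p, sp) else dxp
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

pool_fwd <- function(x) {
  dm <- dim(x); d <- length(dm) - 1L
  sp <- dm[seq_len(d)]
  offs <- as.matrix(expand.grid(rep(list(0:1), d)))
  best <- NULL; arg <- NULL
  for (t in seq_len(nrow(offs))) {
    cand <- if (d == 2L) x[seq(1L, sp[1], 2L) + offs[t, 1],
                           seq(1L, sp[2], 2L) + offs[t, 2], , drop = FALSE]
            else x[seq(1L, sp[1], 2L) + offs[t, 1],
                   seq(1L, sp[2], 2L) + offs[t, 2],
                   seq(1L, sp[3], 2L) + offs[t, 3], , drop = FALSE]
    if (t == 1L) { best <- cand; arg <- array(1L, dim(cand)) }
    else { upd <- cand > best; best[upd] <- cand[upd]; arg[upd] <- t }
  }
  list(y = best, cache = list(arg = arg, sp = sp, offs = offs))
}

pool_bwd <- function(dy, cache) {
  sp <- cache$sp; d <- length(sp)
  dx <- array(0, c(sp, dim(dy)[d + 1L]))
  for (t in seq_len(nrow(cache$offs))) {
    mask <- cache$arg == t
    contrib <- dy * mask
    if (d == 2L) {
      i1 <- seq(1L, sp[1], 2L) + cache$offs[t, 1]
      i2 <- seq(1L, sp[2], 2L) + cache$offs[t, 2]
      dx[i1, i2, ] <- dx[i1, i2, , drop = FALSE] + contrib
    } else {
      i1 <- seq(1L, sp[1], 2L) + cache$offs[t, 1]
      i2 <- seq(1L, sp[2], 2L) + cache$offs[t, 2]
      i3 <- seq(1L, sp[3], 2L) + cache$offs[t, 3]
      dx[i1, i2, i3, ] <- dx[i1, i2, i3, , drop = FALSE] + contrib
    }
  }
  dx
}

upsample_fwd <- function(x) {
  dm <- dim(x); d <- length(dm) - 1L
  if (d == 2L) x[rep(seq_len(dm[1]), each = 2L),
                 rep(seq_len(dm[2]), each = 2L), , drop = FALSE]
  else x[rep(seq_len(dm[1]), each = 2L), rep(seq_len(dm[2]), each = 2L),
         rep(seq_len(dm[3]), each = 2L), , drop = FALSE]
}

upsample_bwd <- function(dy) {
  dm <- dim(dy); d <- length(dm) - 1L
  sp <- dm[seq_len(d)] %/% 2L
  dx <- array(0, c(sp, dm[d + 1L]))
  offs <- as.matrix(expand.grid(rep(list(0:1), d)))
  for (t in seq_len(nrow(offs))) {
    dx <- dx + (if (d == 2L) dy[seq(1L, dm[1], 2L) + offs[t, 1],
                                seq(1L, dm[2], 2L) + offs[t, 2], , drop = FALSE]
                else dy[seq(1L, dm[1], 2L) + offs[t, 1],
                        seq(1L, dm[2], 2L) + offs[t, 2],
                        seq(1L, dm[3], 2L) + offs[t, 3], , drop = FALSE])
  }
  dx
}

concat_ch <- function(a, b) {
  dm <- dim(a); d <- length(dm) - 1L
  out <- array(0, c(dm[seq_len(d)], dm[d + 1L] + dim(b)[d + 1L]))
  if (d == 2L) { out[, , seq_len(dm[3])] <- a; out[, , dm[3] + seq_len(dim(b)[3])] <- b }
  else { out[, , , seq_len(dm[4])] <- a; out[, , , dm[4] + seq_len(dim(b)[4])] <- b }
  out
}

split_ch <- function(x, c1) {
  dm <- dim(x); d <- length(dm) - 1L
  if (d == 2L) list(x[, , seq_len(c1), drop = FALSE],
                    x[, , c1 + seq_len(dm[3] - c1), drop = FALSE])
  else list(x[, , , seq_len(c1), drop = FALSE],
            x[, , , c1 + seq_len(dm[4] - c1), drop = FALSE])
}

# ---- whole-network forward / backward ----------------------------------

unet_forward <- function(net, x, train = FALSE) {
  sp <- dim(x)
  if (length(sp) != net$d)
    stop("input is ", length(sp), "D but network expects ", net$d, "D")
  if (any(sp %% 2L^net$depth != 0L))
    stop("input spatial sizes (", paste(sp, collapse = "x"),
         ") must be divisible by 2^depth = ", 2L^net$depth,
         "; pad to ", paste(ceiling(sp / 2L^net$depth) * 2L^net$depth,
                            collapse = "x"))
  cc <- list(); skips <- list()
  cur <- array(x, c(sp, 1L))
  cr <- function(name, cur) {
    cf <- conv_fwd(cur, net$params[[name]], if (name == "out") 1L else net$k)
    rf <- relu_fwd(cf$y)
    cc[[name]] <<- list(conv = cf$cache, mask = rf$mask)
    rf$y
  }
  for (i in seq_len(net$depth)) {
    cur <- cr(paste0("enc", i, "a"), cur)
    cur <- cr(paste0("enc", i, "b"), cur)
    skips[[i]] <- cur
    pf <- pool_fwd(cur)
    cc[[paste0("pool", i)]] <- pf$cache
    cur <- pf$y
  }
  cur <- cr("bota", cur)
  cur <- cr("botb", cur)
  for (i in rev(seq_len(net$depth))) {
    cur <- upsample_fwd(cur)
    cur <- concat_ch(skips[[i]], cur)
    cur <- cr(paste0("dec", i, "a"), cur)
    cur <- cr(paste0("dec", i, "b"), cur)
  }
  cf <- conv_fwd(cur, net$params[["out"]], 1L)
  S <- 1 / (1 + exp(-cf$y))
  cc[["out"]] <- list(conv = cf$cache, S = S)
  Sfield <- array(S, sp)
  if (train) list(S = Sfield, cache = cc) else list(S = Sfield)
}

# dS: gradient of the loss w.r.t. the output probability map (same shape).
# Returns gradients for every parameter.
unet_backward <- function(net, cache, dS) {
  grads <- list()
  cbk <- function(name, dy) {
    ca <- cache[[name]]
    dy <- dy * ca$mask
    bb <- conv_bwd(dy, ca$conv, net$params[[name]])
    grads[[name]] <<- list(W = bb$dW, b = bb$db)
    bb$dx
  }
  S <- cache[["out"]]$S
  dz <- array(dS, dim(S)) * S * (1 - S)       # through sigmoid
  bb <- conv_bwd(dz, cache[["out"]]$conv, net$params[["out"]])
  grads[["out"]] <- list(W = bb$dW, b = bb$db)
  dcur <- bb$dx
  chans <- net$base * 2L^(0:net$depth)
  for (i in seq_len(net$depth)) {            # decoder, shallow to deep
    dcur <- cbk(paste0("dec", i, "b"), dcur)
    dcur <- cbk(paste0("dec", i, "a"), dcur)
    parts <- split_ch(dcur, chans[i])
    grads[[paste0(".skip", i)]] <- parts[[1]]
    dcur <- upsample_bwd(parts[[2]])
  }
  dcur <- cbk("botb", dcur)
  dcur <- cbk("bota", dcur)
  for (i in rev(seq_len(net$depth))) {       # encoder, deep to shallow
    dcur <- pool_bwd(dcur, cache[[paste0("pool", i)]])
    dcur <- dcur + grads[[paste0(".skip", i)]]
    grads[[paste0(".skip", i)]] <- NULL
    dcur <- cbk(paste0("enc", i, "b"), dcur)
    dcur <- cbk(paste0("enc", i, "a"), dcur)
  }
  grads
}

# ---- Adam --------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) list(W = p$W * 0, b = p$b * 0)),
       v = lapply(params, function(p) list(W = p$W * 0, b = p$b * 0)),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    for (fld in c("W", "b")) {
      state$m[[nm]][[fld]] <- beta1 * state$m[[nm]][[fld]] + (1 - beta1) * g[[fld]]
      state$v[[nm]][[fld]] <- beta2 * state$v[[nm]][[fld]] + (1 - beta2) * g[[fld]]^2
      mhat <- state$m[[nm]][[fld]] / bc1
      vhat <- state$v[[nm]][[fld]] / bc2
      params[[nm]][[fld]] <- params[[nm]][[fld]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

#' Save / load network weights
#'
#' Weights are serialised as plain JSON (shapes plus flat numeric vectors),
#' so checkpoints are text files and survive any transport.
#'
#' @param net a `"unet"`.
#' @param path file path.
#' @return `path` (save) or the restored `"unet"` (load).
#' @export
save_weights <- function(net, path) {
  stopifnot(inherits(net, "unet"))
  flat <- lapply(net$params, function(p)
    list(W = as.numeric(p$W), dimW = dim(p$W), b = p$b))
  jsonlite::write_json(list(d = net$d, depth = net$depth, base = net$base,
                            k = net$k, params = flat),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(j$params, function(p)
    list(W = matrix(p$W, p$dimW[1], p$dimW[2]), b = as.numeric(p$b)))
  structure(list(params = params, d = as.integer(j$d),
                 depth = as.integer(j$depth), base = as.integer(j$base),
                 k = as.integer(j$k)),
            class = "unet")
}
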