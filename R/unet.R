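# A compact 3-D U-Net: encoder of `n_blocks` double-convolution blocks
# (3x3x3 conv, batch norm, ReLU) with 2x2x2 max-pooling between them, the
# deepest block acting as the bottleneck; a decoder mirroring the encoder
# with 2x2x2/stride-2 transposed convolutions and concatenation skip
# connections; and a 1x1x1 head with a hyperbolic-tangent activation, so
# voxel scores live in (-1, 1). Forward and backward passes are explicit;
# the convolution arithmetic lives in the compiled kernels. No deep
# learning framework ships with this R stack, so the network, its gradients
# and the ADAM optimiser are implemented here from first principles.

#' U-Net architecture hyperparameters
#'
#' Defaults follow the published architecture: three encoder blocks of two
#' convolution layers each, 64 filters in the first block doubling per
#' block (64, 128, 256), batch normalisation and ReLU after every 3x3x3
#' convolution, 2x2x2 max pooling, transposed-convolution upsampling with
#' decoder filters halving per block (128, 64), and a tanh-activated 1x1x1
#' output head.
#'
#' @param in_channels,out_channels input/output channel counts.
#' @param base_filters filters in the first encoder block.
#' @param n_encoder_blocks encoder depth; the last block is the bottleneck,
#'   so there are `n_encoder_blocks - 1` poolings and the input patch edge
#'   must be divisible by `2^(n_encoder_blocks - 1)`.
#' @param layers_per_block convolution layers per block.
#' @param patch_size expected input patch edge (voxels).
#' @param batchnorm apply batch normalisation after each convolution.
#' @param skip_connections concatenate encoder features into the decoder.
#' @return Object of class `unet_config`.
#' @export
unet_config <- function(in_channels = 1L, out_channels = 1L,
                        base_filters = 64L, n_encoder_blocks = 3L,
                        layers_per_block = 2L, patch_size = 64L,
                        batchnorm = TRUE, skip_connections = TRUE) {
  cfg <- list(in_channels = as.integer(in_channels),
              out_channels = as.integer(out_channels),
              base_filters = as.integer(base_filters),
              n_encoder_blocks = as.integer(n_encoder_blocks),
              layers_per_block = as.integer(layers_per_block),
              patch_size = as.integer(patch_size),
              batchnorm = isTRUE(batchnorm),
              skip_connections = isTRUE(skip_connections))
  if (cfg$n_encoder_blocks < 2L) stopf("need at least 2 encoder blocks")
  if (cfg$out_channels != 1L) stopf("only single-structure output supported")
  div <- 2^(cfg$n_encoder_blocks - 1L)
  if (cfg$patch_size %% div != 0L) {
    stopf("patch size %d not divisible by 2^(blocks-1) = %d",
          cfg$patch_size, div)
  }
  class(cfg) <- "unet_config"
  cfg
}

#' Encoder filter counts of a configuration
#' @param config [unet_config()].
#' @return integer vector, e.g. `c(64, 128, 256)` at defaults.
#' @export
encoder_filters <- function(config) {
  as.integer(config$base_filters * 2^(seq_len(config$n_encoder_blocks) - 1))
}

# ---- parameter initialisation -------------------------------------------

kaiming <- function(fan_in, n) rnorm(n, 0, sqrt(2 / fan_in))

#' Build an untrained U-Net
#'
#' Kaiming-style seeded initialisation: two builds with the same seed yield
#' identical parameters (and therefore identical outputs).
#'
#' @param config [unet_config()].
#' @param seed integer seed for the initialisation.
#' @return Object of class `unet_model` with fields `config`, `params`,
#'   `running` (batch-norm running statistics) and `history`.
#' @export
build_unet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  with_seed(seed, {
    params <- list()
    running <- list()
    add_conv <- function(name, cin, cout) {
      params[[paste0(name, "_W")]] <<- matrix(kaiming(cin * 27, cin * 27 *
                                                        cout), cin * 27, cout)
      params[[paste0(name, "_b")]] <<- numeric(cout)
      if (config$batchnorm) {
        params[[paste0(name, "_g")]] <<- rep(1, cout)
        params[[paste0(name, "_be")]] <<- numeric(cout)
        running[[paste0(name, "_rm")]] <<- numeric(cout)
        running[[paste0(name, "_rv")]] <<- rep(1, cout)
      }
    }
    filt <- encoder_filters(config)
    cin <- config$in_channels
    for (b in seq_len(config$n_encoder_blocks)) {
      for (l in seq_len(config$layers_per_block)) {
        add_conv(sprintf("enc%d_conv%d", b, l), cin, filt[b])
        cin <- filt[b]
      }
    }
    for (d in seq_len(config$n_encoder_blocks - 1L)) {
      cout <- cin %/% 2L
      params[[sprintf("up%d_W", d)]] <- matrix(kaiming(cin, cin * cout * 8),
                                               cin, cout * 8)
      params[[sprintf("up%d_b", d)]] <- numeric(cout)
      skip <- filt[config$n_encoder_blocks - d]
      dcin <- cout + if (config$skip_connections) skip else 0L
      for (l in seq_len(config$layers_per_block)) {
        add_conv(sprintf("dec%d_conv%d", d, l), dcin, cout)
        dcin <- cout
      }
      cin <- cout
    }
    params$head_W <- matrix(rnorm(cin, 0, sqrt(1 / cin)), cin, 1)
    params$head_b <- 0
    model <- list(config = config, params = params, running = running,
                  history = NULL, best_epoch = NA_integer_, seed = seed)
    class(model) <- "unet_model"
    model
  })
}

#' @export
print.unet_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<unet_model> encoder filters (%s), %s skips, %d parameters\n",
              paste(encoder_filters(x$config), collapse = ", "),
              if (x$config$skip_connections) "concat" else "no",
              as.integer(np)))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs, best validation loss %.4f (epoch %d)\n",
                nrow(x$history), min(x$history$val_loss), x$best_epoch))
  }
  invisible(x)
}

# ---- layer primitives (R side keeps batch norm / relu / tanh / concat) ---

bn_channel_stats <- function(m, C, N) {
  # m: (V x C*N) matrix with channel fastest over columns
  s <- colSums(m)
  rowSums(matrix(s, C, N)) / (nrow(m) * N)
}

bn_fwd <- function(x, dims, g, be, rm, rv, training, momentum = 0.1,
                   eps = 1e-5) {
  V <- prod(dims[1:3])
  C <- dims[4]
  N <- dims[5]
  m <- matrix(x, V, C * N)
  if (training) {
    mu <- bn_channel_stats(m, C, N)
    va <- bn_channel_stats(m * m, C, N) - mu^2
    rm_new <- (1 - momentum) * rm + momentum * mu
    rv_new <- (1 - momentum) * rv + momentum * va * (V * N) / (V * N - 1)
  } else {
    mu <- rm
    va <- rv
    rm_new <- rm
    rv_new <- rv
  }
  isd <- 1 / sqrt(va + eps)
  mu_c <- rep(mu, N)
  isd_c <- rep(isd, N)
  xhat <- (m - matrix(mu_c, V, C * N, byrow = TRUE)) *
    matrix(isd_c, V, C * N, byrow = TRUE)
  y <- xhat * matrix(rep(g, N), V, C * N, byrow = TRUE) +
    matrix(rep(be, N), V, C * N, byrow = TRUE)
  list(y = as.numeric(y), cache = list(xhat = xhat, isd = isd, g = g,
                                       dims = dims),
       rm = rm_new, rv = rv_new)
}

bn_bwd <- function(cache, dy) {
  dims <- cache$dims
  V <- prod(dims[1:3])
  C <- dims[4]
  N <- dims[5]
  m <- matrix(dy, V, C * N)
  xhat <- cache$xhat
  dg <- bn_channel_stats(m * xhat, C, N) * (V * N)
  dbe <- bn_channel_stats(m, C, N) * (V * N)
  mean_dy <- dbe / (V * N)
  mean_dyx <- dg / (V * N)
  g_isd <- rep(cache$g * cache$isd, N)
  dx <- (m - matrix(rep(mean_dy, N), V, C * N, byrow = TRUE) -
           xhat * matrix(rep(mean_dyx, N), V, C * N, byrow = TRUE)) *
    matrix(g_isd, V, C * N, byrow = TRUE)
  list(dx = as.numeric(dx), dg = dg, dbe = dbe)
}

cat_channels <- function(a, adims, b, bdims) {
  stopifnot(all(adims[c(1:3, 5)] == bdims[c(1:3, 5)]))
  V <- prod(adims[1:3])
  N <- adims[5]
  Ca <- adims[4]
  Cb <- bdims[4]
  am <- matrix(a, V * Ca, N)
  bm <- matrix(b, V * Cb, N)
  out <- matrix(0, V * (Ca + Cb), N)
  out[seq_len(V * Ca), ] <- am
  out[V * Ca + seq_len(V * Cb), ] <- bm
  list(x = as.numeric(out), dims = c(adims[1:3], Ca + Cb, N))
}

split_channels <- function(d, dims, Ca) {
  V <- prod(dims[1:3])
  N <- dims[5]
  C <- dims[4]
  m <- matrix(d, V * C, N)
  list(a = as.numeric(m[seq_len(V * Ca), , drop = FALSE]),
       b = as.numeric(m[V * Ca + seq_len(V * (C - Ca)), , drop = FALSE]),
       adims = c(dims[1:3], Ca, N), bdims = c(dims[1:3], C - Ca, N))
}

# conv + optional BN + ReLU unit; the fused batch-norm/ReLU kernels keep
# only the pre-normalisation activations plus per-channel statistics.
unit_fwd <- function(x, dims, params, running, name, training) {
  W <- params[[paste0(name, "_W")]]
  cout <- ncol(W)
  y <- conv3_fwd(x, dims, W, params[[paste0(name, "_b")]])
  ydims <- c(dims[1:3], cout, dims[5])
  cache <- list(x = x, xdims = dims, name = name)
  if (!is.null(params[[paste0(name, "_g")]])) {
    bn <- bnrelu_fwd(y, ydims, params[[paste0(name, "_g")]],
                     params[[paste0(name, "_be")]],
                     running[[paste0(name, "_rm")]],
                     running[[paste0(name, "_rv")]], training, 0.1, 1e-5)
    cache$conv_out <- y
    cache$mu <- bn$mu
    cache$isd <- bn$isd
    cache$rm <- bn$rm
    cache$rv <- bn$rv
    y <- bn$y
  } else {
    mask <- y > 0
    y <- y * mask
    cache$relu <- mask
  }
  list(y = y, ydims = ydims, cache = cache)
}

unit_bwd <- function(cache, dy, params, grads, skip_dx = FALSE) {
  name <- cache$name
  ydims <- c(cache$xdims[1:3], ncol(params[[paste0(name, "_W")]]),
             cache$xdims[5])
  if (!is.null(cache$conv_out)) {
    bn <- bnrelu_bwd(cache$conv_out, ydims, dy,
                     params[[paste0(name, "_g")]],
                     params[[paste0(name, "_be")]], cache$mu, cache$isd)
    dy <- bn$dx
    grads[[paste0(name, "_g")]] <- (grads[[paste0(name, "_g")]] %||% 0) +
      bn$dg
    grads[[paste0(name, "_be")]] <- (grads[[paste0(name, "_be")]] %||% 0) +
      bn$dbe
  } else {
    dy <- dy * cache$relu
  }
  cv <- conv3_bwd(cache$x, cache$xdims, params[[paste0(name, "_W")]], dy)
  grads[[paste0(name, "_W")]] <- (grads[[paste0(name, "_W")]] %||% 0) + cv$dW
  grads[[paste0(name, "_b")]] <- (grads[[paste0(name, "_b")]] %||% 0) + cv$db
  list(dx = if (skip_dx) NULL else cv$dx, grads = grads)
}

# ---- full network forward / backward ------------------------------------
# The cache mirrors the architecture: per-encoder-block unit caches and pool
# caches, per-decoder-stage upconv/concat/unit caches, then the head. The
# backward pass walks the same structure in reverse, adding each skip
# gradient back where the skip was taken (after the block's units, before
# its pooling).


net_forward <- function(model, x, dims, training = FALSE) {
  cfg <- model$config
  p <- model$params
  r <- model$running
  B <- cfg$n_encoder_blocks
  L <- cfg$layers_per_block
  keep <- training
  enc_units <- vector("list", B)
  pools <- vector("list", B - 1L)
  skips <- vector("list", B - 1L)
  cur <- x
  curdims <- dims
  for (b in seq_len(B)) {
    units <- vector("list", L)
    for (l in seq_len(L)) {
      u <- unit_fwd(cur, curdims, p, r, sprintf("enc%d_conv%d", b, l),
                    training)
      cur <- u$y
      curdims <- u$ydims
      if (!is.null(u$cache$rm)) {
        r[[paste0(u$cache$name, "_rm")]] <- u$cache$rm
        r[[paste0(u$cache$name, "_rv")]] <- u$cache$rv
      }
      if (keep) units[[l]] <- u$cache
    }
    enc_units[[b]] <- units
    if (b < B) {
      skips[[b]] <- list(x = cur, dims = curdims)
      mp <- maxpool_fwd(cur, curdims)
      if (keep) pools[[b]] <- list(idx = mp$idx, xdims = curdims)
      cur <- mp$y
      curdims <- c(curdims[1:3] %/% 2L, curdims[4], curdims[5])
    }
  }
  dec_stages <- vector("list", B - 1L)
  for (d in seq_len(B - 1L)) {
    W <- p[[sprintf("up%d_W", d)]]
    cout <- ncol(W) %/% 8L
    upcache <- list(x = cur, xdims = curdims)
    cur <- upconv_fwd(cur, curdims, W, p[[sprintf("up%d_b", d)]])
    curdims <- c(curdims[1:3] * 2L, cout, curdims[5])
    concat_Ca <- NA_integer_
    catdims <- curdims
    if (cfg$skip_connections) {
      sk <- skips[[B - d]]
      cc <- cat_channels(cur, curdims, sk$x, sk$dims)
      concat_Ca <- curdims[4]
      cur <- cc$x
      curdims <- cc$dims
      catdims <- cc$dims
    }
    units <- vector("list", L)
    for (l in seq_len(L)) {
      u <- unit_fwd(cur, curdims, p, r, sprintf("dec%d_conv%d", d, l),
                    training)
      cur <- u$y
      curdims <- u$ydims
      if (!is.null(u$cache$rm)) {
        r[[paste0(u$cache$name, "_rm")]] <- u$cache$rm
        r[[paste0(u$cache$name, "_rv")]] <- u$cache$rv
      }
      if (keep) units[[l]] <- u$cache
    }
    if (keep) {
      dec_stages[[d]] <- list(up = upcache, Ca = concat_Ca,
                              dims_after_cat = catdims, units = units)
    }
  }
  # 1x1x1 head followed by tanh
  V <- prod(curdims[1:3])
  N <- curdims[5]
  C <- curdims[4]
  xm <- matrix(cur, V, C * N)
  s <- matrix(0, V, N)
  for (n in seq_len(N)) {
    s[, n] <- tanh(xm[, (n - 1) * C + seq_len(C), drop = FALSE] %*%
                     p$head_W + p$head_b)
  }
  cache <- if (keep) {
    list(enc_units = enc_units, pools = pools, dec_stages = dec_stages,
         head = list(x = cur, xdims = curdims, s = s))
  } else {
    NULL
  }
  list(scores = as.numeric(s), sdims = c(curdims[1:3], 1L, N),
       cache = cache, running = r)
}

net_backward <- function(model, cache, dscores) {
  cfg <- model$config
  p <- model$params
  B <- cfg$n_encoder_blocks
  L <- cfg$layers_per_block
  grads <- list()
  hc <- cache$head
  V <- prod(hc$xdims[1:3])
  C <- hc$xdims[4]
  N <- hc$xdims[5]
  ds <- matrix(dscores, V, N) * (1 - hc$s^2)
  xm <- matrix(hc$x, V, C * N)
  dW <- matrix(0, C, 1)
  dx <- matrix(0, V, C * N)
  for (n in seq_len(N)) {
    cols <- (n - 1) * C + seq_len(C)
    dW <- dW + crossprod(xm[, cols, drop = FALSE], ds[, n, drop = FALSE])
    dx[, cols] <- ds[, n] %*% t(p$head_W)
  }
  grads$head_W <- dW
  grads$head_b <- sum(ds)
  cur <- as.numeric(dx)
  skip_grads <- vector("list", B - 1L)
  for (d in rev(seq_len(B - 1L))) {
    st <- cache$dec_stages[[d]]
    for (l in rev(seq_len(L))) {
      ub <- unit_bwd(st$units[[l]], cur, p, grads)
      grads <- ub$grads
      cur <- ub$dx
    }
    if (cfg$skip_connections) {
      sp <- split_channels(cur, st$dims_after_cat, st$Ca)
      skip_grads[[B - d]] <- sp$b
      cur <- sp$a
    }
    uv <- upconv_bwd(st$up$x, st$up$xdims, p[[sprintf("up%d_W", d)]], cur)
    grads[[sprintf("up%d_W", d)]] <- uv$dW
    grads[[sprintf("up%d_b", d)]] <- uv$db
    cur <- uv$dx
  }
  for (b in rev(seq_len(B))) {
    if (b < B) {
      cur <- maxpool_bwd(cur, cache$pools[[b]]$idx, cache$pools[[b]]$xdims)
      if (cfg$skip_connections && !is.null(skip_grads[[b]])) {
        cur <- cur + skip_grads[[b]]
      }
    }
    for (l in rev(seq_len(L))) {
      ub <- unit_bwd(cache$enc_units[[b]][[l]], cur, p, grads,
                     skip_dx = (b == 1L && l == 1L))
      grads <- ub$grads
      cur <- ub$dx
    }
  }
  grads
}

#' Run one patch through the network
#'
#' Evaluation mode: batch normalisation uses running statistics, so repeated
#' calls on the same input are bit-identical. The tanh head keeps every
#' output strictly inside (-1, 1).
#'
#' @param model [build_unet()] result (possibly trained).
#' @param patch cubic numeric array whose edge is divisible by
#'   `2^(n_encoder_blocks - 1)`.
#' @return Array of voxel scores, same shape as `patch`.
#' @export
forward_patch <- function(model, patch) {
  stopifnot(inherits(model, "unet_model"))
  d <- dim(patch)
  if (length(d) != 3L || length(unique(d)) != 1L) {
    stopf("forward_patch expects a cubic 3-D patch")
  }
  div <- 2L^(model$config$n_encoder_blocks - 1L)
  if (d[1] %% div != 0L) {
    stopf("patch edge %d not divisible by %d", d[1], div)
  }
  fw <- net_forward(model, as.numeric(patch), c(d, 1L, 1L),
                    training = FALSE)
  array(fw$scores, d)
}

# ---- generalized Dice loss ----------------------------------------------

#' Generalized Dice loss
#'
#' Scores in (-1, 1) are mapped to foreground probabilities
#' `p = (score + 1)/2`; with two classes (foreground, background =
#' complement) and class weights `w_l = 1 / (sum(r_l) + eps)^2`, the loss is
#' `1 - 2 * sum_l w_l sum_n r_ln p_ln / sum_l w_l sum_n (r_ln + p_ln)`.
#' It is 0 when the probabilities equal the truth and 1 at the complement.
#'
#' @param scores numeric array/vector of voxel scores in \[-1, 1\] (a batch
#'   is pooled into a single sum over voxels).
#' @param truth binary array/vector of the same length.
#' @param eps stabiliser inside the weight denominator, guarding patches
#'   where a class is empty.
#' @return Scalar loss in \[0, 1\].
#' @export
generalized_dice_loss <- function(scores, truth, eps = 1e-6) {
  gdl_forward(scores, truth, eps)$loss
}

gdl_forward <- function(scores, truth, eps = 1e-6) {
  s <- as.numeric(scores)
  r <- as.numeric(truth)
  if (length(s) != length(r)) stopf("scores and truth lengths differ")
  if (any(r != 0 & r != 1)) stopf("truth must be binary")
  p <- (s + 1) / 2
  sum_rf <- sum(r)
  sum_rb <- length(r) - sum_rf
  wf <- 1 / (sum_rf + eps)^2
  wb <- 1 / (sum_rb + eps)^2
  num <- wf * sum(r * p) + wb * sum((1 - r) * (1 - p))
  den <- wf * (sum_rf + sum(p)) + wb * (sum_rb + length(r) - sum(p))
  loss <- 1 - 2 * num / den
  list(loss = loss, p = p, r = r, wf = wf, wb = wb, num = num, den = den)
}

# gradient of the loss with respect to the raw scores
gdl_backward <- function(fw) {
  dnum_dp <- fw$wf * fw$r - fw$wb * (1 - fw$r)
  dden_dp <- fw$wf - fw$wb
  dl_dp <- -2 * (dnum_dp * fw$den - fw$num * dden_dp) / fw$den^2
  dl_dp / 2  # p = (s + 1)/2
}

# ---- ADAM ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(params[[nm]])) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- serialization -------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A single-file checkpoint holding the architecture configuration,
#' parameters, running statistics and training history. Reloading restores
#' bit-identical inference behaviour.
#'
#' @param model `unet_model`.
#' @param path checkpoint path.
#' @return `save_model`: `path` invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stopf("checkpoint does not exist: %s", path)
  model <- readRDS(path)
  if (!inherits(model, "unet_model")) stopf("not a unet checkpoint: %s", path)
  model
}
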