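# Network architecture contracts, determinism, serialization, and the
# generalized Dice loss against direct formula evaluation.

test_that("encoder filter progression doubles per block", {
  expect_identical(encoder_filters(unet_config()), c(64L, 128L, 256L))
  expect_identical(encoder_filters(unet_config(base_filters = 8L)),
                   c(8L, 16L, 32L))
  expect_error(unet_config(patch_size = 33L), "divisible")
  expect_error(unet_config(patch_size = 50L), "divisible")
})

test_that("output shape equals input shape for 32 and 64 voxel edges", {
  cfg <- unet_config(base_filters = 4L, patch_size = 32L)
  m <- build_unet(cfg, seed = 3)
  for (edge in c(32L, 64L)) {
    x <- array(0, rep(edge, 3))
    out <- forward_patch(m, x)
    expect_identical(dim(out), rep(edge, 3L))
    expect_true(all(is.finite(out)))
    expect_true(all(out > -1 & out < 1))  # tanh range, strictly
  }
  expect_error(forward_patch(m, array(0, c(10, 10, 10))), "divisible")
  expect_error(forward_patch(m, array(0, c(8, 8, 4))), "cubic")
})

test_that("builds and forwards are deterministic and serializable", {
  cfg <- unet_config(base_filters = 4L, patch_size = 16L)
  set.seed(99)
  x <- array(rnorm(16^3), c(16, 16, 16))
  a <- build_unet(cfg, seed = 11)
  b <- build_unet(cfg, seed = 11)
  expect_identical(a$params, b$params)
  expect_identical(forward_patch(a, x), forward_patch(b, x))
  expect_identical(forward_patch(a, x), forward_patch(a, x))
  expect_false(identical(build_unet(cfg, seed = 12)$params, a$params))
  f <- tempfile(fileext = ".rds")
  save_model(a, f)
  expect_identical(forward_patch(load_model(f), x), forward_patch(a, x))
})

test_that("generalized Dice loss hits its limits and the worked fixture", {
  r <- array(0, c(4, 4, 4))
  r[1:2, 1:2, 1:2] <- 1
  expect_equal(generalized_dice_loss(2 * r - 1, r), 0, tolerance = 1e-9)
  expect_equal(generalized_dice_loss(2 * (1 - r) - 1, r), 1,
               tolerance = 1e-9)
  # worked fixture: p = 0.75 on the 8-voxel corner cube, 0.25 elsewhere
  p <- ifelse(r == 1, 0.75, 0.25)
  eps <- 1e-6
  wf <- 1 / (sum(r) + eps)^2
  wb <- 1 / (sum(1 - r) + eps)^2
  direct <- 1 - 2 * (wf * sum(r * p) + wb * sum((1 - r) * (1 - p))) /
    (wf * (sum(r) + sum(p)) + wb * (sum(1 - r) + sum(1 - p)))
  expect_equal(generalized_dice_loss(2 * p - 1, r), direct,
               tolerance = 1e-9)
  expect_error(generalized_dice_loss(2 * p - 1, p), "binary")
  expect_error(generalized_dice_loss(c(0, 0), c(0, 1, 1)), "length")
})

test_that("loss decreases monotonically from complement toward truth", {
  set.seed(5)
  r <- array(rbinom(6^3, 1, 0.3), c(6, 6, 6))
  ts <- seq(0, 1, by = 0.1)
  losses <- sapply(ts, function(t) {
    p <- (1 - t) * (1 - r) + t * r
    generalized_dice_loss(2 * p - 1, r)
  })
  expect_true(all(diff(losses) < 0))
  expect_true(all(losses >= 0 & losses <= 1))
})

test_that("analytic gradients match finite differences through the net", {
  set.seed(7)
  cfg <- unet_config(base_filters = 2L, patch_size = 8L)
  m <- build_unet(cfg, seed = 1)
  dims <- c(8L, 8L, 8L, 1L, 2L)
  xb <- as.numeric(array(rnorm(prod(dims)), dims))
  yb <- as.numeric(array(rbinom(prod(dims), 1, 0.2), dims))
  loss_at <- function(params) {
    m$params <- params
    fw <- plexseg:::net_forward(m, xb, dims, training = TRUE)
    plexseg:::gdl_forward(fw$scores, yb)$loss
  }
  fw <- plexseg:::net_forward(m, xb, dims, training = TRUE)
  gf <- plexseg:::gdl_forward(fw$scores, yb)
  gr <- plexseg:::net_backward(m, fw$cache, plexseg:::gdl_backward(gf))
  u <- lapply(m$params, function(p) {
    if (is.matrix(p)) matrix(rnorm(length(p)), nrow(p)) else rnorm(length(p))
  })
  h <- 3e-4
  up <- m$params
  dn <- m$params
  for (nm in names(up)) {
    up[[nm]] <- up[[nm]] + h * u[[nm]]
    dn[[nm]] <- dn[[nm]] - h * u[[nm]]
  }
  fd <- (loss_at(up) - loss_at(dn)) / (2 * h)
  analytic <- sum(mapply(function(g, uu) sum(g * uu), gr[names(u)], u))
  # single-precision convolution arithmetic bounds the agreement
  expect_lt(abs(fd - analytic) / abs(fd), 0.05)
})

test_that("tiny network overfits one separable batch to Dice 1", {
  cfg <- unet_config(base_filters = 4L, patch_size = 16L)
  m <- build_unet(cfg, seed = 2)
  opt <- plexseg:::adam_init(m$params)
  set.seed(3)
  xb <- array(rnorm(16^3 * 2, 0, 0.2), c(16, 16, 16, 1, 2))
  yb <- array(0, c(16, 16, 16, 1, 2))
  yb[6:11, 6:11, 6:11, 1, ] <- 1
  xb[yb == 1] <- xb[yb == 1] + 1
  dims <- as.integer(c(16, 16, 16, 1, 2))
  losses <- numeric(0)
  for (it in 1:50) {
    fw <- plexseg:::net_forward(m, as.numeric(xb), dims, training = TRUE)
    m$running <- fw$running
    gf <- plexseg:::gdl_forward(fw$scores, as.numeric(yb))
    gr <- plexseg:::net_backward(m, fw$cache, plexseg:::gdl_backward(gf))
    st <- plexseg:::adam_step(m$params, gr, opt, 3e-3)
    m$params <- st$params
    opt <- st$state
    losses <- c(losses, gf$loss)
  }
  expect_lt(losses[50], losses[1])
  fw <- plexseg:::net_forward(m, as.numeric(xb), dims, training = FALSE)
  pred <- fw$scores > 0
  expect_gt(2 * sum(pred & yb == 1) / (sum(pred) + sum(yb)), 0.95)
})
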