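# Independent brute-force oracles, deliberately naive: triple loops and
# exhaustive enumeration, kept separate from the package implementations.

# all-pairs directed surface distances, surfaces by exhaustive neighbour
# inspection
oracle_surface <- function(mask) {
  m <- mask$data
  d <- dim(m)
  pts <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (m[i, j, k] == 0) next
    on_surface <- FALSE
    for (off in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                     c(0, 0, -1), c(0, 0, 1))) {
      ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 ||
          kk > d[3] || m[ii, jj, kk] == 0) {
        on_surface <- TRUE
        break
      }
    }
    if (on_surface) pts <- rbind(pts, c(i, j, k))
  }
  # 0-based indices through the affine
  t(mask$affine %*% t(cbind(pts - 1, 1)))[, 1:3, drop = FALSE]
}

oracle_hd95 <- function(a, b, q = 0.95) {
  sa <- oracle_surface(a)
  sb <- oracle_surface(b)
  directed <- function(from, to) {
    dmin <- apply(from, 1, function(p) {
      sqrt(min(colSums((t(to) - p)^2)))
    })
    unname(stats::quantile(dmin, q, type = 7))
  }
  max(directed(sa, sb), directed(sb, sa))
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# explicit two-way ANOVA mean squares
oracle_icc21 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  gm <- mean(x)
  msr <- k * sum((rowMeans(x) - gm)^2) / (n - 1)
  msc <- n * sum((colMeans(x) - gm)^2) / (k - 1)
  mse <- (sum((x - gm)^2) - k * sum((rowMeans(x) - gm)^2) -
            n * sum((colMeans(x) - gm)^2)) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# exact Wilcoxon two-sided p by enumerating all 2^n sign assignments
oracle_wilcoxon_p <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[1:n]
    ws[m + 1] <- sum(r[signs == 1])
  }
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Benjamini-Hochberg step-up by the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

oracle_dice <- function(a, b) {
  ia <- sum(a$data); ib <- sum(b$data)
  if (ia + ib == 0) return(1)
  2 * sum(a$data == 1 & b$data == 1) / (ia + ib)
}
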