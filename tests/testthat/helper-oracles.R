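# Independent oracles, coded from the definitions and kept free of the
# package's internals so agreement is a real cross-check.

# random K x 3 configuration
random_config <- function(k, sd = 1) matrix(rnorm(3 * k, sd = sd), k, 3)

random_rotation_oracle <- function() {
  repeat {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(q) > 0) return(q)
  }
}

# naive fixed-point GPA: centers/scales, then repeatedly rotates every
# configuration onto the running mean shape using an inline SVD solution,
# recomputing and renormalizing the mean each pass
oracle_gpa_consensus <- function(mats, iters = 200) {
  mats <- lapply(mats, function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  })
  cons <- mats[[1]]
  for (it in seq_len(iters)) {
    mats <- lapply(mats, function(m) {
      s <- svd(t(m) %*% cons)
      r <- s$u %*% diag(c(1, 1, sign(det(s$u %*% t(s$v))))) %*% t(s$v)
      m %*% r
    })
    cons <- Reduce(`+`, mats) / length(mats)
    cons <- cons / sqrt(sum(sweep(cons, 2, colMeans(cons))^2))
  }
  cons
}

# pooled within-group covariance (divisor n - G) and size-weighted
# between-group covariance (divisor G - 1), straight from the formulas
oracle_wb <- function(x, g) {
  g <- as.character(g)
  levs <- unique(g)
  n <- nrow(x); G <- length(levs); p <- ncol(x)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  grand <- colMeans(x)
  for (lv in levs) {
    xg <- x[g == lv, , drop = FALSE]
    mg <- colMeans(xg)
    W <- W + crossprod(sweep(xg, 2, mg))
    B <- B + nrow(xg) * tcrossprod(mg - grand)
  }
  list(W = W / (n - G), B = B / (G - 1))
}

# CVA eigenvalues by direct (nonsymmetric) eigendecomposition of W^-1 B
oracle_cva_eigenvalues <- function(x, g) {
  wb <- oracle_wb(x, g)
  ev <- eigen(solve(wb$W) %*% wb$B, only.values = TRUE)$values
  sort(Re(ev), decreasing = TRUE)
}

# full-Mahalanobis nearest-group classification in the raw variable space
oracle_mahalanobis_classify <- function(x, g, newdata) {
  wb <- oracle_wb(x, g)
  Winv <- solve(wb$W)
  levs <- unique(as.character(g))
  means <- sapply(levs, function(lv)
    colMeans(x[g == lv, , drop = FALSE]))
  apply(as.matrix(newdata), 1, function(v) {
    d2 <- apply(means, 2, function(m) {
      dd <- v - m
      drop(t(dd) %*% Winv %*% dd)
    })
    levs[which.min(d2)]
  })
}
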