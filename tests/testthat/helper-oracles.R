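# Independent oracle implementations used to cross-check the package's
# statistics. These are deliberately written as literal, loop-based
# transcriptions of the published procedures, sharing no code with R/.

# percentile-bend correlation, step by step
oracle_percbend <- function(x, y, beta = 0.2) {
  n <- length(x)
  one_var <- function(v) {
    med <- median(v)
    w <- sort(abs(v - med))
    m <- floor((1 - beta) * n)
    omega <- w[m]
    psi <- (v - med) / omega
    i1 <- 0
    i2 <- 0
    s <- 0
    for (vi in v) {
      u <- (vi - med) / omega
      if (u < -1) i1 <- i1 + 1 else if (u > 1) i2 <- i2 + 1 else s <- s + vi
    }
    phi <- (omega * (i2 - i1) + s) / (n - i1 - i2)
    a <- numeric(n)
    for (i in seq_len(n)) {
      u <- (v[i] - phi) / omega
      a[i] <- if (u < -1) -1 else if (u > 1) 1 else u
    }
    a
  }
  a <- one_var(x)
  b <- one_var(y)
  num <- 0
  da <- 0
  db <- 0
  for (i in seq_len(n)) {
    num <- num + a[i] * b[i]
    da <- da + a[i]^2
    db <- db + b[i]^2
  }
  num / sqrt(da * db)
}

# GEV and residual-variance criterion by per-sample loops
oracle_gev_cv <- function(chi, z, labels) {
  chi <- chi - rowMeans(chi)
  N <- nrow(chi)
  C <- ncol(chi)
  K <- nrow(z)
  gfp <- numeric(N)
  for (i in seq_len(N)) gfp[i] <- sqrt(sum(chi[i, ]^2) / C)
  denom <- sum(gfp^2)
  gev <- numeric(N)
  resid <- 0
  for (i in seq_len(N)) {
    zi <- z[labels[i], ]
    gev[i] <- (cor(chi[i, ], zi) * gfp[i])^2 / denom
    resid <- resid + sum(chi[i, ] * chi[i, ]) - sum(chi[i, ] * zi)^2
  }
  sigma2 <- resid / (N * (C - 1))
  list(
    gev_total = sum(gev),
    sigma2 = sigma2,
    cv = sigma2 * (C - 1) / (C - K - 1)
  )
}

# spherical-spline surface Laplacian via pracma's Legendre functions and an
# explicitly partitioned solve (coded independently of csd_transform)
oracle_csd <- function(data, pos, m = 4, lambda = 1e-5, nmax = 50) {
  pos <- pos / sqrt(rowSums(pos^2))
  C <- nrow(pos)
  cosang <- pos %*% t(pos)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  gmat <- matrix(0, C, C)
  hmat <- matrix(0, C, C)
  for (i in seq_len(C)) {
    for (j in seq_len(C)) {
      gs <- 0
      hs <- 0
      for (n in seq_len(nmax)) {
        pn <- pracma::legendre(n, cosang[i, j])[1] # P_n^0
        gs <- gs + (2 * n + 1) / (n * (n + 1))^m * pn
        hs <- hs - (2 * n + 1) / (n * (n + 1))^(m - 1) * pn
      }
      gmat[i, j] <- gs / (4 * pi)
      hmat[i, j] <- hs / (4 * pi)
    }
  }
  gl <- gmat + lambda * diag(C)
  gi <- solve(gl)
  out <- matrix(0, C, ncol(data))
  ones <- rep(1, C)
  for (t in seq_len(ncol(data))) {
    v <- data[, t]
    # constrained spline: coefficients sum to zero
    c0 <- sum(gi %*% v) / sum(gi %*% ones)
    cc <- gi %*% (v - c0 * ones)
    out[, t] <- hmat %*% cc
  }
  out
}

# best permutation/sign matching of fitted prototypes to planted ones;
# returns the mean and min absolute spatial correlation over matched pairs
match_prototypes <- function(fitted, planted) {
  k <- nrow(planted)
  cors <- abs(cor(t(fitted), t(planted))) # k_fit x k_true
  perms <- pracma::perms(seq_len(k))
  best <- -Inf
  best_assign <- NULL
  for (p in seq_len(nrow(perms))) {
    v <- cors[cbind(perms[p, ], seq_len(k))]
    if (sum(v) > best) {
      best <- sum(v)
      best_assign <- v
    }
  }
  list(mean = mean(best_assign), min = min(best_assign))
}

# label accuracy against ground truth, maximized over label permutations
label_accuracy <- function(fitted_labels, true_labels, k) {
  ok <- !is.na(fitted_labels)
  f <- fitted_labels[ok]
  tr <- true_labels[ok]
  perms <- pracma::perms(seq_len(k))
  best <- 0
  for (p in seq_len(nrow(perms))) {
    best <- max(best, mean(perms[p, ][f] == tr))
  }
  best
}
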