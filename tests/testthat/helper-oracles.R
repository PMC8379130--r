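# Independent brute-force oracles used to validate the implementations.
# Each oracle enumerates the definition directly and shares no code with the
# package internals.

# mean over exhaustively enumerated pixels with centers inside the ellipse
oracle_roi_mean <- function(image, cr, cc, a, b) {
  vals <- c()
  n <- 0L
  for (r in 0:(nrow(image) - 1L)) {
    for (col in 0:(ncol(image) - 1L)) {
      if (((r - cr) / a)^2 + ((col - cc) / b)^2 <= 1 + 1e-12) {
        vals <- c(vals, image[r + 1L, col + 1L])
        n <- n + 1L
      }
    }
  }
  list(mean = mean(vals), n = n)
}

# two-sided Fisher p: enumerate all tables at fixed margins, sum those with
# hypergeometric probability <= observed
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0L, k - m2); hi <- min(k, m1)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(m1, x) + lchoose(m2, k - x) - lchoose(m1 + m2, k))
  }, numeric(1))
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# full permutation distribution of the Mann-Whitney U statistic (midranks)
oracle_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_stat <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  obs <- u_stat(seq_len(nx))
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  mu <- nx * ny / 2
  # two-sided by symmetry of |U - mean| under the permutation distribution
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# AUC by direct pair counting: concordant + half ties over all pos x neg pairs
oracle_auc <- function(scores, is_pos) {
  xp <- scores[is_pos]; xn <- scores[!is_pos]
  tot <- 0
  for (p in xp) for (q in xn) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(xp) * length(xn))
}

# brute-force scan of every distinct score cut for the three ROC criteria;
# ties toward the higher cut
oracle_threshold_cuts <- function(scores, is_pos) {
  cuts <- sort(unique(scores))
  crit <- t(vapply(cuts, function(t) {
    sens <- mean(scores[is_pos] >= t)
    spec <- mean(scores[!is_pos] < t)
    c(youden = sens + spec - 1,
      hmean = if (sens + spec > 0) 2 * sens * spec / (sens + spec) else 0,
      corner = -sqrt((1 - sens)^2 + (1 - spec)^2))
  }, numeric(3)))
  apply(crit, 2, function(cv) cuts[max(which(cv >= max(cv) - 1e-12))])
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  mu <- sum(r) / 2
  mean(abs(vs - mu) >= abs(obs - mu) - 1e-9)
}

# logistic log-likelihood maximized with a generic optimizer (independent of
# the IRLS path used by the implementation)
oracle_logistic_coefs <- function(X, y, start = NULL) {
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  start <- start %||% rep(0, ncol(X))
  opt <- optim(start, nll, method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
  opt$par
}

`%||%` <- function(a, b) if (is.null(a)) b else a
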