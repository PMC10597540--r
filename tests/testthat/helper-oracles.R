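# Independent oracles kept deliberately naive; they never share code with the
# implementation paths they check.

# O(n^3) Lance-Williams agglomeration returning merge heights
naive_agglomerate <- function(D, linkage) {
  D <- as.matrix(D)
  n <- nrow(D)
  d <- if (linkage == "ward_d2") D^2 else D
  active <- seq_len(n)
  size <- rep(1, n)
  heights <- numeric(0)
  while (length(active) > 1) {
    bv <- Inf; bi <- bj <- NA
    for (ii in seq_along(active)) for (jj in seq_along(active)) if (jj > ii) {
      i <- active[ii]; j <- active[jj]
      if (d[i, j] < bv) { bv <- d[i, j]; bi <- i; bj <- j }
    }
    heights <- c(heights, if (linkage == "ward_d2") sqrt(bv) else bv)
    for (k in setdiff(active, c(bi, bj))) {
      dk <- if (linkage == "complete") max(d[bi, k], d[bj, k]) else
        ((size[bi] + size[k]) * d[bi, k] + (size[bj] + size[k]) * d[bj, k] -
           size[k] * d[bi, bj]) / (size[bi] + size[bj] + size[k])
      d[bi, k] <- d[k, bi] <- dk
    }
    size[bi] <- size[bi] + size[bj]
    active <- setdiff(active, bj)
  }
  heights
}

# Newton/IRLS logistic fit from first principles: coefficients, Wald SEs, p
irls_logistic <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    xtw <- t(X * w)
    beta_new <- as.vector(solve(xtw %*% X, xtw %*% z))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  mu <- 1 / (1 + exp(-as.vector(X %*% beta)))
  info <- t(X * (mu * (1 - mu))) %*% X
  se <- unname(sqrt(diag(solve(info))))
  list(beta = unname(beta), se = se, p = 2 * pnorm(-abs(beta / se)))
}

# hypergeometric upper tail by full enumeration of the intersection count
enum_hyper_upper <- function(n_universe, n_a, n_b, x) {
  js <- x:min(n_a, n_b)
  sum(choose(n_a, js) * choose(n_universe - n_a, n_b - js)) / choose(n_universe, n_b)
}

# BH step-up from the definition, without monotonicity shortcuts
bh_by_hand <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  if (n > 1) for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# running-sum enrichment score recomputed step by step (ties in magnitude
# resolve to the positive peak, matching the documented convention)
naive_es <- function(stats, members, w = 1) {
  s <- stats[order(-stats, names(stats))]
  inset <- names(s) %in% members
  denom <- sum(abs(s[inset])^w)
  run <- 0; hi <- -Inf; lo <- Inf
  for (i in seq_along(s)) {
    run <- run + if (inset[i]) abs(s[i])^w / denom else -1 / (length(s) - sum(inset))
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  unname(if (hi >= -lo - 1e-12) hi else lo)
}
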