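# Independent oracle implementations used across the suite. These are
# deliberately written as naive enumerations/closed forms, sharing no code
# with the package internals they check.

# Erlangen Score recomputed literally from the verbal scoring rule:
# zone-score amyloid and tau markers 0/1/2 with if-chains, take the higher
# tau score, add, then add +/-1 for the amyloid ratio and retain 0/4 when
# the result leaves the range.
oracle_ers <- function(ab42, ab40, ptau, ttau, panel) {
  zone_low <- function(v, c) {
    if (v < 0.9 * c) 2L else if (v <= 1.1 * c) 1L else 0L
  }
  zone_high <- function(v, c) {
    if (v > 1.1 * c) 2L else if (v >= 0.9 * c) 1L else 0L
  }
  a <- zone_low(ab42, panel$ab42_cutoff)
  t_ <- max(zone_high(ptau, panel$ptau_cutoff),
            zone_high(ttau, panel$ttau_cutoff))
  s <- a + t_
  if (!is.na(ab40)) {
    s <- s + (if (ab42 / ab40 < panel$amyloid_ratio_cutoff) 1L else -1L)
    if (s < 0L) s <- 0L
    if (s > 4L) s <- 4L
  }
  s
}

# exhaustive Youden scan: evaluate J at every midpoint between consecutive
# distinct pooled values plus outer sentinels, return the maximum J and all
# maximizing thresholds
oracle_youden_scan <- function(cases, controls) {
  pooled <- sort(unique(c(cases, controls)))
  cand <- c(min(pooled) - 1, (head(pooled, -1) + tail(pooled, -1)) / 2,
            max(pooled) + 1)
  j <- sapply(cand, function(c_) {
    mean(cases > c_) + mean(controls <= c_) - 1
  })
  list(max_j = max(j), cutoffs = cand[j == max(j)], cand = cand, j = j)
}

# all-pairs Mann-Whitney AUC
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# DeLong variance components by direct double-loop enumeration
oracle_delong <- function(xa, xb, labels) {
  labels <- as.logical(labels)
  psi <- function(x, y) if (x > y) 1 else if (x == y) 0.5 else 0
  comp <- function(x) {
    xp <- x[labels]; xn <- x[!labels]
    m <- length(xp); n <- length(xn)
    v10 <- numeric(m); v01 <- numeric(n)
    for (i in seq_len(m)) v10[i] <- mean(sapply(xn, function(y) psi(xp[i], y)))
    for (j in seq_len(n)) v01[j] <- mean(sapply(xp, function(p) psi(p, xn[j])))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  ca <- comp(xa); cb <- comp(xb)
  m <- sum(labels); n <- sum(!labels)
  s10 <- cov(cbind(ca$v10, cb$v10)); s01 <- cov(cbind(ca$v01, cb$v01))
  S <- s10 / m + s01 / n
  list(auc_a = ca$auc, auc_b = cb$auc,
       var_a = S[1, 1], var_b = S[2, 2], cov_ab = S[1, 2])
}

# Breslow partial log-likelihood for a single covariate
oracle_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# two-stage grid-search maximizer of the Breslow partial likelihood
oracle_cox_grid <- function(time, event, x, lim = 5) {
  coarse <- seq(-lim, lim, by = 0.01)
  ll <- sapply(coarse, oracle_partial_loglik, time = time, event = event, x = x)
  b0 <- coarse[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  llf <- sapply(fine, oracle_partial_loglik, time = time, event = event, x = x)
  fine[which.max(llf)]
}

# naive dense multivariate-normal evaluation of the mixed-model likelihood:
# covariance assembled entry by entry, solve()/determinant() instead of a
# Cholesky pipeline
oracle_lmm_dense <- function(beta, vc, visits, group_df, ar1 = "order") {
  g <- setNames(as.character(group_df$group), group_df$subject_id)
  lev <- sort(unique(g))
  ll <- 0
  for (id in unique(visits$subject_id)) {
    s <- visits[visits$subject_id == id, ]
    s <- s[order(s$time), ]
    n <- nrow(s)
    V <- matrix(0, n, n)
    for (j in 1:n) for (k in 1:n) {
      zj <- c(1, s$time[j]); zk <- c(1, s$time[k])
      G <- matrix(c(vc$var_u0, vc$cov_u01, vc$cov_u01, vc$var_u1), 2, 2)
      lag <- if (ar1 == "order") abs(j - k) else abs(s$time[j] - s$time[k])
      V[j, k] <- sum(zj * (G %*% zk)) + vc$var_e * vc$rho^lag
    }
    lvl <- g[[as.character(id)]]
    dum <- as.numeric(lvl == lev[-1])
    mu <- sapply(s$time, function(t_) {
      xi <- c(1, t_, dum, t_ * dum)
      sum(xi * beta)
    })
    r <- s$zmmse - mu
    ll <- ll - 0.5 * (n * log(2 * pi) +
                        as.numeric(determinant(V)$modulus) +
                        sum(r * solve(V, r)))
  }
  ll
}

# random profile spanning all three zones of every marker
random_profiles <- function(n, panel = default_panel()) {
  data.frame(
    subject_id = sprintf("R%05d", seq_len(n)),
    ab42 = panel$ab42_cutoff * exp(runif(n, log(0.4), log(2.5))),
    ab40 = ifelse(runif(n) < 0.15, NA,
                  panel$ab42_cutoff / panel$amyloid_ratio_cutoff *
                    exp(runif(n, log(0.5), log(2)))),
    ptau = panel$ptau_cutoff * exp(runif(n, log(0.4), log(2.5))),
    ttau = panel$ttau_cutoff * exp(runif(n, log(0.4), log(2.5))),
    panel_id = panel$panel_id
  )
}

# subjects frame with a fixed group split and resampled follow-up
design_subjects <- function(n_normal, n_path) {
  n <- n_normal + n_path
  data.frame(
    subject_id = sprintf("D%04d", seq_len(n)),
    group = factor(rep(c("normal", "pathologic"), c(n_normal, n_path)),
                   levels = c("normal", "pathologic")),
    followup = sample_followup(n)
  )
}
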