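#' Exact marginal log-likelihood of the longitudinal MMSE z-score model
#'
#' The model for subject i at visit time t (years) is
#' \deqn{z_{i,t} = \beta_0 + \beta_1 t + \beta_2' g_i + \beta_3' g_i t
#'       + u_{0i} + u_{1i} t + \epsilon_{i,t}}
#' with subject-level random intercept and slope \eqn{(u_{0i}, u_{1i})
#' \sim N(0, G)} and AR(1)-correlated residuals:
#' \eqn{cov(\epsilon_{i,j}, \epsilon_{i,k}) = \sigma^2_e \rho^{|j-k|}}
#' over the within-subject visit order (`ar1 = "order"`, the
#' repeated-effects convention of the usual mixed-model software) or
#' \eqn{\sigma^2_e \rho^{|t_j - t_k|}} (`ar1 = "continuous"`).
#' Marginally each subject's response vector is multivariate normal with
#' covariance \eqn{V_i = Z_i G Z_i' + R_i}, \eqn{Z_i = [1, t]}; the
#' function returns the exact sum of per-subject Gaussian log-densities.
#'
#' @param beta Fixed-effect vector in the order: intercept, time, group
#'   dummies (non-reference levels), group-by-time interactions (matching
#'   [fit_zmmse_lmm()] output).
#' @param varcomp List with `var_u0`, `var_u1`, `cov_u01`, `rho`, `var_e`.
#'   The implied G must be positive semi-definite, `|rho| < 1`,
#'   `var_e > 0`.
#' @param visits Data.frame with columns `subject_id`, `time`, `zmmse`.
#' @param group Per-subject group labels: a data.frame with `subject_id`
#'   and `group` columns, or a vector named by subject id.
#' @param include_interaction Include the group-by-time term (the study
#'   models always do).
#' @param ar1 Residual correlation convention, see above.
#' @return The log-likelihood (scalar).
#' @export
lmm_loglik <- function(beta, varcomp, visits, group,
                       include_interaction = TRUE,
                       ar1 = c("order", "continuous")) {
  ar1 <- match.arg(ar1)
  d <- lmm_data(visits, group)
  check_varcomp(varcomp)
  p_fixed <- if (include_interaction) 2L * length(d$levels) else length(d$levels) + 1L
  if (length(beta) != p_fixed) {
    stop_field("beta", sprintf("expected %d fixed effects, got %d",
                               p_fixed, length(beta)))
  }
  G <- matrix(c(varcomp$var_u0, varcomp$cov_u01,
                varcomp$cov_u01, varcomp$var_u1), 2, 2)
  ll <- 0
  for (s in split(d$frame, d$frame$subject_id, drop = TRUE)) {
    t_ <- s$time
    Z <- cbind(1, t_)
    V <- Z %*% G %*% t(Z) + varcomp$var_e * ar1_corr(t_, varcomp$rho, ar1)
    X <- lmm_design(t_, s$group[1], d$levels, include_interaction)
    r <- s$zmmse - drop(X %*% beta)
    ch <- chol(V)
    w <- backsolve(ch, r, transpose = TRUE)
    ll <- ll - 0.5 * (length(t_) * log(2 * pi) +
                        2 * sum(log(diag(ch))) + sum(w^2))
  }
  ll
}

check_varcomp <- function(varcomp) {
  need <- c("var_u0", "var_u1", "cov_u01", "rho", "var_e")
  miss <- setdiff(need, names(varcomp))
  if (length(miss)) {
    stop_field("varcomp", paste("missing:", paste(miss, collapse = ", ")))
  }
  if (varcomp$var_u0 < 0 || varcomp$var_u1 < 0 ||
      varcomp$cov_u01^2 > varcomp$var_u0 * varcomp$var_u1 + 1e-12) {
    stop_field("varcomp", "random-effects covariance must be positive semi-definite")
  }
  if (abs(varcomp$rho) >= 1) stop_field("rho", "must satisfy |rho| < 1")
  if (varcomp$var_e <= 0) stop_field("var_e", "must be positive")
  invisible(varcomp)
}

ar1_corr <- function(times, rho, ar1) {
  if (ar1 == "order") {
    idx <- seq_along(times)
    rho^abs(outer(idx, idx, "-"))
  } else {
    rho^abs(outer(times, times, "-"))
  }
}

# canonical per-subject design matrix for given visit times and group level
lmm_design <- function(times, level, levels, include_interaction) {
  n <- length(times)
  dum <- outer(rep(as.character(level), n), levels[-1], "==") * 1
  if (include_interaction) {
    cbind(1, times, dum, times * dum)
  } else {
    cbind(1, times, dum)
  }
}

# validate + merge visits and group labels; returns ordered frame and levels
lmm_data <- function(visits, group, min_groups = 1L) {
  need <- c("subject_id", "time", "zmmse")
  miss <- setdiff(need, names(visits))
  if (length(miss)) {
    stop_field("visits", paste("missing column(s):", paste(miss, collapse = ", ")))
  }
  if (any(visits$time < 0)) stop_field("time", "visit times must be >= 0")
  if (anyNA(visits$zmmse)) stop_field("zmmse", "missing values not supported")
  g <- if (is.data.frame(group)) {
    stats::setNames(group$group, as.character(group$subject_id))
  } else {
    group
  }
  ids <- unique(as.character(visits$subject_id))
  absent <- setdiff(ids, names(g))
  if (length(absent)) {
    stop_field("group", paste("no group label for subject(s):",
                              paste(utils::head(absent, 3), collapse = ", ")))
  }
  fr <- visits[order(visits$subject_id, visits$time),
               c("subject_id", "time", "zmmse")]
  fr$subject_id <- as.character(fr$subject_id)
  dup <- duplicated(fr[c("subject_id", "time")])
  if (any(dup)) {
    stop_field("visits", paste("duplicated visit time for subject",
                               fr$subject_id[dup][1]))
  }
  fr$group <- factor(g[fr$subject_id])
  if (nlevels(fr$group) < min_groups) stop_field("group", "needs >= 2 groups")
  list(frame = fr, levels = levels(fr$group))
}

# unconstrained parameterization of the 5 covariance parameters:
# G = L L' with L = [[exp(a), 0], [b, exp(c)]]; rho = tanh(d); sd_e = exp(e)
theta_to_varcomp <- function(theta) {
  l11 <- exp(theta[1]); l21 <- theta[2]; l22 <- exp(theta[3])
  list(var_u0 = l11^2,
       var_u1 = l21^2 + l22^2,
       cov_u01 = l11 * l21,
       rho = tanh(theta[4]),
       var_e = exp(2 * theta[5]))
}

# profiled negative log-likelihood; patterns precomputed by the caller
lmm_negloglik <- function(theta, patterns, N, L, ar1) {
  vc <- theta_to_varcomp(theta)
  G <- matrix(c(vc$var_u0, vc$cov_u01, vc$cov_u01, vc$var_u1), 2, 2)
  p <- 2L * L
  A <- matrix(0, p, p)
  bvec <- numeric(p)
  quad <- 0
  logdet <- 0
  for (pt in patterns) {
    V <- pt$B %*% G %*% t(pt$B) + vc$var_e * ar1_corr(pt$t, vc$rho, ar1)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(nll = 1e10))
    Vinv <- chol2inv(ch)
    BtVi <- crossprod(pt$B, Vinv)
    A <- A + kronecker(crossprod(pt$W), BtVi %*% pt$B)
    bvec <- bvec + as.vector((BtVi %*% pt$Y) %*% pt$W)
    quad <- quad + sum(pt$Y * (Vinv %*% pt$Y))
    logdet <- logdet + ncol(pt$Y) * 2 * sum(log(diag(ch)))
  }
  beta <- tryCatch(solve(A, bvec), error = function(e) NULL)
  if (is.null(beta)) return(list(nll = 1e10))
  nll <- 0.5 * (N * log(2 * pi) + logdet + quad - sum(bvec * beta))
  list(nll = nll, beta = beta, A = A)
}

#' Fit the longitudinal MMSE z-score mixed model by maximum likelihood
#'
#' Fits the model documented in [lmm_loglik()] by full maximum likelihood
#' (ML, not REML). The fixed effects are profiled out by generalized least
#' squares given the covariance parameters; the five covariance parameters
#' are optimized on an unconstrained scale (Cholesky factor of the
#' random-effects covariance, Fisher-z transform of the AR(1) correlation,
#' log residual standard deviation) with `nlminb` from a deterministic
#' OLS-based start, so refits are bit-reproducible. Subjects sharing a
#' visit-time pattern share one covariance factorization per likelihood
#' evaluation, which keeps cohort-scale fits fast.
#'
#' Inference on the fixed effects uses the asymptotic GLS covariance at
#' the ML estimates (Wald z tests and normal confidence intervals).
#' `aic = -2 logLik + 2 k` and `bic = -2 logLik + k log(N)` with
#' `k = n_params` = number of fixed effects + 5 covariance parameters and
#' `N` the number of observations.
#'
#' @inheritParams lmm_loglik
#' @param time_unit Label for the time axis (metadata only; estimates are
#'   per unit of the supplied `time` column).
#' @return An object of class `ers_lmm`. Components include
#'   `coefficients`, `se`, `vcov`, `varcomp`, `logLik`, `n_params`, `aic`,
#'   `bic`, `n_obs`, `n_subjects`, `convergence` (0 = converged),
#'   `random_effects` (per-subject empirical-Bayes intercept/slope) and
#'   the model `frame` with marginal and conditional fitted values.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 60), seed = 1)
#' fit <- fit_zmmse_lmm(cohort$visits, cohort$groups)
#' summary(fit)
#' @seealso [rmse()], [compare_lmm()], [random_effects()]
#' @export
fit_zmmse_lmm <- function(visits, group, include_interaction = TRUE,
                          ar1 = c("order", "continuous"),
                          time_unit = "years") {
  ar1 <- match.arg(ar1)
  d <- lmm_data(visits, group, min_groups = 2L)
  fr <- d$frame
  L <- length(d$levels)
  N <- nrow(fr)
  sub_rows <- split(seq_len(N), fr$subject_id)
  n_subj <- length(sub_rows)
  if (any(lengths(sub_rows) < 1L)) stop_field("visits", "each subject needs >= 1 visit")

  if (include_interaction) {
    keys <- vapply(sub_rows,
                   function(ix) paste(signif(fr$time[ix], 12), collapse = ","),
                   character(1))
    patterns <- lapply(split(names(sub_rows), keys), function(ids) {
      t_ <- fr$time[sub_rows[[ids[1]]]]
      Y <- vapply(ids, function(id) fr$zmmse[sub_rows[[id]]], numeric(length(t_)))
      Y <- matrix(Y, nrow = length(t_))
      lev <- vapply(ids, function(id) as.character(fr$group[sub_rows[[id]][1]]),
                    character(1))
      W <- cbind(1, outer(lev, d$levels[-1], "==") * 1)
      list(t = t_, B = cbind(1, t_), Y = Y, W = W, ids = ids)
    })
    p_fixed <- 2L * L
    # vec(M)-order -> conventional order (intercept, time, groups, interactions)
    perm <- c(1L, 2L,
              if (L > 1L) seq(3L, 2L * L - 1L, by = 2L),
              if (L > 1L) seq(4L, 2L * L, by = 2L))
    nll_fun <- function(theta) lmm_negloglik(theta, patterns, N, L, ar1)
  } else {
    # no-interaction variant: generic per-subject accumulation
    p_fixed <- L + 1L
    perm <- seq_len(p_fixed)
    subj <- lapply(sub_rows, function(ix) {
      t_ <- fr$time[ix]
      list(t = t_, y = fr$zmmse[ix],
           X = lmm_design(t_, fr$group[ix[1]], d$levels, FALSE))
    })
    nll_fun <- function(theta) {
      vc <- theta_to_varcomp(theta)
      G <- matrix(c(vc$var_u0, vc$cov_u01, vc$cov_u01, vc$var_u1), 2, 2)
      A <- matrix(0, p_fixed, p_fixed); bvec <- numeric(p_fixed)
      quad <- 0; logdet <- 0
      for (s in subj) {
        Z <- cbind(1, s$t)
        V <- Z %*% G %*% t(Z) + vc$var_e * ar1_corr(s$t, vc$rho, ar1)
        ch <- tryCatch(chol(V), error = function(e) NULL)
        if (is.null(ch)) return(list(nll = 1e10))
        Vinv <- chol2inv(ch)
        XtVi <- crossprod(s$X, Vinv)
        A <- A + XtVi %*% s$X
        bvec <- bvec + drop(XtVi %*% s$y)
        quad <- quad + sum(s$y * (Vinv %*% s$y))
        logdet <- logdet + 2 * sum(log(diag(ch)))
      }
      beta <- tryCatch(solve(A, bvec), error = function(e) NULL)
      if (is.null(beta)) return(list(nll = 1e10))
      list(nll = 0.5 * (N * log(2 * pi) + logdet + quad - sum(bvec * beta)),
           beta = beta, A = A)
    }
  }

  # deterministic start: split the OLS residual variance between the random
  # intercept and the residual, small slope variance, mild autocorrelation
  ols <- stats::lm(
    if (include_interaction) zmmse ~ time * group else zmmse ~ time + group,
    data = fr
  )
  s2 <- max(mean(stats::resid(ols)^2), 1e-4)
  theta0 <- c(0.5 * log(s2 / 2), 0, 0.5 * log(s2 / 50), atanh(0.2),
              0.5 * log(s2 / 2))

  opt <- stats::nlminb(theta0, function(th) nll_fun(th)$nll,
                       control = list(iter.max = 300, eval.max = 600))
  final <- nll_fun(opt$par)
  vc <- theta_to_varcomp(opt$par)
  beta <- final$beta[perm]
  vcov_beta <- solve(final$A)[perm, perm, drop = FALSE]
  nm <- c("(Intercept)", "time",
          if (L > 1L) paste0("group", d$levels[-1]),
          if (include_interaction && L > 1L) paste0("time:group", d$levels[-1]))
  names(beta) <- nm
  dimnames(vcov_beta) <- list(nm, nm)

  if (opt$convergence != 0) {
    warning("mixed-model fit did not converge (", opt$message, ")", call. = FALSE)
  }

  # empirical-Bayes random effects and fitted values, one pass per subject
  G <- matrix(c(vc$var_u0, vc$cov_u01, vc$cov_u01, vc$var_u1), 2, 2)
  fr$fitted_marginal <- NA_real_
  fr$fitted_conditional <- NA_real_
  re <- matrix(NA_real_, n_subj, 2,
               dimnames = list(names(sub_rows), c("intercept", "slope")))
  for (id in names(sub_rows)) {
    ix <- sub_rows[[id]]
    t_ <- fr$time[ix]
    Z <- cbind(1, t_)
    V <- Z %*% G %*% t(Z) + vc$var_e * ar1_corr(t_, vc$rho, ar1)
    X <- lmm_design(t_, fr$group[ix[1]], d$levels, include_interaction)
    mu <- drop(X %*% beta)
    b <- drop(G %*% crossprod(Z, solve(V, fr$zmmse[ix] - mu)))
    re[id, ] <- b
    fr$fitted_marginal[ix] <- mu
    fr$fitted_conditional[ix] <- mu + drop(Z %*% b)
  }

  n_params <- p_fixed + 5L
  ll <- -final$nll
  structure(
    list(
      coefficients = beta,
      se = sqrt(diag(vcov_beta)),
      vcov = vcov_beta,
      varcomp = vc,
      logLik = ll,
      n_params = n_params,
      aic = -2 * ll + 2 * n_params,
      bic = -2 * ll + n_params * log(N),
      n_obs = N,
      n_subjects = n_subj,
      convergence = opt$convergence,
      message = opt$message,
      random_effects = re,
      frame = fr,
      levels = d$levels,
      include_interaction = include_interaction,
      ar1 = ar1,
      time_unit = time_unit,
      data_hash = paste(nrow(fr), signif(sum(fr$time), 12),
                        signif(sum(fr$zmmse^2), 12))
    ),
    class = "ers_lmm"
  )
}

#' @export
print.ers_lmm <- function(x, ...) {
  cat("Linear mixed model of MMSE z-scores (ML, AR(1) residuals)\n")
  cat(sprintf("  %d observations, %d subjects, groups: %s\n",
              x$n_obs, x$n_subjects, paste(x$levels, collapse = "/")))
  cat("Fixed effects:\n")
  print(round(x$coefficients, 4))
  with(x$varcomp, cat(sprintf(
    "Variance components: var_u0 %.3f, var_u1 %.3f, cov %.3f, rho %.3f, var_e %.3f\n",
    var_u0, var_u1, cov_u01, rho, var_e)))
  cat(sprintf("logLik %.3f  AIC %.3f  BIC %.3f (k = %d)\n",
              x$logLik, x$aic, x$bic, x$n_params))
  if (x$convergence != 0) cat("WARNING: optimizer did not report convergence\n")
  invisible(x)
}

#' @export
summary.ers_lmm <- function(object, level = 0.95, ...) {
  z <- object$coefficients / object$se
  q <- stats::qnorm(1 - (1 - level) / 2)
  tab <- cbind(
    Estimate = object$coefficients,
    `Std.Error` = object$se,
    t = z,
    p = 2 * stats::pnorm(-abs(z)),
    lower = object$coefficients - q * object$se,
    upper = object$coefficients + q * object$se
  )
  out <- list(coefficients = tab, varcomp = object$varcomp,
              logLik = object$logLik, aic = object$aic, bic = object$bic,
              n_obs = object$n_obs, n_subjects = object$n_subjects,
              convergence = object$convergence)
  class(out) <- "summary.ers_lmm"
  out
}

#' @export
print.summary.ers_lmm <- function(x, ...) {
  cat("Fixed effects (Wald z inference):\n")
  stats::printCoefmat(x$coefficients[, 1:4, drop = FALSE],
                      P.values = TRUE, has.Pvalue = TRUE)
  cat("\n95% CI:\n")
  print(round(x$coefficients[, 5:6, drop = FALSE], 4))
  with(x$varcomp, cat(sprintf(
    "\nVariance components: var_u0 %.4f, var_u1 %.4f, cov %.4f, rho %.4f, var_e %.4f\n",
    var_u0, var_u1, cov_u01, rho, var_e)))
  cat(sprintf("logLik %.3f  AIC %.3f  BIC %.3f  (N = %d, subjects = %d)\n",
              x$logLik, x$aic, x$bic, x$n_obs, x$n_subjects))
  invisible(x)
}

#' @export
coef.ers_lmm <- function(object, ...) object$coefficients

#' @export
vcov.ers_lmm <- function(object, ...) object$vcov

#' @export
logLik.ers_lmm <- function(object, ...) {
  structure(object$logLik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' Predicted MMSE z-scores from a fitted mixed model
#'
#' @param object An `ers_lmm` fit.
#' @param newdata Optional data.frame with `time` and `group` columns for
#'   marginal (fixed-effects-only) prediction; defaults to the training
#'   frame.
#' @param level `"marginal"` (fixed effects only) or `"conditional"`
#'   (adds the subject's empirical-Bayes random effects; training frame
#'   only).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.ers_lmm <- function(object, newdata = NULL,
                            level = c("marginal", "conditional"), ...) {
  level <- match.arg(level)
  if (is.null(newdata)) {
    return(switch(level,
                  marginal = object$frame$fitted_marginal,
                  conditional = object$frame$fitted_conditional))
  }
  if (level == "conditional") {
    stop_field("newdata", "conditional predictions are defined for the training frame only")
  }
  X <- do.call(rbind, lapply(seq_len(nrow(newdata)), function(i) {
    lmm_design(newdata$time[i], newdata$group[i], object$levels,
               object$include_interaction)
  }))
  drop(X %*% object$coefficients)
}

#' @export
residuals.ers_lmm <- function(object, level = c("marginal", "conditional"), ...) {
  level <- match.arg(level)
  object$frame$zmmse - predict(object, level = level)
}

#' Per-subject empirical-Bayes random effects
#' @param object An `ers_lmm` fit.
#' @return Matrix with one row per subject, columns `intercept`, `slope`.
#' @export
random_effects <- function(object) {
  stopifnot(inherits(object, "ers_lmm"))
  object$random_effects
}

#' @export
simulate.ers_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fr <- object$frame
  vc <- object$varcomp
  G <- matrix(c(vc$var_u0, vc$cov_u01, vc$cov_u01, vc$var_u1), 2, 2)
  cg <- chol(G + diag(1e-12, 2))
  sub_rows <- split(seq_len(nrow(fr)), fr$subject_id)
  out <- replicate(nsim, {
    y <- numeric(nrow(fr))
    for (ix in sub_rows) {
      t_ <- fr$time[ix]
      u <- drop(crossprod(cg, stats::rnorm(2)))
      e <- ar1_series(length(t_), vc$rho, vc$var_e)
      y[ix] <- fr$fitted_marginal[ix] + u[1] + u[2] * t_ + e
    }
    y
  })
  as.data.frame(out)
}

# stationary AR(1) series of length n with marginal variance var_e
ar1_series <- function(n, rho, var_e) {
  z <- stats::rnorm(n)
  e <- numeric(n)
  e[1] <- sqrt(var_e) * z[1]
  if (n > 1) {
    for (j in 2:n) e[j] <- rho * e[j - 1] + sqrt(var_e * (1 - rho^2)) * z[j]
  }
  e
}

#' Root-mean-squared prediction error of a fitted mixed model
#'
#' `sqrt(mean((y - yhat)^2))` over all observations, with `yhat` from the
#' fixed effects only (`marginal`) or fixed effects plus the subject's
#' empirical-Bayes random effects (`conditional`).
#'
#' @param fit An `ers_lmm` fit.
#' @param mode `"marginal"` or `"conditional"`.
#' @return RMSE in z-score units.
#' @export
rmse <- function(fit, mode = c("marginal", "conditional")) {
  UseMethod("rmse")
}

#' @export
rmse.ers_lmm <- function(fit, mode = c("marginal", "conditional")) {
  mode <- match.arg(mode)
  sqrt(mean(residuals(fit, level = mode)^2))
}

#' Compare mixed-model fits on the same visit data
#'
#' Builds the model-comparison table used to rank the candidate grouping
#' schemes (ordinal score, binary score, ratio classifier, ratio-free
#' score): AIC, BIC, log-likelihood, parameter count and marginal /
#' conditional RMSE, sorted by AIC. All fits must be on the identical
#' visit records.
#'
#' @param ... Named `ers_lmm` fits, or a single named list of them.
#' @return A data.frame of class `lmm_comparison`, sorted by AIC.
#' @export
compare_lmm <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1]], "ers_lmm")) fits <- fits[[1]]
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, logical(1), "ers_lmm")))
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  hashes <- vapply(fits, `[[`, character(1), "data_hash")
  if (length(unique(hashes)) != 1L) {
    stop_field("fits", "all models must be fitted to the same visit data")
  }
  out <- data.frame(
    model = names(fits),
    n_params = vapply(fits, `[[`, numeric(1), "n_params"),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    AIC = vapply(fits, `[[`, numeric(1), "aic"),
    BIC = vapply(fits, `[[`, numeric(1), "bic"),
    rmse_marginal = vapply(fits, rmse, numeric(1), mode = "marginal"),
    rmse_conditional = vapply(fits, rmse, numeric(1), mode = "conditional"),
    row.names = NULL
  )
  out <- out[order(out$AIC), ]
  class(out) <- c("lmm_comparison", "data.frame")
  out
}

#' @export
print.lmm_comparison <- function(x, ...) {
  cat("Mixed-model comparison (sorted by AIC)\n")
  print.data.frame(
    within(as.data.frame(x), {
      logLik <- round(logLik, 2); AIC <- round(AIC, 2); BIC <- round(BIC, 2)
      rmse_marginal <- round(rmse_marginal, 4)
      rmse_conditional <- round(rmse_conditional, 4)
    }),
    row.names = FALSE
  )
  invisible(x)
}
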