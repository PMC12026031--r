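vc0 <- function(var_u0 = 0, var_u1 = 0, cov_u01 = 0, rho = 0, var_e = 1) {
  list(var_u0 = var_u0, var_u1 = var_u1, cov_u01 = cov_u01, rho = rho,
       var_e = var_e)
}

# merge visits with the binary group indicator, for closed-form checks
lmm_data_frame <- function(visits, subjects) {
  m <- match(visits$subject_id, subjects$subject_id)
  data.frame(time = visits$time, zmmse = visits$zmmse,
             g = as.integer(subjects$group[m] == "pathologic"))
}

test_that("the structured likelihood matches closed forms in degenerate cases", {
  # single visit observed exactly at its mean: standard normal density at 0
  v <- data.frame(subject_id = "a", time = 0, zmmse = -1.3)
  g <- c(a = "x")
  ll <- lmm_loglik(c(-1.3, 0), vc0(), v, g)
  expect_equal(ll, -0.5 * log(2 * pi))
  # no random effects, rho = 0: sum of independent Gaussian log-densities
  set.seed(41)
  subj <- design_subjects(20, 20)
  cfg <- cohort_config(lmm_truth = c(list(beta = c(-1.3, -0.07, -0.4, -0.4)),
                                     vc0(var_e = 0.3)))
  vis <- generate_trajectories(subj, cfg)
  beta <- c(-1.2, -0.05, -0.3, -0.35)
  grp <- setNames(as.character(subj$group), subj$subject_id)
  ll <- lmm_loglik(beta, vc0(var_e = 0.3), vis, grp)
  d <- lmm_data_frame(vis, subj)
  mu <- beta[1] + beta[2] * d$time + beta[3] * d$g + beta[4] * d$g * d$time
  expect_equal(ll, sum(dnorm(d$zmmse, mu, sqrt(0.3), log = TRUE)))
})

test_that("the structured likelihood equals naive dense MVN evaluation", {
  set.seed(42)
  subj <- design_subjects(5, 5)
  cfg <- cohort_config()
  vis <- generate_trajectories(subj, cfg)
  grp <- data.frame(subject_id = subj$subject_id, group = subj$group)
  for (rep in 1:5) {
    beta <- rnorm(4, c(-1.3, -0.1, -0.4, -0.4), 0.3)
    vc <- list(var_u0 = runif(1, 0.2, 2), var_u1 = runif(1, 0.005, 0.1),
               cov_u01 = 0, rho = runif(1, -0.5, 0.8), var_e = runif(1, 0.1, 1))
    vc$cov_u01 <- runif(1, -1, 1) * sqrt(vc$var_u0 * vc$var_u1)
    for (ar1 in c("order", "continuous")) {
      expect_equal(lmm_loglik(beta, vc, vis, grp, ar1 = ar1),
                   oracle_lmm_dense(beta, vc, vis, grp, ar1 = ar1),
                   tolerance = 1e-10)
    }
  }
})

test_that("invalid variance components and mismatched beta are rejected", {
  v <- data.frame(subject_id = c("a", "b"), time = c(0, 0), zmmse = c(0, 1))
  g <- c(a = "x", b = "y")
  expect_error(lmm_loglik(rep(0, 4), vc0(rho = 1), v, g), "rho")
  expect_error(lmm_loglik(rep(0, 4), vc0(var_e = 0), v, g), "var_e")
  expect_error(
    lmm_loglik(rep(0, 4), vc0(var_u0 = 1, var_u1 = 0.01, cov_u01 = 0.5), v, g),
    "semi-definite")
  expect_error(lmm_loglik(rep(0, 3), vc0(), v, g), "fixed effects")
})

test_that("ML fit agrees with the independent mixed-model implementation", {
  set.seed(43)
  subj <- design_subjects(60, 60)
  cfg <- cohort_config()
  vis <- generate_trajectories(subj, cfg)
  grp <- setNames(as.character(subj$group), subj$subject_id)
  fit <- fit_zmmse_lmm(vis, grp)
  expect_equal(fit$convergence, 0)
  # reported log-likelihood is the exact likelihood at the estimates
  expect_equal(fit$logLik, lmm_loglik(coef(fit), fit$varcomp, vis, grp),
               tolerance = 1e-8)
  # cross-check against nlme (random intercept+slope, AR(1) by visit order)
  vis$group <- factor(grp[vis$subject_id], levels = c("normal", "pathologic"))
  nf <- nlme::lme(zmmse ~ time * group, random = ~ time | subject_id,
                  correlation = nlme::corAR1(form = ~ 1 | subject_id),
                  data = vis, method = "ML",
                  control = nlme::lmeControl(returnObject = TRUE))
  expect_equal(unname(coef(fit)), unname(nlme::fixef(nf)[c(1, 2, 3, 4)]),
               tolerance = 5e-3)
  expect_equal(fit$logLik, as.numeric(stats::logLik(nf)), tolerance = 1e-3)
  expect_equal(fit$n_params, attr(stats::logLik(nf), "df"))
  expect_equal(fit$varcomp$rho,
               as.numeric(coef(nf$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 0.02)
})

test_that("with vanishing variance the estimates collapse to least squares", {
  set.seed(44)
  subj <- design_subjects(30, 30)
  cfg <- cohort_config(lmm_truth = c(list(beta = c(-1.3, -0.07, -0.4, -0.4)),
                                     vc0(var_e = 1e-6)))
  vis <- generate_trajectories(subj, cfg)
  grp <- setNames(as.character(subj$group), subj$subject_id)
  fit <- suppressWarnings(fit_zmmse_lmm(vis, grp))
  d <- lmm_data_frame(vis, subj)
  ols <- lm(zmmse ~ time * g, data = d)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-4)
})

test_that("information-criterion identities hold and time units rescale exactly", {
  set.seed(45)
  subj <- design_subjects(40, 40)
  vis <- generate_trajectories(subj, cohort_config())
  grp <- setNames(as.character(subj$group), subj$subject_id)
  fit <- fit_zmmse_lmm(vis, grp)
  expect_equal(fit$aic, -2 * fit$logLik + 2 * fit$n_params)
  expect_equal(fit$bic, -2 * fit$logLik + fit$n_params * log(fit$n_obs))
  expect_equal(AIC(fit), fit$aic)
  expect_equal(BIC(fit), fit$bic)
  # months vs years: slopes scale by 12, the maximized likelihood is unchanged
  vis_m <- transform(vis, time = time * 12)
  fit_m <- fit_zmmse_lmm(vis_m, grp, time_unit = "months")
  expect_equal(fit_m$logLik, fit$logLik, tolerance = 1e-4)
  expect_equal(coef(fit_m)[["time"]] * 12, coef(fit)[["time"]], tolerance = 1e-3)
  expect_equal(coef(fit_m)[["time:grouppathologic"]] * 12,
               coef(fit)[["time:grouppathologic"]], tolerance = 1e-3)
})

test_that("conditional predictions beat marginal ones when subjects differ", {
  set.seed(46)
  wins <- 0L
  for (rep in 1:10) {
    subj <- design_subjects(25, 25)
    vis <- generate_trajectories(subj, cohort_config())
    grp <- setNames(as.character(subj$group), subj$subject_id)
    fit <- fit_zmmse_lmm(vis, grp)
    if (rmse(fit, "conditional") < rmse(fit, "marginal")) wins <- wins + 1L
    expect_gte(rmse(fit, "marginal"), 0)
  }
  expect_gte(wins, 9L)
})

test_that("model comparison ranks groupings fitted to identical visits", {
  set.seed(47)
  subj <- design_subjects(50, 50)
  vis <- generate_trajectories(subj, cohort_config())
  grp_bin <- setNames(as.character(subj$group), subj$subject_id)
  fit1 <- fit_zmmse_lmm(vis, grp_bin)
  fit1b <- fit_zmmse_lmm(vis, grp_bin)
  cmp <- compare_lmm(binary = fit1, again = fit1b)
  expect_equal(cmp$AIC[1], cmp$AIC[2])
  expect_equal(cmp$BIC[1], cmp$BIC[2])
  # a shuffled 4-level grouping carrying the same binary signal loses on AIC
  set.seed(48)
  lv <- paste0(grp_bin, sample(c("a", "b"), length(grp_bin), replace = TRUE))
  fit4 <- fit_zmmse_lmm(vis, setNames(lv, names(grp_bin)))
  cmp <- compare_lmm(binary = fit1, four_level = fit4)
  expect_equal(cmp$model[1], "binary")
  # fits on different data are rejected
  vis2 <- generate_trajectories(design_subjects(50, 50), cohort_config())
  fit_other <- fit_zmmse_lmm(vis2, grp_bin)
  expect_error(compare_lmm(a = fit1, b = fit_other), "same visit data")
})

test_that("degenerate grouping inputs are rejected", {
  subj <- design_subjects(10, 0)
  vis <- generate_trajectories(subj, cohort_config())
  grp <- setNames(rep("x", 10), subj$subject_id)
  expect_error(fit_zmmse_lmm(vis, grp), "groups")
})
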