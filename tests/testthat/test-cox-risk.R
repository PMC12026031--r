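fake_cox <- function(beta, times, hazards, horizon = 10) {
  structure(list(beta = beta,
                 baseline_cumhaz = data.frame(time = times, hazard = hazards),
                 horizon = horizon, n = 10, n_events = 5,
                 separation = FALSE),
            class = "ers_cox")
}

test_that("the Cox estimate maximizes the Breslow partial likelihood", {
  # 6-subject worked dataset with a tie
  out <- data.frame(subject_id = letters[1:6],
                    event = c(1, 1, 0, 1, 0, 1),
                    time = c(1.0, 2.0, 2.5, 3.0, 3.0, 4.5))
  x <- c(2, 1, 0, 3, 1, 0)
  fit <- fit_conversion_cox(out, setNames(x, out$subject_id))
  b_grid <- oracle_cox_grid(out$time, out$event, x)
  expect_equal(fit$beta, b_grid, tolerance = 1e-4)
  # scale equivariance: doubling the covariate halves the coefficient
  fit2 <- fit_conversion_cox(out, setNames(2 * x, out$subject_id))
  expect_equal(fit2$beta, fit$beta / 2, tolerance = 1e-6)
  # random instances, <= 8 subjects
  set.seed(51)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    out <- data.frame(subject_id = seq_len(n),
                      event = rbinom(n, 1, 0.7),
                      time = round(rexp(n, 0.3) + 0.1, 2))
    if (sum(out$event) == 0) out$event[1] <- 1
    x <- rnorm(n)
    fit <- suppressWarnings(fit_conversion_cox(out, x))
    if (!fit$separation) {
      expect_equal(fit$beta, oracle_cox_grid(out$time, out$event, x),
                   tolerance = 1e-3)
    }
  }
})

test_that("degenerate Cox inputs are rejected or flagged", {
  out <- data.frame(subject_id = 1:4, event = c(0, 0, 0, 0), time = 1:4)
  expect_error(fit_conversion_cox(out, 1:4), "event")
  out$event <- c(1, 1, 0, 0)
  expect_error(fit_conversion_cox(out, rep(1, 4)), "constant")
  # monotone separation: every event subject has the largest covariate in
  # its risk set, so the partial likelihood increases without bound
  out <- data.frame(subject_id = 1:8, event = rep(c(1, 0), each = 4),
                    time = c(1, 2, 3, 4, 0.5, 0.5, 0.5, 0.5))
  w <- capture_warnings(fit <- fit_conversion_cox(out, c(8, 7, 6, 5, 4, 3, 2, 1)))
  expect_true(any(grepl("separation", w)))
  expect_true(fit$separation)
})

test_that("conversion probability follows the Breslow closed form", {
  fit <- fake_cox(beta = log(2), times = c(1, 5), hazards = c(0.2, 0.5))
  expect_equal(predict_event_probability(fit, 1, horizon = 5), 1 - exp(-1))
  expect_equal(predict_event_probability(fit, 0, horizon = 1), 1 - exp(-0.2))
  # before the first event the cumulative hazard is zero
  expect_equal(predict_event_probability(fit, 3, horizon = 0.5), 0)
  # beyond the last step: warn and carry the last value forward
  expect_warning(p <- predict_event_probability(fit, 1, horizon = 20),
                 "last cumulative-hazard step")
  expect_equal(p, 1 - exp(-1))
})

test_that("empirical AUC equals the all-pairs Mann-Whitney statistic", {
  expect_equal(roc_auc(c(1, 2, 10, 20), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(roc_auc(c(1, 2, 2, 4), c(0, 0, 1, 1)),
               oracle_auc(c(1, 2, 2, 4), c(0, 0, 1, 1)))
  set.seed(52)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    s <- sample(round(rnorm(n), 1), n, replace = TRUE)
    l <- rbinom(n, 1, 0.4)
    if (sum(l) %in% c(0, n)) l[1:2] <- c(0, 1)
    expect_equal(roc_auc(s, l), oracle_auc(s, l))
    expect_equal(roc_auc(s, l), as.numeric(pROC::auc(l, s, direction = "<",
                                                     quiet = TRUE)))
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("DeLong components match direct enumeration and pROC", {
  set.seed(53)
  n <- 60
  l <- rbinom(n, 1, 0.4)
  l[1:2] <- c(0, 1)
  xa <- rnorm(n) + l
  xb <- 0.5 * xa + rnorm(n)
  d <- delong_compare(xa, xb, l)
  o <- oracle_delong(xa, xb, l)
  expect_equal(d$auc_a, o$auc_a)
  expect_equal(d$auc_b, o$auc_b)
  expect_equal(d$var_a, o$var_a)
  expect_equal(d$var_b, o$var_b)
  expect_equal(d$cov_ab, o$cov_ab)
  rt <- pROC::roc.test(pROC::roc(l, xa, direction = "<", quiet = TRUE),
                       pROC::roc(l, xb, direction = "<", quiet = TRUE),
                       method = "delong", paired = TRUE)
  expect_equal(d$p, as.numeric(rt$p.value), tolerance = 1e-10)
  # identical scores: zero difference, degenerate variance
  dd <- delong_compare(xa, xa, l)
  expect_true(dd$degenerate)
  expect_equal(dd$auc_a, dd$auc_b)
  expect_true(is.na(dd$z))
})

test_that("the 2x2 diagnostic summary matches the textbook formulas", {
  dt <- diagnostic_table(rep(c(TRUE, FALSE), c(60, 90)),
                         c(rep(c(TRUE, FALSE), c(40, 20)),
                           rep(c(TRUE, FALSE), c(10, 80))))
  expect_equal(c(dt$tp, dt$fp, dt$fn, dt$tn), c(40, 20, 10, 80))
  expect_equal(dt$odds_ratio, 16)
  expect_equal(dt$sensitivity, 0.8)
  expect_equal(dt$specificity, 0.8)
  expect_equal(dt$lr_pos, 4)
  expect_equal(dt$lr_neg, 0.25)
  expect_false(dt$corrected)
  # perfect classifier: Haldane-Anscombe correction keeps the OR finite
  dp <- diagnostic_table(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(dp$corrected)
  expect_true(is.finite(dp$odds_ratio))
  # random tables vs the direct formula
  set.seed(54)
  for (rep in 1:20) {
    cells <- rmultinom(1, 200, c(0.3, 0.2, 0.15, 0.35))[, 1] + 1
    ph <- rep(c(TRUE, TRUE, FALSE, FALSE), cells)
    ev <- rep(c(TRUE, FALSE, TRUE, FALSE), cells)
    dt <- diagnostic_table(ph, ev)
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    se <- sqrt(sum(1 / cells))
    expect_equal(dt$odds_ratio, or)
    expect_equal(dt$or_ci, exp(log(or) + c(-1, 1) * qnorm(0.975) * se))
  }
})

test_that("the Cox probability step cannot change the AUC when beta > 0", {
  set.seed(55)
  subj <- design_subjects(80, 80)
  cfg <- cohort_config()
  out <- generate_outcomes(subj, cfg)
  x <- as.integer(subj$group == "pathologic") + rnorm(160, sd = 0.2)
  fit <- fit_conversion_cox(out, setNames(x, subj$subject_id))
  expect_gt(fit$beta, 0)
  p <- predict_event_probability(fit, x)
  expect_equal(roc_auc(p, out$event), roc_auc(x, out$event), tolerance = 1e-12)
})

test_that("compare_risk_scores assembles AUCs and paired comparisons", {
  set.seed(56)
  subj <- design_subjects(90, 70)
  out <- generate_outcomes(subj, cohort_config())
  g <- as.integer(subj$group == "pathologic")
  scores <- list(ratio = g + rnorm(160, sd = 0.5),
                 ers = 2 * g + sample(0:2, 160, replace = TRUE))
  cmp <- compare_risk_scores(scores, out)
  expect_equal(cmp$auc$score, c("ratio", "ers"))
  expect_true(all(cmp$auc$auc > 0 & cmp$auc$auc < 1))
  expect_named(cmp$delong, "ratio vs ers")
  expect_false(cmp$delong[["ratio vs ers"]]$degenerate)
})
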