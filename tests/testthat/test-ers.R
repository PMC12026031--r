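# helper: build a one-row profile from zone choices on the default panel
# (cut-offs 600 / 60 / 400, ratio 0.05); multipliers place values clearly
# inside the requested zone
zone_profile <- function(a_zone, tau_zone, ratio = c("path", "normal", "absent")) {
  ratio <- match.arg(ratio)
  ab42 <- c(`0` = 900, `1` = 600, `2` = 300)[[as.character(a_zone)]]
  ptau <- c(`0` = 30, `1` = 60, `2` = 90)[[as.character(tau_zone)]]
  ab40 <- switch(ratio,
                 path = ab42 / 0.03,
                 normal = ab42 / 0.08,
                 absent = NA)
  data.frame(ab42 = ab42, ab40 = ab40, ptau = ptau, ttau = 200)
}

test_that("tau sub-score takes the higher of the two tau zone scores", {
  expect_equal(tau_subscore(2L, 0L), 2L)
  expect_equal(tau_subscore(1L, 1L), 1L)
  expect_equal(tau_subscore(0L, 0L), 0L)
  expect_equal(tau_subscore(c(0L, 1L), c(2L, 0L)), c(2L, 1L))
})

test_that("reference scoring cases reproduce the published cell logic", {
  panel <- default_panel()
  # clear AD profile: 2 + 2, ratio +1, clamped to 4
  e <- ers_score(data.frame(ab42 = 300, ab40 = 10000, ptau = 90, ttau = 650), panel)
  expect_equal(e$total, 4L)
  expect_equal(e$risk_class, factor("high", levels = c("low", "medium", "high")))
  # biomarker negative: 0 + 0, ratio -1, clamped to 0
  e <- ers_score(data.frame(ab42 = 900, ab40 = 12000, ptau = 30, ttau = 200), panel)
  expect_equal(e$total, 0L)
  expect_equal(as.character(e$risk_class), "low")
  # ratio-positive, normal Abeta1-42, clear tau pathology: 0 + 2 + 1 = 3
  e <- ers_score(data.frame(ab42 = 900, ab40 = 20000, ptau = 90, ttau = 650), panel)
  expect_equal(e$total, 3L)
  # same but ratio-negative: 0 + 2 - 1 = 1, low risk
  e <- ers_score(data.frame(ab42 = 900, ab40 = 12000, ptau = 90, ttau = 650), panel)
  expect_equal(e$total, 1L)
  expect_equal(as.character(e$risk_class), "low")
  # borderline-normal Abeta1-42 with ratio and tau pathology: 1 + 2 + 1 = 4
  e <- ers_score(data.frame(ab42 = 630, ab40 = 21000, ptau = 90, ttau = 650), panel)
  expect_equal(e$amyloid_subscore, 1L)
  expect_equal(e$total, 4L)
})

test_that("scores stay in 0..4 and the ratio adjustment is exactly +/-1 pre-clamp", {
  panel <- default_panel()
  for (a in 0:2) for (t_ in 0:2) for (r in c("path", "normal", "absent")) {
    p <- zone_profile(a, t_, r)
    e <- ers_score(p, panel)
    expect_equal(e$amyloid_subscore, a)
    expect_equal(e$tau_subscore, t_)
    expect_gte(e$total, 0L)
    expect_lte(e$total, 4L)
    expect_equal(e$total, max(0L, min(4L, a + t_ + e$ratio_adjustment)))
    expect_equal(e$suspicious_for_ad, e$total >= 2L)
    nr <- ers_score(p, panel, use_ratio = FALSE)
    expect_equal(nr$total, a + t_)
    if (r != "absent") {
      expect_equal(abs((e$sum_score + e$ratio_adjustment) - nr$total), 1L)
      # flipping the ratio moves the total by exactly 2 unless clamping binds
      flipped <- ers_score(zone_profile(a, t_, if (r == "path") "normal" else "path"),
                           panel)
      unclamped <- abs((e$sum_score + e$ratio_adjustment) -
                         (flipped$sum_score + flipped$ratio_adjustment))
      expect_equal(unclamped, 2L)
    }
  }
})

test_that("the ratio-free variant maps 0-1/2/3-4 to low/medium/high", {
  panel <- default_panel()
  expected <- c(`0` = "low", `1` = "low", `2` = "medium", `3` = "high", `4` = "high")
  for (a in 0:2) for (t_ in 0:2) {
    nr <- ers_score(zone_profile(a, t_, "absent"), panel)
    expect_equal(as.character(nr$risk_class), unname(expected[as.character(a + t_)]))
    expect_equal(nr$ratio_adjustment, 0L)
    expect_equal(nr$suspicious_for_ad, a + t_ >= 2L)
  }
})

test_that("the score is monotone in each marker's pathological direction", {
  panel <- default_panel()
  ab42_grid <- seq(1500, 200, by = -25)
  tot <- sapply(ab42_grid, function(v) {
    ers_score(data.frame(ab42 = v, ab40 = 12000, ptau = 55, ttau = 350), panel)$total
  })
  expect_true(all(diff(tot) >= 0))
  ptau_grid <- seq(20, 120, by = 2)
  tot <- sapply(ptau_grid, function(v) {
    ers_score(data.frame(ab42 = 700, ab40 = 12000, ptau = v, ttau = 350), panel)$total
  })
  expect_true(all(diff(tot) >= 0))
})

test_that("vectorized scoring agrees with the verbal-rule oracle", {
  set.seed(21)
  panel <- default_panel()
  prof <- random_profiles(2000, panel)
  got <- ers_score(prof, panel)$total
  want <- vapply(seq_len(nrow(prof)), function(i) {
    oracle_ers(prof$ab42[i], prof$ab40[i], prof$ptau[i], prof$ttau[i], panel)
  }, integer(1))
  expect_identical(got, want)
})

test_that("scoring requires the three mandatory analytes", {
  expect_error(ers_score(data.frame(ab42 = 600, ptau = NA, ttau = 300)), "ptau")
  expect_error(ers_score(data.frame(ab42 = 600, ttau = 300)), "ptau")
})
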