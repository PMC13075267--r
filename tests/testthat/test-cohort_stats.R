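default_slopes <- c(pitch_csd = 0.71, roll_csd = 3.63, yaw_csd = 4.17,
                    gen_var = 0.06)

age_term <- function(res, term = "age_c") {
  i <- match(term, res$fixed$term)
  c(estimate = res$fixed$estimate[i], se = res$fixed$se[i])
}

test_that("age slopes injected into a simulated cohort are recovered", {
  tab <- simulate_cohort(synth_cohort_config(n_children = c(ILA = 25, LLA = 25),
                                             seed = 41))
  for (met in names(default_slopes)) {
    res <- fit_age_lmm(tab, met)
    a <- age_term(res)
    expect_lt(abs(a[["estimate"]] - default_slopes[[met]]), 2 * a[["se"]])
    expect_gt(a[["se"]], 0)
    expect_equal(res$n_obs, 200L)
    expect_equal(res$n_children, 50L)
  }
})

test_that("cohorts generated identically show no cohort or interaction effect", {
  tab <- simulate_cohort(synth_cohort_config(n_children = c(ILA = 30, LLA = 30),
                                             seed = 42))
  res <- fit_age_lmm(tab, "roll_csd")
  coh <- age_term(res, "cohortILA")
  int <- age_term(res, "cohortILA:age_c")
  expect_lt(abs(coh[["estimate"]]), 2 * coh[["se"]])
  expect_lt(abs(int[["estimate"]]), 2 * int[["se"]])
})

test_that("angle-contrast model recovers level and slope differences", {
  cfg <- synth_cohort_config(n_children = c(ILA = 25, LLA = 25), seed = 43)
  tab <- simulate_cohort(cfg)
  res <- fit_angle_contrast_lmm(tab)
  # truth implied by the generator: contrasts of baselines at the mean age
  # (7.5 months) and of the per-month slopes
  slope_rp <- cfg$slope[["roll_csd"]] - cfg$slope[["pitch_csd"]]
  slope_yp <- cfg$slope[["yaw_csd"]] - cfg$slope[["pitch_csd"]]
  level_rp <- (cfg$baseline[["roll_csd"]] - cfg$baseline[["pitch_csd"]]) +
    slope_rp * (7.5 - 3)
  level_yp <- (cfg$baseline[["yaw_csd"]] - cfg$baseline[["pitch_csd"]]) +
    slope_yp * (7.5 - 3)
  for (chk in list(c("angleroll", level_rp), c("angleyaw", level_yp),
                   c("angleroll:age_c", slope_rp),
                   c("angleyaw:age_c", slope_yp))) {
    a <- age_term(res, chk[[1]])
    expect_lt(abs(a[["estimate"]] - as.numeric(chk[[2]])), 2 * a[["se"]])
  }
})

test_that("identical angle series yield null contrasts; scaling is equivariant", {
  tab <- simulate_cohort(synth_cohort_config(n_children = c(ILA = 20, LLA = 20),
                                             seed = 44))
  tab$roll_csd <- tab$pitch_csd
  tab$yaw_csd <- tab$pitch_csd
  res <- fit_angle_contrast_lmm(tab)
  for (term in c("angleroll", "angleyaw", "angleroll:age_c",
                 "angleyaw:age_c")) {
    a <- age_term(res, term)
    expect_lt(abs(a[["estimate"]]), 1e-8)
  }
  # doubling every circular SD doubles every estimate
  tab2 <- simulate_cohort(synth_cohort_config(n_children = c(ILA = 20, LLA = 20),
                                              seed = 44))
  tab3 <- tab2
  for (cl in c("pitch_csd", "roll_csd", "yaw_csd")) tab3[[cl]] <- 2 * tab3[[cl]]
  r2 <- fit_angle_contrast_lmm(tab2)
  r3 <- fit_angle_contrast_lmm(tab3)
  expect_equal(r3$fixed$estimate, 2 * r2$fixed$estimate, tolerance = 1e-6)
})

test_that("with no child-level variance the LMM collapses to least squares", {
  cfg <- synth_cohort_config(
    n_children = c(ILA = 15, LLA = 15),
    between_sd = c(pitch_csd = 0, roll_csd = 0, yaw_csd = 0, gen_var = 0),
    seed = 45)
  tab <- simulate_cohort(cfg)
  res <- suppressMessages(fit_age_lmm(tab, "roll_csd"))
  expect_true(res$singular)
  df <- as.data.frame(tab)
  df$cohort <- factor(df$cohort, levels = c("LLA", "ILA"))
  df$age_c <- df$age_months - mean(df$age_months)
  ols <- stats::lm(roll_csd ~ cohort + age_c, data = df)
  expect_equal(res$fixed$estimate, unname(stats::coef(ols)), tolerance = 1e-6)
})

test_that("p-value machinery is recorded and Satterthwaite df are finite", {
  tab <- simulate_cohort(synth_cohort_config(seed = 46))
  rw <- fit_age_lmm(tab, "yaw_csd", ddf = "wald")
  rs <- fit_age_lmm(tab, "yaw_csd", ddf = "satterthwaite")
  expect_equal(rw$p_method, "wald")
  expect_equal(rs$p_method, "satterthwaite")
  expect_true(all(is.finite(rs$fixed$df)))
  expect_equal(rw$fixed$estimate, rs$fixed$estimate, tolerance = 1e-9)
  expect_true(all(rw$fixed$p > 0 & rw$fixed$p <= 1))
})

test_that("Spearman correlation equals Pearson on ranks and handles contracts", {
  tab <- simulate_cohort(synth_cohort_config(seed = 47))
  out <- correlate_msel(tab, 9, 12)
  df <- as.data.frame(tab)
  x <- df[df$age_months == 9, c("child_id", "gen_var")]
  y <- df[df$age_months == 12, c("child_id", "msel_gm")]
  m <- merge(x, y, by = "child_id")
  oracle <- stats::cor(rank(m$gen_var), rank(m$msel_gm))
  expect_equal(out$r, oracle, tolerance = 1e-9)
  expect_equal(out$n, nrow(m))
  # strictly monotone pairs give r = 1
  tab2 <- tab
  tab2$msel_gm <- tab2$gen_var * 3 + 1
  expect_equal(correlate_msel(tab2, 9, 9)$r, 1)
  # future-to-past pairing is refused
  expect_error(correlate_msel(tab, 12, 9), "concurrent and future")
  # walking infants are excluded
  tab3 <- tab
  tab3$walking[tab3$age_months == 9][1:10] <- TRUE
  out3 <- correlate_msel(tab3, 9, 12)
  expect_equal(out3$n, out$n - 10)
})

test_that("a monotone metric-score link produces a strong concurrent correlation", {
  tab <- simulate_cohort(synth_cohort_config(msel_link = 10, msel_resid = 0.1,
                                             seed = 48))
  out <- correlate_msel(tab, 9, 9)
  expect_gt(out$r, 0.95)
  null_tab <- simulate_cohort(synth_cohort_config(msel_link = 0, seed = 48))
  expect_lt(abs(correlate_msel(null_tab, 9, 12)$r), 0.3)
})
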