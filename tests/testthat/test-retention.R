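test_that("correct_time is the affine map through the two anchors", {
  ## identity when the run shows no drift
  expect_equal(correct_time(7.3, ref = c(2, 10), obs = c(2, 10)), 7.3)
  ## stretch: observed 10 -> 12 while 2 stays put maps 7 back to 6
  expect_equal(correct_time(7.0, ref = c(2, 10), obs = c(2, 12)), 6.0)
  ## exact at an anchor
  expect_equal(correct_time(3.0, ref = c(2.7, 9.3), obs = c(3.0, 9.0)), 2.7)
  expect_equal(correct_time(9.0, ref = c(2.7, 9.3), obs = c(3.0, 9.0)), 9.3)
  expect_error(correct_time(5, ref = c(2, 10), obs = c(4, 4)), "degenerate")
})

test_that("correct_time composed with its inverse is the identity", {
  set.seed(41)
  for (i in 1:20) {
    ref <- sort(runif(2, 1, 20))
    obs <- ref * runif(1, 0.9, 1.1) + runif(1, -0.5, 0.5)
    t <- runif(5, 0, 30)
    there <- correct_time(t, ref, obs)
    back <- correct_time(there, ref = obs, obs = ref)
    expect_equal(back, t, tolerance = 1e-12)
  }
})

test_that("retention_factor implements (tR - t0) / t0", {
  expect_equal(retention_factor(5.0, 2.5), 1.0)
  expect_equal(retention_factor(27.5, 2.5), 10.0)
  expect_equal(retention_factor(4.1, 2.05), 1.0)
  expect_error(retention_factor(2.4, 2.5), "non-retained")
  expect_error(retention_factor(5, -1), "positive")
})

test_that("fit_lss recovers an exact LSS line", {
  phi <- seq(0.1, 0.5, by = 0.1)
  ser <- data.frame(phi = phi, tR = 2.5 * (1 + 10^(2 - 3 * phi)), t0 = 2.5)
  fit <- fit_lss(ser)
  expect_s3_class(fit, "lss_fit")
  expect_equal(fit$logkw, 2, tolerance = 1e-10)
  expect_equal(fit$S, 3, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_lt(fit$rss, 1e-20)
  expect_equal(fit$n_points, 5)
})

test_that("fit_lss equals the closed-form OLS oracle on noisy data", {
  set.seed(51)
  for (i in 1:10) {
    phi <- sort(runif(6, 0.05, 0.7))
    logk <- 1.8 - 2.6 * phi + rnorm(6, 0, 0.02)
    t0 <- 2.0
    ser <- data.frame(phi = phi, tR = t0 * (1 + 10^logk), t0 = t0)
    fit <- suppressWarnings(fit_lss(ser))
    orc <- ols_oracle(matrix(phi), log10(retention_factor(ser$tR, t0)))
    expect_equal(fit$logkw, orc$coef[1], tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(fit$S, -orc$coef[2], tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(unname(c(fit$se_logkw, fit$se_S)), unname(orc$se),
                 tolerance = 1e-10)
  }
})

test_that("fit_lss is invariant to point order and replicate averaging", {
  set.seed(61)
  phi <- seq(0.1, 0.5, by = 0.1)
  ser <- data.frame(phi = phi, tR = 2.2 * (1 + 10^(1.4 - 2.2 * phi)), t0 = 2.2)
  base <- fit_lss(ser)
  shuffled <- fit_lss(ser[sample(nrow(ser)), ])
  expect_equal(shuffled$logkw, base$logkw)
  expect_equal(shuffled$S, base$S)
  ## duplicating every point (a replicate-averaged set) changes nothing
  doubled <- fit_lss(rbind(ser, ser))
  expect_equal(doubled$logkw, base$logkw)
  expect_equal(doubled$S, base$S)
  expect_equal(doubled$n_points, base$n_points)
})

test_that("fit_lss applies the anchor correction before fitting", {
  phi <- seq(0.1, 0.5, by = 0.1)
  clean <- data.frame(phi = phi, tR = 2.5 * (1 + 10^(1.8 - 2.5 * phi)),
                      t0 = 2.5)
  drift <- function(t) 1.03 * t + 0.2
  drifted <- clean
  drifted$tR <- drift(clean$tR)
  drifted$anchor1_ref <- 4
  drifted$anchor1_obs <- drift(4)
  drifted$anchor2_ref <- 12
  drifted$anchor2_obs <- drift(12)
  expect_equal(fit_lss(drifted)$logkw, fit_lss(clean)$logkw,
               tolerance = 1e-10)
  expect_equal(fit_lss(drifted)$S, fit_lss(clean)$S, tolerance = 1e-10)
})

test_that("fit_lss rejects deficient designs and warns on poor linearity", {
  ser <- data.frame(phi = c(0.1, 0.2, 0.3), tR = c(20, 12, 8), t0 = 2)
  expect_error(fit_lss(ser), "insufficient")
  ser4 <- data.frame(phi = rep(0.2, 4), tR = c(10, 10.1, 9.9, 10), t0 = 2)
  expect_error(fit_lss(ser4), "insufficient|degenerate")
  set.seed(71)
  wiggly <- data.frame(phi = seq(0.1, 0.6, 0.1),
                       tR = 2 * (1 + 10^(1 - 1.5 * seq(0.1, 0.6, 0.1) +
                                           rnorm(6, 0, 0.15))), t0 = 2)
  expect_warning(fit_lss(wiggly), "below 0.99")
})

test_that("logkw extrapolation is unchanged by rescaling the phi axis", {
  ## expressing phi in different units (here halved) rescales S but leaves
  ## the aqueous-intercept logkw alone
  phi <- seq(0.1, 0.6, by = 0.1)
  ser <- data.frame(phi = phi, tR = 2 * (1 + 10^(1.6 - 2 * phi)), t0 = 2)
  half <- transform(ser, phi = phi / 2)
  expect_equal(fit_lss(half)$logkw, fit_lss(ser)$logkw, tolerance = 1e-10)
  expect_equal(fit_lss(half)$S, 2 * fit_lss(ser)$S, tolerance = 1e-10)
})

test_that("build_logkw_matrix assembles per-series fits", {
  set.seed(81)
  truth <- expand.grid(compound_id = c("a", "b", "c"), pH = c(7, 9),
                       stringsAsFactors = FALSE)
  truth$logkw <- runif(6, 0.5, 3)
  truth$S <- runif(6, 1.5, 4)
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    phi <- seq(0.1, 0.5, by = 0.1)
    data.frame(compound_id = truth$compound_id[i], pH = truth$pH[i],
               phi = phi,
               tR = 2 * (1 + 10^(truth$logkw[i] - truth$S[i] * phi)), t0 = 2)
  })
  ret <- do.call(rbind, rows)
  mat <- build_logkw_matrix(ret)
  for (i in seq_len(nrow(truth))) {
    got <- mat[mat$compound_id == truth$compound_id[i],
               as.character(truth$pH[i])]
    expect_equal(got, truth$logkw[i], tolerance = 1e-10)
  }
  ## empty input gives an empty table
  expect_equal(nrow(build_logkw_matrix(ret[0, ], ph = c(7, 9))), 0)
  ## a missing cell is NA and logged
  expect_message(m2 <- build_logkw_matrix(ret[ret$compound_id != "b" |
                                                ret$pH != 9, ]),
                 "no measurements")
  expect_true(is.na(m2[m2$compound_id == "b", "9"]))
})

test_that("the published logkw matrix passes through the reader unchanged", {
  kw <- study_logkw()
  expect_equal(nrow(kw), 42)
  expect_named(kw, c("compound_id", "7", "8", "9", "10"))
  expect_equal(kw[kw$compound_id == "9", "7"], 0.36)   # benzylamine pH 7
  expect_equal(kw[kw$compound_id == "27", "10"], 4.54) # dibenzylamine pH 10
})
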