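test_that("fit_mlr matches the normal-equations oracle", {
  set.seed(91)
  for (i in 1:10) {
    n <- sample(10:25, 1)
    d <- data.frame(logkw = runif(n, -0.5, 4.5), ne = runif(n),
                    A = runif(n, 0, 0.4), B = runif(n, 0.3, 1))
    d$logD <- 0.9 * d$logkw - 0.7 * d$ne + 0.2 * d$A - 0.4 * d$B +
      rnorm(n, 0, 0.1)
    m <- fit_mlr(d, descriptors = c("ne", "A", "B"))
    orc <- ols_oracle(as.matrix(d[, c("logkw", "ne", "A", "B")]), d$logD)
    expect_equal(unname(m$coef), unname(orc$coef[c(1, 2, 3, 4, 5)]),
                 tolerance = 1e-10)
    expect_equal(unname(m$se), unname(orc$se), tolerance = 1e-10)
    expect_equal(m$r2, orc$r2, tolerance = 1e-12)
    expect_equal(m$r2_adj, orc$r2_adj, tolerance = 1e-12)
  }
})

test_that("two points are interpolated exactly by the univariate model", {
  d <- data.frame(logkw = c(1, 3), logD = c(0.8, 2.9))
  m <- suppressWarnings(fit_mlr(d))
  expect_equal(unname(m$coef["logkw"]), diff(d$logD) / diff(d$logkw))
  expect_equal(m$r2, 1)
  expect_lt(m$rss, 1e-25)
})

test_that("fit_mlr rejects deficient or collinear designs", {
  d <- data.frame(logkw = 1:6, ne = (1:6) / 2)  # ne is 0.5 * logkw
  d$logD <- d$logkw
  expect_error(fit_mlr(d, "ne"), "collinear.*ne")
  expect_error(fit_mlr(d[1:2, ], "ne"), "at least")
  d$ne[1] <- NA
  expect_error(fit_mlr(d, "ne"), "missing cells")
})

test_that("coefficients are invariant to row order", {
  set.seed(101)
  d <- study_frame(8, ids = 1:14)
  m1 <- fit_mlr(d, ph = 8)
  m2 <- fit_mlr(d[sample(nrow(d)), ], ph = 8)
  expect_equal(m1$coef, m2$coef)
  expect_equal(m1$r2, m2$r2)
})

test_that("r2 never decreases across the nested subset lattice", {
  set.seed(111)
  for (rep in 1:5) {
    n <- 23
    d <- data.frame(logkw = runif(n, -0.5, 4.5), ne = runif(n),
                    A = runif(n, 0, 0.4), B = runif(n, 0.3, 1))
    d$logD <- 0.95 * d$logkw - 0.6 * d$ne + rnorm(n, 0, 0.1)
    sel <- select_model(d)
    r2 <- setNames(sel$ranking$r2, sel$ranking$subset)
    subsets <- list(character(0), "ne", "A", "B", c("ne", "A"),
                    c("ne", "B"), c("A", "B"), c("ne", "A", "B"))
    for (s1 in subsets) for (s2 in subsets) {
      if (length(s1) < length(s2) && all(s1 %in% s2)) {
        lab1 <- if (length(s1) == 0) "(none)" else paste(s1, collapse = "+")
        lab2 <- paste(s2, collapse = "+")
        expect_gte(r2[[lab2]], r2[[lab1]] - 1e-12)
      }
    }
  }
})

test_that("select_model recovers the generating subset when A and B are noise", {
  set.seed(121)
  n <- 23
  d <- data.frame(logkw = runif(n, -0.5, 4.5), ne = runif(n),
                  A = runif(n, 0, 0.4), B = runif(n, 0.3, 1))
  d$logD <- 1.0 * d$logkw - 0.8 * d$ne + rnorm(n, 0, 0.1)
  sel <- select_model(d)
  expect_equal(sel$model$subset, "ne")
  expect_equal(nrow(sel$ranking), 8)
})

test_that("select_model with a single candidate returns it unchanged", {
  d <- study_frame(7, ids = 1:14)
  d$ne <- default_ne(study_compounds()$pKa1[1:14], 7)
  sel <- select_model(d, candidates = "ne")
  expect_equal(nrow(sel$ranking), 2)  # with and without ne
  direct <- fit_mlr(d, sel$model$subset)
  expect_equal(sel$model$coef, direct$coef)
})

test_that("noise-free data from a five-term coefficient set is recovered exactly", {
  ## generating vector patterned on the published pH 9.0 multi-parameter model
  beta <- c(`(Intercept)` = 0.21, logkw = 0.93, ne = -0.29, A = 0.21,
            B = -0.49)
  set.seed(131)
  n <- 23
  d <- data.frame(logkw = runif(n, -0.5, 4.5), ne = runif(n),
                  A = runif(n, 0, 0.4), B = runif(n, 0.3, 1))
  d$logD <- beta["(Intercept)"] + beta["logkw"] * d$logkw +
    beta["ne"] * d$ne + beta["A"] * d$A + beta["B"] * d$B
  sel <- suppressWarnings(select_model(d))
  expect_equal(sort(sel$model$subset), c("A", "B", "ne"))
  expect_equal(sel$model$coef[names(beta)], beta, tolerance = 1e-8)
})

test_that("model_report renders published-style equations and round-trips", {
  m <- fit_mlr(study_frame(8, ids = 1:14), ph = 8)
  expect_equal(model_report(m),
               "logD = (1.02 ± 0.07) logkw - (0.21 ± 0.12)")
  ## parser recovers the rounded estimates from the rendered string
  d <- study_frame(9, ids = 1:14)
  d$ne <- default_ne(study_compounds()$pKa1[1:14], 9)
  m2 <- fit_mlr(d, "ne", ph = 9)
  parsed <- chromlogd:::parse_model_report(model_report(m2))
  expect_equal(parsed$coef[c("logkw", "ne", "(Intercept)")],
               round(m2$coef[c("logkw", "ne", "(Intercept)")], 2),
               tolerance = 1e-12)
  expect_equal(unname(parsed$se), unname(round(m2$se[c(2, 3, 1)], 2)))
  ## degenerate all-zero render stays parseable
  m0 <- m
  m0$coef[] <- 0
  m0$se[] <- 0
  expect_match(model_report(m0), "^logD = \\(0\\.00 ± 0\\.00\\) logkw")
})

test_that("removing benzylamine strictly improves the pH 7 univariate fit", {
  d <- study_frame(7, ids = 1:14)
  with_bz <- fit_mlr(d, ph = 7)
  without_bz <- fit_mlr(d[d$compound_id != "9", ], ph = 7)
  expect_gt(without_bz$r2, with_bz$r2)
  ## the improvement is large, as the retention outlier dominates the residual
  expect_gt(without_bz$r2 - with_bz$r2, 0.05)
})
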