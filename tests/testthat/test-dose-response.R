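test_that("a symmetric response pattern puts TD50 at the midpoint", {
  e <- make_counts_experiment(c(18, 22), c(5, 5), c(1, 4))
  fit <- fit_dose_response(e, use_effective = FALSE)
  expect_equal(fit$td50, 20, tolerance = 1e-8)
  expect_true(fit$converged)
  expect_false(fit$se_estimated)
})

test_that("the fitted curve passes through 50% at TD50", {
  e <- make_counts_experiment(c(14, 16, 18, 20), c(5, 6, 5, 5),
                              c(0, 2, 4, 5))
  for (link in c("logit", "probit")) {
    fit <- fit_dose_response(e, use_effective = FALSE, link = link)
    F_ <- if (link == "logit") plogis else pnorm
    expect_equal(F_(fit$b0 + fit$b1 * fit$td50), 0.5, tolerance = 1e-10)
  }
})

test_that("the optimum dominates random parameter perturbations", {
  e <- make_counts_experiment(c(14, 16, 18, 20), c(5, 6, 5, 5),
                              c(0, 2, 4, 5))
  fit <- fit_dose_response(e, use_effective = FALSE)
  ll <- function(b0, b1) {
    p <- pmin(pmax(plogis(b0 + b1 * fit$groups$total_dose), 1e-12),
              1 - 1e-12)
    sum(fit$groups$r * log(p) + (fit$groups$n - fit$groups$r) *
          log1p(-p))
  }
  set.seed(42)
  for (i in 1:100) {
    cand <- ll(fit$b0 + rnorm(1, 0, 0.5), fit$b1 + rnorm(1, 0, 0.1))
    expect_lte(cand, fit$loglik + 1e-9)
  }
})

test_that("the ML fitter agrees with glm on integer-count data", {
  e <- make_counts_experiment(c(14, 16, 18, 20), c(5, 6, 5, 5),
                              c(0, 2, 4, 5))
  fit <- fit_dose_response(e, use_effective = FALSE)
  g <- e$groups
  gl <- glm(cbind(r_raw, n_raw - r_raw) ~ total_dose,
            family = binomial, data = g)
  expect_equal(fit$b0, unname(coef(gl)[1]), tolerance = 1e-6)
  expect_equal(fit$b1, unname(coef(gl)[2]), tolerance = 1e-6)
  expect_equal(fit$cov, unname(vcov(gl)), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(fit$td50, -coef(gl)[[1]] / coef(gl)[[2]],
               tolerance = 1e-6)
})

test_that("effective counts equal to raw counts give identical fits", {
  e <- make_counts_experiment(c(14, 16, 18, 20), c(5, 5, 5, 5),
                              c(0, 1, 4, 5))
  # complete follow-up: actuarial correction is the identity
  f_raw <- fit_dose_response(e, use_effective = FALSE)
  f_eff <- fit_dose_response(e, use_effective = TRUE)
  expect_equal(f_eff$td50, f_raw$td50, tolerance = 1e-10)
  expect_equal(f_eff$se_td50, f_raw$se_td50, tolerance = 1e-8)
})

test_that("complete separation triggers the midpoint + fallback branch", {
  e <- make_counts_experiment(c(15, 16), c(5, 5), c(0, 5))
  fit <- fit_dose_response(e, use_effective = FALSE)
  expect_true(fit$separation)
  expect_true(fit$se_estimated)
  expect_equal(fit$td50, 15.5)
  expect_equal(fit$se_td50, 0.25)
})

test_that("constant response patterns are rejected as unidentifiable", {
  e0 <- make_counts_experiment(c(15, 16), c(5, 5), c(0, 0))
  expect_error(fit_dose_response(e0, use_effective = FALSE),
               "unidentifiable")
  e1 <- make_counts_experiment(c(15, 16), c(5, 5), c(5, 5))
  expect_error(fit_dose_response(e1, use_effective = FALSE),
               "unidentifiable")
})

test_that("identical doses are pooled before fitting", {
  a <- make_counts_experiment(c(16, 18), c(10, 10), c(2, 8))
  b <- a
  # split each group into two half-groups at the same dose
  g <- a$groups
  b$groups <- rbind(
    transform(g, n_raw = n_raw / 2, r_raw = r_raw / 2),
    transform(g, n_raw = n_raw / 2, r_raw = r_raw / 2))
  f_a <- fit_dose_response(a, use_effective = FALSE)
  f_b <- fit_dose_response(b, use_effective = FALSE)
  expect_equal(f_a$td50, f_b$td50, tolerance = 1e-10)
  expect_equal(f_a$b1, f_b$b1, tolerance = 1e-8)
})

test_that("fit recovers a known TD50 within its own 90% CL in at least
           85 of 100 seeded replicates", {
  hits <- 0
  for (s in 1:100) {
    e <- simulate_experiment(
      td50_true = 17.5, dose_levels = 15:20, n_fractions = 6,
      let_value = 99, slope_b1 = 2, group_size = 5,
      dropout_prob = 0, seed = s, experiment_id = "rec")
    fit <- tryCatch(fit_dose_response(e, use_effective = FALSE),
                    error = function(e) NULL)
    if (is.null(fit)) next
    cl <- if (!is.null(fit$cl90) && all(is.finite(fit$cl90))) fit$cl90
    else fit$td50 + c(-1, 1) * qnorm(0.95) * fit$se_td50
    if (cl[1] <= 17.5 && 17.5 <= cl[2]) hits <- hits + 1
  }
  expect_gte(hits, 85)
})

test_that("fallback SE rule is 25% of the 0-to-100% dose gap", {
  e <- make_counts_experiment(c(25.5, 28.5, 31.5, 34.5),
                              c(5, 4, 5, 5), c(0, 2, 5, 5))
  expect_equal(estimate_se_fallback(e), 0.25 * (31.5 - 25.5))

  e2 <- make_counts_experiment(c(15, 16), c(5, 5), c(0, 5))
  expect_equal(estimate_se_fallback(e2), 0.25)

  # overlap: 100% group below the highest 0% group -> bracket 50%
  e3 <- make_counts_experiment(c(14, 16, 18), c(5, 5, 5), c(5, 0, 5))
  expect_equal(estimate_se_fallback(e3), 0.25 * 2)

  # no 0% or no 100% level: no estimate possible
  e4 <- make_counts_experiment(c(15, 16), c(5, 5), c(1, 4))
  expect_error(estimate_se_fallback(e4), "cannot be estimated")
})

test_that("Fieller limits reproduce the published ratio interval", {
  cl <- fieller_cl(57.0, 2.0, 39.1, 0.4, cov = 0, level = 0.90)
  expect_equal(round(cl[["low"]], 2), 1.37)
  expect_equal(round(cl[["high"]], 2), 1.55)
})

test_that("Fieller limits degenerate and unbounded cases behave", {
  cl <- fieller_cl(3, 0, 2, 0)
  expect_equal(as.numeric(cl), c(1.5, 1.5))
  cl2 <- fieller_cl(3, 0.5, 0.5, 2)   # g >> 1
  expect_false(attr(cl2, "bounded"))
  expect_true(all(is.na(cl2)))
})

test_that("Fieller limits narrow monotonically as both SEs shrink", {
  widths <- vapply(c(1, 0.5, 0.25, 0.1), function(f) {
    cl <- fieller_cl(57, 2 * f, 39.1, 0.4 * f)
    cl[["high"]] - cl[["low"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("Fieller limits match Monte-Carlo ratio quantiles", {
  set.seed(1234)
  n <- 2e5
  a <- rnorm(n, 30, 3); b <- rnorm(n, 20, 1.5)
  q <- quantile(a / b, c(0.05, 0.95), names = FALSE)
  cl <- fieller_cl(30, 3, 20, 1.5, cov = 0, level = 0.90)
  expect_equal(cl[["low"]], q[1], tolerance = 0.01)
  expect_equal(cl[["high"]], q[2], tolerance = 0.01)
})
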