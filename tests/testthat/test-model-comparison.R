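mk_table <- function(rbe, let = c(16, 21, 36, 45, 66, 99), fx = 6,
                     se = NULL) {
  t <- data.frame(let = let, n_fractions = fx, rbe = rbe)
  if (!is.null(se)) t$se <- se
  t
}

test_that("percent deviation has the model-vs-measurement sign
           convention", {
  e <- mk_table(c(2.0, 4.0), let = c(16, 99))
  m <- mk_table(c(1.8, 3.6), let = c(16, 99))
  d <- percent_deviation(m, e)
  expect_equal(d$dev_pct, c(-10, -10))
  expect_equal(percent_deviation(e, e)$dev_pct, c(0, 0))
})

test_that("key mismatches are reported with the missing keys", {
  e <- mk_table(c(2, 3), let = c(16, 99))
  m <- mk_table(c(2, 3), let = c(16, 66))
  expect_error(percent_deviation(m, e), "99")
})

test_that("region averages reproduce published summary arithmetic", {
  # in-peak means across the three measured fractionation schedules
  lem4 <- region_average(c(-6.6, -7.0, -11.3))
  expect_equal(lem4[["mean_pct"]], -8.3, tolerance = 1e-9)
  lem1 <- region_average(c(-20.7, -19.9, -19.9))
  expect_equal(lem1[["mean_pct"]], -20.1667, tolerance = 1e-4)
  expect_equal(lem1[["sd_pct"]], sd(c(-20.7, -19.9, -19.9)))
})

test_that("single-point regions report zero SD with a flag", {
  r <- region_average(-5)
  expect_equal(r[["sd_pct"]], 0)
  expect_true(attr(r, "single_point"))
})

test_that("region averages combine consistently over a partition", {
  d <- data.frame(let = c(16, 21, 36, 45, 66, 99), n_fractions = 6,
                  dev_pct = c(-5, -7, -12, -15, -20, -25))
  ent <- region_average(d, c(16, 21))
  sob <- region_average(d, c(36, 45, 66, 99))
  all_ <- region_average(d, c(16, 21, 36, 45, 66, 99))
  expect_equal(all_[["mean_pct"]],
               (2 * ent[["mean_pct"]] + 4 * sob[["mean_pct"]]) / 6)
})

test_that("deviation is antisymmetric up to the ratio of the bases", {
  e <- mk_table(c(2.0, 3.1, 4.2), let = c(16, 45, 99))
  m <- mk_table(c(1.7, 3.3, 3.6), let = c(16, 45, 99))
  d_me <- percent_deviation(m, e)$dev_pct
  d_em <- percent_deviation(e, m)$dev_pct
  expect_equal(d_me, -d_em * (m$rbe / e$rbe), tolerance = 1e-10)
})

test_that("polynomial LET trends interpolate and honour weights", {
  t3 <- data.frame(let = c(10, 20, 30), rbe = c(1, 2, 3))
  cf1 <- fit_rbe_let_poly(t3, order = 1)
  expect_equal(as.numeric(cf1), c(0, 0.1), tolerance = 1e-10)

  t3$rbe <- c(1, 2.5, 3)
  cf2 <- fit_rbe_let_poly(t3, order = 2)
  pred <- cf2[[1]] + cf2[[2]] * t3$let + cf2[[3]] * t3$let^2
  expect_equal(pred, t3$rbe, tolerance = 1e-10)

  t4 <- data.frame(let = c(10, 20, 30, 40), rbe = c(1, 2.4, 2.9, 4.2),
                   se = c(0.1, 0.5, 0.5, 0.1))
  cw <- fit_rbe_let_poly(t4, order = 1)
  cu <- fit_rbe_let_poly(t4, order = 1, weighted = FALSE)
  # normal-equations oracle for the weighted straight line
  w <- 1 / t4$se^2
  X <- cbind(1, t4$let)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * t4$rbe))
  expect_equal(as.numeric(cw), as.numeric(beta), tolerance = 1e-10)
  expect_false(isTRUE(all.equal(as.numeric(cw), as.numeric(cu))))
})

test_that("slope ratios reproduce constructed and hand-computed
           values", {
  region <- c(36, 45, 66, 99)
  e <- mk_table(c(2.0, 2.2, 3.1, 3.3), let = region)
  expect_equal(slope_ratio(e, e, region)[["ratio"]], 1)

  m <- e; m$rbe <- 1 + 0.5 * (e$rbe - 1)  # slope exactly halved
  expect_equal(slope_ratio(m, e, region)[["ratio"]], 0.5,
               tolerance = 1e-10)

  # closed-form OLS oracle on a shallow model over 4 points
  shallow <- mk_table(c(2.1, 2.15, 2.4, 2.5), let = region)
  ols <- function(x, y) {
    xm <- mean(x); ym <- mean(y)
    sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  }
  want <- ols(region, shallow$rbe) / ols(region, e$rbe)
  expect_equal(slope_ratio(shallow, e, region)[["ratio"]], want,
               tolerance = 1e-12)

  flat <- e; flat$rbe <- rep(2.5, 4)
  expect_error(slope_ratio(m, flat, region), "slope")
})

test_that("slope ratio is invariant under affine rescaling of the LET
           axis", {
  region <- c(36, 45, 66, 99)
  e <- mk_table(c(2.0, 2.2, 3.1, 3.3), let = region)
  m <- mk_table(c(1.9, 2.0, 2.5, 2.8), let = region)
  r0 <- slope_ratio(m, e, region)[["ratio"]]
  resc <- function(t) transform(t, let = 3 * let + 7)
  r1 <- slope_ratio(resc(m), resc(e), 3 * region + 7)[["ratio"]]
  expect_equal(r1, r0, tolerance = 1e-12)
})

test_that("alpha/beta rises with LET for the published table", {
  cf <- fit_ab_vs_let(ab_carbon)
  expect_gt(cf[["slope"]], 0)

  two <- data.frame(let = c(10, 50), alpha_beta = c(5, 25))
  cf2 <- fit_ab_vs_let(two)
  expect_equal(as.numeric(cf2), c(0, 0.5), tolerance = 1e-10)

  flat <- data.frame(let = c(10, 30, 50), alpha_beta = c(7, 7, 7))
  expect_equal(fit_ab_vs_let(flat)[["slope"]], 0, tolerance = 1e-12)
})

test_that("the table-level benchmark aggregates per fraction number or
           per LET", {
  e6 <- mk_table(c(1.46, 1.69, 1.98, 2.12, 3.07, 3.26))
  e1 <- mk_table(c(1.3, 1.4, 1.6, 1.7, 2.1, 2.2), fx = 1)
  exp_tab <- rbind(e6, e1)
  model <- transform(exp_tab, rbe = rbe * 0.9)  # uniform -10%
  cmp <- compare_rbe_tables(model, exp_tab)
  expect_s3_class(cmp, "rbe_comparison")
  expect_equal(nrow(cmp$summary), 2)
  expect_equal(cmp$summary$sobp_mean_pct, c(-10, -10), tolerance = 1e-9)
  expect_equal(cmp$summary$slope_ratio, c(0.9, 0.9), tolerance = 1e-9)

  cmp2 <- compare_rbe_tables(model, exp_tab,
                             aggregate_over = "fractions")
  expect_equal(nrow(cmp2$summary), 6)
  expect_equal(cmp2$summary$mean_pct, rep(-10, 6), tolerance = 1e-9)
})
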