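.check_rbe_table <- function(x, name = deparse(substitute(x))) {
  stopifnot(is.data.frame(x))
  need <- c("let", "n_fractions", "rbe")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop(name, " lacks column(s): ", paste(miss, collapse = ", "))
  key <- paste(x$let, x$n_fractions)
  if (anyDuplicated(key))
    stop(name, " has duplicate (let, n_fractions) keys")
  invisible(x)
}

#' Per-point percent deviation of model RBE from experimental RBE
#'
#' Matches the two tables on the key (LET, fraction number) and
#' returns \code{dev = 100 * (rbe_model - rbe_exp) / rbe_exp}, so that
#' a model underestimating the measured RBE gives negative values.
#'
#' @param model,experiment data.frames with columns \code{let},
#'   \code{n_fractions}, \code{rbe} (an \code{se} column is carried
#'   along when present); fraction number may be \code{Inf} for
#'   low-dose-limit rows.
#' @return data.frame with the matched keys, both RBE values and
#'   \code{dev_pct}.
#' @export
percent_deviation <- function(model, experiment) {
  .check_rbe_table(model, "model")
  .check_rbe_table(experiment, "experiment")
  km <- paste(model$let, model$n_fractions)
  ke <- paste(experiment$let, experiment$n_fractions)
  missing_in_model <- setdiff(ke, km)
  missing_in_exp <- setdiff(km, ke)
  if (length(missing_in_model) > 0 || length(missing_in_exp) > 0)
    stop("key mismatch between tables; missing in model: {",
         paste(missing_in_model, collapse = "; "),
         "}; missing in experiment: {",
         paste(missing_in_exp, collapse = "; "), "}")
  m <- model[match(ke, km), ]
  data.frame(
    let = experiment$let,
    n_fractions = experiment$n_fractions,
    rbe_exp = experiment$rbe,
    rbe_model = m$rbe,
    dev_pct = 100 * (m$rbe - experiment$rbe) / experiment$rbe
  )
}

#' Mean and SD of percent deviations over an LET region
#'
#' Arithmetic mean and sample standard deviation (denominator n-1) of
#' the per-point deviations whose LET lies in \code{region}.  With a
#' single point the SD is reported as 0 and flagged.
#'
#' @param devs either the data.frame from [percent_deviation()] or a
#'   bare numeric vector of percent deviations.
#' @param region LET values defining the region; ignored when
#'   \code{devs} is a bare vector.
#' @return Named vector \code{c(mean_pct, sd_pct)} with attributes
#'   \code{n} and \code{single_point}.
#' @export
region_average <- function(devs, region = NULL) {
  if (is.data.frame(devs)) {
    if (!is.null(region)) devs <- devs[devs$let %in% region, , drop = FALSE]
    v <- devs$dev_pct
  } else {
    v <- as.numeric(devs)
  }
  if (length(v) == 0) stop("no deviation points in region")
  single <- length(v) == 1
  out <- c(mean_pct = mean(v), sd_pct = if (single) 0 else sd(v))
  attr(out, "n") <- length(v)
  attr(out, "single_point") <- single
  out
}

#' Polynomial fit of RBE against LET
#'
#' Least-squares polynomial (default order 2) of RBE on LET, using
#' inverse-variance weights when the table carries finite positive
#' SEs.
#'
#' @param table RBE table (columns \code{let}, \code{rbe}, optional
#'   \code{se}).
#' @param order polynomial order (default 2).
#' @param weighted use \code{1/se^2} weights when available (default
#'   TRUE).
#' @return Named coefficient vector (intercept first) with the
#'   underlying \code{lm} fit in attribute \code{"fit"}.
#' @export
fit_rbe_let_poly <- function(table, order = 2, weighted = TRUE) {
  stopifnot(all(c("let", "rbe") %in% names(table)))
  if (nrow(table) < order + 1)
    stop("need at least order + 1 points")
  w <- NULL
  if (weighted && !is.null(table$se) &&
      all(is.finite(table$se)) && all(table$se > 0))
    w <- 1 / table$se^2
  fit <- lm(rbe ~ poly(let, degree = order, raw = TRUE),
            data = table, weights = w)
  cf <- setNames(coef(fit), paste0("c", 0:order))
  attr(cf, "fit") <- fit
  cf
}

#' Ratio of model to experimental RBE-vs-LET slope over a region
#'
#' Fits the trend of RBE against LET over the region points for the
#' model and the experimental table and returns the ratio
#' model-slope / experimental-slope with an SE propagated from both
#' slope SEs (zero covariance).  The default trend is a straight-line
#' least-squares fit; \code{"poly_deriv"} uses the derivative of the
#' order-2 polynomial at the region's mean LET, \code{"endpoint"} the
#' difference quotient between the extreme region points.
#'
#' @param model,experiment RBE tables restricted to one fraction
#'   number (columns \code{let}, \code{rbe}).
#' @param region LET values defining the region.
#' @param method \code{"regression"} (default), \code{"poly_deriv"} or
#'   \code{"endpoint"}.
#' @return Named vector \code{c(ratio, se)} (SE is NA for the
#'   endpoint method).
#' @export
slope_ratio <- function(model, experiment, region,
                        method = c("regression", "poly_deriv",
                                   "endpoint")) {
  method <- match.arg(method)
  sub <- function(t) {
    t <- t[t$let %in% region, , drop = FALSE]
    if (nrow(t) < 2) stop("need at least two region points per table")
    t[order(t$let), , drop = FALSE]
  }
  m <- sub(model); e <- sub(experiment)
  slope <- function(t) {
    if (method == "regression") {
      f <- lm(rbe ~ let, data = t)
      c(coef(f)[["let"]],
        if (nrow(t) > 2)
          suppressWarnings(
            summary(f)$coefficients["let", "Std. Error"])
        else 0)
    } else if (method == "poly_deriv") {
      if (nrow(t) < 3) stop("poly_deriv needs >= 3 region points")
      f <- lm(rbe ~ poly(let, 2, raw = TRUE), data = t)
      c(coef(f)[[2]] + 2 * coef(f)[[3]] * mean(t$let), NA_real_)
    } else {
      k <- nrow(t)
      c((t$rbe[k] - t$rbe[1]) / (t$let[k] - t$let[1]), NA_real_)
    }
  }
  sm <- slope(m); se_ <- slope(e)
  if (abs(se_[1]) < 1e-10)
    stop("experimental slope is (near) zero; ratio unstable")
  ratio <- sm[1] / se_[1]
  se <- if (all(is.finite(c(sm[2], se_[2]))))
    abs(ratio) * sqrt((sm[2] / sm[1])^2 + (se_[2] / se_[1])^2)
  else NA_real_
  c(ratio = ratio, se = se)
}

#' Weighted linear regression of alpha/beta on LET
#'
#' @param ab_table data.frame with columns \code{let},
#'   \code{alpha_beta} and optionally \code{se} (inverse-variance
#'   weights when present).
#' @return Named vector \code{c(intercept, slope)} with SEs in
#'   attribute \code{"se"} and the \code{lm} fit in attribute
#'   \code{"fit"}.
#' @export
fit_ab_vs_let <- function(ab_table) {
  stopifnot(all(c("let", "alpha_beta") %in% names(ab_table)))
  if (nrow(ab_table) < 2) stop("need at least two points")
  w <- NULL
  if (!is.null(ab_table$se) && all(is.finite(ab_table$se)) &&
      all(ab_table$se > 0))
    w <- 1 / ab_table$se^2
  fit <- lm(alpha_beta ~ let, data = ab_table, weights = w)
  cf <- setNames(coef(fit), c("intercept", "slope"))
  se <- if (nrow(ab_table) > 2)
    setNames(suppressWarnings(
      summary(fit)$coefficients[, "Std. Error"]),
             c("intercept", "slope"))
  else setNames(c(NA_real_, NA_real_), c("intercept", "slope"))
  attr(cf, "se") <- se
  attr(cf, "fit") <- fit
  cf
}

#' Full benchmark of a model RBE table against experimental values
#'
#' Convenience wrapper producing the region-averaged deviations and
#' slope ratios for every fraction number present in both tables
#' (aggregating over LET points within each region), or the per-LET
#' deviations aggregated over fraction numbers.
#'
#' @param model,experiment RBE tables (columns \code{let},
#'   \code{n_fractions}, \code{rbe}).
#' @param entrance,sobp LET values of the entrance and in-peak
#'   regions.
#' @param aggregate_over \code{"let"} (default; one summary row per
#'   fraction number) or \code{"fractions"} (one row per LET).
#' @return Object of class \code{rbe_comparison}: the per-point
#'   deviations plus a \code{summary} data.frame.
#' @export
compare_rbe_tables <- function(model, experiment,
                               entrance = c(16, 21),
                               sobp = c(36, 45, 66, 99),
                               aggregate_over = c("let", "fractions")) {
  aggregate_over <- match.arg(aggregate_over)
  devs <- percent_deviation(model, experiment)
  if (aggregate_over == "let") {
    fx <- sort(unique(devs$n_fractions))
    summary <- do.call(rbind, lapply(fx, function(f) {
      dv <- devs[devs$n_fractions == f, , drop = FALSE]
      ent <- tryCatch(region_average(dv, entrance),
                      error = function(e) c(NA_real_, NA_real_))
      sob <- tryCatch(region_average(dv, sobp),
                      error = function(e) c(NA_real_, NA_real_))
      sr <- tryCatch(
        slope_ratio(model[model$n_fractions == f, ],
                    experiment[experiment$n_fractions == f, ], sobp),
        error = function(e) c(NA_real_, NA_real_))
      data.frame(n_fractions = f,
                 entrance_mean_pct = ent[1], entrance_sd_pct = ent[2],
                 sobp_mean_pct = sob[1], sobp_sd_pct = sob[2],
                 slope_ratio = sr[1], slope_ratio_se = sr[2])
    }))
  } else {
    lets <- sort(unique(devs$let))
    summary <- do.call(rbind, lapply(lets, function(l) {
      dv <- devs$dev_pct[devs$let == l]
      ra <- region_average(dv)
      data.frame(let = l, mean_pct = ra[1], sd_pct = ra[2],
                 n = length(dv))
    }))
  }
  structure(
    list(deviations = devs, summary = summary,
         entrance = entrance, sobp = sobp,
         aggregate_over = aggregate_over),
    class = "rbe_comparison")
}

#' @export
print.rbe_comparison <- function(x, ...) {
  cat(sprintf(
    "Model benchmark (aggregated over %s; entrance {%s}, SOBP {%s})\n",
    x$aggregate_over, paste(x$entrance, collapse = ", "),
    paste(x$sobp, collapse = ", ")))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
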