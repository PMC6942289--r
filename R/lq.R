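#' Biologically effective dose at a tolerance dose
#'
#' For a schedule of \code{n} equal fractions delivering total dose
#' \code{td50}, the linear-quadratic biologically effective dose is
#' \code{BED = td50 * (1 + d / (alpha/beta))} with per-fraction dose
#' \code{d = td50 / n}.
#'
#' @param td50 total dose in Gy.
#' @param n_fractions number of fractions.
#' @param alpha_beta alpha/beta ratio in Gy (may be \code{Inf}).
#' @return BED in Gy.
#' @examples
#' bed_from_td50(39.1, 6, 6.9)  # 76.03 Gy
#' @export
bed_from_td50 <- function(td50, n_fractions, alpha_beta) {
  stopifnot(all(td50 > 0), all(n_fractions > 0), all(alpha_beta > 0))
  td50 * (1 + td50 / (n_fractions * alpha_beta))
}

#' Total dose at a given BED (inverse of [bed_from_td50()])
#'
#' Solves \code{d (1 + d / (alpha/beta)) = bed50 / n} for the
#' per-fraction dose \code{d} (unique positive root) and returns the
#' total dose \code{n * d}.
#'
#' @param bed50 biologically effective dose in Gy.
#' @param alpha_beta alpha/beta ratio in Gy (may be \code{Inf}).
#' @param n_fractions number of fractions.
#' @return Total dose in Gy.
#' @export
invert_bed <- function(bed50, alpha_beta, n_fractions) {
  stopifnot(all(bed50 > 0), all(n_fractions > 0), all(alpha_beta > 0))
  len <- max(length(bed50), length(alpha_beta), length(n_fractions))
  bed50 <- rep_len(bed50, len)
  ab <- rep_len(alpha_beta, len)
  n <- rep_len(n_fractions, len)
  per_fx <- bed50 / n
  d <- per_fx                      # alpha/beta = Inf limit: BED is dose
  fin <- is.finite(ab)
  d[fin] <- ab[fin] / 2 * (sqrt(1 + 4 * per_fx[fin] / ab[fin]) - 1)
  n * d
}

#' Joint linear-quadratic isoeffect fit across fraction numbers
#'
#' Estimates the fractionation parameter alpha/beta and the
#' biologically effective dose at 50% complication probability, BED50,
#' from tolerance doses TD50 measured at two or more fraction numbers.
#' The isoeffect model predicts \code{TD50(n) = invert_bed(bed50,
#' alpha/beta, n)}; it is fitted on the dose scale by weighted least
#' squares with known weights \code{1/se_td50^2}, so the reported
#' parameter covariance is the error-propagation matrix
#' \code{(J' W J)^{-1}} evaluated at the optimum (exact for two
#' schedules, where the solution interpolates).  90% confidence limits
#' use the log-scale normal approximation, giving the asymmetric
#' intervals expected for positive ratio parameters.  A classical
#' reciprocal-dose (Fe-plot) regression is available as a cross-check
#' via \code{method = "reciprocal"}.
#'
#' @param schedules data.frame with columns \code{n_fractions},
#'   \code{td50}, \code{se_td50} (Gy); at least two distinct fraction
#'   numbers.
#' @param level confidence level (default 0.90).
#' @param method \code{"isoeffect"} (default, dose-scale WLS) or
#'   \code{"reciprocal"} (linear fit of 1/TD50 on dose per fraction).
#' @return Object of class \code{lq_fit}: \code{alpha_beta},
#'   \code{se_alpha_beta}, \code{bed50}, \code{se_bed50},
#'   \code{cov} (2x2, order bed50 then alpha/beta), \code{cl90_ab},
#'   \code{cl90_bed}, \code{fitted}, \code{residuals}, \code{chisq},
#'   \code{df}, \code{converged}, \code{method}.
#' @export
fit_lq <- function(schedules, level = 0.90,
                   method = c("isoeffect", "reciprocal")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(schedules),
            all(c("n_fractions", "td50", "se_td50") %in% names(schedules)))
  if (length(unique(schedules$n_fractions)) < 2)
    stop("need at least two schedules with distinct fraction numbers")
  if (any(schedules$td50 <= 0) || any(schedules$se_td50 <= 0))
    stop("td50 and se_td50 must be positive")
  n <- schedules$n_fractions
  y <- schedules$td50
  w <- 1 / schedules$se_td50^2

  # Fe-plot start / cross-check: 1/TD50 = 1/BED + d / (BED * ab)
  dpf <- y / n
  fe <- lm(I(1 / y) ~ dpf, weights = w * y^4)  # var(1/T) ~ se^2 / T^4
  a0 <- coef(fe)[[1]]; a1 <- coef(fe)[[2]]
  start_bed <- if (is.finite(a0) && a0 > 0) 1 / a0 else
    max(bed_from_td50(y, n, 10))
  start_ab <- if (is.finite(a1) && a1 > 0 && a0 > 0) a0 / a1 else 10

  if (method == "reciprocal") {
    V <- vcov(fe)
    bed <- 1 / a0; ab <- a0 / a1
    # delta method through (a0, a1) -> (bed, ab)
    Jr <- matrix(c(-1 / a0^2, 0, 1 / a1, -a0 / a1^2), 2, 2, byrow = TRUE)
    covp <- Jr %*% V %*% t(Jr)
    return(.lq_result(bed, ab, covp, n, y, w, level, "reciprocal",
                      converged = TRUE))
  }

  df_fit <- data.frame(y = y, n = n)
  fit <- minpack.lm::nlsLM(
    y ~ invert_bed(bed50, ab, n), data = df_fit, weights = w,
    start = list(bed50 = start_bed, ab = start_ab),
    lower = c(1e-8, 1e-8),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  est <- coef(fit)
  bed <- est[["bed50"]]; ab <- est[["ab"]]
  # error-propagation covariance with known measurement variances
  J <- .num_jacobian(function(p) invert_bed(p[1], p[2], n), c(bed, ab))
  covp <- tryCatch(solve(t(J) %*% (w * J)), error = function(e)
    matrix(NA_real_, 2, 2))
  .lq_result(bed, ab, covp, n, y, w, level, "isoeffect",
             converged = fit$convInfo$isConv %||% TRUE)
}

.lq_result <- function(bed, ab, covp, n, y, w, level, method, converged) {
  se_bed <- sqrt(covp[1, 1]); se_ab <- sqrt(covp[2, 2])
  z <- qnorm((1 + level) / 2)
  cl_log <- function(est, se) {
    if (!is.finite(se) || est <= 0) return(c(NA_real_, NA_real_))
    est * exp(c(-1, 1) * z * se / est)
  }
  pred <- invert_bed(bed, ab, n)
  structure(
    list(alpha_beta = ab, se_alpha_beta = se_ab,
         bed50 = bed, se_bed50 = se_bed,
         cov = covp, cov_ab_bed = covp[1, 2],
         cl90_ab = cl_log(ab, se_ab), cl90_bed = cl_log(bed, se_bed),
         fitted = pred, residuals = y - pred,
         chisq = sum(w * (y - pred)^2),
         df = length(y) - 2, level = level, method = method,
         converged = isTRUE(converged)),
    class = "lq_fit")
}

.num_jacobian <- function(f, p, eps = 1e-6) {
  f0 <- f(p)
  J <- matrix(NA_real_, length(f0), length(p))
  for (k in seq_along(p)) {
    h <- eps * max(abs(p[k]), 1)
    pp <- p; pp[k] <- p[k] + h
    pm <- p; pm[k] <- p[k] - h
    J[, k] <- (f(pp) - f(pm)) / (2 * h)
  }
  J
}

#' @export
print.lq_fit <- function(x, ...) {
  cat(sprintf("LQ isoeffect fit (%s, %d schedules)\n", x$method,
              length(x$fitted)))
  cat(sprintf("  alpha/beta = %.1f +/- %.1f Gy (%.0f%% CL %.1f-%.1f)\n",
              x$alpha_beta, x$se_alpha_beta, 100 * x$level,
              x$cl90_ab[1], x$cl90_ab[2]))
  cat(sprintf("  BED50      = %.1f +/- %.1f Gy (%.0f%% CL %.1f-%.1f)\n",
              x$bed50, x$se_bed50, 100 * x$level,
              x$cl90_bed[1], x$cl90_bed[2]))
  invisible(x)
}
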