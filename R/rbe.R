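.as_estimate_pair <- function(x, value_name) {
  # accept c(value, se), named vectors, lists, or fit objects
  if (inherits(x, "dose_response_fit"))
    return(c(x$td50, x$se_td50))
  if (inherits(x, "lq_fit"))
    return(c(x$bed50, x$se_bed50))
  if (is.list(x)) {
    v <- x[[value_name]] %||% x[[1]]
    s <- x$se %||% x[[2]]
    return(c(v, s))
  }
  stopifnot(is.numeric(x), length(x) >= 2)
  unname(x[1:2])
}

#' Relative biological effectiveness from TD50 values
#'
#' RBE at the isoeffect level is the ratio of the photon tolerance
#' dose to the ion tolerance dose at the same endpoint and fraction
#' number, \code{RBE = TD50_photon / TD50_ion}.  The two experiments
#' use different cohorts and beams, so the SE is propagated with zero
#' cross-covariance,
#' \code{se = RBE * sqrt((se_x/TD50_x)^2 + (se_c/TD50_c)^2)}, and the
#' confidence limits come from [fieller_cl()].
#'
#' @param photon,carbon numeric \code{c(td50, se)} (Gy), a list with
#'   elements \code{td50}/\code{se} (optionally \code{n_fractions}),
#'   or a [fit_dose_response()] result.
#' @param level confidence level (default 0.90).
#' @return Object of class \code{rbe_estimate} with \code{rbe},
#'   \code{se}, \code{cl90}, \code{basis = "td50_ratio"}.
#' @examples
#' compute_rbe(c(57.0, 2.0), c(39.1, 0.4))  # 1.46 +/- 0.05
#' @export
compute_rbe <- function(photon, carbon, level = 0.90) {
  nf <- function(x) {
    if (inherits(x, "dose_response_fit")) return(x$n_fractions)
    if (is.list(x)) return(x$n_fractions)
    NULL
  }
  nx <- nf(photon); nc <- nf(carbon)
  if (!is.null(nx) && !is.null(nc) && nx != nc)
    stop("photon and carbon experiments have different fraction numbers")
  p <- .as_estimate_pair(photon, "td50")
  cc <- .as_estimate_pair(carbon, "td50")
  .ratio_estimate(p, cc, level, basis = "td50_ratio",
                  n_fractions = nc %||% nx)
}

#' Maximum RBE in the low-dose limit from BED50 values
#'
#' As the dose per fraction vanishes, the LQ isoeffect RBE approaches
#' the ratio of the biologically effective doses,
#' \code{RBE_max = BED50_photon / BED50_ion}.  SEs are propagated with
#' zero cross-covariance between the photon and ion studies;
#' confidence limits come from [fieller_cl()].
#'
#' @param photon,carbon numeric \code{c(bed50, se)} (Gy), a list, or a
#'   [fit_lq()] result.
#' @param level confidence level (default 0.90).
#' @return Object of class \code{rbe_estimate} with
#'   \code{basis = "bed50_ratio"} and \code{n_fractions = Inf}.
#' @examples
#' compute_rbe_max(c(244.9, 24.3), c(76.3, 7.2))  # 3.21 +/- 0.44
#' @export
compute_rbe_max <- function(photon, carbon, level = 0.90) {
  p <- .as_estimate_pair(photon, "bed50")
  cc <- .as_estimate_pair(carbon, "bed50")
  .ratio_estimate(p, cc, level, basis = "bed50_ratio", n_fractions = Inf)
}

#' Maximum RBE of a radiation-quality model from its alpha values
#'
#' RBE-model predictions tabulate the LQ intercept alpha; in the
#' low-dose limit the model RBE is the ratio of ion to photon alpha.
#' Provided for benchmarking user-supplied model tables.
#'
#' @param alpha_ion,alpha_photon LQ alpha values in 1/Gy.
#' @param se_ion,se_photon optional SEs (default 0).
#' @param level confidence level (default 0.90).
#' @return An \code{rbe_estimate} with \code{basis = "alpha_ratio"}.
#' @export
rbe_max_from_alpha <- function(alpha_ion, alpha_photon,
                               se_ion = 0, se_photon = 0, level = 0.90) {
  .ratio_estimate(c(alpha_ion, se_ion), c(alpha_photon, se_photon),
                  level, basis = "alpha_ratio", n_fractions = Inf)
}

.ratio_estimate <- function(num, den, level, basis, n_fractions = NULL) {
  stopifnot(num[1] > 0, den[1] > 0)
  rbe <- num[1] / den[1]
  se <- rbe * sqrt((num[2] / num[1])^2 + (den[2] / den[1])^2)
  cl <- fieller_cl(num[1], num[2], den[1], den[2], cov = 0, level = level)
  structure(
    list(rbe = rbe, se = se,
         cl90 = c(low = unname(cl[1]), high = unname(cl[2])),
         level = level, basis = basis,
         n_fractions = n_fractions),
    class = "rbe_estimate")
}

#' @export
print.rbe_estimate <- function(x, ...) {
  lab <- switch(x$basis, td50_ratio = "RBE",
                bed50_ratio = "RBE_max", alpha_ratio = "RBE_max (model)")
  cl <- if (all(is.finite(x$cl90)))
    sprintf(" (%.0f%% CL %.2f-%.2f)", 100 * x$level,
            x$cl90[1], x$cl90[2]) else ""
  cat(sprintf("%s = %.2f +/- %.2f%s\n", lab, x$rbe, x$se, cl))
  invisible(x)
}

#' LQ inter/extrapolation of the RBE over dose per fraction
#'
#' Given the low-dose limit \code{rbe_max} and the photon and ion
#' alpha/beta ratios, the isoeffective photon dose per fraction
#' \code{d_x} for an ion dose per fraction \code{d_c} solves
#' \code{d_x (1 + d_x / ab_photon) = rbe_max * d_c *
#' (1 + d_c / ab_carbon)}; the dose-dependent RBE is \code{d_x / d_c}.
#' It equals \code{rbe_max} as \code{d_c -> 0} and falls to
#' \code{sqrt(rbe_max * ab_photon / ab_carbon)} as \code{d_c -> Inf}.
#'
#' @param d_carbon ion dose per fraction in Gy (vectorised; 0 allowed,
#'   returning the low-dose limit).
#' @param rbe_max low-dose RBE limit.
#' @param ab_photon,ab_carbon alpha/beta ratios in Gy.
#' @return RBE value(s), dimensionless.
#' @export
rbe_vs_dose <- function(d_carbon, rbe_max, ab_photon, ab_carbon) {
  stopifnot(all(d_carbon >= 0), rbe_max > 0, ab_photon > 0, ab_carbon > 0)
  bed_fx <- rbe_max * d_carbon * (1 + d_carbon / ab_carbon)
  d_x <- ab_photon / 2 * (sqrt(1 + 4 * bed_fx / ab_photon) - 1)
  out <- d_x / d_carbon
  out[d_carbon == 0] <- rbe_max
  out
}
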