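#' Maximum-likelihood dose-response fit for one experiment
#'
#' Fits a two-parameter sigmoid complication-probability curve
#' \code{p(D) = F(b0 + b1 * D)} (logistic \code{F} by default, probit
#' optional) to the per-group responder counts by maximising the
#' binomial log-likelihood.  The effective counts from the actuarial
#' stage enter as real-valued weights; with complete follow-up they
#' coincide with the raw counts and the fit is the ordinary logistic
#' ML fit.  TD50 is the dose of 50% complication probability,
#' \code{-b0/b1} for both links; its standard error comes from the
#' delta method using the full parameter covariance, and 90%
#' confidence limits from [fieller_cl()] applied to the ratio
#' \code{-b0 / b1}.
#'
#' A completely separated response pattern (every group at 0%
#' response below some dose and at 100% above, with no partial group)
#' has no finite ML estimate.  Following common practice for such
#' steep curves, TD50 is then taken as the midpoint between the
#' bracketing doses and its SE from the fallback rule
#' [estimate_se_fallback()]; \code{se_estimated} marks these fits.
#'
#' @param experiment an \code{rbe_experiment}; groups with identical
#'   doses are pooled beforehand.
#' @param use_effective logical; use \code{(n_eff, r_eff)} (running
#'   [apply_actuarial()] first if needed) rather than raw counts.
#' @param link \code{"logit"} (default) or \code{"probit"}.
#' @param level confidence level for the TD50 limits (default 0.90).
#' @return Object of class \code{dose_response_fit} with elements
#'   \code{b0}, \code{b1}, \code{cov}, \code{td50}, \code{se_td50},
#'   \code{cl90}, \code{se_estimated}, \code{separation},
#'   \code{converged}, \code{loglik}, \code{link}, \code{level},
#'   \code{groups} (the counts used).
#' @export
fit_dose_response <- function(experiment, use_effective = TRUE,
                              link = c("logit", "probit"),
                              level = 0.90) {
  link <- match.arg(link)
  stopifnot(inherits(experiment, "rbe_experiment"))
  if (use_effective && any(is.na(experiment$groups$n_eff)))
    experiment <- apply_actuarial(experiment)
  g <- experiment$groups
  if (use_effective) {
    d <- g$total_dose; n <- g$n_eff; r <- g$r_eff
  } else {
    d <- g$total_dose; n <- g$n_raw; r <- g$r_raw
  }
  keep <- n > 0
  d <- d[keep]; n <- n[keep]; r <- r[keep]
  # pool identical doses (hand-built experiments may duplicate levels)
  if (anyDuplicated(d)) {
    n <- tapply(n, d, sum); r <- tapply(r, d, sum)
    d <- as.numeric(names(n)); n <- as.numeric(n); r <- as.numeric(r)
  }
  o <- order(d); d <- d[o]; n <- n[o]; r <- r[o]
  if (length(d) < 2)
    stop("need at least two dose groups with response information")
  prop <- r / n
  if (all(r == 0) || all(r >= n))
    stop("response is constant across groups; TD50 unidentifiable")

  counts <- data.frame(total_dose = d, n = n, r = r, prop = prop)

  # complete separation: all-0% then all-100%, no partial group
  degenerate <- all(prop < 1e-12 | prop > 1 - 1e-12)
  if (degenerate && !is.unsorted(prop)) {
    d0 <- max(d[prop < 0.5]); d100 <- min(d[prop > 0.5])
    se <- estimate_se_fallback(experiment, use_effective = use_effective)
    fit <- structure(
      list(b0 = NA_real_, b1 = NA_real_, cov = NULL,
           td50 = (d0 + d100) / 2, se_td50 = se, cl90 = NULL,
           se_estimated = TRUE, separation = TRUE, converged = TRUE,
           loglik = 0, link = link, level = level, groups = counts,
           experiment_id = experiment$experiment_id,
           let_value = experiment$let_value,
           n_fractions = experiment$n_fractions),
      class = "dose_response_fit")
    return(fit)
  }

  F_ <- if (link == "logit") plogis else pnorm
  negll <- function(th) {
    p <- F_(th[1] + th[2] * d)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(r * log(p) + (n - r) * log1p(-p))
  }
  grad <- function(th) {
    eta <- th[1] + th[2] * d
    if (link == "logit") {
      p <- plogis(eta)
      w <- r - n * p                     # dll/deta
    } else {
      p <- pmin(pmax(pnorm(eta), 1e-12), 1 - 1e-12)
      w <- (r / p - (n - r) / (1 - p)) * dnorm(eta)
    }
    -c(sum(w), sum(w * d))
  }

  start <- .start_values(d, prop, link)
  opt <- optim(start, negll, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  # Newton polish to drive the gradient norm down to ~1e-10
  th <- opt$par
  for (i in 1:50) {
    gr <- grad(th)
    if (sqrt(sum(gr^2)) < 1e-10) break
    H <- optimHess(th, negll, grad)
    step <- tryCatch(solve(H, gr), error = function(e) NULL)
    if (is.null(step)) break
    if (negll(th - step) < negll(th)) th <- th - step else break
  }
  H <- optimHess(th, negll, grad)
  cov <- tryCatch(solve(H), error = function(e) NULL)
  b0 <- th[1]; b1 <- th[2]
  td50 <- -b0 / b1
  se_td50 <- NA_real_; cl <- NULL; se_estimated <- FALSE
  if (!is.null(cov) && all(is.finite(cov)) && all(diag(cov) > 0)) {
    gdelta <- c(-1 / b1, b0 / b1^2)
    v <- drop(t(gdelta) %*% cov %*% gdelta)
    se_td50 <- sqrt(max(v, 0))
    cl <- fieller_cl(-b0, sqrt(cov[1, 1]), b1, sqrt(cov[2, 2]),
                     cov = -cov[1, 2], level = level)
  }
  if (!is.finite(se_td50) || se_td50 <= 0) {
    se_td50 <- tryCatch(
      estimate_se_fallback(experiment, use_effective = use_effective),
      error = function(e) NA_real_)
    se_estimated <- TRUE
    cl <- NULL
  }
  structure(
    list(b0 = b0, b1 = b1, cov = cov, td50 = td50, se_td50 = se_td50,
         cl90 = cl, se_estimated = se_estimated, separation = FALSE,
         converged = opt$convergence == 0, loglik = -negll(th),
         link = link, level = level, groups = counts,
         experiment_id = experiment$experiment_id,
         let_value = experiment$let_value,
         n_fractions = experiment$n_fractions),
    class = "dose_response_fit")
}

.start_values <- function(d, prop, link) {
  qf <- if (link == "logit") qlogis else qnorm
  pc <- pmin(pmax(prop, 0.05), 0.95)
  # slope from the two groups bracketing 50% response, else the extremes
  below <- which(prop < 0.5); above <- which(prop >= 0.5)
  if (length(below) > 0 && length(above) > 0) {
    i <- max(below); j <- min(above[above > max(below)], length(d))
  } else {
    i <- 1; j <- length(d)
  }
  if (j <= i) { i <- 1; j <- length(d) }
  b1 <- (qf(pc[j]) - qf(pc[i])) / (d[j] - d[i])
  if (!is.finite(b1) || b1 <= 0) b1 <- 2 / (max(d) - min(d))
  mid <- (d[i] + d[j]) / 2
  c(-b1 * mid, b1)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("Dose-response fit (%s link)%s\n", x$link,
              if (!is.null(x$experiment_id))
                paste0(" for '", x$experiment_id, "'") else ""))
  cl <- if (!is.null(x$cl90) && all(is.finite(x$cl90)))
    sprintf(" (%.0f%% CL %.2f-%.2f)", 100 * x$level,
            x$cl90[1], x$cl90[2]) else ""
  cat(sprintf("  TD50 = %.2f +/- %.2f Gy%s%s\n", x$td50, x$se_td50, cl,
              if (x$se_estimated) " [SE estimated]" else ""))
  invisible(x)
}

#' Fallback standard error of TD50 from the dose grid
#'
#' When a fit cannot provide a standard error (complete separation or
#' a singular information matrix), the SE is estimated as 25% of the
#' dose difference between the neighbouring dose levels observed at
#' 0% and 100% response.  If those levels overlap in dose, the two
#' levels bracketing 50% response are used instead.
#'
#' @param experiment an \code{rbe_experiment}.
#' @param use_effective logical; judge response rates on effective
#'   rather than raw counts (default FALSE: observed raw rates).
#' @return SE estimate in Gy.
#' @export
estimate_se_fallback <- function(experiment, use_effective = FALSE) {
  stopifnot(inherits(experiment, "rbe_experiment"))
  g <- experiment$groups
  if (use_effective && !any(is.na(g$n_eff))) {
    d <- g$total_dose; prop <- g$r_eff / g$n_eff
  } else {
    d <- g$total_dose; prop <- g$r_raw / g$n_raw
  }
  keep <- is.finite(prop)
  d <- d[keep]; prop <- prop[keep]
  o <- order(d); d <- d[o]; prop <- prop[o]
  at0 <- d[prop < 1e-12]; at100 <- d[prop > 1 - 1e-12]
  if (length(at0) == 0 || length(at100) == 0)
    stop("no 0% or no 100% response level; SE cannot be estimated")
  diff <- min(at100) - max(at0)
  if (diff > 0) return(0.25 * diff)
  if (diff == 0) stop("degenerate dose grid; SE cannot be estimated")
  # overlapping pattern: use the adjacent doses bracketing 50% response
  k <- length(d)
  idx <- which(prop[-k] < 0.5 & prop[-1] >= 0.5)
  if (length(idx) == 0)
    stop("no pair of doses bracketing 50% response; SE cannot be estimated")
  width <- d[idx[1] + 1] - d[idx[1]]
  if (width <= 0) stop("degenerate dose grid; SE cannot be estimated")
  0.25 * width
}

#' Fieller confidence limits for a ratio of two normal estimates
#'
#' Exact normal-theory confidence limits for \code{num/den} given the
#' standard errors of numerator and denominator and their covariance.
#' The limits are the roots of
#' \code{(den^2 - z^2 se_den^2) R^2 - 2 (num*den - z^2 cov) R +
#' (num^2 - z^2 se_num^2) = 0}.  When
#' \code{g = (z se_den / den)^2 >= 1} the denominator is not
#' significantly different from zero and the interval is unbounded.
#'
#' @param num,se_num numerator estimate and its SE.
#' @param den,se_den denominator estimate and its SE (\code{den != 0}).
#' @param cov covariance between numerator and denominator (default 0).
#' @param level two-sided confidence level in (0,1), default 0.90.
#' @return Numeric vector \code{c(low, high)} with attributes
#'   \code{level}, \code{g} and \code{bounded}; \code{c(NA, NA)} with
#'   \code{bounded = FALSE} when the interval is unbounded.
#' @examples
#' fieller_cl(57.0, 2.0, 39.1, 0.4)  # 90% CL of the ratio 1.46
#' @export
fieller_cl <- function(num, se_num, den, se_den, cov = 0, level = 0.90) {
  stopifnot(den != 0, level > 0, level < 1, se_num >= 0, se_den >= 0)
  ratio <- num / den
  if (se_num == 0 && se_den == 0) {
    out <- c(low = ratio, high = ratio)
    attr(out, "level") <- level; attr(out, "g") <- 0
    attr(out, "bounded") <- TRUE
    return(out)
  }
  z <- qnorm((1 + level) / 2)
  g <- (z * se_den / den)^2
  if (g >= 1) {
    out <- c(low = NA_real_, high = NA_real_)
    attr(out, "level") <- level; attr(out, "g") <- g
    attr(out, "bounded") <- FALSE
    return(out)
  }
  A <- den^2 - z^2 * se_den^2
  B <- -2 * (num * den - z^2 * cov)
  C <- num^2 - z^2 * se_num^2
  disc <- B^2 - 4 * A * C
  if (disc < 0) disc <- 0
  roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  out <- c(low = min(roots), high = max(roots))
  attr(out, "level") <- level; attr(out, "g") <- g
  attr(out, "bounded") <- TRUE
  out
}
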