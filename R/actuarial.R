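#' Actuarial response probability at the follow-up horizon
#'
#' Computes the actuarial (product-limit) probability of having shown
#' the toxicity endpoint by \code{horizon}, \code{p_act = 1 - S(horizon)},
#' where \code{S} is the Kaplan-Meier survivor function of the event
#' process.  Animals dying or withdrawn without the endpoint are
#' censored at their last observation day.  The variance attached to
#' \code{p_act} is the Greenwood variance of \code{S(horizon)} (a
#' crude binomial variance \code{p(1-p)/n} is available as an
#' alternative estimator).
#'
#' @param times positive follow-up times in days, one per animal.
#' @param events 0/1 event indicators (1 = endpoint observed at
#'   \code{times}).
#' @param horizon evaluation horizon in days (default 300).
#' @param estimator \code{"greenwood"} (default) or \code{"binomial"}.
#' @return An object of class \code{actuarial_estimate}: list with
#'   \code{p_act}, \code{var_act} (capped at 0.25), \code{n_at_risk}
#'   (number of animals entering), \code{immature} (TRUE when every
#'   animal was censored before the horizon, so the estimate rests on
#'   incomplete information) and \code{estimator}.
#' @examples
#' actuarial_response(c(150, 200), c(1, 0))  # p_act 0.5, var 0.125
#' @export
actuarial_response <- function(times, events, horizon = 300,
                               estimator = c("greenwood", "binomial")) {
  estimator <- match.arg(estimator)
  if (length(times) == 0) stop("empty input")
  if (length(times) != length(events))
    stop("times and events must have equal length")
  if (any(!(times > 0))) stop("times must be positive")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")

  # observations beyond the horizon carry no event information for it
  ev <- ifelse(times > horizon, 0, events)
  tt <- pmin(times, horizon)
  immature <- all(ev == 0) && all(tt < horizon)

  if (all(ev == 1)) {
    s <- 0; v <- 0
  } else if (all(ev == 0)) {
    s <- 1; v <- 0
  } else {
    fit <- survival::survfit(survival::Surv(tt, ev) ~ 1,
                             conf.type = "none")
    sm <- summary(fit, times = horizon, extend = TRUE)
    s <- sm$surv
    v <- if (is.na(sm$std.err)) 0 else sm$std.err^2
    if (s <= 0) v <- 0
  }
  p <- 1 - s
  if (estimator == "binomial") v <- p * (1 - p) / length(tt)
  v <- min(v, 0.25)
  structure(
    list(p_act = p, var_act = v, n_at_risk = length(tt),
         immature = immature, estimator = estimator),
    class = "actuarial_estimate"
  )
}

#' @export
print.actuarial_estimate <- function(x, ...) {
  cat(sprintf("Actuarial response: p = %.4f (var %.5f, %s), n = %d%s\n",
              x$p_act, x$var_act, x$estimator, x$n_at_risk,
              if (x$immature) " [immature follow-up]" else ""))
  invisible(x)
}

#' Effective sample size from an actuarial estimate
#'
#' Replaces the raw treated/responder counts of a dose group by
#' effective counts whose binomial variance matches the actuarial
#' response rate and its variance: \code{n_eff = p(1-p)/var},
#' \code{r_eff = n_eff * p}.  Censoring can only lose information, so
#' \code{n_eff} is capped at \code{n_raw}; with degenerate rates
#' (\code{p} of 0 or 1) or zero variance the raw counts are returned
#' unchanged.
#'
#' @param est an [actuarial_response()] result.
#' @param n_raw raw number of analysable (non-excluded) animals.
#' @param r_raw raw number of responders among them.
#' @return Named numeric vector \code{c(n_eff, r_eff)}.
#' @export
effective_sample_size <- function(est, n_raw, r_raw) {
  stopifnot(inherits(est, "actuarial_estimate"), r_raw <= n_raw)
  p <- est$p_act
  v <- est$var_act
  if (p > 0 && p < 1) {
    if (v <= 0) {
      warning("zero variance with 0 < p_act < 1; using raw counts")
      return(c(n_eff = n_raw, r_eff = r_raw))
    }
    n_eff <- p * (1 - p) / v
    if (n_eff > n_raw) n_eff <- n_raw
    return(c(n_eff = n_eff, r_eff = n_eff * p))
  }
  c(n_eff = n_raw, r_eff = r_raw)
}

#' Apply the actuarial correction to every dose group of an experiment
#'
#' For each dose group the Kaplan-Meier estimate at the horizon is
#' computed from all animals of the group (excluded animals enter as
#' censored observations at their last day -- their incomplete
#' follow-up is exactly what the correction accounts for) and
#' converted into effective counts with [effective_sample_size()],
#' using the non-excluded count as the cap.
#'
#' @param experiment an \code{rbe_experiment}.
#' @param estimator variance estimator, see [actuarial_response()].
#' @return The experiment with \code{groups$n_eff}, \code{r_eff},
#'   \code{p_act}, \code{var_act} filled in.
#' @export
apply_actuarial <- function(experiment, estimator = "greenwood") {
  stopifnot(inherits(experiment, "rbe_experiment"))
  g <- experiment$groups
  for (i in seq_len(nrow(g))) {
    a <- experiment$animals[
      experiment$animals$total_dose == g$total_dose[i], , drop = FALSE]
    est <- actuarial_response(a$time_days, a$event,
                              horizon = experiment$horizon,
                              estimator = estimator)
    eff <- effective_sample_size(est, g$n_raw[i], g$r_raw[i])
    g$n_eff[i] <- eff[["n_eff"]]
    g$r_eff[i] <- eff[["r_eff"]]
    g$p_act[i] <- est$p_act
    g$var_act[i] <- est$var_act
  }
  experiment$groups <- g
  experiment
}

#' Latency summary over responders
#'
#' Minimum, mean and maximum time to onset of the endpoint, taken over
#' responders only; censored animals are ignored.
#'
#' @param records the \code{animals} data.frame of an experiment (or
#'   an \code{rbe_experiment}, whose animal table is then used).
#' @return List with \code{min_days}, \code{mean_days},
#'   \code{max_days}, \code{n_responders}; all-NA sentinel with
#'   \code{n_responders = 0} when there are no responders.
#' @export
latency_summary <- function(records) {
  if (inherits(records, "rbe_experiment")) records <- records$animals
  t_resp <- records$time_days[records$event == 1]
  if (length(t_resp) == 0)
    return(list(min_days = NA_real_, mean_days = NA_real_,
                max_days = NA_real_, n_responders = 0L))
  list(min_days = min(t_resp), mean_days = mean(t_resp),
       max_days = max(t_resp), n_responders = length(t_resp))
}
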