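# run code under a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# stable 31-bit stream id from (seed, experiment_id), so that adding
# experiments to a study never perturbs the existing ones
.stream_seed <- function(seed, id) {
  h <- 0
  for (k in utf8ToInt(as.character(id))) h <- (h * 31 + k) %% 2147483647
  as.integer((h + as.numeric(seed) * 7919) %% 2147483647)
}

#' Latency-model configuration for the cohort simulator
#'
#' Onset times of responders are drawn from a lognormal distribution
#' whose median decreases mildly with LET and with dose above the
#' tolerance dose, mirroring the observed behaviour of late
#' spinal-cord toxicity where latency shortens slightly with
#' increasing LET, fraction number and dose.  The log-median is
#' \code{log(median_days) - dose_let_trend * (let/100 + dose/td50 - 1)}.
#'
#' @param median_days baseline median onset time in days (default 200,
#'   giving medians of roughly 150-250 d across the study designs).
#' @param sigma_log lognormal shape (SD of log time, default 0.25).
#' @param dose_let_trend strength of the LET/dose shortening (default
#'   0.3; 0 switches the trend off).
#' @return A list used by [simulate_experiment()].
#' @export
latency_model <- function(median_days = 200, sigma_log = 0.25,
                          dose_let_trend = 0.3) {
  stopifnot(median_days > 0, sigma_log > 0, dose_let_trend >= 0)
  list(median_days = median_days, sigma_log = sigma_log,
       dose_let_trend = dose_let_trend)
}

#' Simulate one dose-response experiment
#'
#' Generates animal-level records under the model assumed by the
#' analysis chain: each animal at total dose D responds with
#' probability \code{plogis(slope_b1 * (D - td50_true))}; responders
#' receive a lognormal onset time truncated to the follow-up horizon,
#' non-responders are censored at the horizon, and each animal is
#' independently lost to follow-up (intercurrent death, censored
#' uniformly over the follow-up period and flagged as excluded) with
#' probability \code{dropout_prob}.  Output is deterministic given
#' \code{seed} and \code{experiment_id}; the stream is private, so the
#' caller's RNG state is untouched.
#'
#' @param td50_true true tolerance dose in Gy.
#' @param dose_levels total doses in Gy (strictly increasing).
#' @param n_fractions fraction number.
#' @param let_value LET in keV/um (0 for photons).
#' @param slope_b1 logistic slope per Gy; default \code{10 /
#'   diff(range(dose_levels))}, which makes the dose grid span the
#'   0-100% response range.
#' @param group_size animals per dose level (default 5); or supply
#'   \code{group_sizes} for unequal groups.
#' @param group_sizes optional integer vector, one entry per dose
#'   level.
#' @param horizon follow-up in days (default 300).
#' @param latency a [latency_model()] list.
#' @param dropout_prob per-animal loss-to-follow-up probability
#'   (default 0.02).
#' @param seed integer seed.
#' @param experiment_id identifier (also salts the RNG stream).
#' @param modality \code{"carbon"} or \code{"photon"}.
#' @param depth_water_mm optional depth for the metadata.
#' @return An \code{rbe_experiment}.
#' @export
simulate_experiment <- function(td50_true, dose_levels, n_fractions,
                                let_value, slope_b1 = NULL,
                                group_size = 5, group_sizes = NULL,
                                horizon = 300,
                                latency = latency_model(),
                                dropout_prob = 0.02, seed = 1,
                                experiment_id = "sim",
                                modality = c("carbon", "photon"),
                                depth_water_mm = NA_real_) {
  modality <- match.arg(modality)
  stopifnot(td50_true > 0, all(dose_levels >= 0),
            !is.unsorted(dose_levels, strictly = TRUE),
            dropout_prob >= 0, dropout_prob <= 1, horizon > 0)
  if (is.null(slope_b1)) {
    rng <- diff(range(dose_levels[dose_levels > 0]))
    slope_b1 <- if (rng > 0) 10 / rng else 1
  }
  if (is.null(group_sizes)) group_sizes <- rep(group_size,
                                               length(dose_levels))
  stopifnot(length(group_sizes) == length(dose_levels),
            all(group_sizes >= 1))

  animals <- .with_seed(.stream_seed(seed, experiment_id), {
    rows <- vector("list", length(dose_levels))
    for (i in seq_along(dose_levels)) {
      D <- dose_levels[i]
      m <- group_sizes[i]
      p <- plogis(slope_b1 * (D - td50_true))
      event <- as.integer(runif(m) < p)
      time <- rep(as.numeric(horizon), m)
      resp <- which(event == 1)
      if (length(resp) > 0) {
        med <- latency$median_days *
          exp(-latency$dose_let_trend *
                (let_value / 100 + D / td50_true - 1))
        t_on <- rlnorm(length(resp), meanlog = log(med),
                       sdlog = latency$sigma_log)
        # truncate onsets to the follow-up window by resampling
        for (try in 1:100) {
          late <- t_on > horizon
          if (!any(late)) break
          t_on[late] <- rlnorm(sum(late), meanlog = log(med),
                               sdlog = latency$sigma_log)
        }
        t_on[t_on > horizon] <- horizon
        time[resp] <- t_on
      }
      excluded <- rep(FALSE, m)
      reason <- rep(NA_character_, m)
      drop <- which(runif(m) < dropout_prob)
      if (length(drop) > 0) {
        t_drop <- runif(length(drop), 1, horizon)
        # a loss to follow-up censors the animal unless the endpoint
        # had already occurred
        hit <- !(event[drop] == 1 & time[drop] <= t_drop)
        k <- drop[hit]
        time[k] <- t_drop[hit]
        event[k] <- 0L
        excluded[k] <- TRUE
        reason[k] <- "intercurrent death"
      }
      rows[[i]] <- data.frame(
        animal_id = sprintf("%s_d%02d_%05d", experiment_id, i,
                            seq_len(m)),
        total_dose = D, event = event, time_days = round(time, 1),
        excluded = excluded, exclusion_reason = reason,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  new_experiment(animals, experiment_id = experiment_id,
                 let_value = let_value, depth_water_mm = depth_water_mm,
                 n_fractions = n_fractions, modality = modality,
                 horizon = horizon)
}

# The 6-fraction study design: one experiment per SOBP depth, dose
# grids and animal numbers as used in the underlying study, with the
# measured tolerance doses as simulation truth.
.study_design <- function() {
  list(
    list(id = "photon_6fx", let = 0, depth = NA_real_, td50 = 57.0,
         doses = c(46, 50, 54, 58, 62, 66),
         sizes = rep(5L, 6), modality = "photon"),
    list(id = "c12_let16", let = 16, depth = 35, td50 = 39.1,
         doses = c(37, 38, 39, 40, 41, 45, 49),
         sizes = c(7L, 5L, 5L, 5L, 5L, 5L, 5L), modality = "carbon"),
    list(id = "c12_let21", let = 21, depth = 65, td50 = 33.8,
         doses = c(30, 32, 34, 36, 38, 40),
         sizes = rep(5L, 6), modality = "carbon"),
    list(id = "c12_let36", let = 36, depth = 80, td50 = 28.7,
         doses = c(25.5, 28.5, 31.5, 34.5),
         sizes = rep(5L, 4), modality = "carbon"),
    list(id = "c12_let45", let = 45, depth = 100, td50 = 26.9,
         doses = c(21.67, 24.49, 26.38, 28.26, 30.14, 32.97),
         sizes = rep(5L, 6), modality = "carbon"),
    list(id = "c12_let66", let = 66, depth = 120, td50 = 18.6,
         doses = seq(14.5, 24.5, by = 1),
         sizes = rep(5L, 11), modality = "carbon"),
    list(id = "c12_let99", let = 99, depth = 127, td50 = 17.5,
         doses = c(15, 16, 17, 18, 19, 20),
         sizes = c(5L, 5L, 5L, 6L, 5L, 6L), modality = "carbon")
  )
}

#' Simulate a full replica of the 6-fraction study design
#'
#' Generates the photon reference experiment and six carbon-ion
#' experiments (LET 16-99 keV/um, 6 daily fractions, 300-day
#' follow-up) with the study's dose grids and per-level animal
#' numbers, using the measured tolerance doses as ground truth.
#' Optionally adds the five sham-treated controls as a dose-0 group of
#' the photon experiment.
#'
#' @param seed integer seed.
#' @param dropout_prob per-animal loss to follow-up (default 0.02;
#'   set 0 for a censoring-free cohort).
#' @param include_controls add the 5 sham animals (default FALSE).
#' @param latency a [latency_model()] list.
#' @return List with \code{experiments} (class \code{rbe_cohort}) and
#'   \code{truth}, a data.frame of the generating parameters.
#' @export
make_study_replica <- function(seed = 1, dropout_prob = 0.02,
                               include_controls = FALSE,
                               latency = latency_model()) {
  design <- .study_design()
  exps <- list()
  truth <- list()
  for (d in design) {
    doses <- d$doses; sizes <- d$sizes
    if (include_controls && d$modality == "photon") {
      doses <- c(0, doses); sizes <- c(5L, sizes)
    }
    b1 <- 10 / diff(range(d$doses))
    exps[[d$id]] <- simulate_experiment(
      td50_true = d$td50, dose_levels = doses, n_fractions = 6,
      let_value = d$let, slope_b1 = b1, group_sizes = sizes,
      latency = latency, dropout_prob = dropout_prob, seed = seed,
      experiment_id = d$id, modality = d$modality,
      depth_water_mm = d$depth)
    truth[[d$id]] <- data.frame(
      experiment_id = d$id, let = d$let, n_fractions = 6,
      modality = d$modality, td50_true = d$td50, slope_b1 = b1,
      n_animals = sum(sizes), stringsAsFactors = FALSE)
  }
  list(experiments = structure(exps, class = "rbe_cohort"),
       truth = do.call(rbind, truth))
}
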