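#' @importFrom stats coef lm median optim optimHess plogis pnorm qnorm
#'   quantile rbinom rlnorm runif sd setNames vcov dnorm qlogis
#' @importFrom utils read.csv write.csv
NULL

# Required columns of the animal-level cohort CSV dialect.
.cohort_columns <- c(
  "experiment_id", "let_kev_um", "depth_mm", "n_fractions",
  "total_dose_gy", "animal_id", "event", "time_days",
  "excluded", "exclusion_reason"
)

#' Construct a single-experiment object from animal-level records
#'
#' An experiment is one irradiation series at a fixed beam position
#' (LET, depth) and fraction number, owning one dose group per distinct
#' total dose.  Animals flagged as excluded (intercurrent death, second
#' tumour) are kept for audit but do not count towards the raw group
#' size \code{n_raw}; they re-enter the analysis as censored
#' observations in the actuarial stage.
#'
#' @param animals data.frame with columns \code{animal_id},
#'   \code{total_dose}, \code{event} (1 = endpoint observed),
#'   \code{time_days}, \code{excluded} (logical), and optionally
#'   \code{exclusion_reason}.
#' @param experiment_id character identifier.
#' @param let_value dose-averaged LET in keV/um.
#' @param depth_water_mm water-equivalent depth in mm (NA if not
#'   applicable, e.g. photons).
#' @param n_fractions number of daily fractions (positive integer).
#' @param modality \code{"photon"} or \code{"carbon"}.
#' @param horizon follow-up horizon in days (default 300).
#' @return An object of class \code{rbe_experiment}: a list with the
#'   metadata above, the \code{animals} table, and a \code{groups}
#'   data.frame (one row per dose level, doses strictly increasing)
#'   with raw counts \code{n_raw}, \code{r_raw} and placeholders for
#'   the effective counts \code{n_eff}, \code{r_eff}.
#' @seealso [read_cohort()], [apply_actuarial()], [fit_dose_response()]
#' @export
new_experiment <- function(animals, experiment_id, let_value = NA_real_,
                           depth_water_mm = NA_real_, n_fractions = 1L,
                           modality = c("carbon", "photon"),
                           horizon = 300) {
  modality <- match.arg(modality)
  stopifnot(is.data.frame(animals), nrow(animals) > 0)
  needed <- c("animal_id", "total_dose", "event", "time_days", "excluded")
  miss <- setdiff(needed, names(animals))
  if (length(miss) > 0)
    stop("animals table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(animals$exclusion_reason))
    animals$exclusion_reason <- NA_character_
  animals$excluded <- as.logical(animals$excluded)
  if (any(animals$total_dose < 0))
    stop("negative dose in animals table")
  if (any(animals$time_days <= 0))
    stop("non-positive follow-up time in animals table")
  if (n_fractions < 1) stop("n_fractions must be a positive integer")

  # A responder is never dropped from the analysis, whatever the flag says.
  bad <- animals$event == 1 & animals$excluded
  if (any(bad)) {
    warning(sum(bad), " responder(s) flagged as excluded; ",
            "exclusion ignored for responders")
    animals$excluded[bad] <- FALSE
  }
  if (any(animals$excluded & is.na(animals$exclusion_reason)))
    warning("excluded animals without an exclusion reason")

  doses <- sort(unique(animals$total_dose))
  groups <- do.call(rbind, lapply(doses, function(d) {
    a <- animals[animals$total_dose == d, , drop = FALSE]
    keep <- !a$excluded
    data.frame(
      total_dose = d,
      n_raw = sum(keep),
      r_raw = sum(a$event[keep] == 1),
      n_eff = NA_real_, r_eff = NA_real_,
      p_act = NA_real_, var_act = NA_real_
    )
  }))
  structure(
    list(experiment_id = as.character(experiment_id),
         let_value = let_value, depth_water_mm = depth_water_mm,
         n_fractions = as.integer(n_fractions), modality = modality,
         horizon = horizon, animals = animals, groups = groups),
    class = "rbe_experiment"
  )
}

#' @export
print.rbe_experiment <- function(x, ...) {
  cat(sprintf(
    "Experiment '%s' (%s, LET %s keV/um, %d Fx, horizon %g d)\n",
    x$experiment_id, x$modality,
    ifelse(is.na(x$let_value), "-", format(x$let_value)),
    x$n_fractions, x$horizon))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Read an animal-level cohort CSV into experiment objects
#'
#' The file must carry a header with the columns
#' \code{experiment_id, let_kev_um, depth_mm, n_fractions,
#' total_dose_gy, animal_id, event, time_days, excluded,
#' exclusion_reason} (an optional \code{modality} column is honoured).
#' Doses are total physical doses in Gy over all fractions and are
#' matched exactly as printed -- no tolerance binning.  Dose-0 control
#' rows are permitted and become an ordinary 0-dose group.
#'
#' @param path path to the CSV file.
#' @param schema_options list; \code{horizon} (default 300 days) and
#'   \code{modality_default} (default \code{"carbon"}).
#' @return A named list of [new_experiment()] objects, class
#'   \code{rbe_cohort}.
#' @export
read_cohort <- function(path, schema_options = list()) {
  horizon <- schema_options$horizon %||% 300
  modality_default <- schema_options$modality_default %||% "carbon"
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.cohort_columns, names(raw))
  if (length(miss) > 0)
    stop("cohort CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  bad_dose <- which(raw$total_dose_gy < 0)
  if (length(bad_dose) > 0)
    stop("negative total_dose_gy at row(s): ",
         paste(bad_dose, collapse = ", "))
  bad_time <- which(!(raw$time_days > 0))
  if (length(bad_time) > 0)
    stop("non-positive time_days at row(s): ",
         paste(bad_time, collapse = ", "))
  if (!all(raw$event %in% c(0, 1)))
    stop("event must be 0/1")
  if (is.null(raw$modality)) raw$modality <- modality_default

  out <- lapply(split(raw, raw$experiment_id), function(df) {
    animals <- data.frame(
      animal_id = as.character(df$animal_id),
      total_dose = df$total_dose_gy,
      event = df$event,
      time_days = df$time_days,
      excluded = as.logical(df$excluded),
      exclusion_reason = ifelse(is.na(df$exclusion_reason) |
                                  df$exclusion_reason == "",
                                NA_character_,
                                as.character(df$exclusion_reason)),
      stringsAsFactors = FALSE
    )
    new_experiment(
      animals,
      experiment_id = df$experiment_id[1],
      let_value = df$let_kev_um[1],
      depth_water_mm = df$depth_mm[1],
      n_fractions = df$n_fractions[1],
      modality = df$modality[1],
      horizon = horizon
    )
  })
  # keep file order of first appearance, not alphabetical split() order
  out <- out[unique(raw$experiment_id)]
  structure(out, class = "rbe_cohort")
}

#' Write a cohort back to the CSV dialect read by [read_cohort()]
#'
#' @param cohort a list of \code{rbe_experiment} objects.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  rows <- lapply(cohort, function(e) {
    a <- e$animals
    data.frame(
      experiment_id = e$experiment_id,
      let_kev_um = e$let_value,
      depth_mm = e$depth_water_mm,
      n_fractions = e$n_fractions,
      total_dose_gy = a$total_dose,
      animal_id = a$animal_id,
      event = a$event,
      time_days = a$time_days,
      excluded = as.integer(a$excluded),
      exclusion_reason = ifelse(is.na(a$exclusion_reason), "",
                                a$exclusion_reason),
      modality = e$modality,
      stringsAsFactors = FALSE
    )
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Serialize a result object to JSON
#'
#' Writes the full-precision fields plus a \code{"rounded"} block
#' holding the customary display precision (2 decimals for TD50- and
#' RBE-like quantities).  Non-finite standard errors are serialized as
#' null together with \code{se_estimated = false}.
#'
#' @param results a fit/estimate object produced by this package, or a
#'   plain named list of such objects.
#' @param path output path for the JSON file.
#' @return The path, invisibly.
#' @export
write_results <- function(results, path) {
  payload <- .result_payload(results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read back a JSON file written by [write_results()]
#'
#' @param path path to the JSON file.
#' @return A list mirroring the serialized object(s); the originating
#'   class is restored from the stored \code{.class} field.
#' @export
read_results <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  .restore_result(x)
}

.restore_result <- function(x) {
  if (!is.list(x)) return(x)
  if (!is.null(x$.class)) {
    cls <- x$.class
    x$.class <- NULL
    x$rounded <- NULL
    if (!is.null(x$cov)) x$cov <- matrix(unlist(x$cov), nrow = 2)
    for (nm in c("cl90", "cl90_ab", "cl90_bed")) {
      lo <- x[[paste0(nm, "_low")]]; hi <- x[[paste0(nm, "_high")]]
      if (!is.null(lo)) {
        x[[nm]] <- c(low = lo, high = hi)
        x[[paste0(nm, "_low")]] <- NULL
        x[[paste0(nm, "_high")]] <- NULL
      }
    }
    return(structure(x, class = cls))
  }
  lapply(x, .restore_result)
}

.round_block <- function(x, digits = 2) {
  lapply(x, function(v) {
    if (is.numeric(v)) round(v, digits) else v
  })
}

.result_payload <- function(x) {
  if (inherits(x, c("dose_response_fit", "lq_fit", "rbe_estimate",
                    "rbe_comparison", "actuarial_estimate"))) {
    out <- unclass(x)
    if (!is.null(out$se_td50) && !is.finite(out$se_td50) &&
        !isTRUE(out$se_estimated)) {
      out$se_td50 <- NA_real_
      out$se_estimated <- FALSE
    }
    # flatten confidence limits to explicit low/high keys
    for (nm in c("cl90", "cl90_ab", "cl90_bed")) {
      if (!is.null(out[[nm]])) {
        v <- as.numeric(out[[nm]])
        out[[paste0(nm, "_low")]] <- v[1]
        out[[paste0(nm, "_high")]] <- v[2]
        out[[nm]] <- NULL
      }
    }
    num <- out[vapply(out, function(v)
      is.numeric(v) && !is.matrix(v), logical(1))]
    out$rounded <- .round_block(num, 2)
    out$.class <- class(x)
    return(out)
  }
  if (is.list(x)) return(lapply(x, .result_payload))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
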