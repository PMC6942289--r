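#' Configuration for [run_pipeline()]
#'
#' @param input path to a cohort CSV ([read_cohort()] dialect), or
#'   NULL to simulate a study replica.
#' @param out_dir output directory (created if absent).
#' @param seed integer seed; drives the simulator when \code{input}
#'   is NULL.
#' @param link dose-response link function, \code{"logit"} or
#'   \code{"probit"}.
#' @param use_actuarial apply the effective-sample-size correction
#'   (default TRUE).
#' @param level confidence level (default 0.90).
#' @param entrance,sobp LET regions for the model benchmark.
#' @param aggregate_over \code{"let"} or \code{"fractions"}.
#' @param model_table optional path to a model RBE CSV (columns
#'   \code{let, n_fractions, rbe}); enables the comparison stage.
#' @param td50_table optional path to a CSV of additional schedules
#'   (columns \code{modality, let_kev_um, n_fractions, td50_gy,
#'   se_gy}), e.g. single- and split-dose tolerance doses, enabling
#'   the joint LQ stage.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(input = NULL, out_dir = tempfile("ionrbe_"),
                            seed = 1, link = "logit",
                            use_actuarial = TRUE, level = 0.90,
                            entrance = c(16, 21),
                            sobp = c(36, 45, 66, 99),
                            aggregate_over = "let",
                            model_table = NULL, td50_table = NULL) {
  stopifnot(level > 0, level < 1,
            length(intersect(entrance, sobp)) == 0)
  structure(list(input = input, out_dir = out_dir, seed = seed,
                 link = link, use_actuarial = use_actuarial,
                 level = level, entrance = entrance, sobp = sobp,
                 aggregate_over = aggregate_over,
                 model_table = model_table, td50_table = td50_table),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load -> actuarial correction -> per-experiment
#' dose-response fits -> RBE ratios against the photon reference ->
#' (optionally) joint LQ analysis per LET and model benchmarking.
#' Writes \code{cohort.csv} (when simulated), \code{fits.json},
#' \code{rbe.json}, optionally \code{lq.json} and \code{cmp.json},
#' plus \code{run_log.txt} echoing the configuration.  Deterministic
#' given the inputs and seed.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the cohort, fits, RBE estimates and
#'   any LQ/comparison results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- .stage("input", {
    if (is.null(config$input)) {
      rep <- make_study_replica(seed = config$seed)
      write_cohort(rep$experiments,
                   file.path(config$out_dir, "cohort.csv"))
      rep$experiments
    } else read_cohort(config$input)
  })

  cohort <- .stage("actuarial", {
    structure(lapply(cohort, apply_actuarial), class = "rbe_cohort")
  })

  fits <- .stage("dose_response", {
    fitable <- Filter(function(e) {
      g <- e$groups
      sum(g$n_raw > 0) >= 2 && any(g$r_raw > 0) &&
        any(g$r_raw < g$n_raw)
    }, cohort)
    lapply(fitable, fit_dose_response,
           use_effective = config$use_actuarial, link = config$link,
           level = config$level)
  })
  write_results(fits, file.path(config$out_dir, "fits.json"))

  rbes <- .stage("rbe", {
    is_photon <- vapply(fits, function(f)
      cohort[[f$experiment_id]]$modality == "photon", logical(1))
    if (!any(is_photon)) list() else {
      photon <- fits[[which(is_photon)[1]]]
      carbon <- fits[!is_photon]
      out <- lapply(carbon, function(f) {
        est <- compute_rbe(photon, f, level = config$level)
        est$let_value <- f$let_value
        est
      })
      names(out) <- vapply(carbon, function(f) f$experiment_id,
                           character(1))
      out
    }
  })
  write_results(rbes, file.path(config$out_dir, "rbe.json"))

  lq <- NULL
  if (!is.null(config$td50_table)) {
    lq <- .stage("lq_analysis", {
      extra <- read.csv(config$td50_table, stringsAsFactors = FALSE)
      need <- c("modality", "let_kev_um", "n_fractions", "td50_gy",
                "se_gy")
      miss <- setdiff(need, names(extra))
      if (length(miss) > 0)
        stop("td50 table lacks column(s): ", paste(miss, collapse = ", "))
      own <- do.call(rbind, lapply(fits, function(f) data.frame(
        modality = cohort[[f$experiment_id]]$modality,
        let_kev_um = f$let_value, n_fractions = f$n_fractions,
        td50_gy = f$td50, se_gy = f$se_td50)))
      tab <- rbind(extra, own)
      keys <- unique(tab[, c("modality", "let_kev_um")])
      res <- list()
      for (i in seq_len(nrow(keys))) {
        sub <- tab[tab$modality == keys$modality[i] &
                     tab$let_kev_um == keys$let_kev_um[i], ]
        if (length(unique(sub$n_fractions)) < 2) next
        key <- sprintf("%s_let%g", keys$modality[i], keys$let_kev_um[i])
        res[[key]] <- fit_lq(data.frame(
          n_fractions = sub$n_fractions, td50 = sub$td50_gy,
          se_td50 = sub$se_gy), level = config$level)
      }
      res
    })
    write_results(lq, file.path(config$out_dir, "lq.json"))
  }

  cmp <- NULL
  if (!is.null(config$model_table)) {
    cmp <- .stage("model_comparison", {
      if (!file.exists(config$model_table))
        stop("model table not found: ", config$model_table)
      model <- read.csv(config$model_table, stringsAsFactors = FALSE)
      expr_tab <- do.call(rbind, lapply(names(rbes), function(id) {
        data.frame(let = rbes[[id]]$let_value,
                   n_fractions = cohort[[id]]$n_fractions,
                   rbe = rbes[[id]]$rbe, se = rbes[[id]]$se)
      }))
      compare_rbe_tables(model, expr_tab,
                         entrance = config$entrance, sobp = config$sobp,
                         aggregate_over = config$aggregate_over)
    })
    write_results(list(comparison = cmp),
                  file.path(config$out_dir, "cmp.json"))
  }

  log <- c(
    sprintf("ionrbe %s on R %s.%s",
            as.character(utils::packageVersion("ionrbe")),
            R.version$major, R.version$minor),
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    "config:",
    vapply(names(unclass(config)), function(k)
      sprintf("  %s = %s", k,
              paste(format(config[[k]] %||% "NULL"), collapse = ", ")),
      character(1)))
  writeLines(log, file.path(config$out_dir, "run_log.txt"))

  invisible(list(cohort = cohort, fits = fits, rbe = rbes, lq = lq,
                 comparison = cmp, config = config))
}
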