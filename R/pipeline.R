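#' Compute signed errors and flanker offsets from a trial table
#'
#' Turns the canonical trial table into the error representation the models
#' consume: `theta = circ_diff(response_ori, target_ori)` (zero indicates
#' the target value) and, for each flanker role present,
#' `off_<role> = circ_diff(ori_<role>, target_ori)`.
#'
#' @param trials canonical trial table with responses, see [read_trials()].
#' @return a data frame of class `crowdmix_errors` with `observer_id`,
#'   `experiment` (if present), `condition`, `theta`, the `off_<role>`
#'   columns and `latent_source` (if present).
#' @export
compute_errors <- function(trials) {
  need <- c("observer_id", "condition", "target_ori", "response_ori")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("trial table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyNA(trials$response_ori)) {
    stop("column `response_ori` contains missing values", call. = FALSE)
  }
  out <- data.frame(
    observer_id = trials$observer_id,
    condition = trials$condition,
    theta = circ_diff(trials$response_ori, trials$target_ori),
    stringsAsFactors = FALSE
  )
  if ("experiment" %in% names(trials)) out$experiment <- trials$experiment
  for (r in flanker_roles()) {
    col <- paste0("ori_", r)
    if (col %in% names(trials) && any(!is.na(trials[[col]]))) {
      off <- rep(NA_real_, nrow(trials))
      ok <- !is.na(trials[[col]])
      off[ok] <- circ_diff(trials[[col]][ok], trials$target_ori[ok])
      out[[paste0("off_", r)]] <- off
    }
  }
  if ("latent_source" %in% names(trials)) {
    out$latent_source <- trials$latent_source
  }
  class(out) <- c("crowdmix_errors", "data.frame")
  out
}

#' Per-observer precision and mean error
#'
#' Precision summarises overall crowding strength as the inverse dispersion
#' of the signed errors after conversion to radians (errors in degrees
#' times pi/180). The default is the inverse of the variance
#' (`mode = "variance"`); the inverse of the standard deviation is available
#' as `mode = "sd"`. Zero-variance cells yield an infinite precision and are
#' flagged with a warning so they can be excluded from group averages.
#'
#' @param errors a `crowdmix_errors` data frame (any number of observers and
#'   conditions).
#' @param mode `"variance"` (default, precision = 1/var) or `"sd"`
#'   (precision = 1/sd).
#' @return a data frame with one row per observer-condition: `observer_id`,
#'   `condition`, `n`, `mean_error` (degrees), `sd_error` (degrees), and
#'   `precision` (1/radians^2 or 1/radians).
#' @export
precision_summary <- function(errors, mode = c("variance", "sd")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(errors), all(c("observer_id", "condition",
                                         "theta") %in% names(errors)))
  cells <- split(errors,
                 list(errors$observer_id, errors$condition), drop = TRUE)
  rows <- lapply(cells, function(cell) {
    if (nrow(cell) < 2L) {
      stop("precision needs at least 2 trials per observer-condition",
           call. = FALSE)
    }
    v_rad <- stats::var(cell$theta * pi / 180)
    prec <- if (v_rad == 0) Inf
            else if (mode == "variance") 1 / v_rad else 1 / sqrt(v_rad)
    data.frame(observer_id = cell$observer_id[1],
               condition = cell$condition[1],
               n = nrow(cell),
               mean_error = mean(cell$theta),
               sd_error = stats::sd(cell$theta),
               precision = prec,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(!is.finite(out$precision))) {
    warning("zero-variance cell(s) produced infinite precision; ",
            "exclude them from group averages", call. = FALSE)
  }
  out[order(out$observer_id, out$condition), , drop = FALSE]
}

#' Realign errors so the first-outer flanker is positive
#'
#' Flips the sign of `theta` and of every flanker offset on trials whose
#' first-outer (1O) flanker lies on the negative side of the target, so that
#' after realignment every `off_1O > 0`. A positive mean of the realigned
#' errors then indicates a bias of reports towards the outer flanker. The
#' operation is idempotent and leaves the likelihood of the symmetric
#' (non-bias) models unchanged.
#'
#' @param errors a `crowdmix_errors` data frame of crowded trials that all
#'   carry a 1O flanker.
#' @return the realigned errors data frame.
#' @export
realign_outward <- function(errors) {
  stopifnot(is.data.frame(errors), "theta" %in% names(errors))
  if (!"off_1O" %in% names(errors) || anyNA(errors$off_1O)) {
    stop("realignment requires a first-outer (1O) flanker on every trial",
         call. = FALSE)
  }
  flip <- errors$off_1O < 0
  out <- errors
  out$theta[flip] <- wrap_error(-errors$theta[flip])
  for (col in grep("^off_", names(errors), value = TRUE)) {
    idx <- which(flip & !is.na(errors[[col]]))
    out[[col]][idx] <- wrap_error(-errors[[col]][idx])
  }
  out
}

#' Candidate model sets per crowding condition
#'
#' The comparison sets used throughout: uncrowded data are described by the
#' standard mixture only; two-flanker data by \{S, M, 2M, 2B\}; four-flanker
#' data by \{S, M, 4M, 4B\}. Bias models are fitted on outward-realigned
#' errors and are dropped (with a message) for conditions without a 1O
#' flanker, where outward realignment is undefined.
#'
#' @return named list of character vectors of model names.
#' @export
default_candidates <- function() {
  list(
    uncrowded = "standard",
    two_flanker = c("standard", "misreport", "two_misreport",
                    "two_misreport_bias"),
    four_flanker = c("standard", "misreport", "four_misreport",
                     "four_misreport_bias")
  )
}

# the maximal independent-misreport model of a condition; its fit supplies
# the per-flanker report rates
.independent_model <- function(condition) {
  switch(condition,
         uncrowded = "standard",
         two_flanker = "two_misreport",
         four_flanker = "four_misreport")
}

#' Fit candidate models to every observer-condition cell
#'
#' Fits each condition's candidate set to each observer independently
#' (non-bias models on raw errors, bias models on outward-realigned errors),
#' compares them by AICc within each cell, and aggregates mean AICc across
#' observers per condition (the group-level model comparison). Fit failures
#' are propagated as flagged rows, never aborting the batch.
#'
#' @param errors a `crowdmix_errors` data frame.
#' @param candidates named list of model-name vectors per condition;
#'   defaults to [default_candidates()].
#' @param n_starts,seed,... forwarded to [fit_mle()]; per-cell seeds are
#'   derived deterministically from `seed`.
#' @return a list with `fits` (nested list
#'   `fits[[observer]][[condition]][[model]]`), `comparison` (per-cell AICc
#'   table with observer/condition columns), and `group` (per
#'   condition-model: mean AICc across observers and its delta to the
#'   condition's best mean).
#' @export
fit_condition_set <- function(errors, candidates = default_candidates(),
                              n_starts = 20L, seed = 1L, ...) {
  stopifnot(is.data.frame(errors))
  observers <- unique(errors$observer_id)
  conditions <- intersect(c("uncrowded", "two_flanker", "four_flanker"),
                          unique(errors$condition))
  fits <- list()
  comp_rows <- list()
  cell_i <- 0L
  for (ob in observers) {
    fits[[ob]] <- list()
    for (cond in conditions) {
      cell_i <- cell_i + 1L
      cell <- errors[errors$observer_id == ob & errors$condition == cond, ,
                     drop = FALSE]
      models <- candidates[[cond]]
      if (is.null(models)) next
      has_1O <- "off_1O" %in% names(cell) && !anyNA(cell$off_1O)
      realigned <- if (has_1O) realign_outward(cell) else NULL
      cell_fits <- list()
      for (mname in models) {
        spec <- model_spec(mname)
        if (spec$has_bias && !has_1O) {
          message("skipping bias model '", mname, "' for ", ob, "/", cond,
                  ": no 1O flanker to realign by")
          next
        }
        dat <- if (spec$has_bias) realigned else cell
        fit <- tryCatch(
          fit_mle(dat, mname, n_starts = n_starts,
                  seed = seed + 7L * cell_i, ...),
          error = function(e) {
            structure(list(model = mname, params = NULL,
                           log_likelihood = NA_real_, n_trials = nrow(cell),
                           k = spec$k, converged = FALSE,
                           n_starts_used = n_starts, seed = seed,
                           error = conditionMessage(e)),
                      class = "crowdmix_fit")
          })
        cell_fits[[mname]] <- fit
      }
      fits[[ob]][[cond]] <- cell_fits
      ok <- cell_fits[vapply(cell_fits, function(f)
        is.finite(f$log_likelihood), logical(1))]
      if (length(ok)) {
        cmp <- compare_models(ok)
        cmp <- cbind(observer_id = ob, condition = cond, cmp,
                     stringsAsFactors = FALSE)
        comp_rows[[length(comp_rows) + 1L]] <- cmp
      }
    }
  }
  comparison <- if (length(comp_rows)) do.call(rbind, comp_rows) else
    data.frame()
  group <- NULL
  if (nrow(comparison)) {
    agg <- stats::aggregate(aicc ~ condition + model, comparison, mean)
    names(agg)[names(agg) == "aicc"] <- "mean_aicc"
    grp <- lapply(split(agg, agg$condition), function(g) {
      g$delta_mean_aicc <- g$mean_aicc - min(g$mean_aicc)
      g$is_best <- g$delta_mean_aicc == 0
      g[order(g$mean_aicc), , drop = FALSE]
    })
    group <- do.call(rbind, grp)
    rownames(group) <- NULL
  }
  list(fits = fits, comparison = comparison, group = group)
}

#' Per-flanker report rates from independent-misreport fits
#'
#' Extracts the fitted independent misreport weight of each flanker role
#' (and the target-report rate `P_T` and guessing rate as their own rows)
#' from two-/four-misreport fits, and aggregates group means and SDs across
#' observers.
#'
#' @param fits the nested fit list from [fit_condition_set()]; only fits of
#'   independent-misreport models (and the uncrowded standard fit, for its
#'   `P_T`) contribute.
#' @return a list with `rates` (observer, condition, role, rate; role is a
#'   flanker role, `"target"`, or `"guess"`) and `group` (condition, role,
#'   mean, sd, n).
#' @export
flanker_report_rates <- function(fits) {
  rows <- list()
  for (ob in names(fits)) {
    for (cond in names(fits[[ob]])) {
      mname <- .independent_model(cond)
      fit <- fits[[ob]][[cond]][[mname]]
      if (is.null(fit) || is.null(fit$params)) next
      p <- fit$params
      rr <- data.frame(
        observer_id = ob, condition = cond,
        role = c("target", "guess", names(p$betas)),
        rate = c(target_report_rate(p), p$gamma, as.numeric(p$betas)),
        stringsAsFactors = FALSE
      )
      rows[[length(rows) + 1L]] <- rr
    }
  }
  rates <- if (length(rows)) do.call(rbind, rows) else
    data.frame(observer_id = character(0), condition = character(0),
               role = character(0), rate = numeric(0))
  group <- NULL
  if (nrow(rates)) {
    group <- do.call(rbind, lapply(
      split(rates, list(rates$condition, rates$role), drop = TRUE),
      function(g) data.frame(condition = g$condition[1], role = g$role[1],
                             mean = mean(g$rate), sd = stats::sd(g$rate),
                             n = nrow(g), stringsAsFactors = FALSE)))
    group <- group[order(group$condition, group$role), , drop = FALSE]
    rownames(group) <- NULL
  }
  list(rates = rates, group = group)
}

#' Binned distribution of reports around each flanker's value
#'
#' For each flanker role, histograms the circular difference between the
#' response and that flanker's orientation (`theta - off_role`, wrapped), so
#' a peak in the 0-centred bin indicates reports of that flanker. Intended
#' for plotting and eyeball validation.
#'
#' @param errors a `crowdmix_errors` data frame.
#' @param binwidth bin width in degrees (default 10; must divide 180).
#' @return a data frame with `role`, `bin_mid` (degrees), `count`.
#' @export
flanker_relative_histogram <- function(errors, binwidth = 10) {
  stopifnot(is.data.frame(errors), 180 %% binwidth == 0)
  breaks <- seq(-90, 90, by = binwidth)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  rows <- list()
  for (col in grep("^off_", names(errors), value = TRUE)) {
    ok <- !is.na(errors[[col]])
    if (!any(ok)) next
    rel <- wrap_error(errors$theta[ok] - errors[[col]][ok])
    rel[rel == 90] <- -90 + 1e-9  # +90 boundary falls in the first bin
    cnt <- as.integer(table(cut(rel, breaks, include.lowest = TRUE)))
    rows[[length(rows) + 1L]] <- data.frame(
      role = sub("^off_", "", col), bin_mid = mids, count = cnt,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full crowding-error analysis
#'
#' End-to-end composition: trial table (given, or simulated from a design
#' configuration plus generative scenario) -> signed errors -> per-observer
#' precision -> per-condition candidate fits and AICc comparison ->
#' per-flanker report rates -> observer summary table. Deterministic given
#' the inputs and `seed`.
#'
#' @param trials canonical trial table, or NULL to simulate.
#' @param config,scen a [design_config()] and [scenario()], used when
#'   `trials` is NULL.
#' @param candidates candidate model sets, see [fit_condition_set()].
#' @param n_starts,seed forwarded to the fitting stage.
#' @param precision_mode `"variance"` or `"sd"`, see [precision_summary()].
#' @param out_dir optional directory; when given, the summary, comparison,
#'   group-comparison and rate tables are written there as CSV together
#'   with a plain-text run log.
#' @return a list with `trials`, `errors`, `precision`, `fits`,
#'   `comparison`, `group`, `rates`, and `summary` — one row per
#'   observer-condition with `mean_error`, `precision`, `best_model` (by
#'   per-observer AICc), and the parameters of the condition's independent
#'   model (`gamma`, `sigma`, `p_t`, `beta_<role>` columns, `mu` where
#'   fitted).
#' @export
run_pipeline <- function(trials = NULL, config = NULL, scen = NULL,
                         candidates = default_candidates(),
                         n_starts = 20L, seed = 1L,
                         precision_mode = c("variance", "sd"),
                         out_dir = NULL) {
  precision_mode <- match.arg(precision_mode)
  if (is.null(trials)) {
    if (is.null(config) || is.null(scen)) {
      stop("provide `trials`, or both `config` and `scen`", call. = FALSE)
    }
    trials <- generate_dataset(config, scen)
  }
  errors <- compute_errors(trials)
  precision <- precision_summary(errors, mode = precision_mode)
  fitres <- fit_condition_set(errors, candidates = candidates,
                              n_starts = n_starts, seed = seed)
  rates <- flanker_report_rates(fitres$fits)

  summary_rows <- list()
  for (ob in names(fitres$fits)) {
    for (cond in names(fitres$fits[[ob]])) {
      prow <- precision[precision$observer_id == ob &
                          precision$condition == cond, , drop = FALSE]
      cmp <- fitres$comparison
      cmp <- cmp[cmp$observer_id == ob & cmp$condition == cond, ,
                 drop = FALSE]
      best <- if (nrow(cmp)) cmp$model[cmp$is_best] else NA_character_
      fit <- fitres$fits[[ob]][[cond]][[.independent_model(cond)]]
      row <- data.frame(observer_id = ob, condition = cond,
                        n = prow$n, mean_error = prow$mean_error,
                        precision = prow$precision,
                        best_model = best, stringsAsFactors = FALSE)
      if (!is.null(fit$params)) {
        p <- fit$params
        row$gamma <- p$gamma
        row$sigma <- p$sigma
        row$p_t <- target_report_rate(p)
        for (r in names(p$betas)) row[[paste0("beta_", r)]] <- p$betas[[r]]
      }
      summary_rows[[length(summary_rows) + 1L]] <- row
    }
  }
  summary <- if (length(summary_rows)) {
    cols <- unique(unlist(lapply(summary_rows, names)))
    do.call(rbind, lapply(summary_rows, function(r) {
      for (cl in setdiff(cols, names(r))) r[[cl]] <- NA
      r[cols]
    }))
  } else data.frame()

  result <- list(trials = trials, errors = errors, precision = precision,
                 fits = fitres$fits, comparison = fitres$comparison,
                 group = fitres$group, rates = rates, summary = summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(out_dir, "observer_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(fitres$comparison,
                     file.path(out_dir, "model_comparison.csv"),
                     row.names = FALSE)
    if (!is.null(fitres$group)) {
      utils::write.csv(fitres$group,
                       file.path(out_dir, "group_comparison.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(rates$rates, file.path(out_dir, "report_rates.csv"),
                     row.names = FALSE)
    log <- c(sprintf("crowdmix %s run log",
                     as.character(utils::packageVersion("crowdmix"))),
             sprintf("time: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
             sprintf("R: %s", R.version.string),
             sprintf("seed: %d | n_starts: %d | precision_mode: %s",
                     seed, n_starts, precision_mode),
             sprintf("trials: %d rows, %d observers, conditions: %s",
                     nrow(trials), length(unique(trials$observer_id)),
                     paste(unique(trials$condition), collapse = ", ")))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  result
}
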