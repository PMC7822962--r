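#' Stimulus-design configuration for the synthetic generator
#'
#' Encodes the radial crowding designs of the two experiments. In both, a
#' Gabor target on the horizontal meridian is surrounded by collinear
#' flankers at 1.5 degree centre-to-centre spacing. Experiment 1 places the
#' target at 7 degrees eccentricity, with flankers at 5.5/8.5 degrees
#' (two-flanker) or 4/5.5/8.5/10 degrees (four-flanker). Experiment 2 shifts
#' the reported item one position outward: target at 8.5 degrees, flankers
#' at 5.5/7 (two-flanker, both inner) or 4/5.5/7/10 (four-flanker). Each
#' observer runs 200 trials per condition by default (600 in total over the
#' three conditions).
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param n_observers number of simulated observers.
#' @param trials_per_condition trials per crowding condition per observer.
#' @param conditions subset of `c("uncrowded", "two_flanker", "four_flanker")`.
#' @param seed integer seed for the design RNG.
#' @return a list of class `crowdmix_design_config`.
#' @export
design_config <- function(experiment = c("exp1", "exp2"),
                          n_observers = 13L,
                          trials_per_condition = 200L,
                          conditions = c("uncrowded", "two_flanker",
                                         "four_flanker"),
                          seed = 1L) {
  experiment <- match.arg(experiment)
  all_cond <- c("uncrowded", "two_flanker", "four_flanker")
  stopifnot(all(conditions %in% all_cond),
            n_observers >= 0, trials_per_condition >= 0)
  structure(list(experiment = experiment,
                 n_observers = as.integer(n_observers),
                 trials_per_condition = as.integer(trials_per_condition),
                 conditions = conditions,
                 seed = as.integer(seed)),
            class = "crowdmix_design_config")
}

#' Flanker/target geometry of a condition
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param condition one of the three crowding conditions.
#' @return a list with `target_ecc` (degrees of visual angle) and
#'   `flankers`, a named numeric vector of flanker eccentricities keyed by
#'   role (inner to outer order).
#' @export
condition_geometry <- function(experiment, condition) {
  geom <- list(
    exp1 = list(
      target_ecc = 7,
      uncrowded = c(),
      two_flanker = c("1I" = 5.5, "1O" = 8.5),
      four_flanker = c("2I" = 4, "1I" = 5.5, "1O" = 8.5, "2O" = 10)
    ),
    exp2 = list(
      target_ecc = 8.5,
      uncrowded = c(),
      two_flanker = c("2I" = 5.5, "1I" = 7),
      four_flanker = c("3I" = 4, "2I" = 5.5, "1I" = 7, "1O" = 10)
    )
  )
  g <- geom[[match.arg(experiment, c("exp1", "exp2"))]]
  condition <- match.arg(condition,
                         c("uncrowded", "two_flanker", "four_flanker"))
  list(target_ecc = g$target_ecc, flankers = g[[condition]])
}

# minimum circular target-flanker orientation separation, degrees
.MIN_FLANKER_SEP <- 15

# draw n flanker orientations from the 180-value grid, each at least 15
# degrees (circular) from its target; vectorised rejection sampling
.draw_flankers <- function(targets) {
  n <- length(targets)
  out <- sample.int(180, n, replace = TRUE)
  bad <- abs(circ_diff(out, targets)) < .MIN_FLANKER_SEP
  while (any(bad)) {
    out[bad] <- sample.int(180, sum(bad), replace = TRUE)
    bad <- abs(circ_diff(out, targets)) < .MIN_FLANKER_SEP
  }
  out
}

#' Generate a stimulus design (trial table without responses)
#'
#' Draws target and flanker orientations uniformly from the 180 discrete
#' orientation values (1..180 degrees), enforcing that every flanker differs
#' from its target by at least 15 degrees on the 180-periodic circle
#' (rejection sampling). Hemifields are balanced within each
#' observer-condition cell and trial order is fully randomised within
#' observer. Deterministic given `config$seed`.
#'
#' @param config a [design_config()].
#' @return a data frame in the canonical trial-table schema: `observer_id`,
#'   `experiment`, `condition`, `hemifield`, `target_ori`, `ori_3I`,
#'   `ori_2I`, `ori_1I`, `ori_1O`, `ori_2O` (NA for absent positions),
#'   `target_ecc`, `response_ori` (NA until simulated or observed).
#' @export
generate_design <- function(config) {
  stopifnot(inherits(config, "crowdmix_design_config"))
  roles <- flanker_roles()
  .with_seed(config$seed, {
    per_obs <- lapply(seq_len(config$n_observers), function(ob) {
      per_cond <- lapply(config$conditions, function(cond) {
        nt <- config$trials_per_condition
        if (nt == 0L) return(NULL)
        geom <- condition_geometry(config$experiment, cond)
        targets <- sample.int(180, nt, replace = TRUE)
        df <- data.frame(
          observer_id = sprintf("obs%02d", ob),
          experiment = config$experiment,
          condition = cond,
          hemifield = sample(rep_len(c("left", "right"), nt)),
          target_ori = as.numeric(targets),
          stringsAsFactors = FALSE
        )
        for (r in roles) df[[paste0("ori_", r)]] <- NA_real_
        for (r in names(geom$flankers)) {
          df[[paste0("ori_", r)]] <- as.numeric(.draw_flankers(targets))
        }
        df$target_ecc <- geom$target_ecc
        df$response_ori <- NA_real_
        df
      })
      obdf <- do.call(rbind, per_cond)
      if (is.null(obdf)) return(NULL)
      obdf[sample.int(nrow(obdf)), , drop = FALSE]
    })
    out <- do.call(rbind, per_obs)
    if (is.null(out)) {
      out <- data.frame(observer_id = character(0))
    }
    rownames(out) <- NULL
    out
  })
}

#' Generative scenario: one true model per condition
#'
#' Pairs each crowding condition with a generating model and parameter
#' vector used by [simulate_responses()]. The uncrowded condition must use
#' the standard model (there are no flankers to misreport).
#'
#' @param uncrowded,two_flanker,four_flanker each a list
#'   `list(model = <name>, params = mixture_params(...))`, or NULL if the
#'   condition is not simulated. For independent-misreport generators the
#'   betas are matched to the condition's flanker roles by position (inner
#'   to outer) unless named.
#' @param seed integer seed for response sampling.
#' @return a list of class `crowdmix_scenario`.
#' @export
scenario <- function(uncrowded = NULL, two_flanker = NULL,
                     four_flanker = NULL, seed = 1L) {
  sc <- list(uncrowded = uncrowded, two_flanker = two_flanker,
             four_flanker = four_flanker, seed = as.integer(seed))
  if (!is.null(uncrowded)) {
    spec <- model_spec(uncrowded$model)
    if (spec$flanker_structure != "none") {
      stop("uncrowded condition must use the standard model", call. = FALSE)
    }
  }
  for (cond in c("uncrowded", "two_flanker", "four_flanker")) {
    if (!is.null(sc[[cond]])) validate_params(sc[[cond]]$params)
  }
  structure(sc, class = "crowdmix_scenario")
}

#' Simulate responses for a stimulus design
#'
#' For each trial, a latent report source is drawn with probabilities
#' (`P_T`, `gamma`, `beta_i`) for (target, guess, flanker i); the response is
#' the source orientation plus von Mises report noise with variability
#' `sigma` (guesses are uniform over the 180-degree wheel). For bias-model
#' generators the target component's mean is shifted by `mu` towards the
#' first-outer flanker (the shift is applied with the sign of that trial's
#' 1O offset). The latent source is recorded for oracle checks.
#' Deterministic given `scenario$seed`.
#'
#' @param trials a design table from [generate_design()].
#' @param scen a [scenario()].
#' @return the trial table with `response_ori` filled in and a
#'   `latent_source` column (`"target"`, `"guess"`, or a flanker role).
#' @export
simulate_responses <- function(trials, scen) {
  stopifnot(inherits(scen, "crowdmix_scenario"))
  out <- trials
  out$latent_source <- NA_character_
  .with_seed(scen$seed, {
    for (cond in unique(trials$condition)) {
      gen <- scen[[cond]]
      if (is.null(gen)) {
        stop("scenario has no generator for condition '", cond, "'",
             call. = FALSE)
      }
      spec <- model_spec(gen$model)
      rows <- which(trials$condition == cond)
      sub <- trials[rows, , drop = FALSE]
      role_cols <- paste0("ori_", flanker_roles())
      present <- role_cols[role_cols %in% names(sub)]
      present <- present[colSums(!is.na(sub[present])) > 0]
      roles <- sub("^ori_", "", present)
      m <- length(roles)
      if (!is.na(spec$n_flankers_required) &&
          spec$n_flankers_required != m) {
        stop("generator '", gen$model, "' incompatible with condition '",
             cond, "' (", m, " flankers)", call. = FALSE)
      }
      if (spec$has_bias && !"1O" %in% roles) {
        stop("bias generator needs a 1O flanker in condition '", cond, "'",
             call. = FALSE)
      }
      p <- gen$params
      betas <- switch(spec$flanker_structure,
                      none = numeric(0),
                      pooled = rep(p$betas / m, m),
                      independent = {
                        b <- p$betas
                        if (!is.null(names(b)) && all(roles %in% names(b))) {
                          b[roles]
                        } else b
                      })
      roles_used <- if (spec$flanker_structure == "none") character(0) else
        roles
      probs <- c(target = max(0, 1 - p$gamma - sum(p$betas)),
                 guess = p$gamma,
                 stats::setNames(as.numeric(betas), roles_used))
      src <- sample(names(probs), nrow(sub), replace = TRUE, prob = probs)
      resp <- numeric(nrow(sub))
      noise <- rvm_deg(nrow(sub), p$sigma)
      is_t <- src == "target"
      if (any(is_t)) {
        mu_eff <- 0
        if (spec$has_bias && p$mu != 0) {
          mu_eff <- p$mu * sign(circ_diff(sub$ori_1O[is_t],
                                          sub$target_ori[is_t]))
        }
        resp[is_t] <- sub$target_ori[is_t] + mu_eff + noise[is_t]
      }
      is_g <- src == "guess"
      if (any(is_g)) resp[is_g] <- stats::runif(sum(is_g), 0, 180)
      for (r in roles) {
        is_f <- src == r
        if (any(is_f)) {
          resp[is_f] <- sub[[paste0("ori_", r)]][is_f] + noise[is_f]
        }
      }
      out$response_ori[rows] <- wrap_ori(resp)
      out$latent_source[rows] <- src
    }
  })
  out
}

#' Generate a complete synthetic observer dataset
#'
#' Composition of [generate_design()] and [simulate_responses()].
#'
#' @param config a [design_config()].
#' @param scen a [scenario()].
#' @return the canonical trial table with responses and latent sources.
#' @export
generate_dataset <- function(config, scen) {
  design <- generate_design(config)
  if (nrow(design) == 0L) {
    design$response_ori <- numeric(0)
    design$latent_source <- character(0)
    return(design)
  }
  simulate_responses(design, scen)
}

#' Read / write a canonical trial table
#'
#' The canonical schema is CSV (UTF-8, header row) with columns
#' `observer_id`, `experiment`, `condition`, `hemifield`, `target_ori`,
#' `ori_3I`, `ori_2I`, `ori_1I`, `ori_1O`, `ori_2O` (empty for absent
#' positions), `response_ori`, and optionally `latent_source`. A column
#' mapping can rename externally named columns on read.
#'
#' @param path file path.
#' @param mapping optional named character vector `c(canonical = "external")`
#'   renaming columns of an external file to the canonical schema.
#' @param trials a trial table.
#' @return `read_trials()`: the trial table; `write_trials()`: `path`,
#'   invisibly.
#' @export
read_trials <- function(path, mapping = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      ext <- mapping[[canon]]
      if (!ext %in% names(df)) {
        stop("mapped column not found in file: ", ext, call. = FALSE)
      }
      names(df)[names(df) == ext] <- canon
    }
  }
  need <- c("observer_id", "condition", "target_ori", "response_ori")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("trial table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}
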