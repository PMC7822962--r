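#' The six crowding mixture models
#'
#' Every model describes the distribution of signed estimation errors theta
#' (report minus target, 180-degree periodic) on a single trial, given the
#' flanker offsets theta*_i (flanker minus target) of that trial:
#'
#' * `standard` (S): `(1 - gamma) f(theta) + gamma / 180` — a zero-mean von
#'   Mises report-noise component plus uniform guessing.
#' * `misreport` (M): adds one pooled misreport weight `beta` split equally
#'   over the m flankers: `+ beta * (1/m) * sum_i f(theta - theta*_i)`.
#' * `two_misreport` (2M): an independent weight per flanker of a
#'   two-flanker trial (`beta_1I`, `beta_1O`).
#' * `two_misreport_bias` (2B): 2M plus a mean-bias `mu` on the target
#'   component, fitted on outward-realigned errors.
#' * `four_misreport` (4M): independent weights for the four flankers
#'   (`beta_2I`, `beta_1I`, `beta_1O`, `beta_2O`).
#' * `four_misreport_bias` (4B): 4M plus the target mean-bias `mu`.
#'
#' All von Mises components share one variability `sigma`; flanker component
#' means are fixed at the observed offsets. The target weight is
#' `P_T = 1 - gamma - sum(beta)`.
#'
#' @return `model_catalog()` returns a named list of the six model specs in
#'   canonical order; `model_spec(name)` returns one spec: a list with
#'   `name`, `label`, `flanker_structure` (`"none"`, `"pooled"`, or the
#'   number of independent components), `n_flankers_required` (NA when any
#'   number is accepted), `has_bias`, `k` (free-parameter count) and
#'   `parameter_names`.
#' @examples
#' names(model_catalog())
#' model_spec("two_misreport")$k  # 4
#' @export
model_catalog <- function() {
  specs <- list(
    list(name = "standard", label = "S", flanker_structure = "none",
         n_flankers_required = NA_integer_, has_bias = FALSE,
         parameter_names = c("gamma", "sigma")),
    list(name = "misreport", label = "M", flanker_structure = "pooled",
         n_flankers_required = NA_integer_, has_bias = FALSE,
         parameter_names = c("gamma", "sigma", "beta")),
    list(name = "two_misreport", label = "2M", flanker_structure = "independent",
         n_flankers_required = 2L, has_bias = FALSE,
         parameter_names = c("gamma", "sigma", "beta_1I", "beta_1O")),
    list(name = "two_misreport_bias", label = "2B",
         flanker_structure = "independent",
         n_flankers_required = 2L, has_bias = TRUE,
         parameter_names = c("gamma", "sigma", "beta_1I", "beta_1O", "mu")),
    list(name = "four_misreport", label = "4M",
         flanker_structure = "independent",
         n_flankers_required = 4L, has_bias = FALSE,
         parameter_names = c("gamma", "sigma",
                             "beta_2I", "beta_1I", "beta_1O", "beta_2O")),
    list(name = "four_misreport_bias", label = "4B",
         flanker_structure = "independent",
         n_flankers_required = 4L, has_bias = TRUE,
         parameter_names = c("gamma", "sigma",
                             "beta_2I", "beta_1I", "beta_1O", "beta_2O", "mu"))
  )
  specs <- lapply(specs, function(s) {
    s$k <- length(s$parameter_names)
    class(s) <- "crowdmix_model"
    s
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' @rdname model_catalog
#' @param name model name (one of the six in `model_catalog()`) or a spec
#'   returned by it (passed through).
#' @export
model_spec <- function(name) {
  if (inherits(name, "crowdmix_model")) return(name)
  cat <- model_catalog()
  if (!is.character(name) || length(name) != 1L || !name %in% names(cat)) {
    stop("unknown model: ", deparse(name), "; see model_catalog()",
         call. = FALSE)
  }
  cat[[name]]
}

#' @export
print.crowdmix_model <- function(x, ...) {
  cat(sprintf("<crowdmix model %s (%s): %d free parameters: %s>\n",
              x$label, x$name, x$k,
              paste(x$parameter_names, collapse = ", ")))
  invisible(x)
}

#' Construct and validate a mixture parameter vector
#'
#' @param gamma guessing rate in [0, 1].
#' @param sigma report variability in degrees, > 0.
#' @param betas numeric vector of misreport weights (empty for the standard
#'   model, length 1 for the pooled model, one per flanker otherwise); may
#'   be named by flanker role.
#' @param mu target mean bias in degrees, in (-90, 90] (bias models only).
#' @return a validated list of class `crowdmix_params`. The implied target
#'   weight `1 - gamma - sum(betas)` must be non-negative.
#' @export
mixture_params <- function(gamma, sigma, betas = numeric(0), mu = 0) {
  p <- structure(list(gamma = gamma, sigma = sigma,
                      betas = betas, mu = mu),
                 class = "crowdmix_params")
  validate_params(p)
  p
}

#' @rdname mixture_params
#' @param params a `crowdmix_params` list (or plain list with the same
#'   fields).
#' @export
validate_params <- function(params) {
  with(params, {
    stopifnot(
      is.numeric(gamma), length(gamma) == 1L, gamma >= 0, gamma <= 1,
      is.numeric(sigma), length(sigma) == 1L, sigma > 0,
      is.numeric(betas), all(betas >= 0),
      is.numeric(mu), length(mu) == 1L, mu > -90, mu <= 90
    )
    if (gamma + sum(betas) > 1 + 1e-12) {
      stop("gamma + sum(betas) exceeds 1", call. = FALSE)
    }
  })
  invisible(params)
}

#' Target-report rate implied by a parameter vector
#'
#' The probability mass of reports centred on the target,
#' `P_T = 1 - gamma - sum(betas)`.
#'
#' @inheritParams validate_params
#' @return a probability in [0, 1].
#' @export
target_report_rate <- function(params) {
  validate_params(params)
  max(0, min(1, 1 - params$gamma - sum(params$betas)))
}

# Extract theta and the flanker-offset matrix (columns in inner -> outer
# role order) from a trial-errors data frame; checks model compatibility.
.trial_matrices <- function(errors, model) {
  model <- model_spec(model)
  if (!is.data.frame(errors) || !"theta" %in% names(errors)) {
    stop("`errors` must be a data frame with a `theta` column", call. = FALSE)
  }
  roles <- flanker_roles()
  cols <- paste0("off_", roles)
  present <- cols[cols %in% names(errors)]
  present <- present[vapply(present, function(cl) !all(is.na(errors[[cl]])),
                            logical(1))]
  if (length(present)) {
    off <- as.matrix(errors[present])
    if (anyNA(off)) {
      stop("flanker offset columns contain NA within used roles",
           call. = FALSE)
    }
  } else {
    off <- matrix(numeric(0), nrow = nrow(errors), ncol = 0)
  }
  m <- ncol(off)
  if (model$flanker_structure == "pooled" && m < 1L) {
    stop("model '", model$name, "' needs at least one flanker offset",
         call. = FALSE)
  }
  if (!is.na(model$n_flankers_required) && m != model$n_flankers_required) {
    stop("model '", model$name, "' requires ", model$n_flankers_required,
         " flankers, trials have ", m, call. = FALSE)
  }
  list(theta = errors$theta, offsets = off,
       roles = sub("^off_", "", present), model = model)
}

# expand the parameter vector into per-component weights matching the
# offset matrix: pooled beta is split 1/m over the m flankers
.component_weights <- function(params, m, model) {
  if (model$flanker_structure == "none") {
    if (length(params$betas) != 0 && any(params$betas > 0)) {
      stop("standard model takes no misreport weights", call. = FALSE)
    }
    return(numeric(0))
  }
  if (model$flanker_structure == "pooled") {
    if (length(params$betas) != 1L) {
      stop("pooled misreport model takes a single beta", call. = FALSE)
    }
    return(rep(params$betas / m, m))
  }
  if (length(params$betas) != m) {
    stop("independent misreport model needs one beta per flanker (",
         m, "), got ", length(params$betas), call. = FALSE)
  }
  params$betas
}

#' Mixture density of a trial's estimation error
#'
#' Evaluates the model density at each trial's observed error given that
#' trial's flanker offsets. The density is per degree of orientation and
#' integrates to 1 over any 180-degree span for every fixed trial.
#'
#' @param params a `crowdmix_params` vector, see [mixture_params()].
#' @param errors a trial-errors data frame as produced by
#'   [compute_errors()]: column `theta` plus `off_<role>` offset columns for
#'   the flanker roles present.
#' @param model a model name or spec, see [model_catalog()].
#' @return numeric vector of densities, one per row of `errors`.
#' @export
trial_density <- function(params, errors, model) {
  validate_params(params)
  tm <- .trial_matrices(errors, model)
  w <- as.numeric(.component_weights(params, ncol(tm$offsets), tm$model))
  if (!tm$model$has_bias && params$mu != 0) {
    stop("model '", tm$model$name, "' has no bias parameter", call. = FALSE)
  }
  kappa <- sigma_to_kappa(params$sigma)
  p_t <- 1 - params$gamma - sum(params$betas)
  dens <- p_t * vm_density_kappa(tm$theta - params$mu, kappa) +
    params$gamma / 180
  for (j in seq_along(w)) {
    dens <- dens + w[j] * vm_density_kappa(tm$theta - tm$offsets[, j], kappa)
  }
  unname(dens)
}

#' Log-likelihood of a trial set under a mixture model
#'
#' @inheritParams trial_density
#' @return the summed log density over trials.
#' @export
log_likelihood <- function(params, errors, model) {
  if (!is.data.frame(errors) || nrow(errors) == 0L) {
    stop("`errors` must be a non-empty trial-errors data frame",
         call. = FALSE)
  }
  sum(log(trial_density(params, errors, model)))
}

#' Canonical flanker role order (inner to outer)
#'
#' @return character vector `c("3I", "2I", "1I", "1O", "2O")`.
#' @export
flanker_roles <- function() c("3I", "2I", "1I", "1O", "2O")
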