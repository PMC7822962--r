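# run code with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Unconstrained parameterisation used by the optimiser:
#   weights (P_T, gamma, beta_1..b) = softmax(0, z_1..nw)  -- exact simplex
#   log kappa = logit-bounded between kappa(sigma_hi) and kappa(sigma_lo)
#   mu = logit-bounded on mu_bounds (bias models only)
.make_negll <- function(theta, offsets, model, sigma_bounds, mu_bounds) {
  m <- ncol(offsets)
  nw <- if (model$flanker_structure == "none") 1L
        else if (model$flanker_structure == "pooled") 2L
        else 1L + m
  # precompute doubled-angle cosines: cos(2(theta - off)) expands over the
  # per-trial constants, leaving only exp() in the hot loop
  c0 <- cos(.deg2double(theta))
  s0 <- sin(.deg2double(theta))
  cfl <- NULL
  if (m > 0L) {
    cfl <- c0 * cos(.deg2double(offsets)) + s0 * sin(.deg2double(offsets))
  }
  lk_lo <- log(sigma_to_kappa(sigma_bounds[2]))  # wide sigma -> small kappa
  lk_hi <- log(sigma_to_kappa(sigma_bounds[1]))
  has_bias <- model$has_bias
  pooled <- model$flanker_structure == "pooled"

  negll <- function(par) {
    z <- par[seq_len(nw)]
    e <- exp(c(0, z) - max(0, z))
    w <- e / sum(e)                       # (P_T, gamma, betas...)
    lk <- lk_lo + (lk_hi - lk_lo) * stats::plogis(par[nw + 1L])
    kappa <- exp(lk)
    i0e <- 180 * besselI(kappa, 0, expon.scaled = TRUE)
    if (has_bias) {
      mu <- mu_bounds[1] +
        diff(mu_bounds) * stats::plogis(par[nw + 2L])
      ct <- c0 * cos(.deg2double(mu)) + s0 * sin(.deg2double(mu))
    } else {
      ct <- c0
    }
    dens <- w[1] * exp(kappa * (ct - 1)) / i0e + w[2] / 180
    if (m > 0L && nw > 1L) {
      wb <- if (pooled) rep(w[3] / m, m) else w[-(1:2)]
      for (j in seq_len(m)) {
        dens <- dens + wb[j] * exp(kappa * (cfl[, j] - 1)) / i0e
      }
    }
    -sum(log(dens))
  }

  decode <- function(par) {
    z <- par[seq_len(nw)]
    e <- exp(c(0, z) - max(0, z))
    w <- e / sum(e)
    lk <- lk_lo + (lk_hi - lk_lo) * stats::plogis(par[nw + 1L])
    betas <- if (nw > 1L) w[-(1:2)] else numeric(0)
    mu <- if (has_bias) {
      mu_bounds[1] + diff(mu_bounds) * stats::plogis(par[nw + 2L])
    } else 0
    list(gamma = w[2], sigma = kappa_to_sigma(exp(lk)), betas = betas,
         mu = mu)
  }

  list(negll = negll, decode = decode, nw = nw,
       npar = nw + 1L + as.integer(has_bias),
       lk_lo = lk_lo, lk_hi = lk_hi)
}

# map a Latin-hypercube row in [0,1]^d to an unconstrained start:
# first nw+1 uniforms -> Dirichlet(1) weights on the simplex, next one ->
# log-uniform sigma, last (bias) -> uniform mu
.lhs_start <- function(u, obj) {
  nw <- obj$nw
  g <- -log(pmax(u[seq_len(nw + 1L)], 1e-12))
  w <- g / sum(g)
  z <- log(pmax(w[-1], 1e-8) / max(w[1], 1e-8))
  t_sig <- stats::qlogis(pmin(pmax(u[nw + 2L], 1e-6), 1 - 1e-6))
  par <- c(z, t_sig)
  if (obj$npar > nw + 1L) {
    par <- c(par, stats::qlogis(pmin(pmax(u[nw + 3L], 1e-6), 1 - 1e-6)))
  }
  par
}

#' Maximum-likelihood fit of a mixture model to one trial set
#'
#' Fits a model from [model_catalog()] to the trials of a single observer
#' and condition by multi-start bounded maximum likelihood. The mixture
#' weights (target, guess, per-flanker misreport) are optimised through an
#' exact softmax simplex reparameterisation, and sigma through a bounded
#' transform of the von Mises concentration, so returned parameters always
#' satisfy the simplex and bound constraints. Starting points are a Latin
#' hypercube over the bounds with the weights drawn on the simplex; each
#' start is refined by Nelder-Mead with a quasi-Newton polish. Results are
#' deterministic given (`errors`, `seed`).
#'
#' @param errors trial-errors data frame for one observer-condition, see
#'   [compute_errors()].
#' @param model model name or spec.
#' @param n_starts number of multi-start optimisations (default 20).
#' @param seed integer seed controlling start placement.
#' @param tol relative convergence tolerance on the objective.
#' @param sigma_bounds length-2 bounds on sigma in degrees.
#' @param mu_bounds length-2 bounds on the bias mean in degrees.
#' @param min_trials minimum number of trials accepted for fitting.
#' @return an object of class `crowdmix_fit`: a list with `model`, `params`
#'   ([mixture_params()], betas named by flanker role), `log_likelihood`,
#'   `n_trials`, `k`, `converged`, `n_starts_used` and `seed`.
#' @export
fit_mle <- function(errors, model, n_starts = 20L, seed = 1L, tol = 1e-8,
                    sigma_bounds = c(0.5, 80), mu_bounds = c(-45, 45),
                    min_trials = 20L) {
  tm <- .trial_matrices(errors, model)
  model <- tm$model
  n <- length(tm$theta)
  if (n < min_trials) {
    stop("need at least ", min_trials, " trials, got ", n, call. = FALSE)
  }
  obj <- .make_negll(tm$theta, tm$offsets, model, sigma_bounds, mu_bounds)

  # one LHS column per weight (nw + 1 on the simplex), one for sigma,
  # one for mu in bias models
  n_lhs <- obj$nw + 2L + as.integer(model$has_bias)
  starts <- .with_seed(seed, lhs::randomLHS(n_starts, n_lhs))
  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(n_starts)) {
    par0 <- .lhs_start(starts[i, ], obj)
    fit <- tryCatch(
      stats::optim(par0, obj$negll, method = "Nelder-Mead",
                   control = list(reltol = tol, maxit = 3000L)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    polished <- tryCatch(
      stats::optim(fit$par, obj$negll, method = "BFGS",
                   control = list(reltol = tol, maxit = 500L)),
      error = function(e) NULL
    )
    if (!is.null(polished) && polished$value <= fit$value) fit <- polished
    any_conv <- any_conv || fit$convergence == 0L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(model = model$name, params = NULL,
                          log_likelihood = NA_real_, n_trials = n,
                          k = model$k, converged = FALSE,
                          n_starts_used = n_starts, seed = seed,
                          flanker_roles = tm$roles),
                     class = "crowdmix_fit"))
  }
  dec <- obj$decode(best$par)
  betas <- dec$betas
  if (model$flanker_structure == "independent") names(betas) <- tm$roles
  if (model$flanker_structure == "pooled") names(betas) <- "pooled"
  params <- mixture_params(dec$gamma, dec$sigma, betas, dec$mu)
  structure(list(
    model = model$name,
    params = params,
    log_likelihood = log_likelihood(params, errors, model),
    n_trials = n,
    k = model$k,
    converged = any_conv,
    n_starts_used = n_starts,
    seed = seed,
    flanker_roles = tm$roles
  ), class = "crowdmix_fit")
}

#' @export
print.crowdmix_fit <- function(x, ...) {
  cat(sprintf("<crowdmix fit: %s, n = %d, logLik = %.3f, converged = %s>\n",
              x$model, x$n_trials, x$log_likelihood, x$converged))
  if (!is.null(x$params)) {
    p <- x$params
    cat(sprintf("  gamma = %.4f, sigma = %.2f deg, P_T = %.4f\n",
                p$gamma, p$sigma, target_report_rate(p)))
    if (length(p$betas)) {
      cat("  betas:", paste(sprintf("%s = %.4f", names(p$betas), p$betas),
                            collapse = ", "), "\n")
    }
    if (p$mu != 0) cat(sprintf("  mu = %.2f deg\n", p$mu))
  }
  invisible(x)
}

#' Akaike information criterion with small-sample correction
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param log_likelihood maximised log-likelihood.
#' @param k free-parameter count.
#' @param n number of trials; must exceed `k + 1`.
#' @return the AICc value (lower is better).
#' @examples
#' aicc(0, 2, 200)  # 4 + 12/197
#' @export
aicc <- function(log_likelihood, k, n) {
  stopifnot(is.numeric(log_likelihood), is.numeric(k), is.numeric(n))
  if (any(n <= k + 1)) {
    stop("AICc requires n > k + 1", call. = FALSE)
  }
  -2 * log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Compare fitted models by AICc
#'
#' Ranks a set of fits of different models to the *same* trials. Ties in
#' AICc are broken by smaller `k`, then by catalog order.
#'
#' @param fits a list of `crowdmix_fit` objects on the same data (equal
#'   `n_trials`).
#' @return a data frame with one row per model: `model`, `k`,
#'   `log_likelihood`, `aicc`, `delta_aicc` (vs. the best) and `is_best`,
#'   sorted by AICc ascending.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  ns <- vapply(fits, `[[`, numeric(1), "n_trials")
  if (length(unique(ns)) != 1L) {
    stop("all fits must be on the same trials (equal n)", call. = FALSE)
  }
  cat_order <- names(model_catalog())
  df <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    log_likelihood = vapply(fits, `[[`, numeric(1), "log_likelihood"),
    n = ns,
    converged = vapply(fits, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE
  )
  df$aicc <- aicc(df$log_likelihood, df$k, df$n)
  ord <- order(df$aicc, df$k, match(df$model, cat_order))
  df <- df[ord, , drop = FALSE]
  df$delta_aicc <- df$aicc - df$aicc[1]
  df$is_best <- seq_len(nrow(df)) == 1L
  rownames(df) <- NULL
  df
}
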