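# shared generators for the test suite; everything is built in code under a
# fixed seed so fixtures never live on disk

# the two-flanker scenario used throughout recovery tests: the asymmetric
# regime with a dominant first-outer weight
tf_truth <- function() mixture_params(0.05, 15, c("1I" = 0.05, "1O" = 0.25))

# Exp. 1 four-flanker truth with the reported group-mean report rates
ff_truth <- function() {
  mixture_params(0.05, 15,
                 c("2I" = 0.07, "1I" = 0.07, "1O" = 0.24, "2O" = 0.07))
}

# errors data frame for one observer-condition, simulated from a given
# generating model
sim_errors <- function(condition, model, params, n_trials, seed,
                       experiment = "exp1") {
  cfg <- design_config(experiment, n_observers = 1,
                       trials_per_condition = n_trials,
                       conditions = condition, seed = seed)
  args <- list(seed = seed + 1L)
  args[[condition]] <- list(model = model, params = params)
  sc <- do.call(scenario, args)
  compute_errors(generate_dataset(cfg, sc))
}

# a small deterministic set of random valid parameter vectors for a model
random_params <- function(model, n, seed) {
  spec <- model_spec(model)
  n_beta <- switch(spec$flanker_structure,
                   none = 0L, pooled = 1L,
                   independent = spec$n_flankers_required)
  crowdmix:::.with_seed(seed, {
    lapply(seq_len(n), function(i) {
      g <- -log(runif(n_beta + 2L))
      w <- g / sum(g)   # (P_T, gamma, betas)
      mixture_params(w[2], runif(1, 2, 40),
                     if (n_beta) w[-(1:2)] else numeric(0),
                     mu = if (spec$has_bias) runif(1, -30, 30) else 0)
    })
  })
}

# one random trial-errors row set compatible with a model (offsets respect
# the >= 15 degree separation rule)
random_trials <- function(model, n_trials, seed) {
  spec <- model_spec(model)
  m <- if (!is.na(spec$n_flankers_required)) spec$n_flankers_required
       else if (spec$flanker_structure == "none") 0L else 2L
  roles <- switch(as.character(m),
                  "0" = character(0),
                  "2" = c("1I", "1O"),
                  "4" = c("2I", "1I", "1O", "2O"))
  crowdmix:::.with_seed(seed, {
    df <- data.frame(theta = runif(n_trials, -90, 90))
    for (r in roles) {
      s <- sample(c(-1, 1), n_trials, TRUE)
      df[[paste0("off_", r)]] <- s * runif(n_trials, 15, 90)
    }
    df
  })
}

# grid integral of a model density over one 180-degree period at a fixed
# trial (independent quadrature route for normalization checks)
integrate_density <- function(params, trial_row, model) {
  stats::integrate(function(th) {
    vapply(th, function(t1) {
      row <- trial_row
      row$theta <- t1
      trial_density(params, row, model)
    }, numeric(1))
  }, -90, 90, rel.tol = 1e-9, subdivisions = 400L)$value
}
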