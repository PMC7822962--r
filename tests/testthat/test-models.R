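test_that("the catalog holds the six models with their parameter counts", {
  cat6 <- model_catalog()
  expect_length(cat6, 6)
  expect_equal(names(cat6),
               c("standard", "misreport", "two_misreport",
                 "two_misreport_bias", "four_misreport",
                 "four_misreport_bias"))
  expect_equal(vapply(cat6, `[[`, numeric(1), "k"),
               c(standard = 2, misreport = 3, two_misreport = 4,
                 two_misreport_bias = 5, four_misreport = 6,
                 four_misreport_bias = 7))
  expect_length(model_spec("two_misreport")$parameter_names, 4)
  expect_length(model_spec("standard")$parameter_names, 2)
  expect_error(model_spec("weighted_average"), "unknown model")
})

test_that("parameter vectors enforce the simplex and bounds", {
  expect_silent(mixture_params(0.1, 15, c(0.2, 0.3)))
  expect_error(mixture_params(0.5, 15, c(0.4, 0.3)), "exceeds 1")
  expect_error(mixture_params(-0.1, 15))
  expect_error(mixture_params(0.1, 0))
  expect_equal(target_report_rate(mixture_params(0.1, 15, c(0.05, 0.25))),
               0.6)
  expect_equal(target_report_rate(mixture_params(0, 15)), 1)
  expect_equal(target_report_rate(mixture_params(1, 15)), 0)
})

test_that("the pure-guess limit is the uniform density", {
  trials <- random_trials("two_misreport", 25, seed = 1)
  p <- mixture_params(1, 15, c(0, 0))
  expect_equal(trial_density(p, trials, "two_misreport"),
               rep(1 / 180, 25))
  # gamma = 1 log-likelihood closed form
  expect_equal(log_likelihood(p, trials, "two_misreport"),
               25 * log(1 / 180))
})

test_that("all betas zero reduces every model to the standard mixture", {
  trials <- random_trials("four_misreport", 30, seed = 2)
  p0 <- mixture_params(0.2, 12)
  base <- trial_density(p0, trials, "standard")
  p4 <- mixture_params(0.2, 12, c(0, 0, 0, 0))
  expect_equal(trial_density(p4, trials, "four_misreport"), base)
  pm <- mixture_params(0.2, 12, 0)
  expect_equal(trial_density(pm, trials, "misreport"), base)
})

test_that("pooled misreport equals the equal-split independent models", {
  for (cfg in list(list(m = "two_misreport", n = 2L),
                   list(m = "four_misreport", n = 4L))) {
    trials <- random_trials(cfg$m, 50, seed = 3)
    beta <- 0.3
    pooled <- mixture_params(0.1, 18, beta)
    split <- mixture_params(0.1, 18, rep(beta / cfg$n, cfg$n))
    expect_equal(trial_density(pooled, trials, "misreport"),
                 trial_density(split, trials, cfg$m), tolerance = 1e-12)
    expect_equal(log_likelihood(pooled, trials, "misreport"),
                 log_likelihood(split, trials, cfg$m), tolerance = 1e-9)
  }
})

test_that("the density decomposes term-by-term over mixture components", {
  # direct evaluation against the circular core, one term at a time
  trial <- data.frame(theta = 40, off_1I = -40, off_1O = 40)
  p <- mixture_params(0, 5, c("1I" = 0.1, "1O" = 0.9) * 0.999)
  got <- trial_density(p, trial, "two_misreport")
  p_t <- 1 - sum(p$betas)
  manual <- p_t * vm_density(40, 5) +
    0.0999 * vm_density(wrap_error(40 - (-40)), 5) +
    0.8991 * vm_density(0, 5)
  expect_equal(got, manual, tolerance = 1e-12)
  # the dominant term is the outer-flanker component at its own offset
  expect_gt(got, 0.8 * vm_density(0, 5))
})

test_that("every model's trial density integrates to one", {
  for (mname in names(model_catalog())) {
    trials <- random_trials(mname, 3, seed = 7)
    for (p in random_params(mname, 3, seed = 11)) {
      for (i in seq_len(nrow(trials))) {
        z <- integrate_density(p, trials[i, , drop = FALSE], mname)
        expect_equal(z, 1, tolerance = 1e-6,
                     label = sprintf("integral for %s", mname))
      }
    }
  }
})

test_that("densities are invariant under joint 180-degree shifts", {
  trials <- random_trials("four_misreport", 20, seed = 5)
  p <- mixture_params(0.1, 20, c(0.05, 0.1, 0.2, 0.05))
  shifted <- trials
  shifted$theta <- wrap_error(trials$theta + 180)
  for (col in grep("^off_", names(trials), value = TRUE)) {
    shifted[[col]] <- wrap_error(trials[[col]] + 180)
  }
  expect_equal(trial_density(p, shifted, "four_misreport"),
               trial_density(p, trials, "four_misreport"))
})

test_that("model/condition mismatches are rejected", {
  trials2 <- random_trials("two_misreport", 10, seed = 6)
  expect_error(
    trial_density(mixture_params(0.1, 15, rep(0.1, 4)), trials2,
                  "four_misreport"),
    "requires 4 flankers")
  none <- random_trials("standard", 10, seed = 6)
  expect_error(
    trial_density(mixture_params(0.1, 15, 0.2), none, "misreport"),
    "at least one flanker")
  expect_error(log_likelihood(mixture_params(0.1, 15),
                              data.frame(theta = numeric(0)), "standard"),
               "non-empty")
})
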