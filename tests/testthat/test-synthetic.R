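test_that("the default design reproduces the experimental protocol", {
  cfg <- design_config("exp1", n_observers = 1, seed = 31)
  d <- generate_design(cfg)
  expect_equal(nrow(d), 600)
  expect_equal(as.vector(table(d$condition)),
               c(200, 200, 200))
  expect_true(all(d$target_ori %in% 1:180))
  ori_cols <- grep("^ori_", names(d), value = TRUE)
  fl <- unlist(d[ori_cols])
  expect_true(all(fl[!is.na(fl)] %in% 1:180))
  # hemifields balanced within each condition
  tab <- table(d$condition, d$hemifield)
  expect_true(all(tab == 100))
})

test_that("every flanker is at least 15 degrees from its target", {
  cfg <- design_config("exp2", n_observers = 2, trials_per_condition = 300,
                       conditions = c("two_flanker", "four_flanker"),
                       seed = 32)
  d <- generate_design(cfg)
  for (col in grep("^ori_", names(d), value = TRUE)) {
    ok <- !is.na(d[[col]])
    if (!any(ok)) next
    expect_gte(min(abs(circ_diff(d[[col]][ok], d$target_ori[ok]))), 15)
  }
})

test_that("designs carry the correct radial geometry per experiment", {
  g1 <- condition_geometry("exp1", "two_flanker")
  expect_equal(g1$target_ecc, 7)
  expect_equal(g1$flankers, c("1I" = 5.5, "1O" = 8.5))
  g1f <- condition_geometry("exp1", "four_flanker")
  expect_equal(g1f$flankers, c("2I" = 4, "1I" = 5.5, "1O" = 8.5, "2O" = 10))
  # adjacent spacing 1.5 degrees around the 7-degree target
  expect_equal(diff(sort(c(7, g1f$flankers))), rep(1.5, 4),
               ignore_attr = TRUE)
  g2 <- condition_geometry("exp2", "two_flanker")
  expect_equal(g2$target_ecc, 8.5)
  expect_equal(g2$flankers, c("2I" = 5.5, "1I" = 7))  # both inner
  g2f <- condition_geometry("exp2", "four_flanker")
  expect_equal(g2f$flankers, c("3I" = 4, "2I" = 5.5, "1I" = 7, "1O" = 10))
  # role columns follow the geometry
  d <- generate_design(design_config("exp2", 1, 10, "two_flanker", seed = 3))
  expect_true(all(!is.na(d$ori_2I)) && all(!is.na(d$ori_1I)))
  expect_true(all(is.na(d$ori_1O)) && all(is.na(d$ori_2O)))
})

test_that("design generation is deterministic given the seed", {
  cfg <- design_config("exp1", n_observers = 2, trials_per_condition = 50,
                       seed = 33)
  expect_identical(generate_design(cfg), generate_design(cfg))
  cfg2 <- cfg; cfg2$seed <- 34L
  expect_false(identical(generate_design(cfg), generate_design(cfg2)))
})

test_that("flanker offsets are uniform over the allowed +/-15..90 band", {
  cfg <- design_config("exp1", n_observers = 1, trials_per_condition = 4000,
                       conditions = "two_flanker", seed = 35)
  d <- generate_design(cfg)
  off <- circ_diff(d$ori_1O, d$target_ori)
  expect_true(all(abs(off) >= 15))
  # the allowed offsets form a discrete set of 151 grid values (-89..-15,
  # 15..89, and the single value 90); the generator should be uniform on it
  allowed <- c(-89:-15, 15:90)
  expect_true(all(off %in% allowed))
  counts <- table(factor(off, levels = allowed))
  p <- chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("simulated responses follow the generative mixture", {
  # pure guessing: uniform response histogram
  e <- sim_errors("uncrowded", "standard", mixture_params(1, 15),
                  n_trials = 20000, seed = 36)
  p <- chisq.test(table(cut(e$theta, seq(-90, 90, by = 10))))$p.value
  expect_gt(p, 0.01)

  # degenerate outer-flanker reporting: responses concentrate on 1O
  p1O <- mixture_params(0, 5, c("1I" = 0, "1O" = 1) + c(1e-9, -1e-9))
  e2 <- sim_errors("two_flanker", "two_misreport", p1O,
                   n_trials = 500, seed = 37)
  rel <- wrap_error(e2$theta - e2$off_1O)
  expect_lt(median(abs(rel)), 5)

  # latent bookkeeping matches the target weight
  tr <- generate_dataset(
    design_config("exp1", 1, 20000, "two_flanker", seed = 38),
    scenario(two_flanker = list(model = "two_misreport",
                                params = tf_truth()), seed = 39))
  expect_lt(abs(mean(tr$latent_source == "target") - 0.65), 0.01)
})

test_that("dataset generation composes and round-trips through CSV", {
  cfg <- design_config("exp1", n_observers = 13, trials_per_condition = 10,
                       seed = 40)
  sc <- scenario(
    uncrowded = list(model = "standard", params = mixture_params(0.05, 12)),
    two_flanker = list(model = "two_misreport", params = tf_truth()),
    four_flanker = list(model = "four_misreport", params = ff_truth()),
    seed = 41)
  d <- generate_dataset(cfg, sc)
  expect_equal(nrow(d), 13 * 30)
  expect_true(all(d$response_ori > 0 & d$response_ori <= 180))

  # empty condition list
  empty <- generate_dataset(design_config("exp1", 2, 10,
                                          conditions = character(0),
                                          seed = 1), sc)
  expect_equal(nrow(empty), 0)

  # byte-identical reruns and CSV round trip
  expect_identical(d, generate_dataset(cfg, sc))
  tmp <- tempfile(fileext = ".csv")
  write_trials(d, tmp)
  back <- read_trials(tmp)
  expect_equal(back$response_ori, d$response_ori)
  expect_equal(back$ori_1O, d$ori_1O)
  # column mapping renames external headers
  ext <- d; names(ext)[names(ext) == "response_ori"] <- "resp"
  write_trials(ext, tmp)
  mapped <- read_trials(tmp, mapping = c(response_ori = "resp"))
  expect_true("response_ori" %in% names(mapped))
  expect_error(read_trials(tmp), "missing required column")
})

test_that("incompatible generators are rejected", {
  cfg <- design_config("exp1", 1, 30, "two_flanker", seed = 42)
  expect_error(
    scenario(uncrowded = list(model = "two_misreport",
                              params = tf_truth())),
    "standard model")
  sc <- scenario(two_flanker = list(model = "four_misreport",
                                    params = ff_truth()), seed = 1)
  expect_error(generate_dataset(cfg, sc), "incompatible")
})
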