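# Synthetic-data generators: seeded reproducibility, declared noise laws,
# expression-panel normalisation, and the transport-parameter estimator.

test_that("parameter perturbation is seeded, multiplicative and cv-faithful", {
  p <- test_params()
  expect_identical(perturb_parameters(p, cv = 0), p)
  a <- perturb_parameters(p, cv = 0.2, seed = 11)
  b <- perturb_parameters(p, cv = 0.2, seed = 11)
  expect_identical(a, b)
  expect_true(all(a$provenance == "estimated"))
  # zero-capacity entries stay zero under multiplicative noise
  zero_keys <- p$value == 0
  expect_true(all(a$value[zero_keys] == 0))

  # noise-law check: 1000 independent factors of one entry have sample cv
  # within 20% of the nominal 0.1
  one <- tibble::tibble(reaction = 1:1000, parameter = "k", value = 2,
                        unit = "1/min", provenance = "estimated")
  drawn <- perturb_parameters(one, cv = 0.1, seed = 5)
  cv_hat <- stats::sd(drawn$value) / mean(drawn$value)
  expect_lt(abs(cv_hat - 0.1) / 0.1, 0.2)
})

test_that("noisy time courses retain truth and honour the noise model", {
  tc <- test_run("classical", "normoxia")
  clean <- generate_noisy_timecourse(tc, noise = list(type = "lognormal",
                                                      sigma = 0),
                                     seed = 3, keys = "ATP@Nm")
  expect_equal(clean$observed, clean$truth)
  n1 <- generate_noisy_timecourse(tc, seed = 9, keys = "ATP@Nm")
  n2 <- generate_noisy_timecourse(tc, seed = 9, keys = "ATP@Nm")
  expect_identical(n1$observed, n2$observed)
  expect_false(identical(
    n1$observed,
    generate_noisy_timecourse(tc, seed = 10, keys = "ATP@Nm")$observed))

  # lognormal mean identity: across replicates the mean observation at a
  # fixed time point is truth * exp(sigma^2 / 2)
  sg <- 0.05
  truth_pt <- tc$data$`ATP@Nm`[101]
  obs <- vapply(1:500, function(s) {
    generate_noisy_timecourse(tc, noise = list(type = "lognormal", sigma = sg),
                              seed = s, keys = "ATP@Nm")$observed$`ATP@Nm`[101]
  }, numeric(1))
  expect_lt(abs(mean(obs) - truth_pt * exp(sg^2 / 2)) / truth_pt, 0.02)
})

test_that("noisy series serialise with their noise metadata", {
  tc <- test_run("classical", "normoxia")
  ns <- generate_noisy_timecourse(tc, seed = 2, keys = c("ATP@Nm", "Lac@e"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_noisy_series(ns, f)
  lines <- readLines(f)
  expect_match(lines[1], "lognormal sigma=0.05")
  expect_match(lines[2], "seed: 2")
})

test_that("expression panels normalise to the reference gene", {
  flat <- generate_expression_panel(effects = c(PK = 1, HK = 1, PFK = 1,
                                                CS = 1, GAPDH = 1),
                                    sigma = 0, seed = 1)
  expect_equal(flat$abundance[flat$condition == "normoxia"],
               flat$abundance[flat$condition == "hypoxia"])
  expect_true(all(flat$abundance[flat$is_reference] == 1))

  two <- generate_expression_panel(effects = c(GAPDH = 2), sigma = 0)
  ratio <- two$abundance[two$condition == "hypoxia" & two$gene == "GAPDH"] /
    two$abundance[two$condition == "normoxia" & two$gene == "GAPDH"]
  expect_equal(ratio, 2)
  expect_error(generate_expression_panel(effects = c(HK = -1)), "> 0")
})

test_that("panel ratios track effect sizes over 200 replicates within 5%", {
  effects <- c(PK = 2.5, HK = 2, PFK = 2.5, CS = 1.8, GAPDH = 2)
  ratios <- sapply(1:200, function(s) {
    p <- generate_expression_panel(effects, sigma = 0.1, seed = s)
    vapply(names(effects), function(g) {
      p$abundance[p$condition == "hypoxia" & p$gene == g] /
        p$abundance[p$condition == "normoxia" & p$gene == g]
    }, numeric(1))
  })
  mean_ratio <- rowMeans(ratios)
  expect_true(all(abs(mean_ratio - effects) / effects < 0.05))
})

test_that("a noiseless uptake series recovers (v, km) to 0.1%", {
  ser <- generate_uptake_series(0.8, 1, 10, times = seq(0, 16, length.out = 50),
                                sigma = 0)
  f <- recover_transport_parameters(ser, c0 = 10)
  expect_lt(abs(f$v - 0.8) / 0.8, 1e-3)
  expect_lt(abs(f$km - 1) / 1, 1e-3)
  expect_true(f$identifiable)
  expect_s3_class(tidy(f), "tbl_df")
  expect_equal(glance(f)$n, 50)
})

test_that("recovery error decreases monotonically as noise shrinks", {
  meds <- vapply(c(0.2, 0.1, 0.05, 0), function(sg) {
    errs <- vapply(1:20, function(s) {
      ser <- generate_uptake_series(0.8, 1, 10,
                                    times = seq(0, 16, length.out = 50),
                                    sigma = sg, seed = s)
      f <- recover_transport_parameters(ser, c0 = 10)
      abs(f$v - 0.8) / 0.8 + abs(f$km - 1)
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("linear-regime series are flagged, with the rate ratio still recovered", {
  ser <- generate_uptake_series(0.5, 60, 2, times = seq(0, 60, length.out = 50),
                                sigma = 0.02, seed = 3)
  f <- recover_transport_parameters(ser, c0 = 2)
  expect_false(f$identifiable)
  expect_lt(abs(f$ratio - 0.5 / 60) / (0.5 / 60), 0.05)
})
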