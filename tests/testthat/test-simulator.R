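# ODE assembly and integration: conservation-by-construction, analytic
# oracles on reduced models, solver reproducibility, plateau detection.

test_that("volume bookkeeping conserves amounts for every reaction column", {
  for (variant in c("classical", "anlsh")) {
    m <- test_model(variant)
    ode <- assemble_odes(m)
    vols <- ode$volumes
    carbon <- stats::setNames(m$species$carbon,
                              paste0(m$species$id, "@", m$species$compartment))
    # carbon amount is structurally invariant reaction by reaction
    # (clamped states all carry zero carbon under the default clamps)
    drift <- colSums(ode$M * vols[ode$keys] * carbon[ode$keys])
    expect_lt(max(abs(drift)), 1e-9)
  }
})

test_that("a cross-compartment transport column moves equal and opposite amounts", {
  m <- test_model("classical")
  ode <- assemble_odes(m)
  r <- which(m$reactions$name == "glut_blood_to_acyt")
  col <- ode$M[, r]
  nz <- which(col != 0)
  amounts <- col[nz] * ode$volumes[ode$keys[nz]]
  expect_equal(sum(amounts), 0, tolerance = 1e-15)
  expect_equal(length(nz), 2)
})

test_that("assembly refuses a model with outstanding diagnostics", {
  m <- test_model("classical")
  m$reactions$substrates[[1]] <- tibble::tibble(
    species = "X", compartment = "Nc", stoich = 1)
  expect_error(assemble_odes(m), "fails validation")
})

test_that("closed two-species interconversion matches the linear closed form", {
  k1 <- 0.3; k2 <- 0.12; a0 <- 2; b0 <- 0.5
  m <- toy_two_pool_model(k1, k2, a0, b0)
  tc <- simulate_timecourse(m, make_scenario("normoxia", t_end = 40),
                            output_step = 0.5)
  tt <- tc$data$time
  total <- a0 + b0
  a_inf <- k2 * total / (k1 + k2)
  a_exact <- a_inf + (a0 - a_inf) * exp(-(k1 + k2) * tt)
  expect_equal(tc$data$`A@Nc`, a_exact, tolerance = 1e-6)
  expect_equal(tc$data$`B@Nc`, total - a_exact, tolerance = 1e-6)
})

test_that("passive diffusion between unequal volumes matches the exponential form", {
  gamma <- 0.5; vb <- 0.095; ve <- 0.2; cb0 <- 4; ce0 <- 1
  m <- toy_transport_model(gamma, 1, vb, ve, cb0, ce0)
  tc <- simulate_timecourse(m, make_scenario("normoxia", t_end = 30),
                            output_step = 0.25)
  tt <- tc$data$time
  c_inf <- (vb * cb0 + ve * ce0) / (vb + ve)
  rate <- gamma * (1 + vb / ve)
  cb_exact <- c_inf + (cb0 - c_inf) * exp(-rate * tt)
  expect_equal(tc$data$`X@b`, cb_exact, tolerance = 1e-6)
  # amounts conserved throughout
  amt <- vb * tc$data$`X@b` + ve * tc$data$`X@e`
  expect_equal(amt, rep(vb * cb0 + ve * ce0, length(tt)), tolerance = 1e-9)
})

test_that("an all-zero unclamped state stays identically zero", {
  m <- test_model("classical")
  m$species <- m$species[m$species$role != "gene", ]
  m$species$initial <- 0
  m$species$clamped <- FALSE
  m$regulation <- NULL
  ode <- assemble_odes(m)
  expect_equal(max(abs(ode$rates(ode$y0))), 0)
  sol <- deSolve::lsoda(ode$y0, 0:10, ode$func, parms = NULL,
                        rtol = 1e-8, atol = 1e-12)
  expect_equal(max(abs(sol[, -1])), 0)
})

test_that("simulation output is dense, ordered, clamp-respecting and reproducible", {
  tc <- test_run("classical", "normoxia")
  expect_true(all(diff(tc$data$time) > 0))
  expect_equal(nrow(tc$data), 251)
  # clamped blood O2 stays at the scenario value in every row
  expect_equal(tc$data$`O2@b`, rep(7, nrow(tc$data)))
  expect_equal(unique(tc$data$`PHase@Nc`), 0.001)
  # two short runs with identical inputs are bit-identical
  sc <- make_scenario("normoxia", t_end = 25)
  a <- simulate_timecourse(test_model("classical"), sc)
  b <- simulate_timecourse(test_model("classical"), sc)
  expect_identical(a$data, b$data)
})

test_that("no concentration dips below the solver tolerance band", {
  for (run in list(test_run("classical", "normoxia"),
                   test_run("classical", "hypoxia"),
                   test_run("anlsh", "normoxia", 500),
                   test_run("anlsh", "hypoxia", 500),
                   test_run("anlsh", "starvation"))) {
    expect_equal(nrow(run$diagnostics), 0)
    expect_gt(min(as.matrix(run$data[-1])), -1e-9)
  }
})

test_that("halving solver tolerances moves plateau values by far less than 0.1%", {
  tc1 <- test_run("classical", "normoxia")
  tc2 <- cached("run_tightened", simulate_timecourse(
    test_model("classical"), make_scenario("normoxia"),
    rtol = 5e-9, atol = 5e-12))
  for (k in c("ATP@Nm", "ATP@Am", "Lac@e", "ATP@Nc")) {
    p1 <- detect_steady_state(tc1, k)$plateau
    p2 <- detect_steady_state(tc2, k)$plateau
    expect_lt(abs(p1 - p2) / max(abs(p1), 1e-8), 1e-3)
  }
})

test_that("plateau detection: constant, saturating and rising series", {
  tt <- 0:200
  const <- tibble::tibble(time = tt, value = rep(3.2, length(tt)))
  r <- detect_steady_state(const, "const", window = 25, rel_tol = 0.01)
  expect_true(r$attained)
  expect_equal(r$time_attained, 0)
  expect_equal(r$plateau, 3.2)

  a <- 5; k <- 0.1
  sat <- tibble::tibble(time = tt, value = a * (1 - exp(-k * tt)))
  r <- detect_steady_state(sat, "sat", window = 25, rel_tol = 0.01)
  expect_true(r$attained)
  expect_equal(r$plateau, a, tolerance = 0.01)
  expect_lte(r$time_attained, log(1 / 0.01) / k + 2)

  lin <- tibble::tibble(time = tt, value = 1 + tt)
  r <- detect_steady_state(lin, "lin", window = 25, rel_tol = 0.01)
  expect_false(r$attained)
  expect_true(is.na(r$time_attained))

  expect_error(detect_steady_state(const, "x", window = 300), "window")
})

test_that("time-course CSV round-trips with metadata in both layouts", {
  tc <- test_run("classical", "normoxia")
  for (layout in c("wide", "long")) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_timecourse(tc, f, layout = layout)
    back <- read_timecourse(f)
    expect_true(any(grepl("variant: classical", back$metadata)))
    expect_true(any(grepl("solver: lsoda", back$metadata)))
    if (layout == "wide") {
      expect_equal(back$data$`ATP@Nm`, tc$data$`ATP@Nm`, tolerance = 1e-12)
    } else {
      sub <- back$data[back$data$species == "ATP" &
                         back$data$compartment == "Nm", ]
      expect_equal(sub$value, tc$data$`ATP@Nm`, tolerance = 1e-12)
    }
  }
})

test_that("glucose is essentially depleted within 50 minutes under normoxia", {
  tc <- test_run("classical", "normoxia")
  at50 <- tc$data[tc$data$time == 50, ]
  expect_lt(at50$`Glc@b`, 0.05 * 4.56)
  expect_lt(at50$`Glc@Nc`, 0.05 * max(tc$data$`Glc@Nc`))
  expect_lt(at50$`Glc@Ac`, 0.05 * max(tc$data$`Glc@Ac`))
})
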