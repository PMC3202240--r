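# Oxygen sensor and gene-expression cascade: anoxic limits, closed-form
# steady states, hypoxic dominance, and the capacity coupling.

reg_of <- function() test_model("classical")$regulation

test_that("at zero oxygen the hydroxylation term vanishes exactly", {
  reg <- reg_of()
  cp <- reg$neuron
  st <- list(hif_cytosol = 0.4, hif_nucleus = 0.2, hifoh = 0.05)
  d <- hif_derivatives(st, o2 = 0, p = cp)
  # cytosolic balance reduces to synthesis minus translocation
  expect_equal(unname(d["hif_cytosol"]),
               cp$synthesis - cp$translocation * st$hif_cytosol)
  expect_equal(unname(d["hifoh"]), -cp$hifoh_decay * st$hifoh)
})

test_that("all-zero state with zero synthesis gives zero derivatives", {
  cp <- reg_of()$neuron
  cp$synthesis <- 0
  d <- hif_derivatives(list(hif_cytosol = 0, hif_nucleus = 0, hifoh = 0),
                       o2 = 5, p = cp)
  expect_equal(unname(d), c(0, 0, 0))
})

test_that("nuclear HIF steady state is higher under hypoxia than normoxia", {
  cp <- reg_of()$neuron
  ss_norm <- hif_steady_state(cp, 7)
  ss_hyp <- hif_steady_state(cp, 0.35)
  expect_lt(ss_norm$hif_nucleus, ss_hyp$hif_nucleus)
  expect_lt(ss_norm$hif_cytosol, ss_hyp$hif_cytosol)
})

test_that("the clamped-O2 sensor ODE settles onto the closed form to 1e-8", {
  cp <- reg_of()$neuron
  for (o2 in c(7, 0.35)) {
    ss <- hif_steady_state(cp, o2)
    deriv <- function(t, y, parms) {
      list(unname(hif_derivatives(as.list(y), o2, cp)))
    }
    y0 <- c(hif_cytosol = 0, hif_nucleus = 0, hifoh = 0)
    sol <- deSolve::lsoda(y0, c(0, 2000), deriv, parms = NULL,
                          rtol = 1e-12, atol = 1e-14)
    final <- sol[nrow(sol), -1]
    expect_equal(unname(final["hif_cytosol"]), ss$hif_cytosol,
                 tolerance = 1e-8)
    expect_equal(unname(final["hif_nucleus"]), ss$hif_nucleus,
                 tolerance = 1e-8)
    # and the derivatives vanish at the closed form
    expect_equal(max(abs(hif_derivatives(ss, o2, cp))), 0, tolerance = 1e-12)
  }
})

test_that("transcription is basal at zero HIF, half-activated at K", {
  reg <- reg_of()
  tb <- reg$transcription
  expect_equal(transcription_rate(0, reg), tb$basal)
  expect_equal(transcription_rate(tb$k_hif, reg), tb$basal + tb$v_hif / 2)
  # strictly increasing
  h <- seq(0, 0.2, by = 0.01)
  expect_true(all(diff(transcription_rate(h, reg)) > 0))
  # composition with the sensor steady states: hypoxia transcribes faster
  cp <- reg$neuron
  expect_lt(transcription_rate(hif_steady_state(cp, 7)$hif_nucleus, reg),
            transcription_rate(hif_steady_state(cp, 0.35)$hif_nucleus, reg))
})

test_that("protein pool relaxes to translate*m/degrade under constant mRNA", {
  reg <- reg_of()
  p_full <- c(reg, reg$neuron)
  m_const <- 0.004
  target <- reg$protein$translate * m_const / reg$protein$degrade
  d <- protein_derivatives(
    list(mrna_nucleus = 0, mrna_cytosol = m_const, protein = target,
         hif_nucleus = 0), p_full)
  expect_equal(unname(d["protein"]), 0, tolerance = 1e-14)
  # zero mRNA everywhere: protein decays first order
  d0 <- protein_derivatives(
    list(mrna_nucleus = 0, mrna_cytosol = 0, protein = 0.3, hif_nucleus = 0),
    p_full)
  expect_equal(unname(d0["protein"]), -reg$protein$degrade * 0.3)
})

test_that("gene_steady_state matches the simulated cascade", {
  m <- test_model("classical")
  reg <- m$regulation
  norm <- test_regulation_run("neuron", 7)
  prot_end <- norm$value[norm$gene == "HK" & norm$quantity == "protein" &
                           norm$time == max(norm$time)]
  ss <- gene_steady_state(reg, reg$neuron,
                          hif_steady_state(reg$neuron, 7)$hif_nucleus)
  expect_equal(prot_end, ss$protein, tolerance = 1e-6)
})

test_that("hypoxic mRNA and protein trajectories dominate normoxic ones", {
  for (cell in c("neuron", "astrocyte")) {
    norm <- test_regulation_run(cell, 7)
    hyp <- test_regulation_run(cell, 0.35)
    for (q in c("mrna_nucleus", "mrna_cytosol", "protein")) {
      for (g in reg_of()$genes) {
        vn <- norm$value[norm$gene == g & norm$quantity == q]
        vh <- hyp$value[hyp$gene == g & hyp$quantity == q]
        expect_true(all(vh >= vn - 1e-10))
        expect_gt(vh[length(vh)], vn[length(vn)])
      }
    }
  }
})

test_that("all seven genes share identical trajectories", {
  hyp <- test_regulation_run("neuron", 0.35)
  genes <- reg_of()$genes
  ref <- hyp$value[hyp$gene == genes[1] & hyp$quantity == "protein"]
  for (g in genes[-1]) {
    expect_equal(hyp$value[hyp$gene == g & hyp$quantity == "protein"], ref)
  }
})

test_that("hypoxic steady protein is 2-3x the normoxic level within 250 min", {
  cell <- "astrocyte"
  norm <- test_regulation_run(cell, 7)
  hyp <- test_regulation_run(cell, 0.35)
  at_end <- function(x) x$value[x$gene == "HK" & x$quantity == "protein" &
                                  x$time == max(x$time)]
  ratio <- at_end(hyp) / at_end(norm)
  expect_gt(ratio, 2)
  expect_lt(ratio, 3)
})

test_that("effective capacity is linear in protein and anchored at the reference", {
  expect_equal(effective_capacity(2.5, 0.02, 0.02), 2.5)
  expect_equal(effective_capacity(2.5, 0, 0.02), 0)
  expect_equal(effective_capacity(2.5, 0.04, 0.02), 5)
  expect_equal(effective_capacity(2.5, -1, 0.02), 0) # clipped below
  expect_error(effective_capacity(2.5, 0.02, 0), "protein_ref")
})

test_that("negative regulation states are rejected", {
  cp <- reg_of()$neuron
  expect_error(hif_derivatives(list(hif_cytosol = -1, hif_nucleus = 0,
                                    hifoh = 0), 1, cp), "non-negative")
  expect_error(transcription_rate(-0.1, reg_of()), ">= 0")
})
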