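#' Hypoxia gene-regulation module
#'
#' The oxygen sensor and its downstream gene expression: prolyl hydroxylase
#' (PHase) hydroxylates cytosolic HIF in an O2-dependent mass-action step,
#' marking it for degradation; under hypoxia this route stalls, HIF
#' accumulates, translocates to the nucleus and drives transcription of the
#' seven regulated genes (GLUT, MCT, HK, PFK, GAPDH, PK, LDH), all of which
#' share the same rate equations. Translated protein linearly scales the
#' effective capacity of the regulated metabolic reactions.
#'
#' Cell-level parameter lists (as stored in `model$regulation$neuron` /
#' `$astrocyte`) carry: `synthesis` (mM/min), `hydroxylation`
#' (1/(mM^2 min)), `phase` (mM, held constant), `hifoh_decay`,
#' `translocation`, `nuclear_decay`, `nuclear_export` (all 1/min), and the
#' cytosol/nucleus volumes used for cross-compartment bookkeeping.
#'
#' @name gene-regulation
NULL

.chk_state_nonneg <- function(state) {
  v <- unlist(state)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("regulation state must be finite and non-negative", call. = FALSE)
  }
  invisible(state)
}

#' Time derivatives of the HIF pools
#'
#' Cytosolic HIF: constant synthesis, minus O2- and PHase-dependent
#' mass-action hydroxylation (`k_h * PHase * O2 * HIF`), minus first-order
#' nuclear translocation, plus (optional, zero by default) nuclear export.
#' Nuclear HIF: translocation inflow (volume-scaled so amounts are
#' conserved) minus first-order decay. The hydroxylated intermediate decays
#' first-order.
#'
#' @param state List or named vector with `hif_cytosol`, `hif_nucleus`,
#'   `hifoh` (mM).
#' @param o2 Cytosolic oxygen concentration (mM).
#' @param p Cell-level regulation parameter list (see [gene-regulation]).
#' @return Named numeric vector of derivatives (mM/min):
#'   `hif_cytosol`, `hif_nucleus`, `hifoh`.
#' @export
hif_derivatives <- function(state, o2, p) {
  .chk_state_nonneg(state)
  if (!is.finite(o2) || o2 < 0) stop("o2 must be >= 0", call. = FALSE)
  hc <- state[["hif_cytosol"]]; hn <- state[["hif_nucleus"]]
  hoh <- state[["hifoh"]] %||% 0
  hydrox <- p$hydroxylation * p$phase * o2 * hc
  ratio_nc <- p$v_nuc / p$v_cyt
  c(
    hif_cytosol = p$synthesis - hydrox - p$translocation * hc +
      p$nuclear_export * hn * ratio_nc,
    hif_nucleus = p$translocation * hc / ratio_nc -
      (p$nuclear_decay + p$nuclear_export) * hn,
    hifoh = hydrox - p$hifoh_decay * hoh
  )
}

#' Closed-form steady state of the HIF sensor
#'
#' The sensor is linear at fixed O2; its steady state is solved exactly and
#' used both to initialise models at the normoxic reference point and as the
#' analytic oracle for the simulated subsystem.
#'
#' @param p Cell-level regulation parameter list.
#' @param o2 Clamped cytosolic oxygen (mM).
#' @return List with `hif_cytosol`, `hif_nucleus`, `hifoh` (mM).
#' @export
hif_steady_state <- function(p, o2) {
  d <- p$hydroxylation * p$phase * o2
  a <- p$nuclear_decay + p$nuclear_export
  hc <- p$synthesis / (d + p$translocation * (1 - p$nuclear_export / a))
  hn <- p$translocation * (p$v_cyt / p$v_nuc) * hc / a
  list(hif_cytosol = hc, hif_nucleus = hn,
       hifoh = if (p$hifoh_decay > 0) d * hc / p$hifoh_decay else 0)
}

#' HIF-activated transcription rate
#'
#' Basal transcription plus a saturating HIF-driven term:
#' `basal + v_hif * H / (k_hif + H)`; strictly increasing and bounded in
#' nuclear HIF.
#'
#' @param hif_nucleus Nuclear HIF concentration (mM), >= 0.
#' @param p Regulation parameter list containing a `transcription` block
#'   (`basal`, `v_hif` in mM/min; `k_hif` in mM).
#' @return mRNA synthesis rate (mM/min, referenced to the nucleus).
#' @export
transcription_rate <- function(hif_nucleus, p) {
  if (any(hif_nucleus < 0)) stop("hif_nucleus must be >= 0", call. = FALSE)
  tp <- p$transcription
  tp$basal + tp$v_hif * hif_nucleus / (tp$k_hif + hif_nucleus)
}

#' Time derivatives of one gene's mRNA and protein pools
#'
#' Nuclear mRNA: transcription in, nuclear export and degradation out.
#' Cytosolic mRNA: volume-scaled export in, degradation out. Protein:
#' first-order translation of cytosolic mRNA in, degradation out. All seven
#' regulated genes use these same equations.
#'
#' @param state List with `mrna_nucleus`, `mrna_cytosol`, `protein`, and
#'   `hif_nucleus` (mM).
#' @param p Full regulation parameter list (with `transcription`, `mrna`,
#'   `protein` blocks) combined with the cell-level volumes, e.g.
#'   `c(model$regulation, model$regulation$neuron)`.
#' @return Named derivative vector (mM/min).
#' @export
protein_derivatives <- function(state, p) {
  .chk_state_nonneg(state)
  mn <- state[["mrna_nucleus"]]; mc <- state[["mrna_cytosol"]]
  pr <- state[["protein"]]
  tr <- transcription_rate(state[["hif_nucleus"]], p)
  ratio_nc <- p$v_nuc / p$v_cyt
  c(
    mrna_nucleus = tr - (p$mrna$export + p$mrna$degrade_nucleus) * mn,
    mrna_cytosol = p$mrna$export * mn * ratio_nc - p$mrna$degrade_cytosol * mc,
    protein = p$protein$translate * mc - p$protein$degrade * pr
  )
}

#' Closed-form steady state of one gene's expression cascade
#'
#' @param reg Full regulation parameter list (`model$regulation`).
#' @param cell_p Cell-level parameter list (`reg$neuron` or `reg$astrocyte`).
#' @param hif_nucleus Nuclear HIF (mM) at which to evaluate transcription.
#' @return List with `mrna_nucleus`, `mrna_cytosol`, `protein` (mM).
#' @export
gene_steady_state <- function(reg, cell_p, hif_nucleus) {
  tr <- transcription_rate(hif_nucleus, reg)
  mn <- tr / (reg$mrna$export + reg$mrna$degrade_nucleus)
  mc <- reg$mrna$export * mn * (cell_p$v_nuc / cell_p$v_cyt) /
    reg$mrna$degrade_cytosol
  pr <- reg$protein$translate * mc / reg$protein$degrade
  list(mrna_nucleus = mn, mrna_cytosol = mc, protein = pr)
}

#' Scale an enzyme capacity by its regulated protein level
#'
#' Effective capacity is linear in the protein pool, calibrated so that the
#' normoxic reference protein level reproduces the base capacity exactly:
#' `base_vmax * protein / protein_ref`, clipped below at zero.
#'
#' @param base_vmax Base limiting rate (mM/min).
#' @param protein Current protein level (mM), >= 0 after clipping.
#' @param protein_ref Normoxic reference protein level (mM), > 0.
#' @return Scaled capacity (mM/min).
#' @export
effective_capacity <- function(base_vmax, protein, protein_ref) {
  if (any(!is.finite(protein_ref)) || any(protein_ref <= 0)) {
    stop("protein_ref must be > 0", call. = FALSE)
  }
  base_vmax * pmax(protein, 0) / protein_ref
}

#' Simulate the regulation subsystem in isolation
#'
#' Integrates the HIF sensor plus all seven gene-expression cascades of one
#' cell with cytosolic O2 clamped, starting from the normoxic steady state.
#' This reproduces the hypoxia-vs-normoxia mRNA/protein kinetics panels of
#' the coupled model without the metabolic network.
#'
#' @param model An `anlsim_model` (source of regulation parameters).
#' @param cell `"neuron"` or `"astrocyte"`.
#' @param o2 Clamped cytosolic O2 (mM); 7 for normoxia, 0.35 for hypoxia.
#' @param t_end Horizon (min).
#' @param output_step Output grid spacing (min).
#' @return Tibble in long format: `time`, `gene`, `quantity`
#'   (`hif_cytosol`, `hif_nucleus`, `mrna_nucleus`, `mrna_cytosol`,
#'   `protein`), `value` (mM). HIF rows carry `gene = NA`.
#' @export
simulate_regulation <- function(model, cell = c("neuron", "astrocyte"),
                                o2 = 7, t_end = 250, output_step = 1) {
  cell <- match.arg(cell)
  reg <- model$regulation
  cp <- reg[[cell]]
  p_full <- c(reg, cp)
  genes <- reg$genes
  ss <- hif_steady_state(cp, reg$reference_o2)
  gss <- gene_steady_state(reg, cp, ss$hif_nucleus)

  y0 <- c(hif_cytosol = ss$hif_cytosol, hif_nucleus = ss$hif_nucleus,
          hifoh = ss$hifoh)
  for (g in genes) {
    y0[paste0(c("mn_", "mc_", "pr_"), g)] <-
      c(gss$mrna_nucleus, gss$mrna_cytosol, gss$protein)
  }

  deriv <- function(t, y, parms) {
    dh <- hif_derivatives(as.list(y[1:3]), o2, cp)
    dy <- numeric(length(y)); names(dy) <- names(y)
    dy[1:3] <- dh
    for (g in genes) {
      st <- list(mrna_nucleus = y[[paste0("mn_", g)]],
                 mrna_cytosol = y[[paste0("mc_", g)]],
                 protein = y[[paste0("pr_", g)]],
                 hif_nucleus = y[["hif_nucleus"]])
      dg <- protein_derivatives(st, p_full)
      dy[paste0(c("mn_", "mc_", "pr_"), g)] <- dg
    }
    list(dy)
  }

  times <- seq(0, t_end, by = output_step)
  sol <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  out <- tibble::as_tibble(as.data.frame(sol))
  long <- tidyr::pivot_longer(out, -"time", names_to = "key", values_to = "value")
  long$gene <- ifelse(grepl("^(mn|mc|pr)_", long$key),
                      sub("^(mn|mc|pr)_", "", long$key), NA_character_)
  long$quantity <- dplyr::case_when(
    grepl("^mn_", long$key) ~ "mrna_nucleus",
    grepl("^mc_", long$key) ~ "mrna_cytosol",
    grepl("^pr_", long$key) ~ "protein",
    TRUE ~ long$key
  )
  dplyr::select(long, "time", "gene", "quantity", "value")
}
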