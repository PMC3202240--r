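#' Assemble the coupled ODE system of a model
#'
#' Compiles the reaction network plus the gene-regulation layer into a
#' derivative function for a stiff solver. Every reaction rate J (mM/min) is
#' referenced to its host compartment of volume `V_h`; a species in
#' compartment of volume `V_i` changes at `stoich * J * V_h / V_i`, so
#' amounts (concentration x volume) are conserved exactly across transport
#' steps. Regulated reactions read their effective capacity live from the
#' per-gene protein pools ([effective_capacity()]); clamped species have
#' zero derivatives.
#'
#' The model must pass [validate_model()] cleanly; assembly refuses models
#' with outstanding diagnostics.
#'
#' @param model An `anlsim_model`.
#' @param extra_clamps Character vector of additional state keys
#'   (`"species@compartment"`) to clamp, e.g. `"Glc@b"` in the starvation
#'   scenario.
#' @return A list of class `anlsim_ode` with elements `func` (the
#'   deSolve-style derivative function), `y0` (named initial state), `keys`,
#'   `clamped`, and the reaction-rate evaluator `rates(y)` used by tests and
#'   the SBML round-trip check.
#' @export
assemble_odes <- function(model, extra_clamps = character()) {
  diag <- validate_model(model)
  if (nrow(diag) > 0) {
    stop(sprintf("model fails validation (%d diagnostics); see validate_model()",
                 nrow(diag)), call. = FALSE)
  }

  sp <- model$species
  keys <- paste0(sp$id, "@", sp$compartment)
  n <- length(keys)
  idx_of <- stats::setNames(seq_len(n), keys)
  vol_of_comp <- stats::setNames(model$compartments$volume, model$compartments$id)
  vols <- vol_of_comp[sp$compartment]

  clamped <- sp$clamped
  clamped[match(intersect(extra_clamps, keys), keys)] <- TRUE

  rx <- model$reactions
  nr <- nrow(rx)

  # net, volume-scaled stoichiometry matrix (states x reactions)
  M <- matrix(0, n, nr)
  sub_idx <- vector("list", nr)
  mod_idx <- vector("list", nr)
  prod1_idx <- integer(nr)
  host_vol <- vol_of_comp[rx$host]
  law <- rx$law
  p1 <- numeric(nr); p2 <- numeric(nr); p3 <- numeric(nr)

  side_keys <- function(s) {
    if (nrow(s) == 0) return(integer(0))
    idx_of[paste0(s$species, "@", s$compartment)]
  }
  for (r in seq_len(nr)) {
    subs <- rx$substrates[[r]]; prods <- rx$products[[r]]; mods <- rx$modifiers[[r]]
    si <- side_keys(subs)
    pi_ <- side_keys(prods)
    mi <- side_keys(mods)
    sub_idx[[r]] <- unname(si)
    mod_idx[[r]] <- unname(mi)
    prod1_idx[r] <- if (length(pi_) > 0) pi_[1] else NA_integer_
    for (k in seq_along(si)) {
      M[si[k], r] <- M[si[k], r] - subs$stoich[k] * host_vol[r] / vols[si[k]]
    }
    for (k in seq_along(pi_)) {
      M[pi_[k], r] <- M[pi_[k], r] + prods$stoich[k] * host_vol[r] / vols[pi_[k]]
    }
    pars <- rx$params[[r]]
    switch(rx$law[r],
      passive_diffusion = { p1[r] <- pars$gamma; p2[r] <- pars$sigma },
      facilitated_transport = { p1[r] <- pars$v; p2[r] <- pars$km },
      michaelis_menten = { p1[r] <- pars$v_max; p2[r] <- pars$km },
      bimolecular_mm = { p1[r] <- pars$j_max; p2[r] <- pars$k },
      mass_action = { p1[r] <- pars$k },
      uncompetitive_inhibition = { p1[r] <- pars$v_max; p2[r] <- pars$km
                                   p3[r] <- pars$ki })
  }
  M[clamped, ] <- 0

  # regulation wiring: reaction -> protein state index and reference level
  # (absent entirely in reduced models without the regulation layer)
  reg <- model$regulation
  cell_of_rxn <- function(r) {
    comps <- c(rx$substrates[[r]]$compartment, rx$products[[r]]$compartment)
    if (any(comps %in% c("Nc", "Nm", "Nn"))) "neuron"
    else if (any(comps %in% c("Ac", "Am", "An"))) "astrocyte"
    else NA_character_
  }
  reg_prot_idx <- rep(NA_integer_, nr)
  reg_prot_ref <- rep(NA_real_, nr)
  if (!is.null(reg)) {
    for (r in seq_len(nr)) {
      g <- rx$regulated_by[r]
      if (is.na(g)) next
      cell <- cell_of_rxn(r)
      cp <- reg[[cell]]
      reg_prot_idx[r] <- idx_of[paste0("protein_", g, "@", cp$cytosol)]
      reg_prot_ref[r] <- cp$protein_ref
    }
  }
  is_reg <- !is.na(reg_prot_idx)

  # gene-expression wiring (per cell, vectorised over the 7 genes)
  gene_block <- if (is.null(reg)) list() else lapply(
    c("neuron", "astrocyte"), function(cell) {
      cp <- reg[[cell]]
      list(
        hn = idx_of[paste0("HIF@", cp$nucleus)],
        mn = idx_of[paste0("mRNA_", reg$genes, "@", cp$nucleus)],
        mc = idx_of[paste0("mRNA_", reg$genes, "@", cp$cytosol)],
        pr = idx_of[paste0("protein_", reg$genes, "@", cp$cytosol)],
        ratio_nc = cp$v_nuc / cp$v_cyt
      )
    })

  tb <- reg$transcription; mb <- reg$mrna; pb <- reg$protein

  rates <- function(y) {
    cap <- p1
    if (any(is_reg)) {
      cap[is_reg] <- p1[is_reg] *
        pmax(y[reg_prot_idx[is_reg]], 0) / reg_prot_ref[is_reg]
    }
    J <- numeric(nr)
    for (r in seq_len(nr)) {
      si <- sub_idx[[r]]
      J[r] <- switch(law[r],
        passive_diffusion =
          cap[r] * (y[si[1]] - p2[r] * y[prod1_idx[r]]),
        facilitated_transport = {
          cs <- max(y[si[1]], 0)
          cap[r] * cs / (p2[r] + cs)
        },
        michaelis_menten = {
          cs <- max(y[si[1]], 0)
          cap[r] * cs / (p2[r] + cs)
        },
        bimolecular_mm = {
          pr <- prod(pmax(y[si], 0))
          cap[r] * pr / (p2[r] + pr)
        },
        mass_action =
          cap[r] * prod(pmax(y[si], 0)) * prod(pmax(y[mod_idx[[r]]], 0)),
        uncompetitive_inhibition = {
          cs <- max(y[si[1]], 0)
          ci <- max(y[mod_idx[[r]][1]], 0)
          cap[r] * cs / (p2[r] + cs * (1 + ci / p3[r]))
        })
    }
    J
  }

  func <- function(t, y, parms) {
    dy <- as.vector(M %*% rates(y))
    for (gb in gene_block) {
      hn <- max(y[gb$hn], 0)
      tr <- tb$basal + tb$v_hif * hn / (tb$k_hif + hn)
      mn <- y[gb$mn]; mc <- y[gb$mc]; pr <- y[gb$pr]
      dy[gb$mn] <- dy[gb$mn] + tr - (mb$export + mb$degrade_nucleus) * mn
      dy[gb$mc] <- dy[gb$mc] + mb$export * mn * gb$ratio_nc -
        mb$degrade_cytosol * mc
      dy[gb$pr] <- dy[gb$pr] + pb$translate * mc - pb$degrade * pr
    }
    dy[clamped] <- 0
    list(dy)
  }

  structure(list(
    func = func, rates = rates,
    y0 = stats::setNames(sp$initial, keys),
    keys = keys, clamped = stats::setNames(clamped, keys),
    volumes = stats::setNames(unname(vols), keys), M = M
  ), class = "anlsim_ode")
}

#' Deterministically simulate a model under a scenario
#'
#' Stiff implicit integration (LSODA) of the assembled metabolic plus
#' regulatory system on a dense output grid. Blood O2 is clamped at the
#' scenario value for the whole run; blood glucose is clamped only when the
#' scenario says so (glucose starvation). Results are reproducible
#' bit-for-bit at fixed tolerances.
#'
#' @param model An `anlsim_model`.
#' @param scenario A scenario from [make_scenario()].
#' @param t_end Horizon (min); defaults to the scenario's.
#' @param output_step Output grid spacing (min).
#' @param rtol,atol Relative/absolute solver tolerances.
#' @return An `anlsim_timecourse`: wide tibble of concentrations (`$data`),
#'   scenario and model provenance, solver diagnostics, and any
#'   negative-concentration excursions beyond the 1e-9 tolerance band
#'   (`$diagnostics`; excursions are reported, never clipped).
#' @export
simulate_timecourse <- function(model, scenario, t_end = scenario$t_end,
                                output_step = 1, rtol = 1e-8, atol = 1e-11) {
  stopifnot(inherits(model, "anlsim_model"), t_end > 0)
  m <- model
  set_init <- function(id, comp, value) {
    i <- m$species$id == id & m$species$compartment == comp
    m$species$initial[i] <<- value
  }
  set_init("Glc", "b", scenario$blood_glucose)
  set_init("O2", "b", scenario$blood_o2)
  extra <- if (isTRUE(scenario$glucose_clamped)) "Glc@b" else character()

  ode <- assemble_odes(m, extra_clamps = extra)
  times <- seq(0, t_end, by = output_step)
  sol <- deSolve::lsoda(ode$y0, times, ode$func, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  di <- attr(sol, "istate")
  if (nrow(sol) < length(times)) {
    stop(sprintf("integrator stopped at t = %.3f min (requested %.0f)",
                 max(sol[, "time"]), t_end), call. = FALSE)
  }
  dat <- tibble::as_tibble(as.data.frame(sol))

  eps <- 1e-9
  mins <- vapply(dat[-1], min, numeric(1))
  neg <- mins < -eps
  diagnostics <- tibble::tibble(
    key = names(mins)[neg], min_value = unname(mins[neg]))

  structure(list(
    data = dat,
    variant = model$variant,
    scenario = scenario,
    solver = list(method = "lsoda", rtol = rtol, atol = atol,
                  steps = di[3], func_evals = di[4], jac_evals = di[5]),
    digest = parameter_digest(model$parameter_table),
    volumes = ode$volumes,
    carbon = stats::setNames(model$species$carbon,
                             paste0(model$species$id, "@", model$species$compartment)),
    clamped = ode$clamped,
    extrapolation = identical(scenario$name, "starvation") &&
      identical(model$variant, "classical"),
    diagnostics = diagnostics
  ), class = "anlsim_timecourse")
}

#' @export
print.anlsim_timecourse <- function(x, ...) {
  cat(sprintf("<anlsim_timecourse: %s / %s>\n", x$variant, x$scenario$name))
  cat(sprintf("  %d time points over %.0f min, %d series; %s\n",
              nrow(x$data), max(x$data$time), ncol(x$data) - 1, x$digest))
  if (nrow(x$diagnostics) > 0) {
    cat(sprintf("  ! %d negative-concentration excursions beyond 1e-9\n",
                nrow(x$diagnostics)))
  }
  invisible(x)
}

#' Long (tidy) view of a time course
#'
#' @param x An `anlsim_timecourse`.
#' @param ... Unused.
#' @return Tibble with `time`, `species`, `compartment`, `value` (mM).
#' @export
tidy.anlsim_timecourse <- function(x, ...) {
  long <- tidyr::pivot_longer(x$data, -"time",
                              names_to = "key", values_to = "value")
  parts <- strsplit(long$key, "@", fixed = TRUE)
  long$species <- vapply(parts, `[`, "", 1)
  long$compartment <- vapply(parts, `[`, "", 2)
  dplyr::select(long, "time", "species", "compartment", "value")
}

#' @export
glance.anlsim_timecourse <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, scenario = x$scenario$name,
    t_end = max(x$data$time), n_series = ncol(x$data) - 1,
    solver_steps = x$solver$steps, func_evals = x$solver$func_evals,
    negative_excursions = nrow(x$diagnostics),
    extrapolation = x$extrapolation
  )
}

#' Extract one concentration series
#'
#' @param tc An `anlsim_timecourse`.
#' @param key State key `"species@compartment"`, e.g. `"ATP@Nm"`.
#' @return Tibble with `time` and `value`.
#' @export
timecourse_series <- function(tc, key) {
  if (!key %in% names(tc$data)) {
    stop(sprintf("unknown species key '%s'", key), call. = FALSE)
  }
  tibble::tibble(time = tc$data$time, value = tc$data[[key]])
}

#' Detect a plateau (steady state) in one series
#'
#' Declares a plateau at the earliest time after which the trajectory stays
#' within `rel_tol` of its final value over the trailing `window`; the
#' reported plateau value is the mean over that trailing window. A series
#' that never settles is reported as not attained (no exception).
#'
#' @param tc An `anlsim_timecourse`, or a two-column data frame
#'   (`time`, `value`).
#' @param key State key (ignored when `tc` is already a series).
#' @param window Trailing window length (min).
#' @param rel_tol Relative tolerance defining "settled" (default 1%).
#' @return One-row tibble: `key`, `plateau`, `attained`, `time_attained`,
#'   `final_value`, `window`, `rel_tol`.
#' @export
detect_steady_state <- function(tc, key = NULL, window = 25, rel_tol = 0.01) {
  if (inherits(tc, "anlsim_timecourse")) {
    ser <- timecourse_series(tc, key)
  } else {
    ser <- tc
    names(ser)[1:2] <- c("time", "value")
    key <- key %||% "series"
  }
  t <- ser$time; v <- ser$value
  span <- max(t) - min(t)
  if (window >= span) stop("window must be shorter than the trajectory span",
                           call. = FALSE)
  in_tail <- t >= max(t) - window
  plateau <- mean(v[in_tail])
  tol <- rel_tol * max(abs(plateau), 1e-8)
  ok <- abs(v - plateau) <= tol
  # earliest T such that every later point is within tolerance
  last_bad <- if (any(!ok)) max(which(!ok)) else 0
  attained <- last_bad < min(which(in_tail))
  time_attained <- if (attained) {
    if (last_bad == 0) t[1] else t[last_bad + 1]
  } else NA_real_
  tibble::tibble(
    key = key, plateau = plateau, attained = attained,
    time_attained = time_attained, final_value = v[length(v)],
    window = window, rel_tol = rel_tol
  )
}

#' Total carbon amount of a time course
#'
#' Sum over all states of carbon count x concentration x compartment
#' volume, per time point. Constant (to integrator tolerance) for a closed
#' model run, e.g. the classical variant without a glucose clamp.
#'
#' @param tc An `anlsim_timecourse`.
#' @return Tibble with `time` and `carbon_mmol`.
#' @export
carbon_total <- function(tc) {
  keys <- setdiff(names(tc$data), "time")
  w <- tc$carbon[keys] * tc$volumes[keys]
  tibble::tibble(
    time = tc$data$time,
    carbon_mmol = as.vector(as.matrix(tc$data[keys]) %*% w)
  )
}

#' Per-compartment conserved-pair totals
#'
#' Time series of `[NAD]+[NADH]`, `[FAD]+[FADH2]`, `[ATP]+[ADP]` and
#' `[Cr]+[P-Cr]` within each compartment that carries the pair.
#'
#' @param tc An `anlsim_timecourse`.
#' @return Tibble with `time`, `pair`, `compartment`, `total` (mM).
#' @export
moiety_totals <- function(tc) {
  out <- list()
  for (pair in .conjugate_pairs) {
    a <- pair[1]; b <- pair[2]
    comps <- intersect(
      sub(paste0(a, "@"), "", grep(paste0("^", a, "@"), names(tc$data), value = TRUE)),
      sub(paste0(b, "@"), "", grep(paste0("^", b, "@"), names(tc$data), value = TRUE)))
    for (cp in comps) {
      out[[length(out) + 1]] <- tibble::tibble(
        time = tc$data$time,
        pair = paste0(a, "+", b),
        compartment = cp,
        total = tc$data[[paste0(a, "@", cp)]] + tc$data[[paste0(b, "@", cp)]])
    }
  }
  dplyr::bind_rows(out)
}

#' Write / read a time course as CSV with a metadata header
#'
#' The header is a block of `# key: value` comment lines (variant, scenario,
#' solver settings, parameter digest) followed by the table in long or wide
#' layout.
#'
#' @param tc An `anlsim_timecourse`.
#' @param path Output file.
#' @param layout `"long"` or `"wide"`.
#' @export
write_timecourse <- function(tc, path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  sc <- tc$scenario
  hdr <- c(
    sprintf("# variant: %s", tc$variant),
    sprintf("# scenario: %s", sc$name),
    sprintf("# blood_glucose_mM: %g (clamped: %s)", sc$blood_glucose,
            sc$glucose_clamped),
    sprintf("# blood_o2_mM: %g (clamped: TRUE)", sc$blood_o2),
    sprintf("# solver: %s rtol=%g atol=%g", tc$solver$method,
            tc$solver$rtol, tc$solver$atol),
    sprintf("# provenance: %s", tc$digest),
    sprintf("# layout: %s", layout)
  )
  dat <- if (layout == "wide") tc$data else tidy.anlsim_timecourse(tc)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(dat, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse
#' @return `read_timecourse()` returns a list with `metadata` (character)
#'   and `data` (tibble).
#' @export
read_timecourse <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  dat <- utils::read.csv(text = paste(lines[-hdr], collapse = "\n"),
                         check.names = FALSE)
  list(metadata = sub("^# ", "", lines[hdr]), data = tibble::as_tibble(dat))
}
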