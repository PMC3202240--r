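#' Synthetic-data generators and a transport-parameter estimator
#'
#' Generators standing in for the study's raw inputs: perturbed kinetic
#' parameter sets (robustness probes), noisy observation time courses, and
#' hypoxia-vs-normoxia expression panels emulating the qualitative RT-PCR
#' readout (direction of effect, reference-gene normalisation). All
#' generators are pure functions of their inputs and a seed.
#'
#' @name synthetic-data
NULL

.lognormal_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -s^2 / 2, s)) # mean-one multiplicative noise
}

#' Perturb a parameter table multiplicatively
#'
#' Each entry is multiplied by an independent mean-one lognormal factor
#' with the requested coefficient of variation; provenance is re-tagged
#' `estimated`. Reproducible from the seed.
#'
#' @param tab Parameter tibble from [load_parameters()].
#' @param cv Fractional coefficient of variation, >= 0.
#' @param seed Integer seed.
#' @return Perturbed parameter tibble.
#' @export
perturb_parameters <- function(tab, cv, seed = 1) {
  stopifnot(cv >= 0)
  set.seed(seed)
  out <- tab
  out$value <- tab$value * .lognormal_factors(nrow(tab), cv)
  if (cv > 0) out$provenance <- "estimated"
  validate_parameter_table(out)
  out
}

#' Overlay observation noise on a simulated time course
#'
#' Simulates (or reuses) a deterministic time course and applies the
#' declared noise model: multiplicative lognormal (`observed = truth *
#' exp(N(0, sigma))`, the default, since concentrations are positive) or
#' additive Gaussian. The noiseless truth is retained for recovery tests.
#'
#' @param model An `anlsim_model`, or an existing `anlsim_timecourse` (in
#'   which case `scenario` and `...` are ignored).
#' @param scenario An `anlsim_scenario`.
#' @param noise List with `type` (`"lognormal"` or `"additive"`) and
#'   `sigma`.
#' @param seed Integer seed.
#' @param keys Optional subset of state keys to observe.
#' @param ... Passed to [simulate_timecourse()].
#' @return A list of class `anlsim_noisy_series`: `observed` and `truth`
#'   (wide tibbles), `noise`, `seed`.
#' @export
generate_noisy_timecourse <- function(model, scenario = NULL,
                                      noise = list(type = "lognormal", sigma = 0.05),
                                      seed = 1, keys = NULL, ...) {
  tc <- if (inherits(model, "anlsim_timecourse")) model
        else simulate_timecourse(model, scenario, ...)
  truth <- tc$data
  if (!is.null(keys)) truth <- truth[, c("time", keys)]
  obs <- truth
  set.seed(seed)
  for (k in setdiff(names(obs), "time")) {
    n <- nrow(obs)
    obs[[k]] <- switch(noise$type,
      lognormal = truth[[k]] * exp(stats::rnorm(n, 0, noise$sigma)),
      additive = truth[[k]] + stats::rnorm(n, 0, noise$sigma),
      stop("unknown noise type", call. = FALSE))
  }
  structure(list(observed = obs, truth = truth, noise = noise, seed = seed),
            class = "anlsim_noisy_series")
}

#' Serialise a noisy series to CSV (noise metadata in the header)
#'
#' @param x An `anlsim_noisy_series`.
#' @param path Output file.
#' @export
write_noisy_series <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# noise: %s sigma=%g", x$noise$type, x$noise$sigma),
               sprintf("# seed: %d", x$seed)), con)
  utils::write.csv(x$observed, con, row.names = FALSE)
  invisible(path)
}

#' Hypoxia-vs-normoxia expression panel
#'
#' Emulates a reference-normalised transcript panel for the enzymes whose
#' hypoxic induction motivates the regulation module (PK, HK, PFK, CS,
#' GAPDH) with a cytoskeletal reference gene. Normoxic abundances scatter
#' around 1, hypoxic abundances around the per-gene effect size; both
#' panels are normalised to the reference gene, whose ratio is therefore
#' identically 1. Note the panel deliberately allows a glycolytic
#' "housekeeping" gene (GAPDH) to be itself induced.
#'
#' @param effects Named positive vector of hypoxic fold-inductions; the
#'   defaults are 2-3x placeholders matching the regulation calibration.
#' @param sigma Lognormal noise sigma.
#' @param seed Integer seed.
#' @param reference Reference gene name.
#' @return Tibble with `condition`, `gene`, `abundance` (reference-
#'   normalised), `is_reference`; attributes `sigma`, `seed`.
#' @export
generate_expression_panel <- function(effects = c(PK = 2.5, HK = 2, PFK = 2.5,
                                                  CS = 1.8, GAPDH = 2),
                                      sigma = 0.1, seed = 1,
                                      reference = "beta_actin") {
  if (any(effects <= 0)) stop("effect sizes must be > 0", call. = FALSE)
  set.seed(seed)
  genes <- c(names(effects), reference)
  draw <- function(mu) mu * exp(stats::rnorm(length(mu), 0, sigma))
  panel <- function(cond, mu) {
    raw <- draw(mu)
    tibble::tibble(
      condition = cond, gene = genes,
      abundance = raw / raw[length(raw)],
      is_reference = genes == reference)
  }
  out <- dplyr::bind_rows(
    panel("normoxia", c(rep(1, length(effects)), 1)),
    panel("hypoxia", c(unname(effects), 1)))
  attr(out, "sigma") <- sigma
  attr(out, "seed") <- seed
  out
}

#' Closed-pool facilitated-uptake series
#'
#' The identification fixture for [recover_transport_parameters()]: a
#' single carrier drains a closed substrate pool, `dC/dt = -v C/(km + C)`,
#' whose exact solution satisfies the implicit relation
#' `km log(C0/C) + (C0 - C) = v t`. The trajectory is evaluated by root
#' finding (machine-precision, no ODE solver), then observation noise is
#' applied.
#'
#' @param v,km True transport parameters (mM/min, mM).
#' @param c0 Initial concentration (mM).
#' @param times Observation times (min).
#' @param sigma Lognormal observation noise sigma (0 = noiseless).
#' @param seed Integer seed.
#' @return Tibble with `time`, `true`, `observed`.
#' @export
generate_uptake_series <- function(v, km, c0, times = seq(0, 50, length.out = 50),
                                   sigma = 0, seed = 1) {
  truth <- uptake_concentration(times, v, km, c0)
  set.seed(seed)
  obs <- if (sigma > 0) truth * exp(stats::rnorm(length(truth), 0, sigma)) else truth
  tibble::tibble(time = times, true = truth, observed = obs)
}

#' @rdname generate_uptake_series
#' @param t Times at which to evaluate the exact solution.
#' @export
uptake_concentration <- function(t, v, km, c0) {
  vapply(t, function(ti) {
    if (ti <= 0) return(c0)
    f <- function(cc) km * log(c0 / cc) + (c0 - cc) - v * ti
    if (f(1e-12) < 0) return(0) # pool numerically exhausted
    stats::uniroot(f, c(1e-12, c0), tol = 1e-12)$root
  }, numeric(1))
}

#' Recover facilitated-transport parameters from a noisy uptake series
#'
#' Least-squares fit of the integrated carrier-uptake model to the observed
#' concentrations (Levenberg-Marquardt). When the fitted affinity constant
#' sits far above the observed concentration range the carrier operated in
#' its linear regime; `v` and `km` are then individually non-identifiable
#' (only their ratio is) and the fit is flagged accordingly.
#'
#' @param series Tibble from [generate_uptake_series()] (columns `time`,
#'   `observed`) or an `anlsim_noisy_series` restricted to one key.
#' @param c0 Initial concentration; defaults to the first observation.
#' @param start Optional named start values `c(v =, km =)`.
#' @param scale `"log"` (default) fits residuals on the log scale, the
#'   correct criterion for the multiplicative observation noise the
#'   generators default to; `"linear"` fits raw residuals (additive noise).
#' @return Object of class `anlsim_recovery_fit`: estimates, residual norm,
#'   identifiability flag, and the underlying `nls` fit.
#' @export
recover_transport_parameters <- function(series, c0 = NULL, start = NULL,
                                         scale = c("log", "linear")) {
  scale <- match.arg(scale)
  keep <- if (scale == "log") series$observed > 0 else rep(TRUE, nrow(series))
  tt <- series$time[keep]
  y <- series$observed[keep]
  # when the designed initial concentration is not supplied it is fitted
  # alongside (v, km): anchoring it to the noisy first observation would
  # bias both kinetic estimates
  fit_c0 <- is.null(c0)
  c0 <- c0 %||% y[which.min(tt)]
  if (is.null(start)) {
    # profile start: for any km the integrated law gives a per-point v
    # estimate v = (km log(c0/C) + (c0 - C)) / t; take the median over the
    # series, then keep the km whose implied fit has the smallest log-RSS
    pos <- tt > 0 & y > 0 & y < c0
    km_grid <- c0 * c(0.05, 0.1, 0.25, 0.5, 1, 2, 5, 20)
    cand <- lapply(km_grid, function(kmg) {
      vg <- stats::median((kmg * log(c0 / y[pos]) + (c0 - y[pos])) / tt[pos])
      vg <- max(vg, 1e-6)
      pred <- pmax(uptake_concentration(tt, vg, kmg, c0), 1e-12)
      list(v = vg, km = kmg, rss = sum((log(pmax(y, 1e-12)) - log(pred))^2))
    })
    best <- cand[[which.min(vapply(cand, `[[`, 0, "rss"))]]
    start <- c(v = best$v, km = best$km)
  }
  dat <- data.frame(time = tt, observed = y)
  # nls treats the names in `start` as parameters; anything else in the
  # formula (c0 when fixed) resolves from this function's environment
  form <- if (scale == "log") {
    log(observed) ~ log(pmax(uptake_concentration(time, v, km, c0), 1e-12))
  } else {
    observed ~ uptake_concentration(time, v, km, c0)
  }
  environment(form) <- environment()
  if (fit_c0) start <- c(start, c0 = c0)
  lower <- stats::setNames(rep(1e-9, length(start)), names(start))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      form, data = dat, start = as.list(start), lower = lower,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    stop(sprintf("transport-parameter fit did not converge (start v=%g, km=%g): %s",
                 start[["v"]], start[["km"]], conditionMessage(fit)),
         call. = FALSE)
  }
  est <- stats::coef(fit)
  # in the linear regime (km >> C) the v/km direction is a likelihood ridge:
  # the estimates are perfectly correlated and only the first-order decay
  # rate v/km is identified
  corr <- tryCatch(stats::cov2cor(stats::vcov(fit))["v", "km"],
                   error = function(e) NA_real_)
  linear_regime <- isTRUE(est[["km"]] > 10 * max(y)) ||
    isTRUE(abs(corr) > 0.999)
  ratio <- if (linear_regime) {
    # exponential-decay limit: log C is linear in t with slope -v/km
    keep <- y > 0
    -unname(stats::coef(stats::lm(log(y[keep]) ~ tt[keep]))[2])
  } else {
    est[["v"]] / est[["km"]]
  }
  structure(list(
    v = est[["v"]], km = est[["km"]], ratio = ratio,
    residual_norm = sqrt(sum(stats::resid(fit)^2)),
    identifiable = !linear_regime, param_correlation = unname(corr),
    n = length(y), fit = fit
  ), class = "anlsim_recovery_fit")
}

#' @export
print.anlsim_recovery_fit <- function(x, ...) {
  cat(sprintf("<recovery fit: v=%.4g mM/min, km=%.4g mM (v/km=%.4g 1/min)>\n",
              x$v, x$km, x$ratio))
  if (!x$identifiable) {
    cat("  linear-regime data: v and km individually non-identifiable\n")
  }
  invisible(x)
}

#' @export
tidy.anlsim_recovery_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s), estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"]
  )
}

#' @export
glance.anlsim_recovery_fit <- function(x, ...) {
  tibble::tibble(
    v = x$v, km = x$km, ratio = x$ratio,
    residual_norm = x$residual_norm,
    identifiable = x$identifiable, n = x$n
  )
}
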