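#' Rate-law evaluators
#'
#' The six kinetic-law forms used by the compartmental models. Every reaction
#' in either model variant is assigned exactly one of these forms; the ODE
#' assembler evaluates fluxes through these functions and nothing else, so
#' they are also the natural target for independent arithmetic oracles in the
#' test-suite.
#'
#' All rates are in mM min^-1 referenced to the host (source) compartment of
#' the reaction; concentrations are mM.
#'
#' @name kinetic-laws
NULL

.chk_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("%s must be finite and non-negative", what), call. = FALSE)
  }
  invisible(x)
}

#' Passive diffusion flux
#'
#' Linear (non-saturable) membrane transport between two compartments:
#' `J = gamma * (c_x - sigma * c_y)`. A positive value is a net flux from
#' compartment x to compartment y; the law is bidirectional and vanishes at
#' the partition equilibrium `c_x == sigma * c_y`.
#'
#' @param gamma Membrane transport coefficient (min^-1), >= 0.
#' @param sigma Dimensionless partition coefficient, > 0.
#' @param c_x,c_y Concentrations (mM) on the two sides, >= 0.
#' @return Net flux (mM min^-1, referenced to compartment x).
#' @family kinetic laws
#' @export
#' @examples
#' passive_diffusion_flux(2, 1, 3, 1) # 4
passive_diffusion_flux <- function(gamma, sigma, c_x, c_y) {
  .chk_nonneg(gamma, "gamma")
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("sigma must be finite and > 0", call. = FALSE)
  }
  .chk_nonneg(c_x, "c_x")
  .chk_nonneg(c_y, "c_y")
  gamma * (c_x - sigma * c_y)
}

#' Facilitated (carrier-mediated) transport flux
#'
#' Michaelis-Menten shaped unidirectional carrier flux out of the source
#' compartment: `J = v * c_x / (km + c_x)`. Monotone increasing in `c_x` and
#' bounded above by `v`.
#'
#' @param v Transport rate coefficient (mM min^-1), >= 0.
#' @param km Affinity coefficient (mM), > 0.
#' @param c_x Source-side concentration (mM), >= 0.
#' @return Flux (mM min^-1, referenced to the source compartment).
#' @family kinetic laws
#' @export
facilitated_transport_flux <- function(v, km, c_x) {
  .chk_nonneg(v, "v")
  if (any(!is.finite(km)) || any(km <= 0)) stop("km must be > 0", call. = FALSE)
  .chk_nonneg(c_x, "c_x")
  v * c_x / (km + c_x)
}

#' Michaelis-Menten enzymatic rate
#'
#' `J = v_max * s / (km + s)`; the enzymatic reading of the same functional
#' form as [facilitated_transport_flux()].
#'
#' @param v_max Limiting rate (mM min^-1), >= 0.
#' @param km Half-saturation constant (mM), > 0.
#' @param s Substrate concentration (mM), >= 0.
#' @family kinetic laws
#' @export
michaelis_menten_rate <- function(v_max, km, s) {
  facilitated_transport_flux(v_max, km, s)
}

#' Bimolecular saturating rate
#'
#' Saturating rate law for two-substrate reactions (X + Y -> Z + W):
#' `J = j_max * (c_x * c_y) / (k + c_x * c_y)`. The denominator carries the
#' concentration *product* (k has units mM^2), so the law is symmetric in its
#' substrates and bounded by `j_max`.
#'
#' @param j_max Limiting rate (mM min^-1), >= 0.
#' @param k Half-saturation constant of the concentration product (mM^2), > 0.
#' @param c_x,c_y Substrate concentrations (mM), >= 0.
#' @family kinetic laws
#' @export
bimolecular_saturating_rate <- function(j_max, k, c_x, c_y) {
  .chk_nonneg(c_x, "c_x")
  .chk_nonneg(c_y, "c_y")
  saturating_product_rate(j_max, k, c_x * c_y)
}

#' Saturating product-form rate (n-ary generalisation)
#'
#' `J = j_max * p / (k + p)` where `p` is the product of all substrate
#' concentrations. [bimolecular_saturating_rate()] is the two-substrate case;
#' the assembler uses this form for the model's few three-substrate reactions
#' (the lumped electron transport chain), keeping them inside the same
#' declared law family.
#'
#' @param j_max Limiting rate (mM min^-1), >= 0.
#' @param k Half-saturation constant of the product term (mM^n), > 0.
#' @param prod_c Product of substrate concentrations (mM^n), >= 0.
#' @family kinetic laws
#' @export
saturating_product_rate <- function(j_max, k, prod_c) {
  .chk_nonneg(j_max, "j_max")
  if (any(!is.finite(k)) || any(k <= 0)) stop("k must be > 0", call. = FALSE)
  .chk_nonneg(prod_c, "substrate concentration product")
  j_max * prod_c / (k + prod_c)
}

#' Mass-action rate
#'
#' `J = k * prod(concentrations)`; the reaction order is the number of
#' concentrations supplied. Zeroth-order kinetics must be expressed
#' explicitly (e.g. first order on a clamped unit species), so an empty
#' concentration list is a domain error.
#'
#' @param k Rate constant (units depend on order), >= 0.
#' @param concentrations Numeric vector of substrate concentrations (mM).
#' @family kinetic laws
#' @export
mass_action_rate <- function(k, concentrations) {
  .chk_nonneg(k, "k")
  if (length(concentrations) == 0) {
    stop("mass action requires at least one concentration; express zeroth-order explicitly",
         call. = FALSE)
  }
  .chk_nonneg(concentrations, "concentrations")
  k * prod(concentrations)
}

#' Uncompetitive inhibition rate
#'
#' Standard textbook uncompetitive scheme (the inhibitor binds only the
#' enzyme-substrate complex): `J = v_max * s / (km + s * (1 + i / ki))`.
#' Reduces to [michaelis_menten_rate()] at `i = 0` and vanishes as `i` grows.
#'
#' @param v_max Limiting rate (mM min^-1), >= 0.
#' @param km Half-saturation constant (mM), > 0.
#' @param s Substrate concentration (mM), >= 0.
#' @param ki Inhibition constant (mM), > 0.
#' @param i Inhibitor concentration (mM), >= 0.
#' @family kinetic laws
#' @export
uncompetitive_inhibition_rate <- function(v_max, km, s, ki, i) {
  .chk_nonneg(v_max, "v_max")
  if (any(!is.finite(km)) || any(km <= 0)) stop("km must be > 0", call. = FALSE)
  if (any(!is.finite(ki)) || any(ki <= 0)) stop("ki must be > 0", call. = FALSE)
  .chk_nonneg(s, "s")
  .chk_nonneg(i, "i")
  v_max * s / (km + s * (1 + i / ki))
}

#' Declared kinetic-law forms
#'
#' @return Character vector of the six law identifiers used in model configs.
#' @export
kinetic_law_forms <- function() {
  c("passive_diffusion", "facilitated_transport", "michaelis_menten",
    "bimolecular_mm", "mass_action", "uncompetitive_inhibition")
}

# Parameter names each law form requires in the parameter table.
.law_param_names <- function(form) {
  switch(form,
    passive_diffusion        = c("gamma", "sigma"),
    facilitated_transport    = c("v", "km"),
    michaelis_menten         = c("v_max", "km"),
    bimolecular_mm           = c("j_max", "k"),
    mass_action              = "k",
    uncompetitive_inhibition = c("v_max", "km", "ki"),
    stop(sprintf("unknown kinetic-law form '%s'", form), call. = FALSE)
  )
}
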