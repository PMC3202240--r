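# Shared fixtures: full-model simulations are expensive, so the suite builds
# each (variant, scenario, horizon) run once and reuses it across test files.
.anlsim_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .anlsim_test_cache)) {
    assign(key, force(expr), envir = .anlsim_test_cache)
  }
  get(key, envir = .anlsim_test_cache)
}

test_params <- function() cached("params", load_parameters())

test_model <- function(variant) {
  cached(paste0("model_", variant), {
    if (variant == "classical") build_classical_model(test_params())
    else build_anlsh_model(test_params())
  })
}

test_run <- function(variant, scenario, t_end = 250) {
  cached(sprintf("run_%s_%s_%d", variant, scenario, t_end), {
    run_experiment(variant, make_scenario(scenario, t_end = t_end),
                   params = test_params())
  })
}

test_regulation_run <- function(cell, o2) {
  cached(sprintf("reg_%s_%g", cell, o2), {
    simulate_regulation(test_model("classical"), cell = cell, o2 = o2,
                        t_end = 250, output_step = 2)
  })
}

# a minimal two-pool model without the regulation layer, for analytic oracles
toy_two_pool_model <- function(k1 = 0.3, k2 = 0.1, a0 = 2, b0 = 0) {
  structure(list(
    variant = "toy",
    compartments = tibble::tibble(
      id = "Nc", description = "single pool", volume = 1),
    species = tibble::tibble(
      id = c("A", "B"), compartment = "Nc", initial = c(a0, b0),
      clamped = FALSE, carbon = c(1, 1), role = "metabolite",
      gene = NA_character_, pool = NA_character_),
    reactions = tibble::tibble(
      number = 1:2, name = c("fwd", "rev"), law = "mass_action", host = "Nc",
      substrates = list(
        tibble::tibble(species = "A", compartment = "Nc", stoich = 1),
        tibble::tibble(species = "B", compartment = "Nc", stoich = 1)),
      products = list(
        tibble::tibble(species = "B", compartment = "Nc", stoich = 1),
        tibble::tibble(species = "A", compartment = "Nc", stoich = 1)),
      modifiers = list(
        tibble::tibble(species = character(), compartment = character(),
                       stoich = numeric()),
        tibble::tibble(species = character(), compartment = character(),
                       stoich = numeric())),
      regulated_by = NA_character_,
      params = list(list(k = k1), list(k = k2))),
    regulation = NULL,
    parameter_table = tibble::tibble(
      reaction = 1:2, parameter = "k", value = c(k1, k2),
      unit = "1/min", provenance = "estimated"),
    membership = NULL
  ), class = "anlsim_model")
}

# passive diffusion between two pools of different volume, clamp-free
toy_transport_model <- function(gamma = 0.5, sigma = 1, vb = 0.095, ve = 0.2,
                                cb0 = 4, ce0 = 1) {
  m <- toy_two_pool_model()
  m$compartments <- tibble::tibble(
    id = c("b", "e"), description = c("blood", "ecs"), volume = c(vb, ve))
  m$species <- tibble::tibble(
    id = "X", compartment = c("b", "e"), initial = c(cb0, ce0),
    clamped = FALSE, carbon = 1, role = "metabolite",
    gene = NA_character_, pool = NA_character_)
  m$reactions <- tibble::tibble(
    number = 1L, name = "diffusion", law = "passive_diffusion", host = "b",
    substrates = list(tibble::tibble(species = "X", compartment = "b",
                                     stoich = 1)),
    products = list(tibble::tibble(species = "X", compartment = "e",
                                   stoich = 1)),
    modifiers = list(tibble::tibble(species = character(),
                                    compartment = character(),
                                    stoich = numeric())),
    regulated_by = NA_character_,
    params = list(list(gamma = gamma, sigma = sigma)))
  m$parameter_table <- tibble::tibble(
    reaction = 1L, parameter = c("gamma", "sigma"), value = c(gamma, sigma),
    unit = c("1/min", "dimensionless"), provenance = "estimated")
  m
}
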