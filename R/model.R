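#' @importFrom rlang .data
NULL

#' Parse a reaction-number range string
#'
#' Turns an enumeration such as `"1-14, 16, 18-26"` into a sorted integer
#' vector. The model configs carry the two model variants' reaction
#' membership in exactly this printed form, so variant construction is
#' table-driven rather than hard-coded.
#'
#' @param txt A range string.
#' @return Sorted integer vector.
#' @export
parse_reaction_ranges <- function(txt) {
  parts <- strsplit(gsub("\\s", "", txt), ",")[[1]]
  out <- unlist(lapply(parts, function(p) {
    if (grepl("-", p)) {
      ab <- as.integer(strsplit(p, "-")[[1]])
      seq.int(ab[1], ab[2])
    } else {
      as.integer(p)
    }
  }))
  sort(unique(out))
}

.load_compartments <- function() {
  raw <- yaml::yaml.load_file(anlsim_config("compartments.yaml"))$compartments
  tibble::tibble(
    id = purrr::map_chr(raw, "id"),
    description = purrr::map_chr(raw, "description"),
    volume = purrr::map_dbl(raw, "volume")
  )
}

.load_species <- function() {
  raw <- yaml::yaml.load_file(anlsim_config("species.yaml"))$species
  tibble::tibble(
    id = purrr::map_chr(raw, "id"),
    compartment = purrr::map_chr(raw, "compartment"),
    initial = purrr::map_dbl(raw, "initial"),
    clamped = purrr::map_lgl(raw, "clamped"),
    carbon = purrr::map_dbl(raw, "carbon"),
    role = "metabolite", gene = NA_character_, pool = NA_character_
  )
}

.load_reactions <- function() {
  raw <- yaml::yaml.load_file(anlsim_config("reactions.yaml"))
  side_tbl <- function(side) {
    if (length(side) == 0) {
      return(tibble::tibble(species = character(), compartment = character(),
                            stoich = numeric()))
    }
    tibble::tibble(
      species = purrr::map_chr(side, "species"),
      compartment = purrr::map_chr(side, "compartment"),
      stoich = purrr::map_dbl(side, "stoich")
    )
  }
  rx <- tibble::tibble(
    number = purrr::map_int(raw$reactions, ~ as.integer(.x$number)),
    name = purrr::map_chr(raw$reactions, "name"),
    law = purrr::map_chr(raw$reactions, "law"),
    host = purrr::map_chr(raw$reactions, "host"),
    substrates = purrr::map(raw$reactions, ~ side_tbl(.x$substrates)),
    products = purrr::map(raw$reactions, ~ side_tbl(.x$products)),
    modifiers = purrr::map(raw$reactions, ~ side_tbl(.x$modifiers)),
    regulated_by = purrr::map_chr(raw$reactions,
                                  ~ .x$regulated_by %||% NA_character_)
  )
  list(reactions = rx, membership = raw$membership)
}

.load_regulation <- function() {
  yaml::yaml.load_file(anlsim_config("regulation.yaml"))$regulation
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a compartmental model variant
#'
#' [build_classical_model()] assembles the variant in which both neuron and
#' astrocyte take up blood glucose and run full glycolysis plus oxidative
#' phosphorylation; [build_anlsh_model()] assembles the lactate-shuttle
#' variant, in which the astrocyte glycolyses glucose to lactate (no
#' astrocyte-mitochondrial reactions) and the neuron imports and oxidises
#' that lactate through two shuttle-specific reactions (numbers 93-94).
#' Which reactions belong to which variant is read from the enumeration in
#' the shipped reaction config, not hard-coded.
#'
#' Both builders resolve every kinetic parameter from `params` (erroring
#' with the reaction number and parameter name if an entry is missing),
#' attach the hypoxia gene-regulation layer, and set the regulatory species
#' (HIF pools, per-gene mRNA and protein pools) to their closed-form
#' normoxic steady state so that a normoxic simulation starts regulated at
#' its reference point.
#'
#' @param params Parameter table from [load_parameters()].
#' @return An object of class `anlsim_model`.
#' @export
build_classical_model <- function(params = load_parameters()) {
  .build_model("classical", params)
}

#' @rdname build_classical_model
#' @export
build_anlsh_model <- function(params = load_parameters()) {
  .build_model("anlsh", params)
}

.build_model <- function(variant, params) {
  validate_parameter_table(params)
  comps <- .load_compartments()
  species <- .load_species()
  rx_all <- .load_reactions()
  reg_cfg <- .load_regulation()

  keep <- parse_reaction_ranges(
    if (variant == "classical") rx_all$membership$model1 else rx_all$membership$model2)
  reactions <- dplyr::filter(rx_all$reactions, .data$number %in% keep)
  if (!setequal(reactions$number, keep)) {
    stop("reaction config does not define every number in the membership list",
         call. = FALSE)
  }

  # resolve kinetic parameters per reaction; error names reaction + parameter
  reactions$params <- purrr::map2(reactions$number, reactions$law, function(n, law) {
    need <- .law_param_names(law)
    vals <- vapply(need, function(pn) param_value(params, n, pn), numeric(1))
    as.list(vals)
  })

  # drop species that belong to compartments with no retained reaction
  # (the ANLSH variant has no astrocyte-mitochondrial chemistry but the
  # compartment itself, and its volume, remain declared)
  genes <- reg_cfg$genes

  model <- structure(list(
    variant = variant,
    compartments = comps,
    species = species,
    reactions = reactions,
    genes = genes,
    regulation = .regulation_params_from(params, reg_cfg, species, comps),
    parameter_table = dplyr::filter(params, .data$reaction %in% keep),
    membership = rx_all$membership
  ), class = "anlsim_model")

  model <- .attach_regulatory_species(model)
  model
}

# Extract the per-cell HIF sensor constants from the numbered reaction block
# and merge them with the gene-expression constants of the regulation config.
.regulation_params_from <- function(params, reg_cfg, species, comps) {
  vol <- function(id) comps$volume[comps$id == id]
  phase0 <- function(comp) species$initial[species$id == "PHase" &
                                             species$compartment == comp]
  cell <- function(cyto, nuc, syn, hyd, doh, tr, dn, ex) {
    list(
      cytosol = cyto, nucleus = nuc,
      v_cyt = vol(cyto), v_nuc = vol(nuc),
      synthesis = param_value(params, syn, "k"),
      hydroxylation = param_value(params, hyd, "k"),
      phase = phase0(cyto),
      hifoh_decay = param_value(params, doh, "k"),
      translocation = param_value(params, tr, "k"),
      nuclear_decay = param_value(params, dn, "k"),
      nuclear_export = param_value(params, ex, "k")
    )
  }
  list(
    genes = reg_cfg$genes,
    reference_o2 = reg_cfg$reference_o2,
    transcription = reg_cfg$transcription,
    mrna = reg_cfg$mrna,
    protein = reg_cfg$protein,
    neuron = cell("Nc", "Nn", 70, 73, 77, 81, 85, 89),
    astrocyte = cell("Ac", "An", 71, 75, 79, 83, 87, 91)
  )
}

# Append per-gene mRNA/protein species and set all regulatory pools to their
# normoxic closed-form steady state; record protein_ref per cell.
.attach_regulatory_species <- function(model) {
  reg <- model$regulation
  o2 <- reg$reference_o2
  for (cell_name in c("neuron", "astrocyte")) {
    cp <- reg[[cell_name]]
    ss <- hif_steady_state(cp, o2)
    gss <- gene_steady_state(reg, cp, ss$hif_nucleus)
    model$regulation[[cell_name]]$protein_ref <- gss$protein

    set_init <- function(id, comp, value) {
      i <- model$species$id == id & model$species$compartment == comp
      model$species$initial[i] <<- value
      invisible(NULL)
    }
    set_init("HIF", cp$cytosol, ss$hif_cytosol)
    set_init("HIF", cp$nucleus, ss$hif_nucleus)
    set_init("HIFOH", cp$cytosol, ss$hifoh)

    pools <- tibble::tibble(
      id = c(paste0("mRNA_", reg$genes), paste0("mRNA_", reg$genes),
             paste0("protein_", reg$genes)),
      compartment = rep(c(cp$nucleus, cp$cytosol, cp$cytosol),
                        each = length(reg$genes)),
      initial = rep(c(gss$mrna_nucleus, gss$mrna_cytosol, gss$protein),
                    each = length(reg$genes)),
      clamped = FALSE, carbon = 0, role = "gene",
      gene = rep(reg$genes, 3),
      pool = rep(c("mrna_nucleus", "mrna_cytosol", "protein"),
                 each = length(reg$genes))
    )
    model$species <- dplyr::bind_rows(model$species, pools)
  }
  model
}

#' @export
print.anlsim_model <- function(x, ...) {
  cat(sprintf("<anlsim_model: %s>\n", x$variant))
  cat(sprintf("  compartments: %d  species: %d  reactions: %d  regulated genes: %d\n",
              nrow(x$compartments), nrow(x$species), nrow(x$reactions),
              length(x$genes)))
  cat(sprintf("  %s\n", parameter_digest(x$parameter_table)))
  invisible(x)
}

#' Tidy the reaction table of a model
#'
#' @param x An `anlsim_model`.
#' @param ... Unused.
#' @return Tibble with one row per reaction (number, name, law, host,
#'   regulated_by).
#' @export
tidy.anlsim_model <- function(x, ...) {
  dplyr::select(x$reactions, "number", "name", "law", "host", "regulated_by")
}

#' @export
glance.anlsim_model <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    n_compartments = nrow(x$compartments),
    n_species = nrow(x$species),
    n_reactions = nrow(x$reactions),
    n_regulated = sum(!is.na(x$reactions$regulated_by)),
    digest = parameter_digest(x$parameter_table)
  )
}

# conjugate pairs whose per-compartment totals are structural invariants
.conjugate_pairs <- list(
  c("NAD", "NADH"), c("FAD", "FADH2"), c("ATP", "ADP"), c("Cr", "PCr")
)

#' Validate a compartmental model
#'
#' Structural diagnostics, returned as a tibble (empty when the model is
#' clean): dangling species references, kinetic-law/parameter-name
#' mismatches, parameter-table entries no reaction uses, per-reaction carbon
#' imbalance (from the per-species carbon annotations), and per-reaction
#' conjugate-pair (NAD/NADH, FAD/FADH2, ATP/ADP, Cr/P-Cr) imbalance within
#' each compartment, which catches redox bookkeeping defects such as an LDH
#' step that consumes NAD without returning NADH.
#'
#' @param model An `anlsim_model`.
#' @return Tibble with columns `check`, `reaction`, `detail`.
#' @export
validate_model <- function(model) {
  diags <- list()
  flag <- function(check, reaction, detail) {
    diags[[length(diags) + 1]] <<- tibble::tibble(
      check = check, reaction = as.integer(reaction), detail = detail)
  }
  spec_key <- paste0(model$species$id, "@", model$species$compartment)
  carbon_of <- stats::setNames(model$species$carbon, spec_key)

  for (i in seq_len(nrow(model$reactions))) {
    rx <- model$reactions[i, ]
    subs <- rx$substrates[[1]]; prods <- rx$products[[1]]; mods <- rx$modifiers[[1]]
    all_ref <- dplyr::bind_rows(subs, prods, mods)
    keys <- paste0(all_ref$species, "@", all_ref$compartment)
    missing <- setdiff(keys, spec_key)
    for (m in missing) flag("dangling_species", rx$number, m)

    need <- .law_param_names(rx$law)
    have <- names(rx$params[[1]])
    for (m in setdiff(need, have)) {
      flag("missing_parameter", rx$number, paste0(rx$law, " needs ", m))
    }
    for (m in setdiff(have, need)) {
      flag("unexpected_parameter", rx$number, m)
    }

    ok_keys <- intersect(keys, spec_key)
    if (length(missing) == 0) {
      cin <- sum(subs$stoich * carbon_of[paste0(subs$species, "@", subs$compartment)])
      cout <- sum(prods$stoich * carbon_of[paste0(prods$species, "@", prods$compartment)])
      if (abs(cin - cout) > 1e-9) {
        flag("carbon_imbalance", rx$number,
             sprintf("in=%g out=%g", cin, cout))
      }
      net <- dplyr::bind_rows(
        dplyr::mutate(subs, stoich = -.data$stoich), prods)
      # pure transport (identical species multiset on both sides) moves pool
      # members between compartments; the pair check is about chemistry
      is_transport <- identical(sort(rep(subs$species, subs$stoich)),
                                sort(rep(prods$species, prods$stoich)))
      for (pair in if (is_transport) list() else .conjugate_pairs) {
        sub_net <- dplyr::filter(net, .data$species %in% pair)
        if (nrow(sub_net) == 0) next
        by_comp <- dplyr::summarise(
          dplyr::group_by(sub_net, .data$compartment),
          d = sum(.data$stoich), .groups = "drop")
        bad <- abs(by_comp$d) > 1e-9
        if (any(bad)) {
          flag("conjugate_pair_imbalance", rx$number,
               sprintf("%s/%s in %s", pair[1], pair[2],
                       paste(by_comp$compartment[bad], collapse = ",")))
        }
      }
    }
  }

  used <- unlist(purrr::map2(model$reactions$number, model$reactions$params,
                             ~ paste0(.x, ":", names(.y))))
  tab_keys <- paste0(model$parameter_table$reaction, ":",
                     model$parameter_table$parameter)
  for (k in setdiff(tab_keys, used)) flag("unreferenced_parameter", NA, k)

  if (length(diags) == 0) {
    tibble::tibble(check = character(), reaction = integer(), detail = character())
  } else {
    dplyr::bind_rows(diags)
  }
}
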