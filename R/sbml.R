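#' Write the network as SBML Level 3
#'
#' Serialises species (with initial amounts), global rate-constant
#' parameters, and all reactions with explicit mass-action kinetic laws
#' (MathML products of one rate constant and the reactant species).
#'
#' @param network A `grn_network`.
#' @param path Output file path.
#' @param initial Initial species counts (default [initial_state()]).
#' @return `path`, invisibly.
#' @export
write_sbml <- function(network, path, initial = initial_state(network)) {
  initial <- as_state(network, initial)
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1"
  )
  model <- xml2::xml_add_child(doc, "model", id = "nfkb_grn",
                               substanceUnits = "item",
                               timeUnits = "second", extentUnits = "item")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1",
                      constant = "true")
  sps <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(network$species))) {
    xml2::xml_add_child(
      sps, "species",
      id = network$species$name[i], compartment = "cell",
      initialAmount = format(initial[i], digits = 17),
      hasOnlySubstanceUnits = "true",
      boundaryCondition = "false", constant = "false")
  }
  pars <- xml2::xml_add_child(model, "listOfParameters")
  for (i in seq_len(nrow(network$reactions))) {
    xml2::xml_add_child(
      pars, "parameter",
      id = network$reactions$rate_name[i],
      value = format(network$reactions$rate[i], digits = 17),
      constant = "true")
  }
  rxs <- xml2::xml_add_child(model, "listOfReactions")
  for (j in seq_len(nrow(network$reactions))) {
    rx <- xml2::xml_add_child(rxs, "reaction",
                              id = network$reactions$name[j],
                              reversible = "false")
    re <- network$reactants[, j]
    pr <- network$stoich[, j] + re
    if (any(re > 0)) {
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      for (i in which(re > 0)) {
        xml2::xml_add_child(lre, "speciesReference",
                            species = network$species$name[i],
                            stoichiometry = as.character(re[i]),
                            constant = "true")
      }
    }
    if (any(pr > 0)) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (i in which(pr > 0)) {
        xml2::xml_add_child(lpr, "speciesReference",
                            species = network$species$name[i],
                            stoichiometry = as.character(pr[i]),
                            constant = "true")
      }
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    factors <- c(network$reactions$rate_name[j],
                 rep(network$species$name[which(re > 0)],
                     times = re[re > 0]))
    if (length(factors) == 1) {
      xml2::xml_add_child(math, "ci", factors)
    } else {
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "times")
      for (f in factors) xml2::xml_add_child(ap, "ci", f)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read an SBML Level 3 mass-action model
#'
#' Parses species, parameters and reactions and reconstructs the reaction
#' network. Every kinetic law must be a plain product of exactly one
#' parameter and the reaction's reactants (mass action); any other rate law
#' raises an error naming the offending reaction.
#'
#' @param path SBML file path.
#' @return List with `network` (a `grn_network`-shaped object), `initial`
#'   (named initial counts) and `params` (a `grn_params` when the model
#'   follows this package's naming convention, otherwise `NULL`).
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = xml2::xml_ns(doc)[[1]])
  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (length(sp_nodes) == 0) stop("no species found in SBML", call. = FALSE)
  sp_names <- xml2::xml_attr(sp_nodes, "id")
  initial <- stats::setNames(
    as.numeric(xml2::xml_attr(sp_nodes, "initialAmount")), sp_names)
  par_nodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter",
                                  ns)
  par_vals <- stats::setNames(
    as.numeric(xml2::xml_attr(par_nodes, "value")),
    xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  n_sp <- length(sp_names); n_rx <- length(rx_nodes)
  S <- matrix(0L, n_sp, n_rx, dimnames = list(sp_names, NULL))
  RM <- matrix(0L, n_sp, n_rx, dimnames = list(sp_names, NULL))
  rate_name <- character(n_rx); rate <- numeric(n_rx)
  rx_ids <- xml2::xml_attr(rx_nodes, "id")
  for (j in seq_len(n_rx)) {
    rx <- rx_nodes[[j]]
    for (sr in xml2::xml_find_all(rx, "./s:listOfReactants/s:speciesReference",
                                  ns)) {
      i <- match(xml2::xml_attr(sr, "species"), sp_names)
      m <- as.integer(as.numeric(xml2::xml_attr(sr, "stoichiometry")))
      RM[i, j] <- RM[i, j] + m
      S[i, j] <- S[i, j] - m
    }
    for (sr in xml2::xml_find_all(rx, "./s:listOfProducts/s:speciesReference",
                                  ns)) {
      i <- match(xml2::xml_attr(sr, "species"), sp_names)
      m <- as.integer(as.numeric(xml2::xml_attr(sr, "stoichiometry")))
      S[i, j] <- S[i, j] + m
    }
    # validate mass-action kinetic law: product of one parameter + reactants
    cis <- xml2::xml_text(
      xml2::xml_find_all(rx, "./s:kineticLaw//*[local-name() = 'ci']", ns))
    cis <- trimws(cis)
    non_ci <- xml2::xml_find_all(
      rx, paste0("./s:kineticLaw//*[local-name() != 'ci' and ",
                 "local-name() != 'apply' and local-name() != 'times' and ",
                 "local-name() != 'math']"), ns)
    pars_in_law <- cis[cis %in% names(par_vals)]
    sp_in_law <- cis[cis %in% sp_names]
    expected_sp <- rep(sp_names[RM[, j] > 0], times = RM[RM[, j] > 0, j])
    if (length(non_ci) > 0 || length(pars_in_law) != 1 ||
        length(pars_in_law) + length(sp_in_law) != length(cis) ||
        !identical(sort(sp_in_law), sort(expected_sp))) {
      stop("unsupported (non-mass-action) kinetic law in reaction ",
           rx_ids[j], call. = FALSE)
    }
    rate_name[j] <- pars_in_law
    rate[j] <- par_vals[[pars_in_law]]
  }

  kind <- dplyr::case_when(
    grepl("^N0_", sp_names) ~ "gene_free",
    grepl("^N1_", sp_names) ~ "gene_bound",
    grepl("^RNA_", sp_names) ~ "rna",
    grepl("^P_", sp_names) ~ "protein",
    sp_names == "NFKB" ~ "dimer",
    TRUE ~ "other"
  )
  gene <- ifelse(kind %in% c("gene_free", "gene_bound", "rna", "protein"),
                 sub("^(N0|N1|RNA|P)_", "", sp_names), NA_character_)
  params <- tryCatch(params_from_rates(rate_name, rate),
                     error = function(e) NULL)
  colnames(S) <- rx_ids
  colnames(RM) <- rx_ids
  net <- structure(
    list(species = tibble::tibble(name = sp_names, kind = kind, gene = gene),
         reactions = tibble::tibble(name = rx_ids, rate_name = rate_name,
                                    rate = rate),
         stoich = S, reactants = RM, conservation = list(),
         params = if (!is.null(params)) params else
           list(gene_copies = 2L, time_unit = "minute")),
    class = "grn_network"
  )
  net$conservation <- conservation_laws(net)
  list(network = net, initial = initial, params = params)
}

# Rebuild a grn_params from rate-constant names following the package's
# naming convention (kon_<gene>, koff_<gene>, ...).
params_from_rates <- function(rate_name, rate) {
  val <- function(nm) {
    i <- match(nm, rate_name)
    if (is.na(i)) NA_real_ else rate[i]
  }
  genes <- unique(sub("^kon_", "", grep("^kon_", rate_name, value = TRUE)))
  if (length(genes) == 0) stop("no per-gene rate constants found")
  g <- purrr::map_dfr(genes, function(gene) {
    tibble::tibble(
      gene = gene,
      kon = val(paste0("kon_", gene)),
      koff = val(paste0("koff_", gene)),
      ktx = val(paste0("ktx_", gene)),
      kbasal = val(paste0("kbasal_", gene)),
      kdR = val(paste0("kdR_", gene)),
      ktl = val(paste0("ktl_", gene)),
      kdP = val(paste0("kdP_", gene)),
      translated = !is.na(val(paste0("ktl_", gene)))
    )
  })
  grn_params(genes = g, ka = val("ka"), kd_dimer = val("kd_dimer"),
             kdP_dimer = if (is.na(val("kdP_NFKB"))) 0 else val("kdP_NFKB"))
}
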