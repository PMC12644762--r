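# Shared fixtures, memoised across test files (test_dir runs all files in
# one process). The default stationary-state report takes a few seconds to
# compute and is reused widely.
.fixtures <- new.env(parent = emptyenv())

default_network <- function() {
  if (is.null(.fixtures$net)) .fixtures$net <- build_network(grn_params())
  .fixtures$net
}

default_report <- function() {
  if (is.null(.fixtures$rep)) {
    .fixtures$rep <- find_stationary_states(default_network())
  }
  .fixtures$rep
}

# Core subnetwork (p50/p65/NFKB only): identical stationary structure and
# transition behaviour, roughly half the simulation cost of the full model.
core_network <- function() {
  if (is.null(.fixtures$core)) {
    g <- grn_params()$genes
    .fixtures$core <- build_network(grn_params(genes = g[g$gene %in%
                                                           c("p50", "p65"), ]))
  }
  .fixtures$core
}

core_report <- function() {
  if (is.null(.fixtures$core_rep)) {
    .fixtures$core_rep <- find_stationary_states(core_network())
  }
  .fixtures$core_rep
}

# Minimal hand-built mass-action network for oracle tests.
# reactions: list of list(re = <names>, pr = <names>, k = rate)
toy_network <- function(species, reactions) {
  n_sp <- length(species)
  n_rx <- length(reactions)
  S <- matrix(0L, n_sp, n_rx, dimnames = list(species, NULL))
  RM <- matrix(0L, n_sp, n_rx, dimnames = list(species, NULL))
  for (j in seq_len(n_rx)) {
    for (s in reactions[[j]]$re) {
      RM[s, j] <- RM[s, j] + 1L
      S[s, j] <- S[s, j] - 1L
    }
    for (s in reactions[[j]]$pr) S[s, j] <- S[s, j] + 1L
  }
  structure(
    list(
      species = tibble::tibble(name = species, kind = "other",
                               gene = NA_character_),
      reactions = tibble::tibble(
        name = paste0("r", seq_len(n_rx)),
        rate_name = paste0("k", seq_len(n_rx)),
        rate = vapply(reactions, `[[`, numeric(1), "k")),
      stoich = S, reactants = RM, conservation = list(),
      params = list(gene_copies = 2L, time_unit = "minute")
    ),
    class = "grn_network"
  )
}

birth_death <- function(k = 10, gamma = 0.1) {
  toy_network("X", list(list(re = character(0), pr = "X", k = k),
                        list(re = "X", pr = character(0), k = gamma)))
}

# Reference stationary states (molecule numbers) used across tests.
reference_states <- function() {
  tibble::tribble(
    ~state,     ~P_p50,    ~P_p65,  ~NFKB,    ~RNA_p50, ~RNA_p65,
    "HER2",     32491.37,  115566,  5893.33,  104.38,   134.99,
    "unstable", 76472,     260132,  31221.9,  245.66,   303.86,
    "TNBC",     150491,    535271,  126429,   483.44,   625.25
  )
}
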