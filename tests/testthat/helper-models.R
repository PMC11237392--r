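# Small models built in code, shared across tests.

# Linear chain: EX_A (uptake up to `uptake`) -> A -> B -> biomass drain.
# Unique optimum: every reaction carries flux `uptake`.
chain_model <- function(uptake = 10, gprs = list()) {
  mets <- data.frame(
    id = c("A", "B", "BM"), name = c("A", "B", "biomass"),
    compartment = "c", formula = NA_character_, charge = NA_real_,
    stringsAsFactors = FALSE
  )
  rxns <- data.frame(
    id = c("EX_A", "R1", "R2", "BIOMASS"),
    name = c("A exchange", "A to B", "B to biomass", "biomass drain"),
    lb = c(-uptake, 0, 0, 0), ub = 1000, sbo = NA_character_,
    stringsAsFactors = FALSE
  )
  st <- list(EX_A = c(A = -1), R1 = c(A = -1, B = 1),
             R2 = c(B = -1, BM = 1), BIOMASS = c(BM = -1))
  new_model("chain", mets, rxns, st, gpr = gprs, objective = "BIOMASS")
}

# Fully allele-redundant hybrid of a toy template: every template gene gets
# both parental alleles, so every GPR leaf becomes an or-pair.
redundant_hybrid <- function(seed = 1, n_internal = 6, n_paths = 2) {
  template <- make_template(n_internal, n_paths, fraction_redundant_genes = 0,
                            seed = seed)
  orth <- make_ortholog_tables(template, fraction_both = 1, fraction_Aonly = 0,
                               fraction_Bonly = 0, seed = seed)
  mapping <- build_mapping(template, orth)
  prune_model(rewrite_gprs(template, mapping))$model
}

# Ortholog record constructor for mapping tests.
orec <- function(hybrid, template, parent, identity = 95, evidence = "gene") {
  data.frame(hybrid_gene_id = hybrid, template_gene_id = template,
             parent = parent, percent_identity = identity,
             evidence = evidence, stringsAsFactors = FALSE)
}
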