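template_for_mapping <- function() {
  gprs <- list(R1 = parse_gpr("PGI1"), R2 = parse_gpr("TAL1 and SUB2"))
  m <- chain_model(gprs = gprs)
  m
}

test_that("mapping applies the strict identity threshold and strata rules", {
  m <- template_for_mapping()
  orth <- rbind(
    orec("H1", "PGI1", "parentA", identity = 95),
    orec("H2", "PGI1", "parentB", identity = 71),
    orec("H3", "TAL1", "parentB", identity = 65),   # below threshold
    orec("H4", "SUB2", "parentA", identity = 70)    # exactly at threshold
  )
  map <- build_mapping(m, orth, identity_threshold = 70)
  v <- venn_summary(map)
  expect_equal(unname(v["both"]), 1L)          # PGI1
  expect_equal(unname(v["parentA_only"]), 0L)
  expect_equal(unname(v["parentB_only"]), 0L)
  expect_equal(unname(v["unmapped"]), 2L)      # TAL1 at 65%, SUB2 at exactly 70%
  expect_setequal(map$unmapped, c("TAL1", "SUB2"))

  # duplicate 1:1 claim within a stratum errors with the offender named
  dup <- rbind(orec("H1", "PGI1", "parentA"), orec("H9", "PGI1", "parentA"))
  expect_error(build_mapping(m, dup), "one-to-one.*PGI1")
  expect_error(build_mapping(m, orec("H1", "ghost", "parentA")), "not in model")
})

test_that("protein evidence rescues unmapped genes and wins conflicts", {
  m <- template_for_mapping()
  orth <- rbind(
    # gene level says H1 is PGI1; protein level says H1 is TAL1 (isoform mixup)
    orec("H1", "PGI1", "parentA", evidence = "gene"),
    orec("H1", "TAL1", "parentA", evidence = "protein"),
    # pure protein-level rescue of SUB2
    orec("H2", "SUB2", "parentB", evidence = "protein")
  )
  map <- build_mapping(m, orth)
  expect_equal(nrow(map$conflicts), 1)
  expect_equal(map$conflicts$hybrid_gene_id, "H1")
  # protein call wins: H1 maps TAL1, PGI1 is left unmapped
  expect_true("PGI1" %in% map$unmapped)
  e <- map$entries
  expect_equal(e$hybrid_gene_id[e$template_gene_id == "TAL1"], "H1")
  expect_equal(e$evidence[e$template_gene_id == "SUB2"], "protein")
})

test_that("venn categories are disjoint and sum to the template gene count", {
  m <- template_for_mapping()
  v <- venn_summary(build_mapping(m, orec("H1", "PGI1", "parentA")[0, ]))
  expect_equal(unname(v), c(0L, 0L, 0L, nrow(m$genes)))
  for (seed in 1:8) {
    tm <- make_template(sample(4:8, 1), sample(1:2, 1), runif(1), seed = seed)
    orth <- make_ortholog_tables(tm, runif(1, 0, 0.5), runif(1, 0, 0.3),
                                 runif(1, 0, 0.2), seed = seed)
    vv <- venn_summary(build_mapping(tm, orth))
    expect_equal(sum(vv), nrow(tm$genes))
  }
})

test_that("GPR rewriting installs allele redundancy and marks lost branches", {
  m <- template_for_mapping()
  orth <- rbind(
    orec("HA", "PGI1", "parentA"), orec("HB", "PGI1", "parentB"),
    orec("HC", "TAL1", "parentB")
    # SUB2 unmapped: the TAL1-and-SUB2 complex loses a subunit
  )
  map <- build_mapping(m, orth)
  hy <- rewrite_gprs(m, map)

  # both parents -> or of suffixed alleles
  expect_equal(format_gpr(hy$gpr$R1), "PGI1_Scer or PGI1_Seub")
  # missing complex subunit -> whole complex unsatisfiable
  expect_equal(hy$gpr$R2$kind, "false")
  # stoichiometry and bounds untouched
  expect_identical(hy$stoichiometry, m$stoichiometry)
  expect_identical(hy$reactions$lb, m$reactions$lb)
  expect_identical(hy$reactions$ub, m$reactions$ub)
  # allele partnership is symmetric, single-parent allele has none
  g <- hy$genes
  expect_equal(g$allele_partner[g$id == "PGI1_Scer"], "PGI1_Seub")
  expect_equal(g$allele_partner[g$id == "PGI1_Seub"], "PGI1_Scer")
  expect_true(is.na(g$allele_partner[g$id == "TAL1_Seub"]))

  # or-context drops only the lost operand
  m2 <- chain_model(gprs = list(R1 = parse_gpr("PGI1 or SUB2")))
  hy2 <- rewrite_gprs(m2, build_mapping(m2, rbind(
    orec("HA", "PGI1", "parentA"), orec("HB", "PGI1", "parentB"))))
  expect_equal(format_gpr(hy2$gpr$R1), "PGI1_Scer or PGI1_Seub")

  # suffix collision is an error
  mm <- chain_model(gprs = list(R1 = parse_gpr("X1"), R2 = parse_gpr("X2")))
  mm$genes$name <- c("SAME", "SAME")
  expect_error(rewrite_gprs(mm, build_mapping(mm, rbind(
    orec("H1", "X1", "parentA"), orec("H2", "X2", "parentA")))),
    "collision")
})

test_that("pruning removes unsupported reactions then orphan genes, with reasons", {
  m <- template_for_mapping()
  orth <- rbind(orec("HA", "PGI1", "parentA"), orec("HB", "PGI1", "parentB"),
                orec("HC", "TAL1", "parentB"))
  hy <- rewrite_gprs(m, build_mapping(m, orth))
  pr <- prune_model(hy)
  # R2 lost its complex: removed; TAL1_Seub orphaned by that removal: removed
  expect_true("R2" %in% pr$report$entity_id[pr$report$kind == "reaction"])
  expect_true("TAL1_Seub" %in% pr$report$entity_id[pr$report$kind == "gene"])
  expect_false("R2" %in% pr$model$reactions$id)
  expect_false("TAL1_Seub" %in% pr$model$genes$id)
  expect_true(all(c("PGI1_Scer", "PGI1_Seub") %in% pr$model$genes$id))
  expect_match(pr$report$reason[pr$report$entity_id == "TAL1_Seub"],
               "not associated")
  # GPR-less reactions are never pruned
  expect_true(all(c("EX_A", "BIOMASS") %in% pr$model$reactions$id))

  # prune removes a reaction iff its GPR is unsatisfiable with all genes present
  for (rid in names(hy$gpr)) {
    expect_equal(!(rid %in% pr$model$reactions$id),
                 !evaluate_gpr(hy$gpr[[rid]], absent = character()))
  }
})

test_that("fully redundant hybrids tolerate any single allele deletion", {
  hy <- redundant_hybrid(seed = 4)
  for (g in hy$genes$id) {
    expect_true(all(vapply(hy$gpr, evaluate_gpr, logical(1), absent = g)))
  }
  es <- essentiality_scan(hy, mode = "gene")
  expect_equal(sum(es$essential), 0L)
})

test_that("curation adds balanced reactions, is idempotent and guards ids", {
  mets <- data.frame(
    id = c("mel", "h2o", "glc", "gal", "BM"),
    name = c("melibiose", "water", "glucose", "galactose", "biomass"),
    compartment = "c",
    formula = c("C12H22O11", "H2O", "C6H12O6", "C6H12O6", NA),
    charge = c(0, 0, 0, 0, NA), stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("EX_mel", "BIOMASS"), name = c("mel exchange", "drain"),
                     lb = c(-10, 0), ub = 1000, sbo = NA, stringsAsFactors = FALSE)
  m <- new_model("cur", mets, rxns,
                 list(EX_mel = c(mel = -1), BIOMASS = c(BM = -1)),
                 objective = "BIOMASS")

  melibiase <- list(
    id = "act1", kind = "add_reaction", target = "MELIBIASE",
    note = "alpha-galactosidase inherited from the cold-tolerant parent",
    payload = list(
      equation = "mel + h2o -> glc + gal",
      gpr = "MEL1_Seub",
      genes = list(list(id = "MEL1_Seub", origin = "parentB"))))
  m2 <- apply_curation(m, list(melibiase))
  expect_equal(nrow(m2$reactions), nrow(m$reactions) + 1)
  expect_equal(nrow(m2$genes), nrow(m$genes) + 1)
  expect_equal(check_balance(m2, "MELIBIASE")$status, "balanced")

  # idempotence: same list twice equals once
  m3 <- apply_curation(m2, list(melibiase))
  expect_identical(m3$reactions, m2$reactions)
  expect_identical(m3$genes, m2$genes)

  # re-adding an existing id without the amend flag errors
  clash <- melibiase; clash$id <- "act2"
  expect_error(apply_curation(m2, list(clash)), "already exists")

  # remove then re-add: present exactly once
  m4 <- apply_curation(m2, list(
    list(id = "act3", kind = "remove_reaction", target = "MELIBIASE"),
    list(id = "act4", kind = "add_reaction", target = "MELIBIASE",
         payload = melibiase$payload)))
  expect_equal(sum(m4$reactions$id == "MELIBIASE"), 1L)

  # imbalanced addition rejected unless waived
  bad <- list(id = "act5", kind = "add_reaction", target = "BADR",
              payload = list(equation = "glc -> gal + h2o"))
  expect_error(apply_curation(m, list(bad)), "imbalanced")
  waived <- bad; waived$payload$balance_waiver <- TRUE
  expect_true("BADR" %in% apply_curation(m, list(waived))$reactions$id)
})

test_that("curation lists round-trip through YAML", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "- id: a1",
    "  kind: add_gene",
    "  target: HXT10_Seub",
    "  payload:",
    "    origin: parentB",
    "- id: a2",
    "  kind: remove_gene",
    "  target: HXT10_Seub"
  ), f)
  acts <- read_curation_actions(f)
  expect_length(acts, 2)
  m <- chain_model()
  m2 <- apply_curation(m, acts[1])
  expect_true("HXT10_Seub" %in% m2$genes$id)
  m3 <- apply_curation(m2, acts)
  expect_false("HXT10_Seub" %in% m3$genes$id)
})
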