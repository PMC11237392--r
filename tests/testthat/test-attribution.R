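origin2 <- function(...) {
  v <- c(...)
  stats::setNames(v, names(v))
}

test_that("parental shares: or-pairs weight by TPM, single parents are 0/100", {
  org <- c(G_Scer = "parentA", G_Seub = "parentB")
  sh <- attribute_reaction(parse_gpr("G_Scer or G_Seub"),
                           c(G_Scer = 20, G_Seub = 80), org)
  expect_equal(sh$prop_parentA, 0.20)
  expect_equal(sh$prop_parentB, 0.80)
  expect_equal(sh$status, "conclusive")

  sh2 <- attribute_reaction(parse_gpr("FBP1_Seub"), c(FBP1_Seub = 50),
                            c(FBP1_Seub = "parentB"))
  expect_equal(sh2$prop_parentA, 0)
  expect_equal(sh2$prop_parentB, 1)
})

test_that("complexes average their subunit groups without weighting", {
  org <- c(a_Scer = "parentA", a_Seub = "parentB",
           b_Scer = "parentA", b_Seub = "parentB")
  tpm <- c(a_Scer = 10, a_Seub = 10, b_Scer = 30, b_Seub = 10)
  sh <- attribute_reaction(
    parse_gpr("(a_Scer or a_Seub) and (b_Scer or b_Seub)"), tpm, org)
  # group shares 0.5 and 0.75, unweighted mean
  expect_equal(sh$prop_parentA, mean(c(0.5, 0.75)))
  expect_equal(sh$prop_parentB, 1 - mean(c(0.5, 0.75)))
})

test_that("shares sum to one, swap under relabeling, and ignore uniform scaling", {
  set.seed(77)
  for (i in 1:25) {
    tree <- random_gpr(max_depth = 4, genes = c(paste0("x", 1:4, "_Scer"),
                                                paste0("x", 1:4, "_Seub")))
    genes <- gpr_genes(tree)
    org <- stats::setNames(ifelse(endsWith(genes, "_Scer"), "parentA", "parentB"),
                           genes)
    tpm <- stats::setNames(runif(length(genes), 20, 200), genes)
    sh <- attribute_reaction(tree, tpm, org)
    expect_equal(sh$status, "conclusive")
    expect_equal(sh$prop_parentA + sh$prop_parentB, 1, tolerance = 1e-9)

    flipped <- stats::setNames(
      ifelse(org == "parentA", "parentB", "parentA"), names(org))
    sh_f <- attribute_reaction(tree, tpm, flipped)
    expect_equal(sh_f$prop_parentA, sh$prop_parentB, tolerance = 1e-9)

    sh_s <- attribute_reaction(tree, tpm * 7.3, org)
    expect_equal(sh_s$prop_parentA, sh$prop_parentA, tolerance = 1e-9)
  }
})

test_that("weak or absent expression yields an inconclusive call", {
  org <- c(Z_Scer = "parentA", Z_Seub = "parentB")
  sh <- attribute_reaction(parse_gpr("Z_Scer or Z_Seub"),
                           c(Z_Scer = 0, Z_Seub = 0), org)
  expect_equal(sh$status, "inconclusive")
  expect_true(is.na(sh$prop_parentA))
  # at the threshold exactly: still inconclusive (strictly-above rule)
  sh2 <- attribute_reaction(parse_gpr("Z_Scer or Z_Seub"),
                            c(Z_Scer = 5, Z_Seub = 5), org, threshold = 10)
  expect_equal(sh2$status, "inconclusive")
  # a leaf with no origin mapping is a hard error
  expect_error(attribute_reaction(parse_gpr("Q1"), c(Q1 = 50), org),
               "no parental origin")
})

test_that("model-wide attribution covers reactions x conditions deterministically", {
  hy <- redundant_hybrid(seed = 6)
  profiles <- make_expression(hy, parentB_bias = 0.7, seed = 6)
  att <- attribute_model(hy, profiles)
  expect_equal(nrow(att), length(hy$gpr) * length(profiles))
  expect_setequal(unique(att$condition), names(profiles))
  att2 <- attribute_model(hy, profiles)
  expect_identical(att, att2)

  # a silent condition drives every reaction inconclusive
  silent <- list(quiet = stats::setNames(rep(0, nrow(hy$genes)), hy$genes$id))
  att3 <- attribute_model(hy, silent)
  expect_true(all(att3$status == "inconclusive"))

  # unresolvable origin (template gene, no parent suffix) is a hard error
  bad <- chain_model(gprs = list(R1 = parse_gpr("anon1 or anon2")))
  expect_error(
    attribute_model(bad, list(c1 = c(anon1 = 50, anon2 = 50))),
    "cannot resolve parental origin")
})

test_that("engineered parental bias is recovered from synthetic expression", {
  recovered <- numeric()
  for (seed in 1:20) {
    hy <- redundant_hybrid(seed = seed)
    profiles <- make_expression(hy, parentB_bias = 0.9, noise_cv = 0, seed = seed)
    att <- attribute_model(hy, profiles[1])
    ok <- att[att$status == "conclusive", ]
    recovered <- c(recovered, ok$prop_parentB)
  }
  expect_true(all(abs(recovered - 0.9) < 0.02))
})

test_that("temperature shifts are detected from ordered share series", {
  mk <- function(props) data.frame(
    prop_parentA = props, status = "conclusive", stringsAsFactors = FALSE)
  # ribokinase-like: 0.50, 0.50, 0.45 stays stable at delta 0.10
  expect_equal(detect_shift(mk(c(0.50, 0.50, 0.45))), "stable")
  # phosphopentomutase-like: 0.50 -> 0.40 -> 0.30 shifts
  expect_equal(detect_shift(mk(c(0.50, 0.40, 0.30))), "shifted")
  expect_equal(detect_shift(mk(c(0.6, 0.6, 0.6)), delta = 0.001), "stable")
  # fewer than two conclusive conditions: indeterminate
  one <- mk(c(0.5, 0.4)); one$status[2] <- "inconclusive"
  expect_equal(detect_shift(one), "indeterminate")
})

test_that("report rounding snaps conclusive shares to 5% steps", {
  sh <- data.frame(reaction_id = c("r1", "r2"), condition = "22C",
                   prop_parentA = c(0.433, NA), prop_parentB = c(0.567, NA),
                   status = c("conclusive", "inconclusive"))
  rep <- attribution_report(sh)
  expect_equal(rep$prop_parentA[1], 0.45)
  expect_equal(rep$prop_parentB[1], 0.55)
  expect_true(is.na(rep$prop_parentA[2]))
})
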