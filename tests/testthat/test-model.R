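test_that("model validation rejects inconsistent structure", {
  m <- chain_model()
  expect_s3_class(m, "gem_model")

  bad <- m; bad$reactions$lb[2] <- 2000
  expect_error(validate_model(bad), "lb > ub")

  bad <- m; bad$stoichiometry$R1 <- c(A = -1, Z = 1)
  expect_error(validate_model(bad), "undeclared metabolite")

  bad <- m; bad$metabolites <- rbind(bad$metabolites, bad$metabolites[1, ])
  expect_error(validate_model(bad), "duplicate metabolite")

  bad <- m; bad$objective <- "nope"
  expect_error(validate_model(bad), "objective")

  expect_error(
    new_model("x", m$metabolites, m$reactions, m$stoichiometry,
              gpr = list(R1 = parse_gpr("ghost")),
              genes = data.frame(id = "g1", name = "g1", origin = "template"),
              objective = "BIOMASS"),
    "undeclared gene"
  )

  # asymmetric allele partnership
  genes <- data.frame(id = c("a", "b"), name = c("a", "b"),
                      origin = c("parentA", "parentB"),
                      allele_partner = c("b", NA))
  expect_error(
    new_model("x", m$metabolites, m$reactions, m$stoichiometry,
              genes = genes, objective = "BIOMASS"),
    "not symmetric"
  )
})

test_that("exchange reactions are single-metabolite boundary reactions", {
  m <- chain_model()
  ex <- is_exchange(m)
  expect_true(ex[["EX_A"]])
  expect_true(ex[["BIOMASS"]])   # drain on one metabolite
  expect_false(ex[["R1"]])
  expect_equal(sum(vapply(m$reactions$id[ex], function(rid)
    sum(m$stoichiometry[[rid]] != 0), integer(1)) == 1L), sum(ex))
})

test_that("elemental balance: melibiose hydrolysis balances, C1->C2 does not", {
  mets <- data.frame(
    id = c("melibiose", "h2o", "glucose", "galactose", "a1", "a2"),
    name = c("melibiose", "water", "glucose", "galactose", "a1", "a2"),
    compartment = "c",
    formula = c("C12H22O11", "H2O", "C6H12O6", "C6H12O6", "C1", "C2"),
    charge = 0, stringsAsFactors = FALSE
  )
  rxns <- data.frame(
    id = c("MELIBIASE", "BADC", "EX_mel", "NOFORM"),
    name = c("alpha-galactosidase", "carbon typo", "melibiose exchange", "x"),
    lb = 0, ub = 1000, sbo = NA_character_, stringsAsFactors = FALSE
  )
  st <- list(
    MELIBIASE = c(melibiose = -1, h2o = -1, glucose = 1, galactose = 1),
    BADC = c(a1 = -1, a2 = 1),
    EX_mel = c(melibiose = -1),
    NOFORM = c(glucose = -1, a1 = 1)
  )
  m <- new_model("bal", mets, rxns, st, objective = "MELIBIASE")

  expect_equal(check_balance(m, "MELIBIASE")$status, "balanced")
  bad <- check_balance(m, "BADC")
  expect_equal(bad$status, "imbalanced")
  expect_equal(unname(bad$elements["C"]), 1)
  expect_equal(check_balance(m, "EX_mel")$status, "exempt")

  m$metabolites$formula[m$metabolites$id == "a1"] <- NA
  expect_equal(check_balance(m, "NOFORM")$status, "indeterminate")
})

test_that("balance report equals a direct stoichiometric dot product", {
  set.seed(13)
  els <- c("C", "H", "O", "N")
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    counts <- matrix(sample(0:6, k * length(els), replace = TRUE), k, length(els))
    formulas <- apply(counts, 1, function(row)
      paste0(els[row > 0], row[row > 0], collapse = ""))
    formulas[formulas == ""] <- "C1"
    counts[rowSums(counts) == 0, 1] <- 1
    mets <- data.frame(id = paste0("m", 1:k), name = paste0("m", 1:k),
                       compartment = "c", formula = formulas, charge = 0)
    coef <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
    if (all(coef > 0)) coef[1] <- -coef[1]
    if (all(coef < 0)) coef[k] <- -coef[k]
    rxns <- data.frame(id = "R", name = "R", lb = 0, ub = 1, sbo = NA)
    m <- new_model("p", mets, rxns, list(R = stats::setNames(coef, mets$id)),
                   objective = "R")
    rep_bal <- check_balance(m, "R")
    expected <- as.vector(coef %*% counts)
    names(expected) <- els
    expected <- expected[abs(expected) > 0]
    expect_equal(rep_bal$elements[order(names(rep_bal$elements))],
                 expected[order(names(expected))], tolerance = 1e-12)
  }
})

test_that("applying a medium sets listed bounds and closes unlisted uptake", {
  m <- chain_model(uptake = 10)
  med <- data.frame(exchange_id = "EX_A", lb = -20, ub = 1000)
  m2 <- apply_medium(m, med)
  expect_equal(m2$reactions$lb[m2$reactions$id == "EX_A"], -20)
  expect_equal(run_fba(m2)$objective, 20, tolerance = 1e-9)

  # empty medium: all uptakes closed, optimum 0
  m0 <- apply_medium(m, list())
  expect_equal(m0$reactions$lb[m0$reactions$id == "EX_A"], 0)
  expect_equal(run_fba(m0)$objective, 0, tolerance = 1e-9)

  # secretion stays open for unlisted exchanges
  expect_equal(m0$reactions$ub[m0$reactions$id == "EX_A"], 1000)

  expect_error(apply_medium(m, data.frame(exchange_id = "R1", lb = -5, ub = 5)),
               "non-exchange.*R1")
  expect_error(apply_medium(m, data.frame(exchange_id = "ghost", lb = 0, ub = 0)),
               "unknown")
})

test_that("medium files round through TSV and JSON", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("exchange_id\tlb\tub", "EX_A\t-20\t1000"), tsv)
  med <- read_medium(tsv)
  expect_equal(med$lb, -20)

  js <- tempfile(fileext = ".json")
  jsonlite::write_json(list(EX_A = c(-20, 1000)), js)
  med2 <- read_medium(js)
  expect_equal(med2$exchange_id, "EX_A")
  expect_equal(med2$ub, 1000)
})
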