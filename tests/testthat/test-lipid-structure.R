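test_that("the parser handles all three nomenclature dialects", {
  p <- parseLipidName("PC aa C30:0")
  expect_identical(p$class, "PC")
  expect_equal(p$carbons, 30)
  expect_equal(p$doubleBonds, 0)

  p <- parseLipidName("SM (OH) C22:2")
  expect_identical(p$class, "SM")
  expect_equal(c(p$carbons, p$doubleBonds), c(22, 2))

  p <- parseLipidName("FA 16:0")
  expect_identical(p$class, "FFA")
  expect_equal(p$carbons, 16)

  p <- parseLipidName("TAG52:2-FA18:1")
  expect_identical(p$class, "TAG")
  expect_equal(p$faComponents[[1]], c(18, 1))

  expect_identical(parseLipidName("lysoPC a C18:2")$class, "LPC")
  expect_error(parseLipidName("not a lipid"), "dialects tried")
  expect_error(parseLipidName("PC aa C4:7"), "infeasible")
})

test_that("format(parse(name)) round-trips canonical names", {
  names <- c("PC aa C30:0", "PC ae C38:3", "SM (OH) C22:2", "SM C24:1",
             "lysoPC a C18:2", "FA 16:0", "FA 22:6", "TAG52:2-FA18:1",
             "DAG36:2-FA18:1", "CE16:0", "PE38:4", "LCER24:1")
  for (nm in names)
    expect_identical(formatLipidName(parseLipidName(nm)), nm)
  # every generated panel species parses and round-trips
  panel <- lipidomicsPanel(scale = 0.05)
  ann <- parseLipidName(panel$analyte)
  expect_identical(ann$class, panel$class)
})

test_that("chain-length bins follow the standard convention", {
  b <- chainLengthBin(c(10, 13, 14, 20, 22, 26))
  expect_identical(as.character(b),
                   c("medium", "medium", "long", "long", "very-long",
                     "very-long"))
})

test_that("structure grid maps species and conserves counts", {
  de <- data.frame(
    analyte = c("TAG52:3-FA18:1", "TAG52:3-FA16:0", "TAG54:2-FA18:1",
                "DAG36:2-FA18:1"),
    log2FC = c(-0.4, -0.3, 0.1, -0.2),
    FDR = c(0.01, 0.2, 0.8, 0.03), stringsAsFactors = FALSE)
  ann <- parseLipidName(de$analyte)
  grid <- aggregateByStructure(de, ann)
  cell <- grid[grid$class == "TAG" & grid$carbons == 52 &
                 grid$doubleBonds == 3, ]
  expect_equal(cell$n, 2)
  expect_identical(cell$flag, "down")
  expect_true(cell$significant)
  # conservation: cell memberships sum to the annotated species count
  expect_equal(sum(grid$n), nrow(de))

  empty <- aggregateByStructure(de[0, ], ann)
  expect_equal(nrow(empty), 0)

  expect_warning(
    g2 <- aggregateByStructure(
      rbind(de, data.frame(analyte = "mystery", log2FC = 1, FDR = 0.5)),
      ann),
    "lack annotations")
  expect_identical(attr(g2, "unannotated"), "mystery")
})

test_that("even-carbon planted effects enrich even-carbon grid cells", {
  set.seed(50)
  carbons <- rep(40:59, each = 2)
  bonds <- rep(c(1, 3), 20)
  species <- paste0("TAG", carbons, ":", bonds, "-FA18:1")
  even <- carbons %% 2 == 0
  de <- data.frame(analyte = species,
                   log2FC = ifelse(even, -0.5, 0) + rnorm(40, 0, 0.05),
                   FDR = ifelse(even, 0.01, 0.6),
                   stringsAsFactors = FALSE)
  grid <- aggregateByStructure(de, parseLipidName(species))
  sigShare <- tapply(grid$significant, grid$carbons %% 2 == 0, mean)
  expect_gt(sigShare[["TRUE"]], sigShare[["FALSE"]])
})

test_that("fatty-acid composition matrix flags directions and gaps", {
  de <- data.frame(
    analyte = c("TAG52:2-FA18:1", "TAG54:2-FA18:1", "DAG36:2-FA16:0"),
    log2FC = c(0.5, 0.4, -0.3),
    FDR = c(0.01, 0.02, 0.2), stringsAsFactors = FALSE)
  fam <- fattyAcidCompositionMatrix(de, parseLipidName(de$analyte))
  expect_identical(fam$flag["TAG", "FA 18:1"], "significant-up")
  expect_identical(fam$flag["DAG", "FA 16:0"], "not-significant")
  expect_identical(fam$flag["CE", "FA 18:1"], "not-detected")
  expect_true(is.na(fam$log2FC["CE", "FA 18:1"]))
})

test_that("planted chain-length split is recovered in the FA matrix", {
  set.seed(51)
  fa <- c(16, 18, 20, 22, 24, 26)
  species <- unlist(lapply(fa, function(f)
    paste0("TAG", f + 30, ":2-FA", f, ":0")))
  ann <- parseLipidName(species)
  long <- ann$faCarbons <= 20
  de <- data.frame(analyte = species,
                   log2FC = ifelse(long, -0.6, 0.6),
                   FDR = 0.01, stringsAsFactors = FALSE)
  fam <- fattyAcidCompositionMatrix(de, ann)
  flags <- fam$flag["TAG", paste0("FA ", fa, ":0")]
  expect_true(all(flags[fa <= 20] == "significant-down"))
  expect_true(all(flags[fa >= 22] == "significant-up"))
})
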