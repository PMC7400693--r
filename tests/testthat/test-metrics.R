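test_that("unique-clonotype quantification, raw and scaled", {
  q <- quantifyUnique(c(A = 5, B = 3, C = 2), scaled = TRUE)
  expect_equal(q$unique, 3)
  expect_equal(q$value, 30)            # 3/10 * 100
  singletons <- stats::setNames(rep(1, 17), paste0("k", 1:17))
  expect_equal(quantifyUnique(singletons, scaled = TRUE)$value, 100)
  q2 <- quantifyUnique(c(big = 50), scaled = TRUE)
  expect_equal(q2$unique, 1)
  expect_equal(q2$value, 2)            # 1/50 * 100
  expect_equal(quantifyUnique(c(A = 5, B = 3))$value, 2)
})

test_that("scaled quantification lies in (0,100], 100 iff all singletons", {
  set.seed(101)
  for (i in 1:50) {
    cv <- randomCountVector()
    v <- quantifyUnique(cv, scaled = TRUE)$value
    expect_gt(v, 0)
    expect_lte(v, 100)
    expect_equal(v == 100, all(cv == 1))
  }
})

test_that("abundance tables sort by count with lexicographic tie-break", {
  tab <- abundanceTable(c(B = 2, A = 2))
  expect_equal(tab$clonotype, c("A", "B"))
  expect_equal(tab$proportion, c(0.5, 0.5))
  tab2 <- abundanceTable(c(C = 20, A = 50, B = 30))
  expect_equal(tab2$clonotype[1], "A")
  expect_equal(tab2[1, c("count", "proportion")],
               data.frame(count = 50, proportion = 0.5))
  expect_equal(nrow(abundanceTable(numeric(0))), 0)
  set.seed(7)
  for (i in 1:25) {
    p <- abundanceTable(randomCountVector())$proportion
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(diff(p) <= 0) || length(p) == 1)
  }
})

test_that("combined CDR3 lengths count sequence only, never the NA literal", {
  tab <- contigTable(
    contigRow("c1", "TRA", cdr3_aa = "CAVNGGSQGNLIF",
              cdr3_nt = "TGTGCTGTGAAT"),
    contigRow("c1", "TRB", cdr3_aa = "CSAEREDTDTQYF",
              cdr3_nt = "TGCAGTGCTGAA"),
    contigRow("c2", "TRB", cdr3_aa = "CATSATLRVVAEKLFF",
              cdr3_nt = "TGTGCCACCAGT"))
  rep <- combineReceptors(list(tab), samples = "s")
  len <- cdr3Lengths(rep, "aa")
  expect_equal(len$length[len$sequence == "CAVNGGSQGNLIF_CSAEREDTDTQYF"],
               26)  # 13 + 13
  expect_equal(len$length[len$sequence == "NA_CATSATLRVVAEKLFF"], 16)
  per_chain <- cdr3Lengths(rep, "aa", perChain = TRUE)
  expect_equal(nrow(per_chain), 3)
  expect_equal(sort(per_chain$length), c(13, 13, 16))
})

test_that("a single/dual-chain mixture makes combined lengths bimodal", {
  mix <- simulateRepertoire(nCells = 1200, dualAlphaRate = 0.1,
                            chainDropoutRate = 0.25, seed = 2,
                            sampleName = "m")
  lens <- cdr3Lengths(combineReceptors(list(mix$contigs), samples = "m"),
                      "aa")$length
  expect_equal(nModes(lens), 2L)
})

test_that("clonal homeostasis bins proportions with closed right edges", {
  occ <- clonalHomeostasis(c(A = 60, B = 30, C = 10))
  expect_equal(occ[["Large"]], 0.1)          # p = 0.1 in (0.01, 0.1]
  expect_equal(occ[["Hyperexpanded"]], 0.9)  # 0.6 + 0.3
  expect_equal(sum(occ), 1)

  single <- clonalHomeostasis(c(only = 42))
  expect_equal(single[["Hyperexpanded"]], 1)
  expect_equal(sum(single[names(single) != "Hyperexpanded"]), 0)

  # p = 1e-4 exactly lands in the closed right edge of the first bin
  many <- clonalHomeostasis(stats::setNames(rep(1, 10000),
                                            paste0("s", 1:10000)))
  expect_equal(many[["Rare"]], 1)
})

test_that("homeostasis conserves clonal space over random repertoires", {
  set.seed(11)
  for (i in 1:200) {
    occ <- clonalHomeostasis(randomCountVector())
    expect_equal(sum(occ), 1, tolerance = 1e-12)
    expect_true(all(occ >= 0))
  }
})

test_that("clonal proportion sums rank-range counts to the total", {
  v <- c(A = 50, B = 20, C = 10, D = 10, E = 10)
  occ <- clonalProportion(v, split = c(10, 100))
  expect_equal(occ[["[1:10]"]], 100)   # all five ranks <= 10
  expect_equal(occ[["[11:100]"]], 0)

  singletons <- stats::setNames(rep(1, 150), sprintf("c%03d", 1:150))
  occ2 <- clonalProportion(singletons, split = c(10, 100, 1000))
  expect_equal(unname(occ2), c(10, 90, 50))

  empty <- clonalProportion(numeric(0), split = c(10, 100))
  expect_equal(unname(empty), c(0, 0))

  set.seed(12)
  for (i in 1:200) {
    cv <- randomCountVector()
    expect_equal(sum(clonalProportion(cv)), sum(cv))
  }
})

test_that("RepertoireSet methods return tidy per-sample tables", {
  sims <- lapply(1:2, function(i) {
    simulateRepertoire(nCells = 120, seed = i, sampleName = paste0("s", i))
  })
  rep <- combineReceptors(lapply(sims, `[[`, "contigs"),
                          samples = c("s1", "s2"))
  q <- clonalQuant(rep, scaled = TRUE)
  expect_equal(q$sample, c("s1", "s2"))
  expect_true(all(q$value > 0 & q$value <= 100))
  hom <- clonalHomeostasis(rep)
  expect_equal(as.numeric(tapply(hom$occupancy, hom$sample, sum)),
               c(1, 1), tolerance = 1e-12)
  prop <- clonalProportion(rep)
  ab <- clonalAbundance(rep)
  expect_equal(sum(prop$count), sum(ab$count))
  f <- tempfile()
  exportTable(q, f)
  expect_identical(utils::read.delim(f, stringsAsFactors = FALSE)$sample,
                   q$sample)
})

test_that("bin constructors validate their edges", {
  expect_error(homeostasisBins(c(a = 0.5, b = 0.2)))
  expect_error(homeostasisBins(c(a = 0.5, b = 0.9)))     # must end at 1
  expect_error(clonalProportion(c(A = 3), split = c(10, 5)))
  expect_error(frequencyBins(c(x = 5, y = 2)))
})
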