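test_that("paired and single-chain clonotype strings are constructed correctly", {
  tab <- contigTable(
    contigRow("cell1", "TRA", cdr3_nt = "TGTGCTGTGAAT",
              cdr3_aa = "CAVNGGSQGNLIF", v = "TRAV1", j = "TRAJ1",
              c_gene = "TRAC"),
    contigRow("cell1", "TRB", cdr3_nt = "TGCAGTGCTGAA",
              cdr3_aa = "CSAEREDTDTQYF", v = "TRBV2", d = "TRBD1",
              j = "TRBJ2", c_gene = "TRBC1"),
    contigRow("cell2", "TRB", cdr3_nt = "TGTGCCACCAGT",
              cdr3_aa = "CATSATLRVVAEKLFF", v = "TRBV7", d = "TRBD2",
              j = "TRBJ1", c_gene = "TRBC2"))
  rep <- combineReceptors(list(tab), samples = "s1")
  calls <- rep[["s1"]]
  expect_equal(calls$CTaa[calls$barcode == "s1_cell1"],
               "CAVNGGSQGNLIF_CSAEREDTDTQYF")
  # missing locus 1 is the literal "NA", not an empty string
  expect_equal(calls$CTaa[calls$barcode == "s1_cell2"],
               "NA_CATSATLRVVAEKLFF")
  expect_equal(calls$CTgene[calls$barcode == "s1_cell1"],
               "TRAV1.TRAJ1.TRAC_TRBV2.TRBD1.TRBJ2.TRBC1")
  expect_equal(calls$CTnt[calls$barcode == "s1_cell2"],
               "NA_TGTGCCACCAGT")
  expect_equal(calls$CTstrict[calls$barcode == "s1_cell2"],
               "NA_TRBV7.TRBD2.TRBJ1.TRBC2:TGTGCCACCAGT")
})

test_that("more than two same-locus contigs keep the top two by UMI", {
  tab <- contigTable(
    contigRow("c1", "TRA", cdr3_nt = "TGTAAA", cdr3_aa = "CKA", umis = 5),
    contigRow("c1", "TRA", cdr3_nt = "TGTCCC", cdr3_aa = "CPA", umis = 3),
    contigRow("c1", "TRA", cdr3_nt = "TGTGGG", cdr3_aa = "CGA", umis = 1),
    contigRow("c1", "TRB", cdr3_nt = "TGTTTT", cdr3_aa = "CFA", umis = 9))
  rep <- combineReceptors(list(tab), samples = "s")
  calls <- rep[["s"]]
  # umis=1 contig excluded; survivors joined ";" in lexicographic nt order
  expect_equal(calls$cdr3_nt1, "TGTAAA;TGTCCC")
  expect_equal(calls$cdr3_aa1, "CKA;CPA")
  expect_false(grepl("CGA", calls$CTaa))
  # removeMulti drops the whole cell instead
  rep2 <- combineReceptors(list(tab), samples = "s", removeMulti = TRUE)
  expect_equal(nrow(rep2[["s"]]), 0)
})

test_that("UMI ties break by reads then contig id, deterministically", {
  tab <- contigTable(
    contigRow("c1", "TRA", cdr3_nt = "TGTAAA", umis = 5, reads = 10,
              contig_id = "z"),
    contigRow("c1", "TRA", cdr3_nt = "TGTCCC", umis = 5, reads = 50,
              contig_id = "m"),
    contigRow("c1", "TRA", cdr3_nt = "TGTGGG", umis = 5, reads = 10,
              contig_id = "a"),
    contigRow("c1", "TRB", cdr3_nt = "TGTTTT", umis = 2))
  rep <- combineReceptors(list(tab), samples = "s")
  # reads=50 wins, then contig_id "a" beats "z"
  expect_equal(rep[["s"]]$cdr3_nt1, "TGTCCC;TGTGGG")
})

test_that("removeNA drops cells missing either locus", {
  tab <- contigTable(
    contigRow("c1", "TRA", cdr3_nt = "TGTAAA"),
    contigRow("c1", "TRB", cdr3_nt = "TGTCCC"),
    contigRow("c2", "TRB", cdr3_nt = "TGTGGG"))
  both <- combineReceptors(list(tab), samples = "s")
  expect_equal(nrow(both[["s"]]), 2)
  paired <- combineReceptors(list(tab), samples = "s", removeNA = TRUE)
  expect_equal(paired[["s"]]$barcode, "s_c1")
})

test_that("clonotypeKey returns the chosen identifier, pure and deterministic", {
  tab <- contigTable(
    contigRow("c1", "TRA", cdr3_nt = "TGT", cdr3_aa = "C", v = "Va"),
    contigRow("c2", "TRA", cdr3_nt = "TGC", cdr3_aa = "C", v = "Va"))
  rep <- combineReceptors(list(tab), samples = "s")
  calls <- rep[["s"]]
  expect_equal(clonotypeKey(calls, "nt"), calls$CTnt)
  expect_equal(clonotypeKey(calls, "aa"), c("C_NA", "C_NA"))
  # equal gene keys, unequal strict keys for distinct CDR3-nt
  expect_equal(clonotypeKey(calls, "gene")[1], clonotypeKey(calls, "gene")[2])
  expect_false(clonotypeKey(calls, "strict")[1] ==
                 clonotypeKey(calls, "strict")[2])
  expect_identical(clonotypeKey(calls, "nt"), clonotypeKey(calls, "nt"))
})

test_that("countClonotypes counts cells per key and is additive per group", {
  tab1 <- contigTable(
    contigRow("c1", "TRB", cdr3_nt = "TGTAAA", cdr3_aa = "CKA"),
    contigRow("c2", "TRB", cdr3_nt = "TGTAAA", cdr3_aa = "CKA"),
    contigRow("c3", "TRB", cdr3_nt = "TGTAAA", cdr3_aa = "CKA"),
    contigRow("c4", "TRB", cdr3_nt = "TGTCCC", cdr3_aa = "CPA"))
  tab2 <- contigTable(
    contigRow("c1", "TRB", cdr3_nt = "TGTAAA", cdr3_aa = "CKA"))
  rep <- combineReceptors(list(tab1, tab2), samples = c("a", "b"),
                          groups = c("g", "g"))
  per_sample <- countClonotypes(rep, "aa")
  expect_equal(sort(as.integer(per_sample$a)), c(1L, 3L))
  expect_equal(sum(per_sample$a), 4)
  per_group <- countClonotypes(rep, "aa", scope = "per_group")
  expect_equal(per_group$g[["NA_CKA"]],
               per_sample$a[["NA_CKA"]] + per_sample$b[["NA_CKA"]])
})

test_that("planted clone sizes are recovered through the pipeline", {
  sim <- simulateRepertoire(nCells = 100, cloneSizes = c(50, 30, 20),
                            dualAlphaRate = 0.5, chainDropoutRate = 0,
                            multiContigRate = 0, seed = 13,
                            sampleName = "s")
  rep <- combineReceptors(list(sim$contigs), samples = "s")
  cv <- countClonotypes(rep, "aa")$s
  expect_equal(sort(as.integer(cv), decreasing = TRUE), c(50L, 30L, 20L))
})

test_that("cells are conserved and prefixing is injective", {
  sim1 <- simulateRepertoire(nCells = 150, seed = 31, sampleName = "a")
  sim2 <- simulateRepertoire(nCells = 150, seed = 31, sampleName = "b")
  rep <- combineReceptors(list(sim1$contigs, sim2$contigs),
                          samples = c("a", "b"))
  # conservation: one clonotype row per distinct barcode in the input
  expect_equal(nrow(rep[["a"]]), length(unique(sim1$contigs$barcode)))
  # same raw barcodes in both samples, still globally unique after prefix
  all_bc <- c(rep[["a"]]$barcode, rep[["b"]]$barcode)
  expect_false(anyDuplicated(all_bc) > 0)
})

test_that("nt-key equality implies aa-key equality for complete cells", {
  sim <- simulateRepertoire(nCells = 300, seed = 17, chainDropoutRate = 0,
                            sampleName = "s")
  calls <- combineReceptors(list(sim$contigs), samples = "s")[["s"]]
  agg <- tapply(calls$CTaa, calls$CTnt, function(x) length(unique(x)))
  expect_true(all(agg == 1))
})

test_that("configuration errors are caught", {
  tab <- contigRow("c1", "TRB")
  expect_error(combineReceptors(list(tab, tab), samples = c("s", "s")),
               "duplicate")
  expect_warning(
    combineReceptors(list(contigRow("pre_c1", "TRB")), samples = "s"),
    "separator")
})
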