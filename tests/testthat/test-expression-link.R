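# A small repertoire with one clone of 3 cells and two singleton cells.
linkFixture <- function() {
  tab <- contigTable(
    contigRow("c1", "TRB", cdr3_nt = "TGTAAA", cdr3_aa = "CKA"),
    contigRow("c2", "TRB", cdr3_nt = "TGTAAA", cdr3_aa = "CKA"),
    contigRow("c3", "TRB", cdr3_nt = "TGTAAA", cdr3_aa = "CKA"),
    contigRow("c4", "TRB", cdr3_nt = "TGTCCC", cdr3_aa = "CPA"),
    contigRow("c5", "TRB", cdr3_nt = "TGTGGG", cdr3_aa = "CGA"))
  combineReceptors(list(tab), samples = "s1")
}

test_that("joining is a left join that annotates frequency and bin", {
  rep <- linkFixture()
  meta <- data.frame(
    barcode = c("s1_c1", "s1_c2", "s1_c3", "s1_nocall1", "s1_nocall2"),
    cluster = c("C1", "C1", "C2", "C2", "C3"),
    stringsAsFactors = FALSE)
  joined <- joinExpression(meta, rep)
  expect_equal(nrow(joined), 5)                  # nothing dropped
  expect_equal(joined$barcode, meta$barcode)     # order kept
  expect_equal(joined$frequency[1:3], rep(3L, 3))
  expect_true(all(is.na(joined$frequency[4:5])))
  expect_true(all(is.na(joined$clonotype_key[4:5])))
  # freq_bin missing iff clonotype_key missing
  expect_equal(is.na(joined$freq_bin), is.na(joined$clonotype_key))
  expect_equal(as.character(joined$freq_bin[1]), "Small")  # 3 in (1, 5]
})

test_that("frequency bins respect mode and monotonicity", {
  rep <- linkFixture()
  meta <- data.frame(barcode = paste0("s1_c", 1:5),
                     stringsAsFactors = FALSE)
  joined <- joinExpression(meta, rep)
  expect_equal(as.character(joined$freq_bin[joined$frequency == 1]),
               rep("Single", 2))
  # monotone: larger frequency never maps to an earlier bin
  o <- order(joined$frequency)
  expect_true(all(diff(as.integer(joined$freq_bin[o])) >= 0))
  # proportion mode: clone of 3/5 = 0.6 of the sample
  propBins <- c(Rare = 0.1, Common = 0.5, Dominant = 1)
  jp <- joinExpression(meta, rep, bins = propBins, proportionMode = TRUE)
  expect_equal(as.character(jp$freq_bin[jp$frequency == 3]),
               rep("Dominant", 3))
  expect_equal(as.character(jp$freq_bin[jp$frequency == 1]),
               rep("Common", 2))  # 0.2 in (0.1, 0.5]
})

test_that("barcode mismatches and empty repertoires behave as contracted", {
  rep <- linkFixture()
  meta_bad <- data.frame(barcode = c("unprefixed1", "unprefixed2"),
                         stringsAsFactors = FALSE)
  expect_error(joinExpression(meta_bad, rep), "prefix")
  meta <- data.frame(barcode = c("s1_c1", "s1_c2"),
                     stringsAsFactors = FALSE)
  joined_empty <- joinExpression(meta, emptyRepertoire())
  expect_equal(nrow(joined_empty), 2)
  expect_true(all(is.na(joined_empty$clonotype_key)))
  expect_true(all(is.na(joined_empty$freq_bin)))
})

test_that("highlighting labels exactly the requested clonotypes", {
  rep <- linkFixture()
  meta <- data.frame(barcode = paste0("s1_c", 1:5),
                     stringsAsFactors = FALSE)
  joined <- joinExpression(meta, rep)
  hl <- highlightClonotypes(joined, c("NA_CKA", "NA_CPA"))
  expect_equal(sum(hl$highlight == "NA_CKA", na.rm = TRUE), 3)
  expect_equal(sum(hl$highlight == "NA_CPA", na.rm = TRUE), 1)
  expect_true(is.na(hl$highlight[hl$clonotype_key == "NA_CGA"]))
  expect_warning(highlightClonotypes(joined, "NA_ABSENT"), "NA_ABSENT")
  hl0 <- highlightClonotypes(joined, character(0))
  expect_true(all(is.na(hl0$highlight)))
})

test_that("cluster composition is dense and its proportions sum to one", {
  meta <- compositionMeta()
  comp <- clusterComposition(meta, "cluster", "group")
  expect_equal(comp$count, c(8, 2, 2, 8))
  expect_equal(comp$proportion, c(0.8, 0.2, 0.2, 0.8))
  # equal group totals: scaling is the identity
  comp_s <- clusterComposition(meta, "cluster", "group", scaled = TRUE)
  expect_equal(comp_s$proportion, comp$proportion, tolerance = 1e-12)
  # unequal totals: scaled proportions differ but still sum to 1
  meta2 <- rbind(meta, data.frame(barcode = paste0("x", 1:20),
                                  cluster = "c1", group = "g2"))
  comp2 <- clusterComposition(meta2, "cluster", "group", scaled = TRUE)
  expect_equal(as.numeric(tapply(comp2$proportion, comp2$cluster, sum)),
               c(1, 1), tolerance = 1e-12)
  # a group absent from a cluster appears with proportion 0
  meta3 <- meta[!(meta$cluster == "c2" & meta$group == "g1"), ]
  comp3 <- clusterComposition(meta3, "cluster", "group")
  row <- comp3[comp3$cluster == "c2" & comp3$group == "g1", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$count, 0)
  expect_error(clusterComposition(meta, "nope", "group"), "nope")
})

test_that("composition proportions always sum to one per cluster", {
  set.seed(59)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    meta <- data.frame(
      barcode = paste0("b", 1:n),
      cluster = sample(paste0("c", 1:sample(2:5, 1)), n, replace = TRUE),
      group = sample(c("g1", "g2", "g3"), n, replace = TRUE))
    comp <- clusterComposition(meta, "cluster", "group",
                               scaled = sample(c(TRUE, FALSE), 1))
    sums <- tapply(comp$proportion, comp$cluster, sum)
    expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-9)
  }
})

test_that("alluvial tables aggregate weights across axes", {
  meta <- compositionMeta()
  tab <- alluvialTable(meta, c("cluster", "group"))
  expect_equal(tab$weight, c(8, 2, 2, 8))
  expect_equal(sum(tab$weight), nrow(meta))
  one <- alluvialTable(meta[1, ], c("cluster", "group"))
  expect_equal(one$weight, 1)
  expect_error(alluvialTable(meta, "cluster"), "two axes")
  wide <- data.frame(barcode = sprintf("b%04d", 1:1100),
                     a = sprintf("l%04d", 1:1100), b = "x")
  expect_error(alluvialTable(wide, c("a", "b")), "unreadable")
  # frequency weighting follows the joined frequency column
  rep <- linkFixture()
  jm <- joinExpression(data.frame(barcode = paste0("s1_c", 1:5)), rep)
  jm$cluster <- c("C1", "C1", "C2", "C2", "C2")
  tw <- alluvialTable(jm, c("cluster", "freq_bin"),
                      weight = "clonotype_frequency")
  expect_equal(sum(tw$weight), sum(jm$frequency))
})

test_that("metadata splits are disjoint partitions reusable as repertoires", {
  rep <- linkFixture()
  meta <- joinExpression(data.frame(barcode = paste0("s1_c", 1:5)), rep)
  meta$cluster <- c("C1", "C1", "C2", "C2", "C2")
  parts <- splitByMetadata(meta, "cluster")
  expect_equal(sort(names(parts)), c("C1", "C2"))
  expect_equal(sum(vapply(parts, nrow, integer(1))), nrow(meta))
  expect_identical(do.call(rbind, unname(parts))[order(
    do.call(rbind, unname(parts))$barcode), ]$barcode,
    meta$barcode[order(meta$barcode)])
  # per-level count vectors feed the diversity metrics
  cvs <- lapply(parts, metaCountVector)
  expect_equal(sum(unlist(cvs)), 5)
  expect_equal(cvs$C1[["NA_CKA"]], 2)
  expect_equal(cvs$C2[["NA_CKA"]], 1)
  div <- clonalDiversity(cvs)
  expect_equal(nrow(div), 2)
  # single-level split returns the input
  meta$all <- "one"
  expect_equal(nrow(splitByMetadata(meta, "all")$one), nrow(meta))
  expect_error(splitByMetadata(meta, "frequency"), "categorical")
})
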