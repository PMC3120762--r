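test_that("haplotype collapse matches hand enumeration", {
  dm <- data.frame(sample_id = c("a", "b", "c"), deme = "F")
  tab <- collapseHaplotypes(c(a = "ACGT", b = "ACGT", c = "ACGA"), dm)
  expect_identical(nrow(tab@counts), 2L)
  expect_identical(sort(as.integer(tab@counts)), c(1L, 2L))

  ten <- setNames(rep("AAAA", 10), paste0("s", 1:10))
  tab1 <- collapseHaplotypes(ten, data.frame(sample_id = names(ten), deme = "F"))
  expect_identical(as.integer(tab1@counts), 10L)

  toy <- toyAlignment() # 6 sequences, 3 distinct, 3 demes
  tab3 <- collapseHaplotypes(toy$alignment, toy$demeMap)
  expect_identical(dim(tab3@counts), c(3L, 3L))
  # hand enumeration: ACGTACGT x3 (F2, A1), ACGAACGT x2 (S2), ACGAACTT x1 (A1)
  h1 <- names(which(tab3@sequences == "ACGTACGT"))
  expect_identical(as.integer(tab3@counts[h1, c("F", "S", "A")]), c(2L, 0L, 1L))
  expect_identical(colSums(tab3@counts), c(F = 2, S = 2, A = 2))
})

test_that("collapse validates its input", {
  dm <- data.frame(sample_id = c("a", "b"), deme = "F")
  expect_error(collapseHaplotypes(c(a = "ACGT", b = "ACG"), dm), "equal length")
  expect_error(collapseHaplotypes(c(a = "ACGT", b = "ACGR"), dm),
               "phased")
  expect_error(collapseHaplotypes(c(a = "ACGT", x = "ACGT"), dm),
               "missing from deme map")
})

test_that("Nei's haplotype diversity matches the closed form", {
  expect_identical(haplotypeDiversity(5), 0)
  expect_identical(haplotypeDiversity(c(1, 1)), 1)
  expect_equal(haplotypeDiversity(c(3, 1)), 0.5) # (4/3)(1 - 9/16 - 1/16)
  expect_error(haplotypeDiversity(1), "n < 2")
})

test_that("nucleotide diversity equals brute-force pair enumeration", {
  dm <- data.frame(sample_id = c("a", "b"), deme = "F")
  L <- 100
  s1 <- paste(rep("A", L), collapse = "")
  s2 <- paste(c("T", rep("A", L - 1)), collapse = "")
  tab <- collapseHaplotypes(setNames(c(s1, s1), c("a", "b")), dm)
  expect_identical(nucleotideDiversity(tab), 0)
  tab2 <- collapseHaplotypes(setNames(c(s1, s2), c("a", "b")), dm)
  expect_equal(nucleotideDiversity(tab2), 0.01)

  # counts (2,2) of two haplotypes 3 sites apart, L = 219
  h1 <- paste(rep("A", 219), collapse = "")
  h2 <- paste(c("T", "T", "T", rep("A", 216)), collapse = "")
  aln <- setNames(c(h1, h1, h2, h2), c("a", "b", "c", "d"))
  dm4 <- data.frame(sample_id = names(aln), deme = "F")
  tab4 <- collapseHaplotypes(aln, dm4)
  # brute force over all 6 pairs: 4 pairs differ at 3 sites
  brute <- (4 * 3) / 6 / 219
  expect_equal(nucleotideDiversity(tab4), brute)
})

test_that("segregating sites are classified as singleton or informative", {
  mono <- setNames(rep("AAAA", 4), paste0("s", 1:4))
  expect_identical(classifySegregatingSites(mono),
                   c(singleton = 0L, parsimony_informative = 0L))
  toy <- c(a = "AAT", b = "AAT", c = "AAC", d = "GAC")
  expect_identical(classifySegregatingSites(toy),
                   c(singleton = 1L, parsimony_informative = 1L))
})

test_that("biallelic variable sites are all singleton or informative", {
  cfg <- presetConfig("mito", seed = 3)
  sim <- demeflow:::simulateDataset(cfg)
  aln <- demeflow:::asAlignmentMatrix(sim$alignment)
  counts <- classifySegregatingSites(sim$alignment)
  nAlleles <- apply(aln, 2, function(col) length(unique(col)))
  if (all(nAlleles <= 2)) {
    # every biallelic variable site is one singleton or one PI site
    expect_identical(sum(counts), sum(nAlleles == 2))
  } else {
    expect_gte(sum(counts), sum(nAlleles >= 2))
  }
})

test_that("diversities are invariant to relabeling and column permutation", {
  toy <- toyAlignment()
  tab <- collapseHaplotypes(toy$alignment, toy$demeMap)
  set.seed(1)
  perm <- sample(nchar(toy$alignment[1]))
  shuffled <- vapply(toy$alignment, function(s)
    paste(strsplit(s, "")[[1]][perm], collapse = ""), "")
  names(shuffled) <- rev(names(toy$alignment))
  dm2 <- toy$demeMap
  dm2$sample_id <- rev(dm2$sample_id) # same deme assignment per sequence
  tab2 <- collapseHaplotypes(shuffled, dm2)
  expect_equal(haplotypeDiversity(rowSums(tab@counts)),
               haplotypeDiversity(rowSums(tab2@counts)))
  expect_equal(nucleotideDiversity(tab), nucleotideDiversity(tab2))
})

test_that("columns with non-ACGT symbols are excluded from statistics", {
  aln <- c(a = "AC-T", b = "ACGT", c = "TCGT")
  dm <- data.frame(sample_id = names(aln), deme = "F")
  tab <- collapseHaplotypes(aln, dm)
  expect_identical(tab@excludedColumns, 3L)
  # distances use only columns 1, 2, 4
  d <- demeflow:::haplotypeDistances(tab)
  expect_identical(max(d), 1L)
})
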