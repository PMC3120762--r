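test_that("connection limit behaves at its boundaries", {
  # vanishing confidence: every step count is acceptable, capped at L
  expect_identical(connectionLimit(50, confidence = 1e-30), 50L)
  expect_identical(connectionLimit(1), 1L)
  # non-decreasing in L by direct computation
  lims <- vapply(c(100, 300, 604), connectionLimit, 1L)
  expect_true(all(diff(lims) >= 0))
})

test_that("the 95% limit matches a Monte-Carlo probability-of-parsimony oracle", {
  # simulate j mutations on an L-site sequence; the connection is
  # parsimonious iff no site is hit twice (any repeat, parallel or back
  # mutation shortens the observable path)
  L <- 604L
  mcParsimonyProb <- function(j, reps = 20000) {
    set.seed(j * 1000 + 7)
    hits <- matrix(sample.int(L, j * reps, replace = TRUE), reps, j)
    mean(apply(hits, 1, anyDuplicated) == 0)
  }
  lim <- connectionLimit(L, 0.95)
  pIn <- mcParsimonyProb(lim)
  pOut <- mcParsimonyProb(lim + 1L)
  seIn <- sqrt(pIn * (1 - pIn) / 20000)
  seOut <- sqrt(pOut * (1 - pOut) / 20000)
  expect_gt(pIn, 0.95 - 3 * seIn)
  expect_lt(pOut, 0.95 + 3 * seOut)
})

test_that("minimal networks match the spec toys", {
  dm1 <- data.frame(sample_id = "a", deme = "F")
  tab1 <- collapseHaplotypes(c(a = "ACGT"), dm1)
  net1 <- buildNetwork(tab1)
  expect_equal(igraph::vcount(net1@graph), 1)
  expect_equal(igraph::ecount(net1@graph), 0)

  # distances 1, 1, 2: chain through the middle haplotype
  aln <- c(a = "AAAA", b = "AAAT", c = "AATT")
  dm <- data.frame(sample_id = names(aln), deme = "F")
  net <- buildNetwork(collapseHaplotypes(aln, dm), limit = 5)
  g <- net@graph
  expect_equal(igraph::ecount(g), 2)
  expect_equal(igraph::components(g)$no, 1)
  dd <- igraph::distances(g)
  mid <- names(collapseHaplotypes(aln, dm)@sequences)[
    collapseHaplotypes(aln, dm)@sequences == "AAAT"]
  ends <- setdiff(rownames(dd), mid)
  expect_identical(as.integer(dd[ends[1], ends[2]]), 2L)

  # beyond the limit: disconnected
  far <- c(a = "AAAAAA", b = "TTTAAA")
  tabf <- collapseHaplotypes(far, data.frame(sample_id = c("a", "b"), deme = "F"))
  netf <- buildNetwork(tabf, limit = 2)
  expect_equal(igraph::components(netf@graph)$no, 2)
})

test_that("networks equal the brute-force minimal-connection construction", {
  set.seed(11)
  for (rep in 1:12) {
    nh <- sample(3:6, 1)
    L <- 12
    seqs <- character(0)
    while (length(unique(seqs)) < nh) {
      base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      seqs <- vapply(seq_len(nh), function(i) {
        s <- base
        k <- sample(0:3, 1)
        if (k > 0) {
          pos <- sample(L, k)
          s[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
        }
        paste(s, collapse = "")
      }, "")
    }
    names(seqs) <- paste0("h", seq_len(nh))
    dm <- data.frame(sample_id = names(seqs), deme = "F")
    tab <- collapseHaplotypes(seqs, dm)
    limit <- 3L
    net <- buildNetwork(tab, limit = limit)
    ref <- bruteForceNetwork(tab@sequences, limit)
    memb <- networkComponents(net)
    # identical component partition of the sampled haplotypes
    expect_identical(length(unique(memb)), length(unique(ref$comp)))
    same <- outer(memb, memb, "==")
    sameRef <- outer(ref$comp, ref$comp, "==")
    expect_true(all(same == sameRef))
    # connection distances between sampled haplotypes match
    dd <- igraph::distances(net@graph)
    dd <- dd[names(memb), names(memb)]
    expect_true(all(abs(dd[is.finite(dd)] - ref$dist[is.finite(ref$dist)]) < 1e-9))
  }
})

test_that("node frequencies sum to the sample size", {
  toy <- toyAlignment()
  tab <- collapseHaplotypes(toy$alignment, toy$demeMap)
  net <- buildNetwork(tab)
  expect_equal(sum(igraph::V(net@graph)$frequency), 6)
})
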