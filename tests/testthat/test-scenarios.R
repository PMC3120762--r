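test_that("nine constrained hypotheses plus the full model are enumerated", {
  sc <- enumerateScenarios(c("F", "S", "A"))
  expect_length(sc, 10L)
  ks <- vapply(sc, function(s) s@k, 1L)
  expect_identical(sum(ks == 5L), 9L)
  expect_identical(sum(ks == 9L), 1L)
  expect_identical(anyDuplicated(names(sc)), 0L)
  expect_true("S>A>F" %in% names(sc))
  # every constrained mask frees exactly 2 rates; the full model all 6
  nf <- vapply(sc, function(s) sum(s@mask), 1L)
  expect_identical(sort(unique(nf[names(sc) != "full model"])), 2L)
  expect_identical(nf[["full model"]], 6L)
})

test_that("forward colonization edges map to backward rate constraints", {
  sc <- enumerateScenarios(c("F", "S", "A"))
  m <- scenarioMask(sc[["S>A>F"]])
  expect_true(m["A", "S"] && m["F", "A"])
  expect_identical(sum(m), 2L)
  m2 <- scenarioMask(sc[["S>A, S>F"]])
  expect_true(m2["A", "S"] && m2["F", "S"])
  expect_identical(sum(scenarioMask(sc[["full model"]])), 6L)
})

test_that("scenario masks are a bijection and sequential origins are reachable", {
  sc <- enumerateScenarios(c("F", "S", "A"))
  keys <- vapply(sc, function(s) paste(as.integer(s@mask), collapse = ""), "")
  expect_identical(anyDuplicated(keys), 0L)
  reach <- function(mask, from) {
    r <- logical(3); r[from] <- TRUE
    repeat {
      r2 <- r
      for (a in which(r)) r2 <- r2 | mask[a, ]
      if (identical(r2, r)) break
      r <- r2
    }
    r
  }
  for (s in sc) {
    if (s@name == "full model" || nrow(s@edges) != 2) next
    if (s@edges[1, 2] != s@edges[2, 1]) next # sequential only
    origin <- match(s@origin, s@demeLabels)
    for (d in 1:3)
      expect_true(reach(s@mask, d)[origin],
                  label = sprintf("%s: origin reachable from deme %d",
                                  s@name, d))
  }
})

test_that("non-3-deme label sets are refused", {
  expect_error(enumerateScenarios(c("X", "Y")), "3-deme")
})

test_that("scenario rates fill only the free entries", {
  sc <- enumerateScenarios(c("F", "S", "A"))[["S>A>F"]]
  M <- scenarioRates(sc, c(10, 20))
  expect_identical(sum(M > 0), 2L)
  expect_identical(M[!sc@mask], rep(0, 7))
})
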