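test_that("AIC arithmetic reproduces the published decision values", {
  expect_equal(aic(21.6, 5), -33.2)
  expect_equal(aic(21.6, 9), -25.2)
  expect_identical(aic(0, 0), 0)
})

test_that("model ranking reproduces the published decisive gaps", {
  tab <- referenceModelTable()
  coi <- tab[tab$locus == "COI" & tab$scenario != "full model",
             c("scenario", "k", "logLik")]
  r <- rankModels(coi)
  expect_identical(r$scenario[r$best], "S>A>F")
  expect_equal(attr(r, "deltaBestVsRunnerUp"), 55.2, tolerance = 1e-9)

  hsp <- tab[tab$locus == "hsp70" & tab$scenario != "full model",
             c("scenario", "k", "aic_printed")]
  names(hsp)[3] <- "aic"
  r2 <- rankModels(hsp)
  expect_identical(r2$scenario[r2$best], "S>A>F")
  expect_equal(attr(r2, "deltaBestVsRunnerUp"), 478.94, tolerance = 1e-9)
})

test_that("the full model is excluded from the best-vs-rest comparison", {
  tab <- referenceModelTable("COI")[, c("scenario", "k", "logLik")]
  r <- rankModels(tab)
  # full model AIC (-25.2) lies between the best constrained (-33.2) and
  # the constrained runner-up (22.0); the decisive gap must ignore it
  expect_equal(attr(r, "deltaBestVsRunnerUp"), 55.2, tolerance = 1e-9)
  expect_false(r$best[r$scenario == "full model"])
  expect_true(all(r$deltaAIC[r$scenario != "full model"] >= 0))
})

test_that("ranking is invariant to input row order and rejects duplicates", {
  tab <- referenceModelTable("COI")[, c("scenario", "k", "logLik")]
  set.seed(2)
  r1 <- rankModels(tab)
  r2 <- rankModels(tab[sample(nrow(tab)), ])
  expect_identical(r1$scenario, r2$scenario)
  expect_equal(r1$aic, r2$aic)
  expect_error(rankModels(rbind(tab, tab[1, ])), "duplicate")
  r3 <- rankModels(tab[3, ])
  expect_identical(r3$deltaAIC, 0)
  expect_identical(r3$rank, 1L)
})

test_that("recomputed AIC matches the printed table to printed rounding", {
  tab <- referenceModelTable()
  recomputed <- aic(tab$logLik, tab$k)
  expect_true(all(abs(recomputed - tab$aic_printed) <= 0.15))
  expect_gte(sum(abs(recomputed - tab$aic_printed) < 0.005), 16L)
})
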