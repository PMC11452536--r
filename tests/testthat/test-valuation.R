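test_that("subset evaluation memoizes and honors the empty coalition", {
  calls <- new.env(); calls$n <- 0L
  vf <- valueFunction(c("a", "b"), function(subset) {
    calls$n <- calls$n + 1L
    0.5 + 0.1 * length(subset)
  })
  expect_equal(evaluateSubset(vf, character(0)), 0.5)
  expect_equal(evaluateSubset(vf, "a"), 0.6)
  expect_equal(evaluateSubset(vf, c("b", "a")),
               evaluateSubset(vf, c("a", "b")))
  expect_equal(calls$n, 2L)  # {a} once, {a,b} once; empty set short-circuits
  expect_error(evaluateSubset(vf, "zz"), "unknown")
})

test_that("exact Shapley reproduces the worked two-slide example and axioms", {
  v <- c("1" = 0.7, "2" = 0.6, "1+2" = 0.8)
  vf <- valueFunction(c("1", "2"), function(s) {
    v[[paste(sort(s), collapse = "+")]]
  }, vEmpty = 0.5)
  est <- shapleyExact(vf)
  expect_equal(unname(est@phi), c(0.2, 0.1), tolerance = 1e-12)
  expect_equal(sum(est@phi), est@vFull - est@vEmpty, tolerance = 1e-10)

  # null player: a slide that never changes V gets phi = 0
  vfNull <- valueFunction(c("a", "n"), function(s) {
    if ("a" %in% s) 0.9 else 0.5
  }, vEmpty = 0.5)
  estN <- shapleyExact(vfNull)
  expect_equal(unname(estN@phi["n"]), 0)
  expect_equal(unname(estN@phi["a"]), 0.4)

  # symmetry: interchangeable slides get equal phi
  vfSym <- valueFunction(c("x", "y", "z"), function(s) {
    0.5 + 0.1 * ("z" %in% s) + 0.07 * sum(c("x", "y") %in% s)
  }, vEmpty = 0.5)
  estS <- shapleyExact(vfSym)
  expect_equal(unname(estS@phi["x"]), unname(estS@phi["y"]),
               tolerance = 1e-12)

  # efficiency on arbitrary value functions up to n = 6
  for (n in 2:6) {
    ids <- letters[seq_len(n)]
    vfR <- randomValueFunction(ids, seed = 100 + n)
    estR <- shapleyExact(vfR)
    expect_equal(sum(estR@phi),
                 evaluateSubset(vfR, ids) - vfR@vEmpty,
                 tolerance = 1e-10)
  }
})

test_that("Monte Carlo Shapley converges to the exact values", {
  ids <- paste0("s", 1:5)
  for (seed in 1:3) {
    vf <- randomValueFunction(ids, seed = 7)
    exact <- shapleyExact(vf)
    mc <- shapleyMonteCarlo(vf, nPermutations = 2000L, seed = seed)
    expect_true(all(abs(mc@phi - exact@phi) <=
                      3 * pmax(mc@se, 1e-12)))
    expect_equal(sum(mc@phi), mc@vFull - mc@vEmpty,
                 tolerance = 3 * sqrt(sum(mc@se^2)) + 1e-12)
  }
  # determinism and degenerate truncation
  vf <- randomValueFunction(ids, seed = 7)
  a <- shapleyMonteCarlo(vf, 50L, seed = 2)
  b <- shapleyMonteCarlo(vf, 50L, seed = 2)
  expect_identical(a@phi, b@phi)
  tAll <- shapleyMonteCarlo(vf, 50L, seed = 2, truncationTol = Inf)
  expect_true(all(tAll@phi == 0))
})

test_that("slide costs are itemized, linear in spots, and favor enhanced per patient", {
  zero <- new("CostModel", baseCost = c(traditional = 0, enhanced = 0),
              perSpot = 0, labor = c(traditional = 0, enhanced = 0),
              sequencing = c(traditional = 0, enhanced = 0), label = "zero")
  expect_equal(as.numeric(slideCost(list(protocol = "traditional",
                                         nSpots = 500), zero)), 0)

  cm <- defaultCostModel()
  c1 <- slideCost(list(protocol = "enhanced", nSpots = 1000), cm)
  c2 <- slideCost(list(protocol = "enhanced", nSpots = 2000), cm)
  expect_equal(as.numeric(c2) - as.numeric(c1), 1000 * cm@perSpot)
  expect_named(attr(c1, "components"),
               c("base", "spots", "labor", "sequencing"))

  # defaults: traditional capture area (1 patient) dearer per patient
  # than an enhanced one (2 patients) despite fewer spots
  trad <- as.numeric(slideCost(list(protocol = "traditional",
                                    nSpots = 920), cm))
  enh <- as.numeric(slideCost(list(protocol = "enhanced",
                                   nSpots = 1840), cm))
  expect_gt(trad, enh)          # per capture area (the study's direction)
  expect_gt(trad / 1, enh / 2)  # per patient
})

test_that("group comparison follows the stated rank-biserial convention", {
  cg <- compareGroups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cg$U, 0)
  expect_equal(cg$rankBiserial, 1)

  same <- compareGroups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$rankBiserial, 0)
  expect_equal(same$p, 1)
})

test_that("duplicating an informative slide never lowers the coalition value", {
  prof <- noiselessProfile("enhanced")
  W <- generateGeneWeights(4L, 8L, seed = 55L)
  fp <- list(P = 4L, G = 8L, geneWeights = W)
  tr <- generateSlide(list(captureMm = 1.0), fp, prof,
                      list(librarySizeMean = 8000), seed = 61L,
                      slideId = "tr")
  val <- generateSlide(list(captureMm = 1.0), fp, prof,
                       list(librarySizeMean = 8000), seed = 62L,
                       slideId = "val")
  vf <- makeValueFunction(list(a = tr, dup = tr), val)
  vSingle <- evaluateSubset(vf, "a")
  vBoth <- evaluateSubset(vf, c("a", "dup"))
  expect_gt(vSingle, 0.5)  # an informative slide beats the empty set
  # n-scaled ridge penalty makes the duplicated fit identical
  expect_equal(vBoth, vSingle, tolerance = 1e-10)
})

test_that("cohort valuation produces a coherent table and comparisons", {
  coh <- generateCohort(cohortConfig(seed = 2L, genes = 10L,
                                     captureMm = 1.0,
                                     nTrainingSlidesPerProtocol = 2L))
  v <- valuateCohort(coh, seed = 1L)
  tab <- v@table
  expect_equal(nrow(tab), 4L * 2L)  # 4 training slides x 2 validations
  expect_equal(tab$ratio, tab$phi / tab$cost)
  # efficiency per validation slide
  for (est in v@estimates) {
    expect_equal(sum(est@phi), est@vFull - est@vEmpty, tolerance = 1e-10)
  }
  expect_setequal(
    v@comparisons$comparison,
    c("cost", "phi_on_traditional", "ratio_on_traditional",
      "phi_on_enhanced", "ratio_on_enhanced"))
  # group stats recompute from the per-slide table
  sub <- tab[tab$validation == "enhanced", ]
  cg <- compareGroups(sub$phi[sub$protocol == "traditional"],
                      sub$phi[sub$protocol == "enhanced"])
  row <- v@comparisons[v@comparisons$comparison == "phi_on_enhanced", ]
  expect_equal(row$U, cg$U)
  expect_equal(row$p, cg$p)
})
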