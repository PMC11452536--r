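test_that("k-means ground truth recovers separated blobs", {
  set.seed(13)
  n <- 60
  blob <- rep(1:2, each = n / 2)
  # blobs differ in composition: first half of genes high in blob 1,
  # second half high in blob 2
  lam <- outer(blob, rep(1:2, each = 5),
               function(b, gset) ifelse(b == gset, 50, 5))
  expr <- matrix(rpois(n * 10, lam), n, 10)
  cl <- clusterGroundTruth(expr, kClusters = 2L, seed = 4L)
  agree <- max(mean((cl == 1) == (blob == 1)),
               mean((cl == 2) == (blob == 1)))
  expect_equal(agree, 1)

  expect_equal(clusterGroundTruth(expr, kClusters = 1L, seed = 4L),
               rep(1L, n))
  expect_identical(cl, clusterGroundTruth(expr, kClusters = 2L, seed = 4L))
})

test_that("k-NN recovery is exact on identical embeddings and at chance on shuffles", {
  set.seed(21)
  n <- 150
  expr <- matrix(rnorm(n * 12, mean = rep(c(0, 2, 4), each = n / 3)),
                 n, 12)
  cl <- clusterGroundTruth(expr, kClusters = 3L, seed = 1L)
  for (k in c(3L, 5L)) {
    expect_equal(knnClusterRecovery(expr, expr, cl, k), 1)
  }

  # random spot permutation: analytic chance level is
  # sum_k p_k (n p_k - 1) / (n - 1)
  pk <- table(cl) / n
  chance <- sum(pk * (n * pk - 1) / (n - 1))
  rec <- mean(sapply(1:20, function(s) {
    set.seed(s)
    knnClusterRecovery(expr, expr[sample(n), ], cl, 1L)
  }))
  expect_lt(abs(rec - chance), 0.05)

  expect_error(knnClusterRecovery(expr, expr, cl, kNN = n + 1L), "kNN")
})

test_that("recovery degrades monotonically with prediction noise", {
  set.seed(31)
  n <- 120
  expr <- matrix(rnorm(n * 10, mean = rep(c(0, 3), each = n / 2)), n, 10)
  cl <- clusterGroundTruth(expr, kClusters = 2L, seed = 2L)
  noise <- c(0, 0.5, 1.5, 4, 10)
  rec <- sapply(noise, function(ns) {
    mean(sapply(1:10, function(s) {
      set.seed(s)
      knnClusterRecovery(expr, expr + matrix(rnorm(n * 10, sd = ns), n, 10),
                         cl, 3L)
    }))
  })
  expect_true(all(diff(rec) <= 0))
  expect_equal(rec[1], 1)
})

test_that("DE localization shift is null for perfect predictions", {
  set.seed(41)
  n <- 90
  region <- sample(c("tumor", "interface", "distal"), n, replace = TRUE,
                   prob = c(0.3, 0.3, 0.4))
  truth <- matrix(rnorm(n * 8) + 2 * (region == "interface"), n, 8,
                  dimnames = list(NULL, paste0("g", 1:8)))
  rho <- setNames(seq(0.9, 0.2, length.out = 8), colnames(truth))
  res <- deLocalizationShift(truth, truth, region, rho, topN = 8,
                             nBoot = 50, seed = 1)
  expect_equal(res$medianPct, 0)
  expect_lte(res$ci[1], 0)
  expect_gte(res$ci[2], 0)

  # single-gene reduction
  res1 <- deLocalizationShift(truth, truth + 0.1 * matrix(rnorm(n * 8), n, 8),
                              region, rho, topN = 1, nBoot = 20, seed = 1)
  expect_equal(res1$medianPct, unname(res1$pct[1]))
  expect_length(res1$pct, 1)

  expect_error(deLocalizationShift(truth, truth, rep("tumor", n), rho),
               "interface")
})

test_that("region-independent predictions shift U toward its null center", {
  set.seed(43)
  n <- 200
  region <- rep(c("interface", "distal"), each = n / 2)
  g <- 6
  truth <- matrix(rnorm(n * g) + 1.5 * (region == "interface"), n, g,
                  dimnames = list(NULL, paste0("g", 1:g)))
  rho <- setNames(rep(0.5, g), colnames(truth))
  n1 <- sum(region == "interface"); n2 <- n - n1
  shifts <- sapply(1:20, function(s) {
    set.seed(s)
    pred <- matrix(rnorm(n * g), n, g, dimnames = dimnames(truth))
    deLocalizationShift(truth, pred, region, rho, topN = g,
                        nBoot = 1, seed = s)$medianPct
  })
  uTruth <- vapply(seq_len(g), function(gi) {
    bruteU(truth[region == "interface", gi], truth[region != "interface", gi])
  }, numeric(1))
  # analytic displacement: U_pred concentrates at n1*n2/2
  expected <- median(100 * (n1 * n2 / 2 - uTruth) / uTruth)
  expect_lt(abs(mean(shifts) - expected), 5)

  # a gene with U_truth = 0 is excluded with a reason
  truth0 <- truth
  truth0[, 1] <- ifelse(region == "interface", 0, 1) + 0.001 * seq_len(n)
  res <- deLocalizationShift(truth0, truth0, region, rho, topN = g,
                             nBoot = 5, seed = 1)
  expect_true("g1" %in% res$excluded)
  expect_false("g1" %in% res$genes)
})
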