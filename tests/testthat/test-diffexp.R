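test_that("library-size normalization: column sums and TMM behaviour", {
  set.seed(41)
  m <- matrix(rnbinom(2000, mu = 80, size = 10), 500, 4,
              dimnames = list(paste0("g", 1:500), paste0("s", 1:4)))
  expect_equal(unname(normalizeLibSizes(m, "libsize")), unname(colSums(m)))

  same <- cbind(a = m[, 1], b = m[, 1], c = m[, 1])
  ls <- normalizeLibSizes(same, "tmm")
  expect_equal(unname(ls / colSums(same)), rep(1, 3), tolerance = 1e-9)

  # a doubled sample has no composition bias: its TMM factor matches the
  # original sample's factor, so normalized expression is restored
  dbl <- cbind(a = m[, 1], b = m[, 1] * 2, c = m[, 2])
  ls2 <- normalizeLibSizes(dbl, "tmm")
  fac <- ls2 / colSums(dbl)
  expect_equal(fac[["a"]], fac[["b"]], tolerance = 1e-6)

  two <- matrix(c(60, 40, 120, 80), 2, 2,
                dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_equal(unname(normalizeLibSizes(two, "libsize")), c(100, 200))

  mz <- m; mz[, 1] <- 0
  expect_error(normalizeLibSizes(mz), "all-zero sample")
})

test_that("TMM factors agree with the reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(42)
  m <- matrix(rnbinom(4000, mu = 100, size = 5), 1000, 4)
  m[1, 2] <- 5000
  dimnames(m) <- list(paste0("g", 1:1000), paste0("s", 1:4))
  mine <- normalizeLibSizes(m, "tmm") / colSums(m)
  ref <- edgeR::calcNormFactors(edgeR::DGEList(m))$samples$norm.factors
  expect_equal(unname(mine), ref, tolerance = 1e-4)
})

test_that("common dispersion recovers the simulation truth", {
  sim0 <- simulateDeCounts(nGenes = 2000, fracDe = 0, phi = 0, seed = 51)
  est0 <- estimateCommonDispersion(sim0$counts, sim0$groups)
  expect_lte(est0$phi_common, 0.01)

  sim2 <- simulateDeCounts(nGenes = 2000, fracDe = 0, phi = 0.2, seed = 52)
  est2 <- estimateCommonDispersion(sim2$counts, sim2$groups)
  expect_gte(est2$phi_common, 0.15)
  expect_lte(est2$phi_common, 0.25)

  # a flat single gene carries no overdispersion signal
  flat <- matrix(7, 1, 6, dimnames = list("g", paste0("s", 1:6)))
  estf <- estimateCommonDispersion(flat, rep(c("A", "B"), each = 3))
  expect_lte(estf$phi_common, 1e-5)

  expect_error(estimateCommonDispersion(flat * 0,
                                        rep(c("A", "B"), each = 3)),
               "all-zero")
})

test_that("common dispersion matches the reference implementation", {
  skip_if_not_installed("edgeR")
  sim <- simulateDeCounts(nGenes = 1500, fracDe = 0, phi = 0.15, seed = 53)
  mine <- estimateCommonDispersion(sim$counts, sim$groups)$phi_common
  d <- edgeR::estimateCommonDisp(edgeR::DGEList(sim$counts,
                                                group = sim$groups))
  expect_equal(mine, d$common.dispersion, tolerance = 0.02)
})

test_that("exact test: symmetry, Poisson closed form and the enumeration
           oracle", {
  # equal group sums give p = 1 at any dispersion
  m <- matrix(c(5, 5, 5, 5), 1, 4,
              dimnames = list("g", paste0("s", 1:4)))
  for (phi in c(0, 0.1, 1)) {
    r <- exactTestNb(m, rep(c("A", "B"), each = 2), phi = phi,
                     libSizes = rep(100, 4))
    expect_equal(r$pvalue, 1)
  }

  # Poisson limit, 1 vs 1 samples, counts 0 | 10: p = 2 * 0.5^10
  m2 <- matrix(c(0, 10), 1, 2, dimnames = list("g", c("a", "b")))
  r2 <- exactTestNb(m2, c("A", "B"), phi = 0, libSizes = c(100, 100))
  expect_equal(r2$pvalue, 2 * 0.5^10, tolerance = 1e-12)

  # exhaustive-split oracle over random small cases, s <= 30
  set.seed(61)
  for (i in 1:60) {
    nA <- sample(1:3, 1)
    nB <- sample(1:3, 1)
    phi <- sample(c(0, 0.05, 0.2, 1), 1)
    s <- sample(0:30, 1)
    a <- sample(0:s, 1)
    mine <- SialoKit:::.exactPvalOne(a, s, nA, nB, phi)
    orc <- oracleExactP(a, s, nA, nB, phi)
    expect_equal(mine, orc, tolerance = 1e-9)
  }
})

test_that("exact test agrees with the reference implementation", {
  skip_if_not_installed("edgeR")
  sim <- simulateDeCounts(nGenes = 300, fracDe = 0.1, phi = 0.1, seed = 62)
  ls <- colSums(sim$counts)
  mine <- exactTestNb(sim$counts, sim$groups, phi = 0.1, libSizes = ls,
                      reference = "A")
  d <- edgeR::DGEList(sim$counts, group = factor(sim$groups,
                                                 levels = c("A", "B")))
  d$common.dispersion <- 0.1
  ref <- edgeR::exactTest(d, rejection.region = "smallp")$table
  expect_gt(cor(mine$pvalue, ref$PValue), 0.999)
  expect_gt(cor(mine$logFC, ref$logFC), 0.999)
})

test_that("BH adjustment and status calls follow the stated rules", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.73), 0.73)
  set.seed(71)
  p <- runif(50)
  adj <- bhAdjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")

  res <- data.frame(logFC = c(-2.5, -2.5, 1.5, 2.5),
                    fdr = c(0.01, 0.2, 0.001, 0.01))
  out <- callDe(res)
  expect_equal(out$status, c("up", "ns", "ns", "down"))
  expect_equal(unname(attr(out, "census")), c(1, 1, 2))
})

test_that("the p-value distribution is uniform under the null", {
  sim <- simulateDeCounts(nGenes = 5000, fracDe = 0, phi = 0.1, seed = 81)
  est <- estimateCommonDispersion(sim$counts, sim$groups)
  res <- exactTestNb(sim$counts, sim$groups, phi = est$phi_common,
                     libSizes = colSums(sim$counts), reference = "A")
  frac <- mean(res$pvalue < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("planted fold changes are recovered with controlled FDR", {
  sim <- simulateDeCounts(nGenes = 2000, fracDe = 0.1, lfc = 3, phi = 0.1,
                          seed = 91)
  sc <- makeCounts(sim$counts, sim$groups)
  res <- diffExpress(sc, reference = "A")
  called <- res$status != "ns"
  sens <- sum(called & sim$de) / sum(sim$de)
  fdr <- if (any(called)) sum(called & !sim$de) / sum(called) else 0
  expect_gte(sens, 0.8)
  expect_lte(fdr, 0.1)
})

test_that("swapping group labels negates logFC and swaps the census", {
  sim <- simulateDeCounts(nGenes = 400, fracDe = 0.15, phi = 0.1, seed = 92)
  ls <- colSums(sim$counts)
  a <- exactTestNb(sim$counts, sim$groups, phi = 0.1, libSizes = ls,
                   reference = "A")
  b <- exactTestNb(sim$counts, sim$groups, phi = 0.1, libSizes = ls,
                   reference = "B")
  expect_equal(a$logFC, -b$logFC)
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-12)
  ca <- attr(callDe(a), "census")
  cb <- attr(callDe(b), "census")
  expect_equal(unname(ca["n_up"]), unname(cb["n_down"]))
  expect_equal(unname(ca["n_down"]), unname(cb["n_up"]))
})

test_that("MDS separates groups and reproduces exact small distances", {
  set.seed(93)
  m <- matrix(rnbinom(1200, mu = 60, size = 10), 200, 6,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  dup <- m
  dup[, 2] <- dup[, 1]
  mdsDup <- mdsCoordinates(dup, topN = 100)
  expect_equal(mdsDup$dist[1, 2], 0)
  expect_equal(mdsDup$coords[1, ], mdsDup$coords[2, ], tolerance = 1e-9)

  sim <- simulateDeCounts(nGenes = 1000, fracDe = 0.3, lfc = 4, phi = 0.05,
                          seed = 94)
  mds <- mdsCoordinates(sim$counts, topN = 500)
  grp <- rep(c("A", "B"), each = 3)
  sep <- mean(mds$coords[grp == "A", 1]) - mean(mds$coords[grp == "B", 1])
  within <- max(stats::dist(mds$coords[grp == "A", 1]),
                stats::dist(mds$coords[grp == "B", 1]))
  expect_gt(abs(sep), within)
  expect_gt(mds$var_share[1], mds$var_share[2])

  # three samples: configuration reproduces the input distances exactly
  m3 <- m[, 1:3]
  mds3 <- mdsCoordinates(m3, topN = 50)
  rec <- as.matrix(stats::dist(mds3$coords))
  expect_equal(unname(rec), unname(mds3$dist), tolerance = 1e-6)
  expect_error(mdsCoordinates(m[, 1:2]), "3 samples")
})
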