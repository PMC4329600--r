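test_that("simulateKinship builds the requested family blocks", {
  expect_equal(kinshipValues(simulateKinship(simConfig(n = 5, familySize = 1))),
               diag(5))
  phi <- kinshipValues(simulateKinship(simConfig(n = 4, familySize = 2)))
  blk <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(phi[1:2, 1:2], blk)
  expect_equal(phi[3:4, 3:4], blk)
  expect_equal(phi[1:2, 3:4], matrix(0, 2, 2))
  ## remainder forms a smaller family
  phi5 <- kinshipValues(simulateKinship(simConfig(n = 5, familySize = 3)))
  expect_equal(phi5[4:5, 4:5], blk)
})

test_that("simulated kinships are positive definite (no clipping on decomposition)", {
  cfg <- simConfig(n = 30, familySize = 5)
  expect_no_warning(ek <- eigenKinship(simulateKinship(cfg)))
  expect_gt(min(eigenValues(ek)), 0)
})

test_that("with h2 = 0 phenotype draws are uncorrelated with unit-scale variance", {
  ## independent traits double as replicates: rows of t(Y) are iid N(0, I)
  cfg <- simConfig(n = 6, m = 2, t = 2000, familySize = 3,
                   h2 = 0, sigma2 = 1, seed = 77)
  dat <- simulateDataset(cfg)
  S <- cov(t(dat$phenotypes))
  expect_true(all(abs(diag(S) - 1) < 0.15))
  R <- cov2cor(S)
  expect_lt(max(abs(R[upper.tri(R)])), 0.05)
})

test_that("family pairs correlate at h2 / 2 under the block kinship", {
  cfg <- simConfig(n = 1000, m = 2, t = 20, familySize = 2,
                   h2 = rep(0.8, 20), seed = 101)
  phi <- simulateKinship(cfg)
  G <- simulateGenotypes(cfg)
  Y <- simulatePhenotypes(cfg, phi, G)
  odd <- seq(1, 999, by = 2)
  r <- cor(as.vector(Y[odd, ]), as.vector(Y[odd + 1, ]))
  expect_lt(abs(r - 0.4), 0.05)
})

test_that("the generator is seed-deterministic and trait streams are stable", {
  cfg <- simConfig(n = 40, m = 15, t = 3, seed = 55, h2 = rep(0.5, 3))
  a <- simulateDataset(cfg)
  b <- simulateDataset(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotypes, b$phenotypes)
  ## adding traits must not perturb existing traits or genotypes
  cfg5 <- simConfig(n = 40, m = 15, t = 5, seed = 55, h2 = rep(0.5, 5))
  c5 <- simulateDataset(cfg5)
  expect_identical(c5$genotypes, a$genotypes)
  expect_identical(c5$phenotypes[, 1:3], a$phenotypes)
})

test_that("degenerate generator settings are refused", {
  expect_error(simConfig(n = 50, h2 = 1), "h2")
  expect_error(simConfig(n = 50, causal = 5, gamma = numeric(0)), "gamma")
})

test_that("ratioTraits expands k base columns into k^2 traits", {
  base <- matrix(runif(12) + 0.5, 4, 3,
                 dimnames = list(NULL, c("A", "B", "C")))
  out <- ratioTraits(base)
  expect_identical(ncol(out), 9L)
  expect_identical(colnames(out),
                   c("A", "B", "C", "A/B", "A/C", "B/A", "B/C", "C/A", "C/B"))
  expect_equal(out[, "B/C"], base[, "B"] / base[, "C"])
  expect_equal(out[, 1:3], base)
  ## single column: no ratios
  expect_identical(ncol(ratioTraits(base[, 1, drop = FALSE])), 1L)
  bad <- base; bad[2, 3] <- 0
  expect_error(ratioTraits(bad), "row 2, column 3")
})

test_that("meanImpute fills gaps with the observed mean and only the gaps", {
  expect_equal(meanImpute(c(2, NA, 4)), c(2, 3, 4))
  y <- rnorm(10)
  expect_identical(meanImpute(y), y)
  y[c(2, 5)] <- NA
  z <- meanImpute(y)
  expect_equal(mean(z), mean(y, na.rm = TRUE))
  expect_identical(z[-c(2, 5)], y[-c(2, 5)])
  expect_error(meanImpute(c(NA_real_, NA)), "all values missing")
})

test_that("genomicKinship behaves like a standardized-dosage GRM", {
  set.seed(60)
  cfg <- simConfig(n = 200, m = 1000, seed = 3)
  G <- simulateGenotypes(cfg)
  phi <- genomicKinship(G)
  v <- kinshipValues(phi)
  expect_identical(v, t(v))
  expect_lt(abs(mean(diag(v)) - 1), 0.1)
  ## duplicated samples: off-diagonal equals the shared diagonal
  G2 <- rbind(G[1, , drop = FALSE], G[1, , drop = FALSE], G[2:20, ])
  v2 <- kinshipValues(suppressWarnings(genomicKinship(G2)))
  expect_equal(v2[1, 2], v2[1, 1], tolerance = 1e-12)
  ## monomorphic columns are dropped with a warning; all-monomorphic errors
  Gm <- G[1:20, 1:10]; Gm[, 1] <- 2
  expect_warning(genomicKinship(Gm), "monomorphic")
  expect_error(genomicKinship(matrix(1, 10, 5)), "monomorphic")
})

test_that("a causal SNP with noncentrality ~30 tops the scan in nearly every replicate", {
  n <- 300; m <- 500
  cfg0 <- simConfig(n = n, m = m, t = 1, h2 = 0.5, seed = 1)
  phi <- simulateKinship(cfg0)
  ek <- eigenKinship(phi)
  hits <- vapply(1:20, function(s) {
    cfgG <- simConfig(n = n, m = m, t = 1, h2 = 0.5, seed = s)
    G <- simulateGenotypes(cfgG)
    f <- mean(G[, 250]) / 2
    gam <- sqrt(30 / (n * 2 * f * (1 - f)))  # expected Wald chi2 about 30
    cfg <- simConfig(n = n, m = m, t = 1, h2 = 0.5, seed = s,
                     causal = 250L, gamma = gam)
    XL <- simulateCovariates(cfg)
    y <- simulatePhenotypes(cfg, phi, G, XL)[, 1]
    ve <- estimateH2(y, XL, ek)
    res <- runEigGwas(G, matrix(y, ncol = 1), XL, phi, list(ve), ek = ek)
    which.max(chiSquared(res)[, 1]) == 250L
  }, logical(1))
  expect_gte(sum(hits), 19L)
})
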