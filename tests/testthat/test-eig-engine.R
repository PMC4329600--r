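test_that("rotateMatrix is orthogonal and invertible", {
  ## identity kinship: any orthogonal eigenbasis is valid, so the rotation
  ## must be an isometry that the eigenvectors undo exactly
  ekI <- eigenKinship(diag(5))
  A <- matrix(rnorm(15), 5)
  RI <- rotateMatrix(ekI, A)
  expect_equal(eigenVectors(ekI) %*% RI, A)
  expect_equal(colSums(RI^2), colSums(A^2))
  set.seed(30)
  phi <- randomPSD(20)
  ek <- eigenKinship(phi)
  B <- matrix(rnorm(20 * 4), 20)
  R <- rotateMatrix(ek, B)
  expect_lt(abs(norm(R, "F") - norm(B, "F")) / norm(B, "F"), 1e-10)
  expect_lt(max(abs(eigenVectors(ek) %*% R - B)), 1e-8)
  expect_error(rotateMatrix(ek, matrix(1, 3, 2)), "dimension mismatch")
})

test_that("wlsSolve solves the diagonal-weight problem", {
  set.seed(31)
  n <- 20
  X <- randomDesign(n, 3); y <- rnorm(n)
  expect_lt(relDiff(wlsSolve(X, y, rep(1, n))$beta, lm.fit(X, y)$coefficients),
            1e-10)
  expect_equal(wlsSolve(matrix(1, 2, 1), c(2, 4), c(1, 0.25))$beta, 2.4)
  w <- runif(n, 0.2, 3)
  got <- wlsSolve(X, y, w)
  want <- glsOracle(X, y, diag(1 / w))
  expect_lt(relDiff(got$beta, want$beta), 1e-10)
  expect_lt(relDiff(got$se, want$se), 1e-10)
  expect_error(wlsSolve(X, y, c(-1, w[-1])), "positive")
})

test_that("runEigGwas fills every grid cell with the dense GLS solution", {
  set.seed(32)
  cfg <- simConfig(n = 30, m = 40, t = 6, p = 3,
                   h2 = c(0.2, 0.5, 0.7, 0, 0.4, 0.6), seed = 12)
  dat <- simulateDataset(cfg)
  ek <- eigenKinship(dat$phi)
  ves <- lapply(1:6, function(j) estimateH2(dat$phenotypes[, j], dat$XL, ek))
  res <- runEigGwas(dat$genotypes, dat$phenotypes, dat$XL, dat$phi, ves,
                    blockSize = 16, ek = ek)
  B <- effectArray(res); S <- seArray(res)
  for (j in 1:6) {
    M <- buildCovariance(kinshipValues(dat$phi), sigma2(ves[[j]]),
                         heritability(ves[[j]]))
    for (i in seq(1, 40, by = 7)) {
      want <- glsOracle(cbind(dat$XL, dat$genotypes[, i]),
                        dat$phenotypes[, j], M)
      expect_lt(relDiff(B[i, j, ], want$beta), 1e-8)
      expect_lt(relDiff(S[i, j, ], want$se), 1e-8)
    }
  }
})

test_that("with a single trait the two engines agree", {
  set.seed(33)
  cfg <- simConfig(n = 35, m = 25, t = 1, p = 3, h2 = 0.5, seed = 4)
  dat <- simulateDataset(cfg)
  ek <- eigenKinship(dat$phi)
  ve <- estimateH2(dat$phenotypes[, 1], dat$XL, ek)
  a <- runEigGwas(dat$genotypes, dat$phenotypes, dat$XL, dat$phi, list(ve),
                  ek = ek)
  b <- runCholGwas(dat$genotypes, dat$phenotypes[, 1], dat$XL, dat$phi, ve)
  expect_lt(relDiff(effectArray(a), effectArray(b)), 1e-8)
  expect_lt(relDiff(seArray(a), seArray(b)), 1e-8)
})

test_that("identical trait columns yield identical result slices", {
  set.seed(34)
  cfg <- simConfig(n = 30, m = 15, t = 2, h2 = c(0.3, 0.3), seed = 6)
  dat <- simulateDataset(cfg)
  Y <- dat$phenotypes
  Y[, 2] <- Y[, 1]
  ek <- eigenKinship(dat$phi)
  ves <- lapply(1:2, function(j) estimateH2(Y[, j], dat$XL, ek))
  res <- runEigGwas(dat$genotypes, Y, dat$XL, dat$phi, ves, ek = ek)
  expect_identical(effectArray(res)[, 1, ], effectArray(res)[, 2, ])
  expect_identical(chiSquared(res)[, 1], chiSquared(res)[, 2])
})

test_that("missing phenotypes are refused with a pointer to imputation", {
  cfg <- simConfig(n = 20, m = 5, t = 2, seed = 3)
  dat <- simulateDataset(cfg)
  Y <- dat$phenotypes; Y[4, 2] <- NA
  ek <- eigenKinship(dat$phi)
  ves <- lapply(1:2, function(j) estimateH2(dat$phenotypes[, j], dat$XL, ek))
  expect_error(runEigGwas(dat$genotypes, Y, dat$XL, dat$phi, ves, ek = ek),
               "meanImpute")
})

test_that("each genotype and trait column is rotated exactly once", {
  cfg <- simConfig(n = 25, m = 18, t = 4, h2 = rep(0.4, 4), seed = 8)
  dat <- simulateDataset(cfg)
  ek <- eigenKinship(dat$phi)
  ves <- lapply(1:4, function(j) estimateH2(dat$phenotypes[, j], dat$XL, ek))
  instrReset()
  runEigGwas(dat$genotypes, dat$phenotypes, dat$XL, dat$phi, ves,
             blockSize = 5, ek = ek)
  cols <- instrColCounts()
  instrReset()
  expect_identical(cols[["rotate_snp_cols"]], 18)
  expect_identical(cols[["rotate_trait_cols"]], 4)
})

test_that("eig scan output is bit-identical across block sizes", {
  set.seed(35)
  cfg <- simConfig(n = 30, m = 33, t = 3, h2 = rep(0.5, 3), seed = 10)
  dat <- simulateDataset(cfg)
  ek <- eigenKinship(dat$phi)
  ves <- lapply(1:3, function(j) estimateH2(dat$phenotypes[, j], dat$XL, ek))
  runs <- lapply(c(1, 7, 64), function(bs)
    runEigGwas(dat$genotypes, dat$phenotypes, dat$XL, dat$phi, ves,
               blockSize = bs, ek = ek))
  expect_identical(effectArray(runs[[1]]), effectArray(runs[[2]]))
  expect_identical(effectArray(runs[[1]]), effectArray(runs[[3]]))
  expect_identical(chiSquared(runs[[1]]), chiSquared(runs[[3]]))
})

test_that("counted operations scale linearly in traits and markers", {
  base <- countOperations(n = 30, m = 20, t = 4, p = 3, seed = 2)
  dbl_t <- countOperations(n = 30, m = 20, t = 8, p = 3, seed = 2)
  dbl_m <- countOperations(n = 30, m = 40, t = 4, p = 3, seed = 2)
  r_t <- dbl_t$eig[["wls"]] / base$eig[["wls"]]
  expect_gte(r_t, 1.9); expect_lte(r_t, 2.1)
  ## SNP-rotation share of the rotation phase grows linearly in m
  rot_m <- (dbl_m$eig[["rotate"]] - base$eig[["rotate"]])
  expect_equal(rot_m, 20 * 30^2)  # 20 extra columns of length 30
})
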