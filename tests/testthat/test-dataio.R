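test_that("TSV matrices round-trip with values and labels", {
  set.seed(40)
  x <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("S", 1:10), paste0("C", 1:4)))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeMatrixFile(x, path, "tsv")
  y <- readMatrixFile(path)
  expect_equal(unname(y), unname(x), tolerance = 1e-12)
  expect_identical(dimnames(y), dimnames(x))
})

test_that("binary matrices round-trip bit-identically", {
  set.seed(41)
  x <- matrix(rnorm(100 * 100), 100)
  path <- withr::local_tempfile(fileext = ".mmg")
  writeMatrixFile(x, path, "binary")
  y <- readMatrixFile(path)
  expect_identical(as.vector(y), as.vector(x))
})

test_that("reader validation: dosage bounds warn, bad cells and ids error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  g <- matrix(c(0, 1, 2, 3.5), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  writeMatrixFile(g, path, "tsv")
  expect_warning(got <- readMatrixFile(path, role = "genotype"),
                 "outside \\[0, 2\\]")
  expect_equal(got[2, 2], 3.5)  # retained, not clipped

  writeLines(c("id\tc1", "a\t1", "a\t2"), path)
  expect_error(readMatrixFile(path), "duplicate")

  writeLines(c("id\tc1", "a\t1", "b\tx"), path)
  expect_error(readMatrixFile(path), "non-numeric")
})

test_that("MMG1 payload size must match the declared dimensions", {
  path <- withr::local_tempfile(fileext = ".mmg")
  writeMatrixFile(matrix(1:6, 2), path, "binary")
  size <- file.size(path)
  ## truncate the payload
  con <- file(path, "r+b")
  truncate_at <- size - 8
  seek(con, truncate_at); truncate(con); close(con)
  expect_error(readMatrixFile(path), "dimension mismatch")
})

test_that("blockIterator partitions columns exactly once, in order", {
  x <- matrix(seq_len(50), 5, 10)
  it <- blockIterator(x, 3)
  sizes <- integer(0); cols <- integer(0); parts <- list()
  repeat {
    blk <- it$nextBlock()
    if (is.null(blk)) break
    sizes <- c(sizes, length(blk$cols))
    cols <- c(cols, blk$cols)
    parts <- c(parts, list(blk$values))
  }
  expect_identical(sizes, c(3L, 3L, 3L, 1L))
  expect_identical(cols, 1:10)
  expect_identical(do.call(cbind, parts), x)
})

test_that("file-backed block streaming matches the in-memory matrix and flags truncation", {
  set.seed(42)
  x <- matrix(rnorm(8 * 11), 8, 11)
  path <- withr::local_tempfile(fileext = ".mmg")
  writeMatrixFile(x, path, "binary")
  it <- blockIterator(path, 4)
  expect_identical(it$n, 8)
  got <- list()
  repeat {
    blk <- it$nextBlock()
    if (is.null(blk)) break
    got <- c(got, list(blk$values))
  }
  expect_identical(do.call(cbind, got), x)

  ## truncated mid-stream: the error names the byte offset
  con <- file(path, "r+b")
  seek(con, file.size(path) - 16); truncate(con); close(con)
  it2 <- blockIterator(path, 11)
  expect_error(it2$nextBlock(), "byte offset [0-9]+")
})

test_that("result cubes round-trip bit-identically through the binary format", {
  cfg <- simConfig(n = 25, m = 8, t = 3, h2 = rep(0.4, 3), seed = 13)
  dat <- simulateDataset(cfg)
  G <- dat$genotypes
  G[, 5] <- 2  # monomorphic -> NaN cells survive the round trip
  ek <- eigenKinship(dat$phi)
  ves <- lapply(1:3, function(j) estimateH2(dat$phenotypes[, j], dat$XL, ek))
  res <- runEigGwas(G, dat$phenotypes, dat$XL, dat$phi, ves, ek = ek)
  path <- withr::local_tempfile(fileext = ".cube")
  writeCube(res, path)
  back <- readCube(path)
  expect_identical(effectArray(back), effectArray(res))
  expect_identical(seArray(back), seArray(res))
  expect_identical(chiSquared(back), chiSquared(res))
  expect_identical(snpIds(back), snpIds(res))
  expect_identical(coefNames(back), coefNames(res))
})

test_that("TSV export is long format with NA for degenerate cells", {
  cfg <- simConfig(n = 20, m = 6, t = 2, h2 = c(0.3, 0.3), seed = 19)
  dat <- simulateDataset(cfg)
  G <- dat$genotypes
  G[, 3] <- 0
  ek <- eigenKinship(dat$phi)
  ves <- lapply(1:2, function(j) estimateH2(dat$phenotypes[, j], dat$XL, ek))
  res <- runEigGwas(G, dat$phenotypes, dat$XL, dat$phi, ves, ek = ek)
  path <- withr::local_tempfile(fileext = ".tsv")
  exportCubeTSV(res, path)
  tab <- read.delim(path)
  p <- length(coefNames(res))
  expect_identical(nrow(tab), 6L * 2L * p)
  expect_true(all(is.na(tab$beta[tab$snp_id == "snp3"])))
  expect_true(all(c("snp_id", "trait_id", "coefficient", "beta", "se",
                    "chi2", "pvalue") %in% names(tab)))
})

test_that("the command-line pipeline runs end to end and rejects reordered samples", {
  dir <- withr::local_tempdir()
  expect_identical(cliMain(c("simulate", "--n", "30", "--m", "12", "--t", "2",
                             "--seed", "5", "--out-dir", dir)), 0L)
  cube <- file.path(dir, "results.cube")
  expect_identical(cliMain(c("gwas",
                             "--genotypes", file.path(dir, "genotypes.tsv"),
                             "--phenotypes", file.path(dir, "phenotypes.tsv"),
                             "--covariates", file.path(dir, "covariates.tsv"),
                             "--kinship", file.path(dir, "kinship.tsv"),
                             "--engine", "eig", "--out", cube)), 0L)
  res <- readCube(cube)
  expect_identical(dim(res), c(12L, 2L))

  out <- file.path(dir, "out.tsv")
  expect_identical(cliMain(c("export", "--cube", cube, "--out", out)), 0L)
  expect_true(file.exists(out))

  ## silently reordered samples must be an error, never an implicit join
  ph <- readMatrixFile(file.path(dir, "phenotypes.tsv"))
  ph <- ph[rev(seq_len(nrow(ph))), , drop = FALSE]
  writeMatrixFile(ph, file.path(dir, "phenotypes.tsv"), "tsv")
  expect_error(cliMain(c("gwas",
                         "--genotypes", file.path(dir, "genotypes.tsv"),
                         "--phenotypes", file.path(dir, "phenotypes.tsv"),
                         "--covariates", file.path(dir, "covariates.tsv"),
                         "--kinship", file.path(dir, "kinship.tsv"),
                         "--engine", "chol", "--out", cube)),
               "never reordered")
})

test_that("h2 estimation subcommand writes the per-trait table", {
  dir <- withr::local_tempdir()
  cliMain(c("simulate", "--n", "40", "--m", "10", "--t", "3",
            "--seed", "9", "--out-dir", dir))
  out <- file.path(dir, "h2.tsv")
  expect_identical(cliMain(c("estimate-h2",
                             "--phenotypes", file.path(dir, "phenotypes.tsv"),
                             "--covariates", file.path(dir, "covariates.tsv"),
                             "--kinship", file.path(dir, "kinship.tsv"),
                             "--out", out)), 0L)
  tab <- read.delim(out)
  expect_identical(nrow(tab), 3L)
  expect_true(all(c("trait_id", "sigma2", "h2", "loglik", "n_iter")
                  %in% names(tab)))
  expect_true(all(tab$h2 >= 0 & tab$h2 < 1))
})
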