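test_that("computeMAF folds to the minor allele and flags the flip", {
  expect_equal(as.numeric(computeMAF(c(1, 1, 1))), 0.5)
  expect_equal(as.numeric(computeMAF(c(0, 0, 1))), 1 / 6)
  m <- computeMAF(c(2, 2, 1))
  expect_equal(as.numeric(m), 1 / 6)
  expect_true(attr(m, "flipped"))
  expect_false(attr(computeMAF(c(0, 0, 1)), "flipped"))
  expect_error(computeMAF(numeric()), "empty")
})

test_that("HWE exact test matches convention and enumeration oracle", {
  expect_equal(hweExactTest(10, 0, 0), 1)          # monomorphic
  expect_equal(hweExactTest(25, 50, 25), 1)        # modal configuration
  expect_lt(hweExactTest(0, 68, 0), 1e-6)          # all-heterozygote tail
  expect_error(hweExactTest(-1, 2, 3), "non-negative")

  # exhaustive cross-check against the closed-form enumeration oracle
  for (n in c(5, 9, 14)) {
    for (nAA in 0:n) for (nAa in 0:(n - nAA)) {
      naa <- n - nAA - nAa
      expect_equal(hweExactTest(nAA, nAa, naa), hweOracle(nAA, nAa, naa),
                   tolerance = 1e-12,
                   info = sprintf("(%d,%d,%d)", nAA, nAa, naa))
    }
  }
})

test_that("snpFilter drops SNPs below the MAF and HWE thresholds", {
  d <- rbind(
    c(rep(0, 48), rep(1, 2)),   # maf 0.02: below 5%
    rep(1, 50),                 # all heterozygous: HWE violation
    c(rep(0, 30), rep(1, 15), rep(2, 5)))  # maf 0.25, in HWE
  rownames(d) <- c("1:100", "1:200", "1:300")
  colnames(d) <- sprintf("S%02d", 1:50)
  gm <- GenotypeMatrix(d)
  out <- suppressMessages(snpFilter(gm))
  expect_identical(rownames(out), "1:300")
  expect_identical(unname(attr(out, "removed")["maf"]), 1L)
  cfgAll <- AnalysisConfig(mafMin = 0.4, hwePMin = 0.5)
  expect_warning(suppressMessages(snpFilter(gm, cfgAll)), "empty panel")
})

test_that("regressTrait handles exact fits, orthogonal traits and degeneracy", {
  x <- c(0, 1, 2, 0, 1, 2, 1, 0, 2, 1)
  r <- regressTrait(x, x)
  expect_equal(r$r2, 1)
  expect_lt(r$p, 1e-15)

  # orthogonal trait: slope exactly 0
  y <- rnorm(10)
  y <- residuals(lm(y ~ x))
  r0 <- regressTrait(x, y)
  expect_equal(r0$beta, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1)

  rc <- regressTrait(rep(1, 10), rnorm(10))
  expect_true(rc$degenerate)
  expect_equal(rc$p, 1)
})

test_that("regressTrait matches the independent least-squares oracle", {
  set.seed(99)
  for (i in 1:100) {
    x <- rbinom(20, 2, runif(1, 0.1, 0.5))
    if (sd(x) == 0) next
    y <- rnorm(20) + 0.3 * x
    y[sample(20, rbinom(1, 3, 0.5))] <- NA
    got <- regressTrait(x, y)
    if (got$degenerate) next
    want <- olsOracle(x, y)
    expect_equal(got$beta, want$beta, tolerance = 1e-10)
    expect_equal(got$se, want$se, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_equal(got$r2, got$t^2 / (got$t^2 + got$n - 2), tolerance = 1e-9)
  }
})

test_that("associationScan agrees with per-pair regression and aligns samples", {
  gm <- makePanel(nSamples = 25, nSnps = 6, seed = 17)
  set.seed(17)
  traits <- matrix(rnorm(25 * 3), 25, 3,
                   dimnames = list(colnames(gm), c("tA", "tB", "tC")))
  traits[3, 1] <- NA
  scan <- associationScan(gm, traits)
  expect_identical(nrow(scan), 18L)
  for (k in c(1, 7, 18)) {
    row <- scan[k, ]
    single <- regressTrait(dosages(gm)[row$snp_id, ], traits[, row$trait_id])
    expect_equal(row$beta, single$beta, tolerance = 1e-12)
    expect_equal(row$p, single$p, tolerance = 1e-12)
  }
  # shuffled sample order must give identical results
  scan2 <- associationScan(gm, traits[sample(rownames(traits)), ])
  expect_equal(scan2$p, scan$p, tolerance = 1e-12)
  # unknown sample ids are an alignment error
  rownames(traits)[1] <- "NOT_A_SAMPLE"
  expect_error(associationScan(gm, traits), "sample-id mismatch")
  # empty trait matrix: empty result, no error
  empty <- associationScan(gm, matrix(numeric(), nrow = 25, ncol = 0))
  expect_identical(nrow(empty), 0L)
})

test_that("a planted effect dominates the scan minimum", {
  wins <- vapply(1:60, function(i) {
    cfg <- SimulationConfig(
      nSamples = 68, nSnps = 100, nGenes = 20,
      plantedEffects = plantedEffect("1:1000", "gene", "gene0001", 0.36),
      seed = 5000 + i)
    co <- simulateCohort(cfg)
    scan <- associationScan(co$genotypes, co$expression)
    top <- scan[which.min(scan$p), ]
    top$snp_id == "1:1000" && top$trait_id == "gene0001"
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("ldR2 is the squared dosage correlation", {
  g <- c(0, 1, 2, 1, 0, 2, 1, 1, 0, 2)
  expect_equal(as.numeric(ldR2(g, g)), 1)
  expect_equal(as.numeric(ldR2(g, 2 - g)), 1)  # complementary coding
  set.seed(31)
  a <- rbinom(10000, 2, 0.3); b <- rbinom(10000, 2, 0.3)
  expect_lt(ldR2(a, b), 0.01)
  const <- ldR2(rep(1, 10), g)
  expect_true(is.na(const))
  expect_true(attr(const, "undefined"))
})

test_that("greedy LD pruning keeps the best SNP per correlated cluster", {
  set.seed(7)
  base <- rbinom(60, 2, 0.4)
  d <- rbind(base, base, rbinom(60, 2, 0.4))
  rownames(d) <- c("1:1000", "1:2000", "1:900000")
  colnames(d) <- sprintf("S%02d", 1:60)
  gm <- GenotypeMatrix(d)
  cand <- data.frame(snp_id = c("1:2000", "1:1000", "1:900000"),
                     p = c(1e-4, 1e-5, 5e-3))
  kept <- ldPrune(cand, gm)
  expect_identical(kept, c("1:1000", "1:900000"))
  expect_identical(ldPrune(cand, gm), kept)  # deterministic

  # no LD: everything is retained
  gmInd <- makePanel(nSamples = 80, nSnps = 4, seed = 3)
  candInd <- data.frame(snp_id = rownames(gmInd), p = c(0.2, 0.1, 0.3, 0.05))
  expect_setequal(ldPrune(candInd, gmInd), rownames(gmInd))

  # retained pairs within the window satisfy the r2 bound
  gm2 <- simulateGenotypes(SimulationConfig(
    nSamples = 100, nSnps = 30, mafSpec = rep(0.3, 30),
    ldBlocks = data.frame(size = c(10, 10), r = 0.9), seed = 21))
  cand2 <- data.frame(snp_id = rownames(gm2), p = runif(30))
  kept2 <- ldPrune(cand2, gm2)
  D <- dosages(gm2)
  pos <- snpInfo(gm2)$pos
  for (a in seq_along(kept2)) for (b in seq_len(a - 1)) {
    ia <- kept2[a]; ib <- kept2[b]
    if (abs(pos[match(ia, rownames(gm2))] - pos[match(ib, rownames(gm2))]) <= 1e6)
      expect_lte(as.numeric(ldR2(D[ia, ], D[ib, ])), 0.2)
  }
})

test_that("QTL classification applies the scan thresholds", {
  mkScan <- function(snp, trait, p)
    data.frame(snp_id = snp, trait_id = trait, n = 68, beta = 1, se = 1,
               t = 1, r2 = 0.1, p = p, degenerate = FALSE)
  pheno <- mkScan(c("s1", "s2", "s3"), "log2_ic50", c(0.0009, 0.002, 0.5))
  expr <- rbind(mkScan(c("s1", "s2", "s3"), "g1", c(5e-5, 2e-4, 0.9)),
                mkScan(c("s1", "s2", "s3"), "g2", c(0.5, 0.5, 0.5)))
  qt <- classifyQTLs(pheno, expr)
  expect_identical(qt$is_dqtl, c(TRUE, FALSE, FALSE))
  expect_identical(qt$is_eqtl, c(TRUE, FALSE, FALSE))  # 2e-4 misses 1e-4
  expect_identical(qt$eqtl_best_trait[1], "g1")
  expect_true(all(is.na(qt$is_pqtl)))
})

test_that("Benjamini-Hochberg matches the step-up definition", {
  r <- bhFDR(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
  expect_identical(sort(r$rejected), 1:3)  # 0.03 <= 3 * 0.05 / 4
  expect_identical(bhFDR(rep(0.9, 10), 0.05)$rejected, integer())
  expect_identical(bhFDR(numeric(), 0.05)$rejected, integer())
  set.seed(12)
  for (i in 1:50) {
    p <- runif(rpois(1, 20) + 1)^rexp(1, 0.5)
    expect_identical(sort(bhFDR(p, 0.05)$rejected), bhOracle(p, 0.05))
  }
})

test_that("qqPoints pairs sorted observations with i/(m+1) quantiles", {
  m <- 9
  grid <- (1:m) / (m + 1)
  qq <- qqPoints(sample(grid))
  expect_equal(qq$observed, qq$expected)
  one <- qqPoints(0.5)
  expect_equal(one$expected, -log10(0.5))
  expect_warning(qq0 <- qqPoints(c(0, 0.5)), "clipped")
  expect_true(all(is.finite(qq0$observed)))
  expect_error(qqPoints(numeric()), "empty")
})

test_that("protein-phenotype scan controls FDR and reports q-q points", {
  set.seed(44)
  n <- 68
  pheno <- rnorm(n); names(pheno) <- sprintf("S%03d", 1:n)
  prot <- matrix(rnorm(n * 30), n, 30,
                 dimnames = list(names(pheno), sprintf("p%02d", 1:30)))
  prot[, 1] <- pheno + rnorm(n, 0, 0.4)  # one strongly associated protein
  out <- proteinPhenotypeScan(prot, pheno)
  expect_true(out$results$fdr_reject[out$results$feature_id == "p01"])
  expect_lte(sum(out$results$fdr_reject), 3)
  expect_identical(nrow(out$qq), 30L)
})
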