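test_that("null sets match the target's per-bin MAF histogram exactly", {
  gm <- simulateGenotypes(SimulationConfig(nSamples = 200, nSnps = 400,
                                           seed = 13))
  target <- rownames(gm)[c(1:20, 101:110)]
  cfg <- AnalysisConfig(nPermutations = 100)
  sets <- mafMatchedNullSets(target, gm, cfg, seed = 5)
  expect_length(sets, 100)
  maf <- setNames(snpInfo(gm)$maf, rownames(gm))
  binOf <- function(ids) table(factor(floor(maf[ids] / 0.02), levels = 0:25))
  targetHist <- binOf(target)
  for (s in sets[c(1, 50, 100)]) {
    expect_length(s, length(target))
    expect_identical(binOf(s), targetHist)
  }
  expect_identical(mafMatchedNullSets(target, gm, cfg, seed = 5), sets)
  expect_false(identical(mafMatchedNullSets(target, gm, cfg, seed = 6), sets))
})

test_that("infeasible MAF matching names the offending bin", {
  # MAFs 0.25, 0.45, 0.10: three singleton bins at width 0.02
  d <- rbind(rep(c(0L, 1L), 10),
             c(rep(1L, 18), 0L, 0L),
             c(rep(0L, 16), rep(1L, 4)))
  rownames(d) <- c("1:1", "1:2", "1:3"); colnames(d) <- sprintf("S%02d", 1:20)
  gm <- GenotypeMatrix(d)
  # a target demanding two draws from the singleton 0.25 bin cannot match
  expect_error(
    mafMatchedNullSets(c("1:1", "1:1"), gm,
                       AnalysisConfig(nPermutations = 100), 1),
    "infeasible.*0.240")
  # matching the full universe is feasible and exact
  sets <- mafMatchedNullSets(rownames(gm), gm,
                             AnalysisConfig(nPermutations = 100), 1)
  expect_true(all(vapply(sets, setequal, logical(1), rownames(gm))))
})

test_that("empirical enrichment p is add-one smoothed and monotone", {
  nulls <- rep(0:9, 100)  # B = 1000
  expect_equal(empiricalP(empiricalEnrichmentP(10, nulls)), 1 / 1001)
  expect_equal(empiricalP(empiricalEnrichmentP(-1, nulls)), 1)
  med <- empiricalEnrichmentP(5, nulls)
  expect_gt(empiricalP(med), 0.4)
  expect_lt(empiricalP(med), 0.6)
  ps <- vapply(0:10, function(o) empiricalP(empiricalEnrichmentP(o, nulls)),
               numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(empiricalEnrichmentP(3, rep(1, 50)), "100")
})

test_that("countQTLs is additive and rejects unknown SNPs", {
  qt <- data.frame(snp_id = sprintf("s%d", 1:10),
                   is_eqtl = rep(c(TRUE, FALSE), 5))
  expect_identical(countQTLs(character(), qt, "eqtl"), 0L)
  expect_identical(countQTLs(qt$snp_id[qt$is_eqtl], qt, "eqtl"), 5L)
  a <- countQTLs(sprintf("s%d", 1:4), qt, "eqtl")
  b <- countQTLs(sprintf("s%d", 5:10), qt, "eqtl")
  expect_identical(a + b, countQTLs(qt$snp_id, qt, "eqtl"))
  expect_error(countQTLs("nope", qt, "eqtl"), "unknown SNP")
})

test_that("protein residualization adjusts, falls back, and stays orthogonal", {
  set.seed(88)
  mrna <- rnorm(68)
  rr <- residualizeProteinOnMrna(2 * mrna, mrna)
  expect_identical(rr$status, "adjusted")
  expect_true(all(abs(rr$residuals) < 1e-10))

  prot <- rnorm(68) + 0.5 * mrna
  rr2 <- residualizeProteinOnMrna(prot, mrna)
  expect_lt(abs(sum(rr2$residuals * (mrna - mean(mrna)))), 1e-8)

  # mRNA detected in 3 of 68 samples: unadjusted, centered protein
  sparse <- rep(NA_real_, 68); sparse[1:3] <- rnorm(3)
  rr3 <- residualizeProteinOnMrna(prot, sparse)
  expect_identical(rr3$status, "unadjusted_mrna_missing")
  expect_equal(rr3$residuals, prot - mean(prot))

  expect_warning(rr4 <- residualizeProteinOnMrna(prot, rep(1, 68)),
                 "constant")
  expect_identical(rr4$status, "unadjusted_mrna_missing")
})

test_that("the residual scan separates direct from mediated protein QTLs", {
  flagOne <- function(mode, v, seed) {
    cfg <- SimulationConfig(
      nSamples = 68, nSnps = 1, mafSpec = 0.3, nGenes = 1, nProteins = 1,
      plantedEffects = rbind(
        if (mode == "mediated")
          plantedEffect("1:1000", "gene", "gene0001", 0.3),
        plantedEffect("1:1000", "protein", "prot0001", v, mode = mode)),
      seed = seed)
    co <- simulateCohort(cfg)
    out <- mrnaIndependentPqtlScan(co$genotypes, co$proteins, co$expression)
    out$qtls$is_mrna_independent_pqtl[1]
  }
  direct <- vapply(1:60, function(i) flagOne("direct", 0.21, 7000 + i),
                   logical(1))
  mediated <- vapply(1:60, function(i) flagOne("mediated", 0.3, 8000 + i),
                     logical(1))
  # analytic power at the 1e-4 call threshold is ~0.5 for R^2 = 0.21 at
  # n = 68; require well above the null rate without overclaiming
  expect_gte(mean(direct), 0.25)
  expect_lte(mean(mediated), 0.05)
})

test_that("proteins without expression data are scanned unadjusted and labeled", {
  cfg <- SimulationConfig(nSamples = 30, nSnps = 2, mafSpec = c(0.2, 0.4),
                          nGenes = 1, nProteins = 2, seed = 19)
  co <- simulateCohort(cfg)
  out <- mrnaIndependentPqtlScan(co$genotypes, co$proteins, expression = NULL)
  expect_true(all(out$status == "unadjusted_mrna_missing"))
  expect_true(all(out$results$adjustment_status == "unadjusted_mrna_missing"))
})

test_that("enrichmentTest reports the boundary p when the signal is planted", {
  gm <- simulateGenotypes(SimulationConfig(nSamples = 100, nSnps = 300,
                                           seed = 23))
  qt <- data.frame(snp_id = rownames(gm),
                   is_eqtl = c(rep(TRUE, 30), rep(FALSE, 270)))
  er <- enrichmentTest(rownames(gm)[1:30], qt, gm, "eqtl",
                       AnalysisConfig(nPermutations = 500), seed = 2)
  expect_identical(observedCount(er), 30L)
  expect_lte(empiricalP(er), 0.01)
  expect_identical(length(nullCounts(er)), 500L)
})
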