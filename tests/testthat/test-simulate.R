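test_that("genotype generator is deterministic and matches its sampling model", {
  cfg <- SimulationConfig(nSamples = 10000, nSnps = 1, mafSpec = 0.5, seed = 3)
  gm1 <- simulateGenotypes(cfg)
  gm2 <- simulateGenotypes(cfg)
  expect_identical(dosages(gm1), dosages(gm2))
  # binomial(2, 0.5) sampling: mean dosage near 1
  expect_gt(mean(dosages(gm1)), 0.97)
  expect_lt(mean(dosages(gm1)), 1.03)

  gm3 <- simulateGenotypes(SimulationConfig(nSamples = 10000, nSnps = 1,
                                            mafSpec = 0.5, seed = 4))
  expect_false(identical(dosages(gm1), dosages(gm3)))
})

test_that("invalid simulation configs are rejected", {
  expect_error(SimulationConfig(nSamples = 2), "n_samples")
  expect_error(SimulationConfig(mafSpec = numeric()), "MAF")
  expect_error(SimulationConfig(mafSpec = 0.02), "0.05")
  expect_error(SimulationConfig(concentrations = c(100, 50)), "increasing")
  expect_error(SimulationConfig(hillSlope = -1), "hill")
  expect_error(SimulationConfig(
    nSnps = 2, plantedEffects = plantedEffect("1:1000", "phenotype",
                                              "log2_ic50", 1.2)),
    "variance_explained")
})

test_that("generated genotypes conform to Hardy-Weinberg equilibrium", {
  gm <- simulateGenotypes(SimulationConfig(nSamples = 1000, nSnps = 1000,
                                           mafSpec = 0.3, seed = 5))
  expect_gte(mean(snpInfo(gm)$hwe_p >= 0.001), 0.99)
})

test_that("LD blocks correlate SNPs within but not across blocks", {
  cfg <- SimulationConfig(nSamples = 2000, nSnps = 6, mafSpec = rep(0.3, 6),
                          ldBlocks = data.frame(size = c(3), r = 0.9),
                          seed = 8)
  D <- dosages(simulateGenotypes(cfg))
  expect_gt(cor(D[1, ], D[2, ])^2, 0.4)   # within block
  expect_lt(cor(D[1, ], D[5, ])^2, 0.01)  # across blocks
})

test_that("null expression R2 sits at 1/(n-1) and planted effects recover their target", {
  # null: mean in-sample R2 of SNP-gene regressions ~ 1/(n-1) = 0.0149
  cfg <- SimulationConfig(nSamples = 68, nSnps = 100, nGenes = 100, seed = 11)
  gm <- simulateGenotypes(cfg)
  ex <- simulateExpression(gm, cfg)
  scan <- associationScan(gm, ex$expression)  # 10,000 null pairs
  expect_gt(mean(scan$r2), 0.012)
  expect_lt(mean(scan$r2), 0.018)

  # planted variance_explained 0.36 at n = 68: mean realized R2 in [0.33, 0.43]
  r2 <- vapply(1:300, function(i) {
    cfg <- SimulationConfig(
      nSamples = 68, nSnps = 1, mafSpec = 0.3, nGenes = 1,
      plantedEffects = plantedEffect("1:1000", "gene", "gene0001", 0.36),
      seed = 1000 + i)
    gm <- simulateGenotypes(cfg)
    ex <- simulateExpression(gm, cfg)
    regressTrait(dosages(gm)[1, ],
                 SummarizedExperiment::assay(ex$expression)[1, ])$r2
  }, numeric(1))
  expect_gt(mean(r2), 0.33)
  expect_lt(mean(r2), 0.43)
})

test_that("undetected genes are missing in all but the configured handful", {
  cfg <- SimulationConfig(nSamples = 68, nSnps = 2, mafSpec = c(0.2, 0.3),
                          nGenes = 3, undetectedGenes = "gene0002", seed = 2)
  gm <- simulateGenotypes(cfg)
  E <- SummarizedExperiment::assay(simulateExpression(gm, cfg)$expression)
  expect_identical(sum(is.na(E["gene0002", ])), 68L - 3L)
  expect_identical(sum(is.na(E["gene0001", ])), 0L)
})

test_that("planted effects on unknown SNPs or genes are rejected", {
  cfg <- SimulationConfig(nSamples = 10, nSnps = 2, mafSpec = c(0.2, 0.3),
                          nGenes = 1,
                          plantedEffects = plantedEffect("1:99999", "gene",
                                                         "gene0001", 0.3),
                          seed = 1)
  gm <- simulateGenotypes(cfg)
  expect_error(simulateExpression(gm, cfg), "unknown SNP")
})

test_that("variance bookkeeping is exact in the generating population", {
  cfg <- SimulationConfig(
    nSamples = 20, nSnps = 3, mafSpec = c(0.1, 0.25, 0.4),
    nGenes = 2, nProteins = 2,
    plantedEffects = rbind(
      plantedEffect("1:1000", "phenotype", "log2_ic50", 0.36),
      plantedEffect("1:2000", "gene", "gene0001", 0.3, sign = -1),
      plantedEffect("1:2000", "protein", "prot0001", 0.25, mode = "mediated"),
      plantedEffect("1:3000", "protein", "prot0002", 0.21, mode = "direct")),
    seed = 6)
  co <- simulateCohort(cfg)
  eff <- truthEffects(co$truth)
  expect_identical(nrow(eff), 4L)
  expect_true(all(abs(eff$genetic_var / eff$trait_var -
                        eff$variance_explained) < 1e-12))
  expect_equal(plantedVariance(co$truth, "1:2000", "gene0001"), 0.3)
  expect_equal(plantedVariance(co$truth, "1:9999", "geneX"), 0)
})

test_that("mediated proteins lose their signal in mRNA residuals; direct ones keep it", {
  # zero protein noise, mediated: protein is an exact multiple of mRNA,
  # so mRNA residuals are identically zero
  cfg <- SimulationConfig(
    nSamples = 40, nSnps = 1, mafSpec = 0.3, nGenes = 1, nProteins = 1,
    plantedEffects = rbind(
      plantedEffect("1:1000", "gene", "gene0001", 0.3),
      plantedEffect("1:1000", "protein", "prot0001", 0.5, mode = "mediated")),
    proteinNoiseSd = 0, seed = 9)
  gm <- simulateGenotypes(cfg)
  ex <- simulateExpression(gm, cfg)
  pr <- simulateProteins(gm, ex$expression, cfg)
  p <- SummarizedExperiment::assay(pr$proteins)[1, ]
  m <- SummarizedExperiment::assay(ex$expression)[1, ]
  rr <- residualizeProteinOnMrna(p, m)
  expect_true(all(abs(rr$residuals) < 1e-10))
  expect_equal(regressTrait(dosages(gm)[1, ], rr$residuals)$r2, 0,
               tolerance = 1e-9)
})

test_that("direct protein effects reach their target R2 and stay out of mRNA", {
  r2p <- r2m <- numeric(200)
  for (i in 1:200) {
    cfg <- SimulationConfig(
      nSamples = 68, nSnps = 1, mafSpec = 0.3, nGenes = 1, nProteins = 1,
      plantedEffects = plantedEffect("1:1000", "protein", "prot0001", 0.21,
                                     mode = "direct"),
      seed = 3000 + i)
    gm <- simulateGenotypes(cfg)
    ex <- simulateExpression(gm, cfg)
    pr <- simulateProteins(gm, ex$expression, cfg)
    r2p[i] <- regressTrait(dosages(gm)[1, ],
                           SummarizedExperiment::assay(pr$proteins)[1, ])$r2
    r2m[i] <- regressTrait(dosages(gm)[1, ],
                           SummarizedExperiment::assay(ex$expression)[1, ])$r2
  }
  expect_gt(mean(r2p), 0.18)
  expect_lt(mean(r2p), 0.28)
  expect_lt(mean(r2m), 0.05)  # null level ~ 1/(n-1)
})

test_that("isoform pairs require opposite-sign planted effects", {
  mkCfg <- function(signB) SimulationConfig(
    nSamples = 10, nSnps = 1, mafSpec = 0.3, nGenes = 1, nProteins = 2,
    proteinGeneMap = data.frame(
      protein_id = c("gene0001|38kDa", "gene0001|75kDa"),
      gene_id = "gene0001", isoform = c("38kDa", "75kDa")),
    plantedEffects = rbind(
      plantedEffect("1:1000", "protein", "gene0001|38kDa", 0.2,
                    sign = 1, mode = "direct"),
      plantedEffect("1:1000", "protein", "gene0001|75kDa", 0.2,
                    sign = signB, mode = "direct")),
    isoformPairs = list(c("gene0001|38kDa", "gene0001|75kDa")), seed = 4)
  expect_error(mkCfg(1), "opposite sign")
  cfg <- mkCfg(-1)
  gm <- simulateGenotypes(cfg)
  ex <- simulateExpression(gm, cfg)
  pr <- simulateProteins(gm, ex$expression, cfg)
  eff <- truthEffects(pr$truth)
  expect_identical(sign(eff$beta[1]) * sign(eff$beta[2]), -1)
})

test_that("mediated effects cannot route through an undetected gene", {
  expect_error(SimulationConfig(
    nSamples = 10, nSnps = 1, mafSpec = 0.3, nGenes = 1, nProteins = 1,
    undetectedGenes = "gene0001",
    plantedEffects = rbind(
      plantedEffect("1:1000", "gene", "gene0001", 0.3),
      plantedEffect("1:1000", "protein", "prot0001", 0.3, mode = "mediated")),
    seed = 1), "mediator must exist")
})

test_that("dose-response curves hit their logistic midpoint and default IC50", {
  cfg <- SimulationConfig(nSamples = 5, nSnps = 1, mafSpec = 0.3,
                          survivalNoiseSd = 0, log2Ic50Sd = 0, seed = 12)
  gm <- simulateGenotypes(cfg)
  dr <- simulateDoseResponse(gm, cfg)
  # no planted effects, zero noise: every true IC50 is the 176.5 uM default
  expect_true(all(abs(truthPhenotype(dr$truth)$ic50 - 176.5) < 1e-9))
  # survival at c = IC50 is exactly 50% (logistic midpoint); 175 uM is on
  # the grid and close: check the exact midpoint via the model directly
  s <- dr$doseResponse
  surv175 <- s$pct_survival[s$concentration_uM == 175]
  expect_true(all(abs(surv175 - 100 / (1 + (175 / 176.5)^cfg@hillSlope)) < 1e-9))

  dr2 <- simulateDoseResponse(gm, cfg)
  expect_identical(dr$doseResponse, dr2$doseResponse)
})
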