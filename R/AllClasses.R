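#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

## ---------------------------------------------------------------------------
## GenotypeMatrix
## ---------------------------------------------------------------------------

#' Genotype dosage container
#'
#' A \linkS4class{SummarizedExperiment} holding minor-allele dosages (SNPs in
#' rows, samples in columns, assay \code{"dosage"}) together with per-SNP
#' metadata in \code{rowData}: chromosome, 1-based position, ref/alt alleles,
#' realized minor allele frequency (\code{maf}), exact-test Hardy-Weinberg
#' p-value (\code{hwe_p}) and an orientation flag (\code{flipped}) set when
#' the stored dosage counts the allele that was the alt/coded allele's
#' complement in the source data.
#'
#' @name GenotypeMatrix-class
#' @aliases GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  d <- SummarizedExperiment::assay(object, "dosage")
  msg <- character()
  if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
    msg <- c(msg, "SNP ids must be present and unique")
  if (is.null(colnames(d)) || anyDuplicated(colnames(d)))
    msg <- c(msg, "sample ids must be present and unique")
  if (any(d < -1e-9 | d > 2 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "dosages must lie in [0, 2]")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("chrom", "pos", "maf", "hwe_p", "flipped")
  if (!all(need %in% colnames(rd))) {
    msg <- c(msg, paste("rowData must contain:", paste(need, collapse = ", ")))
  } else if (nrow(d) > 0) {
    f <- rowMeans(d, na.rm = TRUE) / 2
    if (any(abs(pmin(f, 1 - f) - rd$maf) > 1e-9, na.rm = TRUE))
      msg <- c(msg, "maf must equal min(f, 1-f) of the stored dosages within 1e-9")
    if (any(f > 0.5 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "dosages must be oriented to the minor allele (column mean/2 <= 0.5)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix from a dosage matrix
#'
#' Orients each SNP to its minor allele (flipping \code{dosage <- 2 - dosage}
#' where the coded-allele frequency exceeds 0.5), computes realized MAF and
#' the Hardy-Weinberg exact-test p-value (on dosages rounded to hard calls),
#' and assembles the annotated container.
#'
#' @param dosage numeric matrix of coded-allele copies, SNPs in rows
#'   (rownames = SNP ids), samples in columns (colnames = sample ids),
#'   values in \code{[0, 2]}.
#' @param chrom,pos,ref,alt optional per-SNP annotation vectors. When absent,
#'   chromosome/position are parsed from SNP ids of the form
#'   \code{"chrom:pos"}, otherwise left \code{NA}.
#' @param genMaf optional generating (population) allele frequency, recorded
#'   for simulated panels and used to scale planted effects.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(dosage, chrom = NULL, pos = NULL,
                           ref = NULL, alt = NULL, genMaf = NULL) {
  stopifnot(is.matrix(dosage), !is.null(rownames(dosage)),
            !is.null(colnames(dosage)))
  m <- nrow(dosage)
  parsed <- .parseSnpIds(rownames(dosage))
  if (is.null(chrom)) chrom <- parsed$chrom
  if (is.null(pos)) pos <- parsed$pos
  if (is.null(ref)) ref <- rep(NA_character_, m)
  if (is.null(alt)) alt <- rep(NA_character_, m)
  if (is.null(genMaf)) genMaf <- rep(NA_real_, m)

  f <- rowMeans(dosage, na.rm = TRUE) / 2
  flip <- !is.na(f) & f > 0.5
  if (any(flip)) {
    dosage[flip, ] <- 2 - dosage[flip, ]
    tmp <- ref[flip]; ref[flip] <- alt[flip]; alt[flip] <- tmp
  }
  maf <- rowMeans(dosage, na.rm = TRUE) / 2

  hwe <- vapply(seq_len(m), function(i) {
    g <- round(dosage[i, ])
    g <- g[!is.na(g)]
    hweExactTest(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))

  rd <- S4Vectors::DataFrame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    maf = unname(maf), hwe_p = hwe, flipped = unname(flip),
    gen_maf = as.numeric(genMaf), row.names = rownames(dosage))
  new("GenotypeMatrix",
      SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage), rowData = rd))
}

.parseSnpIds <- function(ids) {
  ok <- grepl("^[^:]+:[0-9]+$", ids)
  chrom <- rep(NA_character_, length(ids))
  pos <- rep(NA_integer_, length(ids))
  chrom[ok] <- sub(":.*$", "", ids[ok])
  pos[ok] <- as.integer(sub("^[^:]+:", "", ids[ok]))
  list(chrom = chrom, pos = pos)
}

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object), "SNPs x", ncol(object), "samples\n")
  rd <- SummarizedExperiment::rowData(object)
  if (nrow(object)) {
    cat("  MAF range:", sprintf("%.3f-%.3f", min(rd$maf), max(rd$maf)), "\n")
    cat("  flipped to minor allele:", sum(rd$flipped), "SNPs\n")
  }
})

## ---------------------------------------------------------------------------
## SimulationConfig
## ---------------------------------------------------------------------------

#' Synthetic cohort configuration
#'
#' Parameters of the synthetic cohort generator: panel dimensions, the MAF
#' distribution, optional LD block structure, planted genetic effects on
#' phenotype / gene expression / protein expression, the dose-response grid
#' and curve parameters, and the root seed.  See \code{\link{SimulationConfig}}.
#'
#' @name SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
  nSamples = "integer", nSnps = "integer",
  mafSpec = "numeric", ldBlocks = "data.frame",
  nGenes = "integer", nProteins = "integer",
  plantedEffects = "data.frame",
  isoformPairs = "list", undetectedGenes = "character",
  detectedCount = "integer", proteinGeneMap = "data.frame",
  concentrations = "numeric", meanLog2Ic50 = "numeric",
  log2Ic50Sd = "numeric", hillSlope = "numeric",
  survivalNoiseSd = "numeric", exprNoiseSd = "numeric",
  proteinNoiseSd = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSamples < 3) msg <- c(msg, "n_samples must be >= 3")
  if (object@nSnps < 1) msg <- c(msg, "need at least one SNP")
  if (length(object@mafSpec) == 0) msg <- c(msg, "empty MAF specification")
  if (any(object@mafSpec < 0.05 - 1e-12 | object@mafSpec > 0.5 + 1e-12))
    msg <- c(msg, "all MAFs must lie in [0.05, 0.5]")
  if (!(length(object@mafSpec) %in% c(1L, 2L, object@nSnps)))
    msg <- c(msg, "mafSpec must have length 1 (fixed), 2 (uniform range) or n_snps")
  if (any(diff(object@concentrations) <= 0) || any(object@concentrations <= 0))
    msg <- c(msg, "concentrations must be positive and strictly increasing")
  if (object@hillSlope <= 0) msg <- c(msg, "hill slope must be positive")
  pe <- object@plantedEffects
  if (nrow(pe)) {
    if (any(pe$variance_explained < 0 | pe$variance_explained >= 1))
      msg <- c(msg, "variance_explained must lie in [0, 1)")
    if (!all(pe$trait_kind %in% c("phenotype", "gene", "protein")))
      msg <- c(msg, "trait_kind must be phenotype, gene or protein")
    if (!all(pe$sign %in% c(-1, 1)))
      msg <- c(msg, "effect sign must be +1 or -1")
    if (anyDuplicated(pe[, c("snp_id", "trait_id")]))
      msg <- c(msg, "each (snp, trait) pair may carry at most one planted effect")
    vsum <- sum(pe$variance_explained[pe$trait_kind == "phenotype"])
    if (vsum >= 1)
      msg <- c(msg, "phenotype variance_explained values must sum to < 1")
    pv <- tapply(pe$variance_explained, pe$trait_id, sum)
    if (any(pv >= 1))
      msg <- c(msg, "per-trait variance_explained must sum to < 1")
    prot <- pe[pe$trait_kind == "protein", , drop = FALSE]
    if (nrow(prot) && !all(prot$mode %in% c("mediated", "direct")))
      msg <- c(msg, "protein effects need mode 'mediated' or 'direct'")
    med <- prot[!is.na(prot$mode) & prot$mode == "mediated", , drop = FALSE]
    if (nrow(med)) {
      map <- object@proteinGeneMap
      genes <- map$gene_id[match(med$trait_id, map$protein_id)]
      geneEff <- pe$trait_id[pe$trait_kind == "gene"]
      if (any(is.na(genes)))
        msg <- c(msg, "mediated protein effects require a protein->gene mapping")
      else if (!all(genes %in% geneEff))
        msg <- c(msg, "mediated mode requires a planted effect on the encoding gene's mRNA")
      if (any(genes %in% object@undetectedGenes))
        msg <- c(msg, "mediated effect routed through an undetected gene: the mediator must exist")
    }
  }
  for (pair in object@isoformPairs) {
    if (length(pair) != 2) { msg <- c(msg, "isoform pairs must have two members"); next }
    s <- pe$sign[match(pair, pe$trait_id)]
    if (any(is.na(s)) || s[1] * s[2] != -1)
      msg <- c(msg, sprintf("isoform pair (%s, %s) must carry planted effects of opposite sign",
                            pair[1], pair[2]))
  }
  if (length(msg)) msg else TRUE
})

#' Create a synthetic cohort configuration
#'
#' Defaults mirror the study design the generator emulates: 68 unrelated cell
#' lines, biallelic SNPs with MAF in [0.05, 0.5] in Hardy-Weinberg
#' equilibrium, a six-point colistin concentration grid (50, 100, 175, 250,
#' 375, 500 uM) and a mean IC50 of 176.5 uM.  The default spread of
#' log2 IC50 (0.45) corresponds to the reported standard error of the mean
#' IC50 (6.6 uM over 68 lines, i.e. an SD of ~54 uM at 176.5 uM).
#'
#' @param nSamples number of cell lines (default 68).
#' @param nSnps number of SNPs.
#' @param mafSpec minor allele frequency specification: a single frequency,
#'   a range \code{c(lo, hi)} sampled uniformly, or one value per SNP.
#' @param ldBlocks \code{data.frame(size, r)} of LD blocks; blocks consume
#'   SNPs from the start of the panel, remaining SNPs are independent.
#'   \code{r} is the latent Gaussian-copula correlation within a block.
#' @param nGenes,nProteins numbers of expression / protein features.
#' @param plantedEffects \code{data.frame} of planted effects, see
#'   \code{\link{plantedEffect}}.
#' @param isoformPairs list of character pairs of protein ids constrained to
#'   opposite-sign genotype effects (two isoforms of one protein).
#' @param undetectedGenes gene ids whose mRNA is reported missing in all but
#'   \code{detectedCount} samples.
#' @param detectedCount samples in which an undetected gene is still
#'   quantified (default 3).
#' @param proteinGeneMap \code{data.frame(protein_id, gene_id, isoform)};
#'   default maps protein i to gene i.
#' @param concentrations drug concentration grid, uM, strictly increasing.
#' @param meanLog2Ic50 population mean of log2 IC50 (log2 uM).
#' @param log2Ic50Sd total SD of log2 IC50 across samples.
#' @param hillSlope slope of the logistic survival curve.
#' @param survivalNoiseSd additive Gaussian noise SD on percent survival
#'   (default 2: curves are replicate-averaged, so per-point noise is the
#'   raw assay noise shrunk by the replicate count).
#' @param exprNoiseSd,proteinNoiseSd residual SDs of expression features.
#' @param seed root seed; all generator randomness derives from it.
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
SimulationConfig <- function(nSamples = 68, nSnps = 100,
                             mafSpec = c(0.05, 0.5),
                             ldBlocks = data.frame(size = integer(), r = numeric()),
                             nGenes = 0, nProteins = 0,
                             plantedEffects = emptyPlantedEffects(),
                             isoformPairs = list(),
                             undetectedGenes = character(),
                             detectedCount = 3,
                             proteinGeneMap = NULL,
                             concentrations = c(50, 100, 175, 250, 375, 500),
                             meanLog2Ic50 = log2(176.5),
                             log2Ic50Sd = 0.45,
                             hillSlope = 1.5,
                             survivalNoiseSd = 2,
                             exprNoiseSd = 1,
                             proteinNoiseSd = 1,
                             seed = 1L) {
  if (is.null(proteinGeneMap)) {
    k <- min(nProteins, nGenes)
    proteinGeneMap <- data.frame(
      protein_id = if (nProteins) sprintf("prot%04d", seq_len(nProteins)) else character(),
      gene_id = if (nProteins) c(sprintf("gene%04d", seq_len(k)),
                                 rep(NA_character_, nProteins - k)) else character(),
      isoform = rep(NA_character_, nProteins),
      stringsAsFactors = FALSE)
  }
  new("SimulationConfig",
      nSamples = as.integer(nSamples), nSnps = as.integer(nSnps),
      mafSpec = as.numeric(mafSpec), ldBlocks = ldBlocks,
      nGenes = as.integer(nGenes), nProteins = as.integer(nProteins),
      plantedEffects = plantedEffects, isoformPairs = isoformPairs,
      undetectedGenes = undetectedGenes, detectedCount = as.integer(detectedCount),
      proteinGeneMap = proteinGeneMap,
      concentrations = as.numeric(concentrations),
      meanLog2Ic50 = as.numeric(meanLog2Ic50),
      log2Ic50Sd = as.numeric(log2Ic50Sd), hillSlope = as.numeric(hillSlope),
      survivalNoiseSd = as.numeric(survivalNoiseSd),
      exprNoiseSd = as.numeric(exprNoiseSd),
      proteinNoiseSd = as.numeric(proteinNoiseSd),
      seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nSamples, "samples,", object@nSnps, "SNPs,",
      object@nGenes, "genes,", object@nProteins, "proteins\n")
  cat("  planted effects:", nrow(object@plantedEffects),
      " | concentrations (uM):", paste(object@concentrations, collapse = ", "), "\n")
  cat("  mean log2 IC50:", sprintf("%.3f", object@meanLog2Ic50),
      "(", sprintf("%.1f", 2^object@meanLog2Ic50), "uM ) | seed:", object@seed, "\n")
})

#' Describe a planted genetic effect
#'
#' @param snpId SNP carrying the effect.
#' @param traitKind \code{"phenotype"}, \code{"gene"} or \code{"protein"}.
#' @param traitId target trait id (\code{"log2_ic50"} for the phenotype).
#' @param varianceExplained fraction of trait variance attributable to the
#'   SNP in the generating population, in \code{[0, 1)}.  For mediated
#'   protein effects this is the fraction of protein variance explained by
#'   the mediating mRNA.
#' @param sign direction of the minor-allele effect, +1 or -1.
#' @param mode for proteins only: \code{"mediated"} (the genotype effect is
#'   routed entirely through the encoding gene's mRNA) or \code{"direct"}
#'   (the genotype acts on the protein bypassing mRNA).
#' @return One-row \code{data.frame}; rows may be combined with \code{rbind}.
#' @export
plantedEffect <- function(snpId, traitKind, traitId, varianceExplained,
                          sign = 1, mode = NA_character_) {
  data.frame(snp_id = snpId, trait_kind = traitKind, trait_id = traitId,
             mode = mode, variance_explained = varianceExplained,
             sign = sign, stringsAsFactors = FALSE)
}

#' @rdname plantedEffect
#' @export
emptyPlantedEffects <- function() {
  data.frame(snp_id = character(), trait_kind = character(),
             trait_id = character(), mode = character(),
             variance_explained = numeric(), sign = numeric(),
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## GroundTruth
## ---------------------------------------------------------------------------

#' Generating truth of a synthetic cohort
#'
#' Records, for every planted effect, the generating coefficient, noise SD,
#' and the population trait / genetic-component variances (so that
#' \code{genetic_var / trait_var} equals the planted variance_explained
#' exactly); plus the per-sample true dose-response parameters when the
#' phenotype generator ran.
#'
#' @name GroundTruth-class
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
  effects = "data.frame", phenotype = "data.frame"))

setValidity("GroundTruth", function(object) {
  e <- object@effects
  if (nrow(e) && anyDuplicated(e[, c("snp_id", "trait_id")]))
    "each planted (snp, trait) effect must appear exactly once" else TRUE
})

.emptyTruthEffects <- function() {
  data.frame(snp_id = character(), trait_kind = character(),
             trait_id = character(), mode = character(),
             sign = numeric(), variance_explained = numeric(),
             beta = numeric(), noise_sd = numeric(),
             trait_var = numeric(), genetic_var = numeric(),
             stringsAsFactors = FALSE)
}

#' @describeIn GroundTruth-class planted effects table
#' @param x,truth a \code{GroundTruth}
#' @export
truthEffects <- function(x) x@effects

#' @describeIn GroundTruth-class per-sample true phenotype table
#' @export
truthPhenotype <- function(x) x@phenotype

#' @describeIn GroundTruth-class planted variance explained for a (snp, trait)
#'   pair; 0 when no effect was planted.
#' @param snpId,traitId pair to look up
#' @export
plantedVariance <- function(truth, snpId, traitId) {
  e <- truth@effects
  hit <- e$snp_id == snpId & e$trait_id == traitId
  if (any(hit)) e$variance_explained[hit] else 0
}

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@effects), "planted effects")
  if (nrow(object@phenotype)) cat(";", nrow(object@phenotype), "phenotyped samples")
  cat("\n")
})

## ---------------------------------------------------------------------------
## AnalysisConfig
## ---------------------------------------------------------------------------

#' Association / enrichment analysis configuration
#'
#' @name AnalysisConfig-class
#' @exportClass AnalysisConfig
setClass("AnalysisConfig", representation(
  dqtlP = "numeric", qtlP = "numeric", mafMin = "numeric",
  hwePMin = "numeric", fdrQ = "numeric", ldR2Max = "numeric",
  ldWindowBp = "numeric", nPermutations = "integer",
  mafBinWidth = "numeric", detectFraction = "numeric",
  usePruned = "logical"))

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  for (s in c("dqtlP", "qtlP", "mafMin", "hwePMin", "fdrQ", "ldR2Max",
              "mafBinWidth", "detectFraction")) {
    v <- slot(object, s)
    if (length(v) != 1 || is.na(v) || v <= 0 || v >= 1)
      msg <- c(msg, sprintf("%s must be a single value in (0, 1)", s))
  }
  if (object@nPermutations < 100) msg <- c(msg, "n_permutations must be >= 100")
  if (object@ldWindowBp <= 0) msg <- c(msg, "LD window must be positive")
  if (length(msg)) msg else TRUE
})

#' Analysis thresholds
#'
#' Defaults are the scan's operating points: drug-QTL call at p <= 0.001,
#' expression/protein QTL call at p <= 0.0001, MAF >= 5\% and Hardy-Weinberg
#' p >= 0.001 SNP filters, FDR 0.05 for the protein-phenotype scan, greedy LD
#' pruning at r^2 <= 0.2 within 1 Mb, and 1000 MAF-matched permutation sets
#' binned at width 0.02.
#'
#' @param dqtlP drug-QTL significance threshold.
#' @param qtlP expression/protein QTL significance threshold.
#' @param mafMin minimum minor allele frequency retained.
#' @param hwePMin minimum Hardy-Weinberg exact-test p retained.
#' @param fdrQ false discovery rate for the protein-phenotype scan.
#' @param ldR2Max maximum pairwise dosage r^2 among retained SNPs.
#' @param ldWindowBp window (bp) within which LD is evaluated.
#' @param nPermutations number of MAF-matched null sets (>= 100).
#' @param mafBinWidth width of the MAF matching bins.
#' @param detectFraction minimum fraction of samples in which a gene's mRNA
#'   must be detected for protein residualization to adjust for it.
#' @param usePruned use the LD-pruned drug-QTL set for enrichment (default);
#'   \code{FALSE} runs the sensitivity analysis on the unpruned set.
#' @return A validated \linkS4class{AnalysisConfig}.
#' @export
AnalysisConfig <- function(dqtlP = 0.001, qtlP = 0.0001, mafMin = 0.05,
                           hwePMin = 0.001, fdrQ = 0.05, ldR2Max = 0.2,
                           ldWindowBp = 1e6, nPermutations = 1000,
                           mafBinWidth = 0.02, detectFraction = 0.5,
                           usePruned = TRUE) {
  new("AnalysisConfig", dqtlP = dqtlP, qtlP = qtlP, mafMin = mafMin,
      hwePMin = hwePMin, fdrQ = fdrQ, ldR2Max = ldR2Max,
      ldWindowBp = ldWindowBp, nPermutations = as.integer(nPermutations),
      mafBinWidth = mafBinWidth, detectFraction = detectFraction,
      usePruned = usePruned)
}

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig: dQTL p<=", object@dqtlP, ", QTL p<=", object@qtlP,
      ", MAF>=", object@mafMin, ", HWE p>=", object@hwePMin, "\n", sep = "")
  cat("  LD prune r2<=", object@ldR2Max, " within ", object@ldWindowBp / 1e6,
      " Mb; ", object@nPermutations, " permutations, MAF bin ",
      object@mafBinWidth, "\n", sep = "")
})

## ---------------------------------------------------------------------------
## EnrichmentResult
## ---------------------------------------------------------------------------

#' MAF-matched permutation enrichment result
#'
#' Holds the observed QTL count in the target SNP set, the null counts from
#' B MAF-matched random sets, and the add-one-smoothed empirical p-value
#' \code{(1 + #\{null >= observed\}) / (1 + B)} (minimum 1/(B+1)).
#'
#' @name EnrichmentResult-class
#' @exportClass EnrichmentResult
setClass("EnrichmentResult", representation(
  flag = "character", targetSize = "integer", observed = "integer",
  nullCounts = "integer", empiricalP = "numeric",
  mafBinWidth = "numeric", seed = "integer"))

setValidity("EnrichmentResult", function(object) {
  msg <- character()
  B <- length(object@nullCounts)
  if (B < 1) msg <- c(msg, "null counts must be non-empty")
  if (object@observed > object@targetSize)
    msg <- c(msg, "observed count cannot exceed the target set size")
  lo <- 1 / (B + 1)
  if (object@empiricalP < lo - 1e-12 || object@empiricalP > 1 + 1e-12)
    msg <- c(msg, "empirical p must lie in [1/(B+1), 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn EnrichmentResult-class empirical p-value
#' @param x an \code{EnrichmentResult}
#' @export
empiricalP <- function(x) x@empiricalP

#' @describeIn EnrichmentResult-class observed QTL count in the target set
#' @export
observedCount <- function(x) x@observed

#' @describeIn EnrichmentResult-class integer vector of null counts
#' @export
nullCounts <- function(x) x@nullCounts

setMethod("show", "EnrichmentResult", function(object) {
  B <- length(object@nullCounts)
  cat("EnrichmentResult (", object@flag, "): observed ", object@observed,
      " of ", object@targetSize, " target SNPs\n", sep = "")
  cat(sprintf("  null (B = %d): mean %.2f, sd %.2f, max %d\n", B,
              mean(object@nullCounts), stats::sd(object@nullCounts),
              max(object@nullCounts)))
  cat(sprintf("  empirical p = %.4g%s\n", object@empiricalP,
              if (object@empiricalP <= 1 / (B + 1) + 1e-12)
                sprintf(" (minimum reportable at B = %d)", B) else ""))
})
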