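#' Simulate a genotype panel
#'
#' Draws each SNP as two Bernoulli(MAF) allele copies, so genotype
#' proportions are in Hardy-Weinberg equilibrium in expectation.  LD blocks
#' are induced by a Gaussian copula: within a block, the latent normal
#' deviates behind the two allele draws share an exchangeable correlation
#' \code{r} before thresholding at \code{qnorm(MAF)}; SNPs across blocks are
#' independent.  SNPs are laid on chromosome 1 at 1 kb spacing with ids
#' \code{"1:<pos>"}, so positional LD windows are meaningful downstream.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{GenotypeMatrix} with the generating (population)
#'   MAF recorded in \code{rowData$gen_maf}.
#' @examples
#' gm <- simulateGenotypes(SimulationConfig(nSamples = 50, nSnps = 20, seed = 7))
#' dim(dosages(gm))
#' @export
simulateGenotypes <- function(config) {
  methods::validObject(config)
  set.seed(.deriveSeed(config@seed, "genotypes"))
  n <- config@nSamples
  m <- config@nSnps
  mafs <- .resolveMafs(config)

  # block assignment: listed blocks consume SNPs from the start of the panel
  blocks <- config@ldBlocks
  sizes <- if (nrow(blocks)) as.integer(blocks$size) else integer()
  if (sum(sizes) > m) stop("LD blocks reference more SNPs than the panel holds")
  rs <- if (nrow(blocks)) as.numeric(blocks$r) else numeric()
  rest <- m - sum(sizes)
  allSizes <- c(sizes, rep(1L, rest))
  allRs <- c(rs, rep(0, rest))

  dosage <- matrix(0L, nrow = m, ncol = n)
  at <- 1L
  for (b in seq_along(allSizes)) {
    k <- allSizes[b]
    idx <- at:(at + k - 1L)
    thr <- qnorm(mafs[idx])
    for (copy in 1:2) {
      if (k == 1L || allRs[b] == 0) {
        z <- matrix(rnorm(n * k), n, k)
      } else {
        S <- matrix(allRs[b], k, k); diag(S) <- 1
        z <- matrix(rnorm(n * k), n, k) %*% chol(S)
      }
      dosage[idx, ] <- dosage[idx, ] +
        t(z < matrix(thr, n, k, byrow = TRUE)) * 1L
    }
    at <- at + k
  }
  pos <- seq_len(m) * 1000L
  rownames(dosage) <- sprintf("1:%d", pos)
  colnames(dosage) <- sprintf("S%03d", seq_len(n))
  GenotypeMatrix(dosage, chrom = rep("1", m), pos = pos,
                 ref = rep("A", m), alt = rep("G", m), genMaf = mafs)
}

.resolveMafs <- function(config) {
  s <- config@mafSpec
  m <- config@nSnps
  if (length(s) == m && m != 2L) return(s)
  if (length(s) == 1L) return(rep(s, m))
  if (length(s) == 2L && m != 2L) return(runif(m, s[1], s[2]))
  # ambiguous only when nSnps == 2: treat length-2 spec as per-SNP values
  s
}

# beta scaled against the population dosage variance 2f(1-f) so that the
# genetic component explains exactly `v` of the population trait variance;
# realized in-sample R^2 then fluctuates around v as in real cohorts.
# With zero residual noise the trait is fully determined by the genetic
# part (variance explained 1 whatever was requested); a unit-variance
# loading is used and the truth records variance_explained = 1.
.effectBeta <- function(v, sign, noiseSd, genMaf) {
  sg <- sqrt(2 * genMaf * (1 - genMaf))
  if (noiseSd == 0) return(sign / sg)
  sign * sqrt(v / (1 - v)) * noiseSd / sg
}

.lookupSnpRows <- function(gm, snps) {
  i <- match(snps, rownames(gm))
  if (anyNA(i)) stop("unknown SNP in planted effects: ",
                     paste(snps[is.na(i)], collapse = ", "))
  i
}

#' Simulate gene expression with planted cis/trans effects
#'
#' Unplanted genes are Gaussian noise.  For each planted gene effect the
#' genotype coefficient is scaled against the population dosage variance
#' \code{2f(1-f)} so the population variance explained equals the planted
#' value exactly (recorded in the returned truth).  Genes listed as
#' undetected are reported missing (NA) in all but
#' \code{config@detectedCount} randomly chosen samples, mimicking a
#' transcript detected above background in only a handful of lines.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix} from
#'   \code{\link{simulateGenotypes}}.
#' @param config the same \linkS4class{SimulationConfig}.
#' @return \code{list(expression = SummarizedExperiment (genes x samples),
#'   truth = GroundTruth)}.
#' @export
simulateExpression <- function(genotypes, config) {
  methods::validObject(config)
  set.seed(.deriveSeed(config@seed, "expression"))
  n <- ncol(genotypes)
  genes <- sprintf("gene%04d", seq_len(config@nGenes))
  E <- matrix(rnorm(n * config@nGenes, 0, config@exprNoiseSd),
              nrow = n, ncol = config@nGenes,
              dimnames = list(colnames(genotypes), genes))

  pe <- config@plantedEffects
  pe <- pe[pe$trait_kind == "gene", , drop = FALSE]
  eff <- .emptyTruthEffects()
  if (nrow(pe)) {
    bad <- setdiff(pe$trait_id, genes)
    if (length(bad)) stop("planted effect on unknown gene: ",
                          paste(bad, collapse = ", "))
    rows <- .lookupSnpRows(genotypes, pe$snp_id)
    gmaf <- snpInfo(genotypes)$gen_maf[rows]
    D <- dosages(genotypes)
    for (i in seq_len(nrow(pe))) {
      beta <- .effectBeta(pe$variance_explained[i], pe$sign[i],
                          config@exprNoiseSd, gmaf[i])
      E[, pe$trait_id[i]] <- E[, pe$trait_id[i]] + beta * D[rows[i], ]
      gvar <- beta^2 * 2 * gmaf[i] * (1 - gmaf[i])
      eff <- rbind(eff, data.frame(
        snp_id = pe$snp_id[i], trait_kind = "gene", trait_id = pe$trait_id[i],
        mode = NA_character_, sign = pe$sign[i],
        variance_explained = if (config@exprNoiseSd == 0) 1
                             else pe$variance_explained[i],
        beta = beta,
        noise_sd = config@exprNoiseSd, trait_var = gvar + config@exprNoiseSd^2,
        genetic_var = gvar, stringsAsFactors = FALSE))
    }
  }
  for (g in intersect(config@undetectedGenes, genes)) {
    keep <- sample.int(n, min(config@detectedCount, n))
    E[-keep, g] <- NA_real_
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = t(E)),
    rowData = S4Vectors::DataFrame(gene_id = genes, row.names = genes))
  list(expression = se, truth = new("GroundTruth", effects = eff,
                                    phenotype = data.frame()))
}

#' Simulate protein expression with mediated and direct genotype effects
#'
#' Two causal structures are planted, distinguishable by regressing protein
#' on mRNA: a \emph{mediated} protein is \code{a * mRNA + noise} (its
#' genotype association exists only through the encoding gene's mRNA, and
#' vanishes in mRNA residuals), while a \emph{direct} protein is
#' \code{b * dosage + noise} with no mRNA dependence.  Isoform pairs in the
#' configuration are constrained to genotype coefficients of opposite sign.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param expression the expression \code{SummarizedExperiment} from
#'   \code{\link{simulateExpression}} (mediators are read from it).
#' @param config the shared \linkS4class{SimulationConfig}.
#' @return \code{list(proteins = SummarizedExperiment (proteins x samples,
#'   rowData: gene_id, isoform), truth = GroundTruth)}.
#' @export
simulateProteins <- function(genotypes, expression, config) {
  methods::validObject(config)
  set.seed(.deriveSeed(config@seed, "proteins"))
  n <- ncol(genotypes)
  map <- config@proteinGeneMap
  prots <- map$protein_id
  P <- matrix(rnorm(n * length(prots), 0, config@proteinNoiseSd),
              nrow = n, ncol = length(prots),
              dimnames = list(colnames(genotypes), prots))

  pe <- config@plantedEffects
  pe <- pe[pe$trait_kind == "protein", , drop = FALSE]
  eff <- .emptyTruthEffects()
  if (nrow(pe)) {
    bad <- setdiff(pe$trait_id, prots)
    if (length(bad)) stop("planted effect on unknown protein: ",
                          paste(bad, collapse = ", "))
    rows <- .lookupSnpRows(genotypes, pe$snp_id)
    gmaf <- snpInfo(genotypes)$gen_maf[rows]
    D <- dosages(genotypes)
    Em <- t(SummarizedExperiment::assay(expression))
    allEff <- config@plantedEffects
    for (i in seq_len(nrow(pe))) {
      v <- pe$variance_explained[i]
      if (pe$mode[i] == "direct") {
        beta <- .effectBeta(v, pe$sign[i], config@proteinNoiseSd, gmaf[i])
        P[, pe$trait_id[i]] <- P[, pe$trait_id[i]] + beta * D[rows[i], ]
        gvar <- beta^2 * 2 * gmaf[i] * (1 - gmaf[i])
      } else {  # mediated: load on the encoding gene's mRNA
        gene <- map$gene_id[match(pe$trait_id[i], map$protein_id)]
        if (gene %in% config@undetectedGenes)
          stop("mediated effect on undetected gene ", gene,
               ": the mediator must exist to be simulated")
        gEff <- allEff[allEff$trait_kind == "gene" & allEff$trait_id == gene, , drop = FALSE]
        if (!nrow(gEff))
          stop("mediated protein ", pe$trait_id[i],
               " requires a planted effect on gene ", gene)
        # population SD of the mediating mRNA trait
        sdM <- config@exprNoiseSd / sqrt(1 - sum(gEff$variance_explained))
        a <- if (config@proteinNoiseSd == 0) pe$sign[i] / sdM
             else pe$sign[i] * sqrt(v / (1 - v)) * config@proteinNoiseSd / sdM
        # sign convention: planted sign is the genotype->protein direction,
        # so fold the mRNA effect's own sign out of the loading
        a <- a * sign(gEff$sign[1])
        P[, pe$trait_id[i]] <- P[, pe$trait_id[i]] + a * Em[, gene]
        beta <- a
        gvar <- a^2 * sdM^2  # variance carried by the mediator
      }
      eff <- rbind(eff, data.frame(
        snp_id = pe$snp_id[i], trait_kind = "protein",
        trait_id = pe$trait_id[i], mode = pe$mode[i], sign = pe$sign[i],
        variance_explained = if (config@proteinNoiseSd == 0) 1 else v,
        beta = beta,
        noise_sd = config@proteinNoiseSd,
        trait_var = gvar + config@proteinNoiseSd^2, genetic_var = gvar,
        stringsAsFactors = FALSE))
    }
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(protein = t(P)),
    rowData = S4Vectors::DataFrame(gene_id = map$gene_id,
                                   isoform = map$isoform,
                                   row.names = prots))
  list(proteins = se, truth = new("GroundTruth", effects = eff,
                                  phenotype = data.frame()))
}

#' Simulate dose-response survival curves with a planted genotype effect
#'
#' Per-sample true \code{log2 IC50 = meanLog2Ic50 + sum(sign * beta * dosage)
#' + noise}, with each beta scaled to its planted variance explained and the
#' noise SD set so the total phenotype SD equals \code{log2Ic50Sd}.  Percent
#' survival at concentration c is \code{100 / (1 + (c / IC50)^hill)} plus
#' additive Gaussian measurement noise truncated at 0 (values above 100 are
#' allowed, as normalized viability readouts exceed the no-drug control).
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param config the shared \linkS4class{SimulationConfig}.
#' @return \code{list(doseResponse = data.frame(sample_id, concentration_uM,
#'   pct_survival), truth = GroundTruth)} where the truth carries per-sample
#'   true IC50s and curve parameters.
#' @export
simulateDoseResponse <- function(genotypes, config) {
  methods::validObject(config)
  set.seed(.deriveSeed(config@seed, "dose_response"))
  n <- ncol(genotypes)
  pe <- config@plantedEffects
  pe <- pe[pe$trait_kind == "phenotype", , drop = FALSE]

  lp <- rep(config@meanLog2Ic50, n)
  eff <- .emptyTruthEffects()
  vsum <- 0
  if (nrow(pe)) {
    rows <- .lookupSnpRows(genotypes, pe$snp_id)
    gmaf <- snpInfo(genotypes)$gen_maf[rows]
    D <- dosages(genotypes)
    vsum <- sum(pe$variance_explained)
    for (i in seq_len(nrow(pe))) {
      v <- pe$variance_explained[i]
      beta <- pe$sign[i] * sqrt(v) * config@log2Ic50Sd /
        sqrt(2 * gmaf[i] * (1 - gmaf[i]))
      lp <- lp + beta * D[rows[i], ]
      eff <- rbind(eff, data.frame(
        snp_id = pe$snp_id[i], trait_kind = "phenotype",
        trait_id = pe$trait_id[i], mode = NA_character_, sign = pe$sign[i],
        variance_explained = v, beta = beta,
        noise_sd = config@log2Ic50Sd * sqrt(1 - vsum),
        trait_var = config@log2Ic50Sd^2,
        genetic_var = v * config@log2Ic50Sd^2, stringsAsFactors = FALSE))
    }
  }
  noiseSd <- config@log2Ic50Sd * sqrt(1 - vsum)
  log2ic50 <- lp + rnorm(n, 0, noiseSd)
  ic50 <- 2^log2ic50

  conc <- config@concentrations
  surv <- 100 / (1 + outer(ic50, conc, function(i, c) (c / i)^config@hillSlope))
  surv <- surv + matrix(rnorm(length(surv), 0, config@survivalNoiseSd),
                        nrow = n)
  surv <- pmax(surv, 0)

  dr <- data.frame(
    sample_id = rep(colnames(genotypes), each = length(conc)),
    concentration_uM = rep(conc, n),
    pct_survival = as.vector(t(surv)), stringsAsFactors = FALSE)
  ph <- data.frame(sample_id = colnames(genotypes), log2_ic50 = log2ic50,
                   ic50 = ic50, hill = config@hillSlope,
                   bottom = 0, top = 100, stringsAsFactors = FALSE)
  list(doseResponse = dr,
       truth = new("GroundTruth", effects = eff, phenotype = ph))
}

#' Simulate a full cohort
#'
#' Runs the genotype, expression, protein and dose-response generators in a
#' fixed order (each on its own seed stream derived from the config's root
#' seed) and merges the ground truth.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return \code{list(genotypes, expression, proteins, doseResponse, truth,
#'   config)}; \code{expression}/\code{proteins} are \code{NULL} when the
#'   config requests zero features.
#' @export
simulateCohort <- function(config) {
  methods::validObject(config)
  gm <- simulateGenotypes(config)
  expr <- if (config@nGenes > 0) simulateExpression(gm, config) else NULL
  prot <- if (config@nProteins > 0) {
    if (is.null(expr)) stop("protein simulation requires an expression matrix")
    simulateProteins(gm, expr$expression, config)
  } else NULL
  dr <- simulateDoseResponse(gm, config)
  eff <- rbind(if (!is.null(expr)) expr$truth@effects else .emptyTruthEffects(),
               if (!is.null(prot)) prot$truth@effects else .emptyTruthEffects(),
               dr$truth@effects)
  list(genotypes = gm,
       expression = if (!is.null(expr)) expr$expression else NULL,
       proteins = if (!is.null(prot)) prot$proteins else NULL,
       doseResponse = dr$doseResponse,
       truth = new("GroundTruth", effects = eff,
                   phenotype = dr$truth@phenotype),
       config = config)
}
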