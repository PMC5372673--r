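.mafBin <- function(maf, width) as.integer(floor(maf / width + 1e-9))

#' MAF-matched random SNP sets
#'
#' Partitions the MAF axis into bins of \code{mafBinWidth} and draws, for
#' each of B sets and each bin occupied by the target, exactly as many
#' universe SNPs (uniformly, without replacement within a bin) as the target
#' holds in that bin -- so the per-bin MAF histogram of every null set
#' equals the target's histogram exactly.  Target SNPs remain eligible for
#' sampling: depleting the universe of the target would bias expected
#' counts in small universes.
#'
#' @param targetSnps character vector of target SNP ids (must be in the
#'   universe).
#' @param genotypes the \linkS4class{GenotypeMatrix} defining the SNP
#'   universe (typically the post-filter panel).
#' @param cfg an \linkS4class{AnalysisConfig} (uses \code{nPermutations},
#'   \code{mafBinWidth}).
#' @param seed integer seed; identical seeds give identical collections.
#' @return List of B character vectors, each of length
#'   \code{length(targetSnps)}.
#' @export
mafMatchedNullSets <- function(targetSnps, genotypes, cfg = AnalysisConfig(),
                               seed = 1L) {
  univ <- rownames(genotypes)
  if (!all(targetSnps %in% univ))
    stop("target SNP absent from universe: ",
         paste(setdiff(targetSnps, univ)[1:min(3, length(setdiff(targetSnps, univ)))],
               collapse = ", "))
  maf <- snpInfo(genotypes)$maf
  names(maf) <- univ
  binAll <- .mafBin(maf, cfg@mafBinWidth)
  binTarget <- binAll[match(targetSnps, univ)]
  targetCounts <- table(binTarget)
  univByBin <- split(univ, binAll)

  for (b in names(targetCounts)) {
    avail <- length(univByBin[[b]])
    if (avail < targetCounts[[b]]) {
      lo <- as.integer(b) * cfg@mafBinWidth
      stop(sprintf(
        "infeasible MAF matching in bin [%.3f, %.3f): target has %d SNPs, universe only %d",
        lo, lo + cfg@mafBinWidth, targetCounts[[b]], avail))
    }
  }
  set.seed(seed)
  lapply(seq_len(cfg@nPermutations), function(i) {
    unlist(lapply(names(targetCounts), function(b) {
      pool <- univByBin[[b]]
      if (length(pool) == 1) pool else sample(pool, targetCounts[[b]])
    }), use.names = FALSE)
  })
}

#' Count flagged QTLs in a SNP set
#'
#' @param snpSet character vector of SNP ids.
#' @param qtls QTL flag table from \code{\link{classifyQTLs}} (optionally
#'   augmented by \code{\link{mrnaIndependentPqtlScan}}).
#' @param flag which flag to count: \code{"dqtl"}, \code{"eqtl"},
#'   \code{"pqtl"} or \code{"mrna_independent_pqtl"}.
#' @return Integer count of SNPs in the set with the flag set.
#' @export
countQTLs <- function(snpSet, qtls,
                      flag = c("eqtl", "pqtl", "mrna_independent_pqtl", "dqtl")) {
  flag <- match.arg(flag)
  col <- paste0("is_", flag)
  if (!col %in% colnames(qtls)) stop("QTL table lacks column ", col)
  i <- match(snpSet, qtls$snp_id)
  if (anyNA(i)) stop("unknown SNP in set: ",
                     paste(snpSet[is.na(i)][1:min(3, sum(is.na(i)))], collapse = ", "))
  sum(qtls[[col]][i], na.rm = TRUE)
}

#' Empirical permutation p-value for an enrichment
#'
#' Add-one smoothed: \code{(1 + #\{null >= observed\}) / (1 + B)}, so the
#' minimum reportable value with B = 1000 null sets is 1/1001 and p = 0 is
#' impossible (standard permutation-test practice).
#'
#' @param observed observed QTL count in the target set.
#' @param nullCounts integer vector of counts from the B null sets
#'   (B >= 100).
#' @param flag label recorded in the result.
#' @param targetSize size of the target set (defaults to
#'   \code{max(observed, nullCounts)} when unknown).
#' @param mafBinWidth,seed provenance recorded in the result.
#' @return An \linkS4class{EnrichmentResult}.
#' @export
empiricalEnrichmentP <- function(observed, nullCounts, flag = "eqtl",
                                 targetSize = NA, mafBinWidth = NA_real_,
                                 seed = NA_integer_) {
  B <- length(nullCounts)
  if (B < 100) stop("need at least 100 null sets")
  if (is.na(targetSize)) targetSize <- max(observed, nullCounts)
  p <- (1 + sum(nullCounts >= observed)) / (1 + B)
  new("EnrichmentResult", flag = flag, targetSize = as.integer(targetSize),
      observed = as.integer(observed), nullCounts = as.integer(nullCounts),
      empiricalP = p, mafBinWidth = as.numeric(mafBinWidth),
      seed = as.integer(seed))
}

#' MAF-matched permutation enrichment test
#'
#' Counts flagged QTLs among the target SNPs, draws B MAF-matched null sets
#' from the universe, counts QTLs in each, and reports the empirical
#' p-value for the observed count.
#'
#' @inheritParams mafMatchedNullSets
#' @inheritParams countQTLs
#' @return An \linkS4class{EnrichmentResult}.
#' @export
enrichmentTest <- function(targetSnps, qtls, genotypes,
                           flag = c("eqtl", "pqtl", "mrna_independent_pqtl"),
                           cfg = AnalysisConfig(), seed = 1L) {
  flag <- match.arg(flag)
  nulls <- mafMatchedNullSets(targetSnps, genotypes, cfg, seed)
  observed <- countQTLs(targetSnps, qtls, flag)
  nullCounts <- vapply(nulls, countQTLs, integer(1), qtls = qtls, flag = flag)
  empiricalEnrichmentP(observed, nullCounts, flag = flag,
                       targetSize = length(targetSnps),
                       mafBinWidth = cfg@mafBinWidth, seed = seed)
}

#' Residualize protein expression on its encoding gene's mRNA
#'
#' When the gene's mRNA is detected in at least \code{detectFraction} of
#' samples, the protein is regressed on mRNA (OLS with intercept, complete
#' pairs) and the residuals returned with status \code{"adjusted"}; the
#' residuals are orthogonal to the centered mRNA.  When the mRNA is mostly
#' missing -- the situation of a transcript detected in only a handful of
#' lines -- no adjustment is possible and the centered protein values are
#' returned with status \code{"unadjusted_mrna_missing"}.  Constant mRNA
#' among complete pairs takes the unadjusted path with a warning.
#'
#' @param protein numeric protein values per sample.
#' @param mrna numeric mRNA values per sample (may be NA / entirely absent).
#' @param detectFraction detection threshold (default 0.5).
#' @return \code{list(residuals, status, nUsed)}.
#' @export
residualizeProteinOnMrna <- function(protein, mrna, detectFraction = 0.5) {
  n <- length(protein)
  unadjusted <- function(status) {
    list(residuals = protein - mean(protein, na.rm = TRUE),
         status = status, nUsed = sum(!is.na(protein)))
  }
  if (is.null(mrna) || all(is.na(mrna)) ||
      mean(!is.na(mrna)) < detectFraction)
    return(unadjusted("unadjusted_mrna_missing"))
  if (length(mrna) != n) stop("protein and mRNA vectors must be paired")
  ok <- !is.na(protein) & !is.na(mrna)
  if (sum(ok) < 3 || stats::sd(mrna[ok]) == 0) {
    warning("constant or insufficient mRNA among complete pairs; protein left unadjusted")
    return(unadjusted("unadjusted_mrna_missing"))
  }
  x <- mrna[ok]; y <- protein[ok]
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  r <- y - mean(y) - beta * (x - mean(x))
  # residuals at floating-point rounding level (exact linear dependence)
  # are snapped to zero so downstream scans see a degenerate trait rather
  # than regressing on numerical noise
  if (max(abs(r)) < 1e-10 * max(stats::sd(y), .Machine$double.xmin)) r[] <- 0
  res <- rep(NA_real_, n)
  res[ok] <- r
  list(residuals = res, status = "adjusted", nUsed = sum(ok))
}

#' mRNA-independent protein QTL scan
#'
#' Builds residual traits for every protein (protein residualized on its
#' encoding gene's mRNA, or centered protein when the mRNA is undetected or
#' unmapped), scans all SNPs against the residuals and flags SNPs whose
#' best residual-trait p reaches \code{cfg qtlP}.  An association that
#' survives this residualization cannot be carried by the mRNA and is
#' mRNA-independent by construction.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param proteins protein container (\code{SummarizedExperiment} proteins x
#'   samples, rowData \code{gene_id}; or matrix samples x proteins with a
#'   \code{map}).
#' @param expression expression container (\code{SummarizedExperiment} genes
#'   x samples or matrix samples x genes); \code{NULL} scans all proteins
#'   unadjusted.
#' @param map optional \code{data.frame(protein_id, gene_id)}; defaults to
#'   the proteins' rowData, else protein ids of the form
#'   \code{"gene|isoform"} are parsed.
#' @param cfg an \linkS4class{AnalysisConfig}.
#' @return \code{list(results (scan rows with adjustment_status), qtls
#'   (data.frame snp_id, is_mrna_independent_pqtl, best trait and p),
#'   status (per-protein adjustment status))}.
#' @export
mrnaIndependentPqtlScan <- function(genotypes, proteins, expression = NULL,
                                    map = NULL, cfg = AnalysisConfig()) {
  P <- .asTraitMatrix(proteins, "protein")
  E <- if (!is.null(expression)) .asTraitMatrix(expression, "gene") else NULL
  samples <- colnames(genotypes)
  if (!is.null(rownames(P))) P <- P[samples, , drop = FALSE]
  if (!is.null(E) && !is.null(rownames(E))) E <- E[samples, , drop = FALSE]

  if (is.null(map)) {
    if (methods::is(proteins, "SummarizedExperiment") &&
        "gene_id" %in% colnames(SummarizedExperiment::rowData(proteins))) {
      map <- data.frame(
        protein_id = rownames(proteins),
        gene_id = SummarizedExperiment::rowData(proteins)$gene_id,
        stringsAsFactors = FALSE)
    } else {
      ids <- colnames(P)
      map <- data.frame(
        protein_id = ids,
        gene_id = ifelse(grepl("|", ids, fixed = TRUE),
                         sub("\\|.*$", "", ids), NA_character_),
        stringsAsFactors = FALSE)
    }
  }
  R <- P
  status <- setNames(character(ncol(P)), colnames(P))
  for (j in seq_len(ncol(P))) {
    gene <- map$gene_id[match(colnames(P)[j], map$protein_id)]
    mrna <- if (!is.null(E) && !is.na(gene) && gene %in% colnames(E))
      E[, gene] else NULL
    rr <- residualizeProteinOnMrna(P[, j], mrna, cfg@detectFraction)
    R[, j] <- rr$residuals
    status[j] <- rr$status
  }
  scan <- associationScan(genotypes, R, keep = "all")
  scan$adjustment_status <- status[scan$trait_id]
  best <- .bestPerSnp(scan)
  qtls <- data.frame(
    snp_id = best$snp_id,
    is_mrna_independent_pqtl = best$p <= cfg@qtlP,
    mrna_independent_best_trait = best$trait_id,
    mrna_independent_p = best$p, stringsAsFactors = FALSE)
  list(results = scan, qtls = qtls, status = status)
}
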