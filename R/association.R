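#' Minor allele frequency of a dosage vector
#'
#' @param dosage numeric vector of allele copies in [0, 2]; NAs ignored.
#' @return Frequency \code{min(f, 1 - f)} where \code{f = mean(dosage) / 2},
#'   with attribute \code{"flipped"} set when the coded allele was the major
#'   one (orientation flip needed).
#' @examples
#' computeMAF(c(0, 0, 1))  # 1 minor allele of 6
#' @export
computeMAF <- function(dosage) {
  d <- dosage[!is.na(dosage)]
  if (!length(d)) stop("empty dosage vector")
  if (any(d < 0 | d > 2)) stop("dosages must lie in [0, 2]")
  f <- mean(d) / 2
  out <- min(f, 1 - f)
  attr(out, "flipped") <- f > 0.5
  out
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test: given the allele counts, sums the probabilities
#' of all heterozygote counts whose probability under Hardy-Weinberg does
#' not exceed that of the observed count.  Probabilities are computed by the
#' standard recurrence between adjacent heterozygote configurations.
#' Monomorphic SNPs return p = 1 by convention.
#'
#' @param nAA,nAa,naa genotype counts (major homozygote, heterozygote,
#'   minor homozygote); non-negative, total >= 1.
#' @return Two-sided exact p-value in (0, 1].
#' @examples
#' hweExactTest(25, 50, 25)  # modal configuration: 1
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  cnt <- c(nAA, nAa, naa)
  if (anyNA(cnt) || any(cnt < 0)) stop("genotype counts must be non-negative")
  if (any(cnt != round(cnt))) stop("genotype counts must be integers")
  n <- sum(cnt)
  if (n < 1) stop("total genotype count must be >= 1")
  rare <- 2 * min(nAA, naa) + nAa
  rare <- min(rare, 2 * n - rare)
  if (rare == 0) return(1)

  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  # start from the smallest heterozygote count, unnormalized, via the
  # recurrence P(h+2)/P(h) = 4 * homRare(h) * homCommon(h) / ((h+1)(h+2))
  probs[1] <- 1
  if (length(hets) > 1) {
    for (k in seq_len(length(hets) - 1)) {
      h <- hets[k]
      homR <- (rare - h) / 2
      homC <- n - h - homR
      probs[k + 1] <- probs[k] * 4 * homR * homC / ((h + 1) * (h + 2))
    }
  }
  probs <- probs / sum(probs)
  obs <- which(hets == nAa)
  if (!length(obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(probs[probs <= probs[obs] * (1 + 1e-7)]))
}

#' Filter a genotype panel on MAF and Hardy-Weinberg equilibrium
#'
#' Retains SNPs with \code{maf >= cfg mafMin} and \code{hwe_p >= cfg
#' hwePMin}; counts removed per criterion are attached as attribute
#' \code{"removed"} and reported via \code{message}.  An empty result is a
#' warning, not an error.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param cfg an \linkS4class{AnalysisConfig}.
#' @return The filtered \linkS4class{GenotypeMatrix}.
#' @export
snpFilter <- function(genotypes, cfg = AnalysisConfig()) {
  rd <- snpInfo(genotypes)
  badMaf <- rd$maf < cfg@mafMin
  badHwe <- rd$hwe_p < cfg@hwePMin
  keep <- !(badMaf | badHwe)
  message(sprintf("snpFilter: %d/%d SNPs retained (%d below MAF %.3g, %d below HWE p %.3g)",
                  as.integer(sum(keep)), length(keep), as.integer(sum(badMaf)),
                  cfg@mafMin, as.integer(sum(badHwe)), cfg@hwePMin))
  if (!any(keep)) warning("empty panel: all SNPs removed by filters")
  out <- genotypes[keep, ]
  attr(out, "removed") <- c(maf = sum(badMaf), hwe = sum(badHwe))
  out
}

#' Single SNP-trait linear association
#'
#' Ordinary least squares of the trait on minor-allele copies with an
#' intercept; two-sided p from the t distribution with n - 2 degrees of
#' freedom; missing trait values dropped pairwise.  A constant dosage or
#' trait yields a flagged degenerate result (beta = 0, p = 1) rather than an
#' error, so genome-scale scans never abort mid-run.
#'
#' @param dosage numeric vector of allele copies.
#' @param trait numeric trait vector (may contain NA).
#' @return One-row \code{data.frame(n, beta, se, t, r2, p, degenerate)},
#'   satisfying \code{r2 = t^2 / (t^2 + n - 2)}.
#' @export
regressTrait <- function(dosage, trait) {
  if (length(dosage) != length(trait))
    stop("dosage and trait must have equal length")
  ok <- !is.na(dosage) & !is.na(trait)
  n <- sum(ok)
  degen <- function(n) data.frame(n = n, beta = 0, se = NA_real_,
                                  t = 0, r2 = 0, p = 1, degenerate = TRUE)
  if (n < 3) return(degen(n))
  x <- dosage[ok]; y <- trait[ok]
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  if (sxx <= 0 || syy <= 0) return(degen(n))
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  beta <- sxy / sxx
  df <- n - 2
  sse <- max(syy - beta * sxy, 0)
  if (sse == 0) {
    return(data.frame(n = n, beta = beta, se = 0, t = Inf, r2 = 1, p = 0,
                      degenerate = FALSE))
  }
  se <- sqrt(sse / df / sxx)
  t <- beta / se
  data.frame(n = n, beta = beta, se = se, t = t,
             r2 = t^2 / (t^2 + df), p = 2 * stats::pt(-abs(t), df),
             degenerate = FALSE)
}

# vectorized scan of one trait against every SNP column of G (samples x SNPs)
.scanOneTrait <- function(G, y) {
  ok <- !is.na(y)
  n <- sum(ok)
  m <- ncol(G)
  if (n < 3) {
    return(data.frame(n = rep(n, m), beta = 0, se = NA_real_, t = 0,
                      r2 = 0, p = 1, degenerate = TRUE))
  }
  g <- G[ok, , drop = FALSE]
  y <- y[ok]
  gm <- colMeans(g)
  ym <- mean(y)
  sxx <- colSums(g^2) - n * gm^2
  sxy <- as.vector(crossprod(g, y)) - n * gm * ym
  syy <- sum(y^2) - n * ym^2
  df <- n - 2
  beta <- ifelse(sxx > 1e-12, sxy / sxx, 0)
  sse <- pmax(syy - beta * sxy, 0)
  se <- sqrt(sse / df / pmax(sxx, 1e-300))
  t <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf))
  p <- 2 * stats::pt(-abs(t), df)
  r2 <- ifelse(is.finite(t), t^2 / (t^2 + df), 1)
  degenerate <- sxx <= 1e-12 | syy <= 1e-12
  beta[degenerate] <- 0; t[degenerate] <- 0; p[degenerate] <- 1
  r2[degenerate] <- 0; se[degenerate] <- NA_real_
  data.frame(n = rep(n, m), beta = beta, se = se, t = t, r2 = r2, p = p,
             degenerate = degenerate)
}

#' Genome-wide association scan
#'
#' Applies \code{\link{regressTrait}} (in vectorized form) to every
#' (SNP, trait) pair.  All traits are scanned genome-wide; there is no cis
#' window.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param traits trait container: numeric vector (one trait), matrix with
#'   samples in rows, or \code{SummarizedExperiment} (features x samples).
#'   Sample names, when present, must match the genotype panel.
#' @param keep \code{"all"} returns every pair; \code{"min"} returns one row
#'   per SNP holding its best (smallest p) trait -- the form used for QTL
#'   classification at genome scale.
#' @param traitName label used when \code{traits} is an unnamed vector.
#' @return \code{data.frame(snp_id, trait_id, n, beta, se, t, r2, p,
#'   degenerate)}.
#' @export
associationScan <- function(genotypes, traits, keep = c("all", "min"),
                            traitName = "trait") {
  keep <- match.arg(keep)
  M <- .asTraitMatrix(traits, traitName)
  samples <- colnames(genotypes)
  if (!is.null(rownames(M))) {
    unknown <- setdiff(rownames(M), samples)
    if (length(unknown))
      stop("sample-id mismatch: traits carry samples absent from the panel: ",
           paste(unknown[1:min(3, length(unknown))], collapse = ", "))
    # samples without a trait value (e.g. censored phenotypes) enter as NA
    # and drop out pairwise
    full <- matrix(NA_real_, length(samples), ncol(M),
                   dimnames = list(samples, colnames(M)))
    full[rownames(M), ] <- M
    M <- full
  } else if (nrow(M) != length(samples)) {
    stop("sample-id mismatch: trait rows != number of samples")
  }
  G <- t(dosages(genotypes))
  snps <- rownames(genotypes)
  if (ncol(M) == 0)
    return(data.frame(snp_id = character(), trait_id = character(),
                      n = integer(), beta = numeric(), se = numeric(),
                      t = numeric(), r2 = numeric(), p = numeric(),
                      degenerate = logical()))
  best <- NULL
  chunks <- vector("list", ncol(M))
  for (j in seq_len(ncol(M))) {
    res <- .scanOneTrait(G, M[, j])
    if (keep == "min") {
      if (is.null(best)) {
        best <- cbind(data.frame(snp_id = snps, trait_id = colnames(M)[j],
                                 stringsAsFactors = FALSE), res)
      } else {
        better <- res$p < best$p
        if (any(better)) {
          best[better, names(res)] <- res[better, ]
          best$trait_id[better] <- colnames(M)[j]
        }
      }
    } else {
      chunks[[j]] <- cbind(data.frame(snp_id = snps,
                                      trait_id = colnames(M)[j],
                                      stringsAsFactors = FALSE), res)
    }
  }
  out <- if (keep == "min") best else do.call(rbind, chunks)
  rownames(out) <- NULL
  out
}

#' Pairwise linkage disequilibrium as squared dosage correlation
#'
#' @param dosageI,dosageJ dosage vectors of equal length.
#' @return r^2 in [0, 1]; \code{NA} with attribute \code{"undefined"} when
#'   either vector is constant (treated as 0 by the pruner).
#' @export
ldR2 <- function(dosageI, dosageJ) {
  if (length(dosageI) != length(dosageJ))
    stop("dosage vectors must have equal length")
  ok <- !is.na(dosageI) & !is.na(dosageJ)
  x <- dosageI[ok]; y <- dosageJ[ok]
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  stats::cor(x, y)^2
}

#' Greedy LD pruning of association candidates
#'
#' Iterates candidates by ascending p (ties broken by chromosome, then
#' position, then SNP id) and keeps a SNP iff its dosage r^2 with every
#' already-kept SNP within \code{ldWindowBp} on the same chromosome is at
#' most \code{ldR2Max}.  Deterministic given the stated tie-break.
#'
#' @param candidates \code{data.frame} with columns \code{snp_id} and
#'   \code{p} (e.g. a filtered \code{\link{associationScan}} result).
#' @param genotypes the \linkS4class{GenotypeMatrix} the candidates refer to.
#' @param cfg an \linkS4class{AnalysisConfig}.
#' @return Character vector of retained SNP ids, in keep order.
#' @export
ldPrune <- function(candidates, genotypes, cfg = AnalysisConfig()) {
  if (!nrow(candidates)) return(character())
  rd <- snpInfo(genotypes)
  i <- match(candidates$snp_id, rownames(genotypes))
  if (anyNA(i)) stop("candidate SNP absent from genotype panel: ",
                     paste(candidates$snp_id[is.na(i)], collapse = ", "))
  chrom <- as.character(rd$chrom[i])
  pos <- rd$pos[i]
  ord <- order(candidates$p, chrom, pos, candidates$snp_id)
  D <- dosages(genotypes)
  keptIdx <- integer()
  for (k in ord) {
    ok <- TRUE
    if (length(keptIdx)) {
      near <- keptIdx[!is.na(chrom[keptIdx]) & !is.na(chrom[k]) &
                        chrom[keptIdx] == chrom[k] &
                        abs(pos[keptIdx] - pos[k]) <= cfg@ldWindowBp]
      for (j in near) {
        r2 <- ldR2(D[i[k], ], D[i[j], ])
        if (!is.na(r2) && r2 > cfg@ldR2Max) { ok <- FALSE; break }
      }
    }
    if (ok) keptIdx <- c(keptIdx, k)
  }
  candidates$snp_id[keptIdx]
}

#' Classify SNPs as drug / expression / protein QTLs
#'
#' A SNP is a drug QTL (dQTL) when its phenotype association reaches
#' \code{dqtlP}; an eQTL (pQTL) when its best gene (protein) association
#' reaches \code{qtlP}.  All trait scans are genome-wide.
#'
#' @param phenotypeScan \code{\link{associationScan}} result against the
#'   log2 IC50 phenotype.
#' @param expressionScan,proteinScan optional scan results against gene /
#'   protein expression (either full or \code{keep = "min"} form).
#' @param cfg an \linkS4class{AnalysisConfig}.
#' @return \code{data.frame} keyed by \code{snp_id} with flags
#'   \code{is_dqtl}, \code{is_eqtl}, \code{is_pqtl} and the best supporting
#'   trait and p per flag.
#' @export
classifyQTLs <- function(phenotypeScan, expressionScan = NULL,
                         proteinScan = NULL, cfg = AnalysisConfig()) {
  ph <- .bestPerSnp(phenotypeScan)
  out <- data.frame(snp_id = ph$snp_id,
                    is_dqtl = ph$p <= cfg@dqtlP, dqtl_p = ph$p,
                    stringsAsFactors = FALSE)
  addFlag <- function(out, scan, flag, traitCol, pCol) {
    b <- .bestPerSnp(scan)
    j <- match(out$snp_id, b$snp_id)
    out[[flag]] <- !is.na(j) & b$p[j] <= cfg@qtlP
    out[[traitCol]] <- b$trait_id[j]
    out[[pCol]] <- b$p[j]
    out
  }
  out <- if (!is.null(expressionScan))
    addFlag(out, expressionScan, "is_eqtl", "eqtl_best_trait", "eqtl_p")
  else cbind(out, is_eqtl = NA, eqtl_best_trait = NA_character_,
             eqtl_p = NA_real_)
  out <- if (!is.null(proteinScan))
    addFlag(out, proteinScan, "is_pqtl", "pqtl_best_trait", "pqtl_p")
  else cbind(out, is_pqtl = NA, pqtl_best_trait = NA_character_,
             pqtl_p = NA_real_)
  out
}

.bestPerSnp <- function(scan) {
  if (!nrow(scan)) return(scan)
  ord <- order(scan$snp_id, scan$p)
  s <- scan[ord, ]
  s[!duplicated(s$snp_id), ]
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure: rejects the k smallest p-values where k is the largest
#' index with \code{p[(k)] <= k * q / m}.
#'
#' @param p p-values in [0, 1].
#' @param q target false discovery rate.
#' @return \code{list(rejected (indices into p), threshold (largest rejected
#'   p, 0 when none), adjusted (BH-adjusted p-values))}.
#' @export
bhFDR <- function(p, q = 0.05) {
  if (!length(p)) return(list(rejected = integer(), threshold = 0,
                              adjusted = numeric()))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  rejected <- which(!is.na(adj) & adj <= q)
  list(rejected = rejected,
       threshold = if (length(rejected)) max(p[rejected]) else 0,
       adjusted = adj)
}

#' Quantile-quantile points for a p-value set
#'
#' @param p non-empty p-values in (0, 1]; zeros are clipped to the smallest
#'   representable positive double with a warning.
#' @return \code{data.frame(expected, observed)} of -log10 values: observed
#'   sorted ascending, expected quantile \code{i / (m + 1)} for rank i.
#' @export
qqPoints <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("p-values of 0 clipped to the smallest representable positive value")
    p[p == 0] <- .Machine$double.xmin
  }
  m <- length(p)
  data.frame(expected = -log10(seq_len(m) / (m + 1)),
             observed = -log10(sort(p)))
}

#' Protein-phenotype association scan with FDR control
#'
#' Regresses the phenotype on each protein feature, applies
#' Benjamini-Hochberg FDR and returns quantile-quantile points of the
#' p-value set.
#'
#' @param proteins protein container (matrix samples x proteins or
#'   \code{SummarizedExperiment} proteins x samples).
#' @param phenotype named numeric vector of log2 IC50 values.
#' @param cfg an \linkS4class{AnalysisConfig} (uses \code{fdrQ}).
#' @return \code{list(results (per-protein data.frame with fdr_reject
#'   column), threshold, qq)}.
#' @export
proteinPhenotypeScan <- function(proteins, phenotype, cfg = AnalysisConfig()) {
  M <- .asTraitMatrix(proteins, "protein")
  if (!is.null(rownames(M)) && !is.null(names(phenotype))) {
    shared <- intersect(rownames(M), names(phenotype))
    if (!length(shared))
      stop("sample-id mismatch between proteins and phenotype")
    M <- M[shared, , drop = FALSE]
    phenotype <- phenotype[shared]
  }
  res <- do.call(rbind, lapply(seq_len(ncol(M)), function(j) {
    cbind(data.frame(feature_id = colnames(M)[j], stringsAsFactors = FALSE),
          regressTrait(M[, j], phenotype))
  }))
  fdr <- bhFDR(res$p, cfg@fdrQ)
  res$p_adjusted <- fdr$adjusted
  res$fdr_reject <- seq_len(nrow(res)) %in% fdr$rejected
  list(results = res, threshold = fdr$threshold, qq = qqPoints(res$p))
}
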