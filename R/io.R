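#' Read genotypes from a VCF
#'
#' Converts hard GT calls of biallelic records to minor-allele dosages.
#' Multiallelic records are skipped (count reported via \code{message}).
#' SNPs missing in more than \code{maxMissing} of samples are dropped;
#' remaining missing dosages are mean-imputed with the per-SNP imputation
#' count recorded in \code{rowData$n_imputed}.  Positions are kept 1-based.
#' Orientation to the minor allele (and the resulting \code{flipped} flag)
#' is handled by the \code{\link{GenotypeMatrix}} constructor.
#'
#' @param path path to an uncompressed or gzipped VCF with GT fields.
#' @param maxMissing maximum tolerated per-SNP missing fraction
#'   (default 0.05).
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
readGenotypesVcf <- function(path, maxMissing = 0.05) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@gt) == 0 || nrow(vcf@fix) == 0)
    stop("empty panel: no usable records in ", path)
  bi <- vcfR::is.biallelic(vcf)
  nSkipped <- sum(!bi)
  if (nSkipped) message("readGenotypesVcf: skipped ", nSkipped,
                        " multiallelic record(s)")
  vcf <- vcf[bi, ]
  fix <- vcfR::getFIX(vcf)
  if (nrow(vcf@gt) == 0) stop("empty panel: no biallelic records in ", path)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  lut <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  d <- matrix(unname(lut[gt]), nrow = nrow(gt), ncol = ncol(gt))
  colnames(d) <- colnames(gt)

  ids <- fix[, "ID"]
  noId <- is.na(ids) | ids == "."
  ids[noId] <- paste0(fix[noId, "CHROM"], ":", fix[noId, "POS"])
  rownames(d) <- ids

  missFrac <- rowMeans(is.na(d))
  drop <- missFrac > maxMissing
  if (any(drop)) message("readGenotypesVcf: dropped ", sum(drop),
                         " SNP(s) with > ", maxMissing * 100, "% missing GTs")
  d <- d[!drop, , drop = FALSE]
  fix <- fix[!drop, , drop = FALSE]
  if (!nrow(d)) stop("empty panel: all records dropped by missingness filter")

  nImputed <- integer(nrow(d))
  for (i in which(rowSums(is.na(d)) > 0)) {
    na <- is.na(d[i, ])
    d[i, na] <- mean(d[i, !na])
    nImputed[i] <- sum(na)
  }
  gm <- GenotypeMatrix(d, chrom = fix[, "CHROM"],
                       pos = as.integer(fix[, "POS"]),
                       ref = fix[, "REF"], alt = fix[, "ALT"])
  SummarizedExperiment::rowData(gm)$n_imputed <- nImputed
  gm
}

#' Write genotypes as a minimal VCF
#'
#' One biallelic record per SNP with hard GT calls (dosages rounded).  The
#' ALT column carries the allele the stored dosage counts (the minor
#' allele), so a write/read round trip reproduces the dosage matrix and MAFs
#' exactly.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param path output path (plain text).
#' @export
writeGenotypesVcf <- function(genotypes, path) {
  rd <- snpInfo(genotypes)
  d <- round(dosages(genotypes))
  gtStr <- matrix(c("0/0", "0/1", "1/1")[d + 1], nrow = nrow(d))
  chrom <- ifelse(is.na(rd$chrom), "1", as.character(rd$chrom))
  pos <- ifelse(is.na(rd$pos), seq_len(nrow(d)), rd$pos)
  ref <- ifelse(is.na(rd$ref), "A", rd$ref)
  alt <- ifelse(is.na(rd$alt), "G", rd$alt)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(d)), collapse = "\t"))
  body <- vapply(seq_len(nrow(d)), function(i) {
    paste(c(chrom[i], pos[i], rownames(d)[i], ref[i], alt[i], ".", "PASS",
            ".", "GT", gtStr[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a typed matrix or table from TSV
#'
#' @param path TSV with a header row; sample ids in the first column for
#'   matrix kinds.
#' @param kind \code{"expression"} / \code{"protein"} (samples x features,
#'   returned as a \code{SummarizedExperiment} features x samples; protein
#'   headers of the form \code{"GENE|isoform"} are parsed into rowData),
#'   \code{"dosage"} (returned as a \linkS4class{GenotypeMatrix};
#'   chromosome/position parsed from \code{"chrom:pos"} SNP ids when
#'   possible), or \code{"dose_response"} (tidy survival table).
#' @return Typed object as described above.
#' @export
readMatrixTsv <- function(path, kind = c("expression", "protein", "dosage",
                                         "dose_response")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (kind == "dose_response") {
    need <- c("sample_id", "concentration_uM", "pct_survival")
    if (!all(need %in% colnames(df)))
      stop("dose-response TSV must have columns: ", paste(need, collapse = ", "))
    return(df)
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated sample id in ", path, ": ",
         ids[duplicated(ids)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (kind == "dosage") return(GenotypeMatrix(t(m)))
  feat <- colnames(m)
  rdat <- if (kind == "protein") {
    hasIso <- grepl("|", feat, fixed = TRUE)
    S4Vectors::DataFrame(
      gene_id = ifelse(hasIso, sub("\\|.*$", "", feat), feat),
      isoform = ifelse(hasIso, sub("^[^|]*\\|", "", feat), NA_character_),
      row.names = feat)
  } else {
    S4Vectors::DataFrame(gene_id = feat, row.names = feat)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = stats::setNames(list(t(m)),
                             if (kind == "protein") "protein" else "expr"),
    rowData = rdat)
}

#' Write a matrix or table as TSV
#'
#' Samples in rows, features in columns, \code{NA} for missing values.
#' Numbers are written at full double precision, so a write/read round trip
#' is bit-identical for finite values.
#'
#' @param x matrix (samples x features), \code{SummarizedExperiment}
#'   (features x samples), \linkS4class{GenotypeMatrix} (written as a sample
#'   x SNP dosage table), or a tidy dose-response \code{data.frame}.
#' @param path output path.
#' @param sampleCol header of the sample-id column (matrix kinds).
#' @export
writeMatrixTsv <- function(x, path, sampleCol = "sample_id") {
  if (is.data.frame(x)) {
    out <- x
    for (j in seq_along(out)) if (is.numeric(out[[j]])) out[[j]] <- .fmtNum(out[[j]])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  m <- if (methods::is(x, "GenotypeMatrix")) t(dosages(x))
  else if (methods::is(x, "SummarizedExperiment")) t(SummarizedExperiment::assay(x))
  else x
  body <- cbind(rownames(m), matrix(.fmtNum(m), nrow = nrow(m)))
  lines <- c(paste(c(sampleCol, colnames(m)), collapse = "\t"),
             apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write ground truth tables as TSV
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param effectsPath,phenotypePath output paths (either may be NULL).
#' @export
writeGroundTruthTsv <- function(truth, effectsPath = NULL,
                                phenotypePath = NULL) {
  if (!is.null(effectsPath)) writeMatrixTsv(truth@effects, effectsPath)
  if (!is.null(phenotypePath) && nrow(truth@phenotype))
    writeMatrixTsv(truth@phenotype, phenotypePath)
  invisible(NULL)
}
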