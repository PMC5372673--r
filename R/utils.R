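# Internal helpers shared across modules.

# Stage-keyed seed derivation: one root seed spawns a fixed per-stage stream
# so adding a stage never perturbs earlier stages' randomness.  Kept below
# 2^31 (R integers are 32-bit).
.stageIndex <- c(genotypes = 1L, expression = 2L, proteins = 3L,
                 dose_response = 4L, null_sets = 5L, pipeline = 6L)

.deriveSeed <- function(root, stage) {
  idx <- .stageIndex[[stage]]
  as.integer(((as.numeric(root) %% 2147483647) * 131 + idx * 7919) %% 2147483646) + 1L
}

#' Dosage accessor
#'
#' @param x a \linkS4class{GenotypeMatrix}
#' @return numeric matrix of minor-allele dosages, SNPs in rows, samples in
#'   columns.
#' @export
dosages <- function(x) SummarizedExperiment::assay(x, "dosage")

#' Per-SNP metadata accessor
#'
#' @param x a \linkS4class{GenotypeMatrix}
#' @return \code{DataFrame} with columns chrom, pos, ref, alt, maf, hwe_p,
#'   flipped (and gen_maf for simulated panels), one row per SNP.
#' @export
snpInfo <- function(x) SummarizedExperiment::rowData(x)

# Coerce trait input (matrix samples x traits, SummarizedExperiment features
# x samples, or a named/plain numeric vector) into samples x traits matrix.
.asTraitMatrix <- function(traits, traitName = "trait") {
  if (methods::is(traits, "SummarizedExperiment")) {
    m <- t(SummarizedExperiment::assay(traits))
  } else if (is.matrix(traits)) {
    m <- traits
  } else if (is.numeric(traits)) {
    m <- matrix(traits, ncol = 1, dimnames = list(names(traits), traitName))
  } else stop("unsupported trait container: ", class(traits)[1])
  if (is.null(colnames(m))) colnames(m) <- sprintf("trait%03d", seq_len(ncol(m)))
  m
}

# Numbers are serialized at full double precision so TSV round trips are
# bit-identical for finite values.
.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}
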