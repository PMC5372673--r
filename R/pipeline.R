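#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation (when the config holds a
#' \code{simulate} block) or input loading; IC50 phenotyping; SNP filtering
#' (MAF, Hardy-Weinberg); the drug-QTL scan; LD pruning; genome-wide
#' expression and protein QTL scans; QTL classification; MAF-matched
#' permutation enrichment; the mRNA-independent protein QTL scan; and the
#' protein-phenotype scan with FDR control.  All randomness flows from one
#' root seed through fixed per-stage streams, and every output (including
#' the manifest) is written deterministically, so rerunning an identical
#' config reproduces every artifact byte for byte.  Wall-clock timestamps
#' go to a side \code{run.log} only.
#'
#' @param config a list, or path to a YAML file, with elements
#'   \code{seed} (root seed), either \code{simulate} (arguments to
#'   \code{\link{SimulationConfig}}, \code{plantedEffects} given as a list
#'   of \code{\link{plantedEffect}} argument lists) or \code{inputs} (paths:
#'   \code{genotypes_vcf} or \code{dosage_tsv}, \code{dose_response_tsv},
#'   optional \code{expression_tsv}, \code{protein_tsv}), and optional
#'   \code{analysis} (arguments to \code{\link{AnalysisConfig}}).
#' @param outDir output directory (created if needed).
#' @return The run manifest (a list), invisibly; written to
#'   \code{manifest.json}.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run.log")
  cat("", file = logPath)
  logMsg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
    cat(line, "\n", file = logPath, append = TRUE, sep = "")
    message(line)
  }
  rootSeed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  manifest <- list(config = config, seed = rootSeed, stages = list())
  addStage <- function(name, counts) {
    manifest$stages[[name]] <<- counts
    logMsg("stage ", name, ": ",
           paste(names(counts), unlist(counts), sep = "=", collapse = ", "))
  }

  acfg <- do.call(AnalysisConfig, as.list(config$analysis))

  ## ---- inputs ----
  if (!is.null(config$simulate)) {
    simArgs <- as.list(config$simulate)
    if (!is.null(simArgs$plantedEffects) && is.list(simArgs$plantedEffects) &&
        !is.data.frame(simArgs$plantedEffects)) {
      simArgs$plantedEffects <- do.call(
        rbind, lapply(simArgs$plantedEffects,
                      function(a) do.call(plantedEffect, as.list(a))))
    }
    simArgs$seed <- .deriveSeed(rootSeed, "pipeline")
    scfg <- do.call(SimulationConfig, simArgs)
    cohort <- simulateCohort(scfg)
    gm <- cohort$genotypes
    expression <- cohort$expression
    proteins <- cohort$proteins
    doseResponse <- cohort$doseResponse
    writeGenotypesVcf(gm, file.path(outDir, "genotypes.vcf"))
    writeMatrixTsv(gm, file.path(outDir, "dosages.tsv"))
    if (!is.null(expression))
      writeMatrixTsv(expression, file.path(outDir, "expression.tsv"))
    if (!is.null(proteins))
      writeMatrixTsv(proteins, file.path(outDir, "proteins.tsv"))
    writeMatrixTsv(doseResponse, file.path(outDir, "dose_response.tsv"))
    writeGroundTruthTsv(cohort$truth,
                        file.path(outDir, "truth_effects.tsv"),
                        file.path(outDir, "truth_phenotype.tsv"))
    addStage("simulate", list(n_samples = ncol(gm), n_snps = nrow(gm),
                              n_genes = if (is.null(expression)) 0 else nrow(expression),
                              n_proteins = if (is.null(proteins)) 0 else nrow(proteins)))
  } else {
    inp <- config$inputs
    if (is.null(inp)) stop("config needs either a 'simulate' or an 'inputs' block")
    for (p in unlist(inp)) if (!file.exists(p)) stop("missing input file: ", p)
    gm <- if (!is.null(inp$genotypes_vcf)) readGenotypesVcf(inp$genotypes_vcf)
    else if (!is.null(inp$dosage_tsv)) readMatrixTsv(inp$dosage_tsv, "dosage")
    else stop("inputs must provide genotypes_vcf or dosage_tsv")
    doseResponse <- readMatrixTsv(inp$dose_response_tsv, "dose_response")
    expression <- if (!is.null(inp$expression_tsv))
      readMatrixTsv(inp$expression_tsv, "expression") else NULL
    proteins <- if (!is.null(inp$protein_tsv))
      readMatrixTsv(inp$protein_tsv, "protein") else NULL
    addStage("load", list(n_samples = ncol(gm), n_snps = nrow(gm)))
  }
  inputDigests <- lapply(
    Filter(file.exists, as.character(unlist(config$inputs))),
    function(p) unname(tools::md5sum(p)))
  names(inputDigests) <- Filter(file.exists, as.character(unlist(config$inputs)))
  manifest$input_md5 <- inputDigests

  ## ---- phenotype ----
  phenoTable <- fitIC50Curves(doseResponse)
  writeMatrixTsv(phenoTable, file.path(outDir, "phenotypes.tsv"))
  ph <- log2Phenotypes(phenoTable)
  addStage("phenotype", list(n_fit = nrow(phenoTable),
                             n_censored = ph$nCensored,
                             ks_normality_p = ph$ksP))

  ## ---- SNP filter ----
  nBefore <- nrow(gm)
  gm <- suppressMessages(snpFilter(gm, acfg))
  removed <- attr(gm, "removed")
  addStage("snp_filter", list(n_in = nBefore, n_out = nrow(gm),
                              removed_maf = unname(removed["maf"]),
                              removed_hwe = unname(removed["hwe"])))

  ## ---- dQTL scan ----
  pheno <- ph$values[colnames(gm)]
  names(pheno) <- colnames(gm)
  dscan <- associationScan(gm, pheno, traitName = "log2_ic50")
  writeMatrixTsv(dscan, file.path(outDir, "dqtl_scan.tsv"))
  writeMatrixTsv(
    data.frame(chrom = snpInfo(gm)$chrom, pos = snpInfo(gm)$pos, p = dscan$p),
    file.path(outDir, "manhattan.tsv"))
  dqtlHits <- dscan[dscan$p <= acfg@dqtlP, , drop = FALSE]
  pruned <- ldPrune(dqtlHits, gm, acfg)
  writeLines(pruned, file.path(outDir, "dqtl_pruned.txt"))
  addStage("dqtl_scan", list(n_snps = nrow(dscan),
                             n_dqtl = nrow(dqtlHits),
                             n_dqtl_pruned = length(pruned)))

  ## ---- eQTL / pQTL scans + classification ----
  escan <- if (!is.null(expression))
    associationScan(gm, expression, keep = "min") else NULL
  pscan <- if (!is.null(proteins))
    associationScan(gm, proteins, keep = "min") else NULL
  if (!is.null(escan)) writeMatrixTsv(escan, file.path(outDir, "eqtl_best.tsv"))
  if (!is.null(pscan)) writeMatrixTsv(pscan, file.path(outDir, "pqtl_best.tsv"))
  qtls <- classifyQTLs(dscan, escan, pscan, acfg)
  addStage("classify", list(
    n_dqtl = sum(qtls$is_dqtl),
    n_eqtl = if (is.null(escan)) NA else sum(qtls$is_eqtl),
    n_pqtl = if (is.null(pscan)) NA else sum(qtls$is_pqtl)))

  ## ---- enrichment ----
  target <- if (acfg@usePruned) pruned else dqtlHits$snp_id
  enrichRows <- list()
  if (length(target)) {
    nullSeed <- .deriveSeed(rootSeed, "null_sets")
    flags <- c(if (!is.null(escan)) "eqtl",
               if (!is.null(pscan)) "pqtl")
    for (fl in flags) {
      er <- enrichmentTest(target, qtls, gm, flag = fl, cfg = acfg,
                           seed = nullSeed)
      enrichRows[[fl]] <- data.frame(
        flag = fl, target_size = er@targetSize, observed = er@observed,
        null_mean = mean(er@nullCounts), null_sd = stats::sd(er@nullCounts),
        empirical_p = er@empiricalP, B = length(er@nullCounts),
        maf_bin_width = acfg@mafBinWidth, seed = nullSeed,
        stringsAsFactors = FALSE)
    }
  } else logMsg("no drug-QTL target set; enrichment skipped")
  if (is.null(proteins)) logMsg("no protein matrix; pQTL stages skipped")

  ## ---- conditional (mRNA-independent pQTL) scan ----
  if (!is.null(proteins)) {
    cond <- mrnaIndependentPqtlScan(gm, proteins, expression, cfg = acfg)
    writeMatrixTsv(cond$results, file.path(outDir, "conditional_scan.tsv"))
    qtls <- merge(qtls, cond$qtls, by = "snp_id", sort = TRUE)
    addStage("conditional", list(
      n_mrna_independent_pqtl = sum(qtls$is_mrna_independent_pqtl),
      n_unadjusted = sum(cond$status != "adjusted")))
    if (length(target)) {
      er <- enrichmentTest(target, qtls, gm, flag = "mrna_independent_pqtl",
                           cfg = acfg, seed = .deriveSeed(rootSeed, "null_sets"))
      enrichRows[["mrna_independent_pqtl"]] <- data.frame(
        flag = "mrna_independent_pqtl", target_size = er@targetSize,
        observed = er@observed, null_mean = mean(er@nullCounts),
        null_sd = stats::sd(er@nullCounts), empirical_p = er@empiricalP,
        B = length(er@nullCounts), maf_bin_width = acfg@mafBinWidth,
        seed = .deriveSeed(rootSeed, "null_sets"), stringsAsFactors = FALSE)
    }
  }
  writeMatrixTsv(qtls, file.path(outDir, "qtl_flags.tsv"))
  if (length(enrichRows)) {
    enrichTab <- do.call(rbind, enrichRows)
    writeMatrixTsv(enrichTab, file.path(outDir, "enrichment.tsv"))
    addStage("enrichment", list(n_tests = nrow(enrichTab)))
  }

  ## ---- protein-phenotype scan ----
  if (!is.null(proteins)) {
    pp <- proteinPhenotypeScan(proteins, pheno, acfg)
    writeMatrixTsv(pp$results, file.path(outDir, "protein_phenotype.tsv"))
    writeMatrixTsv(pp$qq, file.path(outDir, "protein_phenotype_qq.tsv"))
    addStage("protein_phenotype", list(
      n_proteins = nrow(pp$results),
      n_fdr_significant = sum(pp$results$fdr_reject),
      fdr_threshold = pp$threshold))
  }

  manifest$outputs <- sort(setdiff(list.files(outDir), c("run.log", "manifest.json")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  logMsg("pipeline complete: ", length(manifest$outputs), " artifacts")
  invisible(manifest)
}
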