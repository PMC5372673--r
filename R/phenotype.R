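#' Fit an IC50 from a single dose-response curve
#'
#' The primary method is a constrained four-parameter logistic fit
#' \code{survival = bottom + (top - bottom) / (1 + (c / ic50)^hill)} with
#' bottom in [0, 30], top in [70, 130], positive hill slope and IC50 within
#' [min(conc)/10, max(conc)*10] -- the assay normalizes to a no-drug control
#' near 100\%, and an unbounded 4PL on six points is ill-posed.  If the fit
#' fails to converge, or the curve rises between consecutive concentrations
#' by more than \code{monotoneTol} percentage points, the estimate falls
#' back to linear interpolation of the 50\%-crossing on the log2
#' concentration axis.  When no crossing exists the sample is censored:
#' \code{above_max} if survival stays above 50\% everywhere, \code{below_min}
#' if below.
#'
#' @param concentrations strictly increasing positive concentrations (uM),
#'   at least 4.
#' @param survival percent survival relative to the no-drug control, one
#'   value per concentration (replicate-averaged), all >= 0.
#' @param method \code{"auto"} (4PL with interpolation fallback),
#'   \code{"fourpl"}, or \code{"interp"}.
#' @param monotoneTol maximum tolerated rise (percentage points) between
#'   consecutive concentrations before the 4PL is abandoned.
#' @return One-row \code{data.frame}: \code{ic50_uM}, \code{log2_ic50},
#'   \code{censor_flag} (\code{none}/\code{below_min}/\code{above_max}),
#'   \code{fit_method} (\code{fourpl}/\code{interpolation}/\code{censored}),
#'   \code{sse} (residual sum of squares of the 4PL, NA otherwise).
#' @examples
#' conc <- c(50, 100, 175, 250, 375, 500)
#' surv <- 100 / (1 + (conc / 100)^1.5)
#' fitIC50(conc, surv)$ic50_uM
#' @export
fitIC50 <- function(concentrations, survival,
                    method = c("auto", "fourpl", "interp"),
                    monotoneTol = 10) {
  method <- match.arg(method)
  if (length(concentrations) < 4)
    stop("at least 4 concentrations are required")
  if (length(survival) != length(concentrations))
    stop("survival and concentrations must have equal length")
  if (any(concentrations <= 0) || any(diff(concentrations) <= 0))
    stop("concentrations must be positive and strictly increasing")
  if (any(survival < 0)) stop("survival values must be >= 0")

  row <- function(ic50, flag, fit, sse = NA_real_) {
    data.frame(ic50_uM = ic50,
               log2_ic50 = if (is.na(ic50)) NA_real_ else log2(ic50),
               censor_flag = flag, fit_method = fit, sse = sse,
               stringsAsFactors = FALSE)
  }
  if (all(survival > 50)) return(row(NA_real_, "above_max", "censored"))
  if (all(survival < 50)) return(row(NA_real_, "below_min", "censored"))

  nonMonotone <- any(diff(survival) > monotoneTol)
  if (method == "fourpl" || (method == "auto" && !nonMonotone)) {
    fit <- .fit4pl(concentrations, survival)
    if (!is.null(fit))
      return(row(fit$ic50, "none", "fourpl", fit$sse))
    if (method == "fourpl")
      warning("4PL fit failed to converge; falling back to interpolation")
  }
  ic50 <- .interpIC50(concentrations, survival)
  row(ic50, "none", "interpolation")
}

.fit4pl <- function(conc, surv) {
  lowerC <- min(conc) / 10
  upperC <- max(conc) * 10
  startIc50 <- .interpIC50(conc, surv)
  if (is.na(startIc50)) startIc50 <- exp(mean(log(range(conc))))
  # multi-start: the 4-parameter surface on few points has local optima
  # when top/bottom and slope trade off, and data-driven plateau starts
  # stall at the bounds when the curve does not reach its plateaus inside
  # the tested range -- so the control-normalized (0, 100) start is always
  # tried as well
  starts <- expand.grid(
    hill = c(0.8, 1.5, 3),
    bottom = unique(c(0, max(0, min(min(surv), 30)))),
    top = unique(c(100, min(130, max(max(surv), 70)))))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    start <- list(bottom = starts$bottom[s], top = starts$top[s],
                  ic50 = min(max(startIc50, lowerC), upperC),
                  hill = starts$hill[s])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        surv ~ bottom + (top - bottom) / (1 + (conc / ic50)^hill),
        start = start,
        lower = c(bottom = 0, top = 70, ic50 = lowerC, hill = 0.1),
        upper = c(bottom = 30, top = 130, ic50 = upperC, hill = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) {
      cf <- stats::coef(fit)
      best <- list(ic50 = unname(cf["ic50"]), hill = unname(cf["hill"]),
                   bottom = unname(cf["bottom"]), top = unname(cf["top"]),
                   sse = sse)
    }
  }
  best
}

# first 50%-crossing between adjacent concentrations, linear on log2(conc)
.interpIC50 <- function(conc, surv) {
  for (i in seq_len(length(conc) - 1)) {
    s1 <- surv[i]; s2 <- surv[i + 1]
    if ((s1 - 50) * (s2 - 50) <= 0 && s1 != s2) {
      l1 <- log2(conc[i]); l2 <- log2(conc[i + 1])
      return(2^(l1 + (50 - s1) * (l2 - l1) / (s2 - s1)))
    }
    if (s1 == 50) return(conc[i])
  }
  if (surv[length(surv)] == 50) return(conc[length(conc)])
  NA_real_
}

#' Fit IC50s for a cohort of dose-response curves
#'
#' @param doseResponse tidy \code{data.frame(sample_id, concentration_uM,
#'   pct_survival)}; replicate rows for the same (sample, concentration) are
#'   averaged before fitting.
#' @inheritParams fitIC50
#' @return Phenotype table: one row per sample with the columns of
#'   \code{\link{fitIC50}} plus \code{sample_id}.
#' @export
fitIC50Curves <- function(doseResponse, method = c("auto", "fourpl", "interp"),
                          monotoneTol = 10) {
  method <- match.arg(method)
  need <- c("sample_id", "concentration_uM", "pct_survival")
  if (!all(need %in% colnames(doseResponse)))
    stop("dose-response table must have columns: ", paste(need, collapse = ", "))
  agg <- stats::aggregate(pct_survival ~ sample_id + concentration_uM,
                          data = doseResponse, FUN = mean)
  out <- do.call(rbind, lapply(split(agg, agg$sample_id), function(d) {
    d <- d[order(d$concentration_uM), ]
    cbind(data.frame(sample_id = d$sample_id[1], stringsAsFactors = FALSE),
          fitIC50(d$concentration_uM, d$pct_survival, method, monotoneTol))
  }))
  rownames(out) <- NULL
  out[order(out$sample_id), ]
}

#' Extract log2 IC50 phenotypes with a normality report
#'
#' Returns the log2 IC50 values of uncensored samples together with a
#' Lilliefors-corrected Kolmogorov-Smirnov normality p-value (the correction
#' is needed because mean and SD are estimated from the same data; a plain
#' KS test against a fitted normal would be anti-conservative) and a
#' pass/fail flag at p >= 0.05.
#'
#' @param phenotypes output of \code{\link{fitIC50Curves}}.
#' @param alpha normality pass level (default 0.05).
#' @return \code{list(values (named numeric), ksP, pass, nCensored)}.
#'   \code{ksP} is \code{NA} with fewer than 5 uncensored samples (the
#'   Lilliefors statistic is undefined below that).
#' @export
log2Phenotypes <- function(phenotypes, alpha = 0.05) {
  ok <- phenotypes$censor_flag == "none"
  v <- phenotypes$log2_ic50[ok]
  names(v) <- phenotypes$sample_id[ok]
  if (length(v) < 3) stop("need at least 3 uncensored samples")
  if (stats::sd(v) == 0) stop("degenerate input: constant phenotype vector")
  if (length(v) >= 5) {
    ksP <- nortest::lillie.test(v)$p.value
    pass <- ksP >= alpha
  } else {
    ksP <- NA_real_; pass <- NA
  }
  list(values = v, ksP = ksP, pass = pass, nCensored = sum(!ok))
}

#' qPCR fold change by the double-delta-CT method
#'
#' \code{ddct = (ctTargetCondition - ctReferenceCondition) -
#' (ctTargetControl - ctReferenceControl)}.  The standard (Livak)
#' convention reports \code{2^-ddct}; the \code{"asWritten"} convention
#' reports \code{2^ddct}, which inverts the knockdown direction.  Both are
#' implemented and the convention used is recorded in the output, so no
#' silent guessing occurs downstream; the two conventions are reciprocal.
#'
#' @param ctTargetCondition,ctReferenceCondition threshold cycles of the
#'   target and reference (housekeeping) gene in the experimental condition.
#' @param ctTargetControl,ctReferenceControl the same in the control.
#' @param convention \code{"livak"} (default) or \code{"asWritten"}.
#' @return \code{list(foldChange, ddct, convention)}.
#' @examples
#' ddctFoldChange(26, 20, 25, 20)$foldChange  # one cycle later: 0.5 (livak)
#' @export
ddctFoldChange <- function(ctTargetCondition, ctReferenceCondition,
                           ctTargetControl, ctReferenceControl,
                           convention = c("livak", "asWritten")) {
  convention <- match.arg(convention)
  cts <- c(ctTargetCondition, ctReferenceCondition,
           ctTargetControl, ctReferenceControl)
  if (length(cts) != 4 || anyNA(cts) || any(cts <= 0))
    stop("all four CT values must be present and positive")
  ddct <- (ctTargetCondition - ctReferenceCondition) -
    (ctTargetControl - ctReferenceControl)
  fc <- if (convention == "livak") 2^(-ddct) else 2^ddct
  list(foldChange = fc, ddct = ddct, convention = convention)
}

#' Relative change in drug resistance after knockdown
#'
#' \code{(survConditionDrug / survConditionControl) /
#' (survScrambleDrug / survScrambleControl)}: the drug-normalized survival
#' of the knockdown condition relative to the scrambled-siRNA control.
#'
#' @param survConditionDrug,survConditionControl survival of the knockdown
#'   cells with drug and with vehicle.
#' @param survScrambleDrug,survScrambleControl the same for the scrambled
#'   control.
#' @return Unitless ratio; > 1 means the knockdown increased resistance.
#' @examples
#' relativeResistance(0.6, 1.0, 0.5, 1.0)  # 1.2
#' @export
relativeResistance <- function(survConditionDrug, survConditionControl,
                               survScrambleDrug, survScrambleControl) {
  s <- c(survConditionDrug, survConditionControl,
         survScrambleDrug, survScrambleControl)
  if (anyNA(s) || any(s < 0)) stop("survival values must be >= 0")
  if (survConditionControl <= 0 || survScrambleControl <= 0)
    stop("control survivals must be > 0")
  if (survScrambleDrug == 0)
    stop("division-degenerate input: scramble drug survival is 0")
  (survConditionDrug / survConditionControl) /
    (survScrambleDrug / survScrambleControl)
}
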