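## Predictive-model pipeline (univariate screen -> stepwise regression with
## variance-inflation checks -> ROC) and the method-agreement statistics
## (Bland-Altman, Lin's concordance, ICC).

#' Fitted multivariate model result
#'
#' @slot retained character, names of the retained predictors.
#' @slot betas named numeric, unstandardised coefficients (incl. intercept).
#' @slot ci95 matrix of per-coefficient 95\% confidence intervals.
#' @slot pValues named numeric per-coefficient p-values.
#' @slot r2,adjR2 coefficient of determination and its adjusted form.
#' @slot fStat numeric(3): F statistic, df1, df2.
#' @slot vifs named numeric variance inflation factors (>= 1).
#' @slot n integer sample size.
#' @slot fit the underlying \code{lm} fit.
#'
#' @export
setClass("ModelResult",
  representation(retained = "character", betas = "numeric", ci95 = "matrix",
                 pValues = "numeric", r2 = "numeric", adjR2 = "numeric",
                 fStat = "numeric", vifs = "numeric", n = "integer",
                 fit = "ANY"))

setValidity("ModelResult", function(object) {
  if (object@r2 < 0 || object@r2 > 1) return("r2 outside [0, 1]")
  if (length(object@vifs) && any(object@vifs < 1 - 1e-9))
    return("VIF < 1")
  TRUE
})

setMethod("show", "ModelResult", function(object) {
  cat(sprintf("ModelResult: n = %d, R2 = %.3f (adj %.3f)\n",
              object@n, object@r2, object@adjR2))
  if (length(object@fStat) == 3L)
    cat(sprintf("  F(%g, %g) = %.2f\n", object@fStat[2], object@fStat[3],
                object@fStat[1]))
  if (length(object@retained))
    cat("  retained:", paste(object@retained, collapse = ", "), "\n")
  else cat("  intercept-only model\n")
  if (length(object@vifs) && any(object@vifs > 10))
    cat("  WARNING: VIF > 10 for",
        paste(names(object@vifs)[object@vifs > 10], collapse = ", "), "\n")
  invisible(NULL)
})

#' Method-agreement report
#'
#' Bland-Altman statistics on d = x - y, Pearson correlation, Lin's
#' concordance correlation and its bias-correction factor, and the
#' intraclass correlation coefficient.
#'
#' @slot meanDiff mean difference with its 95\% CI (\code{ciMean}).
#' @slot loaLow,loaHigh limits of agreement (mean +/- 1.96 SD) with 95\%
#'   CIs (\code{ciLoaLow}, \code{ciLoaHigh}).
#' @slot pearsonR Pearson correlation.
#' @slot linCCC Lin's concordance correlation coefficient.
#' @slot biasCorrectionFactor C_b = CCC / r.
#' @slot icc two-way random-effects, absolute-agreement, single-measure
#'   intraclass correlation.
#' @slot n integer sample size.
#'
#' @export
setClass("AgreementReport",
  representation(meanDiff = "numeric", ciMean = "numeric",
                 loaLow = "numeric", loaHigh = "numeric",
                 ciLoaLow = "numeric", ciLoaHigh = "numeric",
                 pearsonR = "numeric", linCCC = "numeric",
                 biasCorrectionFactor = "numeric", icc = "numeric",
                 n = "integer"))

setValidity("AgreementReport", function(object) {
  if (abs(object@linCCC) > abs(object@pearsonR) + 1e-9)
    return("|CCC| must not exceed |r|")
  if (abs(object@linCCC - object@pearsonR * object@biasCorrectionFactor) >
      1e-9)
    return("CCC must equal r * C_b")
  TRUE
})

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf("AgreementReport (n = %d)\n", object@n))
  cat(sprintf("  mean diff %.4g [%.4g, %.4g]; LoA [%.4g, %.4g]\n",
              object@meanDiff, object@ciMean[1], object@ciMean[2],
              object@loaLow, object@loaHigh))
  cat(sprintf("  Pearson r %.3f; Lin CCC %.3f (C_b %.3f); ICC %.3f\n",
              object@pearsonR, object@linCCC, object@biasCorrectionFactor,
              object@icc))
  invisible(NULL)
})

#' Univariate predictor screen
#'
#' Simple least-squares regression of the outcome on each candidate
#' predictor; predictors with a two-sided slope p-value below
#' \code{alphaKeep} are kept for the multivariate step.
#'
#' @param table data.frame of numeric predictors and outcome.
#' @param outcome outcome column name.
#' @param predictors candidate column names (default: all other numeric
#'   columns).
#' @param alphaKeep keep threshold on the p-value (default 0.2).
#' @return data.frame with predictor, slope, p_value, n and kept flag.
#' @export
univariateScreen <- function(table, outcome, predictors = NULL,
                             alphaKeep = 0.2) {
  stopifnot(is.data.frame(table), outcome %in% names(table))
  y0 <- table[[outcome]]
  if (!is.numeric(y0)) stop("outcome must be numeric")
  if (is.null(predictors)) {
    predictors <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                          outcome)
  }
  res <- lapply(predictors, function(p) {
    ok <- complete.cases(table[[p]], y0)
    x <- table[[p]][ok]; y <- y0[ok]
    n <- length(x)
    if (n < 3L) stop("n < 3 for predictor ", p)
    if (sd(y) == 0) stop("constant outcome")
    if (sd(x) == 0)
      return(data.frame(predictor = p, slope = NA_real_, p_value = 1,
                        n = n, kept = FALSE))
    fit <- lm(y ~ x)
    sm <- summary(fit)$coefficients
    data.frame(predictor = p, slope = sm["x", 1], p_value = sm["x", 4],
               n = n, kept = sm["x", 4] < alphaKeep)
  })
  do.call(rbind, res)
}

## VIFs from the auxiliary regressions 1 / (1 - R2_j)
.vifs <- function(table, predictors) {
  if (length(predictors) < 2L)
    return(setNames(rep(1, length(predictors)), predictors))
  vapply(predictors, function(p) {
    f <- stats::as.formula(paste0("`", p, "` ~ ",
      paste0("`", setdiff(predictors, p), "`", collapse = " + ")))
    r2j <- summary(lm(f, data = table))$r.squared
    if (r2j >= 1 - 1e-12) Inf else 1 / (1 - r2j)
  }, numeric(1))
}

#' Stepwise multivariate regression with partial F-tests
#'
#' Forward selection with backward elimination: at each step the candidate
#' with the smallest partial-F p-value enters if below \code{pEnter}, then
#' any included predictor whose partial-F p-value exceeds \code{pRemove}
#' leaves.  The final model reports unstandardised coefficients, 95\% CIs,
#' R-squared and adjusted R-squared, the overall F statistic, and variance
#' inflation factors from auxiliary regressions, flagging VIF > 10.
#'
#' @param table data.frame.
#' @param outcome outcome column name.
#' @param candidates candidate predictor names.
#' @param pEnter entry threshold (default 0.05).
#' @param pRemove removal threshold (default 0.10).
#' @return A \code{\linkS4class{ModelResult}}.
#' @export
stepwiseRegression <- function(table, outcome, candidates,
                               pEnter = 0.05, pRemove = 0.10) {
  stopifnot(is.data.frame(table), outcome %in% names(table),
            all(candidates %in% names(table)))
  dat <- table[complete.cases(table[c(outcome, candidates)]),
               c(outcome, candidates), drop = FALSE]
  n <- nrow(dat)
  if (n <= length(candidates) + 1L)
    stop("need n > number of candidates + 1")

  ## perfectly collinear candidate pairs are reported by name up front
  if (length(candidates) >= 2L) {
    cm <- suppressWarnings(cor(dat[candidates]))
    cm[!is.finite(cm)] <- 0
    bad <- which(abs(cm) > 1 - 1e-12 & upper.tri(cm), arr.ind = TRUE)
    if (nrow(bad))
      stop("perfectly collinear candidates: ",
           paste(apply(bad, 1L, function(ij)
             paste(candidates[ij[1]], "and", candidates[ij[2]])),
             collapse = "; "))
  }

  inModel <- character()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 4L * length(candidates) + 8L) break   # cycling guard
    changed <- FALSE
    ## forward step
    pool <- setdiff(candidates, inModel)
    if (length(pool)) {
      base <- if (length(inModel))
        lm(stats::reformulate(sprintf("`%s`", inModel), response = outcome),
           data = dat)
      else lm(stats::reformulate("1", response = outcome), data = dat)
      ps <- vapply(pool, function(p) {
        big <- lm(stats::reformulate(sprintf("`%s`", c(inModel, p)),
                                     response = outcome), data = dat)
        a <- anova(base, big)
        pv <- a[["Pr(>F)"]][2]
        if (is.na(pv)) 1 else pv
      }, numeric(1))
      if (min(ps) < pEnter) {
        inModel <- c(inModel, pool[which.min(ps)])
        changed <- TRUE
      }
    }
    ## backward step
    if (length(inModel) >= 1L) {
      fit <- lm(stats::reformulate(sprintf("`%s`", inModel),
                                   response = outcome), data = dat)
      dr <- stats::drop1(fit, test = "F")
      pv <- dr[["Pr(>F)"]][-1]
      names(pv) <- rownames(dr)[-1]
      if (length(pv) && max(pv) > pRemove) {
        worst <- gsub("`", "", names(pv)[which.max(pv)])
        inModel <- setdiff(inModel, worst)
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  if (length(inModel) == 0L) {
    fit <- lm(stats::reformulate("1", response = outcome), data = dat)
    return(new("ModelResult", retained = character(),
               betas = coef(fit), ci95 = confint(fit),
               pValues = setNames(summary(fit)$coefficients[, 4],
                                  names(coef(fit))),
               r2 = 0, adjR2 = 0, fStat = c(NA_real_, NA_real_, NA_real_),
               vifs = setNames(numeric(), character()),
               n = as.integer(n), fit = fit))
  }

  fit <- lm(stats::reformulate(sprintf("`%s`", inModel), response = outcome),
            data = dat)
  sm <- summary(fit)
  fs <- sm$fstatistic
  v <- .vifs(dat, inModel)
  if (any(v > 10))
    warning("VIF > 10 for: ",
            paste(names(v)[v > 10], collapse = ", "))
  cleanNames <- gsub("`", "", names(coef(fit)))
  betas <- setNames(coef(fit), cleanNames)
  ci <- confint(fit); rownames(ci) <- cleanNames
  new("ModelResult",
      retained = inModel, betas = betas, ci95 = ci,
      pValues = setNames(sm$coefficients[, 4], cleanNames),
      r2 = sm$r.squared, adjR2 = sm$adj.r.squared,
      fStat = unname(c(fs[1], fs[2], fs[3])),
      vifs = v, n = as.integer(n), fit = fit)
}

#' ROC analysis against an LVEF abnormality cutoff
#'
#' Labels observed LVEF below \code{cutoff} as abnormal (the positive
#' class), orients the score so that a lower predicted LVEF means more
#' abnormal, and computes the AUC via the rank (Mann-Whitney) formulation
#' with tie correction plus the full (FPR, TPR) curve over all score
#' thresholds.
#'
#' @param scores predicted LVEF values.
#' @param truth observed LVEF values.
#' @param cutoff abnormality cutoff in percent (default 54: abnormal is
#'   strictly below).
#' @return List with \code{auc}, \code{curve} (data.frame fpr/tpr),
#'   \code{n_abnormal}, \code{n_normal}.
#' @export
rocAnalysis <- function(scores, truth, cutoff = 54) {
  stopifnot(length(scores) == length(truth))
  ok <- complete.cases(scores, truth)
  scores <- scores[ok]; truth <- truth[ok]
  pos <- truth < cutoff                  # abnormal
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L)
    stop("both abnormal and normal classes must be present")
  risk <- -scores                        # lower predicted LVEF => higher risk
  r <- rank(risk)
  auc <- (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  thr <- sort(unique(risk), decreasing = TRUE)
  curve <- data.frame(
    fpr = c(0, vapply(thr, function(th) mean(risk[!pos] >= th), numeric(1))),
    tpr = c(0, vapply(thr, function(th) mean(risk[pos] >= th), numeric(1))))
  list(auc = auc, curve = curve, n_abnormal = nPos, n_normal = nNeg)
}

#' Bland-Altman, Lin's concordance and intraclass correlation
#'
#' Computes, for two paired measurement series: the Bland-Altman mean
#' difference and 1.96-SD limits of agreement with their 95\% CIs (t-based;
#' the limit standard error is SD sqrt(3/n)); the Pearson correlation;
#' Lin's concordance correlation coefficient
#' \eqn{2 s_{xy} / (s_x^2 + s_y^2 + (\bar{x} - \bar{y})^2)} on 1/n moments
#' and its bias-correction factor \eqn{C_b = CCC / r}; and the two-way
#' random-effects, absolute-agreement, single-measure ICC from the
#' repeated-measures ANOVA mean squares.
#'
#' @param x,y numeric vectors of equal length (n >= 3) with positive
#'   variance.
#' @return An \code{\linkS4class{AgreementReport}}.
#' @export
agreementStats <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (var(x) == 0 || var(y) == 0) stop("zero variance")

  d <- x - y
  md <- mean(d); sdd <- sd(d)
  tq <- qt(0.975, n - 1)
  seMean <- sdd / sqrt(n)
  seLim <- sdd * sqrt(3 / n)
  loaL <- md - 1.96 * sdd; loaH <- md + 1.96 * sdd

  r <- cor(x, y)
  sxy <- mean((x - mean(x)) * (y - mean(y)))   # 1/n moments (Lin)
  sx2 <- mean((x - mean(x))^2)
  sy2 <- mean((y - mean(y))^2)
  ccc <- 2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
  cb <- ccc / r

  ## ICC(A,1): two-way random effects, absolute agreement, single measure
  k <- 2
  grand <- mean(c(x, y))
  rowM <- (x + y) / 2
  colM <- c(mean(x), mean(y))
  ssr <- k * sum((rowM - grand)^2)
  ssc <- n * sum((colM - grand)^2)
  sst <- sum((c(x, y) - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))

  new("AgreementReport",
      meanDiff = md, ciMean = c(md - tq * seMean, md + tq * seMean),
      loaLow = loaL, loaHigh = loaH,
      ciLoaLow = c(loaL - tq * seLim, loaL + tq * seLim),
      ciLoaHigh = c(loaH - tq * seLim, loaH + tq * seLim),
      pearsonR = r, linCCC = ccc, biasCorrectionFactor = cb,
      icc = icc, n = as.integer(n))
}

#' Bonferroni adjustment
#'
#' \eqn{p_{adj} = \min(1, m p)}, monotone in p.
#'
#' @param p numeric p-values.
#' @param m number of comparisons (default \code{length(p)}).
#' @return Adjusted p-values.
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  if (m == length(p)) p.adjust(p, method = "bonferroni") else pmin(1, m * p)
}
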