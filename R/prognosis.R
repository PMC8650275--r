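#' @importFrom survival Surv coxph survfit survdiff basehaz
NULL

alignSurvival <- function(m, surv) {
  surv <- validateSurvival(surv)
  shared <- intersect(rownames(m), surv$sample)
  if (!length(shared)) stop("no shared samples between scores and survival",
                            call. = FALSE)
  list(m = m[shared, , drop = FALSE],
       surv = surv[match(shared, surv$sample), ])
}

#' Univariate proportional-hazards screen over LR pair scores
#'
#' One single-covariate Cox fit (Breslow ties) per pair on its z-standardized
#' score; Wald p-values. Pairs with p < 0.05 are flagged as candidates for
#' the penalized selection step. Constant pairs cannot be fit and are
#' dropped with a warning.
#'
#' @param scores [PairScoreMatrix-class] or samples x pairs matrix.
#' @param surv data.frame (`sample`, `time_months`, `event`).
#' @return data.frame (`pair_id`, `coef`, `hr`, `p`, `candidate`).
#' @export
univariateScreen <- function(scores, surv) {
  al <- alignSurvival(asScoreMatrix(scores), surv)
  if (sum(al$surv$event) == 0) stop("no events observed", call. = FALSE)
  if (sum(al$surv$event) < 10)
    warning("fewer than 10 events; estimates will be unstable", call. = FALSE)
  z <- standardizeScores(al$m)
  dropped <- setdiff(colnames(al$m), colnames(z))
  if (length(dropped))
    warning("constant pair score(s) dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  y <- Surv(al$surv$time_months, al$surv$event)
  res <- lapply(colnames(z), function(p) {
    fit <- coxph(y ~ z[, p], ties = "breslow")
    s <- summary(fit)$coefficients
    data.frame(pair_id = p, coef = s[1, "coef"], hr = s[1, "exp(coef)"],
               p = s[1, "Pr(>|z|)"], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$candidate <- res$p < 0.05
  rownames(res) <- NULL
  res
}

#' LASSO-penalized Cox selection of prognostic pairs
#'
#' Cross-validated L1-penalized proportional-hazards path over the
#' candidate pairs' standardized scores; the penalty is the
#' one-standard-error choice and the pairs with nonzero coefficients at
#' that penalty are returned. An empty selection is a warning, not an
#' error.
#'
#' @inheritParams univariateScreen
#' @param candidates character vector of candidate pair ids (>= 2).
#' @param nFolds cross-validation folds.
#' @param seed RNG seed for the fold assignment.
#' @return list: `selected` pair ids, `lambda`, `cvfit`.
#' @export
lassoSelect <- function(scores, surv, candidates, nFolds = 10, seed = 1) {
  if (length(candidates) < 2) stop("need >= 2 candidate pairs", call. = FALSE)
  al <- alignSurvival(asScoreMatrix(scores)[, candidates, drop = FALSE], surv)
  if (sum(al$surv$event) < 10)
    stop("need >= 10 events for cross-validated selection", call. = FALSE)
  z <- standardizeScores(al$m)
  y <- Surv(al$surv$time_months, al$surv$event)
  foldid <- withSeed(seed, sample(rep_len(seq_len(nFolds), nrow(z))))
  cvfit <- glmnet::cv.glmnet(z, y, family = "cox", foldid = foldid,
                             standardize = FALSE)
  co <- as.matrix(glmnet::coef.glmnet(cvfit, s = "lambda.1se"))
  selected <- rownames(co)[co[, 1] != 0]
  if (!length(selected))
    warning("LASSO shrank all coefficients to zero", call. = FALSE)
  list(selected = selected, lambda = cvfit$lambda.1se, cvfit = cvfit)
}

#' Fit the multivariate risk model on selected pairs
#'
#' Unpenalized multivariate Cox fit (Breslow ties) on the standardized
#' selected scores. The risk score of a sample is the linear predictor
#' `sum(coef * standardized score)`; the training median becomes the
#' high/low cutoff, and the Breslow baseline cumulative hazard is stored so
#' absolute survival probabilities can be predicted later. Standardization
#' parameters are learned here and reused verbatim on validation cohorts.
#'
#' @inheritParams univariateScreen
#' @param pairs selected pair ids (non-empty; events must be >= length).
#' @return [RiskModel-class].
#' @export
fitRiskModel <- function(scores, surv, pairs) {
  if (!length(pairs)) stop("empty pair selection", call. = FALSE)
  al <- alignSurvival(asScoreMatrix(scores)[, pairs, drop = FALSE], surv)
  if (sum(al$surv$event) < length(pairs))
    stop("fewer events than coefficients to fit", call. = FALSE)
  z <- standardizeScores(al$m)
  y <- Surv(al$surv$time_months, al$surv$event)
  fit <- coxph(y ~ z, ties = "breslow")
  beta <- stats::setNames(as.numeric(stats::coef(fit)), colnames(z))
  if (any(!is.finite(beta)))
    stop("Cox fit did not converge; coefficients: ",
         paste(signif(beta, 3), collapse = ", "), call. = FALSE)
  bh <- basehaz(fit, centered = FALSE)
  risk <- as.numeric(z %*% beta)
  new("RiskModel", pairs = colnames(z), coefficients = beta,
      center = attr(z, "center"), scale = attr(z, "scale"),
      cutoff = median(risk),
      baseline = data.frame(time = bh$time, cumhaz = bh$hazard))
}

#' Risk scores for a cohort under a fitted model
#'
#' Applies the training standardization and coefficients; never re-derives
#' anything from the scored cohort.
#'
#' @param model [RiskModel-class].
#' @param scores [PairScoreMatrix-class] or samples x pairs matrix.
#' @return named numeric risk score per sample.
#' @export
riskScore <- function(model, scores) {
  m <- asScoreMatrix(scores)
  missing <- setdiff(riskPairs(model), colnames(m))
  if (length(missing))
    stop("model pair(s) absent from scores: ",
         paste(missing, collapse = ", "), call. = FALSE)
  z <- standardizeScores(m[, riskPairs(model), drop = FALSE],
                         center = model@center, scale = model@scale)
  stats::setNames(as.numeric(z %*% riskCoefficients(model)), rownames(m))
}

#' Median-split risk stratification
#'
#' `score > cutoff` is high risk, `score <= cutoff` low risk (ties low).
#' Validation cohorts are split at the TRAINING median stored in the model,
#' never at their own.
#'
#' @param scores numeric risk scores.
#' @param cutoff the training-median cutoff (e.g. `riskCutoff(model)`).
#' @return factor with levels `low`, `high`.
#' @export
stratifyMedian <- function(scores, cutoff) {
  factor(ifelse(scores > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit estimates per group plus the standard two-group log-rank
#' statistic (hypergeometric variance, 1 d.f. chi-square).
#'
#' @inheritParams univariateScreen
#' @param groups factor of group labels aligned with `surv` rows.
#' @return list: `curves` data.frame (`group`, `time`, `n_risk`, `n_event`,
#'   `survival`), `chisq`, `p`.
#' @export
kmLogrank <- function(surv, groups) {
  surv <- validateSurvival(surv)
  groups <- droplevels(as.factor(groups))
  stopifnot(length(groups) == nrow(surv))
  if (nlevels(groups) != 2)
    stop("log-rank comparison needs exactly 2 non-empty groups, got ",
         nlevels(groups), call. = FALSE)
  y <- Surv(surv$time_months, surv$event)
  sd <- survdiff(y ~ groups)
  chisq <- sd$chisq
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  sf <- survfit(y ~ groups)
  grp <- rep(sub("^groups=", "", names(sf$strata)), sf$strata)
  curves <- data.frame(group = grp, time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, survival = sf$surv,
                       stringsAsFactors = FALSE)
  list(curves = curves, chisq = chisq, p = p)
}

censoringKM <- function(surv) {
  sf <- survfit(Surv(surv$time_months, 1 - surv$event) ~ 1)
  function(t, minus = FALSE) {
    vapply(t, function(tt) {
      i <- if (minus) sum(sf$time < tt) else sum(sf$time <= tt)
      if (i == 0) 1 else sf$surv[i]
    }, numeric(1))
  }
}

#' IPCW time-dependent AUC at a fixed horizon
#'
#' Cumulative-case / dynamic-control discrimination: cases are subjects
#' with an observed event by the horizon, controls those still at risk past
#' it; concordant (case, control) score pairs are counted with
#' inverse-probability-of-censoring weights from the Kaplan-Meier estimate
#' of the censoring distribution (ties count one half).
#'
#' @inheritParams univariateScreen
#' @param risk numeric risk scores aligned with `surv` rows.
#' @param horizonMonths evaluation horizon (36 and 60 months by
#'   convention for 3- and 5-year discrimination).
#' @return AUC in `[0, 1]`.
#' @export
timeDependentAUC <- function(risk, surv, horizonMonths) {
  surv <- validateSurvival(surv)
  stopifnot(length(risk) == nrow(surv))
  case <- surv$time_months <= horizonMonths & surv$event == 1
  control <- surv$time_months > horizonMonths
  if (!any(case)) stop("no cases by the horizon", call. = FALSE)
  if (!any(control)) stop("no controls past the horizon", call. = FALSE)
  G <- censoringKM(surv)
  wCase <- 1 / G(surv$time_months[case], minus = TRUE)
  wCase[!is.finite(wCase)] <- 0
  wControl <- rep(1 / G(horizonMonths), sum(control))
  mc <- risk[case]; mq <- risk[control]
  conc <- outer(mc, mq, ">") + 0.5 * outer(mc, mq, "==")
  num <- sum(conc * outer(wCase, wControl))
  den <- sum(wCase) * sum(wControl)
  num / den
}

#' Calibration of predicted vs observed survival at a horizon
#'
#' Samples are binned by risk score (quantile bins); per bin the mean
#' Breslow-baseline model prediction `exp(-H0(t) exp(lp))` is compared with
#' the Kaplan-Meier estimate inside the bin. Empty or degenerate bins are
#' merged with their neighbour and logged.
#'
#' @param model [RiskModel-class].
#' @inheritParams univariateScreen
#' @param horizonMonths evaluation horizon; must not exceed the last
#'   observed time.
#' @param nBins number of risk bins.
#' @return data.frame (`bin`, `n`, `predicted`, `observed`).
#' @export
calibrationTable <- function(model, scores, surv, horizonMonths, nBins = 3) {
  al <- alignSurvival(asScoreMatrix(scores), surv)
  surv <- al$surv
  if (horizonMonths > max(surv$time_months))
    stop("horizon beyond the last observed time", call. = FALSE)
  risk <- riskScore(model, al$m)
  bl <- model@baseline
  i <- sum(bl$time <= horizonMonths)
  H0 <- if (i == 0) 0 else bl$cumhaz[i]
  predicted <- exp(-H0 * exp(risk))
  br <- unique(quantile(risk, seq(0, 1, length.out = nBins + 1),
                        names = FALSE))
  if (length(br) - 1 < nBins)
    message("calibration: tied quantiles merged bins (",
            length(br) - 1, " bins used)")
  bin <- if (length(br) > 2)
    cut(risk, breaks = br, include.lowest = TRUE, labels = FALSE)
  else rep(1L, length(risk))
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    inB <- bin == b
    sf <- survfit(Surv(surv$time_months[inB], surv$event[inB]) ~ 1)
    obs <- summary(sf, times = horizonMonths, extend = TRUE)$surv
    data.frame(bin = b, n = sum(inB), predicted = mean(predicted[inB]),
               observed = obs)
  }))
  rownames(out) <- NULL
  out
}

#' Seeded train/validation split of sample ids
#'
#' The conventional 70/30 split used to hold out an internal validation
#' group; all model artifacts (standardization, cutoff) come from the
#' training part only.
#'
#' @param sampleIds character vector of sample ids.
#' @param trainFrac fraction assigned to training.
#' @param seed RNG seed.
#' @return list with `train` and `validation` id vectors.
#' @export
trainValidationSplit <- function(sampleIds, trainFrac = 0.7, seed = 1) {
  stopifnot(trainFrac > 0, trainFrac < 1)
  n <- length(sampleIds)
  idx <- withSeed(seed, sample.int(n, floor(trainFrac * n)))
  list(train = sampleIds[sort(idx)], validation = sampleIds[-sort(idx)])
}
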