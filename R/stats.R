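# Analysis layer: standardized OLS for subject-level outcomes and a
# random-intercept linear mixed model for smoothed GCM on the second grid,
# with content-period (POI) and time interactions.

#' Standardize continuous columns to z-scores
#'
#' Mean 0, standard deviation 1 (denominator n - 1) per column; columns not
#' listed are untouched.
#'
#' @param data a data.frame.
#' @param cols column names to standardize; default every numeric column.
#' @return the data.frame with the named columns standardized.
#' @export
standardize <- function(data, cols = NULL) {
  if (is.null(cols)) cols <- names(data)[vapply(data, is.numeric, logical(1))]
  for (cn in cols) {
    s <- sd(data[[cn]])
    if (!is.finite(s) || s == 0)
      stop("column '", cn, "' has zero variance and cannot be standardized")
    data[[cn]] <- (data[[cn]] - mean(data[[cn]])) / s
  }
  data
}

#' Ordinary least squares with t tests
#'
#' Least-squares fit of `response ~ predictors` (intercept included) through
#' `stats::lm`, reported as a [FitResult-class] with `t = estimate/se`,
#' `df = n - p` and two-sided p-values. For standardized coefficients,
#' standardize the columns first with [standardize()].
#'
#' @param data data.frame holding response and predictors.
#' @param response response column name.
#' @param predictors character vector of predictor column names.
#' @return a [FitResult-class].
#' @export
fitOLS <- function(data, response, predictors) {
  X <- stats::model.matrix(
    stats::reformulate(predictors, intercept = TRUE), data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  if (nrow(X) <= ncol(X)) stop("more observations than parameters required")
  fit <- stats::lm(stats::reformulate(predictors, response), data = data)
  sm <- summary(fit)
  cf <- stats::coef(sm)
  df <- fit$df.residual
  out <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                    t = cf[, 3], df = df, p = cf[, 4], row.names = NULL)
  new("FitResult", coefficients = out,
      varcomp = c(sigma2_residual = sm$sigma^2),
      logREML = NA_real_, nobs = nrow(X), nsubjects = nrow(X))
}

# POI helpers -------------------------------------------------------------

poiLevels <- function(poi) {
  lv <- unique(poi$label)
  ref <- "game_world_explained"
  if (ref %in% lv) c(ref, setdiff(lv, ref)) else lv
}

# label of the segment containing each grid second (start <= g < end)
poiLabelAt <- function(g, poi) {
  out <- rep(NA_character_, length(g))
  for (i in seq_len(nrow(poi))) {
    hit <- g >= poi$start[i] & g < poi$end[i]
    out[hit] <- poi$label[i]
  }
  out
}

#' Build the long per-second GCM table
#'
#' One row per subject per one-second grid point that falls inside an
#' annotated content segment, carrying the smoothed GCM value, the POI label
#' (reference category `game_world_explained` first) and the subject
#' covariates.
#'
#' @param series an [AttentionSeries-class].
#' @param poi data.frame (start, end, label) of non-overlapping segments in
#'   seconds.
#' @param covariates data.frame with columns `subject`, `prior`, `post`.
#' @return data.frame (subject, t, gcm, poi, prior, post).
#' @export
buildLongTable <- function(series, poi, covariates) {
  stopifnot(is(series, "AttentionSeries"))
  o <- order(poi$start)
  ps <- poi[o, ]
  if (nrow(ps) > 1L && any(ps$start[-1] < ps$end[-nrow(ps)]))
    stop("POI intervals overlap")
  grid <- series@grid
  lab <- poiLabelAt(grid, ps)
  keep <- !is.na(lab)
  subs <- colnames(series@smoothedGCM)
  if (is.null(subs)) subs <- sprintf("S%03d", seq_len(ncol(series@smoothedGCM)))
  rows <- lapply(seq_along(subs), function(j) {
    data.frame(subject = subs[j], t = grid[keep],
               gcm = series@smoothedGCM[keep, j],
               poi = lab[keep])
  })
  long <- do.call(rbind, rows)
  long$poi <- factor(long$poi, levels = poiLevels(ps))
  m <- match(long$subject, covariates$subject)
  if (anyNA(m)) stop("covariates missing for some subjects")
  long$prior <- covariates$prior[m]
  long$post <- covariates$post[m]
  long[!is.na(long$gcm), ]
}

# fixed-effect design shared by the simulator and the fitter:
# poi dummies + standardized time, prior, post + post:poi + post:time
lmmDesign <- function(long) {
  d <- long
  d$t_z <- as.numeric(zscoreSafe(d$t))
  d$prior_z <- as.numeric(zscoreSafe(d$prior))
  d$post_z <- as.numeric(zscoreSafe(d$post))
  stats::model.matrix(~ poi + t_z + prior_z + post_z + post_z:poi +
                        post_z:t_z, d)
}

#' Random-intercept linear mixed model for smoothed GCM
#'
#' Fits, by REML through `lme4::lmer`, the model
#' `gcm ~ poi + time + prior + post + post:poi + post:time + (1 | subject)`
#' with continuous predictors z-standardized (and, by default, the response
#' too, so coefficients are standardized betas). t statistics use
#' `df = n_subjects - p` where p is the fixed-effect rank, following the
#' subject-tied degrees-of-freedom convention of reporting in this design
#' (e.g. 105 subjects and 13 fixed-effect columns give t(92)).
#'
#' @param long table from [buildLongTable()] or [simulateGCMLong()].
#' @param standardizeResponse z-score the GCM response (default TRUE); turn
#'   off to recover coefficients on the generating scale.
#' @return a [FitResult-class] with variance components and the restricted
#'   log-likelihood.
#' @export
fitLMMRandomIntercept <- function(long, standardizeResponse = TRUE) {
  if (length(unique(long$subject)) < 2L)
    stop("at least two subjects are required")
  if (min(table(long$subject)) < 2L)
    stop("at least two observations per subject are required")
  d <- long
  d$t_z <- as.numeric(zscoreSafe(d$t))
  d$prior_z <- as.numeric(zscoreSafe(d$prior))
  d$post_z <- as.numeric(zscoreSafe(d$post))
  d$y <- if (standardizeResponse) as.numeric(zscoreSafe(d$gcm)) else d$gcm
  fit <- lme4::lmer(
    y ~ poi + t_z + prior_z + post_z + post_z:poi + post_z:t_z +
      (1 | subject),
    data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  nsub <- length(unique(d$subject))
  p <- length(beta)
  df <- nsub - p
  if (df < 1L) stop("not enough subjects for the fixed-effect rank")
  tval <- beta / se
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2i <- vc$vcov[vc$grp == "subject"]
  s2r <- vc$vcov[vc$grp == "Residual"]
  out <- data.frame(term = names(beta), estimate = unname(beta),
                    se = unname(se), t = unname(tval), df = df,
                    p = 2 * pt(-abs(unname(tval)), df), row.names = NULL)
  new("FitResult", coefficients = out,
      varcomp = c(sigma2_intercept = s2i, sigma2_residual = s2r),
      logREML = as.numeric(stats::logLik(fit)),
      nobs = nrow(d), nsubjects = as.integer(nsub))
}
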