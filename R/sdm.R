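#' Fit the correlative habitat-suitability model
#'
#' Relates presence/absence flags to at most three environmental predictors
#' through a binomial additive model whose smooth terms are restricted to
#' two effective degrees of freedom (enough for a linearly increasing,
#' decreasing or dome-shaped response, while guarding against overfitting).
#' Every subset of one, two or three candidate predictors is fitted by
#' maximum likelihood on a stratified calibration split (75\% of presences
#' and 75\% of absences by default) and the lowest-AIC model is retained.
#' Predictors listed in `log_transform` (by default a `surface_area` column,
#' whose distribution across basins is heavy-tailed) are log-transformed
#' before fitting. The returned fit carries explained deviance, Cohen's
#' kappa at the kappa-maximizing threshold, and AUC, on both the calibration
#' and validation splits.
#'
#' @param data data.frame with a 0/1 presence column and the candidate
#'   predictor columns
#' @param predictors character vector of candidate predictor names
#' @param presence_col name of the presence column
#' @param split calibration fraction of each class
#' @param seed seed for the random stratified split
#' @param max_terms maximal number of predictors in a candidate model
#' @param log_transform predictor names to log-transform (silently skipped
#'   when absent from `predictors`)
#' @param smooth_df effective degrees of freedom of each smooth term
#' @return an object of class `sdm_fit`
#' @export
fit_sdm <- function(data, predictors, presence_col = "presence",
                    split = 0.75, seed = 1, max_terms = 3,
                    log_transform = "surface_area", smooth_df = 2) {
  stopifnot(is.data.frame(data), presence_col %in% names(data),
            all(predictors %in% names(data)), length(predictors) >= 1,
            split > 0, split < 1, smooth_df >= 1)
  y <- data[[presence_col]]
  if (!all(y %in% c(0, 1))) stop("presence column must be 0/1")
  df <- data
  logged <- intersect(log_transform, predictors)
  for (v in logged) {
    if (any(df[[v]] <= 0))
      stop("cannot log-transform non-positive predictor '", v, "'")
    df[[v]] <- log(df[[v]])
  }

  # stratified calibration/validation split
  set.seed(derive_seed(seed, 0L))
  pres <- which(y == 1)
  abse <- which(y == 0)
  cal <- sort(c(sample(pres, round(split * length(pres))),
                sample(abse, round(split * length(abse)))))
  val <- setdiff(seq_along(y), cal)
  if (sum(y[cal] == 1) < 2 || sum(y[cal] == 0) < 2)
    stop("calibration split needs at least two presences and two absences")

  term_of <- function(v) {
    # a smooth needs enough distinct values; degenerate predictors enter
    # linearly
    if (length(unique(df[[v]][cal])) >= smooth_df + 2)
      sprintf("s(%s, k = %d, fx = TRUE)", v, smooth_df + 1L)
    else v
  }
  subsets <- unlist(lapply(seq_len(min(max_terms, length(predictors))),
                           function(m) utils::combn(predictors, m,
                                                    simplify = FALSE)),
                    recursive = FALSE)
  fits <- vector("list", length(subsets))
  aics <- rep(NA_real_, length(subsets))
  for (i in seq_along(subsets)) {
    fml <- stats::as.formula(
      paste(presence_col, "~",
            paste(vapply(subsets[[i]], term_of, character(1)),
                  collapse = " + ")))
    fit <- tryCatch(
      mgcv::gam(fml, family = stats::binomial(), data = df[cal, ],
                method = "ML"),
      error = function(e) {
        warning("candidate model {", paste(subsets[[i]], collapse = ", "),
                "} failed to fit: ", conditionMessage(e))
        NULL
      })
    if (!is.null(fit) && !isTRUE(fit$converged)) {
      warning("candidate model {", paste(subsets[[i]], collapse = ", "),
              "} did not converge; excluded")
      fit <- NULL
    }
    fits[[i]] <- fit
    if (!is.null(fit)) aics[i] <- stats::AIC(fit)
  }
  if (all(is.na(aics))) stop("no candidate model could be fitted")
  best <- which.min(aics)
  model <- fits[[best]]
  sel <- subsets[[best]]

  score_cal <- as.numeric(stats::predict(model, df[cal, ], type = "response"))
  score_val <- as.numeric(stats::predict(model, df[val, ], type = "response"))
  obs_cal <- y[cal] == 1
  obs_val <- y[val] == 1
  thr <- best_threshold(obs_cal, score_cal)
  null_dev <- model$null.deviance
  final_dev <- stats::deviance(model)
  metrics <- list(
    kappa_cal = kappa_statistic(obs_cal, score_cal >= thr),
    kappa_val = if (length(unique(obs_val)) == 2)
      kappa_statistic(obs_val, score_val >= thr) else NA_real_,
    auc_cal = auc_statistic(obs_cal, score_cal),
    auc_val = if (length(unique(obs_val)) == 2)
      auc_statistic(obs_val, score_val) else NA_real_,
    explained_deviance = explained_deviance(null_dev, final_dev))

  aic_table <- data.frame(
    predictors = vapply(subsets, paste, character(1), collapse = "+"),
    n_terms = lengths(subsets), aic = aics)
  aic_table <- aic_table[order(aic_table$aic), ]

  ranges <- lapply(stats::setNames(nm = sel), function(v)
    range(df[[v]][cal]))
  structure(list(model = model, predictors = sel, aic = aics[best],
                 aic_table = aic_table, threshold = thr,
                 null_deviance = null_dev, deviance = final_dev,
                 metrics = metrics, log_transform = logged,
                 calibration_rows = cal, validation_rows = val,
                 predictor_ranges = ranges),
            class = "sdm_fit")
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat("<correlative SDM fit>\n")
  cat("  predictors:", paste(x$predictors, collapse = ", "), "\n")
  cat(sprintf("  AIC %.2f, explained deviance %.1f%%\n",
              x$aic, x$metrics$explained_deviance))
  cat(sprintf("  kappa %.3f / %.3f, AUC %.3f / %.3f (calibration/validation)\n",
              x$metrics$kappa_cal, x$metrics$kappa_val,
              x$metrics$auc_cal, x$metrics$auc_val))
  cat(sprintf("  kappa-maximizing threshold %.3f\n", x$threshold))
  invisible(x)
}

#' Percentage of deviance explained
#'
#' `100 * (null - final) / null`, the usual improvement of a fitted
#' binomial model over the intercept-only model.
#'
#' @param null_dev deviance of the null (intercept-only) model, > 0
#' @param final_dev deviance of the fitted model, in \[0, null_dev\]
#' @return percentage in \[0, 100\]
#' @examples
#' explained_deviance(100, 46)  # 54
#' @export
explained_deviance <- function(null_dev, final_dev) {
  stopifnot(null_dev > 0, final_dev >= 0, final_dev <= null_dev)
  100 * (null_dev - final_dev) / null_dev
}

#' Cohen's kappa
#'
#' Agreement between observed and predicted presence flags after removing
#' chance agreement: `(p_o - p_e) / (1 - p_e)` from the 2x2 confusion
#' table. Returns `NA` in the degenerate case `p_e = 1`.
#'
#' @param observed logical (or 0/1) observed flags; both classes must occur
#' @param predicted logical (or 0/1) predicted flags
#' @return value in \[-1, 1\]
#' @export
kappa_statistic <- function(observed, predicted) {
  observed <- as.logical(observed)
  predicted <- as.logical(predicted)
  stopifnot(length(observed) == length(predicted))
  if (length(unique(observed)) < 2)
    stop("observed flags must contain both classes")
  n <- length(observed)
  tp <- sum(observed & predicted)
  tn <- sum(!observed & !predicted)
  po <- (tp + tn) / n
  pe <- (sum(observed) * sum(predicted) +
           sum(!observed) * sum(!predicted)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random presence
#' scores above a random absence, ties counted half.
#'
#' @param observed logical (or 0/1) flags; both classes must occur
#' @param scores numeric suitability scores
#' @return value in \[0, 1\]
#' @export
auc_statistic <- function(observed, scores) {
  observed <- as.logical(observed)
  stopifnot(length(observed) == length(scores))
  n1 <- sum(observed)
  n0 <- sum(!observed)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[observed]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Kappa-maximizing classification threshold
#'
#' Scans every midpoint between consecutive distinct scores, plus 0 and 1,
#' classifying `score >= threshold` as presence, and returns the threshold
#' with the highest kappa (ties broken toward the smallest threshold).
#'
#' @param observed logical (or 0/1) flags; both classes must occur
#' @param scores numeric suitability scores in \[0, 1\]
#' @return threshold in \[0, 1\]
#' @export
best_threshold <- function(observed, scores) {
  observed <- as.logical(observed)
  stopifnot(length(observed) == length(scores))
  if (length(unique(observed)) < 2)
    stop("observed flags must contain both classes")
  s <- sort(unique(scores))
  cand <- sort(unique(c(0, 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2)))
  kap <- vapply(cand, function(th)
    kappa_statistic(observed, scores >= th), numeric(1))
  kap[is.na(kap)] <- -Inf
  cand[which.max(kap)]  # which.max takes the first (smallest) maximizer
}

#' Project habitat suitability onto new conditions
#'
#' Evaluates a fitted correlative model on new predictor values, returning
#' the per-basin suitability probability. Basins whose predictors fall
#' outside the calibration range are projected anyway but flagged as
#' extrapolated.
#'
#' @param fit an [fit_sdm()] object
#' @param newdata data.frame with the fitted predictor columns (untransformed;
#'   the fit's log transforms are re-applied)
#' @return data.frame with columns `p_suit` and `extrapolated` (plus an
#'   `id` column if present in `newdata`); zero rows in, zero rows out
#' @export
project_sdm <- function(fit, newdata) {
  stopifnot(inherits(fit, "sdm_fit"), is.data.frame(newdata))
  out <- data.frame(p_suit = numeric(0), extrapolated = logical(0))
  if ("id" %in% names(newdata))
    out <- data.frame(id = character(0), out)
  if (nrow(newdata) == 0) return(out)
  missing <- setdiff(fit$predictors, names(newdata))
  if (length(missing))
    stop("newdata is missing predictor(s): ", paste(missing, collapse = ", "))
  df <- newdata
  for (v in intersect(fit$log_transform, fit$predictors)) {
    if (any(df[[v]] <= 0))
      stop("cannot log-transform non-positive predictor '", v, "'")
    df[[v]] <- log(df[[v]])
  }
  p <- as.numeric(stats::predict(fit$model, df, type = "response"))
  extra <- rep(FALSE, nrow(df))
  for (v in fit$predictors) {
    rg <- fit$predictor_ranges[[v]]
    extra <- extra | df[[v]] < rg[1] | df[[v]] > rg[2]
  }
  out <- data.frame(p_suit = p, extrapolated = extra)
  if ("id" %in% names(newdata))
    out <- data.frame(id = as.character(newdata$id), out)
  out
}

#' Argmax of a fitted single-predictor response curve
#'
#' Evaluates the fitted suitability over a grid of one predictor (other
#' predictors held at their calibration medians) and returns the grid value
#' with maximal response — the fitted thermal (or other) optimum.
#'
#' @param fit an [fit_sdm()] object
#' @param predictor predictor name (on the original scale)
#' @param n grid size
#' @return the predictor value maximizing the fitted response
#' @export
fitted_optimum <- function(fit, predictor, n = 201) {
  stopifnot(inherits(fit, "sdm_fit"), predictor %in% fit$predictors)
  rg <- fit$predictor_ranges[[predictor]]
  grid <- data.frame(seq(rg[1], rg[2], length.out = n))
  names(grid) <- predictor
  for (v in setdiff(fit$predictors, predictor))
    grid[[v]] <- mean(fit$predictor_ranges[[v]])
  p <- as.numeric(stats::predict(fit$model, grid, type = "response"))
  x <- grid[[predictor]][which.max(p)]
  if (predictor %in% fit$log_transform) exp(x) else x
}
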