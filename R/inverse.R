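#' Scaling-factor observations for inverse modelling
#'
#' For every matched (sample, taxon) pair with a nonzero prescribed
#' proportion, the scaling factor is the observed proportion divided by the
#' actual (prescribed) proportion. Zero-actual entries emit no observation.
#' The observed proportion vector of the whole sample is retained as the
#' predictor set, since it is the only quantity available when the model is
#' later applied to samples of unknown composition.
#'
#' @param observed proportion matrix (samples x taxa), typically
#'   copy-number-adjusted via [adjust_counts()]; rownames identify samples.
#' @param actual matching matrix of true/prescribed proportions, or a
#'   `mixture_design` (matched by `run_id`).
#' @return Object of class `scaling_obs`: list with `data` (long data frame
#'   `sample_id`, `taxon`, `scaling_factor`), `observed` and `actual`
#'   matrices, and `taxa`.
#' @export
scaling_factors <- function(observed, actual) {
  if (inherits(actual, "mixture_design"))
    actual <- .match_prescribed(observed, actual)
  actual <- as.matrix(actual)[rownames(observed), colnames(observed), drop = FALSE]
  keep <- actual > 0
  idx <- which(keep, arr.ind = TRUE)
  data <- data.frame(
    sample_id = rownames(observed)[idx[, 1]],
    taxon = colnames(observed)[idx[, 2]],
    scaling_factor = observed[keep] / actual[keep],
    stringsAsFactors = FALSE
  )
  structure(list(data = data, observed = observed, actual = actual,
                 taxa = colnames(observed)),
            class = "scaling_obs")
}

#' @export
print.scaling_obs <- function(x, ...) {
  cat(sprintf("Scaling-factor observations: %d over %d samples, %d taxa\n",
              nrow(x$data), nrow(x$observed), length(x$taxa)))
  invisible(x)
}

#' Fit per-taxon inverse scaling-factor models
#'
#' One random-forest regression per taxon of its scaling factor
#' (observed/actual proportion) on the full observed proportion vector of
#' the sample; 500 trees and two splitting variables per tree by default.
#' Taxa with fewer than `min_obs` observations are skipped with a warning.
#'
#' @param scaling a `scaling_obs` object from [scaling_factors()].
#' @param ntree,mtry forest size and splitting variables per tree.
#' @param min_obs minimum observations per taxon (default 10).
#' @param seed integer seed; the fit is deterministic per seed.
#' @return Object of class `inverse_models`: per-taxon forests plus training
#'   metadata. Has `print` and `predict` methods.
#' @export
fit_inverse <- function(scaling, ntree = 500L, mtry = 2L, min_obs = 10L,
                        seed = 1L) {
  stopifnot(inherits(scaling, "scaling_obs"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  forests <- list()
  skipped <- character(0)
  for (tx in scaling$taxa) {
    sub <- scaling$data[scaling$data$taxon == tx, , drop = FALSE]
    if (nrow(sub) < min_obs) {
      skipped <- c(skipped, tx)
      next
    }
    X <- scaling$observed[sub$sample_id, , drop = FALSE]
    colnames(X) <- make.names(colnames(X))  # randomForest needs syntactic names
    forests[[tx]] <- randomForest::randomForest(
      x = as.data.frame(X), y = sub$scaling_factor,
      ntree = ntree, mtry = min(mtry, ncol(X)))
  }
  if (length(skipped))
    warning("too few observations; skipped taxa: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  structure(list(forests = forests, taxa = names(forests),
                 all_taxa = scaling$taxa,
                 ntree = as.integer(ntree), mtry = as.integer(mtry),
                 seed = as.integer(seed)),
            class = "inverse_models")
}

#' @export
print.inverse_models <- function(x, ...) {
  cat(sprintf("Inverse scaling-factor models: %d taxa, %d trees, mtry %d\n",
              length(x$forests), x$ntree, x$mtry))
  oob <- vapply(x$forests, function(f) f$mse[f$ntree], numeric(1))
  for (tx in names(oob)) cat(sprintf("  %-20s OOB MSE %.4g\n", tx, oob[tx]))
  invisible(x)
}

#' Predict scaling factors for new samples
#'
#' @param object an `inverse_models` set.
#' @param newdata observed proportion matrix (samples x taxa).
#' @param ... unused.
#' @return Matrix of predicted observed/actual scaling factors (samples x
#'   modelled taxa).
#' @export
predict.inverse_models <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  X <- newdata[, object$all_taxa, drop = FALSE]
  colnames(X) <- make.names(colnames(X))
  out <- vapply(object$taxa, function(tx)
    unname(stats::predict(object$forests[[tx]], as.data.frame(X))),
    numeric(nrow(X)))
  out <- matrix(out, nrow = nrow(X),
                dimnames = list(rownames(newdata), object$taxa))
  out
}

#' Correct observed counts to predicted true proportions
#'
#' Observed counts are copy-number adjusted and normalized, a scaling factor
#' (observed/actual) is predicted for every taxon with nonzero counts, the
#' correction is applied, and the result is renormalized to sum to 1. Taxa
#' with zero counts stay 0. In the default orientation
#' (`"obs_over_actual"`) the observed proportion is divided by the predicted
#' factor, consistent with the factor's definition; `"actual_over_obs"`
#' instead multiplies, treating the prediction as an actual/observed factor.
#'
#' @param counts count matrix (samples x taxa) or a single named count
#'   vector.
#' @param taxa taxon metadata.
#' @param models an `inverse_models` set covering all taxa with nonzero
#'   counts.
#' @param orientation `"obs_over_actual"` (divide; default) or
#'   `"actual_over_obs"` (multiply).
#' @param floor predicted factors are clipped below at this value before
#'   division (default 1e-6).
#' @return Matrix of predicted true proportions, rows summing to 1.
#' @export
correct_sample <- function(counts, taxa, models,
                           orientation = c("obs_over_actual", "actual_over_obs"),
                           floor = 1e-6) {
  orientation <- match.arg(orientation)
  if (is.null(dim(counts))) counts <- matrix(counts, 1,
                                             dimnames = list("sample1", names(counts)))
  counts <- as.matrix(counts)
  off_panel <- setdiff(colnames(counts), models$all_taxa)
  if (length(off_panel)) {
    warning("dropping taxa absent from the training panel: ",
            paste(off_panel, collapse = ", "), call. = FALSE)
    counts <- counts[, setdiff(colnames(counts), off_panel), drop = FALSE]
  }
  missing_cols <- setdiff(models$all_taxa, colnames(counts))
  if (length(missing_cols)) {
    zero <- matrix(0L, nrow(counts), length(missing_cols),
                   dimnames = list(rownames(counts), missing_cols))
    counts <- cbind(counts, zero)[, models$all_taxa, drop = FALSE]
  }
  unmodelled <- colnames(counts)[colSums(counts > 0) > 0 &
                                   !(colnames(counts) %in% models$taxa)]
  if (length(unmodelled))
    stop("nonzero counts for taxa without an inverse model: ",
         paste(unmodelled, collapse = ", "), call. = FALSE)
  obs <- adjust_counts(counts, taxa, experiment = "cells")
  fac <- predict(models, obs)
  fac <- pmax(fac, floor)
  corrected <- obs[, models$taxa, drop = FALSE]
  corrected <- switch(orientation,
    obs_over_actual = corrected / fac,
    actual_over_obs = corrected * fac
  )
  corrected[obs[, models$taxa, drop = FALSE] == 0] <- 0
  full <- matrix(0, nrow(obs), ncol(obs), dimnames = dimnames(obs))
  full[, models$taxa] <- corrected
  .row_normalize(full)
}

#' Cross-validated accuracy of the inverse correction
#'
#' Samples (not individual observations) are partitioned into `k` folds;
#' for each fold, inverse models are trained on the remaining samples and
#' the held-out samples are corrected from their observed proportions. The
#' per-taxon mean absolute error of corrected versus actual proportions is
#' averaged over folds. `k` equal to the sample count gives leave-one-out.
#'
#' @param scaling a `scaling_obs` object (carries observed and actual
#'   matrices).
#' @param k number of folds (>= 2, <= number of samples).
#' @param seed integer seed for fold assignment and forest fitting.
#' @param ntree,mtry,orientation passed through to [fit_inverse()] /
#'   the correction.
#' @return List: `per_taxon` data frame (`taxon`, `fold`, `mae`), `summary`
#'   data frame (`taxon`, `mae`), and `folds` (fold id per sample).
#' @export
cross_validate <- function(scaling, k = 5L, seed = 1L, ntree = 500L, mtry = 2L,
                           orientation = "obs_over_actual") {
  stopifnot(inherits(scaling, "scaling_obs"))
  samples <- rownames(scaling$observed)
  n <- length(samples)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  folds <- sample(rep_len(seq_len(k), n))
  names(folds) <- samples

  rows <- list()
  for (fold in seq_len(k)) {
    test_ids <- samples[folds == fold]
    train_ids <- samples[folds != fold]
    train <- scaling_factors(scaling$observed[train_ids, , drop = FALSE],
                             scaling$actual[train_ids, , drop = FALSE])
    models <- suppressWarnings(
      fit_inverse(train, ntree = ntree, mtry = mtry, seed = seed + fold))
    obs <- scaling$observed[test_ids, , drop = FALSE]
    fac <- pmax(predict(models, obs), 1e-6)
    corrected <- matrix(0, nrow(obs), ncol(obs), dimnames = dimnames(obs))
    corrected[, models$taxa] <- switch(orientation,
      obs_over_actual = obs[, models$taxa, drop = FALSE] / fac,
      actual_over_obs = obs[, models$taxa, drop = FALSE] * fac)
    corrected[obs == 0] <- 0
    corrected <- .row_normalize(corrected)
    err <- abs(corrected - scaling$actual[test_ids, , drop = FALSE])
    rows[[fold]] <- data.frame(taxon = colnames(err), fold = fold,
                               mae = colMeans(err), row.names = NULL,
                               stringsAsFactors = FALSE)
  }
  per_taxon <- do.call(rbind, rows)
  summary <- stats::aggregate(mae ~ taxon, data = per_taxon, FUN = mean)
  list(per_taxon = per_taxon, summary = summary, folds = folds)
}
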