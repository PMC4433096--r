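#' Adjust counts for copy number and genome size, then normalize
#'
#' Counts from communities mixed as cells are divided by 16S copy number;
#' counts from communities mixed as genomic DNA are multiplied by genome size
#' and divided by copy number (a fixed DNA mass of a small genome carries
#' more 16S templates); counts from mixed PCR product need no adjustment.
#' Each sample is then normalized to proportions.
#'
#' @param counts integer matrix (samples x taxa), e.g. from
#'   [simulate_experiment()] or [read_counts()].
#' @param taxa taxon metadata (see [read_taxa()]).
#' @param experiment `"cells"`, `"dna"` or `"pcr"`; defaults to the matrix's
#'   `experiment` attribute when present.
#' @return Proportion matrix with the same dimnames; rows sum to 1. Carries
#'   an `experiment` attribute.
#' @export
adjust_counts <- function(counts, taxa, experiment = NULL) {
  counts <- as.matrix(counts)
  if (is.null(experiment)) experiment <- attr(counts, "experiment")
  experiment <- match.arg(experiment, c("cells", "dna", "pcr"))
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  meta <- .taxa_lookup(taxa, colnames(counts))
  adj <- switch(experiment,
    cells = sweep(counts, 2, meta$copy_number, "/"),
    dna   = sweep(counts, 2, meta$genome_size / meta$copy_number, "*"),
    pcr   = counts * 1.0
  )
  out <- .row_normalize(adj)
  attr(out, "experiment") <- experiment
  out
}

## match observed sample rows to design runs; returns prescribed matrix
## aligned to the observed rows
.match_prescribed <- function(observed, design) {
  prescribed <- design_proportions(design)
  idx <- match(rownames(observed), rownames(prescribed))
  if (anyNA(idx))
    stop("sample(s) not matched to design run_ids: ",
         paste(rownames(observed)[is.na(idx)], collapse = ", "), call. = FALSE)
  prescribed[idx, , drop = FALSE]
}

#' Per-taxon bias of observed versus prescribed proportions
#'
#' The bias of taxon i in a sample is the observed minus the prescribed
#' proportion; negative values mean the taxon's signal is suppressed,
#' positive values that it is amplified. Samples are matched to design rows
#' by `run_id`.
#'
#' @param observed proportion matrix (samples x taxa), `run_id` rownames.
#' @param design the `mixture_design`.
#' @return Long data frame `sample_id`, `taxon`, `prescribed`, `observed`,
#'   `bias`, plus a logical `present` flag (prescribed proportion > 0).
#' @export
compute_bias <- function(observed, design) {
  prescribed <- .match_prescribed(observed, design)
  taxa <- colnames(observed)
  out <- data.frame(
    sample_id = rep(rownames(observed), times = length(taxa)),
    taxon = rep(taxa, each = nrow(observed)),
    prescribed = as.vector(prescribed),
    observed = as.vector(observed),
    stringsAsFactors = FALSE
  )
  out$bias <- out$observed - out$prescribed
  out$present <- out$prescribed > 0
  out
}

#' Summarize bias per taxon
#'
#' Median and interquartile range of bias, computed only over samples in
#' which the taxon was actually present in the prescribed mixture (absent
#' taxa would dilute the summaries with structural zeros).
#'
#' @param bias long bias data frame from [compute_bias()] (optionally with a
#'   `stage` column from [stage_decomposition()]).
#' @return Data frame `taxon` (and `stage` if present), `n`, `median_bias`,
#'   `iqr`, `q25`, `q75`.
#' @export
summarize_bias <- function(bias) {
  keys <- intersect(c("taxon", "stage"), names(bias))
  sub <- bias[bias$present, , drop = FALSE]
  parts <- split(sub, sub[keys], drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(pp) {
    row <- pp[1, keys, drop = FALSE]
    v <- pp$bias
    cbind(row, data.frame(n = length(v), median_bias = stats::median(v),
                          iqr = stats::IQR(v),
                          q25 = unname(stats::quantile(v, 0.25)),
                          q75 = unname(stats::quantile(v, 0.75))))
  }))
  rownames(out) <- NULL
  out
}

## average replicate samples down to one row per unique treatment
.average_by_treatment <- function(observed, design) {
  trt <- treatment_of(design)
  names(trt) <- design$run_id
  g <- trt[rownames(observed)]
  if (anyNA(g))
    stop("sample(s) not matched to design run_ids: ",
         paste(rownames(observed)[is.na(g)], collapse = ", "), call. = FALSE)
  m <- rowsum(observed, group = g)
  m <- m / as.vector(table(g)[rownames(m)])
  m[order(as.integer(rownames(m))), , drop = FALSE]
}

#' Decompose bias into pipeline-stage contributions
#'
#' The three experiments mix the same prescribed proportions at different
#' pipeline entry points, so pairwise differences isolate stages:
#' total = experiment 1 (cells) - prescribed; extraction = exp1 - exp2;
#' PCR = exp2 - exp3; sequencing/classification = exp3 - prescribed. The
#' stage effects telescope to the total by construction. Replicate samples
#' are averaged within each unique treatment before differencing, since the
#' experiments share treatments rather than physical samples.
#'
#' @param exp1,exp2,exp3 proportion matrices for the cells, DNA and PCR
#'   experiments (adjusted via [adjust_counts()]), rownames = `run_id`.
#' @param design the shared `mixture_design`.
#' @return Long data frame `sample_id` (the unique treatment's run id),
#'   `taxon`, `stage` (`total`, `extraction`, `pcr`, `seq_class`), `bias`,
#'   `present`.
#' @export
stage_decomposition <- function(exp1, exp2, exp3, design) {
  m1 <- .average_by_treatment(exp1, design)
  m2 <- .average_by_treatment(exp2, design)
  m3 <- .average_by_treatment(exp3, design)
  common <- Reduce(intersect, list(rownames(m1), rownames(m2), rownames(m3)))
  if (length(common) < max(nrow(m1), nrow(m2), nrow(m3)))
    stop("treatments present in one experiment but missing from another",
         call. = FALSE)
  m1 <- m1[common, , drop = FALSE]
  m2 <- m2[common, , drop = FALSE]
  m3 <- m3[common, , drop = FALSE]
  prescribed <- .match_prescribed(m1, design)

  long <- function(mat, stage) {
    data.frame(
      sample_id = rep(rownames(mat), times = ncol(mat)),
      taxon = rep(colnames(mat), each = nrow(mat)),
      stage = stage,
      bias = as.vector(mat),
      present = as.vector(prescribed > 0),
      stringsAsFactors = FALSE
    )
  }
  rbind(
    long(m1 - prescribed, "total"),
    long(m1 - m2, "extraction"),
    long(m2 - m3, "pcr"),
    long(m3 - prescribed, "seq_class")
  )
}

#' Technical variation among replicates (median absolute error)
#'
#' For every replicated treatment, the absolute deviation of each member's
#' observed proportion from the replicate-group mean is computed; the median
#' of these deviations, over all groups and samples in which the taxon was
#' prescribed, is the taxon's median absolute error. It measures technical
#' variation only — bias cancels within a group.
#'
#' @param observed proportion matrix, `run_id` rownames.
#' @param design the `mixture_design`; groups are a unique run plus its
#'   replicates.
#' @return Data frame `taxon`, `n_deviations`, `mae`. When the design has no
#'   replicated treatment a zero-row frame is returned with a warning.
#' @export
technical_variation <- function(observed, design) {
  trt <- treatment_of(design)
  names(trt) <- design$run_id
  g <- trt[rownames(observed)]
  tab <- table(g)
  groups <- names(tab)[tab >= 2]
  taxa <- colnames(observed)
  if (length(groups) == 0) {
    warning("design has no replicated treatments; no technical variation to report")
    return(data.frame(taxon = character(0), n_deviations = integer(0),
                      mae = numeric(0)))
  }
  prescribed <- .match_prescribed(observed, design)
  devs <- vector("list", length(taxa))
  names(devs) <- taxa
  for (grp in groups) {
    rows <- which(g == grp)
    sub <- observed[rows, , drop = FALSE]
    ctr <- colMeans(sub)
    d <- abs(sweep(sub, 2, ctr))
    pres <- prescribed[rows[1], ] > 0  # same treatment -> same presence
    for (tx in taxa[pres])
      devs[[tx]] <- c(devs[[tx]], d[, tx])
  }
  data.frame(
    taxon = taxa,
    n_deviations = vapply(devs, length, integer(1)),
    mae = vapply(devs, function(v) if (length(v)) stats::median(v) else NA_real_,
                 numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Bootstrap Mahalanobis test for multivariate bias
#'
#' Tests whether a set of per-sample difference vectors (e.g. observed minus
#' prescribed proportions, or differences between two experiments) is
#' centred at zero. The statistic is the Mahalanobis distance of the mean
#' difference vector from the origin under the sample covariance, which
#' upweights departures along directions of low variation. A percentile
#' bootstrap over samples gives the confidence interval; the bias is flagged
#' significant when zero lies outside the interval (lower bound > 0).
#'
#' Compositional difference vectors sum to zero across the full taxon set,
#' making the covariance singular; a Moore-Penrose pseudo-inverse is then
#' used (with a warning). Dropping one taxon column beforehand avoids this.
#'
#' @param differences numeric matrix, one row per matched sample, one column
#'   per taxon.
#' @param n_boot bootstrap resamples (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return List: `distance`, `ci` (length-2), `significant`, `n`, `n_boot`,
#'   `level`.
#' @export
mahalanobis_bootstrap <- function(differences, n_boot = 10000L, level = 0.95,
                                  seed = 1L) {
  d <- as.matrix(differences)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 matched samples", call. = FALSE)

  warned <- FALSE
  dist_of <- function(m) {
    mu <- colMeans(m)
    S <- stats::cov(m)
    r <- tryCatch({
      drop(sqrt(stats::mahalanobis(mu, center = rep(0, length(mu)), cov = S)))
    }, error = function(e) NA_real_)
    if (!is.finite(r)) {
      if (!warned) {
        warned <<- TRUE
        warning("singular covariance; using Moore-Penrose pseudo-inverse",
                call. = FALSE)
      }
      Sp <- MASS::ginv(S)
      r <- sqrt(max(0, drop(t(mu) %*% Sp %*% mu)))
    }
    r
  }

  distance <- dist_of(d)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  boot <- vapply(seq_len(n_boot), function(b) {
    dist_of(d[sample.int(n, n, replace = TRUE), , drop = FALSE])
  }, numeric(1))
  alpha <- 1 - level
  ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
  list(distance = distance, ci = ci, significant = ci[1] > 0,
       n = n, n_boot = as.integer(n_boot), level = level)
}
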