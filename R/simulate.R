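#' Ground-truth bias parameters for forward simulation
#'
#' Generates the hidden parameters that drive the simulated pipeline: a
#' strictly positive per-taxon efficiency for each stage (DNA extraction
#' `extraction_eff`, PCR amplification `pcr_eff`, sequencing/classification
#' `seq_eff`), symmetric zero-diagonal pairwise interaction matrices for the
#' extraction and PCR stages, a technical-noise coefficient of variation and
#' a sequencing depth. The mechanism is the smallest one able to produce both
#' the main-effect and the blending-term signals a Scheffe model can detect.
#'
#' Scenarios:
#' \describe{
#'   \item{neutral}{all efficiencies 1, all interactions 0 — an unbiased
#'     pipeline (copy-number and genome-size distortion still applies).}
#'   \item{default}{lognormal extraction and PCR efficiencies (sd 0.5 on the
#'     log scale), near-identity sequencing factors (within 5\% of 1), and
#'     sparse symmetric interactions (20\% of pairs nonzero, magnitude capped
#'     at `min(0.5, 0.9/(p-1))` so template weights stay positive on the
#'     whole simplex).}
#'   \item{extraction_only}{bias confined to the extraction stage:
#'     `pcr_eff = seq_eff = 1` and the PCR interaction matrix is zero.}
#'   \item{pcr_only}{the mirror image: `extraction_eff = 1`, extraction
#'     interactions zero.}
#' }
#'
#' @param p number of taxa (>= 2).
#' @param scenario one of `"neutral"`, `"default"`, `"extraction_only"`,
#'   `"pcr_only"`.
#' @param seed integer seed; the same `(p, scenario, seed)` always yields the
#'   same truth.
#' @param noise_cv coefficient of variation of the per-sample lognormal
#'   technical jitter (default 0.03, calibrated so replicate median absolute
#'   error stays below 5\%).
#' @param depth sequencing depth, reads per sample (default 16000, roughly
#'   3.9 million reads over 240 samples).
#' @return A `bias_truth` list with fields `extraction_eff`, `pcr_eff`,
#'   `seq_eff`, `extraction_interaction`, `pcr_interaction`, `noise_cv`,
#'   `depth`, `seed`, `scenario`.
#' @export
make_truth <- function(p, scenario = c("default", "neutral", "extraction_only",
                                       "pcr_only"),
                       seed = 1L, noise_cv = 0.03, depth = 16000L) {
  if (p < 2) stop("need at least 2 taxa", call. = FALSE)
  scenario <- match.arg(scenario)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))

  draw_eff <- function(sd) exp(stats::rnorm(p, 0, sd))
  draw_seq <- function() stats::runif(p, 0.95, 1.05)
  draw_inter <- function() {
    bound <- min(0.5, 0.9 / (p - 1))
    g <- matrix(0, p, p)
    pairs <- utils::combn(p, 2)
    on_flags <- stats::runif(ncol(pairs)) < 0.20
    vals <- stats::runif(ncol(pairs), -bound, bound)
    for (k in seq_len(ncol(pairs))) if (on_flags[k]) {
      i <- pairs[1, k]; j <- pairs[2, k]
      g[i, j] <- g[j, i] <- vals[k]
    }
    g
  }

  zero <- matrix(0, p, p)
  ones <- rep(1, p)
  truth <- switch(scenario,
    neutral = list(extraction_eff = ones, pcr_eff = ones, seq_eff = ones,
                   extraction_interaction = zero, pcr_interaction = zero),
    default = list(extraction_eff = draw_eff(0.5), pcr_eff = draw_eff(0.5),
                   seq_eff = draw_seq(),
                   extraction_interaction = draw_inter(),
                   pcr_interaction = draw_inter()),
    extraction_only = list(extraction_eff = draw_eff(0.5), pcr_eff = ones,
                           seq_eff = ones,
                           extraction_interaction = draw_inter(),
                           pcr_interaction = zero),
    pcr_only = list(extraction_eff = ones, pcr_eff = draw_eff(0.5),
                    seq_eff = ones, extraction_interaction = zero,
                    pcr_interaction = draw_inter())
  )
  truth$noise_cv <- noise_cv
  truth$depth <- as.integer(depth)
  truth$seed <- as.integer(seed)
  truth$scenario <- scenario
  class(truth) <- "bias_truth"
  truth
}

#' @export
print.bias_truth <- function(x, ...) {
  p <- length(x$extraction_eff)
  cat(sprintf("Bias truth (scenario '%s', %d taxa, seed %d)\n",
              x$scenario, p, x$seed))
  cat(sprintf("  depth %d reads/sample, technical noise cv %.3f\n",
              x$depth, x$noise_cv))
  cat(sprintf("  nonzero interactions: extraction %d, pcr %d (of %d pairs)\n",
              sum(x$extraction_interaction[upper.tri(x$extraction_interaction)] != 0),
              sum(x$pcr_interaction[upper.tri(x$pcr_interaction)] != 0),
              choose(p, 2)))
  invisible(x)
}

## deterministic template weights for one prescribed mixture x (no noise);
## stages included depend on where mixing happens:
##   cells -> extraction + PCR + seq, dna -> PCR + seq, pcr -> seq only
.template_weights <- function(x, truth, taxa, experiment) {
  cn <- taxa$copy_number
  gs <- taxa$genome_size
  e <- truth$extraction_eff; a <- truth$pcr_eff; s <- truth$seq_eff
  gam <- truth$extraction_interaction; del <- truth$pcr_interaction
  w <- switch(experiment,
    cells = x * cn * e * (1 + drop(gam %*% x)) * a * (1 + drop(del %*% x)) * s,
    dna   = x * (cn / gs) * a * (1 + drop(del %*% x)) * s,
    pcr   = x * s,
    stop("unknown experiment: ", experiment, call. = FALSE)
  )
  if (any(w < 0))
    stop("interaction terms drove a template weight negative; ",
         "truth parameters violate the simplex positivity bound", call. = FALSE)
  w
}

#' Expected observed proportions under a bias truth
#'
#' The noise-free, infinite-depth expectation `w / sum(w)` of the observed
#' (unadjusted) proportions for each design row — the closed form the
#' stochastic simulator converges to.
#'
#' @param design a `mixture_design` (or proportion matrix).
#' @param truth a `bias_truth`.
#' @param taxa taxon metadata (see [read_taxa()]).
#' @param experiment `"cells"`, `"dna"` or `"pcr"` — which stage the mixing
#'   happened at.
#' @return Matrix of expected proportions, rows matching the design.
#' @export
expected_proportions <- function(design, truth, taxa,
                                 experiment = c("cells", "dna", "pcr")) {
  experiment <- match.arg(experiment)
  props <- if (inherits(design, "mixture_design")) design_proportions(design)
           else as.matrix(design)
  taxa <- .taxa_lookup(taxa, colnames(props))
  out <- t(apply(props, 1, function(x) {
    w <- .template_weights(x, truth, taxa, experiment)
    w / sum(w)
  }))
  dimnames(out) <- dimnames(props)
  out
}

#' Simulate one mixture experiment
#'
#' For every design run, computes the per-taxon template weight for the given
#' experiment, applies independent per-taxon lognormal technical jitter
#' (coefficient of variation `truth$noise_cv`), and draws read counts from a
#' multinomial at depth `truth$depth`. Replicate runs get independent jitter
#' and draws. Template weights:
#' \describe{
#'   \item{cells}{`x_i * copy_number_i * e_i * (1 + sum_j gamma_ij x_j) * a_i
#'     * (1 + sum_j delta_ij x_j) * s_i` — the full pipeline.}
#'   \item{dna}{`x_i * (copy_number_i / genome_size_i) * a_i *
#'     (1 + sum_j delta_ij x_j) * s_i` — extraction bypassed.}
#'   \item{pcr}{`x_i * s_i` — only sequencing/classification.}
#' }
#'
#' @inheritParams expected_proportions
#' @param seed integer seed; defaults to a value derived from `truth$seed`
#'   and the experiment label so the three experiments get distinct but
#'   reproducible streams.
#' @return Integer count matrix (runs x taxa), `run_id` rownames, with
#'   attributes `experiment` and `depth`. Rows sum exactly to the depth.
#' @export
simulate_experiment <- function(design, truth, taxa,
                                experiment = c("cells", "dna", "pcr"),
                                seed = NULL) {
  experiment <- match.arg(experiment)
  if (truth$depth < 1) stop("depth must be >= 1", call. = FALSE)
  props <- design_proportions(design)
  taxa <- .taxa_lookup(taxa, colnames(props))
  if (is.null(seed))
    seed <- truth$seed + match(experiment, c("cells", "dna", "pcr")) * 1000L

  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + truth$noise_cv^2))
  p <- ncol(props)
  counts <- t(apply(props, 1, function(x) {
    w <- .template_weights(x, truth, taxa, experiment)
    w <- w * stats::rlnorm(p, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    drop(stats::rmultinom(1, truth$depth, w / sum(w)))
  }))
  dimnames(counts) <- dimnames(props)
  storage.mode(counts) <- "integer"
  attr(counts, "experiment") <- experiment
  attr(counts, "depth") <- truth$depth
  counts
}

#' Simulate clinical-like samples with known composition
#'
#' Applies the full cells-experiment mechanism (extraction, PCR and
#' sequencing bias, technical jitter, multinomial sampling) to arbitrary true
#' community profiles, mimicking held-out samples whose composition is known
#' only to the simulator.
#'
#' @param truth a `bias_truth`.
#' @param taxa taxon metadata.
#' @param true_profiles matrix (samples x taxa) of true proportions; rows
#'   must be nonnegative and sum to 1.
#' @param depth reads per sample (defaults to `truth$depth`).
#' @param seed integer seed.
#' @return List: `counts` (integer matrix) and `true_profiles` (retained for
#'   evaluation).
#' @export
simulate_clinical <- function(truth, taxa, true_profiles, depth = truth$depth,
                              seed = 1L) {
  true_profiles <- as.matrix(true_profiles)
  if (any(true_profiles < 0))
    stop("true profiles must be nonnegative", call. = FALSE)
  if (any(abs(rowSums(true_profiles) - 1) > 1e-9))
    stop("true profiles must sum to 1", call. = FALSE)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  taxa <- .taxa_lookup(taxa, colnames(true_profiles))

  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + truth$noise_cv^2))
  p <- ncol(true_profiles)
  counts <- t(apply(true_profiles, 1, function(x) {
    w <- .template_weights(x, truth, taxa, "cells")
    w <- w * stats::rlnorm(p, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    drop(stats::rmultinom(1, depth, w / sum(w)))
  }))
  dimnames(counts) <- dimnames(true_profiles)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("clin", seq_len(nrow(counts)))
  storage.mode(counts) <- "integer"
  list(counts = counts, true_profiles = true_profiles)
}

#' Random community profiles on the simplex
#'
#' Dirichlet draws used to stand in for clinical community compositions.
#'
#' @param n number of profiles.
#' @param taxa character vector of taxon names, or taxon metadata.
#' @param alpha Dirichlet concentration (scalar or per-taxon); the default
#'   0.8 gives moderately uneven communities with occasional near-dominance,
#'   as typically seen in vaginal microbiome profiles.
#' @param seed integer seed.
#' @return Matrix (n x taxa) of proportions summing to 1.
#' @export
random_profiles <- function(n, taxa, alpha = 0.8, seed = 1L) {
  if (is.data.frame(taxa)) taxa <- taxa$name
  p <- length(taxa)
  alpha <- rep(alpha, length.out = p)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  g <- matrix(stats::rgamma(n * p, shape = rep(alpha, each = n)), n, p)
  pr <- g / rowSums(g)
  colnames(pr) <- taxa
  rownames(pr) <- paste0("clin", seq_len(n))
  pr
}

#' Export / import bias truth as JSON
#' @param truth a `bias_truth`.
#' @param path output file.
#' @return `read_truth` returns the reconstructed `bias_truth`.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$extraction_interaction <- as.matrix(x$extraction_interaction)
  x$pcr_interaction <- as.matrix(x$pcr_interaction)
  x$depth <- as.integer(x$depth)
  x$seed <- as.integer(x$seed)
  class(x) <- "bias_truth"
  x
}
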