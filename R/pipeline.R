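#' Run the full mock-community bias pipeline on simulated data
#'
#' Executes the whole protocol end to end: build the D-optimal mixture
#' design, draw the ground-truth bias parameters, simulate the three
#' experiments (cells, DNA, PCR product), adjust and normalize counts,
#' compute the per-stage bias decomposition and replicate technical
#' variation, test each stage with the bootstrap Mahalanobis distance, fit
#' per-taxon Scheffe special cubic models and screen blending terms, fit the
#' inverse scaling-factor models, and evaluate the correction on simulated
#' clinical-like samples. All randomness derives from `config$seed`.
#'
#' @param config named list as produced by [default_config()] /
#'   [read_config()]; unknown keys are rejected.
#' @param write_files write TSV/CSV/JSON artifacts under `config$out_dir`?
#'   Default `FALSE` (results are returned invisibly either way).
#' @return List with elements `design`, `truth`, `counts` (per experiment),
#'   `proportions`, `decomposition`, `bias_summary`, `technical_variation`,
#'   `significance`, `models` (Scheffe fits), `blends`, `inverse`
#'   (`models`, `cv`, `clinical_mae`), and `config`.
#' @export
run_pipeline <- function(config = default_config(), write_files = FALSE) {
  unknown <- setdiff(names(config), names(default_config()))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  config <- utils::modifyList(default_config(), config)
  seed <- as.integer(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  taxa <- stage("taxa", {
    if (is.character(config$taxa)) read_taxa(config$taxa)
    else validate_taxa(config$taxa)
  })
  p <- nrow(taxa)

  design <- stage("design", build_design(
    taxa, n_lack_of_fit = config$n_lack_of_fit,
    n_replicates = config$n_replicates, seed = seed))

  truth <- stage("truth", make_truth(
    p, scenario = config$scenario, seed = seed,
    noise_cv = config$noise_cv, depth = as.integer(config$depth)))

  counts <- stage("simulate", {
    lapply(stats::setNames(nm = c("cells", "dna", "pcr")), function(exp)
      simulate_experiment(design, truth, taxa, exp))
  })

  proportions <- stage("adjust", lapply(counts, adjust_counts, taxa = taxa))

  decomposition <- stage("bias", stage_decomposition(
    proportions$cells, proportions$dna, proportions$pcr, design))
  bias_summary <- summarize_bias(decomposition)

  tech <- stage("technical_variation", {
    out <- lapply(names(proportions), function(exp) {
      tv <- technical_variation(proportions[[exp]], design)
      if (nrow(tv)) tv$experiment <- exp
      tv
    })
    do.call(rbind, out)
  })

  significance <- stage("mahalanobis", {
    stages <- unique(decomposition$stage)
    out <- lapply(stats::setNames(nm = stages), function(st) {
      sub <- decomposition[decomposition$stage == st, , drop = FALSE]
      wide <- stats::reshape(sub[, c("sample_id", "taxon", "bias")],
                             idvar = "sample_id", timevar = "taxon",
                             direction = "wide")
      m <- as.matrix(wide[, -1, drop = FALSE])
      # drop the last taxon: compositional differences sum to zero
      suppressWarnings(mahalanobis_bootstrap(
        m[, -ncol(m), drop = FALSE], n_boot = as.integer(config$n_boot),
        level = config$boot_level, seed = seed))
    })
    out
  })

  models <- stage("scheffe", fit_scheffe_models(proportions$cells, design))
  blends <- stage("screen", lapply(models, screen_blends, alpha = config$alpha))

  inverse <- stage("inverse", {
    scl <- scaling_factors(proportions$cells, design)
    inv_models <- fit_inverse(scl, ntree = as.integer(config$ntree),
                              mtry = as.integer(config$mtry), seed = seed)
    cv <- cross_validate(scl, k = 5L, seed = seed,
                         ntree = as.integer(config$ntree),
                         mtry = as.integer(config$mtry),
                         orientation = config$factor_orientation)
    profiles <- random_profiles(as.integer(config$n_clinical), taxa,
                                seed = seed + 77L)
    clin <- simulate_clinical(truth, taxa, profiles, seed = seed + 78L)
    corrected <- correct_sample(clin$counts, taxa, inv_models,
                                orientation = config$factor_orientation)
    observed <- adjust_counts(clin$counts, taxa, "cells")
    list(models = inv_models, cv = cv,
         clinical_mae = c(
           corrected = mean(abs(corrected - clin$true_profiles)),
           uncorrected = mean(abs(observed - clin$true_profiles))))
  })

  result <- list(design = design, truth = truth, counts = counts,
                 proportions = proportions, decomposition = decomposition,
                 bias_summary = bias_summary, technical_variation = tech,
                 significance = significance, models = models, blends = blends,
                 inverse = inverse, config = config)

  if (write_files) .write_pipeline_files(result)
  invisible(result)
}

.write_pipeline_files <- function(result) {
  dir.create(result$config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- result$config$out_dir
  write_design(result$design, file.path(od, "design.csv"))
  write_truth(result$truth, file.path(od, "truth.json"))
  for (exp in names(result$counts))
    write_counts(result$counts[[exp]], file.path(od, paste0(exp, ".tsv")))
  utils::write.table(result$decomposition, file.path(od, "bias.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(result$bias_summary, file.path(od, "bias_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(result$technical_variation,
                     file.path(od, "technical_variation.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    lapply(result$significance, function(s)
      list(distance = s$distance, ci = s$ci, significant = s$significant)),
    file.path(od, "significance.json"), auto_unbox = TRUE, digits = NA)
  report <- list(
    seed = result$config$seed,
    scenario = result$config$scenario,
    r_squared = vapply(result$models, function(m) m$r.squared, numeric(1)),
    max_replicate_mae = max(result$technical_variation$mae),
    clinical_mae = as.list(result$inverse$clinical_mae))
  jsonlite::write_json(report, file.path(od, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(od)
}
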