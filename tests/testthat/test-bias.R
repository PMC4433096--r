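test_that("count adjustment divides out copy number and genome size", {
  taxa <- data.frame(name = c("a", "b"), copy_number = c(1L, 4L),
                     genome_size = c(2.0, 1.0), gram = c("+", "-"))
  counts <- matrix(c(100L, 100L), 1, dimnames = list("1", c("a", "b")))
  expect_equal(unname(adjust_counts(counts, taxa, "cells")[1, ]), c(0.8, 0.2))

  taxa2 <- data.frame(name = c("a", "b"), copy_number = c(1L, 1L),
                      genome_size = c(2.0, 1.0), gram = c("+", "-"))
  counts2 <- matrix(c(50L, 50L), 1, dimnames = list("1", c("a", "b")))
  expect_equal(unname(adjust_counts(counts2, taxa2, "dna")[1, ]),
               c(2 / 3, 1 / 3))
  expect_equal(unname(adjust_counts(counts2, taxa2, "pcr")[1, ]), c(0.5, 0.5))

  # identical metadata: adjustment cancels
  taxa3 <- uniform_taxa(2, c("a", "b"))
  taxa3$copy_number <- 3L; taxa3$genome_size <- 1.7
  expect_equal(unname(adjust_counts(counts2, taxa3, "cells")[1, ]), c(0.5, 0.5))
  expect_equal(unname(adjust_counts(counts2, taxa3, "dna")[1, ]), c(0.5, 0.5))

  # scale invariance in the counts
  expect_equal(adjust_counts(counts * 13L, taxa, "cells"),
               adjust_counts(counts, taxa, "cells"))

  zero <- matrix(0L, 1, 2, dimnames = list("s1", c("a", "b")))
  expect_error(adjust_counts(zero, taxa, "cells"), "zero total")
  expect_error(adjust_counts(counts, taxa[1, ], "cells"), "no metadata")
  expect_error(adjust_counts(-counts, taxa, "cells"), "nonnegative")
})

test_that("bias is observed minus prescribed and sums to zero per sample", {
  p <- 4
  taxa <- uniform_taxa(p)
  d <- design_from_matrix(candidate_set(p), taxa$name)
  prescribed <- design_proportions(d)

  b0 <- compute_bias(prescribed, d)  # observed == prescribed
  expect_true(all(b0$bias == 0))

  set.seed(1)
  noise <- matrix(rnorm(length(prescribed), 0, 0.02), nrow(prescribed))
  obs <- prescribed + noise - rowMeans(noise)  # keep rows summing to 1
  b <- compute_bias(obs, d)
  sums <- tapply(b$bias, b$sample_id, sum)
  expect_true(all(abs(sums) < 1e-9))
  expect_equal(b$present, b$prescribed > 0)

  # the worked binary-blend example: 92.5% observed vs 50% prescribed
  d2 <- design_from_matrix(matrix(c(0.5, 0.5), 1), c("a", "b"))
  obs2 <- matrix(c(0.925, 0.075), 1, dimnames = list("1", c("a", "b")))
  b2 <- compute_bias(obs2, d2)
  expect_equal(b2$bias[b2$taxon == "a"], 0.425)

  rownames(obs) <- paste0("nope", seq_len(nrow(obs)))
  expect_error(compute_bias(obs, d), "not matched")
})

test_that("stage decomposition telescopes and zeroes out on identical inputs", {
  taxa <- vag_taxa()
  d <- build_design(taxa, seed = 51)
  prescribed <- design_proportions(d)

  dec0 <- stage_decomposition(prescribed, prescribed, prescribed, d)
  expect_true(all(abs(dec0$bias) < 1e-12))

  tr <- make_truth(7, "default", seed = 51)
  pr <- lapply(c(cells = "cells", dna = "dna", pcr = "pcr"), function(e)
    adjust_counts(simulate_experiment(d, tr, taxa, e), taxa))
  dec <- stage_decomposition(pr$cells, pr$dna, pr$pcr, d)
  wide <- stats::reshape(dec[, c("sample_id", "taxon", "stage", "bias")],
                         idvar = c("sample_id", "taxon"), timevar = "stage",
                         direction = "wide")
  expect_equal(wide$bias.total,
               wide$bias.extraction + wide$bias.pcr + wide$bias.seq_class,
               tolerance = 1e-9)
})

test_that("an extraction-only mechanism is attributed to the extraction stage", {
  taxa <- vag_taxa()
  d <- build_design(taxa, seed = 1)
  tr <- make_truth(7, "extraction_only", seed = 1, depth = 100000L)
  pr <- lapply(c(cells = "cells", dna = "dna", pcr = "pcr"), function(e)
    adjust_counts(simulate_experiment(d, tr, taxa, e), taxa))
  dec <- stage_decomposition(pr$cells, pr$dna, pr$pcr, d)
  med <- sapply(split(abs(dec$bias[dec$present]), dec$stage[dec$present]),
                stats::median)
  expect_lt(med[["pcr"]], 0.01)
  expect_lt(med[["seq_class"]], 0.01)
  # extraction carries essentially the whole total
  expect_gt(med[["extraction"]] / med[["total"]], 0.95)
})

test_that("technical variation summarizes replicate deviations", {
  taxa <- uniform_taxa(2, c("a", "b"))
  m <- matrix(c(0.5, 0.5, 0.48, 0.52, 0.52, 0.48), 3, 2, byrow = TRUE)
  colnames(m) <- c("a", "b")
  d <- data.frame(run_id = 1:3, role = c("support", "replicate", "replicate"),
                  replicate_of = c(NA, 1L, 1L), a = m[, 1], b = m[, 2])
  class(d) <- c("mixture_design", "data.frame")
  rownames(m) <- 1:3

  # identical replicates -> zero error
  ident <- m[c(1, 1, 1), ]; rownames(ident) <- 1:3
  expect_true(all(technical_variation(ident, d)$mae == 0))

  # deviations of (0.5, 0.48, 0.52) from their mean 0.5: (0, .02, .02)
  tv <- technical_variation(m, d)
  expect_equal(tv$mae, c(0.02, 0.02))

  d_norep <- design_from_matrix(candidate_set(2), c("a", "b"))
  obs <- design_proportions(d_norep)
  expect_warning(tv0 <- technical_variation(obs, d_norep), "no replicated")
  expect_equal(nrow(tv0), 0)
})

test_that("bootstrap Mahalanobis distance flags real shifts only", {
  # all-zero differences: distance 0, zero inside the (degenerate) CI
  zeros <- matrix(0, 30, 3)
  r0 <- suppressWarnings(mahalanobis_bootstrap(zeros, n_boot = 200, seed = 1))
  expect_equal(r0$distance, 0)
  expect_false(r0$significant)

  # +0.3 shift on one coordinate across 60 samples, tiny noise
  set.seed(2)
  shifted <- matrix(rnorm(60 * 3, 0, 0.01), 60, 3)
  shifted[, 2] <- shifted[, 2] + 0.3
  r1 <- mahalanobis_bootstrap(shifted, n_boot = 2000, level = 0.95, seed = 3)
  expect_true(r1$significant)
  expect_gt(r1$ci[1], 0)

  r2 <- mahalanobis_bootstrap(shifted, n_boot = 2000, level = 0.95, seed = 3)
  expect_identical(r1$ci, r2$ci)

  expect_error(mahalanobis_bootstrap(shifted[1, , drop = FALSE]), "at least 2")
})

test_that("bias summaries cover present taxa only", {
  d <- design_from_matrix(candidate_set(3), c("a", "b", "c"))
  obs <- design_proportions(d)
  obs[, 1] <- obs[, 1] + 0.01
  obs[, 2] <- obs[, 2] - 0.01
  b <- compute_bias(obs, d)
  s <- summarize_bias(b)
  # taxon a prescribed > 0 in 4 of the 7 candidate points
  expect_equal(s$n[s$taxon == "a"], sum(candidate_set(3)[, 1] > 0))
})
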