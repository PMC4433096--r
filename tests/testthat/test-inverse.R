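# shared simulated training set for the inverse models
make_inverse_fixture <- function(scenario = "default", seed = 101,
                                 depth = 16000L) {
  taxa <- vag_taxa()
  d <- build_design(taxa, seed = seed)
  tr <- make_truth(7, scenario, seed = seed, depth = depth)
  pr <- adjust_counts(simulate_experiment(d, tr, taxa, "cells"), taxa)
  list(taxa = taxa, design = d, truth = tr, observed = pr,
       scaling = scaling_factors(pr, d))
}

test_that("scaling factors are observed over actual, for present taxa only", {
  d <- design_from_matrix(candidate_set(3), c("a", "b", "c"))
  prescribed <- design_proportions(d)

  s0 <- scaling_factors(prescribed, d)  # observed == actual
  expect_true(all(s0$data$scaling_factor == 1))
  # only nonzero-actual entries emit observations
  expect_equal(nrow(s0$data), sum(prescribed > 0))

  obs <- matrix(c(0.925, 0.075), 1, dimnames = list("1", c("a", "b")))
  act <- matrix(c(0.5, 0.5), 1, dimnames = list("1", c("a", "b")))
  s1 <- scaling_factors(obs, act)
  expect_equal(s1$data$scaling_factor[s1$data$taxon == "a"], 1.85)

  act0 <- matrix(c(1, 0), 1, dimnames = list("1", c("a", "b")))
  s2 <- scaling_factors(obs, act0)
  expect_equal(s2$data$taxon, "a")
})

test_that("forests of constant responses predict the constant", {
  fx <- make_inverse_fixture()
  const <- fx$scaling
  const$data$scaling_factor <- 2.5
  # constant response triggers randomForest's five-unique-values notice
  models <- suppressWarnings(fit_inverse(const, ntree = 100, seed = 1))
  pred <- predict(models, fx$observed)
  expect_equal(unname(as.vector(pred)), rep(2.5, length(pred)), tolerance = 1e-8)
})

test_that("forest fits are seed-deterministic and beat the response variance", {
  fx <- make_inverse_fixture()
  m1 <- fit_inverse(fx$scaling, seed = 7)
  m2 <- fit_inverse(fx$scaling, seed = 7)
  expect_identical(predict(m1, fx$observed), predict(m2, fx$observed))

  # out-of-bag error below the variance of the responses (model learns signal)
  for (tx in m1$taxa) {
    oob <- m1$forests[[tx]]$mse[m1$ntree]
    v <- stats::var(fx$scaling$data$scaling_factor[fx$scaling$data$taxon == tx])
    expect_lt(oob, v)
  }
})

test_that("taxa with too few observations are skipped with a warning", {
  fx <- make_inverse_fixture()
  starved <- fx$scaling
  amnii_rows <- which(starved$data$taxon == "S. amnii")
  drop_rows <- amnii_rows[-(1:5)]  # leave only 5 observations for this taxon
  starved$data <- starved$data[-drop_rows, , drop = FALSE]
  expect_warning(m <- fit_inverse(starved, ntree = 50, seed = 1), "S. amnii")
  expect_false("S. amnii" %in% m$taxa)
})

test_that("identity scaling leaves adjusted proportions unchanged", {
  taxa <- vag_taxa()
  d <- build_design(taxa, seed = 111)
  prescribed <- design_proportions(d)
  # train on observed == actual so every factor is exactly 1
  s <- scaling_factors(prescribed, d)
  models <- suppressWarnings(fit_inverse(s, ntree = 100, seed = 2))

  counts <- matrix(c(100L, 50L, 200L, 25L, 80L, 140L, 60L), 1,
                   dimnames = list("c1", taxa$name))
  corrected <- correct_sample(counts, taxa, models)
  expect_equal(unname(rowSums(corrected)), 1)
  expect_equal(corrected, adjust_counts(counts, taxa, "cells"),
               tolerance = 1e-6, ignore_attr = TRUE)

  # scale invariance in the input counts
  expect_equal(correct_sample(counts * 5L, taxa, models), corrected,
               tolerance = 1e-10)
})

test_that("corrections error on unmodelled taxa and drop off-panel taxa", {
  fx <- make_inverse_fixture()
  models <- fit_inverse(fx$scaling, ntree = 50, seed = 3)
  counts <- matrix(10L, 1, 8,
                   dimnames = list("c1", c(fx$taxa$name, "E. coli")))
  expect_warning(out <- correct_sample(counts, fx$taxa, models), "E. coli")
  expect_false("E. coli" %in% colnames(out))

  models$taxa <- setdiff(models$taxa, "P. bivia")  # pretend a model is missing
  counts2 <- matrix(10L, 1, 7, dimnames = list("c1", fx$taxa$name))
  expect_error(correct_sample(counts2, fx$taxa, models), "P. bivia")
})

test_that("inverse correction beats raw observation on held-out samples", {
  fx <- make_inverse_fixture(seed = 121)
  models <- fit_inverse(fx$scaling, seed = 121)
  profiles <- random_profiles(50, fx$taxa, seed = 122)
  clin <- simulate_clinical(fx$truth, fx$taxa, profiles, seed = 123)
  corrected <- correct_sample(clin$counts, fx$taxa, models)
  observed <- adjust_counts(clin$counts, fx$taxa, "cells")
  mae_corr <- mean(abs(corrected - clin$true_profiles))
  mae_raw <- mean(abs(observed - clin$true_profiles))
  expect_lt(mae_corr, mae_raw)
})

test_that("extraction-only bias is inverted to within 2% median error", {
  fx <- make_inverse_fixture("extraction_only", seed = 131, depth = 100000L)
  models <- fit_inverse(fx$scaling, seed = 131)
  profiles <- random_profiles(30, fx$taxa, seed = 132)
  clin <- simulate_clinical(fx$truth, fx$taxa, profiles, depth = 100000L,
                            seed = 133)
  corrected <- correct_sample(clin$counts, fx$taxa, models)
  expect_lt(stats::median(abs(corrected - clin$true_profiles)), 0.02)
})

test_that("both factor orientations are available", {
  fx <- make_inverse_fixture(seed = 141)
  models <- fit_inverse(fx$scaling, ntree = 100, seed = 141)
  counts <- matrix(c(100L, 50L, 200L, 25L, 80L, 140L, 60L), 1,
                   dimnames = list("c1", fx$taxa$name))
  a <- correct_sample(counts, fx$taxa, models, orientation = "obs_over_actual")
  b <- correct_sample(counts, fx$taxa, models, orientation = "actual_over_obs")
  expect_equal(unname(rowSums(a)), 1)
  expect_equal(unname(rowSums(b)), 1)
  expect_false(isTRUE(all.equal(a, b)))
})

test_that("cross-validation partitions samples and reports per-taxon error", {
  fx <- make_inverse_fixture(seed = 151)
  cv <- cross_validate(fx$scaling, k = 4, seed = 151, ntree = 100)
  expect_setequal(names(cv$folds), rownames(fx$observed))
  expect_equal(sort(unique(cv$per_taxon$fold)), 1:4)
  expect_equal(nrow(cv$summary), 7)
  expect_true(all(cv$summary$mae >= 0))

  expect_error(cross_validate(fx$scaling, k = 1), "at least 2")
  expect_error(cross_validate(fx$scaling, k = 1000), "exceeds")

  # neutral pipeline: cross-validated error sits near the technical noise floor
  fx0 <- make_inverse_fixture("neutral", seed = 152)
  cv0 <- cross_validate(fx0$scaling, k = 4, seed = 152, ntree = 100)
  tv <- technical_variation(fx0$observed, fx0$design)
  expect_lt(mean(cv0$summary$mae), 5 * stats::median(tv$mae) + 0.02)
})
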