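test_that("the Scheffe basis expands simplex points correctly", {
  expect_equal(unname(scheffe_matrix(matrix(c(0.5, 0.5), 1))[1, ]),
               c(0.5, 0.5, 0.25))
  pure <- matrix(c(1, 0, 0), 1)
  expect_equal(unname(scheffe_matrix(pure)[1, ]), c(1, 0, 0, 0, 0, 0, 0))
  centroid <- matrix(rep(1 / 3, 3), 1)
  expect_equal(unname(scheffe_matrix(centroid)[1, ]),
               c(rep(1 / 3, 3), rep(1 / 9, 3), 1 / 27))
  expect_equal(ncol(scheffe_matrix(candidate_set(7))), 63)
  expect_error(scheffe_matrix(matrix(c(0.5, 0.2), 1)), "simplex")
})

test_that("exact responses are recovered at machine precision", {
  X <- rbind(candidate_set(3), enlarged_candidates_p3()[8:10, ])
  colnames(X) <- c("a", "b", "c")

  fit1 <- scheffe(X, X[, 1])  # y == x_a exactly
  expect_equal(unname(coef(fit1)), c(1, 0, 0, 0, 0, 0, 0), tolerance = 1e-12)

  fit2 <- scheffe(X, rep(0.7, nrow(X)))  # constant response
  expect_equal(unname(coef(fit2)), c(0.7, 0.7, 0.7, 0, 0, 0, 0),
               tolerance = 1e-12)
})

test_that("known coefficients are recovered from a noiseless 80-run design", {
  taxa <- vag_taxa()
  d <- build_design(taxa, seed = 61)
  X <- scheffe_matrix(design_proportions(d))
  set.seed(62)
  beta <- rnorm(ncol(X), 0, 1)
  fit <- scheffe(design_proportions(d), drop(X %*% beta))
  expect_lt(max(abs(coef(fit) - beta)) / max(abs(beta)), 1e-8)
  # noiseless predictions reproduce the response at the design points
  expect_equal(unname(fitted(fit)), unname(drop(X %*% beta)), tolerance = 1e-10)
})

test_that("rank deficiency is reported with the collinear columns named", {
  X <- candidate_set(3)[c(1, 2, 3), ]  # vertices only: product columns are zero
  X <- X[rep(1:3, 4), ]
  colnames(X) <- c("a", "b", "c")
  expect_error(scheffe(X, rnorm(12)), "rank deficient.*a:b")
})

test_that("fits are invariant to component permutation", {
  d <- design_from_matrix(rbind(candidate_set(3), enlarged_candidates_p3()[8:10, ]),
                          c("a", "b", "c"))
  m <- design_proportions(d)
  set.seed(63)
  y <- drop(scheffe_matrix(m) %*% rnorm(7)) + rnorm(nrow(m), 0, 0.01)
  f1 <- scheffe(m, y)
  f2 <- scheffe(m[, c(3, 1, 2)], y)
  expect_equal(predict(f2, m[, c(3, 1, 2)]), predict(f1, m), tolerance = 1e-10)
})

test_that("per-taxon models on simulated data explain nearly all variation", {
  taxa <- vag_taxa()
  d <- build_design(taxa, seed = 71)
  tr <- make_truth(7, "default", seed = 71)
  pr <- adjust_counts(simulate_experiment(d, tr, taxa, "cells"), taxa)
  fits <- fit_scheffe_models(pr, d)
  expect_named(fits, taxa$name)
  for (f in fits) {
    expect_gt(f$r.squared, 0.99)
    expect_equal(length(coef(f)), 63)
    expect_true(f$r.squared <= 1 && f$r.squared.uncentered <= 1)
  }
})

test_that("blend screening applies a per-model Bonferroni correction", {
  d <- build_design(vag_taxa(), seed = 81)
  m <- design_proportions(d)
  X <- scheffe_matrix(m)
  beta <- numeric(ncol(X))
  beta[1:7] <- 0.5
  i_syn <- which(colnames(X) == "A. vaginae:G. vaginalis")
  i_ant <- which(colnames(X) == "L. crispatus:S. agalactiae")
  beta[i_syn] <- 1.41
  beta[i_ant] <- -1.66
  set.seed(82)
  fit <- scheffe(m, drop(X %*% beta) + rnorm(nrow(m), 0, 1e-4))

  n_blend <- choose(7, 2) + choose(7, 3)
  all_terms <- screen_blends(fit, all = TRUE)
  expect_equal(nrow(all_terms), n_blend)
  expect_equal(all_terms$p.adjusted,
               pmin(1, all_terms$p.value * n_blend))
  expect_true(all(diff(all_terms$p.adjusted) >= 0))  # decreasing significance

  sig <- screen_blends(fit, alpha = 0.05)
  expect_setequal(sig$term, colnames(X)[c(i_syn, i_ant)])
  expect_equal(sig$direction[sig$term == colnames(X)[i_syn]], "synergistic")
  expect_equal(sig$direction[sig$term == colnames(X)[i_ant]], "antagonistic")
})

test_that("blending surfaces honor the hypotenuse closed form", {
  m <- rbind(candidate_set(3), enlarged_candidates_p3()[8:10, ])
  colnames(m) <- c("a", "b", "c")
  X <- scheffe_matrix(m)
  beta <- c(0.5, 0.5, 0.2, 1.41, 0, 0, 0)  # beta_ab = 1.41
  fit <- scheffe(m, drop(X %*% beta))
  surf <- blending_surface(fit, "a", "b", grid_resolution = 3)
  hyp <- surf[abs(surf$xi + surf$xj - 1) < 1e-9 & surf$xi == 0.5, ]
  expect_equal(hyp$value, 0.5 * 0.5 + 0.5 * 0.5 + 1.41 * 0.25)

  # a purely linear model gives a planar surface
  lin <- scheffe(m, drop(m %*% c(0.2, 0.5, 0.9)))
  s2 <- blending_surface(lin, "a", "b", grid_resolution = 5)
  pred_plane <- with(s2, 0.2 * xi + 0.5 * xj + 0.9 * (1 - xi - xj))
  expect_equal(s2$value, pred_plane, tolerance = 1e-10)

  expect_error(blending_surface(fit, "a", "a"), "distinct")
  expect_error(blending_surface(fit, "a", "b", grid_resolution = 1), "at least 2")
})

test_that("interior surface averaging matches a brute-force lattice mean", {
  p <- 4
  m <- rbind(candidate_set(p), rep(0.25, p))
  colnames(m) <- paste0("t", 1:4)
  set.seed(91)
  y <- drop(scheffe_matrix(m) %*% rnorm(special_cubic_size(p)))
  fit <- scheffe(m, y)

  xi <- 0.3; xj <- 0.2; r <- 1 - xi - xj
  step <- 0.05
  # independent oracle: explicit lattice over the two remaining components
  w <- seq(0, 1, by = step)
  lattice <- cbind(w, 1 - w)
  pts <- cbind(xi, xj, lattice * r)
  colnames(pts) <- colnames(m)
  oracle <- mean(predict(fit, pts))

  surf <- blending_surface(fit, 1, 2, grid_resolution = 11, lattice_step = step)
  got <- surf$value[abs(surf$xi - xi) < 1e-9 & abs(surf$xj - xj) < 1e-9]
  expect_equal(got, oracle, tolerance = 1e-10)
})
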