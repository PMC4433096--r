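#' Number of parameters in a Scheffe special cubic model
#'
#' A special cubic mixture model in `p` components has one coefficient per
#' component, one per unordered pair, and one per unordered triple, and no
#' intercept. Fitting it therefore needs at least `p + choose(p,2) +
#' choose(p,3)` runs: 63 for seven components, 298 for twelve.
#'
#' @param p integer number of mixture components (taxa); must be >= 1.
#' @return Integer parameter count.
#' @examples
#' special_cubic_size(7)   # 63
#' special_cubic_size(12)  # 298
#' @export
special_cubic_size <- function(p) {
  if (length(p) != 1L || is.na(p) || p < 1 || p != round(p))
    stop("`p` must be a single integer >= 1", call. = FALSE)
  p <- as.integer(p)
  # choose() returns 0 for k > n, so p < 3 needs no special casing
  as.integer(p + choose(p, 2) + choose(p, 3))
}

#' Candidate points for a special cubic mixture design
#'
#' The classical support for special cubic D-optimality: the `p` pure blends
#' (vertices of the simplex), all `choose(p,2)` equal binary blends
#' (edge midpoints) and all `choose(p,3)` equal ternary blends (face
#' centroids). The cardinality equals [special_cubic_size()].
#'
#' @param p integer number of components; must be >= 2.
#' @return Numeric matrix with one candidate per row; rows sum to 1.
#' @export
candidate_set <- function(p) {
  if (length(p) != 1L || is.na(p) || p < 2 || p != round(p))
    stop("`p` must be a single integer >= 2", call. = FALSE)
  p <- as.integer(p)
  pts <- diag(p)
  if (p >= 2) {
    pairs <- utils::combn(p, 2)
    m <- matrix(0, ncol(pairs), p)
    for (k in seq_len(ncol(pairs))) m[k, pairs[, k]] <- 1 / 2
    pts <- rbind(pts, m)
  }
  if (p >= 3) {
    triples <- utils::combn(p, 3)
    m <- matrix(0, ncol(triples), p)
    for (k in seq_len(ncol(triples))) m[k, triples[, k]] <- 1 / 3
    pts <- rbind(pts, m)
  }
  dimnames(pts) <- NULL
  pts
}

## log-determinant of the special cubic information matrix X'X for a set of
## simplex points; -Inf when singular
.design_logdet <- function(points) {
  X <- scheffe_matrix(points, order = "special_cubic", check = FALSE)
  if (nrow(X) < ncol(X)) return(-Inf)
  d <- determinant(crossprod(X), logarithm = TRUE)
  if (d$sign <= 0) -Inf else as.numeric(d$modulus)
}

#' Select a D-optimal subset of candidate mixture points
#'
#' Fedorov point exchange: starting from a random size-`n_support` subset,
#' repeatedly swap the design point and candidate pair giving the largest
#' increase in the determinant of the special cubic information matrix until
#' no swap improves it. Multiple random restarts are taken and the best design
#' kept; ties in exchange deltas are broken by candidate index so the result
#' is deterministic for a fixed seed.
#'
#' @param candidates numeric matrix of simplex points (rows sum to 1).
#' @param n_support number of runs to select; must be at least
#'   [special_cubic_size()] of `ncol(candidates)`.
#' @param seed integer seed for the random restarts.
#' @param n_restarts number of random restarts (default 10).
#' @return Matrix of the selected support rows.
#' @export
select_d_optimal <- function(candidates, n_support, seed = 1L, n_restarts = 10L) {
  candidates <- as.matrix(candidates)
  p <- ncol(candidates)
  k <- special_cubic_size(p)
  if (n_support < k)
    stop(sprintf(paste0("infeasible design: n_support = %d is below the %d ",
                        "parameters of the special cubic model (rank deficient)"),
                 n_support, k), call. = FALSE)
  n_cand <- nrow(candidates)
  if (n_support > n_cand)
    stop("n_support exceeds the number of candidate points", call. = FALSE)
  if (n_support == n_cand) return(candidates)

  best_logdet <- -Inf
  best_idx <- NULL
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  for (restart in seq_len(n_restarts)) {
    idx <- sort(sample.int(n_cand, n_support))
    cur <- .design_logdet(candidates[idx, , drop = FALSE])
    tries <- 0L
    while (!is.finite(cur) && tries < 50L) {  # resample until non-singular start
      idx <- sort(sample.int(n_cand, n_support))
      cur <- .design_logdet(candidates[idx, , drop = FALSE])
      tries <- tries + 1L
    }
    repeat {
      improved <- FALSE
      out_pool <- setdiff(seq_len(n_cand), idx)
      best_delta <- 1e-10  # require a strict improvement
      swap <- NULL
      for (i in seq_along(idx)) {
        for (j in out_pool) {
          trial <- idx
          trial[i] <- j
          ld <- .design_logdet(candidates[trial, , drop = FALSE])
          if (ld - cur > best_delta) {
            best_delta <- ld - cur
            swap <- c(i, j)
          }
        }
      }
      if (is.null(swap)) break
      idx[swap[1]] <- swap[2]
      idx <- sort(idx)
      cur <- .design_logdet(candidates[idx, , drop = FALSE])
      improved <- TRUE
      if (!improved) break
    }
    if (cur > best_logdet) {
      best_logdet <- cur
      best_idx <- idx
    }
  }
  if (!is.finite(best_logdet))
    stop("could not find a non-singular design; candidates do not span the model space",
         call. = FALSE)
  candidates[best_idx, , drop = FALSE]
}

## interior lack-of-fit points: overall centroid first, then equal blends of
## random min(4, p)-subsets, skipping anything already present
.lack_of_fit_points <- function(existing, n, p) {
  pts <- matrix(numeric(0), 0, p)
  is_dup <- function(x, mat) {
    if (nrow(mat) == 0) return(FALSE)
    any(apply(mat, 1, function(r) max(abs(r - x)) < 1e-9))
  }
  add <- function(x) {
    if (!is_dup(x, existing) && !is_dup(x, pts)) pts <<- rbind(pts, x)
  }
  add(rep(1 / p, p))
  kk <- min(4L, p)
  guard <- 0L
  while (nrow(pts) < n && guard < 1000L) {
    x <- numeric(p)
    x[sample.int(p, kk)] <- 1 / kk
    add(x)
    guard <- guard + 1L
  }
  if (nrow(pts) < n)
    stop("could not generate enough unique lack-of-fit points", call. = FALSE)
  pts[seq_len(n), , drop = FALSE]
}

#' Assemble a full mixture design with lack-of-fit and replicate runs
#'
#' Appends `n_lack_of_fit` interior treatment combinations (for testing model
#' adequacy) and `n_replicates` exact copies of randomly chosen unique runs
#' (for estimating pure error variance) to the D-optimal support, then
#' randomizes the run order. With 63 support points, 2 lack-of-fit points and
#' 15 replicates this reproduces the 80-run / 65-unique-treatment layout used
#' for a seven-taxon panel.
#'
#' @param support matrix of support points (rows sum to 1), e.g. from
#'   [select_d_optimal()].
#' @param n_lack_of_fit number of extra unique treatment combinations.
#' @param n_replicates number of replicate runs.
#' @param seed integer seed controlling lack-of-fit choice, replicate choice
#'   and run-order randomization.
#' @param taxa optional character vector of component (taxon) names.
#' @return A `mixture_design`: data frame with columns `run_id`, `role`
#'   (`support`, `lack_of_fit` or `replicate`), `replicate_of` (the `run_id`
#'   a replicate copies, `NA` otherwise) and one proportion column per taxon.
#' @export
assemble_runs <- function(support, n_lack_of_fit = 0L, n_replicates = 0L,
                          seed = 1L, taxa = NULL) {
  support <- as.matrix(support)
  p <- ncol(support)
  if (anyDuplicated(round(support, 9)))
    stop("support rows must be unique treatment combinations", call. = FALSE)
  if (is.null(taxa)) taxa <- colnames(support)
  if (is.null(taxa)) taxa <- paste0("taxon", seq_len(p))

  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))

  lof <- if (n_lack_of_fit > 0) .lack_of_fit_points(support, n_lack_of_fit, p)
         else matrix(numeric(0), 0, p)
  unique_pts <- rbind(support, lof)
  n_unique <- nrow(unique_pts)
  role <- c(rep("support", nrow(support)), rep("lack_of_fit", nrow(lof)))

  if (n_replicates > n_unique)
    stop("more replicates requested than unique runs available", call. = FALSE)
  rep_src <- if (n_replicates > 0) sort(sample.int(n_unique, n_replicates)) else integer(0)

  props <- rbind(unique_pts, unique_pts[rep_src, , drop = FALSE])
  role <- c(role, rep("replicate", n_replicates))
  replicate_of <- c(rep(NA_integer_, n_unique), rep_src)

  ord <- sample.int(nrow(props))  # randomized run order
  props <- props[ord, , drop = FALSE]
  role <- role[ord]
  replicate_of <- replicate_of[ord]
  # run ids follow randomized order; remap replicate links to new ids
  new_id_of_old <- match(seq_len(n_unique + n_replicates), ord)
  replicate_of <- ifelse(is.na(replicate_of), NA_integer_,
                         new_id_of_old[replicate_of])

  d <- data.frame(run_id = seq_len(nrow(props)), role = role,
                  replicate_of = as.integer(replicate_of),
                  stringsAsFactors = FALSE)
  pm <- as.data.frame(props)
  names(pm) <- taxa
  rownames(pm) <- NULL
  d <- cbind(d, pm)
  class(d) <- c("mixture_design", "data.frame")
  validate_design(d)
  d
}

#' Build a complete mixture design for a taxon panel
#'
#' Convenience wrapper running candidate generation, D-optimal selection and
#' run assembly in one call.
#'
#' @param taxa character vector of taxon names (or a taxon metadata data
#'   frame with a `name` column).
#' @param n_support support size; defaults to the special cubic parameter
#'   count (the minimal saturated design).
#' @param n_lack_of_fit,n_replicates extra unique runs and replicate runs.
#' @param seed integer seed.
#' @return A `mixture_design` (see [assemble_runs()]).
#' @export
build_design <- function(taxa, n_support = NULL, n_lack_of_fit = 2L,
                         n_replicates = 15L, seed = 1L) {
  if (is.data.frame(taxa)) taxa <- taxa$name
  p <- length(taxa)
  cand <- candidate_set(p)
  if (is.null(n_support)) n_support <- special_cubic_size(p)
  sup <- select_d_optimal(cand, n_support, seed = seed)
  colnames(sup) <- taxa
  assemble_runs(sup, n_lack_of_fit, n_replicates, seed = seed, taxa = taxa)
}

#' @export
print.mixture_design <- function(x, ...) {
  p <- length(design_taxa(x))
  cat(sprintf("Mixture design: %d runs, %d unique treatments, %d components\n",
              nrow(x), sum(x$role != "replicate"), p))
  cat(sprintf("  roles: %s\n",
              paste(sprintf("%s=%d", names(table(x$role)), table(x$role)),
                    collapse = ", ")))
  invisible(x)
}

#' Taxon (component) names of a mixture design
#' @param design a `mixture_design`.
#' @return Character vector of taxon column names.
#' @export
design_taxa <- function(design) {
  setdiff(names(design), c("run_id", "role", "replicate_of"))
}

#' Prescribed proportion matrix of a design
#' @param design a `mixture_design`.
#' @return Numeric matrix (runs x taxa) with `run_id` rownames.
#' @export
design_proportions <- function(design) {
  m <- as.matrix(design[, design_taxa(design), drop = FALSE])
  rownames(m) <- design$run_id
  m
}

#' Validate mixture-design invariants
#'
#' Checks that every row lies on the simplex (entries in `[0,1]`, sum 1
#' within 1e-12) and that each replicate's proportions equal its referenced
#' run's exactly.
#'
#' @param design a `mixture_design`.
#' @return The design, invisibly; errors on violation.
#' @export
validate_design <- function(design) {
  m <- design_proportions(design)
  if (any(m < 0 | m > 1))
    stop("design proportions must lie in [0, 1]", call. = FALSE)
  if (any(abs(rowSums(m) - 1) > 1e-12))
    stop("design rows must sum to 1 within 1e-12", call. = FALSE)
  reps <- which(design$role == "replicate")
  for (i in reps) {
    src <- match(design$replicate_of[i], design$run_id)
    if (is.na(src) || !identical(unname(m[i, ]), unname(m[src, ])))
      stop("replicate proportions must equal the referenced run exactly",
           call. = FALSE)
  }
  invisible(design)
}

#' Treatment group of each run
#'
#' Replicate runs share a group with the unique run they copy; all other runs
#' form their own group. Used to average replicates before cross-experiment
#' matching and to compute pure-error summaries.
#'
#' @param design a `mixture_design`.
#' @return Integer vector: for each run, the `run_id` of its unique treatment.
#' @export
treatment_of <- function(design) {
  ifelse(design$role == "replicate", design$replicate_of, design$run_id)
}
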