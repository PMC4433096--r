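#' Scheffe mixture model matrix
#'
#' Expands simplex points into the no-intercept Scheffe basis: the component
#' proportions `x_i`, then the pairwise products `x_i x_j` (i < j) and, for
#' the special cubic model, the triple products `x_i x_j x_k` (i < j < k).
#' There is no intercept column: on the simplex the linear terms already span
#' the constant.
#'
#' @param points numeric matrix (rows on the simplex) or a `mixture_design`.
#' @param order `"linear"`, `"quadratic"` or `"special_cubic"`.
#' @param check validate that rows sum to 1 (within 1e-9)?
#' @return Numeric model matrix; column names are taxon names joined by `:`.
#' @export
scheffe_matrix <- function(points, order = c("special_cubic", "quadratic", "linear"),
                           check = TRUE) {
  order <- match.arg(order)
  if (inherits(points, "mixture_design")) points <- design_proportions(points)
  points <- as.matrix(points)
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  p <- ncol(points)
  nm <- colnames(points)
  if (is.null(nm)) nm <- paste0("x", seq_len(p))
  if (check && any(abs(rowSums(points) - 1) > 1e-9))
    stop("rows must lie on the simplex (sum to 1 within 1e-9)", call. = FALSE)

  X <- points
  colnames(X) <- nm
  if (order %in% c("quadratic", "special_cubic") && p >= 2) {
    pairs <- utils::combn(p, 2)
    B <- matrix(0, nrow(points), ncol(pairs))
    for (k in seq_len(ncol(pairs)))
      B[, k] <- points[, pairs[1, k]] * points[, pairs[2, k]]
    colnames(B) <- apply(pairs, 2, function(ij) paste(nm[ij], collapse = ":"))
    X <- cbind(X, B)
  }
  if (order == "special_cubic" && p >= 3) {
    triples <- utils::combn(p, 3)
    Tm <- matrix(0, nrow(points), ncol(triples))
    for (k in seq_len(ncol(triples)))
      Tm[, k] <- points[, triples[1, k]] * points[, triples[2, k]] *
        points[, triples[3, k]]
    colnames(Tm) <- apply(triples, 2, function(ijk) paste(nm[ijk], collapse = ":"))
    X <- cbind(X, Tm)
  }
  X
}

#' Fit a Scheffe mixture-effect model
#'
#' Ordinary least squares of a response (typically the observed proportion of
#' one taxon) on the Scheffe basis of the prescribed mixture proportions,
#' without intercept. Each linear coefficient `beta_i` is the expected
#' response in the pure blend `x_i = 1`; a positive (negative) blending
#' coefficient `beta_ij` or `beta_ijk` indicates synergistic (antagonistic)
#' departure from linear blending when those components co-occur.
#'
#' @param proportions simplex point matrix or `mixture_design` (the
#'   prescribed mixing ratios).
#' @param y numeric response, one value per row of `proportions`.
#' @param order model order, see [scheffe_matrix()].
#' @param response optional label for the response (e.g. the taxon name).
#' @return An object of class `"scheffe"` with `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `simulate` and `plot` methods.
#'   Coefficient-level inference (SE, t, p) uses the residual degrees of
#'   freedom; for a saturated design these are `NA`. Both the centered
#'   R-squared (about the response mean, reported as `r.squared`) and the
#'   uncentered variant are stored.
#' @export
scheffe <- function(proportions, y, order = "special_cubic", response = NULL) {
  X <- scheffe_matrix(proportions, order = order)
  y <- as.numeric(y)
  if (nrow(X) != length(y))
    stop("length of y must match the number of design rows", call. = FALSE)
  if (nrow(X) < ncol(X))
    stop(sprintf("need at least %d runs to fit %d coefficients",
                 ncol(X), ncol(X)), call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("model matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  n <- nrow(X); k <- ncol(X)
  df <- n - k
  sse <- sum(res^2)
  sst_c <- sum((y - mean(y))^2)
  sst_u <- sum(y^2)
  sigma2 <- if (df > 0) sse / df else NA_real_
  R_unpiv <- qr.R(qx)[, order(qx$pivot), drop = FALSE]
  xtx_inv <- chol2inv(chol(crossprod(R_unpiv[seq_len(k), , drop = FALSE])))
  se <- if (df > 0) sqrt(diag(xtx_inv) * sigma2) else rep(NA_real_, k)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  degree <- lengths(strsplit(colnames(X), ":", fixed = TRUE))

  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    t_stats = stats::setNames(tval, colnames(X)),
    p_values = stats::setNames(pval, colnames(X)),
    degree = stats::setNames(degree, colnames(X)),
    fitted.values = fitted,
    residuals = res,
    sigma = sqrt(sigma2),
    df.residual = df,
    n_obs = n,
    r.squared = if (sst_c > 0) 1 - sse / sst_c else NA_real_,
    r.squared.uncentered = 1 - sse / sst_u,
    order = order,
    taxa = colnames(X)[degree == 1],
    response = response
  ), class = "scheffe")
}

#' @export
print.scheffe <- function(x, ...) {
  cat(sprintf("Scheffe %s mixture model%s: %d components, %d coefficients, %d runs\n",
              gsub("_", " ", x$order),
              if (is.null(x$response)) "" else paste0(" for ", x$response),
              length(x$taxa), length(x$coefficients), x$n_obs))
  cat(sprintf("R-squared: %.4f (uncentered %.4f)\n",
              x$r.squared, x$r.squared.uncentered))
  invisible(x)
}

#' @export
summary.scheffe <- function(object, ...) {
  tab <- data.frame(
    term = names(object$coefficients),
    degree = unname(object$degree),
    estimate = unname(object$coefficients),
    std.error = unname(object$se),
    t.value = unname(object$t_stats),
    p.value = unname(object$p_values),
    stringsAsFactors = FALSE
  )
  out <- list(coefficients = tab, r.squared = object$r.squared,
              r.squared.uncentered = object$r.squared.uncentered,
              sigma = object$sigma, df.residual = object$df.residual,
              response = object$response)
  class(out) <- "summary.scheffe"
  out
}

#' @export
print.summary.scheffe <- function(x, ...) {
  if (!is.null(x$response)) cat("Response:", x$response, "\n")
  print(x$coefficients, digits = 4, row.names = FALSE)
  cat(sprintf("\nResidual SE: %.4g on %d df;  R-squared: %.4f\n",
              x$sigma, x$df.residual, x$r.squared))
  invisible(x)
}

#' @export
coef.scheffe <- function(object, ...) object$coefficients

#' @export
fitted.scheffe <- function(object, ...) object$fitted.values

#' @export
residuals.scheffe <- function(object, ...) object$residuals

#' Predict from a Scheffe mixture model
#' @param object a fitted `scheffe` model.
#' @param newdata simplex point matrix or `mixture_design`; when omitted the
#'   fitted values are returned.
#' @param ... unused.
#' @export
predict.scheffe <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  X <- scheffe_matrix(newdata, order = object$order)
  if (!identical(colnames(X), names(object$coefficients))) {
    # allow permuted column order as long as the taxon set matches
    if (!setequal(colnames(X), names(object$coefficients)))
      stop("newdata components do not match the fitted model", call. = FALSE)
    X <- X[, names(object$coefficients), drop = FALSE]
  }
  drop(X %*% object$coefficients)
}

#' @export
simulate.scheffe <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) { old <- .save_seed(); on.exit(.restore_seed(old)); set.seed(seed) }
  s <- if (is.na(object$sigma)) 0 else object$sigma
  n <- object$n_obs
  as.data.frame(replicate(nsim, object$fitted.values + stats::rnorm(n, 0, s)))
}

#' Fit one Scheffe model per taxon
#'
#' Regresses each taxon's observed proportion on the Scheffe basis of the
#' prescribed design proportions, matching observed samples to design runs by
#' `run_id`.
#'
#' @param observed proportion matrix (samples x taxa) with `run_id` rownames,
#'   e.g. from [adjust_counts()].
#' @param design the `mixture_design` the samples were generated from.
#' @param order model order.
#' @return Named list of `scheffe` fits (class `"scheffe_set"`).
#' @export
fit_scheffe_models <- function(observed, design, order = "special_cubic") {
  prescribed <- design_proportions(design)
  idx <- match(rownames(observed), rownames(prescribed))
  if (anyNA(idx))
    stop("observed samples not matched to design run_ids: ",
         paste(rownames(observed)[is.na(idx)], collapse = ", "), call. = FALSE)
  X <- prescribed[idx, , drop = FALSE]
  taxa <- colnames(X)
  fits <- lapply(taxa, function(tx)
    scheffe(X, observed[, tx], order = order, response = tx))
  names(fits) <- taxa
  structure(fits, class = c("scheffe_set", "list"))
}

#' @export
print.scheffe_set <- function(x, ...) {
  cat(sprintf("Scheffe mixture models for %d taxa\n", length(x)))
  for (tx in names(x))
    cat(sprintf("  %-20s R-squared %.4f\n", tx, x[[tx]]$r.squared))
  invisible(x)
}

#' Screen blending terms for significant synergy or antagonism
#'
#' Bonferroni-adjusts the p-values of the blending terms (pairwise and
#' ternary products; linear terms are not screened) by the number of blending
#' terms in the model, and returns the terms whose adjusted p-value falls
#' below `alpha`, labelled `synergistic` (positive coefficient) or
#' `antagonistic` (negative), ordered by decreasing significance.
#'
#' @param model a fitted `scheffe` model.
#' @param alpha significance level on the adjusted p-values (default 0.05).
#' @param all return all blending terms rather than only significant ones?
#' @return Data frame: `term`, `degree`, `estimate`, `p.value`,
#'   `p.adjusted`, `direction`.
#' @export
screen_blends <- function(model, alpha = 0.05, all = FALSE) {
  blend <- model$degree >= 2
  m <- sum(blend)
  p_raw <- model$p_values[blend]
  p_adj <- pmin(1, p_raw * m)
  out <- data.frame(
    term = names(p_raw),
    degree = unname(model$degree[blend]),
    estimate = unname(model$coefficients[blend]),
    p.value = unname(p_raw),
    p.adjusted = unname(p_adj),
    direction = ifelse(model$coefficients[blend] > 0, "synergistic", "antagonistic"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p.adjusted, out$p.value), , drop = FALSE]
  if (!all) out <- out[!is.na(out$p.adjusted) & out$p.adjusted < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## all compositions of the q remaining components on a step lattice
.simplex_lattice <- function(q, step = 0.05) {
  if (q == 0) return(matrix(numeric(0), 1, 0))
  N <- round(1 / step)
  if (q == 1) return(matrix(1, 1, 1))
  rec <- function(q, N) {
    if (q == 1) return(matrix(N, 1, 1))
    do.call(rbind, lapply(0:N, function(i) cbind(i, rec(q - 1, N - i))))
  }
  rec(q, N) / N
}

#' Blending surface for a pair of components
#'
#' Evaluates the expected observed response over a grid of prescribed
#' proportions `(x_i, x_j)` with `x_i + x_j <= 1`. At interior grid points
#' the remaining components share the remainder `1 - x_i - x_j`; the
#' prediction is averaged uniformly over a simplex lattice (step
#' `lattice_step`) of those components scaled to the remainder. Along the
#' hypotenuse `x_i + x_j = 1` the value is exactly
#' `beta_i x_i + beta_j x_j + beta_ij x_i x_j`.
#'
#' @param model a fitted `scheffe` model.
#' @param i,j component names or indices; must differ.
#' @param grid_resolution points per axis (>= 2).
#' @param lattice_step lattice step for averaging over remaining components.
#' @return Data frame `xi`, `xj`, `value` in long format.
#' @export
blending_surface <- function(model, i, j, grid_resolution = 11L,
                             lattice_step = 0.05) {
  taxa <- model$taxa
  if (is.character(i)) i <- match(i, taxa)
  if (is.character(j)) j <- match(j, taxa)
  if (is.na(i) || is.na(j) || i == j)
    stop("i and j must be two distinct components of the model", call. = FALSE)
  if (grid_resolution < 2)
    stop("grid_resolution must be at least 2", call. = FALSE)
  p <- length(taxa)
  rest <- setdiff(seq_len(p), c(i, j))
  lat <- .simplex_lattice(length(rest), lattice_step)

  ax <- seq(0, 1, length.out = grid_resolution)
  grid <- expand.grid(xi = ax, xj = ax)
  grid <- grid[grid$xi + grid$xj <= 1 + 1e-9, , drop = FALSE]
  vals <- vapply(seq_len(nrow(grid)), function(g) {
    xi <- grid$xi[g]; xj <- grid$xj[g]
    r <- max(0, 1 - xi - xj)
    if (r < 1e-12 || length(rest) == 0) {
      x <- matrix(0, 1, p)
      x[1, i] <- xi; x[1, j] <- xj
      if (length(rest)) x[1, rest[1]] <- r
    } else {
      x <- matrix(0, nrow(lat), p)
      x[, i] <- xi; x[, j] <- xj
      x[, rest] <- lat * r
    }
    colnames(x) <- taxa
    mean(predict(model, x))
  }, numeric(1))
  data.frame(xi = grid$xi, xj = grid$xj, value = vals, row.names = NULL)
}

#' Contour plot of a blending surface
#'
#' @param x a fitted `scheffe` model.
#' @param i,j the component pair to display (names or indices).
#' @param grid_resolution,lattice_step passed to [blending_surface()].
#' @param ... passed to [graphics::filled.contour()].
#' @export
plot.scheffe <- function(x, i = 1L, j = 2L, grid_resolution = 21L,
                         lattice_step = 0.1, ...) {
  surf <- blending_surface(x, i, j, grid_resolution, lattice_step)
  taxa <- x$taxa
  if (is.numeric(i)) i <- taxa[i]
  if (is.numeric(j)) j <- taxa[j]
  ax <- sort(unique(surf$xi))
  z <- matrix(NA_real_, length(ax), length(ax))
  z[cbind(match(surf$xi, ax), match(surf$xj, ax))] <- surf$value
  graphics::filled.contour(ax, ax, z, xlab = paste("prescribed", i),
                           ylab = paste("prescribed", j),
                           main = paste("Expected observed", x$response %||% "response"),
                           ...)
  invisible(surf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
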