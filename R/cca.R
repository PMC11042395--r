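#' Column-standardize a phenotype block
#'
#' Centers and scales every column to mean 0 and sample standard deviation 1
#' (denominator \code{n - 1}), storing the transform so that held-out data can
#' later be standardized with the \emph{training} parameters before weight
#' projection.
#'
#' @param block Numeric matrix or data frame, subjects in rows, variables in
#'   columns. Missing values are rejected.
#' @return Numeric matrix with attributes \code{"center"} and \code{"scale"}.
#' @examples
#' standardize(cbind(a = c(1, 2, 3), b = c(2, 4, 9)))
#' @export
standardize <- function(block) {
  x <- as.matrix(block)
  if (!is.numeric(x)) stop("block must be numeric")
  if (anyNA(x)) stop("block contains missing values; subjects with missing data must be dropped first")
  ctr <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad)) {
    nm <- colnames(x)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("constant column: ", paste(nm, collapse = ", "))
  }
  out <- sweep(sweep(x, 2, ctr, "-"), 2, sds, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- sds
  out
}

## Minimal CCA core shared by the user-facing fit and the hot loops
## (permutation, bootstrap). Inputs must be centered; no validation here.
## ridge > 0 shrinks each block's covariance toward a scaled identity
## (regularized whitening); ridge = 0 is plain CCA.
.cca_core <- function(X, Y, rank_tol = 1e-8, ridge = 0) {
  sx <- svd(X)
  sy <- svd(Y)
  kx <- which(sx$d > rank_tol * sx$d[1])
  ky <- which(sy$d > rank_tol * sy$d[1])
  n <- nrow(X)
  fx <- if (ridge > 0) sx$d[kx] / sqrt(sx$d[kx]^2 + (n - 1) * ridge) else rep(1, length(kx))
  fy <- if (ridge > 0) sy$d[ky] / sqrt(sy$d[ky]^2 + (n - 1) * ridge) else rep(1, length(ky))
  Ux <- sweep(sx$u[, kx, drop = FALSE], 2, fx, "*")
  Uy <- sweep(sy$u[, ky, drop = FALSE], 2, fy, "*")
  sm <- svd(crossprod(Ux, Uy))
  K <- min(length(kx), length(ky))
  ## weights scaled so canonical scores have unit sample variance (ridge = 0)
  gx <- sqrt(n - 1) / sqrt(sx$d[kx]^2 + (n - 1) * ridge)
  gy <- sqrt(n - 1) / sqrt(sy$d[ky]^2 + (n - 1) * ridge)
  wx <- sx$v[, kx, drop = FALSE] %*% (sm$u[, seq_len(K), drop = FALSE] * gx)
  wy <- sy$v[, ky, drop = FALSE] %*% (sm$v[, seq_len(K), drop = FALSE] * gy)
  list(rho = pmin(sm$d[seq_len(K)], 1), wx = wx, wy = wy,
       rank_x = length(kx), rank_y = length(ky), K = K)
}

#' Fit a two-block canonical correlation model
#'
#' Whitens each block through a thin SVD (singular values below
#' \code{rank_tol} times the largest are dropped), then takes the SVD of the
#' cross-product of the whitened bases. Canonical correlations are the
#' singular values of that cross-product; weights are back-transformed and
#' scaled so every canonical score vector has unit sample variance. A
#' deterministic sign convention is applied: each component is flipped so
#' that the sleep variable with the largest absolute structure coefficient
#' loads positively.
#'
#' @param X,Y Standardized blocks (see [standardize()]); same subjects in
#'   rows, \code{nrow > ncol} required for both.
#' @param rank_tol Relative singular-value cutoff for the effective rank.
#' @param ridge Nonnegative covariance-shrinkage constant (regularized
#'   whitening); 0 (the default, intended for the n >> p regime) is plain
#'   CCA.
#' @return Object of class \code{cca_model}: weights per block, canonical
#'   correlations \code{rho}, component count \code{K}, the standardization
#'   parameters carried over from the inputs, and effective ranks.
#' @export
fit_cca <- function(X, Y, rank_tol = 1e-8, ridge = 0) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of subjects")
  if (nrow(X) <= ncol(X) || nrow(Y) <= ncol(Y))
    stop("n must exceed the number of variables in each block; reduce dimensionality first")
  xc <- attr(X, "center"); xs <- attr(X, "scale")
  yc <- attr(Y, "center"); ys <- attr(Y, "scale")
  ## defensive centering: CCA is translation-invariant and the core assumes it
  Xc <- sweep(X, 2, colMeans(X), "-")
  Yc <- sweep(Y, 2, colMeans(Y), "-")
  if (ridge < 0) stop("ridge must be nonnegative")
  core <- .cca_core(Xc, Yc, rank_tol, ridge)
  if (core$rank_x < ncol(X) || core$rank_y < ncol(Y))
    warning("rank deficiency detected; K reduced to ", core$K)
  ## sign convention on the sleep-side structure coefficients
  xscores <- Xc %*% core$wx
  for (k in seq_len(core$K)) {
    ld <- suppressWarnings(stats::cor(Xc, xscores[, k]))
    j <- which.max(abs(ld))
    if (is.finite(ld[j]) && ld[j] < 0) {
      core$wx[, k] <- -core$wx[, k]
      core$wy[, k] <- -core$wy[, k]
    }
  }
  structure(list(
    sleep_weights = core$wx, behavior_weights = core$wy,
    rho = core$rho, K = core$K,
    x_center = xc, x_scale = xs, y_center = yc, y_scale = ys,
    x_names = colnames(X), y_names = colnames(Y),
    rank_x = core$rank_x, rank_y = core$rank_y, n = nrow(X),
    rank_tol = rank_tol
  ), class = "cca_model")
}

#' @export
print.cca_model <- function(x, ...) {
  cat("Two-block CCA model: ", x$K, " components, n = ", x$n, "\n", sep = "")
  cat("Canonical correlations:", paste(sprintf("%.3f", x$rho), collapse = ", "), "\n")
  invisible(x)
}

.check_cols <- function(have, want, block) {
  if (is.null(want) || is.null(have)) return(invisible())
  missing <- setdiff(want, have)
  extra <- setdiff(have, want)
  if (length(missing) || length(extra))
    stop(block, " columns do not match training columns; missing: [",
         paste(missing, collapse = ", "), "], extra: [",
         paste(extra, collapse = ", "), "]")
  invisible()
}

#' Project data onto fitted canonical weights
#'
#' New blocks are standardized with the \emph{training} means and standard
#' deviations stored in the model (when available), then multiplied by the
#' canonical weights. Applied to the training data this reproduces the
#' training scores exactly.
#'
#' @param model A [fit_cca()] model.
#' @param X_new,Y_new Blocks with the training column sets. Either may be
#'   \code{NULL} to skip that side.
#' @return List with \code{sleep_scores} and \code{behavior_scores}
#'   (subjects x K matrices, or NULL).
#' @export
project_scores <- function(model, X_new = NULL, Y_new = NULL) {
  out <- list(sleep_scores = NULL, behavior_scores = NULL)
  proj <- function(dat, ctr, scl, w, nm, block) {
    dat <- as.matrix(dat)
    .check_cols(colnames(dat), nm, block)
    if (!is.null(nm) && !is.null(colnames(dat))) dat <- dat[, nm, drop = FALSE]
    if (!is.null(ctr)) dat <- sweep(sweep(dat, 2, ctr, "-"), 2, scl, "/")
    else dat <- sweep(dat, 2, colMeans(dat), "-")
    dat %*% w
  }
  if (!is.null(X_new))
    out$sleep_scores <- proj(X_new, model$x_center, model$x_scale,
                             model$sleep_weights, model$x_names, "sleep")
  if (!is.null(Y_new))
    out$behavior_scores <- proj(Y_new, model$y_center, model$y_scale,
                                model$behavior_weights, model$y_names, "behavior")
  out
}

#' Canonical structure coefficients (loadings)
#'
#' The loading of a variable on a component is the Pearson correlation
#' between that variable's column and the block's canonical score — the
#' interpretation-friendly alternative to raw weights under
#' multicollinearity.
#'
#' @param block_data Subjects x variables matrix.
#' @param scores Subjects x K canonical score matrix (or vector).
#' @return Variables x K matrix of correlations in \[-1, 1\].
#' @export
structure_loadings <- function(block_data, scores) {
  block_data <- as.matrix(block_data)
  scores <- as.matrix(scores)
  if (nrow(block_data) != nrow(scores)) stop("data and scores must cover the same subjects")
  sds <- apply(block_data, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance column in block data")
  if (any(apply(scores, 2, stats::sd) == 0)) stop("zero-variance canonical score")
  stats::cor(block_data, scores)
}

#' Covariance explained per component
#'
#' The fraction of the total sleep-behavior score covariance carried by each
#' component: \eqn{\sigma_k^2 / \sum_j \sigma_j^2}, where \eqn{\sigma_k} is
#' the sample covariance between the paired canonical scores of component
#' \eqn{k}. Fractions sum to one over all fitted components.
#'
#' @param model A [fit_cca()] model.
#' @param X,Y The training blocks the model was fitted on.
#' @return Numeric vector of fractions, one per component.
#' @export
covariance_explained <- function(model, X, Y) {
  sc <- project_scores(model, X, Y)
  sig <- vapply(seq_len(model$K), function(k)
    stats::cov(sc$sleep_scores[, k], sc$behavior_scores[, k]), numeric(1))
  sig^2 / sum(sig^2)
}

#' Per-subject composite scores
#'
#' By default the average of the paired sleep and behavior canonical scores;
#' the single-block variants substitute one side's scores unchanged (used as
#' a robustness check of the connectivity models).
#'
#' @param sleep_scores,behavior_scores Equal-length vectors or matrices.
#' @param mode \code{"averaged"} (default), \code{"sleep"}, or
#'   \code{"behavior"}.
#' @return Same shape as the inputs.
#' @export
composite_scores <- function(sleep_scores, behavior_scores,
                             mode = c("averaged", "sleep", "behavior")) {
  mode <- match.arg(mode)
  if (length(sleep_scores) != length(behavior_scores))
    stop("score vectors differ in length")
  switch(mode,
         averaged = (sleep_scores + behavior_scores) / 2,
         sleep = sleep_scores,
         behavior = behavior_scores)
}

#' Rank-based inverse-normal (quantile) normalization
#'
#' Replaces each column by Blom scores: \code{qnorm((r - 3/8) / (n + 1/4))}
#' with average ranks for ties. Monotone within column; a fully tied column
#' maps to all zeros.
#'
#' @param block Numeric matrix or data frame.
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(block) {
  x <- as.matrix(block)
  n <- nrow(x)
  apply(x, 2, function(col) {
    r <- rank(col, ties.method = "average")
    stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  })
}
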