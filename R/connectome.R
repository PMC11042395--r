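#' Motion-censoring mask for one fMRI run
#'
#' Frames with framewise displacement above \code{fd_max} (mm) or DVARS
#' above \code{dvars_max} are marked outliers; one frame before and two
#' frames after every outlier are censored as well; any surviving contiguous
#' segment shorter than five frames is censored; and the run is excluded
#' when more than half of its frames end up censored.
#'
#' @param fd Per-frame framewise displacement (mm).
#' @param dvars Per-frame DVARS trace (same length); \code{NULL} disables
#'   the DVARS criterion.
#' @param fd_max,dvars_max Thresholds (defaults 0.2 mm and 75).
#' @param min_segment Minimum length of a kept contiguous segment.
#' @param max_censored_frac Run-exclusion threshold on the censored
#'   fraction.
#' @return Object of class \code{censor_mask}: logical \code{keep},
#'   \code{run_excluded}, thresholds.
#' @export
build_censor_mask <- function(fd, dvars = NULL, fd_max = 0.2, dvars_max = 75,
                              min_segment = 5, max_censored_frac = 0.5) {
  if (!length(fd)) stop("empty motion trace")
  if (is.null(dvars)) dvars <- rep(0, length(fd))
  if (length(dvars) != length(fd)) stop("fd and dvars traces differ in length")
  if (fd_max <= 0 || dvars_max <= 0) stop("thresholds must be positive")
  nf <- length(fd)
  outlier <- fd > fd_max | dvars > dvars_max
  censored <- outlier
  for (i in which(outlier)) {
    lo <- max(1L, i - 1L); hi <- min(nf, i + 2L)
    censored[lo:hi] <- TRUE
  }
  r <- rle(!censored)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (s in seq_along(r$values)) {
    if (r$values[s] && r$lengths[s] < min_segment)
      censored[starts[s]:ends[s]] <- TRUE
  }
  frac <- mean(censored)
  structure(list(keep = !censored, run_excluded = frac > max_censored_frac,
                 censored_frac = frac,
                 thresholds = c(fd_max = fd_max, dvars_max = dvars_max)),
            class = "censor_mask")
}

#' Assemble a Fisher-z RSFC matrix from parcel time series
#'
#' Per non-excluded run, Pearson correlations between parcel time series
#' over the kept (uncensored) frames; correlations are clipped to
#' \eqn{\pm(1 - 10^{-7})} before the Fisher z-transform, and z-matrices are
#' averaged across runs. The diagonal is zeroed.
#'
#' @param runs List of runs, each \code{list(ts = parcels x frames matrix,
#'   mask = censor_mask)}; \code{mask} may be omitted to use all frames.
#' @return Symmetric parcels x parcels matrix with attribute
#'   \code{"runs_used"}.
#' @export
compute_rsfc <- function(runs) {
  keep_run <- vapply(runs, function(r)
    is.null(r$mask) || !r$mask$run_excluded, logical(1))
  if (!any(keep_run))
    stop("all runs excluded by censoring; subject-level exclusion")
  zs <- lapply(runs[keep_run], function(r) {
    keep <- if (is.null(r$mask)) rep(TRUE, ncol(r$ts)) else r$mask$keep
    if (sum(keep) < 3) stop("fewer than 3 kept frames in a run")
    tsk <- t(r$ts[, keep, drop = FALSE])
    if (any(apply(tsk, 2, stats::sd) == 0))
      stop("zero-variance parcel in kept frames")
    cc <- stats::cor(tsk)
    cc <- pmin(pmax(cc, -(1 - 1e-7)), 1 - 1e-7)
    z <- atanh(cc)
    diag(z) <- 0
    z
  })
  out <- Reduce(`+`, zs) / length(zs)
  attr(out, "runs_used") <- length(zs)
  out
}

## upper-triangle (no diagonal) vectorization helpers with a fixed order
.ut_idx <- function(p) which(upper.tri(matrix(0, p, p)))
.ut_vec <- function(m) m[upper.tri(m)]
.ut_mat <- function(v, p) {
  m <- matrix(0, p, p)
  m[upper.tri(m)] <- v
  m + t(m)
}

## Stack a list of symmetric matrices into subjects x edges
.edge_stack <- function(matrices) {
  p <- nrow(matrices[[1]])
  E <- t(vapply(matrices, .ut_vec, numeric(p * (p - 1) / 2)))
  attr(E, "p") <- p
  E
}

#' Regress confounds out of connectivity matrices
#'
#' Per edge, ordinary least squares on an intercept plus the covariate
#' columns; residuals replace the edge values. Collinear covariates trigger
#' a rank warning and a pseudo-inverse fit.
#'
#' @param matrices List of symmetric per-subject matrices.
#' @param covariates Subjects x covariates numeric table (age, sex,
#'   education, ...), complete cases only.
#' @return List of residualized matrices, same shape.
#' @export
residualize_confounds <- function(matrices, covariates) {
  C <- cbind(1, as.matrix(covariates))
  if (anyNA(C)) stop("covariates contain missing values")
  n <- length(matrices)
  if (nrow(C) != n) stop("one covariate row per subject required")
  if (n <= ncol(C)) stop("need more subjects than covariates")
  E <- .edge_stack(matrices)
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    warning("collinear covariates; using pseudo-inverse")
    beta <- .pinv(C) %*% E
    R <- E - C %*% beta
  } else {
    R <- E - C %*% qr.coef(qrC, E)
  }
  p <- attr(E, "p")
  out <- lapply(seq_len(n), function(i) .ut_mat(R[i, ], p))
  names(out) <- names(matrices)
  out
}

## SVD pseudo-inverse; only the collinear fallback uses it.
.pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

## Vectorized simple regression of each response column on one predictor.
.simple_glm <- function(Ymat, x) {
  n <- length(x)
  if (stats::sd(x) == 0) stop("constant predictor (composite score)")
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  Yc <- sweep(Ymat, 2, colMeans(Ymat), "-")
  beta <- as.numeric(crossprod(xc, Yc)) / sxx
  res <- Yc - outer(xc, beta)
  df <- n - 2
  rss <- colSums(res^2)
  exact <- rss < 1e-24 * pmax(colSums(Yc^2), 1)
  se <- sqrt(rss / df / sxx)
  tstat <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf))
  fstat <- tstat^2
  pval <- 2 * stats::pt(-abs(tstat), df)
  pval[exact & beta != 0] <- 0
  data.frame(beta = beta, t = tstat, f = fstat, p = pval,
             exact_fit = exact, stringsAsFactors = FALSE)
}

#' Edge-wise linear models of connectivity on a composite score
#'
#' For every parcel pair, fits \code{edge ~ intercept + score} and reports
#' the slope, its T statistic, the model F (= T squared for one predictor),
#' the p-value of the no-effect hypothesis, and BH q-values across edges.
#' Betas are returned unthresholded. Edges fit exactly (zero residual
#' variance) are flagged and given p = 0.
#'
#' @param matrices List of symmetric per-subject matrices (residualize
#'   confounds first).
#' @param composite One composite score per subject.
#' @return Object of class \code{edge_glm}: tidy table (i, j, beta, t, f,
#'   p, q) plus the beta matrix.
#' @export
edgewise_glm <- function(matrices, composite) {
  if (length(matrices) != length(composite))
    stop("one composite score per subject required")
  E <- .edge_stack(matrices)
  p <- attr(E, "p")
  res <- .simple_glm(E, composite)
  res$q <- fdr_bh(res$p)$q_values
  ij <- arrayInd(.ut_idx(p), c(p, p))
  tab <- cbind(data.frame(i = ij[, 1], j = ij[, 2]), res)
  structure(list(table = tab, beta_matrix = .ut_mat(res$beta, p),
                 n = length(composite), df = length(composite) - 2),
            class = "edge_glm")
}

#' Average a parcel-level matrix into network blocks
#'
#' Off-diagonal network pair (A, B): mean over all parcel pairs a in A, b in
#' B. Diagonal block (A, A): mean over unique unordered within-network
#' pairs, excluding self-pairs; a single-parcel network gets \code{NA}
#' within. Output is symmetric with network labels.
#'
#' @param matrix_ Symmetric parcels x parcels matrix.
#' @param map Character vector of network labels, one per parcel.
#' @return Networks x networks symmetric matrix.
#' @export
network_average <- function(matrix_, map) {
  p <- nrow(matrix_)
  if (length(map) != p) stop("map must cover all parcels")
  nets <- sort(unique(map))
  M <- length(nets)
  out <- matrix(NA_real_, M, M, dimnames = list(nets, nets))
  idx <- split(seq_len(p), map)
  for (a in seq_len(M)) {
    ia <- idx[[nets[a]]]
    if (length(ia) > 1) {
      blk <- matrix_[ia, ia]
      out[a, a] <- mean(blk[upper.tri(blk)])
    }
    if (a < M) for (b in (a + 1):M) {
      ib <- idx[[nets[b]]]
      out[a, b] <- out[b, a] <- mean(matrix_[ia, ib])
    }
  }
  out
}

#' Network-wise linear models with FDR correction
#'
#' Each subject's matrix is first averaged into network blocks, then a
#' linear model \code{network edge ~ intercept + score} is fitted per unique
#' network pair (including diagonal blocks: M(M+1)/2 tests for M networks),
#' with BH-FDR across those tests and thresholded betas (beta where
#' q <= level, else 0).
#'
#' @param matrices List of per-subject symmetric parcel matrices.
#' @param composite One score per subject.
#' @param map Parcel-to-network labels.
#' @param q FDR level (default 0.05).
#' @return Object of class \code{network_glm}: tidy table, full and
#'   thresholded beta matrices.
#' @export
networkwise_glm <- function(matrices, composite, map, q = 0.05) {
  if (length(matrices) != length(composite))
    stop("one composite score per subject required")
  netmats <- lapply(matrices, network_average, map = map)
  nets <- rownames(netmats[[1]])
  M <- length(nets)
  keepcell <- which(upper.tri(netmats[[1]], diag = TRUE) &
                      !is.na(netmats[[1]]))
  V <- t(vapply(netmats, function(m) m[keepcell], numeric(length(keepcell))))
  res <- .simple_glm(V, composite)
  bh <- fdr_bh(res$p, q)
  res$q <- bh$q_values
  res$sig <- bh$reject
  ij <- arrayInd(keepcell, c(M, M))
  tab <- cbind(data.frame(net_i = nets[ij[, 1]], net_j = nets[ij[, 2]],
                          stringsAsFactors = FALSE), res)
  bmat <- matrix(NA_real_, M, M, dimnames = list(nets, nets))
  tmat <- matrix(0, M, M, dimnames = list(nets, nets))
  for (r in seq_along(keepcell)) {
    i <- ij[r, 1]; j <- ij[r, 2]
    bmat[i, j] <- bmat[j, i] <- res$beta[r]
    tmat[i, j] <- tmat[j, i] <- if (res$sig[r]) res$beta[r] else 0
  }
  structure(list(table = tab, beta_matrix = bmat,
                 thresholded_beta = tmat, n_tests = length(keepcell),
                 q_level = q),
            class = "network_glm")
}
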