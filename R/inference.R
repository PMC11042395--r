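#' Build exchangeability blocks from a family table
#'
#' Encodes the two levels of admissible shuffling in a related-subjects
#' design: within a family, members sharing a zygosity role (MZ with MZ, DZ
#' with DZ, non-twin siblings with each other) may swap; and whole families
#' whose role multisets are identical may be exchanged as units. Singletons
#' form one big exchange class of size-1 families.
#'
#' @param families Data frame with \code{subject_id}, \code{family_id},
#'   \code{role}.
#' @param scheme \code{"palm"} (default): two-level within-family /
#'   whole-family scheme. \code{"role_stratified"}: the literal reading in
#'   which subjects are freely permuted within role strata across the whole
#'   sample, ignoring family boundaries.
#' @return Object of class \code{exch_blocks}.
#' @export
build_blocks <- function(families, scheme = c("palm", "role_stratified")) {
  scheme <- match.arg(scheme)
  if (anyDuplicated(families$subject_id))
    stop("duplicate subject_id in family table")
  n <- nrow(families)
  if (scheme == "role_stratified") {
    groups <- unname(split(seq_len(n), families$role))
    return(structure(list(
      n = n, family_ids = unique(families$family_id),
      slots = list(), signatures = character(0),
      within_groups = groups[vapply(groups, length, 1L) > 1],
      classes = list(), scheme = scheme
    ), class = "exch_blocks"))
  }
  fam_ids <- unique(families$family_id)
  slots <- vector("list", length(fam_ids))
  signatures <- character(length(fam_ids))
  within_groups <- list()
  for (f in seq_along(fam_ids)) {
    idx <- which(families$family_id == fam_ids[f])
    roles <- families$role[idx]
    ord <- order(roles, idx)       # canonical slot order: role, then position
    slots[[f]] <- idx[ord]
    signatures[f] <- paste(roles[ord], collapse = "+")
    for (g in split(idx, roles)) {
      if (length(g) > 1) within_groups[[length(within_groups) + 1L]] <- g
    }
  }
  classes <- split(seq_along(fam_ids), signatures)
  structure(list(
    n = n, family_ids = fam_ids, slots = slots, signatures = signatures,
    within_groups = within_groups,
    classes = classes[vapply(classes, length, 1L) > 1],
    scheme = scheme
  ), class = "exch_blocks")
}

#' Draw one admissible restricted permutation
#'
#' Composes independent uniform within-group shuffles (same-role family
#' members) with uniform whole-family exchanges inside each
#' identical-signature class; every admissible permutation of the restricted
#' group has equal probability, including the identity. Uses R's current RNG
#' stream.
#'
#' @param blocks An [build_blocks()] object.
#' @return Integer index vector \code{perm} such that \code{Y[perm, ]}
#'   applies the permutation.
#' @export
draw_permutation <- function(blocks) {
  n <- blocks$n
  p1 <- seq_len(n)
  for (g in blocks$within_groups) p1[g] <- g[sample.int(length(g))]
  p2 <- seq_len(n)
  for (cl in blocks$classes) {
    ord <- sample.int(length(cl))
    for (j in seq_along(cl)) p2[blocks$slots[[cl[j]]]] <- blocks$slots[[cl[ord[j]]]]
  }
  p1[p2]
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up q-values plus the rejection mask at level \code{q}.
#'
#' @param pvals P-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return List with \code{q_values} and logical \code{reject}.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(list(q_values = numeric(0), reject = logical(0)))
  qv <- stats::p.adjust(pvals, method = "BH")
  list(q_values = qv, reject = qv <= q)
}

#' Permutation test of canonical correlations with family structure
#'
#' Refits the CCA after permuting the behavior block's rows by an admissible
#' restricted permutation, recording component k's null statistic as the
#' k-th canonical correlation of the refit (the null is therefore not
#' centered at zero). P-values use the add-one Monte-Carlo convention
#' \eqn{(1 + b) / (1 + B)}; q-values are Benjamini-Hochberg across
#' components.
#'
#' @param X,Y Standardized blocks.
#' @param blocks Exchangeability blocks for the same subjects.
#' @param n_perm Number of permutations (>= 99 recommended; >= 1 required).
#' @param seed Integer seed.
#' @param rank_tol Passed to the CCA core.
#' @return Object of class \code{cca_perm}: observed \code{rho}, the
#'   \code{n_perm x K} null matrix, \code{perm_p}, \code{perm_q}.
#' @export
permutation_test <- function(X, Y, blocks, n_perm = 10000, seed = 1,
                             rank_tol = 1e-8) {
  if (n_perm < 1) stop("n_perm must be a positive count")
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != blocks$n || nrow(Y) != blocks$n)
    stop("blocks do not cover the data's subjects")
  Xc <- sweep(X, 2, colMeans(X), "-")
  Yc <- sweep(Y, 2, colMeans(Y), "-")
  sx <- svd(Xc); sy <- svd(Yc)
  kx <- which(sx$d > rank_tol * sx$d[1])
  ky <- which(sy$d > rank_tol * sy$d[1])
  Ux <- sx$u[, kx, drop = FALSE]
  Uy <- sy$u[, ky, drop = FALSE]
  K <- min(length(kx), length(ky))
  obs <- pmin(svd(crossprod(Ux, Uy), nu = 0, nv = 0)$d[seq_len(K)], 1)
  set.seed(seed)
  null <- matrix(0, n_perm, K)
  tUx <- t(Ux)
  for (b in seq_len(n_perm)) {
    perm <- draw_permutation(blocks)
    null[b, ] <- svd(tUx %*% Uy[perm, , drop = FALSE], nu = 0, nv = 0)$d[seq_len(K)]
  }
  p <- vapply(seq_len(K), function(k) (1 + sum(null[, k] >= obs[k])) / (1 + n_perm),
              numeric(1))
  bh <- fdr_bh(p)
  structure(list(rho = obs, null = null, perm_p = p, perm_q = bh$q_values,
                 n_perm = n_perm, seed = seed, K = K),
            class = "cca_perm")
}

## Greedy alignment of replicate components to the reference by maximal
## absolute correlation of stacked weight vectors; returns match + sign.
.match_components <- function(ref_w, rep_w) {
  K <- ncol(ref_w); Kb <- ncol(rep_w)
  C <- suppressWarnings(stats::cor(ref_w, rep_w))
  C[!is.finite(C)] <- 0
  assign <- integer(K); sgn <- numeric(K)
  A <- abs(C)
  for (step in seq_len(min(K, Kb))) {
    ij <- arrayInd(which.max(A), dim(A))
    i <- ij[1]; j <- ij[2]
    assign[i] <- j
    sgn[i] <- sign(C[i, j])
    A[i, ] <- -Inf; A[, j] <- -Inf
  }
  sgn[sgn == 0] <- 1
  list(assign = assign, sign = sgn)
}

#' Bootstrap stability of canonical structure coefficients
#'
#' Resamples subjects with replacement (optionally whole families), refits
#' the CCA per replicate, aligns replicate components to the original fit by
#' maximal absolute weight-vector correlation (with sign flips so the match
#' is positive), and recomputes structure coefficients. Reports per-loading
#' bootstrap mean, standard deviation, normal confidence interval,
#' z = mean/sd, two-sided normal p, and Benjamini-Hochberg q within each
#' component-by-block family of loadings.
#'
#' @param X,Y Blocks (raw or standardized; replicates are re-standardized).
#' @param families Family table; required when \code{resample = "families"}.
#' @param n_boot Number of bootstrap replicates (>= 100 recommended).
#' @param seed Integer seed.
#' @param resample \code{"subjects"} (default, resample individuals) or
#'   \code{"families"} (resample whole families).
#' @param conf Confidence level for the normal intervals (default 0.95).
#' @param q FDR level for the significance mask.
#' @param rank_tol Passed to the CCA core.
#' @return Object of class \code{cca_bootstrap} with per-block loading
#'   tables and alignment diagnostics.
#' @export
bootstrap_loadings <- function(X, Y, families = NULL, n_boot = 1000, seed = 1,
                               resample = c("subjects", "families"),
                               conf = 0.95, q = 0.05, rank_tol = 1e-8) {
  resample <- match.arg(resample)
  if (n_boot < 2) stop("n_boot must be at least 2")
  if (resample == "families" && is.null(families))
    stop("family-level resampling requires a family table")
  X <- standardize(as.matrix(X))
  Y <- standardize(as.matrix(Y))
  n <- nrow(X)
  model <- fit_cca(X, Y, rank_tol = rank_tol)
  K <- model$K
  ref_w <- rbind(model$sleep_weights, model$behavior_weights)
  p <- ncol(X); qv <- ncol(Y)
  sum_s <- sq_s <- matrix(0, p, K)
  sum_b <- sq_b <- matrix(0, qv, K)
  set.seed(seed)
  redraws <- 0L; flips <- 0L; nonidentity <- 0L
  done <- 0L; tries <- 0L
  fam_members <- if (!is.null(families)) split(seq_len(n), families$family_id)
  while (done < n_boot) {
    tries <- tries + 1L
    if (tries > 20L * n_boot)
      stop("too many degenerate bootstrap replicates; check the data")
    idx <- if (resample == "subjects") {
      sample.int(n, n, replace = TRUE)
    } else {
      unlist(fam_members[sample.int(length(fam_members), length(fam_members),
                                    replace = TRUE)], use.names = FALSE)
    }
    Xb <- X[idx, , drop = FALSE]
    Yb <- Y[idx, , drop = FALSE]
    sdx <- apply(Xb, 2, stats::sd); sdy <- apply(Yb, 2, stats::sd)
    if (any(sdx == 0) || any(sdy == 0)) { redraws <- redraws + 1L; next }
    Xb <- sweep(sweep(Xb, 2, colMeans(Xb), "-"), 2, sdx, "/")
    Yb <- sweep(sweep(Yb, 2, colMeans(Yb), "-"), 2, sdy, "/")
    core <- .cca_core(Xb, Yb, rank_tol)
    if (core$K < K) { redraws <- redraws + 1L; next }
    mt <- .match_components(ref_w, rbind(core$wx, core$wy))
    wx <- core$wx[, mt$assign, drop = FALSE]
    wy <- core$wy[, mt$assign, drop = FALSE]
    wx <- sweep(wx, 2, mt$sign, "*")
    wy <- sweep(wy, 2, mt$sign, "*")
    flips <- flips + sum(mt$sign < 0)
    nonidentity <- nonidentity + as.integer(!identical(mt$assign, seq_len(K)))
    ls <- stats::cor(Xb, Xb %*% wx)
    lb <- stats::cor(Yb, Yb %*% wy)
    sum_s <- sum_s + ls; sq_s <- sq_s + ls^2
    sum_b <- sum_b + lb; sq_b <- sq_b + lb^2
    done <- done + 1L
  }
  zcrit <- stats::qnorm(1 - (1 - conf) / 2)
  summarize <- function(s, sq, orig, vars) {
    m <- s / n_boot
    sd <- sqrt(pmax(sq - n_boot * m^2, 0) / (n_boot - 1))
    out <- do.call(rbind, lapply(seq_len(K), function(k) {
      z <- ifelse(sd[, k] > 0, m[, k] / sd[, k], 0)
      pv <- 2 * stats::pnorm(-abs(z))
      pv[sd[, k] == 0 & m[, k] != 0] <- 0
      bh <- fdr_bh(pv, q)
      data.frame(variable = vars, component = k,
                 loading = orig[, k], boot_mean = m[, k], boot_sd = sd[, k],
                 ci_lo = m[, k] - zcrit * sd[, k],
                 ci_hi = m[, k] + zcrit * sd[, k],
                 z = z, p = pv, q = bh$q_values, sig = bh$reject,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  }
  ## X, Y are standardized here, so the training scores are direct products
  orig_s <- stats::cor(X, X %*% model$sleep_weights)
  orig_b <- stats::cor(Y, Y %*% model$behavior_weights)
  vs <- colnames(X); if (is.null(vs)) vs <- paste0("x", seq_len(p))
  vb <- colnames(Y); if (is.null(vb)) vb <- paste0("y", seq_len(qv))
  structure(list(
    sleep = summarize(sum_s, sq_s, orig_s, vs),
    behavior = summarize(sum_b, sq_b, orig_b, vb),
    n_boot = n_boot, seed = seed, resample = resample, conf = conf,
    diagnostics = list(redraws = redraws, sign_flips = flips,
                       nonidentity_matches = nonidentity)
  ), class = "cca_bootstrap")
}

#' Assign families to cross-validation folds
#'
#' Families are shuffled with a seeded generator and dealt round-robin, so
#' all members of a family land in one fold and fold sizes (in families)
#' differ by at most one.
#'
#' @param families Family table.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector: fold index per subject (row of \code{families}).
#' @export
make_folds <- function(families, k, seed = 1) {
  set.seed(seed)
  fams <- unique(families$family_id)
  if (length(fams) < k) stop("fewer families than folds")
  fold_of_fam <- integer(length(fams))
  fold_of_fam[sample.int(length(fams))] <- rep_len(seq_len(k), length(fams))
  names(fold_of_fam) <- fams
  unname(fold_of_fam[families$family_id])
}

#' Family-aware k-fold cross-validation of a CCA
#'
#' Families are shuffled with a seeded generator and dealt round-robin into
#' folds, so no family ever spans folds. Per fold, a CCA is trained on the
#' remaining data, the held-out blocks are standardized with the training
#' means/sds and projected through the training weights, and the per-
#' component correlation between projected sleep and behavior scores is
#' recorded. Significance of the fold-mean correlation uses admissible
#' restricted permutations of each fold's test pairings.
#'
#' @param X,Y Blocks (raw scale; training folds are standardized
#'   internally).
#' @param families Family table aligned to the rows.
#' @param k Number of folds (default 5).
#' @param n_perm Permutations for the test-correlation null (default 999).
#' @param seed Integer seed.
#' @param rank_tol Passed to the CCA core.
#' @return Object of class \code{cca_crossval}: per-fold correlations,
#'   fold-mean per component, permutation p-values, fold assignment.
#' @export
crossval <- function(X, Y, families, k = 5, n_perm = 999, seed = 1,
                     rank_tol = 1e-8) {
  if (k < 2) stop("k must be >= 2")
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  stopifnot(nrow(families) == n)
  fold <- make_folds(families, k, seed)
  set.seed(seed + 1L)
  Kmax <- min(ncol(X), ncol(Y))
  xs_list <- ys_list <- blocks_list <- vector("list", k)
  fold_r <- matrix(NA_real_, k, Kmax)
  for (j in seq_len(k)) {
    test <- which(fold == j); train <- which(fold != j)
    if (length(test) <= Kmax)
      stop("fold ", j, " has fewer subjects than components")
    Xtr <- standardize(X[train, , drop = FALSE])
    Ytr <- standardize(Y[train, , drop = FALSE])
    model <- fit_cca(Xtr, Ytr, rank_tol = rank_tol)
    sc <- project_scores(model, X[test, , drop = FALSE], Y[test, , drop = FALSE])
    kk <- min(model$K, Kmax)
    fold_r[j, seq_len(kk)] <- vapply(seq_len(kk), function(m)
      stats::cor(sc$sleep_scores[, m], sc$behavior_scores[, m]), numeric(1))
    xs_list[[j]] <- sc$sleep_scores
    ys_list[[j]] <- sc$behavior_scores
    blocks_list[[j]] <- build_blocks(families[test, , drop = FALSE])
  }
  mean_r <- colMeans(fold_r)
  null <- matrix(0, n_perm, Kmax)
  for (b in seq_len(n_perm)) {
    acc <- matrix(0, k, Kmax)
    for (j in seq_len(k)) {
      perm <- draw_permutation(blocks_list[[j]])
      yp <- ys_list[[j]][perm, , drop = FALSE]
      acc[j, ] <- vapply(seq_len(Kmax), function(m)
        stats::cor(xs_list[[j]][, m], yp[, m]), numeric(1))
    }
    null[b, ] <- colMeans(acc)
  }
  perm_p <- vapply(seq_len(Kmax), function(m)
    (1 + sum(null[, m] >= mean_r[m])) / (1 + n_perm), numeric(1))
  structure(list(fold_r = fold_r, mean_r = mean_r, perm_p = perm_p,
                 fold = unname(fold), k = k, n_perm = n_perm, seed = seed),
            class = "cca_crossval")
}
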