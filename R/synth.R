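## Family type catalog used by the generator. Sizes stay within 1-3 subjects
## (real twin cohorts rarely contribute more than a handful per household).
.family_types <- list(
  singleton = "SINGLETON",
  mz_pair   = c("MZ", "MZ"),
  dz_pair   = c("DZ", "DZ"),
  sib_pair  = c("SIB", "SIB"),
  mz_sib    = c("MZ", "MZ", "SIB"),
  dz_sib    = c("DZ", "DZ", "SIB"),
  sib_trio  = c("SIB", "SIB", "SIB")
)

#' Family-composition mix resembling a young-adult twin cohort
#'
#' Proportions over family types (each type a fixed multiset of roles) used
#' by [make_family_structure()]: a blend of singletons, monozygotic and
#' dizygotic twin pairs, non-twin sibling pairs/trios, and twin-plus-sibling
#' households.
#'
#' @return Named numeric vector of proportions summing to 1.
#' @export
twin_cohort_mix <- function() {
  c(singleton = 0.20, mz_pair = 0.15, dz_pair = 0.10, sib_pair = 0.30,
    mz_sib = 0.05, dz_sib = 0.05, sib_trio = 0.15)
}

#' Generate a family/zygosity table
#'
#' Partitions \code{n_subjects} into families by repeatedly sampling family
#' types from \code{family_mix} until all subjects are assigned; if the
#' remaining head count is smaller than every sampled type, singletons fill
#' the tail. Deterministic for a fixed seed.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param family_mix Named proportions over the family-type catalog
#'   (\code{singleton}, \code{mz_pair}, \code{dz_pair}, \code{sib_pair},
#'   \code{mz_sib}, \code{dz_sib}, \code{sib_trio}); must sum to 1.
#' @param seed Integer seed.
#' @return Data frame \code{subject_id}, \code{family_id}, \code{role}
#'   (MZ/DZ/SIB/SINGLETON), one row per subject.
#' @export
make_family_structure <- function(n_subjects, family_mix = twin_cohort_mix(),
                                  seed = 1) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (is.null(names(family_mix)) || !all(names(family_mix) %in% names(.family_types)))
    stop("family_mix names must be drawn from: ",
         paste(names(.family_types), collapse = ", "))
  if (any(family_mix < 0) || abs(sum(family_mix) - 1) > 1e-8)
    stop("family_mix proportions must be nonnegative and sum to 1")
  set.seed(seed)
  sizes <- vapply(.family_types[names(family_mix)], length, integer(1))
  roles <- character(0); fam <- character(0)
  remaining <- n_subjects; f <- 0L
  while (remaining > 0) {
    ok <- family_mix > 0 & sizes <= remaining
    f <- f + 1L
    if (!any(ok)) {
      type <- "singleton"
    } else {
      type <- sample(names(family_mix)[ok], 1, prob = family_mix[ok])
    }
    r <- .family_types[[type]]
    roles <- c(roles, r)
    fam <- c(fam, rep(sprintf("fam%04d", f), length(r)))
    remaining <- remaining - length(r)
  }
  data.frame(
    subject_id = sprintf("sub%04d", seq_len(n_subjects)),
    family_id = fam,
    role = roles,
    stringsAsFactors = FALSE
  )
}

.default_patterns <- function(p, K, supports = NULL) {
  ## disjoint contiguous supports with alternating signs; columns orthogonal
  pat <- matrix(0, p, K)
  if (is.null(supports)) {
    width <- max(1L, p %/% K)
    start <- 1L
    for (k in seq_len(K)) {
      idx <- start:min(p, start + width - 1L)
      pat[idx, k] <- rep_len(c(1, 1, -1), length(idx))
      start <- start + width
    }
  } else {
    for (k in seq_len(K)) pat[supports[[k]], k] <- rep_len(c(1, 1, -1), length(supports[[k]]))
  }
  pat
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the generator: cohort size and family mix, block
#' widths, the planted canonical correlations and sparse sign loading
#' patterns, role-specific intra-class correlations, and the connectome
#' dimensions/effects.
#'
#' @param n_subjects Cohort size.
#' @param family_mix See [make_family_structure()].
#' @param p_sleep,p_behavior Block widths (defaults 7 and 20).
#' @param planted_rho Target canonical correlations, strictly descending
#'   where nonzero, values in \[0, 1\].
#' @param loading_patterns Optional list with \code{sleep} (p_sleep x K) and
#'   \code{behavior} (p_behavior x K) sign-pattern matrices; columns must be
#'   mutually orthogonal. Defaults to disjoint contiguous supports.
#' @param family_icc Named intra-class correlations per role
#'   (\code{MZ >= DZ >= SIB >= 0}, all in \[0, 1)).
#' @param n_parcels Parcel count for synthetic connectomes.
#' @param network_map Optional character vector (length \code{n_parcels}) of
#'   network labels; defaults to seven cortical networks plus a subcortical
#'   group, dealt round-robin.
#' @param edge_effects List of planted connectivity effects, each
#'   \code{list(a = <network>, b = <network>, slope = <real>)}.
#' @param noise_sd Edge noise standard deviation for the connectome
#'   generator.
#' @param ordinal_sleep If TRUE, sleep columns are discretized to ordinal
#'   0-3 codes at quartile cutpoints after generation (off by default).
#' @param seed Integer seed.
#' @return Object of class \code{synth_config}.
#' @export
synth_config <- function(n_subjects = 500,
                         family_mix = twin_cohort_mix(),
                         p_sleep = 7, p_behavior = 20,
                         planted_rho = c(0.7, 0.4, 0.1),
                         loading_patterns = NULL,
                         family_icc = c(MZ = 0.5, DZ = 0.3, SIB = 0.2, SINGLETON = 0),
                         n_parcels = 50,
                         network_map = NULL,
                         edge_effects = list(),
                         noise_sd = 1,
                         ordinal_sleep = FALSE,
                         seed = 1) {
  K <- length(planted_rho)
  if (any(planted_rho < 0) || any(planted_rho > 1))
    stop("planted_rho values must lie in [0, 1]")
  nz <- planted_rho[planted_rho > 0]
  if (length(nz) > 1 && any(diff(nz) >= 0))
    stop("planted_rho must be strictly descending where nonzero")
  if (K > min(p_sleep, p_behavior))
    stop("length(planted_rho) must not exceed min(p_sleep, p_behavior)")
  if (any(family_icc < 0) || any(family_icc >= 1))
    stop("family_icc values must lie in [0, 1)")
  if (is.null(loading_patterns))
    loading_patterns <- list(sleep = .default_patterns(p_sleep, K),
                             behavior = .default_patterns(p_behavior, K))
  stopifnot(nrow(loading_patterns$sleep) == p_sleep,
            nrow(loading_patterns$behavior) == p_behavior)
  if (is.null(network_map)) {
    nets <- c(paste0("Net", 1:7), "Subcortical")
    network_map <- rep_len(nets, n_parcels)
  }
  if (length(network_map) != n_parcels)
    stop("network_map must assign every parcel")
  structure(list(
    n_subjects = n_subjects, family_mix = family_mix,
    p_sleep = p_sleep, p_behavior = p_behavior,
    planted_rho = planted_rho, loading_patterns = loading_patterns,
    family_icc = family_icc, n_parcels = n_parcels,
    network_map = network_map, edge_effects = edge_effects,
    noise_sd = noise_sd, ordinal_sleep = ordinal_sleep, seed = seed
  ), class = "synth_config")
}

## Orthonormalize pattern columns (unit norm; QR fallback for non-disjoint
## supports keeps the column span and leading signs).
.orthonormal_patterns <- function(pat) {
  g <- crossprod(pat)
  offdiag <- g - diag(diag(g), nrow(g))
  if (max(abs(offdiag)) < 1e-12) {
    sweep(pat, 2, sqrt(diag(g)), "/")
  } else {
    q <- qr.Q(qr(pat))
    ## keep orientation of the original columns
    for (k in seq_len(ncol(pat))) if (sum(q[, k] * pat[, k]) < 0) q[, k] <- -q[, k]
    q
  }
}

#' Simulate the paired sleep and behavior blocks
#'
#' Rows are drawn from a joint Gaussian whose within-block covariances are
#' identity and whose cross-block covariance is \code{A diag(rho) B'} for
#' orthonormalized sparse patterns \code{A}, \code{B} — so the population
#' canonical correlations equal \code{planted_rho} exactly and the
#' population structure coefficients equal the pattern columns. Family
#' dependence is induced by icc-weighted mixing of a family-level and an
#' individual-level draw of the same law, giving role-dependent intra-class
#' correlation without creating any extra cross-block signal.
#'
#' @param config A [synth_config()].
#' @param families A family table from [make_family_structure()] covering
#'   \code{config$n_subjects} subjects.
#' @param seed Seed; defaults to \code{config$seed}.
#' @return List with standardized matrices \code{X} (sleep) and \code{Y}
#'   (behavior), row names = subject ids.
#' @export
simulate_two_block <- function(config, families, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_subjects
  if (nrow(families) != n) stop("families must cover all subjects")
  p <- config$p_sleep; q <- config$p_behavior
  K <- length(config$planted_rho)
  A <- .orthonormal_patterns(config$loading_patterns$sleep)
  B <- .orthonormal_patterns(config$loading_patterns$behavior)
  Sxy <- A %*% (config$planted_rho * t(B))
  Sigma <- rbind(cbind(diag(p), Sxy), cbind(t(Sxy), diag(q)))
  es <- eigen(Sigma, symmetric = TRUE)
  half <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
  set.seed(seed)
  d <- p + q
  icc <- config$family_icc[families$role]
  icc[is.na(icc)] <- 0
  Z <- matrix(0, n, d)
  for (fid in unique(families$family_id)) {
    idx <- which(families$family_id == fid)
    g <- stats::rnorm(d)
    for (i in idx) {
      e <- stats::rnorm(d)
      Z[i, ] <- sqrt(icc[i]) * g + sqrt(1 - icc[i]) * e
    }
  }
  Z <- Z %*% half
  X <- Z[, seq_len(p), drop = FALSE]
  Y <- Z[, p + seq_len(q), drop = FALSE]
  colnames(X) <- paste0("sleep_", seq_len(p))
  colnames(Y) <- paste0("beh_", seq_len(q))
  rownames(X) <- rownames(Y) <- families$subject_id
  if (config$ordinal_sleep) {
    cuts <- stats::qnorm(c(0.25, 0.5, 0.75))
    X <- apply(X, 2, function(col) findInterval(col, cuts))
    rownames(X) <- families$subject_id
  } else {
    X <- standardize(X)
  }
  Y <- standardize(Y)
  list(X = X, Y = Y)
}

#' Simulate per-subject connectivity matrices with planted effects
#'
#' Each subject's symmetric zero-diagonal matrix is a sum of planted
#' network-block effects — every edge between networks \code{a} and \code{b}
#' gets \code{slope * composite_score} — plus symmetric Gaussian edge noise
#' with standard deviation \code{noise_sd}.
#'
#' @param config A [synth_config()] (supplies \code{n_parcels},
#'   \code{network_map}, \code{edge_effects}, \code{noise_sd}).
#' @param composite_scores One score per subject.
#' @param seed Seed; defaults to \code{config$seed + 1}.
#' @return Named list of parcels x parcels matrices.
#' @export
simulate_connectomes <- function(config, composite_scores,
                                 seed = config$seed + 1L) {
  stopifnot(inherits(config, "synth_config"))
  P <- config$n_parcels
  map <- config$network_map
  for (ef in config$edge_effects) {
    if (!all(c(ef$a, ef$b) %in% map))
      stop("edge effect names a network absent from network_map: ",
           ef$a, "-", ef$b)
  }
  set.seed(seed)
  n <- length(composite_scores)
  ids <- names(composite_scores)
  if (is.null(ids)) ids <- sprintf("sub%04d", seq_len(n))
  base <- matrix(0, P, P)
  masks <- lapply(config$edge_effects, function(ef) {
    ia <- map == ef$a; ib <- map == ef$b
    m <- outer(ia, ib) | outer(ib, ia)
    diag(m) <- FALSE
    m
  })
  ut <- upper.tri(base)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    M <- base
    for (j in seq_along(masks))
      M[masks[[j]]] <- M[masks[[j]]] + config$edge_effects[[j]]$slope * composite_scores[i]
    if (config$noise_sd > 0) {
      E <- matrix(0, P, P)
      E[ut] <- stats::rnorm(sum(ut), sd = config$noise_sd)
      M <- M + E + t(E)
    }
    diag(M) <- 0
    out[[i]] <- M
  }
  names(out) <- ids
  out
}
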