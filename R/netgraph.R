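#' Normalize a weighted connection matrix
#'
#' Divides by the largest absolute weight so entries lie in \[-1, 1\]. A
#' zero matrix is returned unchanged with a warning; asymmetric input (above
#' tolerance 1e-8) is an error.
#'
#' @param W Symmetric numeric matrix.
#' @return Normalized matrix.
#' @export
normalize_weights <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W) || max(abs(W - t(W))) > 1e-8)
    stop("W must be symmetric (tolerance 1e-8)")
  m <- max(abs(W))
  if (m == 0) {
    warning("zero matrix; returned unchanged")
    return(W)
  }
  W / m
}

## Apply the negative-weight policy after normalization; diagonal zeroed.
.prep_weights <- function(W, policy = c("zero", "abs")) {
  policy <- match.arg(policy)
  W <- normalize_weights(W)
  W <- switch(policy, zero = pmax(W, 0), abs = abs(W))
  diag(W) <- 0
  W
}

#' Module-degree z-score (within-module strength)
#'
#' For node i in module m, \eqn{z_i = (k_i - mean_m k) / sd_m k} where
#' \eqn{k_i} is i's summed connection strength to other members of m and the
#' mean/sd are over m's nodes. A zero within-module sd, or a single-node
#' module, yields z = 0.
#'
#' @param W Symmetric weight matrix (signed betas allowed; see
#'   \code{policy}).
#' @param map Module labels, one per node.
#' @param policy Negative-weight policy applied after normalization:
#'   \code{"zero"} (truncate, default) or \code{"abs"}.
#' @return Numeric vector of z-scores.
#' @export
module_degree_z <- function(W, map, policy = c("zero", "abs")) {
  W <- .prep_weights(W, policy)
  n <- nrow(W)
  if (length(map) != n) stop("map must cover all nodes")
  same <- outer(map, map, "==")
  k <- rowSums(W * same)
  z <- numeric(n)
  for (m in unique(map)) {
    idx <- which(map == m)
    if (length(idx) < 2) {
      warning("module of size 1: z set to 0")
      next
    }
    s <- stats::sd(k[idx])
    if (s > 0) z[idx] <- (k[idx] - mean(k[idx])) / s
  }
  z
}

#' Participation coefficient (between-module strength)
#'
#' \eqn{PC_i = 1 - \sum_m (k_{im} / k_i)^2}, with \eqn{k_{im}} node i's
#' strength into module m and \eqn{k_i} its total strength; a node with zero
#' strength gets PC = 0. With nonnegative weights PC lies in
#' \[0, 1 - 1/M\] for M modules.
#'
#' @inheritParams module_degree_z
#' @return Numeric vector of participation coefficients.
#' @export
participation_coefficient <- function(W, map, policy = c("zero", "abs")) {
  W <- .prep_weights(W, policy)
  n <- nrow(W)
  if (length(map) != n) stop("map must cover all nodes")
  mods <- unique(map)
  ind <- vapply(mods, function(m) as.numeric(map == m), numeric(n))
  Kim <- W %*% ind
  k <- rowSums(W)
  pc <- numeric(n)
  pos <- k > 0
  pc[pos] <- 1 - rowSums((Kim[pos, , drop = FALSE] / k[pos])^2)
  pc
}

#' Integration/segregation balance per node
#'
#' Min-max scales the module-degree z and the participation coefficient to
#' \[0, 1\] across nodes and reports the guarded ratio
#' \eqn{(z_s + \epsilon) / (PC_s + \epsilon)} — high values mark nodes
#' whose strength concentrates within their own network (segregation),
#' low values mark connector hubs (integration). Network medians summarize
#' the distribution per module.
#'
#' @inheritParams module_degree_z
#' @param eps Guard constant in the ratio (default 1e-6).
#' @return List with \code{nodes} (node, module, z, pc, scaled values,
#'   ratio) and \code{network_summary} (module, median ratio, n nodes).
#' @export
integration_segregation_ratio <- function(W, map, policy = c("zero", "abs"),
                                          eps = 1e-6) {
  z <- module_degree_z(W, map, policy)
  pc <- participation_coefficient(W, map, policy)
  scale01 <- function(v) {
    r <- range(v)
    if (diff(r) == 0) {
      warning("zero range; scaled values set to 0.5")
      return(rep(0.5, length(v)))
    }
    (v - r[1]) / diff(r)
  }
  zs <- scale01(z)
  ps <- scale01(pc)
  ratio <- (zs + eps) / (ps + eps)
  nodes <- data.frame(
    node = if (!is.null(rownames(W))) rownames(W) else seq_len(nrow(W)),
    module = map, z = z, pc = pc, z_scaled = zs, pc_scaled = ps,
    ratio = ratio, stringsAsFactors = FALSE)
  med <- stats::aggregate(ratio ~ module, nodes, stats::median)
  names(med)[2] <- "median_ratio"
  med$n_nodes <- as.integer(table(map)[med$module])
  list(nodes = nodes, network_summary = med)
}
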