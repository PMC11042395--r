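# Independent oracles used across the suite. These deliberately take the
# slow, direct route (explicit formulas, enumeration, brute-force loops) so
# they share no code path with the package implementation.

# Canonical correlations via the generalized eigenproblem:
# eigenvalues of Sxx^-1 Sxy Syy^-1 Syx are the squared canonical correlations.
cca_eigen_oracle <- function(X, Y) {
  Sxx <- stats::cov(X); Syy <- stats::cov(Y); Sxy <- stats::cov(X, Y)
  M <- solve(Sxx, Sxy) %*% solve(Syy, t(Sxy))
  ev <- sort(Re(eigen(M)$values), decreasing = TRUE)
  sqrt(pmax(pmin(ev, 1), 0))
}

# First canonical correlation for a 2-column X block by scanning the weight
# angle on a fine grid; for each direction the best Y combination is the
# square root of the regression R^2.
cca_angle_scan_oracle <- function(X, Y, step = 1e-4) {
  stopifnot(ncol(X) == 2)
  theta <- seq(0, pi, by = step)
  A <- rbind(cos(theta), sin(theta))
  Xc <- sweep(X, 2, colMeans(X), "-")
  Yc <- sweep(Y, 2, colMeans(Y), "-")
  V <- Xc %*% A                               # n x n_theta candidate scores
  Syy <- crossprod(Yc)
  Cv <- crossprod(Yc, V)                      # q x n_theta
  quad <- colSums(Cv * solve(Syy, Cv))
  r2 <- quad / colSums(V^2)
  sqrt(max(r2))
}

# Enumerate every admissible restricted permutation for a tiny design by
# taking the cartesian product of all within-group shuffles and all
# whole-family orderings per signature class.
enumerate_admissible <- function(blocks) {
  perms_of <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  base <- list(seq_len(blocks$n))
  # within-group shuffles
  for (g in blocks$within_groups) {
    new <- list()
    for (p in base) for (gp in perms_of(g)) {
      q <- p; q[g] <- q[gp]
      new[[length(new) + 1]] <- q
    }
    base <- new
  }
  # whole-family exchanges
  for (cl in blocks$classes) {
    new <- list()
    for (p in base) for (ord in perms_of(seq_along(cl))) {
      q <- seq_len(blocks$n)
      for (j in seq_along(cl)) q[blocks$slots[[cl[j]]]] <- blocks$slots[[cl[ord[j]]]]
      new[[length(new) + 1]] <- p[q]
    }
    base <- new
  }
  unique(lapply(base, as.integer))
}

# Brute-force graph metrics by explicit loops over nodes and modules.
brute_module_z <- function(W, map) {
  n <- nrow(W)
  k <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (j != i && map[j] == map[i]) k[i] <- k[i] + W[i, j]
  z <- numeric(n)
  for (m in unique(map)) {
    idx <- which(map == m)
    if (length(idx) < 2) next
    s <- stats::sd(k[idx])
    if (s > 0) z[idx] <- (k[idx] - mean(k[idx])) / s
  }
  z
}

brute_participation <- function(W, map) {
  n <- nrow(W)
  pc <- numeric(n)
  for (i in seq_len(n)) {
    ki <- sum(W[i, -i])
    if (ki == 0) next
    acc <- 0
    for (m in unique(map)) {
      kim <- sum(W[i, setdiff(which(map == m), i)])
      acc <- acc + (kim / ki)^2
    }
    pc[i] <- 1 - acc
  }
  pc
}

# A small related-subjects design used in several tests.
toy_families <- function() {
  data.frame(
    subject_id = paste0("s", 1:5),
    family_id = c("f1", "f1", "f2", "f2", "f3"),
    role = c("MZ", "MZ", "MZ", "MZ", "SINGLETON"),
    stringsAsFactors = FALSE
  )
}

random_symmetric <- function(p, seed) {
  set.seed(seed)
  m <- matrix(rnorm(p * p), p, p)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}
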