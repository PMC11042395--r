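test_that("censor mask reproduces the hand-simulated 12-frame cases", {
  # single outlier mid-run: dilation censors 5-8, both remnants are short,
  # everything is censored and the run is excluded
  fd <- rep(0, 12); fd[6] <- 0.5
  m <- build_censor_mask(fd)
  expect_true(all(!m$keep))
  expect_true(m$run_excluded)
  expect_equal(m$censored_frac, 1)
  # outlier at frame 1: frames 1-3 censored, 4-12 kept, run retained
  fd2 <- rep(0, 12); fd2[1] <- 0.5
  m2 <- build_censor_mask(fd2)
  expect_equal(which(!m2$keep), 1:3)
  expect_false(m2$run_excluded)
  expect_equal(m2$censored_frac, 3 / 12)
  # clean run: everything kept
  m3 <- build_censor_mask(rep(0, 20), rep(0, 20))
  expect_true(all(m3$keep))
  expect_false(m3$run_excluded)
  # DVARS criterion alone triggers censoring
  m4 <- build_censor_mask(rep(0, 20), c(rep(0, 9), 80, rep(0, 10)))
  expect_false(m4$keep[10])
  expect_error(build_censor_mask(numeric(0)), "empty")
})

test_that("RSFC assembly applies censoring, Fisher z, and run averaging", {
  ts1 <- rbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  r1 <- compute_rsfc(list(list(ts = ts1)))
  expect_equal(r1[1, 2], 0, tolerance = 1e-12)
  expect_equal(unname(diag(r1)), c(0, 0))
  # censored middle frame: correlation over the 4 kept frames only
  set.seed(1)
  ts2 <- matrix(rnorm(10), 2, 5)
  mask <- build_censor_mask(rep(0, 5))
  mask$keep[3] <- FALSE
  r2 <- compute_rsfc(list(list(ts = ts2, mask = mask)))
  direct <- atanh(cor(ts2[1, -3], ts2[2, -3]))
  expect_equal(r2[1, 2], direct, tolerance = 1e-12)
  # two runs average their z-matrices
  ts3 <- matrix(rnorm(12), 2, 6)
  za <- compute_rsfc(list(list(ts = ts2)))
  zb <- compute_rsfc(list(list(ts = ts3)))
  zab <- compute_rsfc(list(list(ts = ts2), list(ts = ts3)))
  expect_equal(zab[1, 2], (za[1, 2] + zb[1, 2]) / 2, tolerance = 1e-12)
  expect_equal(attr(zab, "runs_used"), 2)
  # perfectly correlated parcels are clipped before atanh
  ts4 <- rbind(1:6, 2 * (1:6))
  expect_true(is.finite(compute_rsfc(list(list(ts = ts4)))[1, 2]))
  # excluded runs are skipped; all excluded is a subject-level error
  bad <- build_censor_mask(rep(1, 6))
  ts6 <- matrix(rnorm(12), 2, 6)
  expect_error(compute_rsfc(list(list(ts = ts6, mask = bad))), "all runs excluded")
  expect_error(compute_rsfc(list(list(ts = rbind(rep(1, 5), rnorm(5))))), "zero-variance")
})

test_that("confound residualization matches the normal equations", {
  set.seed(3)
  n <- 6
  age <- rnorm(n)
  mats <- lapply(seq_len(n), function(i) random_symmetric(4, i + 100))
  # an edge that is exactly 2*age is annihilated
  for (i in seq_len(n)) mats[[i]][1, 2] <- mats[[i]][2, 1] <- 2 * age[i]
  res <- residualize_confounds(mats, data.frame(age = age))
  expect_equal(sapply(res, function(m) m[1, 2]), rep(0, n), tolerance = 1e-12)
  # hand-solved normal equations for another edge
  e34 <- sapply(mats, function(m) m[3, 4])
  C <- cbind(1, age)
  beta <- solve(t(C) %*% C, t(C) %*% e34)
  expect_equal(sapply(res, function(m) m[3, 4]), as.numeric(e34 - C %*% beta),
               tolerance = 1e-10)
  # covariate orthogonal to an edge leaves it mean-centered only
  mats2 <- mats
  v <- c(1, -1, 1, -1, 1, -1) * 3 + 5
  for (i in seq_len(n)) mats2[[i]][1, 3] <- mats2[[i]][3, 1] <- v[i]
  ort <- residuals(lm(v ~ age))
  res2 <- residualize_confounds(mats2, data.frame(age = age))
  expect_equal(sapply(res2, function(m) m[1, 3]), as.numeric(ort), tolerance = 1e-10)
  expect_warning(residualize_confounds(mats, data.frame(a = age, b = 2 * age)),
                 "collinear")
})

test_that("edge-wise GLM matches lm and flags exact fits", {
  set.seed(4)
  n <- 8
  score <- rnorm(n)
  mats <- lapply(seq_len(n), function(i) random_symmetric(5, i + 50))
  eg <- edgewise_glm(mats, score)
  # pick three edges, compare against lm()
  for (row in c(1, 4, 9)) {
    i <- eg$table$i[row]; j <- eg$table$j[row]
    y <- sapply(mats, function(m) m[i, j])
    fit <- summary(lm(y ~ score))
    expect_equal(eg$table$beta[row], fit$coefficients["score", 1], tolerance = 1e-10)
    expect_equal(eg$table$t[row], fit$coefficients["score", 3], tolerance = 1e-10)
    expect_equal(eg$table$p[row], fit$coefficients["score", 4], tolerance = 1e-10)
    expect_equal(eg$table$f[row], eg$table$t[row]^2, tolerance = 1e-10)
  }
  # noiseless linear edge: beta exact, flagged
  mats3 <- lapply(seq_len(n), function(i) {
    m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 3 * score[i]; m
  })
  eg3 <- edgewise_glm(mats3, score)
  expect_equal(eg3$table$beta[1], 3, tolerance = 1e-12)
  expect_true(eg3$table$exact_fit[1])
  expect_equal(eg3$table$p[1], 0)
  expect_error(edgewise_glm(mats, rep(1, n)), "constant predictor")
})

test_that("edge-wise GLM is calibrated under a planted null", {
  cfg <- synth_config(n_subjects = 400, n_parcels = 30, noise_sd = 1, seed = 15)
  set.seed(15)
  scores <- rnorm(400)
  mats <- simulate_connectomes(cfg, scores, seed = 16)
  eg <- edgewise_glm(mats, scores)
  rate <- mean(eg$table$p <= 0.05)
  n_edges <- nrow(eg$table)
  ci <- qnorm(0.995) * sqrt(0.05 * 0.95 / n_edges)
  expect_lt(abs(rate - 0.05), ci + 0.005)
})

test_that("network averaging computes block means and is permutation-invariant", {
  map <- c("A", "A", "B", "B")
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 10   # within A
  m[3, 4] <- m[4, 3] <- 20   # within B
  cross <- rbind(c(1, 2), c(3, 4))
  m[1:2, 3:4] <- cross; m[3:4, 1:2] <- t(cross)
  nm <- network_average(m, map)
  expect_equal(nm["A", "A"], 10)
  expect_equal(nm["B", "B"], 20)
  expect_equal(nm["A", "B"], mean(cross))
  expect_equal(nm, t(nm))
  # constant matrix maps to constant blocks
  cm <- matrix(7, 4, 4)
  expect_true(all(network_average(cm, map) == 7))
  # parcel reordering leaves the network matrix unchanged
  p <- c(3, 1, 4, 2)
  expect_equal(network_average(m[p, p], map[p]), nm)
  # single-parcel network yields NA within
  nm2 <- network_average(m, c("A", "A", "B", "C"))
  expect_true(is.na(nm2["C", "C"]))
  # linearity: network-averaging commutes with subject averaging
  m2 <- random_symmetric(4, 77)
  expect_equal(network_average((m + m2) / 2, map),
               (network_average(m, map) + network_average(m2, map)) / 2,
               tolerance = 1e-12)
})

test_that("network-wise GLM isolates a noiseless planted pair and counts tests", {
  map <- rep(c("A", "B", "C"), each = 4)
  cfg <- synth_config(n_subjects = 50, n_parcels = 12, network_map = map,
                      noise_sd = 0,
                      edge_effects = list(list(a = "A", b = "C", slope = 0.4)),
                      seed = 30)
  set.seed(30)
  scores <- rnorm(50)
  mats <- simulate_connectomes(cfg, scores)
  ng <- networkwise_glm(mats, scores, map)
  expect_equal(ng$n_tests, 6)  # 3 networks: 3*4/2
  ac <- ng$table$net_i == "A" & ng$table$net_j == "C"
  expect_equal(ng$table$beta[ac], 0.4, tolerance = 1e-12)
  expect_equal(ng$table$beta[!ac], rep(0, 5), tolerance = 1e-12)
  # 18 networks give 171 tests
  map18 <- rep(paste0("n", sprintf("%02d", 1:18)), each = 2)
  cfg18 <- synth_config(n_subjects = 40, n_parcels = 36, network_map = map18,
                        noise_sd = 1, seed = 31)
  mats18 <- simulate_connectomes(cfg18, rnorm(40))
  ng18 <- networkwise_glm(mats18, rnorm(40), map18)
  expect_equal(ng18$n_tests, 171)
})

test_that("edge-wise beta on residualized data equals the partial coefficient (Frisch-Waugh)", {
  set.seed(40)
  n <- 30
  score <- rnorm(n)
  covars <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  mats <- lapply(seq_len(n), function(i) random_symmetric(4, i + 900))
  # residualize BOTH the edges and the predictor, per Frisch-Waugh
  res <- residualize_confounds(mats, covars)
  score_r <- residuals(lm(score ~ age + sex, data = covars))
  eg <- edgewise_glm(res, score_r)
  y <- sapply(mats, function(m) m[1, 2])
  joint <- lm(y ~ score + age + sex, data = covars)
  expect_equal(eg$table$beta[1], unname(coef(joint)["score"]), tolerance = 1e-10)
})
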