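test_that("exchangeability blocks partition subjects and group families by signature", {
  fam <- toy_families()
  bl <- build_blocks(fam)
  expect_equal(bl$n, 5)
  # two MZ-pair families share a class; the singleton is alone (size-1
  # classes are dropped from the swap list)
  expect_equal(length(bl$classes), 1)
  expect_equal(length(bl$classes[[1]]), 2)
  expect_equal(length(bl$within_groups), 2)
  # a family {MZ,MZ,SIB} never shares a class with {MZ,MZ}
  fam2 <- rbind(fam, data.frame(subject_id = c("s6", "s7", "s8"),
                                family_id = "f4", role = c("MZ", "MZ", "SIB")))
  bl2 <- build_blocks(fam2)
  sig4 <- bl2$signatures[bl2$family_ids == "f4"]
  sig1 <- bl2$signatures[bl2$family_ids == "f1"]
  expect_false(sig4 == sig1)
  expect_error(build_blocks(rbind(fam, fam[1, ])), "duplicate")
})

test_that("all singletons yield free permutation; role-stratified scheme ignores families", {
  fam <- data.frame(subject_id = paste0("s", 1:6),
                    family_id = paste0("f", 1:6),
                    role = "SINGLETON", stringsAsFactors = FALSE)
  bl <- build_blocks(fam)
  expect_equal(length(bl$classes), 1)  # one whole-swap class of all families
  set.seed(1)
  seen <- replicate(300, paste(draw_permutation(bl), collapse = "-"))
  expect_gt(length(unique(seen)), 100)  # many of the 720 free permutations
  # role-stratified: same-role subjects swap across families
  fam2 <- toy_families()
  bl2 <- build_blocks(fam2, scheme = "role_stratified")
  expect_equal(length(bl2$classes), 0)
  expect_equal(sort(unlist(bl2$within_groups)), 1:4)
})

test_that("sampler support equals the enumerated admissible set with uniform frequencies", {
  bl <- build_blocks(toy_families())
  adm <- enumerate_admissible(bl)
  expect_equal(length(adm), 8)
  keys <- sapply(adm, paste, collapse = "-")
  set.seed(42)
  draws <- replicate(8000, paste(draw_permutation(bl), collapse = "-"))
  expect_true(all(draws %in% keys))          # support soundness
  expect_true(paste(1:5, collapse = "-") %in% draws)  # identity occurs
  tab <- table(factor(draws, levels = keys))
  expect_gt(chisq.test(tab)$p.value, 0.01)   # uniformity
})

test_that("every drawn permutation preserves roles and family signatures", {
  fam <- make_family_structure(60, seed = 2)
  bl <- build_blocks(fam)
  set.seed(7)
  for (i in 1:50) {
    p <- draw_permutation(bl)
    expect_equal(sort(p), 1:60)                       # bijection
    expect_equal(fam$role[p], fam$role)               # role preserved
    # each family maps onto a family with identical role multiset
    src_fam <- fam$family_id[p]
    for (fid in unique(fam$family_id)) {
      members <- which(fam$family_id == fid)
      mapped <- unique(src_fam[members])
      expect_equal(length(mapped), 1)
      sig_a <- paste(sort(fam$role[members]), collapse = "+")
      sig_b <- paste(sort(fam$role[fam$family_id == mapped]), collapse = "+")
      expect_equal(sig_a, sig_b)
    }
  }
})

test_that("BH correction matches the brute-force step-up definition", {
  brute_bh <- function(p, q) {
    m <- length(p)
    o <- order(p)
    ok <- which(p[o] <= seq_len(m) * q / m)
    rej <- logical(m)
    if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
    rej
  }
  expect_equal(fdr_bh(rep(1, 5))$reject, rep(FALSE, 5))
  expect_true(fdr_bh(0.04)$reject)
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.2))
  expect_equal(r$reject, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  set.seed(10)
  for (i in 1:200) {
    p <- runif(sample(1:12, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_equal(fdr_bh(p, q)$reject, brute_bh(p, q))
  }
  expect_equal(fdr_bh(numeric(0))$q_values, numeric(0))
})

test_that("permutation p-values honor boundaries and the add-one convention", {
  fam <- make_family_structure(40, seed = 1)
  cfg <- synth_config(n_subjects = 40, p_behavior = 5,
                      planted_rho = c(0.95), seed = 1)
  tb <- simulate_two_block(cfg, fam)
  bl <- build_blocks(fam)
  pr <- permutation_test(tb$X, tb$Y, bl, n_perm = 99, seed = 3)
  expect_equal(pr$perm_p[1], 1 / 100)            # rho1 beats every null draw
  expect_true(all(pr$perm_p >= 1 / 100 & pr$perm_p <= 1))
  expect_equal(pr$perm_p,
               sapply(seq_len(pr$K), function(k)
                 (1 + sum(pr$null[, k] >= pr$rho[k])) / 100))
  # null distribution of rho1 is not centered at zero
  expect_gt(mean(pr$null[, 1]), 0.2)
  expect_error(permutation_test(tb$X, tb$Y, bl, n_perm = 0), "positive count")
})

test_that("Monte-Carlo p converges to the exhaustive-enumeration p on a tiny design", {
  fam <- data.frame(subject_id = paste0("s", 1:4),
                    family_id = paste0("f", 1:4),
                    role = "SINGLETON", stringsAsFactors = FALSE)
  set.seed(5)
  X <- matrix(rnorm(4), 4, 1)
  Y <- matrix(rnorm(4), 4, 1)
  bl <- build_blocks(fam)
  perms <- enumerate_admissible(bl)
  expect_equal(length(perms), 24)
  stat <- function(p) abs(cor(X[, 1], Y[p, 1]))
  obs <- stat(1:4)
  exact_p <- mean(sapply(perms, stat) >= obs - 1e-12)
  Xs <- standardize(X); Ys <- standardize(Y)
  pr <- permutation_test(Xs, Ys, bl, n_perm = 20000, seed = 8)
  expect_lt(abs(pr$perm_p[1] - exact_p), 0.02)
})

test_that("bootstrap alignment flips mirrored components and flags diagnostics", {
  set.seed(20)
  ref <- matrix(rnorm(12), 6, 2)
  mt <- sleepcca:::.match_components(ref, -ref)
  expect_equal(mt$assign, 1:2)
  expect_equal(mt$sign, c(-1, -1))
  mt2 <- sleepcca:::.match_components(ref, ref[, 2:1])
  expect_equal(mt2$assign, 2:1)
})

test_that("bootstrap sd of loadings shrinks with sample size", {
  run_sd <- function(n, seed) {
    cfg <- synth_config(n_subjects = n, p_behavior = 10, planted_rho = c(0.6),
                        family_mix = c(singleton = 1), seed = seed)
    fam <- make_family_structure(n, c(singleton = 1), seed = seed)
    tb <- simulate_two_block(cfg, fam)
    bt <- bootstrap_loadings(tb$X, tb$Y, fam, n_boot = 150, seed = seed + 1)
    mean(bt$sleep$boot_sd[bt$sleep$component == 1])
  }
  expect_lt(run_sd(800, 31), run_sd(200, 31))
})

test_that("family-level resampling keeps families intact and runs end to end", {
  fam <- make_family_structure(120, seed = 4)
  cfg <- synth_config(n_subjects = 120, p_behavior = 8, planted_rho = c(0.6),
                      seed = 4)
  tb <- simulate_two_block(cfg, fam)
  bt <- bootstrap_loadings(tb$X, tb$Y, fam, n_boot = 60, seed = 5,
                           resample = "families")
  expect_equal(nrow(bt$sleep), 7 * 7)
  expect_true(all(bt$sleep$boot_sd >= 0))
  # significant loadings are a subset of |mean|/sd exceeding the normal quantile
  s <- bt$sleep
  expect_true(all(abs(s$z[s$sig]) >= qnorm(0.975)))
})

test_that("cross-validation keeps families within folds and recovers planted correlation", {
  fam <- make_family_structure(600, seed = 6)
  cfg <- synth_config(n_subjects = 600, planted_rho = c(0.8, 0.3), seed = 6)
  tb <- simulate_two_block(cfg, fam)
  cv <- crossval(tb$X, tb$Y, fam, k = 5, n_perm = 99, seed = 7)
  for (fid in unique(fam$family_id))
    expect_equal(length(unique(cv$fold[fam$family_id == fid])), 1)
  expect_lt(abs(cv$mean_r[1] - 0.8), 0.12)
  expect_lt(cv$perm_p[1], 0.05)
  # folds balanced at the family level
  ff <- table(tapply(cv$fold, fam$family_id, unique))
  expect_lte(diff(range(ff)), 1)
})

test_that("cross-validation on null data centers near zero with uniform-ish p", {
  fam <- make_family_structure(300, seed = 8)
  cfg <- synth_config(n_subjects = 300, planted_rho = c(0), seed = 8)
  tb <- simulate_two_block(cfg, fam)
  cv <- crossval(tb$X, tb$Y, fam, k = 5, n_perm = 199, seed = 9)
  expect_lt(abs(cv$mean_r[1]), 0.15)
  expect_gt(cv$perm_p[1], 0.05)
})
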