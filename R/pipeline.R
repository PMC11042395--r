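#' Named per-stage seed stream
#'
#' Derives an independent 32-bit seed from a master seed and a stage name,
#' so adding a stage never perturbs earlier stages' draws.
#'
#' @param master Integer master seed.
#' @param name Stage name.
#' @return Integer seed in \[1, 2^31 - 2\].
#' @export
stage_seed <- function(master, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147480009
  as.integer((abs(master) %% 65521) * 32749 %% 2147480009 + h) %% 2147483646L + 1L
}

#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end run. Defaults mirror the study's
#' stated analysis settings: 10,000 permutations, 1,000 bootstrap samples,
#' 5 folds, FDR level 0.05, averaged composite scores.
#'
#' @param synth A [synth_config()] driving the synthetic cohort, or
#'   \code{NULL} when reading data from files.
#' @param paths Optional named list (\code{sleep}, \code{behavior},
#'   \code{family}, \code{connectivity_dir}) for file-based input.
#' @param out_dir Where result tables and the manifest are written.
#' @param n_perm,n_boot,k_folds,q Analysis settings.
#' @param cv_n_perm Permutations for the cross-validation null.
#' @param composite_mode \code{"averaged"}, \code{"sleep"}, or
#'   \code{"behavior"}.
#' @param quantile_norm If TRUE, both blocks are rank-based
#'   inverse-normal transformed before standardization (robustness
#'   variant).
#' @param perm_scheme Restricted-permutation scheme (see [build_blocks()]).
#' @param neg_policy Negative-weight policy for graph metrics.
#' @param glm_component Which component's composite score drives the
#'   connectivity models (default 1).
#' @param seed Master seed; per-stage streams are derived by [stage_seed()].
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(synth = synth_config(),
                            paths = NULL,
                            out_dir = tempfile("sleepcca_run_"),
                            n_perm = 10000, n_boot = 1000, k_folds = 5,
                            q = 0.05, cv_n_perm = 999,
                            composite_mode = c("averaged", "sleep", "behavior"),
                            quantile_norm = FALSE,
                            perm_scheme = c("palm", "role_stratified"),
                            neg_policy = c("zero", "abs"),
                            glm_component = 1,
                            seed = 1) {
  if (n_perm < 1) stop("n_perm must be a positive count")
  if (n_boot < 2) stop("n_boot must be at least 2")
  if (k_folds < 2) stop("k_folds must be at least 2")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  structure(list(
    synth = synth, paths = paths, out_dir = out_dir,
    n_perm = n_perm, n_boot = n_boot, k_folds = k_folds, q = q,
    cv_n_perm = cv_n_perm,
    composite_mode = match.arg(composite_mode),
    quantile_norm = isTRUE(quantile_norm),
    perm_scheme = match.arg(perm_scheme),
    neg_policy = match.arg(neg_policy),
    glm_component = glm_component, seed = seed
  ), class = "pipeline_config")
}

.synth_covariates <- function(n, seed) {
  set.seed(seed)
  data.frame(age = round(stats::rnorm(n, 28.9, 3.6), 1),
             sex = stats::rbinom(n, 1, 0.5),
             education = sample(11:17, n, replace = TRUE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort assembly (synthetic or from files),
#' standardization, CCA fit, structure coefficients and covariance-explained
#' fractions, the family-restricted permutation test, bootstrap loading
#' stability, family-aware cross-validation, composite scores, confound
#' residualization, edge-wise and network-wise connectivity GLMs, and graph
#' metrics on the edge-wise beta matrix. Every stochastic stage consumes an
#' independent named seed stream. All result tables plus a JSON run manifest
#' (config echo, seeds, per-file digests) are written to
#' \code{config$out_dir}.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list with every stage result and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- sapply(c("families", "phenotypes", "permutation", "bootstrap",
                    "crossval", "connectomes", "covariates", "folds"),
                  function(nm) stage_seed(config$seed, nm))

  if (!is.null(config$paths)) {
    ph <- read_phenotypes(config$paths$sleep, config$paths$behavior,
                          config$paths$family)
    X <- ph$X; Y <- ph$Y; fam <- ph$families
    conn_in <- if (!is.null(config$paths$connectivity_dir))
      read_connectivity(config$paths$connectivity_dir)
    map <- if (!is.null(conn_in)) conn_in$map
  } else {
    fam <- make_family_structure(config$synth$n_subjects,
                                 config$synth$family_mix, seeds[["families"]])
    tb <- simulate_two_block(config$synth, fam, seeds[["phenotypes"]])
    X <- tb$X; Y <- tb$Y
    conn_in <- NULL
    map <- config$synth$network_map
  }

  if (config$quantile_norm) {
    rnX <- rownames(X); rnY <- rownames(Y)
    X <- quantile_normalize(X); Y <- quantile_normalize(Y)
    rownames(X) <- rnX; rownames(Y) <- rnY
  }
  Xs <- standardize(X); Ys <- standardize(Y)
  model <- fit_cca(Xs, Ys)
  ## project_scores applies the stored training transform, so it receives
  ## the pre-standardization data
  sc <- project_scores(model, X, Y)
  sleep_load <- structure_loadings(Xs, sc$sleep_scores)
  behav_load <- structure_loadings(Ys, sc$behavior_scores)
  cov_expl <- covariance_explained(model, X, Y)

  blocks <- build_blocks(fam, scheme = config$perm_scheme)
  perm <- permutation_test(Xs, Ys, blocks, n_perm = config$n_perm,
                           seed = seeds[["permutation"]])
  boot <- bootstrap_loadings(X, Y, fam, n_boot = config$n_boot,
                             seed = seeds[["bootstrap"]], q = config$q)
  cv <- crossval(X, Y, fam, k = config$k_folds, n_perm = config$cv_n_perm,
                 seed = seeds[["crossval"]])

  kc <- config$glm_component
  comp <- composite_scores(sc$sleep_scores[, kc], sc$behavior_scores[, kc],
                           mode = config$composite_mode)
  names(comp) <- rownames(X)

  mats <- if (!is.null(conn_in)) {
    conn_in$matrices[rownames(X)]
  } else {
    simulate_connectomes(config$synth, comp, seeds[["connectomes"]])
  }
  covars <- .synth_covariates(length(comp), seeds[["covariates"]])
  mats_r <- residualize_confounds(mats, covars)
  eg <- edgewise_glm(mats_r, comp)
  ng <- networkwise_glm(mats_r, comp, map, q = config$q)
  graph <- integration_segregation_ratio(eg$beta_matrix, map,
                                         policy = config$neg_policy)

  ## --- write tables -----------------------------------------------------
  od <- config$out_dir
  comp_tab <- data.frame(component = seq_len(model$K), rho = model$rho,
                         cov_explained_pct = 100 * cov_expl,
                         perm_p = perm$perm_p, perm_q = perm$perm_q)
  .write_table(comp_tab, file.path(od, "components.csv"))
  .write_table(boot$sleep, file.path(od, "sleep_loadings.csv"))
  .write_table(boot$behavior, file.path(od, "behavior_loadings.csv"))
  cv_tab <- data.frame(component = seq_along(cv$mean_r), mean_r = cv$mean_r,
                       perm_p = cv$perm_p)
  .write_table(cv_tab, file.path(od, "crossval.csv"))
  .write_table(eg$table, file.path(od, "edge_glm.csv"))
  .write_table(ng$table, file.path(od, "network_glm.csv"))
  .write_table(graph$nodes, file.path(od, "graph_nodes.csv"))
  .write_table(graph$network_summary, file.path(od, "graph_networks.csv"))
  write_cca_model(model, file.path(od, "cca_model.json"))

  files <- c("components.csv", "sleep_loadings.csv", "behavior_loadings.csv",
             "crossval.csv", "edge_glm.csv", "network_glm.csv",
             "graph_nodes.csv", "graph_networks.csv", "cca_model.json")
  manifest <- list(
    package = "sleepcca",
    version = as.character(utils::packageVersion("sleepcca")),
    seed = config$seed,
    stage_seeds = as.list(seeds),
    settings = list(n_perm = config$n_perm, n_boot = config$n_boot,
                    k_folds = config$k_folds, q = config$q,
                    cv_n_perm = config$cv_n_perm,
                    composite_mode = config$composite_mode,
                    quantile_norm = config$quantile_norm,
                    perm_scheme = config$perm_scheme,
                    neg_policy = config$neg_policy,
                    glm_component = config$glm_component,
                    synthetic = is.null(config$paths)),
    n_subjects = nrow(X),
    digests = as.list(tools::md5sum(file.path(od, files)))
  )
  names(manifest$digests) <- files
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = I(17))
  invisible(list(families = fam, X = Xs, Y = Ys, model = model,
                 sleep_loadings = sleep_load, behavior_loadings = behav_load,
                 cov_explained = cov_expl, permutation = perm,
                 bootstrap = boot, crossval = cv, composite = comp,
                 edge_glm = eg, network_glm = ng, graph = graph,
                 manifest = manifest, out_dir = od))
}
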