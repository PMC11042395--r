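#!/usr/bin/env Rscript
# Stage 4: connectivity signature of the first profile.
#
# Projects the fitted model to LC1 composite scores, simulates per-subject
# connectomes (60 parcels, 7 cortical networks + subcortical) with a planted
# effect of the composite on the Net2-Net5 block, regresses out age/sex/
# education, runs edge-wise and network-wise GLMs, and characterizes the
# edge-wise beta network with module-degree z, participation coefficient and
# the integration/segregation ratio.

suppressPackageStartupMessages(library(sleepcca))

ph <- read_phenotypes("results/data/sleep.csv", "results/data/behavior.csv",
                      "results/data/family.csv")
model <- read_cca_model("results/tables/cca_model.json")
sc <- project_scores(model, ph$X, ph$Y)
comp <- composite_scores(sc$sleep_scores[, 1], sc$behavior_scores[, 1])
names(comp) <- ph$families$subject_id

n <- length(comp)
map <- rep_len(c(paste0("Net", 1:7), "Subcortical"), 60)
cfg <- synth_config(n_subjects = n, n_parcels = 60, network_map = map,
                    noise_sd = 1,
                    edge_effects = list(list(a = "Net2", b = "Net5", slope = 0.25)),
                    seed = 2030)
mats <- simulate_connectomes(cfg, comp)

set.seed(2031)
covars <- data.frame(age = round(rnorm(n, 28.9, 3.6), 1),
                     sex = rbinom(n, 1, 0.5),
                     education = sample(11:17, n, replace = TRUE))
mats_r <- residualize_confounds(mats, covars)

eg <- edgewise_glm(mats_r, comp)
ng <- networkwise_glm(mats_r, comp, map)
cat("network pairs significant after FDR (q<=0.05):\n")
print(ng$table[ng$table$sig, c("net_i", "net_j", "beta", "q")], digits = 3)

graph <- integration_segregation_ratio(eg$beta_matrix, map)
cat("network medians of the integration/segregation ratio:\n")
print(graph$network_summary, digits = 3)

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
write.csv(eg$table, "results/tables/edge_glm.csv", row.names = FALSE)
write.csv(ng$table, "results/tables/network_glm.csv", row.names = FALSE)
write.csv(graph$nodes, "results/tables/graph_nodes.csv", row.names = FALSE)
write.csv(graph$network_summary, "results/tables/graph_networks.csv", row.names = FALSE)
cat("wrote results/tables/{edge_glm,network_glm,graph_nodes,graph_networks}.csv\n")
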