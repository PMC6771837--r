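#!/usr/bin/env Rscript
# Step 1: generate the synthetic meta-analysis datasets the workflow
# analyses. Real multi-outcome 2x2 data live inside published systematic
# reviews and are not redistributable, so the workflow runs on synthetic
# datasets with the same statistical structure:
#   (a) a bivariate dataset with a subset-structured outcome pair
#       (analytic within-study correlations available), and
#   (b) a four-outcome scenario patterned on a review with selective
#       reporting of one outcome (no structural relations; small-study
#       effects induced by significance-driven withholding of results).
# Writes the CSV tables, YAML relation configs and truth JSONs under
# results/data/.

suppressMessages(library(mvbmeta))

out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

# (a) subset-structured bivariate meta-analysis, 20 studies
truth_biv <- sim_truth(
  mu_true = c(death = -0.7, death_or_morbidity = -0.4),
  tau_true = c(0.3, 0.3),
  rho_between_true = matrix(c(1, 0.7, 0.7, 1), 2L),
  baseline_risk = c(0.15, 0.35),
  relations = data.frame(outcome_a = "death",
                         outcome_b = "death_or_morbidity",
                         relation = "subset_a_of_b"),
  k_studies = 20L, n_range = c(50L, 500L), seed = 20260919L,
  outcome_ids = c("death", "death_or_morbidity"))
res_biv <- generate_dataset(truth_biv)
write_dataset(res_biv$dataset,
              file.path(out_dir, "bivariate_subset_tables.csv"),
              file.path(out_dir, "bivariate_subset_relations.yaml"))

# (b) selective-reporting scenario, 10 studies, 4 outcomes
res_sel <- generate_dataset(review7_scenario(seed = 20260920L))
write_dataset(res_sel$dataset,
              file.path(out_dir, "selective_scenario_tables.csv"),
              file.path(out_dir, "selective_scenario_relations.yaml"))

truths <- list(
  bivariate_subset = list(
    mu_true = as.list(truth_biv$mu_true),
    tau_true = unname(truth_biv$tau_true),
    rho_between_true = truth_biv$rho_between_true[1, 2],
    seed = truth_biv$seed),
  selective_scenario = list(
    mu_true = as.list(res_sel$truth$mu_true),
    tau_true = unname(res_sel$truth$tau_true),
    rho_between_true = res_sel$truth$rho_between_true[1, 2],
    missingness = res_sel$truth$missingness,
    seed = res_sel$truth$seed))
jsonlite::write_json(truths, file.path(out_dir, "truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat("Wrote datasets to", out_dir, "\n")
print(res_biv$dataset)
print(res_sel$dataset)
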