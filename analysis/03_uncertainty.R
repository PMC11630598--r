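#!/usr/bin/env Rscript
# Stage 3: uncertainty analysis. One-way (tornado) sensitivity over every
# uncertain parameter at its central 95% interval, then a 1,000-draw
# probabilistic sensitivity analysis with the cost-effectiveness plane
# quadrants and the acceptability curve, all under the societal perspective.

suppressPackageStartupMessages(library(bariaCEA))

params <- load_parameters()
lt <- default_life_table()
cfg <- params$config
out_dir <- "results"

message("One-way sensitivity (tornado) ...")
tor <- tornado_analysis(params, lt, perspective = "societal")
print(utils::head(tor, 10), digits = 6)
message("Widest bars: ", paste(utils::head(tor$parameter, 3), collapse = ", "))
write_result_csv(tor, file.path(out_dir, "tornado.csv"))

message(sprintf("PSA with %d draws (seed %d) ...", cfg$psa_draws, cfg$seed))
psa <- run_psa(params, lt, n_draws = cfg$psa_draws, seed = cfg$seed)
print(psa)
soc <- psa$summary$societal
write_result_csv(data.frame(draw = psa$draws$draw,
                            inc_cost = psa$draws$inc_cost_societal,
                            inc_qaly = psa$draws$inc_qaly),
                 file.path(out_dir, "psa_draws_societal.csv"))

cc <- ceac(psa)
at_thr <- ceac(psa, wtp_grid = cfg$wtp_threshold)$probability
message(sprintf(
  "%.0f%% of draws are cost-saving with QALY gains; %.0f%% cost-effective at %s baht/QALY.",
  100 * soc$quadrants[["se"]], 100 * at_thr,
  format(cfg$wtp_threshold, big.mark = ",")))
write_result_csv(cc, file.path(out_dir, "ceac_societal.csv"))
write_result_json(list(
  n_draws = psa$n, seed = psa$seed,
  societal = list(mean_inc_cost = soc$mean_inc_cost,
                  mean_inc_qaly = soc$mean_inc_qaly,
                  icer_ratio_of_means = soc$icer,
                  quadrants = as.list(soc$quadrants),
                  prob_cost_effective_at_threshold = at_thr),
  payer = list(icer_ratio_of_means = psa$summary$payer$icer)),
  file.path(out_dir, "psa_summary.json"))

run_manifest(out_dir,
             inputs = system.file("extdata",
                                  c("parameters.csv",
                                    "life_table_synthetic.csv",
                                    "run_config.yaml"),
                                  package = "bariaCEA"),
             seed = cfg$seed, command = "analysis/03_uncertainty.R")
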