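#!/usr/bin/env Rscript
# Base-case decision tree: expected surgeries and costs per strategy,
# and the incremental IFMI-minus-ST endpoints.

suppressPackageStartupMessages(library(ifmicost))

params <- load_parameters(system.file("extdata", "base_config.json",
                                      package = "ifmicost"))
dir.create("results", showWarnings = FALSE)

tab <- strategy_table(params$margins, params$costs)
inc <- incremental(params$margins, params$costs)

cat("Base case (positive margins: 30% ST, 10% IFMI, 10% second surgery)\n")
print(tab, row.names = FALSE)
cat(sprintf("\nIncremental (IFMI - ST): %.2f surgeries, %.0f EUR\n",
            inc$delta_surgeries, inc$delta_cost))
cat(sprintf("One-time IFMI add-on: %.2f EUR (agent %.0f, device %.0f, draping %.0f, staff %.0f, time delta %.2f)\n",
            ifmi_addon_cost(params$costs), params$costs$agent_cost,
            device_cost_per_surgery(params$costs$device_price,
                                    params$costs$maintenance_rate,
                                    params$costs$device_lifespan,
                                    params$costs$surgeries_per_year),
            params$costs$draping_cost, params$costs$staff_addon_cost,
            time_delta_cost(params$costs$prolongation,
                            params$costs$fsa_duration,
                            params$costs$staff_time_saving_factor,
                            params$costs$cost_per_minute,
                            params$costs$fsa_fixed_saving)))

write.csv(tab, "results/base_case_strategies.csv", row.names = FALSE)
jsonlite::write_json(
  list(delta_surgeries = inc$delta_surgeries, delta_cost = inc$delta_cost,
       ifmi = unclass(inc$ifmi), st = unclass(inc$st)),
  "results/base_case_incremental.json", auto_unbox = TRUE, digits = NA)
run_manifest("results", "base_case", params$seed, params$n_draws)
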