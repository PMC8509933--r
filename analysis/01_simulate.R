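#!/usr/bin/env Rscript
# Stage 1: simulate a study-scale dataset.
#
# Draws 607 spatial units with ground truth set to the headline two-regime
# fit (intercept 5, exponents 1.36 below / 0.92 above a knot at 82,363
# persons, log-noise SD 0.4), splits each unit into 1-6 counties, and
# writes the county-level CSVs the aggregation stage reads. The stored
# truth makes every downstream estimate checkable against known values.

suppressPackageStartupMessages(library(pillscaling))

seed <- 42L
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(n_units = 607, n_counties_per_unit = c(1, 6),
                        seed = seed)
cat(sprintf("simulating %d units (seed %d): beta1=%.2f beta2=%.2f knot=%s sigma=%.1f\n",
            cfg$n_units, cfg$seed, cfg$beta1_true, cfg$beta2_true,
            format(cfg$knot_true, big.mark = ","), cfg$sigma_noise))

d <- generate_units(cfg)
cty <- disaggregate_to_counties(d)

write.csv(cty$pills, file.path(out_dir, "county_pills.csv"), row.names = FALSE)
write.csv(cty$pops, file.path(out_dir, "county_population.csv"),
          row.names = FALSE)
write.csv(cty$xwalk, file.path(out_dir, "county_crosswalk.csv"),
          row.names = FALSE)
write_units_csv(d$units, file.path(out_dir, "units_truth.csv"))
jsonlite::write_json(
  cfg[c("n_units", "alpha_true", "beta1_true", "beta2_true", "knot_true",
        "sigma_noise", "seed")],
  file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA
)

cat(sprintf("wrote %d county-year pill rows across %d counties to %s\n",
            nrow(cty$pills), nrow(cty$xwalk), out_dir))
cat(sprintf("unit population range: %s - %s\n",
            format(round(min(d$units$pop_mean)), big.mark = ","),
            format(round(max(d$units$pop_mean)), big.mark = ",")))
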