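#!/usr/bin/env Rscript
# Stage 3: scaling fits and model comparison.
#
# On the aggregated unit table: (1) the single-exponent power law; (2) the
# exhaustive knot search and the two-regime fit at the selected knot;
# (3) AIC comparison of the two; (4) region-adjusted and region-stratified
# two-regime fits at the selected knot. Writes fit JSONs, the knot-search
# profile, and a summary table of exponents with regimes.

suppressPackageStartupMessages(library(pillscaling))

units <- read_units_csv("results/units.csv")
ll <- log_log_data(units)
dir.create("results/fits", showWarnings = FALSE, recursive = TRUE)

f_line <- fit_power_law(ll)
cat("single-regime model:\n")
print(f_line)
cat(sprintf("  regime: %s\n\n",
            classify_regime(f_line$beta, f_line$beta_ci)$regime))

ks <- search_knot(ll)
cat(sprintf("knot search over %d candidates selected %s (%.1fth percentile of unit population)\n",
            nrow(ks$profile), format(round(ks$knot), big.mark = ","),
            percentile_of(ks$knot, ll$population)))
f_pw <- ks$fit
print(f_pw)
cat(sprintf("  regime below: %s, above: %s\n",
            classify_regime(f_pw$beta1, f_pw$beta1_ci)$regime,
            classify_regime(f_pw$beta2, f_pw$beta2_ci)$regime))

cmp <- compare_aic(f_pw, f_line)
cat(sprintf("AIC spline %.1f vs line %.1f (delta %.1f) -> %s\n\n",
            cmp$aic_a, cmp$aic_b, cmp$delta,
            if (cmp$delta < 0) "two-regime model preferred"
            else "single-regime model preferred"))

f_adj <- fit_piecewise(ll, ks$knot, covariates = "region")
cat("region-adjusted two-regime fit:\n")
print(f_adj)

strat <- fit_stratified(ll, by = "region", knot = ks$knot)

write_fit_json(f_line, "results/fits/single_regime.json")
write_fit_json(f_pw, "results/fits/two_regime.json")
write_fit_json(f_adj, "results/fits/two_regime_region_adjusted.json")
for (r in names(strat)) {
  write_fit_json(strat[[r]], sprintf("results/fits/two_regime_%s.json",
                                     tolower(r)))
}
write.csv(ks$profile, "results/fits/knot_profile.csv", row.names = FALSE)

row_of <- function(label, f) {
  data.frame(model = label, n = f$n,
             beta1 = f$beta1, beta1_lo = f$beta1_ci[1],
             beta1_hi = f$beta1_ci[2],
             beta2 = f$beta2, beta2_lo = f$beta2_ci[1],
             beta2_hi = f$beta2_ci[2])
}
summary_tab <- rbind(
  row_of("unadjusted", f_pw),
  row_of("region-adjusted", f_adj),
  do.call(rbind, lapply(names(strat), function(r) {
    row_of(paste0("stratified: ", r), strat[[r]])
  }))
)
write.csv(summary_tab, "results/fits/exponent_table.csv", row.names = FALSE)
cat("stratified exponents:\n")
print(summary_tab, digits = 3, row.names = FALSE)

truth <- jsonlite::read_json("results/data/truth.json")
cat(sprintf("\nrecovery check vs simulation truth: beta1 %.3f (true %.2f), beta2 %.3f (true %.2f), knot %s (true %s)\n",
            f_pw$beta1, truth$beta1_true, f_pw$beta2, truth$beta2_true,
            format(round(ks$knot), big.mark = ","),
            format(truth$knot_true, big.mark = ",")))
cat("wrote results/fits/\n")
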