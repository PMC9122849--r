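#!/usr/bin/env Rscript
# Step 4: which landscape features drive floral resource availability?
#
# Single-predictor regressions of the index on each land-cover proportion
# and distance, per period, plus the Pearson correlation matrix of the
# explanatory variables.

library(floravail)

bundle <- load_tables("results/synthetic_inputs")
ft <- fai_table(bundle)
comp <- landscape_composition(bundle$landcover, bundle$distances)
lr <- landscape_fai_regressions(ft, comp)

write.csv(lr$regressions, "results/landscape_regressions.csv",
          row.names = FALSE)
write.csv(round(lr$correlations, 4), "results/correlations.csv")

sig <- lr$regressions[lr$regressions$p < 0.05, ]
cat("significant (p < 0.05) single-predictor relations with the index:\n")
print(transform(sig, estimate = signif(estimate, 3), se = signif(se, 3),
                t = round(t, 2), r2_mult = round(r2_mult, 3),
                p = signif(p, 2)), row.names = FALSE)

r <- lr$correlations
cat(sprintf("\ncorrelation(arable, urban): %.2f\n", r["arable", "urban"]))
cat("tables written to results/\n")
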