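#!/usr/bin/env Rscript
# Stage 6 — enrichment batteries over the candidate target genes.
#
# Knockdown-DE enrichment per lncRNA (one-sided Fisher, FDR <= 0.1 in at
# least one ASO, >= 3 DE targets for the headline), GO-style term
# enrichment, TFBS motif batteries with Fisher-combined p-values, target
# expression-correlation preferences, and the RBP batteries (eCLIP target
# filter, knockdown response, ChIP promoter co-occurrence with and without
# PPI expansion, and the bound-vs-unbound N/C comparison).

suppressMessages(library(lnct3d))
cfg <- lnct_config(outdir = "results/run", seed = 1)
run_pipeline(cfg, stages = "enrich")

d <- cfg$outdir
kd <- readr::read_tsv(file.path(d, "kd_enrichment.tsv"),
                      show_col_types = FALSE)
go <- readr::read_tsv(file.path(d, "go_enrichment.tsv"),
                      show_col_types = FALSE)
corr <- readr::read_tsv(file.path(d, "correlation_preference.tsv"),
                        show_col_types = FALSE)
summ <- jsonlite::read_json(file.path(d, "enrich_summary.json"))

cat("Knockdown-DE enrichment (direction = up):\n")
print(as.data.frame(kd[, c("lncrna", "log2_or", "p_value",
                           "n_de_targets", "included")]))
cat(sprintf("Combined p-value (Fisher's method): %.3g\n",
            summ$kd_combined_p))
cat("Significant GO-style terms:", sum(go$significant), "across",
    length(unique(go$lncrna)), "lncRNAs\n")
cat(sprintf("Target correlation: %.1f%% positive / %.1f%% negative at p <= 0.01\n",
            mean(corr$pct_sig_pos), mean(corr$pct_sig_neg)))
cat("RBP batteries, Fisher-combined p-values:\n")
str(summ$rbp_combined)
cat(sprintf("Bound vs unbound lncRNA N/C ratio (one-tailed U test): p = %.3g (%d vs %d)\n",
            summ$rbp_nc_test$p_value, summ$rbp_nc_test$n_bound,
            summ$rbp_nc_test$n_unbound))
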