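#!/usr/bin/env Rscript

# Step 3 — the LIN28 stemness window and phenotype enrichment.
#
# Places the stemness window (middle 30% of median +/- one IQR of pooled
# LIN28, averaged across replicates) and computes p1 = P(window | phenotype)
# and p2 = P(phenotype | window) per replicate, plus the window-width
# sensitivity sweep. Outputs, under results/:
#   base_enrichment.csv           p1/p2 per phenotype per replicate
#   base_enrichment_summary.csv   mean +/- SD across replicates
#   base_window_sensitivity.csv   composition vs window fraction

library(empstem)

z <- read.csv("results/base_solutions_labeled.csv")
z$label <- factor(z$label, levels = c("e", "he", "hm", "m"))

w <- stemness_window(z$LIN28, z$replicate, f = 0.30)
cat(sprintf("Stemness window on LIN28 (z scale): [%.3f, %.3f]\n",
            w$lower, w$upper))

cp <- conditional_probabilities(z$label, z$LIN28, w, z$replicate)
write.csv(cp$per_replicate, "results/base_enrichment.csv", row.names = FALSE)
write.csv(cp$summary, "results/base_enrichment_summary.csv", row.names = FALSE)
print(cp$summary, digits = 3)

hyb <- function(col) sum(cp$summary[[col]][cp$summary$phenotype %in% c("he", "hm")])
non <- function(col) sum(cp$summary[[col]][cp$summary$phenotype %in% c("e", "m")])
cat(sprintf("hybrids p1 %.3f vs e+m %.3f; hybrids p2 %.3f vs e+m %.3f\n",
            hyb("p1_mean"), non("p1_mean"), hyb("p2_mean"), non("p2_mean")))

ws <- window_sensitivity(z$label, z$LIN28, z$replicate,
                         f_list = c(0.1, 0.2, 0.3, 1 / 3, 0.4, 0.5, 0.75, 1))
write.csv(ws, "results/base_window_sensitivity.csv", row.names = FALSE)
hyb_f <- vapply(split(ws, ws$f),
                function(d) sum(d$p2[d$phenotype %in% c("he", "hm")]), 0)
cat("Hybrid share of the window by fraction f:\n")
print(round(hyb_f, 3))
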