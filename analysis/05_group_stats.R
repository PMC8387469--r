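#!/usr/bin/env Rscript
# Stage 5 — group statistics over the bout table.
#
# Compares trained vs yoked animals on total presses, bout frequency, bout
# density and solitary presses (two-tailed t tests), mirroring the standard
# reporting of retention-test microstructure: learning expresses itself as
# more bouts, not more presses per bout.

library(striatlearn)

out_dir <- "results/stats"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
tab <- read.table("results/bouts/bout_summaries.tsv", header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE)

outcomes <- c("n_presses", "bout_frequency", "bout_density", "n_solitary")
rows <- lapply(outcomes, function(oc) {
  d <- data.frame(value = tab[[oc]], group = tab$group)
  d <- d[is.finite(d$value), ]
  cmp <- group_compare(d, "t")
  data.frame(outcome = oc,
             mean_trained = mean(d$value[d$group == "trained"]),
             mean_yoked = mean(d$value[d$group == "yoked"]),
             t = cmp$statistic, df = cmp$df, p = cmp$p)
})
res <- do.call(rbind, rows)
res$p_adj <- p.adjust(res$p, "holm")
write.table(res, file.path(out_dir, "group_comparisons.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(res, digits = 3)
cat("stats written to", out_dir, "\n")
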