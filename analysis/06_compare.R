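#!/usr/bin/env Rscript
# Statistical comparison of LD levels: Mann-Whitney between habitats,
# Kruskal-Wallis across populations (and within habitats), and the nested
# ANCOVA controlling for inter-marker distance, Bonferroni-adjusted.

library(msatLD)

rec <- read.delim(file.path("results", "ld_pairs.tsv"))

# habitat pairs (coastal freshwater treated as its own unit)
rec$unit <- ifelse(rec$coastal, "coastal", rec$habitat)
by_unit <- split(rec, rec$unit)
cmp <- compare_ld_units(lapply(by_unit, function(d) d))
write.table(cmp, file.path("results", "habitat_mannwhitney.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(cmp)))
  cat(sprintf("%s vs %s: U = %.0f, Z = %.2f, p_adj = %.2g\n",
              cmp$unitA[i], cmp$unitB[i], cmp$U[i], cmp$Z[i],
              cmp$p_adjusted[i]))

kw_all <- kruskal_wallis(split(rec$dprime, rec$population))
cat(sprintf("across all populations: chi2 = %.2f, df = %d, p = %.2g\n",
            kw_all$chi2, kw_all$df, kw_all$p_value))
kw_rows <- data.frame(scope = "all_populations", chi2 = kw_all$chi2,
                      df = kw_all$df, p = kw_all$p_value)
for (h in unique(rec$habitat)) {
  sub <- rec[rec$habitat == h, ]
  if (length(unique(sub$population)) < 2) next
  kw <- kruskal_wallis(split(sub$dprime, sub$population))
  kw_rows <- rbind(kw_rows, data.frame(scope = h, chi2 = kw$chi2,
                                       df = kw$df, p = kw$p_value))
}
write.table(kw_rows, file.path("results", "kruskal_wallis.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

ft <- ancova_ld(rec)
write.table(ft, file.path("results", "ancova.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("ANCOVA (D' ~ distance + habitat + population-within-habitat):\n")
print(ft, row.names = FALSE)
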