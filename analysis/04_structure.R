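#!/usr/bin/env Rscript
# Population structure: pairwise Weir-Cockerham F_ST with permutation
# tests, hierarchical AMOVA under three groupings, and within-population
# Queller-Goodnight relatedness.

library(msatLD)

src <- file.path("results", "simulated_study")
ds <- read_genepop(file.path(src, "genotypes.gen"),
                   file.path(src, "habitat_table.tsv"))

fm <- fst_matrix(ds, n_perm = 199, seed = 1234)
write.table(round(fm$theta, 4), file.path("results", "fst_matrix.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)
write.table(fm$p, file.path("results", "fst_pvalues.tsv"), sep = "\t",
            quote = FALSE, col.names = NA)
th <- fm$theta[upper.tri(fm$theta)]
m <- sum(!is.na(th))
sig <- sum(fm$p[upper.tri(fm$p)] < 0.05, na.rm = TRUE)
cat(sprintf("pairwise F_ST range %.3f-%.3f; %d/%d with permutation p < 0.05\n",
            min(th, na.rm = TRUE), max(th, na.rm = TRUE), sig, m))
cat(sprintf(paste0("(Bonferroni threshold 0.05/%d = %.6f needs >= %d\n",
                   " permutations; raise n_perm for a final run)\n"),
            m, 0.05 / m, ceiling(m / 0.05)))

hab <- vapply(ds$pops, `[[`, "", "habitat")
groupings <- list(
  habitat_type_I = hab,
  habitat_type_II = ifelse(hab == "marine", "marine", "freshwater"),
  geography = c(mar1 = "g1", criv = "g1", mar2 = "g2", clak = "g2",
                lak1 = "g3", pon3 = "g3", lak2 = "g4", pon2 = "g4",
                pon1 = "g4", cpon = "g5", mar3 = "g5", lak3 = "g6",
                lak4 = "g7")[pop_names(ds)])
am_rows <- list()
for (g in names(groupings)) {
  gr <- stats::setNames(groupings[[g]], pop_names(ds))
  am <- amova(ds, gr, n_perm = 499, seed = 99)
  am_rows[[g]] <- data.frame(
    grouping = g,
    component = names(am$percent),
    percent = round(unname(am$percent), 2),
    p = c(unname(am$p_values), NA))
  cat(sprintf("%s: among-groups %.2f%% (p = %s)\n", g,
              am$percent["among_groups"],
              format(am$p_values["among_groups"], digits = 3)))
}
write.table(do.call(rbind, am_rows), file.path("results", "amova.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

rel <- do.call(rbind, lapply(pop_names(ds), function(p) {
  r <- relatedness_qg(ds, p)
  v <- r[upper.tri(r)]
  data.frame(population = p, mean_r = mean(v, na.rm = TRUE),
             max_r = max(v, na.rm = TRUE),
             frac_above_0.2 = mean(v > 0.2, na.rm = TRUE))
}))
write.table(rel, file.path("results", "relatedness.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("mean within-population relatedness range: %.3f-%.3f\n",
            min(rel$mean_r), max(rel$mean_r)))
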