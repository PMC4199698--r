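test_that("observed heterozygosity matches a per-individual tally", {
  ds <- one_pop_ds(cbind(c(1L, 1L)), cbind(c(2L, 2L)))
  expect_equal(observed_heterozygosity(ds, "p1")$mean, 1)
  ds0 <- one_pop_ds(cbind(c(1L, 2L)), cbind(c(1L, 2L)))
  expect_equal(observed_heterozygosity(ds0, "p1")$mean, 0)
  expect_error(observed_heterozygosity(ds0, "nope"), "unknown population")
  set.seed(31)
  for (i in 1:10) {
    ds <- random_ds(n_pops = 1, n_ind = 10, n_loci = 4, miss_rate = 0.2)
    ho <- observed_heterozygosity(ds, "pop1")$per_locus
    p <- ds$pops$pop1
    for (l in seq_along(ds$loci)) {
      ok <- !is.na(p$a1[, l])
      if (!any(ok)) { expect_true(is.na(ho[l])); next }
      expect_equal(unname(ho[l]), sum(p$a1[ok, l] != p$a2[ok, l]) /
                     sum(ok))
    }
  }
})

test_that("expected heterozygosity uses Nei's unbiased correction", {
  ds <- one_pop_ds(cbind(c(1L, 1L)), cbind(c(1L, 1L)))
  expect_equal(expected_heterozygosity(ds, "p1")$mean, 0)
  ds2 <- one_pop_ds(cbind(c(1L, 1L)), cbind(c(2L, 2L)))
  expect_equal(expected_heterozygosity(ds2, "p1")$mean, 2 / 3,
               tolerance = 1e-12)
  # unbiased estimate >= plug-in 1 - sum p^2 at finite n
  set.seed(32)
  for (i in 1:10) {
    ds3 <- random_ds(n_pops = 1, n_ind = 8, n_loci = 3, miss_rate = 0.1)
    he <- expected_heterozygosity(ds3, "pop1")$per_locus
    p <- ds3$pops$pop1
    for (l in seq_along(ds3$loci)) {
      al <- c(p$a1[, l], p$a2[, l]); al <- al[!is.na(al)]
      if (length(al) < 2) next
      plugin <- 1 - sum((table(al) / length(al))^2)
      expect_gte(he[l] + 1e-12, plugin)
    }
  }
})

test_that("F_IS is -1 for complete heterozygote excess and ~0 under HWE", {
  ds <- one_pop_ds(cbind(rep(1L, 6), rep(3L, 6)),
                   cbind(rep(2L, 6), rep(4L, 6)))
  f <- fis_with_ci(ds, "p1", n_boot = 100, seed = 1)
  expect_equal(f$fis, -1, tolerance = 1e-12)
  g <- hwe_pop(500, list(c(0.4, 0.3, 0.3), c(0.6, 0.4), c(0.2, 0.5, 0.3),
                         c(0.25, 0.25, 0.5), c(0.5, 0.5)), seed = 5)
  dsh <- one_pop_ds(g$a1, g$a2)
  fh <- fis_with_ci(dsh, "p1", n_boot = 300, seed = 2)
  expect_lt(abs(fh$fis), 0.05)
  expect_true(fh$ci[1] <= 0 && fh$ci[2] >= 0)
  # monomorphic-only data flagged undefined
  dsm <- one_pop_ds(cbind(c(1L, 1L)), cbind(c(1L, 1L)))
  expect_true(fis_with_ci(dsm, "p1")$undefined)
})

test_that("rarefied allelic richness matches direct combinatorics", {
  # monomorphic locus: Ar = 1 for any g
  dsm <- one_pop_ds(cbind(rep(1L, 4)), cbind(rep(1L, 4)))
  expect_equal(allelic_richness(dsm, g = 2)$pops$p1$mean, 1)
  # two equifrequent alleles, N = 4 copies, g = 2 -> 5/3
  ds <- one_pop_ds(cbind(c(1L, 2L)), cbind(c(1L, 2L)))
  expect_equal(allelic_richness(ds, g = 2)$pops$p1$mean, 5 / 3,
               tolerance = 1e-12)
  # g = N recovers the observed allele count; monotone in g
  ds2 <- one_pop_ds(cbind(c(1L, 2L, 3L)), cbind(c(1L, 1L, 2L)))
  expect_equal(allelic_richness(ds2, g = 6)$pops$p1$mean, 3,
               tolerance = 1e-12)
  ar_prev <- 0
  for (g in 2:6) {
    ar <- allelic_richness(ds2, g = g)$pops$p1$mean
    expect_gte(ar + 1e-12, ar_prev)
    ar_prev <- ar
  }
  expect_error(allelic_richness(ds, g = 1), "g must be >= 2")
})

test_that("private allelic richness matches exhaustive subsampling", {
  # allele private and fixed in the focal population contributes 1
  two <- list(
    f = list(habitat = "marine", coastal = FALSE,
             a1 = cbind(rep(1L, 3)), a2 = cbind(rep(1L, 3))),
    o = list(habitat = "pond", coastal = FALSE,
             a1 = cbind(rep(2L, 3)), a2 = cbind(rep(2L, 3))))
  ds <- gtds(two, "L1")
  pr <- private_allelic_richness(ds, g = 2)
  expect_equal(pr$pops$f$mean, 1, tolerance = 1e-12)
  # allele fixed in all populations contributes 0
  same <- list(
    f = list(habitat = "marine", coastal = FALSE,
             a1 = cbind(rep(1L, 3)), a2 = cbind(rep(1L, 3))),
    o = list(habitat = "pond", coastal = FALSE,
             a1 = cbind(rep(1L, 3)), a2 = cbind(rep(1L, 3))))
  expect_equal(private_allelic_richness(gtds(same, "L1"),
                                        g = 2)$pops$f$mean, 0,
               tolerance = 1e-12)
  # 3-population toy vs exhaustive enumeration over all g-subsets
  set.seed(41)
  ds3 <- random_ds(n_pops = 3, n_ind = 3, n_loci = 2, n_alleles = 3,
                   miss_rate = 0)
  g <- 4
  pr3 <- private_allelic_richness(ds3, g = g)
  enum_prob_in <- function(copies, a, g) {
    cs <- utils::combn(length(copies), g)
    mean(apply(cs, 2, function(ix) a %in% copies[ix]))
  }
  for (f in names(ds3$pops)) {
    for (l in seq_along(ds3$loci)) {
      cf <- c(ds3$pops[[f]]$a1[, l], ds3$pops[[f]]$a2[, l])
      others <- setdiff(names(ds3$pops), f)
      expected <- 0
      for (a in unique(cf)) {
        term <- enum_prob_in(cf, a, g)
        for (o in others) {
          co <- c(ds3$pops[[o]]$a1[, l], ds3$pops[[o]]$a2[, l])
          term <- term * (1 - enum_prob_in(co, a, g))
        }
        expected <- expected + term
      }
      expect_equal(unname(pr3$pops[[f]]$per_locus[l]), expected,
                   tolerance = 1e-9)
    }
  }
  expect_error(private_allelic_richness(one_pop_ds(cbind(1L),
                                                   cbind(2L))),
               ">= 2 populations")
})

test_that("rare-allele proportion counts sub-threshold alleles", {
  ds <- one_pop_ds(cbind(rep(1L, 10)), cbind(c(rep(1L, 9), 2L)))
  # allele 2 at frequency 1/20 = 0.05: not strictly below threshold
  expect_equal(rare_allele_proportion(ds, "p1"), 0)
  ds2 <- one_pop_ds(cbind(rep(c(1L, 2L, 3L, 4L), 7)),
                    cbind(c(rep(c(1L, 2L, 3L, 4L), 6), 1L, 2L, 3L, 1L)))
  aft <- allele_frequencies(ds2)
  frs <- aft$pops$p1$freq$L1
  expect_equal(rare_allele_proportion(ds2, "p1"), mean(frs < 0.05))
  # 1 of 4 alleles below 5%
  a1 <- cbind(rep(c(10L, 20L, 30L), 8))
  a2 <- cbind(c(rep(c(10L, 20L, 30L), 7), 10L, 20L, 40L))
  expect_equal(rare_allele_proportion(one_pop_ds(a1, a2), "p1"), 0.25)
})

test_that("diversity summary table is coherent", {
  set.seed(51)
  ds <- random_ds(n_pops = 3, n_ind = 8, n_loci = 5, miss_rate = 0.1)
  dv <- diversity_summary(ds, n_boot = 50, seed = 3)
  expect_identical(dv$population, names(ds$pops))
  expect_true(all(dv$npl <= length(ds$loci)))
  expect_true(all(dv$A >= dv$npl))
  expect_true(all(dv$H_O >= 0 & dv$H_O <= 1))
  expect_true(all(dv$H_E >= 0 & dv$H_E <= 1))
  expect_true(all(dv$rare_allele_prop >= 0 & dv$rare_allele_prop <= 1))
})
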