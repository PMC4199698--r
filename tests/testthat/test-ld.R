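test_that("EM recovers haplotype frequencies", {
  # unambiguous double homozygotes: exact 0.5/0.5 diagonal
  ds <- one_pop_ds(cbind(c(1L, 1L, 2L, 2L), c(5L, 5L, 6L, 6L)),
                   cbind(c(1L, 1L, 2L, 2L), c(5L, 5L, 6L, 6L)),
                   loci = c("A", "B"))
  h <- em_haplotype_frequencies(ds, "p1", "A", "B")
  expect_equal(unname(h$freq), matrix(c(0.5, 0, 0, 0.5), 2),
               tolerance = 1e-12)
  # a single double heterozygote stays at the product fixed point
  ds1 <- one_pop_ds(cbind(1L, 5L), cbind(2L, 6L), loci = c("A", "B"))
  h1 <- em_haplotype_frequencies(ds1, "p1", "A", "B")
  expect_equal(unname(h1$freq), matrix(0.25, 2, 2), tolerance = 1e-12)
  # sampling consistency: 500 individuals from known haplotype frequencies
  truth <- matrix(c(0.4, 0.05, 0.1, 0.25, 0.05, 0.15), 2, 3)
  ds5 <- genotypes_from_haps(500, truth, seed = 61)
  h5 <- em_haplotype_frequencies(ds5, "p1", "A", "B")
  se <- sqrt(truth * (1 - truth) / 1000)
  expect_true(all(abs(h5$freq - truth) < 3 * se + 0.02))
})

test_that("EM margins equal observed allele frequencies, loglik monotone", {
  set.seed(62)
  for (i in 1:15) {
    ds <- random_ds(n_pops = 1, n_ind = 12, n_loci = 2, n_alleles = 4,
                    miss_rate = 0.15)
    p <- ds$pops$pop1
    ok <- !is.na(p$a1[, 1]) & !is.na(p$a1[, 2])
    if (sum(ok) < 2) next
    if (length(unique(c(p$a1[ok, 1], p$a2[ok, 1]))) < 2) next
    h <- em_haplotype_frequencies(ds, "pop1", "L1", "L2",
                                  loglik_trace = TRUE)
    alA <- c(p$a1[ok, 1], p$a2[ok, 1]); alB <- c(p$a1[ok, 2], p$a2[ok, 2])
    expect_equal(unname(h$pA),
                 as.numeric(table(alA) / length(alA)), tolerance = 1e-8)
    expect_equal(unname(h$pB),
                 as.numeric(table(alB) / length(alB)), tolerance = 1e-8)
    expect_true(all(diff(h$loglik_trace) > -1e-9))
    expect_equal(sum(h$freq), 1, tolerance = 1e-9)
  }
})

test_that("multiallelic D' and r2 match the term-by-term oracle", {
  # complete association, biallelic
  h <- hap_freq(matrix(c(0.5, 0, 0, 0.5), 2))
  expect_equal(dprime_multiallelic(h), 1, tolerance = 1e-12)
  # independence
  hi <- hap_freq(outer(c(0.3, 0.7), c(0.2, 0.3, 0.5)))
  expect_equal(dprime_multiallelic(hi), 0, tolerance = 1e-12)
  expect_equal(r2_multiallelic(hi), 0, tolerance = 1e-12)
  # spec'd biallelic case: D = 0.15, r2 = 0.36
  hb <- hap_freq(matrix(c(0.4, 0.1, 0.1, 0.4), 2))
  expect_equal(r2_multiallelic(hb), 0.36, tolerance = 1e-12)
  # random tables vs explicit double-loop oracle
  set.seed(63)
  for (i in 1:200) {
    k <- sample(2:5, 1); l <- sample(2:5, 1)
    f <- random_hap_table(k, l)
    h <- hap_freq(f)
    expect_equal(dprime_multiallelic(h), oracle_dprime(f),
                 tolerance = 1e-12)
    expect_equal(r2_multiallelic(h), oracle_r2(f), tolerance = 1e-12)
  }
})

test_that("biallelic tables reduce to the classical closed forms", {
  set.seed(64)
  for (i in 1:100) {
    f <- random_hap_table(2, 2)
    pA <- rowSums(f)[1]; pB <- colSums(f)[1]
    D <- f[1, 1] - pA * pB
    Dmax <- if (D < 0) min(pA * pB, (1 - pA) * (1 - pB)) else
      min(pA * (1 - pB), pB * (1 - pA))
    h <- hap_freq(f)
    expect_equal(dprime_multiallelic(h), abs(D / Dmax), tolerance = 1e-12)
    expect_equal(r2_multiallelic(h),
                 D^2 / (pA * (1 - pA) * pB * (1 - pB)), tolerance = 1e-12)
  }
})

test_that("D' stays in [0,1] over random frequency tables", {
  set.seed(65)
  for (i in 1:1000) {
    f <- random_hap_table(sample(2:6, 1), sample(2:6, 1))
    d <- dprime_multiallelic(hap_freq(f))
    expect_gte(d, 0); expect_lte(d, 1 + 1e-12)
  }
  # monomorphic locus flagged undefined
  expect_true(is.na(dprime_multiallelic(hap_freq(matrix(c(0.6, 0.4), 1)))))
})

test_that("composite LD behaves like its haplotypic counterpart", {
  # double homozygotes in complete association
  ds <- one_pop_ds(cbind(c(1L, 1L, 2L, 2L), c(5L, 5L, 6L, 6L)),
                   cbind(c(1L, 1L, 2L, 2L), c(5L, 5L, 6L, 6L)),
                   loci = c("A", "B"))
  cp <- composite_ld(ds, "p1", "A", "B")
  expect_equal(cp$composite_dprime, 1, tolerance = 1e-12)
  # random union of independent haplotypes: near zero
  f_ind <- outer(c(0.5, 0.5), c(0.5, 0.5))
  dsi <- genotypes_from_haps(1000, f_ind, seed = 66)
  cpi <- composite_ld(dsi, "p1", "A", "B")
  expect_lt(abs(cpi$composite_dprime), 0.2)
  expect_lt(cpi$composite_r2, 0.02)
  # without double heterozygotes the composite Delta equals haplotypic D
  set.seed(67)
  for (i in 1:10) {
    a_hom <- sample(1:3, 8, TRUE)
    b1 <- sample(5:7, 8, TRUE); b2 <- sample(5:7, 8, TRUE)
    ds2 <- one_pop_ds(cbind(a_hom, b1), cbind(a_hom, b2),
                      loci = c("A", "B"))
    if (length(unique(a_hom)) < 2 ||
        length(unique(c(b1, b2))) < 2) next
    cp2 <- composite_ld(ds2, "p1", "A", "B")
    h2 <- em_haplotype_frequencies(ds2, "p1", "A", "B")
    D <- h2$freq - outer(h2$pA, h2$pB)
    expect_equal(unname(cp2$delta), unname(D), tolerance = 1e-12)
  }
})

test_that("syntenic scans honour the map, polymorphism and rare-allele
           exclusion", {
  map <- marker_map(data.frame(
    marker = c("a", "b", "c", "d", "e"),
    lg = c("LG1", "LG1", "LG1", "LG2", "LG2"),
    position_mb = c(0, 1, 3, 0, 2)))
  set.seed(68)
  g <- hwe_pop(12, rep(list(c(0.5, 0.3, 0.2)), 5), seed = 68)
  ds <- one_pop_ds(g$a1, g$a2, loci = c("a", "b", "c", "d", "e"))
  rec <- syntenic_ld_scan(ds, map, "p1")
  expect_equal(nrow(rec), choose(3, 2) + choose(2, 2))
  expect_true(all(rec$distance_mb > 0))
  # monomorphic locus drops its pairs
  dsm <- ds
  dsm$pops$p1$a1[, "b"] <- 120L; dsm$pops$p1$a2[, "b"] <- 120L
  recm <- syntenic_ld_scan(dsm, map, "p1")
  expect_equal(nrow(recm), 1 + 1)  # (a,c) on LG1 and (d,e) on LG2
  # all markers on distinct LGs: no syntenic pair
  map1 <- marker_map(data.frame(marker = c("a", "b", "c", "d", "e"),
                                lg = paste0("LG", 1:5),
                                position_mb = 0))
  expect_equal(nrow(syntenic_ld_scan(ds, map1, "p1")), 0)
  # rare-allele exclusion never increases allele counts
  g2 <- hwe_pop(40, rep(list(c(0.55, 0.42, 0.03)), 5), seed = 69)
  ds2 <- one_pop_ds(g2$a1, g2$a2, loci = c("a", "b", "c", "d", "e"))
  r_all <- syntenic_ld_scan(ds2, map, "p1")
  r_ex <- syntenic_ld_scan(ds2, map, "p1", exclude_rare = TRUE)
  common <- merge(r_all, r_ex, by = c("locusA", "locusB"))
  expect_true(all(common$n_alleles_A.y <= common$n_alleles_A.x))
  expect_true(all(common$n_alleles_B.y <= common$n_alleles_B.x))
})

test_that("distance bins and their errors are right", {
  rec1 <- data.frame(distance_mb = 2, dprime = 0.6)
  b1 <- bin_ld_by_distance(rec1)
  expect_equal(b1$mean[b1$bin == "[0,5]"], 0.6)
  expect_equal(b1$error[b1$bin == "[0,5]"], 0)
  expect_equal(b1$n_pairs[b1$bin == "(5,10]"], 0)
  expect_true(is.na(b1$mean[b1$bin == "(5,10]"]))
  rec2 <- data.frame(distance_mb = c(0.5, 7), dprime = c(0.4, 0.8))
  b2 <- bin_ld_by_distance(rec2)
  expect_equal(b2$mean[b2$bin == "overall"], 0.6)
  set.seed(70)
  rec10 <- data.frame(distance_mb = runif(10, 0, 4),
                      dprime = runif(10))
  b10 <- bin_ld_by_distance(rec10)
  expect_equal(b10$error[b10$bin == "[0,5]"],
               sd(rec10$dprime) / sqrt(10), tolerance = 1e-12)
  # right-closed edges: 5.0 in the first bin, 5.001 in the second
  rec_e <- data.frame(distance_mb = c(5, 5.001), dprime = c(0.1, 0.9))
  be <- bin_ld_by_distance(rec_e)
  expect_equal(be$mean[be$bin == "[0,5]"], 0.1)
  expect_equal(be$mean[be$bin == "(5,10]"], 0.9)
})

test_that("log-distance decay fits recover closed forms", {
  d <- exp(seq(log(0.2), log(30), length.out = 20))
  # exact line in ln-distance: half-length e^4
  rec <- data.frame(distance_mb = d, dprime = 0.9 - 0.1 * log(d))
  f <- suppressWarnings(fit_ld_decay(rec))  # noise-free line
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_equal(f$half_length_mb, exp(4), tolerance = 1e-6)
  # constant response: zero slope, no half-length
  recc <- data.frame(distance_mb = d, dprime = 0.6)
  fc <- fit_ld_decay(recc)
  expect_equal(fc$slope, 0, tolerance = 1e-12)
  expect_equal(fc$r_squared, 0)
  expect_true(is.na(fc$half_length_mb))
  # all distances equal: degenerate flag
  fd <- fit_ld_decay(data.frame(distance_mb = rep(2, 5),
                                dprime = runif(5)))
  expect_true(fd$degenerate)
  expect_error(fit_ld_decay(data.frame(distance_mb = 1:2,
                                       dprime = c(0.1, 0.2))), ">= 3")
})

test_that("D'-r2 correlations match first-principles oracles", {
  rec <- data.frame(dprime = seq(0.1, 0.9, length.out = 9),
                    r2 = seq(0.1, 0.9, length.out = 9))
  cc <- ld_measure_correlation(rec)
  expect_equal(cc$pearson_r, 1, tolerance = 1e-12)
  expect_equal(cc$kendall_tau, 1, tolerance = 1e-12)
  rec2 <- data.frame(dprime = 1:9, r2 = 9:1)
  expect_equal(ld_measure_correlation(rec2)$kendall_tau, -1,
               tolerance = 1e-12)
  set.seed(71)
  x <- runif(20); y <- x^2 + rnorm(20, 0, 0.1)
  rec3 <- data.frame(dprime = x, r2 = y)
  c3 <- ld_measure_correlation(rec3)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  conc <- 0
  for (i in 1:19) for (j in (i + 1):20)
    conc <- conc + sign(x[j] - x[i]) * sign(y[j] - y[i])
  tau_hand <- conc / choose(20, 2)
  expect_equal(c3$pearson_r, r_hand, tolerance = 1e-12)
  expect_equal(c3$kendall_tau, tau_hand, tolerance = 1e-12)
  # zero variance flagged
  expect_true(ld_measure_correlation(
    data.frame(dprime = rep(0.5, 5), r2 = runif(5)))$undefined)
})
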