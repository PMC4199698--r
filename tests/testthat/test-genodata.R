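test_that("GenePop files round-trip through write/read, missing included", {
  set.seed(11)
  habs_of <- function(ds) data.frame(
    population = names(ds$pops),
    habitat = vapply(ds$pops, `[[`, "", "habitat"),
    coastal = vapply(ds$pops, function(p) isTRUE(p$coastal), logical(1)))
  for (i in 1:100) {
    ds <- random_ds(n_pops = sample(1:3, 1), n_ind = sample(2:6, 1),
                    n_loci = sample(1:5, 1), miss_rate = 0.2)
    gp <- tempfile(fileext = ".gen")
    write_genepop(ds, gp)
    ds2 <- read_genepop(gp, habs_of(ds))
    expect_identical(ds2$loci, ds$loci)
    expect_identical(names(ds2$pops), names(ds$pops))
    for (p in names(ds$pops)) {
      expect_identical(unname(ds2$pops[[p]]$a1), unname(ds$pops[[p]]$a1))
      expect_identical(unname(ds2$pops[[p]]$a2), unname(ds$pops[[p]]$a2))
      expect_identical(ds2$pops[[p]]$habitat, ds$pops[[p]]$habitat)
    }
    unlink(gp)
  }
})

test_that("both GenePop dialects parse; all-zero genotypes are missing", {
  habs <- data.frame(population = c("al", "be"),
                     habitat = c("marine", "pond"), coastal = FALSE)
  # 6-digit dialect, one missing genotype
  ds <- read_genepop_text(c(
    "toy", "locA", "locB", "Pop",
    "al_1 , 120120 130134",
    "al_2 , 120120 000000",
    "Pop",
    "be_1 , 120124 130130"), habs)
  expect_identical(names(ds$pops), c("al", "be"))
  expect_identical(ds$pops$al$a1[1, ], c(locA = 120L, locB = 130L))
  expect_true(all(is.na(ds$pops$al$a1[2, "locB"])))
  expect_identical(sort(unique(ds$pops$be$a1[, "locA"])), 120L)
  # 4-digit dialect; half-missing treated as fully missing
  ds4 <- read_genepop_text(c(
    "toy", "locA", "Pop",
    "al_1 , 1212",
    "al_2 , 1200",
    "Pop",
    "be_1 , 1213"), habs)
  expect_identical(ds4$pops$al$a1[1, 1], c(locA = 12L))
  expect_true(is.na(ds4$pops$al$a1[2, 1]) && is.na(ds4$pops$al$a2[2, 1]))
})

test_that("parse and validation errors are specific", {
  habs <- data.frame(population = "al", habitat = "marine",
                     coastal = FALSE)
  expect_error(read_genepop_text(c("t", "locA", "Pop", "al_1 , 12xx"),
                                 habs), "line")
  expect_error(read_genepop_text(c("t", "locA", "Pop", "al_1 , 1212"),
                                 data.frame(population = "ghost",
                                            habitat = "marine",
                                            coastal = FALSE)),
               "ghost|not listed")
  # genotype count mismatch names the line
  expect_error(read_genepop_text(c("t", "locA", "locB", "Pop",
                                   "al_1 , 1212"), habs), "expected 2")
})

test_that("marker map validates and summarises intervals", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("marker\tlg\tposition_mb",
               "m1\tLG1\t0.0", "m2\tLG1\t2.0", "m3\tLG2\t5.0"), tf)
  m <- read_marker_map(tf)
  expect_s3_class(m, "marker_map")
  expect_identical(sort(table(m$lg), decreasing = TRUE),
                   sort(table(c("LG1", "LG1", "LG2")), decreasing = TRUE))
  expect_error(marker_map(data.frame(marker = c("a", "a"), lg = "LG1",
                                     position_mb = c(0, 1))), "duplicate")
  expect_error(marker_map(data.frame(marker = c("a", "b"), lg = "LG1",
                                     position_mb = c(0, -1))),
               "non-negative")
  s <- map_interval_summary(marker_map(data.frame(
    marker = c("a", "b", "c"), lg = "LG1", position_mb = c(0, 2, 5))))
  expect_equal(s$mean_mb, 2.5)
  expect_equal(s$median_mb, 2.5)
  # a mapped marker absent from the dataset is tolerated: the scan simply
  # uses the intersection
  ds <- one_pop_ds(cbind(c(1L, 2L)), cbind(c(1L, 2L)), loci = "a")
  m2 <- marker_map(data.frame(marker = c("a", "zz"), lg = "LG1",
                              position_mb = c(0, 1)))
  expect_no_error(syntenic_ld_scan(ds, m2, "p1"))
})

test_that("allele frequencies match a direct tally oracle", {
  ds <- one_pop_ds(cbind(c(120L, 120L)), cbind(c(120L, 124L)))
  aft <- allele_frequencies(ds)
  expect_equal(aft$pops$p1$freq$L1, c(`120` = 0.75, `124` = 0.25))
  # all-missing locus flagged absent
  ds2 <- one_pop_ds(cbind(c(NA, NA), c(1L, 1L)),
                    cbind(c(NA, NA), c(1L, 2L)))
  aft2 <- allele_frequencies(ds2)
  expect_null(aft2$pops$p1$freq$L1)
  expect_identical(unname(aft2$pops$p1$n_gene["L1"]), 0L)
  # random datasets vs brute-force count; sums and gene counts
  set.seed(21)
  for (i in 1:20) {
    ds3 <- random_ds(n_pops = 2, n_ind = 6, n_loci = 3, miss_rate = 0.25)
    aft3 <- allele_frequencies(ds3)
    for (p in names(ds3$pops)) for (l in seq_along(ds3$loci)) {
      al <- c(ds3$pops[[p]]$a1[, l], ds3$pops[[p]]$a2[, l])
      al <- al[!is.na(al)]
      expect_identical(unname(aft3$pops[[p]]$n_gene[l]), length(al))
      if (length(al)) {
        f <- aft3$pops[[p]]$freq[[l]]
        expect_equal(sum(f), 1, tolerance = 1e-12)
        for (a in unique(al))
          expect_equal(unname(f[as.character(a)]),
                       mean(al == a), tolerance = 1e-12)
      }
    }
  }
})
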