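small_scenario <- function(map = NULL, ...) {
  if (is.null(map))
    map <- marker_map(data.frame(marker = paste0("M", 1:6),
                                 lg = rep(c("LG1", "LG2"), each = 3),
                                 position_mb = rep(c(0, 1.5, 4), 2),
                                 motif_bp = 4))
  args <- list(ancestral_Ne = 200, demes = list(
    D1 = list(habitat = "lake", t_found = 50, founders = 20, Ne = 50,
              m = 0),
    D2 = list(habitat = "pond", t_found = 50, founders = 20, Ne = 50,
              m = 0)),
    map = map, sample_n = 10)
  args[names(list(...))] <- list(...)
  do.call(demographic_scenario, args)
}

test_that("scenario validation catches impossible settings", {
  map <- marker_map(data.frame(marker = "M1", lg = "LG1",
                               position_mb = 0))
  expect_error(demographic_scenario(100, list(
    D = list(habitat = "lake", t_found = 10, founders = 500, Ne = 50)),
    map), "founders")
  expect_error(demographic_scenario(100, list(
    D = list(habitat = "lake", t_found = 10, founders = 5, Ne = 50,
             m = 1)), map), "m must be")
  expect_error(demographic_scenario(100, list(
    D = list(habitat = "nowhere", t_found = 10, founders = 5, Ne = 50)),
    map), "habitat")
})

test_that("zero mutation from monomorphic founders stays monomorphic", {
  sc <- small_scenario(tpm = tpm_params(mu = 0))
  sim <- simulate_metapopulation(sc, seed = 111)
  for (p in pop_names(sim$dataset))
    expect_equal(expected_heterozygosity(sim$dataset, p)$mean, 0)
})

test_that("fixed seeds reproduce datasets and exported files exactly", {
  sc <- small_scenario()
  s1 <- simulate_metapopulation(sc, seed = 112)
  s2 <- simulate_metapopulation(sc, seed = 112)
  expect_identical(s1$dataset, s2$dataset)
  expect_identical(s1$truth$haplos, s2$truth$haplos)
  d1 <- file.path(tempdir(), "exp1"); d2 <- file.path(tempdir(), "exp2")
  export_dataset(s1$dataset, s1$map, d1, s1$truth)
  export_dataset(s2$dataset, s2$map, d2, s2$truth)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("export round-trips and truth tallies match the dataset", {
  sc <- small_scenario()
  sim <- simulate_metapopulation(sc, seed = 113)
  out <- file.path(tempdir(), "exp3")
  paths <- export_dataset(sim$dataset, sim$map, out, sim$truth)
  ds2 <- read_genepop(paths["genotypes"], paths["habitat"])
  for (p in pop_names(sim$dataset)) {
    expect_identical(unname(ds2$pops[[p]]$a1),
                     unname(sim$dataset$pops[[p]]$a1))
    expect_identical(unname(ds2$pops[[p]]$a2),
                     unname(sim$dataset$pops[[p]]$a2))
  }
  # unphased tallies equal phased truth tallies locus by locus
  aft <- allele_frequencies(sim$dataset)
  for (p in pop_names(sim$dataset)) {
    h <- sim$truth$haplos[[p]]
    for (l in seq_along(sim$dataset$loci)) {
      tal <- table(c(h$h1[, l], h$h2[, l]))
      f <- aft$pops[[p]]$freq[[l]]
      expect_equal(unname(f[names(tal)]),
                   as.numeric(tal) / sum(tal), tolerance = 1e-12)
    }
  }
  # truth two-locus tables are proper frequency tables
  tr <- truth_haplotype_freqs(sim$truth, "D1", sim$dataset$loci[1],
                              sim$dataset$loci[2])
  expect_equal(sum(tr$freq), 1, tolerance = 1e-12)
  expect_identical(tr$source, "simulated-truth")
  unlink(out, recursive = TRUE)
})

test_that("pure drift without mutation loses but never creates alleles", {
  set.seed(114)
  L <- 4
  pop <- list(H1 = matrix(sample(10:14, 20 * L, TRUE), 20, L),
              H2 = matrix(sample(10:14, 20 * L, TRUE), 20, L))
  sw <- rep(0.5, L); lg_start <- rep(TRUE, L)
  seen <- lapply(seq_len(L), function(l) unique(c(pop$H1[, l],
                                                  pop$H2[, l])))
  for (g in 1:30) {
    pop <- msatLD:::wf_generation(pop, 20, sw, lg_start, mu = 0,
                                  params = tpm_params(), bounds = c(5, 60))
    for (l in seq_len(L)) {
      now <- unique(c(pop$H1[, l], pop$H2[, l]))
      expect_true(all(now %in% seen[[l]]))
      seen[[l]] <- now  # allele loss is permanent under pure drift
    }
  }
})

test_that("F_ST between isolates grows with divergence time", {
  sc_t <- function(t) small_scenario()$demes  # template
  mean_fst <- sapply(c(10, 80, 300), function(t) {
    fst <- replicate(4, {
      sc <- small_scenario()
      sc$demes <- lapply(sc$demes, function(d) { d$t_found <- t; d })
      sim <- simulate_metapopulation(sc, seed = 1140 + t +
                                       sample.int(1000, 1))
      pairwise_fst(sim$dataset, "D1", "D2")
    })
    mean(fst, na.rm = TRUE)
  })
  expect_true(mean_fst[1] < mean_fst[2] && mean_fst[2] < mean_fst[3])
})

test_that("rescaling preserves expected diversity within noise", {
  set.seed(115)
  he_at <- function(f, reps) {
    sapply(seq_len(reps), function(i) {
      sc <- small_scenario(rescale = f, ancestral_Ne = 400)
      sim <- simulate_metapopulation(sc, seed = 2000 + 37 * i + f)
      mean(sapply(pop_names(sim$dataset), function(p)
        expected_heterozygosity(sim$dataset, p)$mean))
    })
  }
  h2 <- he_at(2, 8); h4 <- he_at(4, 8)
  expect_lt(abs(mean(h2) - mean(h4)),
            0.06 + 2 * sqrt(var(h2) / 8 + var(h4) / 8))
})

test_that("preset templates encode the habitat contrasts", {
  ps <- preset_scenarios()
  expect_setequal(names(ps),
                  c("marine", "coastal", "inland_lake", "inland_pond"))
  map <- default_marker_map()
  expect_equal(nrow(map), 109)
  expect_equal(length(unique(map$lg)), 20)
  sz <- table(map$lg)
  expect_true(all(sz >= 2 & sz <= 13))
  s <- map_interval_summary(map)
  expect_gte(s$min_mb, 0.001)
  expect_lte(s$max_mb, 11.5)
  expect_true(s$mean_mb > 2 && s$mean_mb < 3.5)
  # coastal demes keep migration from the pool; inland demes are isolated
  expect_true(all(sapply(ps$coastal$demes, `[[`, "m") > 0))
  expect_true(all(sapply(ps$inland_pond$demes, `[[`, "m") == 0))
  expect_true(all(sapply(ps$marine$demes, function(d)
    isTRUE(d$sample_ancestral))))
})
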