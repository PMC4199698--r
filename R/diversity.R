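# Per-population genetic-variability statistics: heterozygosities, F_IS,
# rarefied (private) allelic richness, rare-allele proportions.

#' Observed heterozygosity
#'
#' Per-locus fraction of heterozygous individuals among non-missing
#' genotypes; the multilocus value is the unweighted mean over loci with
#' data (loci monomorphic within the population contribute 0).
#'
#' @param ds a [gtds] object.
#' @param population population name.
#' @return list with `per_locus` (named numeric) and `mean`.
#' @export
observed_heterozygosity <- function(ds, population) {
  p <- gtds_pop(ds, population)
  het <- vapply(seq_along(ds$loci), function(l) {
    ok <- !is.na(p$a1[, l])
    if (!any(ok)) return(NA_real_)
    mean(p$a1[ok, l] != p$a2[ok, l])
  }, numeric(1))
  names(het) <- ds$loci
  list(per_locus = het, mean = mean(het, na.rm = TRUE))
}

#' Expected heterozygosity (Nei's unbiased gene diversity)
#'
#' Per locus, `(2n/(2n-1)) * (1 - sum p_i^2)` with `n` the number of
#' non-missing individuals; this small-sample correction matters at n = 24.
#' Multilocus value is the unweighted mean over loci with data.
#'
#' @inheritParams observed_heterozygosity
#' @return list with `per_locus` and `mean`.
#' @export
expected_heterozygosity <- function(ds, population) {
  p <- gtds_pop(ds, population)
  he <- vapply(seq_along(ds$loci), function(l) {
    al <- locus_copies(p, l)
    n2 <- length(al)
    if (n2 < 2) return(NA_real_)
    pr <- as.numeric(table(al)) / n2
    (n2 / (n2 - 1)) * (1 - sum(pr^2))
  }, numeric(1))
  names(he) <- ds$loci
  list(per_locus = he, mean = mean(he, na.rm = TRUE))
}

# internal: Weir-Cockerham within-population variance components (b, c) for
# a single population at one locus; returns per-allele vectors.
wc_bc_single <- function(a1, a2) {
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  if (n < 2) return(NULL)
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2) return(NULL)
  pfr <- (tabulate(match(a1, alleles), length(alleles)) +
          tabulate(match(a2, alleles), length(alleles))) / (2 * n)
  hfr <- vapply(alleles, function(a)
    mean((a1 == a) != (a2 == a)), numeric(1)) # freq of heterozygotes carrying a
  b <- n / (n - 1) * (pfr * (1 - pfr) - (2 * n - 1) / (4 * n) * hfr)
  c_ <- hfr / 2
  list(b = b, c = c_)
}

#' Weir-Cockerham F_IS with bootstrap confidence interval
#'
#' Single-population inbreeding coefficient `f = 1 - sum(c)/sum(b + c)`
#' combining variance components over alleles and loci (ratio of sums).
#' The 95% interval is a percentile bootstrap over loci.
#'
#' @inheritParams observed_heterozygosity
#' @param n_boot bootstrap resamples over loci.
#' @param seed optional integer seed.
#' @return list with `fis`, `ci` (length-2), `n_loci` (polymorphic loci
#'   used); `fis` is `NA` with `undefined = TRUE` when no locus is
#'   polymorphic.
#' @export
fis_with_ci <- function(ds, population, n_boot = 1000, seed = NULL) {
  p <- gtds_pop(ds, population)
  comp <- lapply(seq_along(ds$loci), function(l) wc_bc_single(p$a1[, l],
                                                              p$a2[, l]))
  keep <- !vapply(comp, is.null, logical(1))
  comp <- comp[keep]
  if (length(comp) == 0)
    return(list(fis = NA_real_, ci = c(NA_real_, NA_real_), n_loci = 0L,
                undefined = TRUE))
  bs <- vapply(comp, function(x) sum(x$b), numeric(1))
  cs <- vapply(comp, function(x) sum(x$c), numeric(1))
  fis <- 1 - sum(cs) / sum(bs + cs)
  ci <- c(NA_real_, NA_real_)
  if (length(comp) >= 2) {
    if (!is.null(seed)) {
      old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
      set.seed(seed)
    }
    boot <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(length(comp), replace = TRUE)
      1 - sum(cs[idx]) / sum(bs[idx] + cs[idx])
    }, numeric(1))
    ci <- unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  }
  list(fis = fis, ci = ci, n_loci = length(comp), undefined = FALSE)
}

# internal RNG-state helpers so seeded routines do not disturb the caller
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# internal: rarefied allele contribution 1 - C(N - Na, g)/C(N, g), computed
# on log scale for stability
rarefac_term <- function(N, Na, g) {
  if (N - Na < g) return(1)
  1 - exp(lchoose(N - Na, g) - lchoose(N, g))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies: `Ar = sum_a [1 - C(N - N_a, g)/C(N, g)]` per locus, averaged
#' over loci. By default `g` is the smallest per-locus non-missing gene
#' count across all populations and loci (so every locus/population supports
#' the rarefaction size).
#'
#' @param ds a [gtds] object.
#' @param g rarefaction size in gene copies (>= 2).
#' @return list with `g` and per population `per_locus`/`mean`.
#' @export
allelic_richness <- function(ds, g = NULL) {
  aft <- allele_frequencies(ds)
  if (is.null(g)) g <- min_gene_count(aft)
  if (g < 2) stop("rarefaction size g must be >= 2")
  res <- lapply(aft$pops, function(pp) {
    ar <- vapply(seq_along(ds$loci), function(l) {
      N <- pp$n_gene[l]
      if (N < g) return(NA_real_)
      counts <- round(pp$freq[[l]] * N)
      sum(vapply(counts, function(Na) rarefac_term(N, Na, g), numeric(1)))
    }, numeric(1))
    names(ar) <- ds$loci
    list(per_locus = ar, mean = mean(ar, na.rm = TRUE))
  })
  list(g = g, pops = res)
}

# internal: smallest positive per-locus gene count over populations x loci
min_gene_count <- function(aft) {
  counts <- unlist(lapply(aft$pops, `[[`, "n_gene"))
  counts <- counts[counts > 0]
  if (!length(counts)) stop("no genotyped locus in any population")
  min(counts)
}

#' Rarefied private allelic richness
#'
#' Kalinowski's estimator: the expected number of alleles that appear in a
#' rarefied sample of `g` copies from the focal population while being
#' absent from independent rarefied samples of `g` copies from every other
#' population: per allele,
#' `[1 - C(N_f - N_af, g)/C(N_f, g)] * prod_o C(N_o - N_ao, g)/C(N_o, g)`.
#'
#' @inheritParams allelic_richness
#' @return list with `g` and per population `per_locus`/`mean`.
#' @export
private_allelic_richness <- function(ds, g = NULL) {
  if (length(ds$pops) < 2) stop("private richness needs >= 2 populations")
  aft <- allele_frequencies(ds)
  if (is.null(g)) g <- min_gene_count(aft)
  if (g < 2) stop("rarefaction size g must be >= 2")
  nm <- names(aft$pops)
  res <- stats::setNames(vector("list", length(nm)), nm)
  for (f in nm) {
    pr <- vapply(seq_along(ds$loci), function(l) {
      Nf <- aft$pops[[f]]$n_gene[l]
      if (Nf < g) return(NA_real_)
      others <- setdiff(nm, f)
      No <- vapply(others, function(o) aft$pops[[o]]$n_gene[l], numeric(1))
      if (any(No < g)) return(NA_real_)
      ff <- aft$pops[[f]]$freq[[l]]
      alleles <- names(ff)
      tot <- 0
      for (a in alleles) {
        Naf <- round(ff[[a]] * Nf)
        inres <- rarefac_term(Nf, Naf, g)
        absent <- 1
        for (o in others) {
          fo <- aft$pops[[o]]$freq[[l]]
          Nao <- if (a %in% names(fo)) round(fo[[a]] * No[[o]]) else 0
          absent <- absent * (1 - rarefac_term(No[[o]], Nao, g))
        }
        tot <- tot + inres * absent
      }
      tot
    }, numeric(1))
    names(pr) <- ds$loci
    res[[f]] <- list(per_locus = pr, mean = mean(pr, na.rm = TRUE))
  }
  list(g = g, pops = res)
}

#' Proportion of rare alleles
#'
#' Fraction of the distinct alleles observed in a population whose relative
#' frequency is below `threshold` (default 5%).
#'
#' @inheritParams observed_heterozygosity
#' @param threshold frequency cut-off.
#' @export
rare_allele_proportion <- function(ds, population, threshold = 0.05) {
  gtds_pop(ds, population)
  aft <- allele_frequencies(ds)
  fr <- unlist(aft$pops[[population]]$freq, use.names = FALSE)
  if (!length(fr)) stop("population has no observed alleles")
  mean(fr < threshold)
}

#' Per-population diversity summary table
#'
#' One row per population with the sample size, polymorphic-locus count,
#' total allele count, rarefied allelic and private allelic richness,
#' observed/expected heterozygosity and F_IS with its bootstrap CI.
#'
#' @inheritParams allelic_richness
#' @param n_boot bootstrap resamples for the F_IS interval.
#' @param seed optional integer seed for the bootstrap.
#' @return data.frame mirroring the standard diversity-table layout.
#' @export
diversity_summary <- function(ds, g = NULL, n_boot = 1000, seed = NULL) {
  aft <- allele_frequencies(ds)
  ar <- allelic_richness(ds, g)
  pr <- if (length(ds$pops) >= 2) private_allelic_richness(ds, ar$g) else NULL
  rows <- lapply(names(ds$pops), function(nm) {
    p <- ds$pops[[nm]]
    npl <- sum(vapply(seq_along(ds$loci), function(l)
      is_polymorphic(p, l), logical(1)))
    A <- sum(vapply(aft$pops[[nm]]$freq, length, integer(1)))
    fis <- fis_with_ci(ds, nm, n_boot = n_boot, seed = seed)
    data.frame(population = nm, habitat = p$habitat,
               coastal = isTRUE(p$coastal), n = nrow(p$a1), npl = npl,
               A = A, Ar = ar$pops[[nm]]$mean,
               Pr = if (is.null(pr)) NA_real_ else pr$pops[[nm]]$mean,
               H_O = observed_heterozygosity(ds, nm)$mean,
               H_E = expected_heterozygosity(ds, nm)$mean,
               F_IS = fis$fis, CI_low = fis$ci[1], CI_high = fis$ci[2],
               rare_allele_prop = rare_allele_proportion(ds, nm),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
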