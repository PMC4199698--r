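# Shared fixture builders: small genotype datasets constructed in code.

# dataset from explicit allele matrices (one population)
one_pop_ds <- function(a1, a2, loci = NULL, habitat = "marine",
                       name = "p1", motif = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(a1)))
  colnames(a1) <- colnames(a2) <- loci
  pops <- stats::setNames(
    list(list(habitat = habitat, coastal = FALSE, a1 = a1, a2 = a2)), name)
  gtds(pops, loci, motif = motif)
}

# random multiallelic dataset with missing entries
random_ds <- function(n_pops = 2, n_ind = 8, n_loci = 4, n_alleles = 4,
                      miss_rate = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loci <- paste0("L", seq_len(n_loci))
  habs <- c("marine", "lake", "pond", "river")
  pops <- list()
  for (p in seq_len(n_pops)) {
    draw <- function() matrix(100L + 4L * sample.int(n_alleles, n_ind *
                                                       n_loci, TRUE),
                              n_ind, n_loci)
    a1 <- draw(); a2 <- draw()
    miss <- matrix(runif(n_ind * n_loci) < miss_rate, n_ind, n_loci)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    pops[[paste0("pop", p)]] <- list(habitat = habs[(p - 1) %% 4 + 1],
                                     coastal = p %% 2 == 0,
                                     a1 = a1, a2 = a2)
  }
  gtds(pops, loci)
}

# genotypes drawn from Hardy-Weinberg with given allele frequencies
hwe_pop <- function(n_ind, freq_by_locus, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(freq_by_locus)
  a1 <- matrix(0L, n_ind, L); a2 <- matrix(0L, n_ind, L)
  for (l in seq_len(L)) {
    f <- freq_by_locus[[l]]
    codes <- 100L + 4L * seq_along(f)
    a1[, l] <- sample(codes, n_ind, TRUE, prob = f)
    a2[, l] <- sample(codes, n_ind, TRUE, prob = f)
  }
  list(a1 = a1, a2 = a2)
}

# diploid genotypes by random union of gametes drawn from a two-locus
# haplotype frequency table (k x l matrix, rows = locus A alleles)
genotypes_from_haps <- function(n_ind, hfreq, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(hfreq); l <- ncol(hfreq)
  idx <- sample.int(k * l, 2 * n_ind, TRUE, prob = as.vector(hfreq))
  ai <- (idx - 1L) %% k + 1L
  bi <- (idx - 1L) %/% k + 1L
  codesA <- 100L + 4L * seq_len(k); codesB <- 200L + 4L * seq_len(l)
  one_pop_ds(cbind(codesA[ai[seq_len(n_ind)]],
                   codesB[bi[seq_len(n_ind)]]),
             cbind(codesA[ai[n_ind + seq_len(n_ind)]],
                   codesB[bi[n_ind + seq_len(n_ind)]]),
             loci = c("A", "B"))
}

# random Dirichlet-ish haplotype frequency table (via gamma normalisation)
random_hap_table <- function(k, l) {
  m <- matrix(stats::rgamma(k * l, shape = 0.8), k, l)
  m / sum(m)
}

# independent term-by-term oracles for the multiallelic LD measures,
# written as explicit double loops over the printed definitions
oracle_dprime <- function(freq) {
  pA <- rowSums(freq); pB <- colSums(freq)
  tot <- 0
  for (i in seq_along(pA)) for (j in seq_along(pB)) {
    D <- freq[i, j] - pA[i] * pB[j]
    Dmax <- if (D < 0) min(pA[i] * pB[j], (1 - pA[i]) * (1 - pB[j]))
    else min(pA[i] * (1 - pB[j]), pB[j] * (1 - pA[i]))
    if (Dmax > 0) tot <- tot + pA[i] * pB[j] * abs(D / Dmax)
  }
  tot
}

oracle_r2 <- function(freq) {
  pA <- rowSums(freq); pB <- colSums(freq)
  tot <- 0
  for (i in seq_along(pA)) for (j in seq_along(pB)) {
    D <- freq[i, j] - pA[i] * pB[j]
    tot <- tot + pA[i] * pB[j] * D^2 /
      (pA[i] * (1 - pA[i]) * pB[j] * (1 - pB[j]))
  }
  tot
}

# write a GenePop file from text lines and read it back with a habitat table
read_genepop_text <- function(lines, habitats) {
  gp <- tempfile(fileext = ".gen")
  writeLines(lines, gp)
  read_genepop(gp, habitats)
}
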