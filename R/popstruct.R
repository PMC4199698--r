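# Population differentiation: Weir-Cockerham theta with permutation tests,
# hierarchical AMOVA, and Queller-Goodnight pairwise relatedness.

# internal: Weir-Cockerham (1984) variance components (a, b, c) for one
# locus over r populations. A1/A2: list per population of allele vectors
# (paired, NA-free after filtering). Returns per-allele component vectors.
wc_abc_locus <- function(A1, A2) {
  keep <- vapply(seq_along(A1), function(i) length(A1[[i]]) >= 1, logical(1))
  A1 <- A1[keep]; A2 <- A2[keep]
  r <- length(A1)
  if (r < 2) return(NULL)
  ni <- vapply(A1, length, numeric(1))
  alleles <- sort(unique(unlist(c(A1, A2))))
  k <- length(alleles)
  if (k < 2) return(NULL)
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  # r x k matrices of allele frequencies and carried-in-heterozygote freqs
  p_mat <- matrix(0, r, k); h_mat <- matrix(0, r, k)
  for (i in seq_len(r)) {
    p_mat[i, ] <- (tabulate(match(A1[[i]], alleles), k) +
                     tabulate(match(A2[[i]], alleles), k)) / (2 * ni[i])
    het <- A1[[i]] != A2[[i]]
    if (any(het))
      h_mat[i, ] <- tabulate(match(c(A1[[i]][het], A2[[i]][het]),
                                   alleles), k) / ni[i]
  }
  pbar <- colSums(ni * p_mat) / (r * nbar)
  s2 <- colSums(ni * (p_mat - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(ni * h_mat) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) *
       hbar)
  list(a = a, b = b, c = hbar / 2)
}

# internal: multilocus theta from population records (ratio of summed
# components over loci and alleles)
theta_from_recs <- function(recs, loci_idx = NULL) {
  L <- ncol(recs[[1]]$a1)
  if (is.null(loci_idx)) loci_idx <- seq_len(L)
  num <- den <- 0
  for (l in loci_idx) {
    A1 <- lapply(recs, function(p) p$a1[!is.na(p$a1[, l]), l])
    A2 <- lapply(recs, function(p) p$a2[!is.na(p$a2[, l]), l])
    cmp <- wc_abc_locus(A1, A2)
    if (is.null(cmp)) next
    num <- num + sum(cmp$a)
    den <- den + sum(cmp$a + cmp$b + cmp$c)
  }
  if (den == 0) return(structure(NA_real_, undefined = TRUE))
  num / den
}

#' Pairwise Weir-Cockerham F_ST
#'
#' Multilocus theta (Weir & Cockerham 1984) between two populations,
#' combining variance components by ratio of sums over shared polymorphic
#' loci. The estimator can be slightly negative.
#'
#' @param ds a [gtds] object.
#' @param popA,popB population names.
#' @return scalar theta (`NA` flagged `undefined` without any shared
#'   polymorphic locus).
#' @export
pairwise_fst <- function(ds, popA, popB) {
  theta_from_recs(list(gtds_pop(ds, popA), gtds_pop(ds, popB)))
}

#' Permutation test for pairwise F_ST
#'
#' Individuals are permuted between the two populations and theta
#' recomputed; `p = (1 + #\{theta_perm >= theta_obs\}) / (n_perm + 1)`.
#'
#' @inheritParams pairwise_fst
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @return list with `theta`, `p_value`, `n_perm`.
#' @export
fst_permutation_test <- function(ds, popA, popB, n_perm = 10000,
                                 seed = NULL) {
  pa <- gtds_pop(ds, popA); pb <- gtds_pop(ds, popB)
  obs <- theta_from_recs(list(pa, pb))
  if (is.na(obs)) return(list(theta = obs, p_value = NA_real_,
                              n_perm = n_perm))
  if (!is.null(seed)) {
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
    set.seed(seed)
  }
  na <- nrow(pa$a1); nb <- nrow(pb$a1)
  A1 <- rbind(pa$a1, pb$a1); A2 <- rbind(pa$a2, pb$a2)
  cnt <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(na + nb)
    ia <- idx[seq_len(na)]; ib <- idx[na + seq_len(nb)]
    th <- theta_from_recs(list(list(a1 = A1[ia, , drop = FALSE],
                                    a2 = A2[ia, , drop = FALSE]),
                               list(a1 = A1[ib, , drop = FALSE],
                                    a2 = A2[ib, , drop = FALSE])))
    if (!is.na(th) && th >= obs) cnt <- cnt + 1L
  }
  list(theta = obs, p_value = (1 + cnt) / (n_perm + 1), n_perm = n_perm)
}

#' All pairwise F_ST values with optional permutation p-values
#'
#' @inheritParams fst_permutation_test
#' @param n_perm permutations per pair (0 skips testing).
#' @return list with symmetric `theta` matrix and `p` matrix (NA diagonal).
#' @export
fst_matrix <- function(ds, n_perm = 0, seed = NULL) {
  nm <- names(ds$pops)
  th <- p <- matrix(NA_real_, length(nm), length(nm),
                    dimnames = list(nm, nm))
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (j <= i) next
    if (n_perm > 0) {
      r <- fst_permutation_test(ds, nm[i], nm[j], n_perm = n_perm,
                                seed = if (is.null(seed)) NULL else
                                  seed + i * 131L + j)
      th[i, j] <- th[j, i] <- r$theta
      p[i, j] <- p[j, i] <- r$p_value
    } else {
      th[i, j] <- th[j, i] <- pairwise_fst(ds, nm[i], nm[j])
    }
  }
  list(theta = th, p = p, n_perm = n_perm)
}

# ---- AMOVA ------------------------------------------------------------------

# internal: per-locus SSD of a set of gene copies under the 0/1 allele
# identity distance: (n^2 - sum n_a^2) / (2 n)
ssd_copies <- function(al) {
  n <- length(al)
  if (n < 1) return(0)
  (n^2 - sum(table(al)^2)) / (2 * n)
}

# internal: one locus's AMOVA sums of squares and coefficient inputs
amova_locus <- function(pops_alleles, group_of_pop) {
  counts <- vapply(pops_alleles, length, numeric(1))
  keep <- counts > 0
  pops_alleles <- pops_alleles[keep]
  group_of_pop <- group_of_pop[keep]
  counts <- counts[keep]
  P <- length(pops_alleles)
  grs <- unique(group_of_pop)
  G <- length(grs)
  N <- sum(counts)
  ssd_wp <- sum(vapply(pops_alleles, ssd_copies, numeric(1)))
  ssd_wg <- sum(vapply(grs, function(g)
    ssd_copies(unlist(pops_alleles[group_of_pop == g])), numeric(1)))
  ssd_tot <- ssd_copies(unlist(pops_alleles))
  Ng <- vapply(grs, function(g) sum(counts[group_of_pop == g]), numeric(1))
  sum_np2_by_g <- vapply(grs, function(g)
    sum(counts[group_of_pop == g]^2), numeric(1))
  list(ssd_ag = ssd_tot - ssd_wg, ssd_ap = ssd_wg - ssd_wp, ssd_wp = ssd_wp,
       df_ag = G - 1, df_ap = P - G, df_wp = N - P,
       n1 = if (P - G > 0) (N - sum(sum_np2_by_g / Ng)) / (P - G) else NA,
       n2 = if (G > 1) (sum(sum_np2_by_g / Ng) - sum(counts^2) / N) /
         (G - 1) else NA,
       n3 = if (G > 1) (N - sum(Ng^2) / N) / (G - 1) else NA)
}

# internal: summed-over-loci variance components from population records
amova_components <- function(recs, group_of_pop) {
  L <- ncol(recs[[1]]$a1)
  sa <- sb <- sc <- 0
  for (l in seq_len(L)) {
    al <- lapply(recs, function(p) locus_copies(p, l))
    if (sum(vapply(al, length, numeric(1)) > 0) < 2) next
    x <- amova_locus(al, group_of_pop)
    ms_wp <- if (x$df_wp > 0) x$ssd_wp / x$df_wp else 0
    sig_c <- ms_wp
    sig_b <- if (x$df_ap > 0 && !is.na(x$n1) && x$n1 > 0)
      (x$ssd_ap / x$df_ap - sig_c) / x$n1 else 0
    sig_a <- if (x$df_ag > 0 && !is.na(x$n3) && x$n3 > 0)
      (x$ssd_ag / x$df_ag - sig_c - x$n2 * sig_b) / x$n3 else 0
    sa <- sa + sig_a; sb <- sb + sig_b; sc <- sc + sig_c
  }
  c(among_groups = sa, among_pops_within = sb, within_pops = sc)
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Three-level AMOVA on the 0/1 allele-identity distance, locus by locus
#' with summed covariance components: among groups, among populations
#' within groups, within populations (gene copies within populations).
#' Components may be negative; percentages sum to 100. Significance by the
#' standard permutation schemes: whole populations among groups (for the
#' among-group component) and individuals among populations within groups
#' (for the among-population component).
#'
#' @param ds a [gtds] object.
#' @param grouping named character: population -> group label.
#' @param n_perm permutations (0 skips testing).
#' @param seed optional integer seed.
#' @return list with `components` (absolute), `percent`, `p_values`, `df`.
#' @export
amova <- function(ds, grouping, n_perm = 10000, seed = NULL) {
  nm <- names(ds$pops)
  unknown <- setdiff(names(grouping), nm)
  if (length(unknown))
    stop("grouping references unknown population(s): ",
         paste(unknown, collapse = ", "))
  if (!all(nm %in% names(grouping)))
    stop("grouping must cover every population")
  grp <- as.character(grouping[nm])
  recs <- ds$pops
  comp <- amova_components(recs, grp)
  tot <- sum(comp)
  pct <- 100 * comp / tot
  p_ag <- p_ap <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) {
      old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
      set.seed(seed)
    }
    if (length(unique(grp)) > 1) {
      cnt <- 0L
      for (i in seq_len(n_perm)) {
        gp <- sample(grp)
        cm <- amova_components(recs, gp)
        if (cm["among_groups"] >= comp["among_groups"]) cnt <- cnt + 1L
      }
      p_ag <- (1 + cnt) / (n_perm + 1)
    }
    # individuals among populations within groups
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      recs_p <- permute_within_groups(recs, grp)
      cm <- amova_components(recs_p, grp)
      if (cm["among_pops_within"] >= comp["among_pops_within"])
        cnt <- cnt + 1L
    }
    p_ap <- (1 + cnt) / (n_perm + 1)
  }
  list(components = comp, percent = pct,
       p_values = c(among_groups = p_ag, among_pops_within = p_ap),
       df = amova_df(recs, grp), n_perm = n_perm)
}

amova_df <- function(recs, grp) {
  P <- length(recs); G <- length(unique(grp))
  N <- sum(vapply(recs, function(p) 2 * nrow(p$a1), numeric(1)))
  c(among_groups = G - 1, among_pops_within = P - G, within_pops = N - P)
}

# internal: shuffle individuals among populations within each group
permute_within_groups <- function(recs, grp) {
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2) next
    A1 <- do.call(rbind, lapply(recs[idx], `[[`, "a1"))
    A2 <- do.call(rbind, lapply(recs[idx], `[[`, "a2"))
    sizes <- vapply(recs[idx], function(p) nrow(p$a1), integer(1))
    ord <- sample.int(nrow(A1))
    off <- 0L
    for (k in seq_along(idx)) {
      take <- ord[off + seq_len(sizes[k])]
      recs[[idx[k]]]$a1 <- A1[take, , drop = FALSE]
      recs[[idx[k]]]$a2 <- A2[take, , drop = FALSE]
      off <- off + sizes[k]
    }
  }
  recs
}

# ---- relatedness ------------------------------------------------------------

#' Queller-Goodnight pairwise relatedness
#'
#' Symmetric matrix of Queller & Goodnight r estimates within a population,
#' summed over loci and averaged over the two reference orderings. For each
#' pair, reference allele frequencies are computed from the population with
#' the focal pair excluded (bias correction). Loci monomorphic in the
#' remaining sample are skipped.
#'
#' @param ds a [gtds] object.
#' @param population population name.
#' @return n x n symmetric matrix (`NA` diagonal).
#' @export
relatedness_qg <- function(ds, population) {
  p <- gtds_pop(ds, population)
  n <- nrow(p$a1); L <- ncol(p$a1)
  if (n < 2) stop("relatedness needs >= 2 individuals")
  # per-locus overall allele counts for fast exclusion
  counts <- lapply(seq_len(L), function(l) table(locus_copies(p, l)))
  r <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    numx <- denx <- numy <- deny <- 0
    used <- FALSE
    for (l in seq_len(L)) {
      a <- p$a1[i, l]; b <- p$a2[i, l]
      c_ <- p$a1[j, l]; d <- p$a2[j, l]
      if (is.na(a) || is.na(c_)) next
      tab <- counts[[l]]
      # remove the focal pair's copies
      tab2 <- tab
      for (al in c(a, b, c_, d)) tab2[as.character(al)] <-
          tab2[as.character(al)] - 1L
      tab2 <- tab2[tab2 > 0]
      if (length(tab2) < 2) next
      tot <- sum(tab2)
      pf <- function(al) {
        v <- tab2[as.character(al)]
        if (is.na(v)) 0 else as.numeric(v) / tot
      }
      sxy <- 0.5 * ((a == c_) + (a == d) + (b == c_) + (b == d))
      nx <- sxy - pf(a) - pf(b)
      dx <- 1 + (a == b) - pf(a) - pf(b)
      ny <- sxy - pf(c_) - pf(d)
      dy <- 1 + (c_ == d) - pf(c_) - pf(d)
      numx <- numx + nx; denx <- denx + dx
      numy <- numy + ny; deny <- deny + dy
      used <- TRUE
    }
    if (used && denx != 0 && deny != 0)
      r[i, j] <- r[j, i] <- (numx / denx + numy / deny) / 2
  }
  if (all(is.na(r[upper.tri(r)])))
    attr(r, "undefined") <- TRUE
  r
}
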