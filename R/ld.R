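# Two-locus haplotype-frequency estimation (EM over diploid phase
# ambiguity) and the multiallelic LD measures D', r2 and their composite
# (phase-free) counterparts.

#' Build a haplotype-frequency table
#'
#' Container for a joint two-locus haplotype frequency matrix with its
#' allele margins. Row/column names are the allele codes.
#'
#' @param freq k x l matrix of haplotype frequencies (sums to 1).
#' @param locusA,locusB marker ids.
#' @param n_chromosomes effective gene count behind the estimate.
#' @param source one of `"EM"`, `"direct"`, `"simulated-truth"`.
#' @param converged,n_iter,loglik EM diagnostics (optional).
#' @return object of class `hap_freq`.
#' @export
hap_freq <- function(freq, locusA = "A", locusB = "B",
                     n_chromosomes = NA_integer_, source = "direct",
                     converged = TRUE, n_iter = 0L, loglik = NA_real_) {
  freq <- as.matrix(freq)
  if (any(freq < -1e-12)) stop("negative haplotype frequency")
  s <- sum(freq)
  if (abs(s - 1) > 1e-9) stop("haplotype frequencies must sum to 1")
  structure(list(freq = freq, pA = rowSums(freq), pB = colSums(freq),
                 locusA = locusA, locusB = locusB,
                 n_chromosomes = n_chromosomes, source = source,
                 converged = converged, n_iter = n_iter, loglik = loglik),
            class = "hap_freq")
}

#' @export
print.hap_freq <- function(x, ...) {
  cat(sprintf("<hap_freq> %s x %s (%dx%d), source=%s, n_chrom=%s\n",
              x$locusA, x$locusB, nrow(x$freq), ncol(x$freq), x$source,
              x$n_chromosomes))
  invisible(x)
}

#' EM estimate of two-locus haplotype frequencies from unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies for a pair of loci under
#' random union of gametes, resolving the phase ambiguity of double
#' heterozygotes by expectation-maximisation. Initialised at the product of
#' the observed allele margins; individuals missing either locus are
#' excluded pairwise. The allele margins of the estimate equal the observed
#' allele frequencies at every iteration, and the log-likelihood is
#' non-decreasing.
#'
#' @param ds a [gtds] object.
#' @param population population name.
#' @param locusA,locusB marker ids.
#' @param tol convergence tolerance on the max absolute frequency change.
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @param loglik_trace if TRUE, attach the per-iteration log-likelihoods.
#' @return a [hap_freq] with `source = "EM"`.
#' @export
em_haplotype_frequencies <- function(ds, population, locusA, locusB,
                                     tol = 1e-8, max_iter = 1000,
                                     loglik_trace = FALSE) {
  p <- gtds_pop(ds, population)
  em_pair(p, match_locus(ds, locusA), match_locus(ds, locusB),
          locusA, locusB, tol = tol, max_iter = max_iter,
          loglik_trace = loglik_trace)
}

match_locus <- function(ds, locus) {
  l <- match(locus, ds$loci)
  if (is.na(l)) stop(sprintf("unknown locus '%s'", locus))
  l
}

# internal EM on a population record and two locus column indices
em_pair <- function(poprec, la, lb, nameA = "A", nameB = "B", tol = 1e-8,
                    max_iter = 1000, loglik_trace = FALSE) {
  ok <- !is.na(poprec$a1[, la]) & !is.na(poprec$a1[, lb])
  if (!any(ok)) stop("no individual genotyped at both loci")
  A1 <- poprec$a1[ok, la]; A2 <- poprec$a2[ok, la]
  B1 <- poprec$a1[ok, lb]; B2 <- poprec$a2[ok, lb]
  aA <- sort(unique(c(A1, A2))); aB <- sort(unique(c(B1, B2)))
  k <- length(aA); l <- length(aB); n <- length(A1)
  iA1 <- match(A1, aA); iA2 <- match(A2, aA)
  iB1 <- match(B1, aB); iB2 <- match(B2, aB)
  pA <- (tabulate(iA1, k) + tabulate(iA2, k)) / (2 * n)
  pB <- (tabulate(iB1, l) + tabulate(iB2, l)) / (2 * n)
  h <- outer(pA, pB)

  # linear indices of the two phase configurations per individual
  i11 <- (iB1 - 1L) * k + iA1; i22 <- (iB2 - 1L) * k + iA2
  i12 <- (iB2 - 1L) * k + iA1; i21 <- (iB1 - 1L) * k + iA2
  ii <- c(i11, i22, i12, i21)

  ll <- numeric(0); iter <- 0L; converged <- FALSE
  repeat {
    w1 <- h[i11] * h[i22]
    w2 <- h[i12] * h[i21]
    tot <- w1 + w2
    zero <- tot <= 0
    p1 <- ifelse(zero, 0.5, w1 / ifelse(zero, 1, tot))
    ll <- c(ll, sum(log(pmax(tot, .Machine$double.xmin))))
    wts <- c(p1, p1, 1 - p1, 1 - p1)
    agg <- rowsum(wts, ii)
    hv <- numeric(k * l)
    hv[as.integer(rownames(agg))] <- agg
    hnew <- matrix(hv / (2 * n), k, l)
    delta <- max(abs(hnew - h))
    h <- hnew
    iter <- iter + 1L
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged)
    warning(sprintf("EM did not converge in %d iterations for %s x %s",
                    max_iter, nameA, nameB))
  dimnames(h) <- list(aA, aB)
  out <- hap_freq(h, nameA, nameB, n_chromosomes = 2L * n, source = "EM",
                  converged = converged, n_iter = iter,
                  loglik = ll[length(ll)])
  if (loglik_trace) out$loglik_trace <- ll
  out
}

# internal: Dij and Dijmax matrices for a frequency table (margins pA, pB)
ld_components <- function(freq, pA, pB) {
  D <- freq - outer(pA, pB)
  dmax_neg <- pmin(outer(pA, pB), outer(1 - pA, 1 - pB))
  dmax_pos <- pmin(outer(pA, 1 - pB), outer(1 - pA, pB))
  Dmax <- ifelse(D < 0, dmax_neg, dmax_pos)
  list(D = D, Dmax = Dmax)
}

# internal: drop alleles with (numerically) zero margin
drop_zero_margins <- function(freq) {
  pA <- rowSums(freq); pB <- colSums(freq)
  freq[pA > 1e-12, pB > 1e-12, drop = FALSE]
}

#' Multiallelic D'
#'
#' Allele-frequency-weighted mean of `|D_ij / D_ijmax|` over all allele
#' pairs, with `D_ij = p(A_iB_j) - p(A_i)p(B_j)` and the usual sign-split
#' normalisation `D_ijmax = min(p_i p_j, (1-p_i)(1-p_j))` for negative
#' `D_ij` and `min(p_i(1-p_j), p_j(1-p_i))` otherwise. Pairs with
#' `D_ijmax = 0` contribute 0, which keeps the measure in \[0, 1\]. Both
#' loci must be polymorphic.
#'
#' @param h a [hap_freq] table.
#' @return scalar D' in \[0, 1\] (`NA` with attribute `undefined` when a
#'   locus is monomorphic).
#' @export
dprime_multiallelic <- function(h) {
  freq <- drop_zero_margins(h$freq)
  if (nrow(freq) < 2 || ncol(freq) < 2)
    return(structure(NA_real_, undefined = TRUE))
  pA <- rowSums(freq); pB <- colSums(freq)
  cmp <- ld_components(freq, pA, pB)
  ratio <- ifelse(cmp$Dmax > 0, abs(cmp$D / ifelse(cmp$Dmax > 0, cmp$Dmax, 1)),
                  0)
  sum(outer(pA, pB) * ratio)
}

#' Multiallelic r2
#'
#' Frequency-weighted aggregation
#' `sum_ij p_i p_j D_ij^2 / [p_i (1-p_i) p_j (1-p_j)]` over all allele
#' pairs. For biallelic loci every per-pair term equals the classical
#' `r2 = D^2/(pA qA pB qB)` and the weights sum to 1, so the measure
#' reduces exactly to the classical closed form; the per-pair correlation
#' bound `D_ij^2 <= p_i(1-p_i)p_j(1-p_j)` keeps it in \[0, 1\].
#'
#' @inheritParams dprime_multiallelic
#' @return non-negative scalar (`NA` when a locus is monomorphic).
#' @export
r2_multiallelic <- function(h) {
  freq <- drop_zero_margins(h$freq)
  if (nrow(freq) < 2 || ncol(freq) < 2)
    return(structure(NA_real_, undefined = TRUE))
  pA <- rowSums(freq); pB <- colSums(freq)
  cmp <- ld_components(freq, pA, pB)
  denom <- outer(pA * (1 - pA), pB * (1 - pB))
  sum(outer(pA, pB) * cmp$D^2 / denom)
}

#' Composite LD from unphased genotype counts
#'
#' Phase-free disequilibrium per allele pair, estimated on the per-gamete
#' scale from two-locus genotype counts:
#' `Delta_ij = sum_ind g_i g_j / (4 n) - p_i p_j`, where `g_i` is the
#' number of copies of allele i the individual carries (0/1/2). This
#' combines the within- and between-gamete association and equals the
#' haplotypic `D_ij` exactly on data without double heterozygotes.
#' `Delta_ij` is substituted for `D_ij` in the multiallelic D' and r2
#' aggregation formulas.
#'
#' @inheritParams em_haplotype_frequencies
#' @return list with `composite_dprime`, `composite_r2`, the `delta`
#'   matrix, allele margins and `n` (individuals used).
#' @export
composite_ld <- function(ds, population, locusA, locusB) {
  p <- gtds_pop(ds, population)
  composite_pair(p, match_locus(ds, locusA), match_locus(ds, locusB))
}

# internal composite on a population record and locus column indices
composite_pair <- function(poprec, la, lb) {
  ok <- !is.na(poprec$a1[, la]) & !is.na(poprec$a1[, lb])
  if (!any(ok)) stop("no individual genotyped at both loci")
  A1 <- poprec$a1[ok, la]; A2 <- poprec$a2[ok, la]
  B1 <- poprec$a1[ok, lb]; B2 <- poprec$a2[ok, lb]
  aA <- sort(unique(c(A1, A2))); aB <- sort(unique(c(B1, B2)))
  k <- length(aA); l <- length(aB); n <- length(A1)
  if (k < 2 || l < 2)
    return(list(composite_dprime = structure(NA_real_, undefined = TRUE),
                composite_r2 = structure(NA_real_, undefined = TRUE),
                delta = NULL, pA = NULL, pB = NULL, n = n))
  gA <- matrix(0L, n, k); gB <- matrix(0L, n, l)
  gA[cbind(seq_len(n), match(A1, aA))] <- gA[cbind(seq_len(n),
                                                   match(A1, aA))] + 1L
  gA[cbind(seq_len(n), match(A2, aA))] <- gA[cbind(seq_len(n),
                                                   match(A2, aA))] + 1L
  gB[cbind(seq_len(n), match(B1, aB))] <- gB[cbind(seq_len(n),
                                                   match(B1, aB))] + 1L
  gB[cbind(seq_len(n), match(B2, aB))] <- gB[cbind(seq_len(n),
                                                   match(B2, aB))] + 1L
  pA <- colSums(gA) / (2 * n); pB <- colSums(gB) / (2 * n)
  delta <- crossprod(gA, gB) / (4 * n) - outer(pA, pB)
  dimnames(delta) <- list(aA, aB)

  dmax_neg <- pmin(outer(pA, pB), outer(1 - pA, 1 - pB))
  dmax_pos <- pmin(outer(pA, 1 - pB), outer(1 - pA, pB))
  Dmax <- ifelse(delta < 0, dmax_neg, dmax_pos)
  ratio <- ifelse(Dmax > 0, abs(delta / ifelse(Dmax > 0, Dmax, 1)), 0)
  cd <- sum(outer(pA, pB) * ratio)
  cr <- sum(outer(pA, pB) * delta^2 / outer(pA * (1 - pA), pB * (1 - pB)))
  list(composite_dprime = cd, composite_r2 = cr, delta = delta, pA = pA,
       pB = pB, n = n)
}
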