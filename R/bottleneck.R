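# Bottleneck detection: M-ratio with coalescent-simulated critical values,
# and the heterozygosity-excess test under a two-phase mutation model.

#' Two-phase mutation model parameters
#'
#' Microsatellite mutation model mixing single-repeat steps (probability
#' `p_single`) with multi-repeat jumps whose size is `1 + Geometric`,
#' chosen so the mean jump equals `mean_multistep` repeat units; signs are
#' symmetric. `p_single = 1` gives the strict stepwise model (SMM).
#'
#' @param p_single probability of a single-step mutation.
#' @param mean_multistep mean multistep jump size in repeat units (> 1).
#' @param mu per-generation mutation rate.
#' @export
tpm_params <- function(p_single = 0.9, mean_multistep = 3.5, mu = 1.5e-4) {
  stopifnot(p_single >= 0, p_single <= 1, mean_multistep > 1, mu >= 0)
  structure(list(p_single = p_single, mean_multistep = mean_multistep,
                 mu = mu), class = "tpm_params")
}

# internal: signed TPM step sizes for n mutations
tpm_steps <- function(n, params) {
  if (n == 0) return(integer(0))
  size <- ifelse(stats::runif(n) < params$p_single, 1L,
                 1L + stats::rgeom(n, prob = 1 / params$mean_multistep))
  size * sample(c(-1L, 1L), n, replace = TRUE)
}

#' Batch coalescent sampler under the TPM
#'
#' Simulates `n_rep` independent Kingman coalescent genealogies for a
#' sample of `n_copies` gene copies with mutations at rate `theta/2` per
#' lineage per unit coalescent time, each mutation shifting the repeat
#' count by a TPM step. All replicates advance through the same epoch
#' schedule, so the whole batch is vectorised.
#'
#' @param n_copies gene copies per sample (2 x individuals).
#' @param theta scaled mutation rate 4*Ne*mu.
#' @param params a [tpm_params].
#' @param n_rep replicates.
#' @return integer matrix `n_rep` x `n_copies` of repeat counts (relative
#'   to the root state 0).
#' @export
rcoal_tpm <- function(n_copies, theta, params = tpm_params(), n_rep = 1) {
  stopifnot(n_copies >= 2, theta >= 0, n_rep >= 1)
  if (theta == 0)
    return(matrix(0L, n_rep, n_copies))
  if (n_copies > 256) {
    # large samples: per-replicate tree propagation is O(n), the batch
    # lineage bookkeeping below is O(n^2)
    out <- matrix(0L, n_rep, n_copies)
    for (r in seq_len(n_rep))
      out[r, ] <- rcoal_tree_once(n_copies, theta, params)
    return(out)
  }
  R <- n_rep; n <- n_copies
  state <- matrix(0L, R, n)
  lin <- matrix(rep(seq_len(n), each = R), R, n)
  ri <- rep(seq_len(R), n)  # row index of each cell, column-major
  for (k in n:2) {
    t <- stats::rexp(R, rate = k * (k - 1) / 2)
    lam <- theta / 2 * t
    M <- matrix(stats::rpois(R * k, lambda = lam), R, k)
    tot <- sum(M)
    if (tot > 0) {
      steps <- tpm_steps(tot, params)
      Mv <- as.vector(M)
      grp <- rep.int(seq_along(Mv), Mv)
      agg <- rowsum(steps, grp)
      ssum <- numeric(length(Mv))
      ssum[as.integer(rownames(agg))] <- agg
      Smat <- matrix(ssum, R, k)
      state <- state + matrix(Smat[cbind(ri, as.vector(lin))], R, n)
    }
    if (k > 1) {
      i <- sample.int(k, R, replace = TRUE)
      j <- sample.int(k - 1, R, replace = TRUE)
      j <- j + (j >= i)
      imat <- matrix(i, R, n); jmat <- matrix(j, R, n)
      mrg <- lin == jmat
      lin[mrg] <- imat[mrg]
      relab <- lin == k
      lin[relab] <- jmat[relab]
    }
  }
  storage.mode(state) <- "integer"
  state
}

# internal: one coalescent TPM sample by explicit tree construction and
# root-to-leaf mutation propagation; O(n) via swap-remove of lineages
rcoal_tree_once <- function(n, theta, params) {
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes); blen <- numeric(n_nodes)
  node_time <- numeric(n_nodes)
  active <- seq_len(n); k <- n; tcur <- 0; nxt <- n + 1L
  while (k > 1L) {
    tcur <- tcur + stats::rexp(1, k * (k - 1) / 2)
    i1 <- sample.int(k, 1L); i2 <- sample.int(k - 1L, 1L)
    i2 <- i2 + (i2 >= i1)
    c1 <- active[i1]; c2 <- active[i2]
    parent[c1] <- nxt; parent[c2] <- nxt
    blen[c1] <- tcur - node_time[c1]; blen[c2] <- tcur - node_time[c2]
    node_time[nxt] <- tcur
    active[i1] <- nxt
    active[i2] <- active[k]
    k <- k - 1L; nxt <- nxt + 1L
  }
  nb <- n_nodes - 1L
  nm <- stats::rpois(nb, theta / 2 * blen[seq_len(nb)])
  stepsum <- numeric(n_nodes)
  tot <- sum(nm)
  if (tot > 0) {
    steps <- tpm_steps(tot, params)
    grp <- rep.int(seq_len(nb), nm)
    agg <- rowsum(steps, grp)
    stepsum[as.integer(rownames(agg))] <- agg
  }
  state <- numeric(n_nodes)
  for (id in nb:1) state[id] <- state[parent[id]] + stepsum[id]
  as.integer(state[seq_len(n)])
}

# internal: per-replicate allele count matrix (alleles x reps) from a
# batch of repeat-count samples; returns list(k, H_unbiased, range)
batch_summary <- function(states) {
  R <- nrow(states); n <- ncol(states)
  v <- as.vector(states)
  v <- v - min(v) + 1L
  Mx <- max(v)
  key <- (rep(seq_len(R), ncol(states)) - 1L) * Mx + v
  cnt <- tabulate(key, nbins = R * Mx)
  cm <- matrix(cnt, nrow = Mx, ncol = R)
  k <- colSums(cm > 0L)
  sum_sq <- colSums((cm / n)^2)
  H <- (n / (n - 1)) * (1 - sum_sq)
  rowmin <- Reduce(pmin, lapply(seq_len(ncol(states)),
                                function(j) states[, j]))
  rowmax <- Reduce(pmax, lapply(seq_len(ncol(states)),
                                function(j) states[, j]))
  list(k = k, H = H, range = rowmax - rowmin)
}

# ---- M-ratio ----------------------------------------------------------------

#' Garza-Williamson M-ratio
#'
#' Per polymorphic locus, `M = k / r` with `k` the number of distinct
#' alleles and `r = (max - min)/motif + 1` the number of lattice states in
#' the observed size range (endpoints inclusive). Allele sizes off the
#' motif lattice are snapped to the nearest lattice point with a warning.
#' The multilocus value is the mean over polymorphic loci.
#'
#' @param ds a [gtds] object.
#' @param population population name.
#' @return list with `per_locus` (NA at monomorphic loci) and `M`.
#' @export
m_ratio <- function(ds, population) {
  p <- gtds_pop(ds, population)
  vals <- vapply(seq_along(ds$loci), function(l) {
    sizes <- unique(locus_copies(p, l))
    if (length(sizes) < 2) return(NA_real_)
    motif <- ds$motif[[ds$loci[l]]]
    lo <- min(sizes)
    off <- (sizes - lo) %% motif
    if (any(off != 0)) {
      warning(sprintf("locus %s: allele sizes off the %g-bp lattice snapped",
                      ds$loci[l], motif))
      sizes <- lo + round((sizes - lo) / motif) * motif
      sizes <- unique(sizes)
      if (length(sizes) < 2) return(NA_real_)
    }
    k <- length(sizes)
    r <- (max(sizes) - min(sizes)) / motif + 1
    k / r
  }, numeric(1))
  names(vals) <- ds$loci
  list(per_locus = vals, M = mean(vals, na.rm = TRUE))
}

#' Critical M value from equilibrium coalescent simulation
#'
#' Simulates `n_iter` equilibrium samples (each `n_loci` independent loci
#' of `2 * n_individuals` gene copies) under the coalescent with TPM
#' mutation at the stated `theta`, computes the multilocus M of each
#' replicate, and returns the 5th percentile of that equilibrium
#' distribution: 95% of equilibrium replicates exceed Mc, so an observed
#' M below Mc signals a bottleneck at the 5% level. Ties at the percentile
#' break conservatively (the lower order statistic is used).
#'
#' @param theta scaled mutation rate 4*Ne*mu of the prebottleneck
#'   population.
#' @param params a [tpm_params].
#' @param n_individuals diploid sample size.
#' @param n_loci loci per replicate.
#' @param n_iter equilibrium replicates (>= 100 for a stable percentile).
#' @param seed optional integer seed.
#' @return list with `Mc`, `M_equilibrium` (the replicate values), and the
#'   settings.
#' @export
critical_m <- function(theta, params = tpm_params(), n_individuals,
                       n_loci, n_iter = 10000, seed = NULL) {
  stopifnot(theta > 0)
  if (n_iter < 100) warning("n_iter < 100 gives an unstable percentile")
  if (!is.null(seed)) {
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
    set.seed(seed)
  }
  n <- 2 * n_individuals
  msum <- numeric(n_iter); mcnt <- integer(n_iter)
  for (l in seq_len(n_loci)) {
    st <- rcoal_tpm(n, theta, params, n_rep = n_iter)
    bs <- batch_summary(st)
    poly <- bs$k >= 2
    m <- ifelse(poly, bs$k / (bs$range + 1), NA_real_)
    msum[poly] <- msum[poly] + m[poly]
    mcnt[poly] <- mcnt[poly] + 1L
  }
  M <- ifelse(mcnt > 0, msum / mcnt, NA_real_)
  Mok <- M[!is.na(M)]
  idx <- max(1L, floor(0.05 * length(Mok)))
  Mc <- sort(Mok)[idx]
  list(Mc = Mc, M_equilibrium = M, theta = theta, n_individuals =
         n_individuals, n_loci = n_loci, n_iter = n_iter)
}

# ---- heterozygosity excess --------------------------------------------------

# internal: mean simulated allele count at a given theta, restricted to
# polymorphic outcomes (k >= 2) to mirror the observed loci
.mean_k <- function(n, theta, params, B) {
  k <- batch_summary(rcoal_tpm(n, theta, params, n_rep = B))$k
  k <- k[k >= 2]
  if (!length(k)) return(1)
  mean(k)
}

# internal: find theta whose equilibrium mean polymorphic allele count
# matches k_target (bisection on log theta, bracket widened as needed)
tune_theta <- function(n, k_target, params, B = 100) {
  lo <- 1e-3; hi <- 10
  while (.mean_k(n, hi, params, B) < k_target && hi < 1e4) hi <- hi * 4
  while (.mean_k(n, lo, params, B) > k_target && lo > 1e-6) lo <- lo / 4
  for (it in 1:12) {
    mid <- sqrt(lo * hi)
    if (.mean_k(n, mid, params, B) < k_target) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

# internal: per-locus tuned rejection fallback for allele counts too rare
# at the population-level theta
h_eq_conditional <- function(n, k_obs, params, n_iter, max_batches = 40,
                             theta0 = NULL) {
  th <- theta0 %||% tune_theta(n, k_obs, params)
  acc <- numeric(0)
  B <- max(200L, as.integer(n_iter))
  for (b in seq_len(max_batches)) {
    bs <- batch_summary(rcoal_tpm(n, th, params, n_rep = B))
    acc <- c(acc, bs$H[bs$k == k_obs])
    if (length(acc) >= n_iter) break
    if (b == 5 && length(acc) < 0.01 * 5 * B) {
      # acceptance below 1%: re-tune with a larger calibration batch
      th <- tune_theta(n, k_obs, params, B = 300)
    }
  }
  if (length(acc) < 30)
    stop(sprintf("could not condition on k = %d (acceptance too low)",
                 k_obs))
  utils::head(acc, n_iter)
}

#' Heterozygosity-excess bottleneck test
#'
#' Tests for the transient elevation of gene diversity relative to the
#' mutation-drift-equilibrium expectation given the observed allele count,
#' the signature of a recent bottleneck. A single population-level theta
#' is tuned by bisection until the mean simulated (polymorphic) allele
#' count matches the mean observed one - under the null all loci share one
#' mutation-drift history - and a large equilibrium reference batch is
#' simulated at that theta for each distinct sample size. Each locus's
#' equilibrium gene-diversity distribution is then the reference draws
#' with exactly its observed allele count k (rejection conditioning at the
#' common theta; loci whose k is too rare at the common theta fall back to
#' a per-locus tuned rejection). The standardised difference
#' `(H_E - mean H_eq)/SD(H_eq)` is computed per locus and a one-tailed
#' Wilcoxon signed-rank test across loci assesses heterozygosity excess.
#'
#' Conditioning at the common theta (rather than re-tuning theta per
#' locus) keeps the null calibrated: per-locus tuning shifts the reference
#' distribution toward each locus's chance deviation in k and biases the
#' standardised differences upward over many loci.
#'
#' @param ds a [gtds] object.
#' @param population population name.
#' @param params a [tpm_params]; 90% single-step is the conventional
#'   setting.
#' @param n_iter minimum equilibrium replicates behind each locus's
#'   reference distribution.
#' @param seed optional integer seed.
#' @param min_loci minimum polymorphic loci (Wilcoxon needs >= 4).
#' @return list with `wilcoxon_p`, `n_loci_used`, `theta_hat`,
#'   `std_diff` (per locus), `undefined`.
#' @export
heterozygosity_excess_test <- function(ds, population,
                                       params = tpm_params(p_single = 0.9),
                                       n_iter = 1000, seed = NULL,
                                       min_loci = 4) {
  p <- gtds_pop(ds, population)
  if (!is.null(seed)) {
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
    set.seed(seed)
  }
  obs <- list()
  for (l in seq_along(ds$loci)) {
    al <- locus_copies(p, l)
    n <- length(al)
    if (n < 4) next
    k_obs <- length(unique(al))
    if (k_obs < 2) next
    pr <- as.numeric(table(al)) / n
    obs[[ds$loci[l]]] <- list(n = n, k = k_obs,
                              H = (n / (n - 1)) * (1 - sum(pr^2)))
  }
  if (length(obs) < min_loci)
    return(list(wilcoxon_p = NA_real_, n_loci_used = length(obs),
                theta_hat = NA_real_, std_diff = numeric(0),
                undefined = TRUE))
  ns <- vapply(obs, `[[`, 0L, "n")
  ks <- vapply(obs, `[[`, 0L, "k")
  n_mode <- as.integer(names(sort(table(ns), decreasing = TRUE))[1])
  theta_hat <- tune_theta(n_mode, mean(ks), params, B = 300)

  # pooled equilibrium reference per sample size, binned by allele count
  ref <- new.env(parent = emptyenv())
  for (n in unique(ns)) {
    need_k <- sort(unique(ks[ns == n]))
    hbin <- stats::setNames(vector("list", length(need_k)),
                            as.character(need_k))
    B <- max(2000L, 4L * as.integer(n_iter))
    for (b in 1:25) {
      bs <- batch_summary(rcoal_tpm(n, theta_hat, params, n_rep = B))
      for (kk in need_k) {
        hv <- bs$H[bs$k == kk]
        if (length(hv))
          hbin[[as.character(kk)]] <- c(hbin[[as.character(kk)]], hv)
      }
      if (all(vapply(hbin, length, 0L) >= n_iter)) break
    }
    assign(as.character(n), hbin, envir = ref)
  }
  dh <- c(); qq <- c()
  for (nm in names(obs)) {
    o <- obs[[nm]]
    heq <- get(as.character(o$n), envir = ref)[[as.character(o$k)]]
    if (length(heq) < 30)
      heq <- tryCatch(h_eq_conditional(o$n, o$k, params, n_iter),
                      error = function(e) NULL)
    if (is.null(heq) || length(heq) < 30) next
    s <- stats::sd(heq)
    if (!is.finite(s) || s == 0) next
    dh <- c(dh, stats::setNames((o$H - mean(heq)) / s, nm))
    # mid-rank conditional quantile of the observed gene diversity
    qq <- c(qq, (sum(heq < o$H) + 0.5 * sum(heq == o$H) + 0.5) /
              (length(heq) + 1))
  }
  if (length(dh) < min_loci)
    return(list(wilcoxon_p = NA_real_, n_loci_used = length(dh),
                theta_hat = theta_hat, std_diff = dh, undefined = TRUE))
  # one-tailed Wilcoxon signed-rank for excess, applied to the conditional
  # quantiles centred at 1/2: under the null each quantile is uniform,
  # hence symmetric about 1/2, which keeps the signed-rank test calibrated
  # for any number of loci (the standardised differences themselves are
  # left-skewed, with a positive median even at equilibrium)
  pval <- suppressWarnings(
    stats::wilcox.test(qq - 0.5, alternative = "greater")$p.value)
  list(wilcoxon_p = pval, n_loci_used = length(dh), theta_hat = theta_hat,
       std_diff = dh, quantiles = qq, undefined = FALSE)
}

#' Per-population bottleneck report
#'
#' Combines the heterozygosity-excess test and the M-ratio with critical
#' values at a grid of prebottleneck theta settings.
#'
#' @param ds a [gtds] object.
#' @param thetas named numeric vector of prebottleneck theta values.
#' @param params_m TPM settings for the M-ratio simulations.
#' @param params_h TPM settings for the heterozygosity-excess test.
#' @param n_iter_mc equilibrium replicates for each Mc.
#' @param n_iter_h accepted replicates per locus for the excess test.
#' @param seed optional integer seed.
#' @return data.frame, one row per population.
#' @export
bottleneck_report <- function(ds, thetas = c(theta1 = 0.6, theta2 = 3,
                                             theta3 = 6),
                              params_m = tpm_params(),
                              params_h = tpm_params(p_single = 0.9),
                              n_iter_mc = 10000, n_iter_h = 1000,
                              seed = NULL) {
  rows <- list()
  for (nm in names(ds$pops)) {
    p <- ds$pops[[nm]]
    mr <- m_ratio(ds, nm)
    n_poly <- sum(!is.na(mr$per_locus))
    he <- heterozygosity_excess_test(ds, nm, params = params_h,
                                     n_iter = n_iter_h, seed = seed)
    mcs <- vapply(seq_along(thetas), function(i)
      critical_m(thetas[i], params_m, nrow(p$a1), max(n_poly, 1),
                 n_iter = n_iter_mc,
                 seed = if (is.null(seed)) NULL else seed + i)$Mc,
      numeric(1))
    row <- data.frame(population = nm, wilcoxon_p = he$wilcoxon_p,
                      n_loci_used = he$n_loci_used, M = mr$M,
                      stringsAsFactors = FALSE)
    for (i in seq_along(thetas)) {
      row[[paste0("Mc_", names(thetas)[i])]] <- mcs[i]
      row[[paste0("bottleneck_", names(thetas)[i])]] <- mr$M < mcs[i]
    }
    rows[[nm]] <- row
  }
  do.call(rbind, rows)
}
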