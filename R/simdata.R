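# Synthetic-data generator: forward-time Wright-Fisher simulation of a
# common ancestral pool with habitat-structured daughter populations
# (recent coastal founders with gene flow, long-isolated small inland
# isolates), TPM microsatellite mutation and map-based recombination.

#' Define a demographic scenario
#'
#' A scenario is a common ancestral pool plus a set of daughter demes, each
#' founded from the pool at a stated time with a stated founder count, with
#' optional continuing migration from the pool. Demes flagged
#' `sample_ancestral` are not simulated forward: they are disjoint samples
#' of the ancestral pool itself (open marine populations).
#'
#' All parameters are on the natural (unscaled) timescale; `rescale = f`
#' divides Ne, founder counts and times by `f` and multiplies the mutation,
#' migration and recombination rates by `f`, preserving the scaled
#' compounds (theta = 4*Ne*mu, Nm, 4*Ne*c). Scaled deme sizes are floored
#' at `sample_n` diploids so the final sample is always possible.
#'
#' @param ancestral_Ne diploid size of the ancestral pool.
#' @param demes named list; each element a list with `habitat`, `coastal`
#'   (logical), and either `sample_ancestral = TRUE` or `t_found`
#'   (generations ago), `founders`, `Ne`, `m` (per-generation migrant
#'   probability from the pool).
#' @param map a `marker_map` (with optional `motif_bp`); marker order
#'   defines the locus order.
#' @param recomb_per_mb recombination probability per Mb per meiosis
#'   between adjacent syntenic markers (capped at 0.5); markers on
#'   different linkage groups segregate independently.
#' @param tpm a [tpm_params] mutation model.
#' @param repeat_bounds allowed repeat-count range (reflecting boundaries).
#' @param sample_n diploid individuals sampled per population.
#' @param burnin_mult forward burn-in length in units of the (scaled)
#'   ancestral Ne, run after the coalescent-equilibrium initialisation.
#' @param rescale Ne-rescaling factor (>= 1) for fast simulation.
#' @param size_offset_bp additive offset when converting repeat counts to
#'   fragment sizes (bp).
#' @return object of class `demographic_scenario`.
#' @export
demographic_scenario <- function(ancestral_Ne, demes, map,
                                 recomb_per_mb = 0.01, tpm = tpm_params(),
                                 repeat_bounds = c(5, 60), sample_n = 24,
                                 burnin_mult = 2, rescale = 1,
                                 size_offset_bp = 100) {
  stopifnot(ancestral_Ne >= 2, rescale >= 1, length(repeat_bounds) == 2,
            repeat_bounds[1] < repeat_bounds[2])
  if (is.null(names(demes)) || any(!nzchar(names(demes))))
    stop("demes must be named")
  for (nm in names(demes)) {
    d <- demes[[nm]]
    if (is.null(d$habitat) || !d$habitat %in% HABITATS)
      stop(sprintf("deme '%s': invalid habitat", nm))
    if (isTRUE(d$sample_ancestral)) next
    if (is.null(d$t_found) || d$t_found < 1)
      stop(sprintf("deme '%s': t_found must be >= 1", nm))
    if (is.null(d$founders) || d$founders < 1 ||
        d$founders > ancestral_Ne)
      stop(sprintf("deme '%s': founders must be in [1, ancestral_Ne]", nm))
    if (is.null(d$Ne) || d$Ne < 2)
      stop(sprintf("deme '%s': Ne must be >= 2", nm))
    m <- d$m %||% 0
    if (m < 0 || m >= 1) stop(sprintf("deme '%s': m must be in [0,1)", nm))
    demes[[nm]]$m <- m
    demes[[nm]]$coastal <- isTRUE(d$coastal)
  }
  structure(list(ancestral_Ne = ancestral_Ne, demes = demes, map = map,
                 recomb_per_mb = recomb_per_mb, tpm = tpm,
                 repeat_bounds = repeat_bounds, sample_n = sample_n,
                 burnin_mult = burnin_mult, rescale = rescale,
                 size_offset_bp = size_offset_bp),
            class = "demographic_scenario")
}

# ---- Wright-Fisher machinery ------------------------------------------------

# internal: reflect repeat counts into [lo, hi]
reflect_bounds <- function(x, bounds) {
  lo <- bounds[1]; hi <- bounds[2]
  for (it in 1:20) {
    out <- x < lo | x > hi
    if (!any(out)) return(x)
    x <- ifelse(x < lo, 2L * lo - x, x)
    x <- ifelse(x > hi, 2L * hi - x, x)
  }
  pmin(pmax(x, lo), hi)
}

# internal: one recombinant gamete per row of pidx. sw_prob[j] is the
# switch probability entering locus j (0.5 at linkage-group starts).
make_gametes <- function(H1, H2, pidx, sw_prob, lg_start) {
  n <- length(pidx); L <- length(sw_prob)
  B <- matrix(stats::runif(n * L) < rep(sw_prob, each = n), n, L)
  S <- B
  if (L >= 2) for (j in 2:L) if (!lg_start[j])
    S[, j] <- S[, j - 1] != B[, j]
  G <- H1[pidx, , drop = FALSE]
  Bm <- H2[pidx, , drop = FALSE]
  G[S] <- Bm[S]
  G
}

# internal: TPM mutation with reflecting boundaries, applied in place
mutate_gametes <- function(G, mu, params, bounds) {
  idx <- which(stats::runif(length(G)) < mu)
  if (length(idx))
    G[idx] <- reflect_bounds(G[idx] + tpm_steps(length(idx), params),
                             bounds)
  G
}

# internal: one Wright-Fisher generation; pop and mig_pool are lists with
# H1, H2 (diploid individuals x loci, repeat counts)
wf_generation <- function(pop, n_off, sw_prob, lg_start, mu, params,
                          bounds, mig_pool = NULL, m = 0) {
  mig <- if (m > 0 && !is.null(mig_pool))
    stats::runif(n_off) < m else rep(FALSE, n_off)
  n_res <- sum(!mig); n_mig <- sum(mig)
  gam <- function(src, n) {
    p1 <- sample.int(nrow(src$H1), n, replace = TRUE)
    p2 <- sample.int(nrow(src$H1), n, replace = TRUE)
    list(make_gametes(src$H1, src$H2, p1, sw_prob, lg_start),
         make_gametes(src$H1, src$H2, p2, sw_prob, lg_start))
  }
  L <- ncol(pop$H1)
  H1 <- matrix(0L, n_off, L); H2 <- matrix(0L, n_off, L)
  if (n_res) {
    g <- gam(pop, n_res)
    H1[!mig, ] <- g[[1]]; H2[!mig, ] <- g[[2]]
  }
  if (n_mig) {
    g <- gam(mig_pool, n_mig)
    H1[mig, ] <- g[[1]]; H2[mig, ] <- g[[2]]
  }
  list(H1 = mutate_gametes(H1, mu, params, bounds),
       H2 = mutate_gametes(H2, mu, params, bounds))
}

# internal: coalescent-equilibrium initial pool (independent loci, linkage
# equilibrium - the neutral equilibrium for a panmictic pool at these
# marker spacings); repeat counts centred in the allowed band
init_pool_equilibrium <- function(N, L, theta, params, bounds) {
  n <- 2L * N
  H1 <- matrix(0L, N, L); H2 <- matrix(0L, N, L)
  centre <- round(mean(bounds))
  for (l in seq_len(L)) {
    st <- drop(rcoal_tpm(n, theta, params, n_rep = 1))
    st <- st - as.integer(round(mean(st))) + centre
    st <- reflect_bounds(st, bounds)
    H1[, l] <- st[seq_len(N)]
    H2[, l] <- st[N + seq_len(N)]
  }
  list(H1 = H1, H2 = H2)
}

#' Simulate a metapopulation under a demographic scenario
#'
#' Forward-time diploid Wright-Fisher simulation. The ancestral pool is
#' initialised at per-locus coalescent equilibrium under the same TPM
#' mutation model and burned forward for `burnin_mult` x Ne generations;
#' daughter demes are founded at their stated times by sampling founder
#' individuals from the pool and thereafter reproduce at their own Ne with
#' optional continuing migration from the pool. Recombination between
#' adjacent syntenic markers uses `min(0.5, rate_per_Mb x gap_Mb)` per
#' meiosis. Finally `sample_n` individuals per population are sampled and
#' emitted as bp fragment sizes (`offset + motif x repeat count`).
#'
#' @param scenario a [demographic_scenario].
#' @param seed optional integer seed (all randomness flows from it).
#' @return list with `dataset` (a [gtds]), `map` (the marker map used) and
#'   `truth` (class `sim_truth`: sampled phased haplotypes per population
#'   and the scenario echo).
#' @export
simulate_metapopulation <- function(scenario, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
    set.seed(seed)
  }
  sc <- scenario
  f <- sc$rescale
  map <- sc$map[order(sc$map$lg, sc$map$position_mb), , drop = FALSE]
  L <- nrow(map)
  lg_start <- !duplicated(map$lg)
  gaps <- c(0, diff(map$position_mb))
  gaps[lg_start] <- 0
  sw_prob <- pmin(0.5, sc$recomb_per_mb * f * gaps)
  sw_prob[lg_start] <- 0.5
  motif <- if ("motif_bp" %in% names(map)) map$motif_bp else rep(4, L)

  Na <- max(2L, as.integer(round(sc$ancestral_Ne / f)))
  mu <- min(0.5, sc$tpm$mu * f)
  theta_anc <- 4 * Na * mu
  bounds <- sc$repeat_bounds

  fwd <- names(sc$demes)[!vapply(sc$demes, function(d)
    isTRUE(d$sample_ancestral), logical(1))]
  anc_demes <- setdiff(names(sc$demes), fwd)
  # founder counts are NOT rescaled: a founding event is an instantaneous
  # sample whose severity is its copy number, which rescaling must preserve
  dscale <- lapply(sc$demes[fwd], function(d) list(
    t = max(1L, as.integer(round(d$t_found / f))),
    founders = min(Na, as.integer(d$founders)),
    Ne = max(sc$sample_n, as.integer(round(d$Ne / f))),
    m = min(0.5, d$m * f)))
  Tmax <- if (length(dscale)) max(vapply(dscale, `[[`, 0L, "t")) else 0L

  anc <- init_pool_equilibrium(Na, L, theta_anc, sc$tpm, bounds)
  pops <- list()
  # when nothing samples or migrates from the evolving pool, the pool is a
  # stationary source and its forward evolution is skipped: each isolated
  # deme is founded from the equilibrium pool and run for its own t
  static_pool <- length(anc_demes) == 0 &&
    all(vapply(dscale, function(d) d$m == 0, logical(1)))
  burnin <- if (static_pool) 0L else as.integer(ceiling(sc$burnin_mult * Na))
  if (static_pool) {
    for (d in fwd) {
      idx <- sample.int(Na, dscale[[d]]$founders)
      pops[[d]] <- list(H1 = anc$H1[idx, , drop = FALSE],
                        H2 = anc$H2[idx, , drop = FALSE])
      for (g in seq_len(dscale[[d]]$t))
        pops[[d]] <- wf_generation(pops[[d]], dscale[[d]]$Ne, sw_prob,
                                   lg_start, mu, sc$tpm, bounds)
    }
  } else {
    for (tbp in seq(burnin + Tmax, 1)) {
      anc <- wf_generation(anc, Na, sw_prob, lg_start, mu, sc$tpm, bounds)
      for (d in names(pops))
        pops[[d]] <- wf_generation(pops[[d]], dscale[[d]]$Ne, sw_prob,
                                   lg_start, mu, sc$tpm, bounds,
                                   mig_pool = anc, m = dscale[[d]]$m)
      for (d in fwd) if (is.null(pops[[d]]) && dscale[[d]]$t == tbp - 1L) {
        idx <- sample.int(Na, dscale[[d]]$founders)
        pops[[d]] <- list(H1 = anc$H1[idx, , drop = FALSE],
                          H2 = anc$H2[idx, , drop = FALSE])
      }
    }
  }
  # demes founded with t = burnin+Tmax edge: found before loop would be
  # needed only if t >= burnin + Tmax, which burnin > 0 precludes

  loci <- map$marker
  to_bp <- function(H) {
    sz <- sweep(H, 2, motif, `*`) + sc$size_offset_bp
    storage.mode(sz) <- "integer"
    sz
  }
  # disjoint samples of the pool for the marine-type demes
  if (length(anc_demes)) {
    need <- sc$sample_n * length(anc_demes)
    if (need > Na) stop("ancestral pool too small for the requested samples")
    pool_idx <- sample.int(Na, need)
  }
  out_pops <- list(); haplos <- list()
  k <- 0L
  for (d in names(sc$demes)) {
    if (d %in% anc_demes) {
      idx <- pool_idx[k * sc$sample_n + seq_len(sc$sample_n)]
      k <- k + 1L
      h1 <- anc$H1[idx, , drop = FALSE]; h2 <- anc$H2[idx, , drop = FALSE]
    } else {
      idx <- sample.int(nrow(pops[[d]]$H1), sc$sample_n)
      h1 <- pops[[d]]$H1[idx, , drop = FALSE]
      h2 <- pops[[d]]$H2[idx, , drop = FALSE]
    }
    b1 <- to_bp(h1); b2 <- to_bp(h2)
    colnames(b1) <- colnames(b2) <- loci
    out_pops[[d]] <- list(habitat = sc$demes[[d]]$habitat,
                          coastal = isTRUE(sc$demes[[d]]$coastal),
                          a1 = b1, a2 = b2)
    haplos[[d]] <- list(h1 = b1, h2 = b2)
  }
  ds <- gtds(out_pops, loci, motif = stats::setNames(motif, loci))
  truth <- structure(list(haplos = haplos, scenario = sc,
                          scaled = list(Na = Na, mu = mu, burnin = burnin,
                                        demes = dscale)),
                     class = "sim_truth")
  list(dataset = ds, map = marker_map(map), truth = truth)
}

#' True two-locus haplotype frequencies from a simulation
#'
#' Joint haplotype frequencies tallied over the sampled phased gametes of
#' a simulated population - the LD oracle the unphased estimators are
#' checked against.
#'
#' @param truth a `sim_truth`.
#' @param population deme name.
#' @param locusA,locusB marker ids.
#' @return a [hap_freq] with `source = "simulated-truth"`.
#' @export
truth_haplotype_freqs <- function(truth, population, locusA, locusB) {
  h <- truth$haplos[[population]]
  if (is.null(h)) stop(sprintf("unknown population '%s'", population))
  ga <- c(h$h1[, locusA], h$h2[, locusA])
  gb <- c(h$h1[, locusB], h$h2[, locusB])
  aA <- sort(unique(ga)); aB <- sort(unique(gb))
  tab <- matrix(0, length(aA), length(aB), dimnames = list(aA, aB))
  for (i in seq_along(ga))
    tab[as.character(ga[i]), as.character(gb[i])] <-
      tab[as.character(ga[i]), as.character(gb[i])] + 1
  hap_freq(tab / length(ga), locusA, locusB, n_chromosomes = length(ga),
           source = "simulated-truth")
}

# ---- presets ----------------------------------------------------------------

#' Default 109-marker, 20-linkage-group map
#'
#' Deterministic marker layout emulating a microsatellite panel mapped to
#' a fish genome: 109 markers over 20 linkage groups (2-13 markers each),
#' adjacent spacings from 0.001 to ~11.5 Mb with mean near 2.7 Mb, and
#' repeat motifs cycling over 2/3/4 bp.
#'
#' @return a `marker_map`.
#' @export
default_marker_map <- function() {
  sizes <- c(13, 11, 10, 9, 8, 7, 6, 6, 5, 5, 4, 4, 4, 3, 3, 3, 2, 2, 2, 2)
  stopifnot(sum(sizes) == 109, all(sizes >= 2))
  spacing <- c(0.5, 2.0, 3.7, 1.2, 5.5, 0.8, 2.7, 9.0, 1.6, 4.2, 0.001,
               3.1, 2.2, 6.5, 1.0, 11.496, 0.3, 4.8, 2.5, 1.8, 0.6, 3.4)
  motifs <- c(4, 2, 3, 4, 2, 4, 3, 2, 4, 3)
  rows <- list(); sp_i <- 1L; mo_i <- 1L; id <- 1L
  for (lg in seq_along(sizes)) {
    pos <- 0
    for (j in seq_len(sizes[lg])) {
      if (j > 1) {
        pos <- pos + spacing[sp_i]
        sp_i <- if (sp_i == length(spacing)) 1L else sp_i + 1L
      }
      rows[[id]] <- data.frame(marker = sprintf("M%03d", id),
                               lg = sprintf("LG%02d", lg),
                               position_mb = pos,
                               motif_bp = motifs[mo_i],
                               stringsAsFactors = FALSE)
      mo_i <- if (mo_i == length(motifs)) 1L else mo_i + 1L
      id <- id + 1L
    }
  }
  marker_map(do.call(rbind, rows))
}

#' Habitat scenario presets
#'
#' Four templates encoding the contrasting demographic histories of the
#' study system: open marine populations (large connected pool), coastal
#' freshwater (recently founded, large, with continuing gene flow from the
#' marine pool), inland lakes (older founder events, moderate Ne, fully
#' isolated) and inland ponds (severe founder events, small Ne, long
#' isolated). Expected diversity ordering marine ~ coastal > lake > pond
#' and LD ordering pond > lake > marine. Each template carries a default
#' Ne-rescaling factor chosen so a replicate simulates in seconds; pass
#' `rescale` to override all of them.
#'
#' @param rescale optional common rescaling factor overriding the
#'   per-template defaults.
#' @param map marker map (default [default_marker_map()]).
#' @param sample_n sampled individuals per population.
#' @return named list of [demographic_scenario] objects:
#'   `marine`, `coastal`, `inland_lake`, `inland_pond`.
#' @export
preset_scenarios <- function(rescale = NULL, map = default_marker_map(),
                             sample_n = 24) {
  mk <- function(anc, demes, f)
    demographic_scenario(anc, demes, map, rescale = rescale %||% f,
                         sample_n = sample_n)
  list(
    marine = mk(5000, list(
      M1 = list(habitat = "marine", sample_ancestral = TRUE),
      M2 = list(habitat = "marine", sample_ancestral = TRUE)), 20),
    coastal = mk(5000, list(
      C1 = list(habitat = "lake", coastal = TRUE, t_found = 500,
                founders = 200, Ne = 1000, m = 0.01),
      C2 = list(habitat = "river", coastal = TRUE, t_found = 500,
                founders = 200, Ne = 1000, m = 0.01)), 20),
    inland_lake = mk(5000, list(
      L1 = list(habitat = "lake", t_found = 4000, founders = 50, Ne = 500,
                m = 0),
      L2 = list(habitat = "lake", t_found = 4000, founders = 50, Ne = 500,
                m = 0)), 4),
    inland_pond = mk(5000, list(
      P1 = list(habitat = "pond", t_found = 2000, founders = 20, Ne = 100,
                m = 0),
      P2 = list(habitat = "pond", t_found = 2000, founders = 20, Ne = 100,
                m = 0)), 4))
}

#' Equilibrium single-population sample via the coalescent
#'
#' Draws a mutation-drift-equilibrium sample directly from the coalescent
#' with TPM mutation (loci independent). Used for null calibrations where
#' no demographic structure is wanted.
#'
#' @param n_ind diploid individuals.
#' @param n_loci loci.
#' @param theta scaled mutation rate 4*Ne*mu.
#' @param params a [tpm_params].
#' @param motif repeat motif (bp) for the emitted fragment sizes.
#' @param population,habitat labels for the emitted dataset.
#' @param seed optional integer seed.
#' @return a single-population [gtds].
#' @export
equilibrium_dataset <- function(n_ind, n_loci, theta,
                                params = tpm_params(), motif = 4,
                                population = "eq1", habitat = "marine",
                                seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
    set.seed(seed)
  }
  n <- 2L * n_ind
  st <- rcoal_tpm(n, theta, params, n_rep = n_loci)
  a1 <- matrix(0L, n_ind, n_loci); a2 <- matrix(0L, n_ind, n_loci)
  for (l in seq_len(n_loci)) {
    sz <- 100L + motif * (st[l, ] - min(st[l, ]))
    a1[, l] <- sz[seq_len(n_ind)]
    a2[, l] <- sz[n_ind + seq_len(n_ind)]
  }
  loci <- sprintf("EQ%03d", seq_len(n_loci))
  colnames(a1) <- colnames(a2) <- loci
  pops <- stats::setNames(list(list(habitat = habitat, coastal = FALSE,
                                    a1 = a1, a2 = a2)), population)
  gtds(pops, loci, motif = stats::setNames(rep(motif, n_loci), loci))
}

# ---- export -----------------------------------------------------------------

#' Export a simulated dataset with its map, habitat table and truth record
#'
#' Writes `genotypes.gen` (GenePop), `marker_map.tsv`, `habitat_table.tsv`
#' and, when a truth record is given, `truth_haplotypes.tsv` (sampled
#' phased gametes) and `scenario.txt` (a key = value echo). The files
#' round-trip through [read_genepop()].
#'
#' @param ds a [gtds].
#' @param map a `marker_map`.
#' @param out_dir output directory (created if needed).
#' @param truth optional `sim_truth`.
#' @return invisible character vector of the paths written.
#' @export
export_dataset <- function(ds, map, out_dir, truth = NULL) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  paths <- c(genotypes = file.path(out_dir, "genotypes.gen"),
             map = file.path(out_dir, "marker_map.tsv"),
             habitat = file.path(out_dir, "habitat_table.tsv"))
  write_genepop(ds, paths["genotypes"])
  write_marker_map(map, paths["map"])
  write_habitat_table(ds, paths["habitat"])
  if (!is.null(truth)) {
    tp <- file.path(out_dir, "truth_haplotypes.tsv")
    rows <- list()
    for (p in names(truth$haplos)) {
      h <- truth$haplos[[p]]
      for (i in seq_len(nrow(h$h1))) {
        rows[[length(rows) + 1L]] <- data.frame(
          population = p, individual = i, phase = 1L,
          t(h$h1[i, , drop = TRUE]), stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          population = p, individual = i, phase = 2L,
          t(h$h2[i, , drop = TRUE]), stringsAsFactors = FALSE)
      }
    }
    utils::write.table(do.call(rbind, rows), tp, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sp <- file.path(out_dir, "scenario.txt")
    sc <- truth$scenario
    con <- file(sp, "w")
    writeLines(c(
      sprintf("ancestral_Ne = %g", sc$ancestral_Ne),
      sprintf("recomb_per_mb = %g", sc$recomb_per_mb),
      sprintf("mu = %g", sc$tpm$mu),
      sprintf("p_single = %g", sc$tpm$p_single),
      sprintf("mean_multistep = %g", sc$tpm$mean_multistep),
      sprintf("repeat_bounds = %g..%g", sc$repeat_bounds[1],
              sc$repeat_bounds[2]),
      sprintf("sample_n = %d", sc$sample_n),
      sprintf("rescale = %g", sc$rescale),
      vapply(names(sc$demes), function(d) {
        x <- sc$demes[[d]]
        if (isTRUE(x$sample_ancestral))
          sprintf("deme %s: habitat=%s ancestral-sample", d, x$habitat)
        else
          sprintf("deme %s: habitat=%s t_found=%g founders=%g Ne=%g m=%g",
                  d, x$habitat, x$t_found, x$founders, x$Ne, x$m)
      }, character(1))), con)
    close(con)
    paths <- c(paths, truth = tp, scenario = sp)
  }
  invisible(paths)
}
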