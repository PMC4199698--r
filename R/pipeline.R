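# End-to-end orchestration: runs the enabled analysis stages in dependency
# order over a dataset + map, writes TSV reports and a manifest.

#' Run the full analysis pipeline
#'
#' Executes the enabled stages (diversity, LD, structure, bottleneck,
#' compare) over a genotype dataset and marker map, writing one TSV per
#' report plus a manifest. Every report carries the package version, the
#' seed and a config echo in comment headers; all randomness flows from
#' the single seed via stage-specific substreams, so disabling one stage
#' never changes another stage's numbers.
#'
#' @param ds a [gtds] object.
#' @param map a `marker_map`.
#' @param out_dir output directory (created if needed).
#' @param stages character subset of
#'   `c("diversity", "ld", "structure", "bottleneck", "compare")`.
#' @param seed integer seed.
#' @param exclude_rare drop sub-5% alleles in the LD stage.
#' @param ld_source `"em"`, `"composite"` or `"both"` for the LD scans.
#' @param n_perm permutations for F_ST tests (structure stage).
#' @param n_boot bootstrap replicates for the F_IS interval.
#' @param bottleneck_thetas prebottleneck theta grid for Mc.
#' @param n_iter_mc,n_iter_h simulation sizes for the bottleneck stage.
#' @return invisible list: `manifest` (data.frame of written files) and
#'   the in-memory stage results.
#' @export
run_pipeline <- function(ds, map, out_dir,
                         stages = c("diversity", "ld", "structure",
                                    "bottleneck", "compare"),
                         seed = 1L, exclude_rare = FALSE,
                         ld_source = "em", n_perm = 1000, n_boot = 200,
                         bottleneck_thetas = c(theta1 = 0.6, theta2 = 3,
                                               theta3 = 6),
                         n_iter_mc = 2000, n_iter_h = 200) {
  stages <- match.arg(stages, c("diversity", "ld", "structure",
                                "bottleneck", "compare"),
                      several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- sprintf("seed=%d exclude_rare=%s ld_source=%s", seed,
                 exclude_rare, ld_source)
  results <- list(); written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    con <- file(path, "w")
    writeLines(c(sprintf("# msatLD %s",
                         as.character(utils::packageVersion("msatLD"))),
                 paste0("# ", cfg)), con)
    suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                        row.names = FALSE))
    close(con)
    written[[length(written) + 1L]] <<- path
    path
  }
  stage_seed <- function(k) seed + 1000L * k

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    results[[name]] <<- res
    res
  }

  if ("diversity" %in% stages) run_stage("diversity", function() {
    div <- diversity_summary(ds, n_boot = n_boot, seed = stage_seed(1L))
    emit(div, "diversity")
    div
  })

  if ("ld" %in% stages) run_stage("ld", function() {
    scans <- lapply(names(ds$pops), function(p)
      syntenic_ld_scan(ds, map, p, exclude_rare = exclude_rare,
                       source = ld_source))
    names(scans) <- names(ds$pops)
    all_rec <- do.call(rbind, lapply(names(scans), function(p) {
      r <- scans[[p]]
      if (nrow(r)) {
        r$population <- p
        r$habitat <- ds$pops[[p]]$habitat
      }
      r
    }))
    emit(all_rec, "ld_pairs")
    bins <- do.call(rbind, lapply(names(scans), function(p) {
      if (!nrow(scans[[p]])) return(NULL)
      b <- bin_ld_by_distance(scans[[p]])
      b$population <- p
      b
    }))
    emit(bins, "ld_bins")
    decays <- do.call(rbind, lapply(names(scans), function(p) {
      r <- scans[[p]]
      if (sum(!is.na(r$dprime) & r$distance_mb > 0) < 3) return(NULL)
      f <- fit_ld_decay(r)
      data.frame(population = p, intercept = f$intercept, slope = f$slope,
                 R2 = f$r_squared, p = f$p_value,
                 half_length_mb = f$half_length_mb,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(decays)) emit(decays, "ld_decay")
    list(scans = scans, records = all_rec)
  })

  if ("structure" %in% stages) run_stage("structure", function() {
    fm <- fst_matrix(ds, n_perm = n_perm, seed = stage_seed(3L))
    emit(as.data.frame(fm$theta), "fst_matrix")
    if (n_perm > 0) emit(as.data.frame(fm$p), "fst_pvalues")
    fm
  })

  if ("bottleneck" %in% stages) run_stage("bottleneck", function() {
    bt <- bottleneck_report(ds, thetas = bottleneck_thetas,
                            n_iter_mc = n_iter_mc, n_iter_h = n_iter_h,
                            seed = stage_seed(4L))
    emit(bt, "bottleneck")
    bt
  })

  if ("compare" %in% stages) run_stage("compare", function() {
    if (is.null(results$ld))
      stop("compare stage needs the ld stage enabled")
    rec <- results$ld$records
    by_hab <- split(rec, rec$habitat)
    cmp <- if (length(by_hab) >= 2) compare_ld_units(by_hab) else NULL
    if (!is.null(cmp)) emit(cmp, "habitat_comparisons")
    kw <- if (length(unique(rec$population)) >= 2)
      kruskal_wallis(split(rec$dprime, rec$population)) else NULL
    anc <- if (length(unique(rec$population)) >= 2)
      ancova_ld(rec) else NULL
    if (!is.null(anc)) emit(anc, "ancova")
    list(pairwise = cmp, kruskal = kw, ancova = anc)
  })

  manifest <- data.frame(file = basename(written),
                         bytes = vapply(written, function(p)
                           file.info(p)$size, numeric(1)),
                         stringsAsFactors = FALSE)
  mp <- file.path(out_dir, "MANIFEST.tsv")
  utils::write.table(manifest, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(manifest = manifest, results = results))
}
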