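# Syntenic LD scans, distance binning, decay regression, and the
# D'-vs-r2 correlation.

# internal: mask genotypes carrying rare alleles (unit-level frequencies);
# a genotype containing a dropped allele becomes missing at that locus, so
# downstream estimates renormalise over the remaining copies.
mask_rare_alleles <- function(poprec, threshold = 0.05) {
  for (l in seq_len(ncol(poprec$a1))) {
    al <- c(poprec$a1[, l], poprec$a2[, l]); al <- al[!is.na(al)]
    if (!length(al)) next
    tab <- table(al)
    rare <- as.integer(names(tab)[tab / length(al) < threshold])
    if (!length(rare)) next
    bad <- (poprec$a1[, l] %in% rare) | (poprec$a2[, l] %in% rare)
    poprec$a1[bad, l] <- NA_integer_
    poprec$a2[bad, l] <- NA_integer_
  }
  poprec
}

#' Scan all syntenic marker pairs for LD
#'
#' One record per unordered pair of mapped markers on the same linkage
#' group with both loci polymorphic in the unit analysed. The unit is
#' either a single population or a habitat, in which case the member
#' populations' raw genotypes are pooled ("combined") before estimation.
#'
#' @param ds a [gtds] object.
#' @param map a `marker_map`; dataset loci absent from the map are skipped.
#' @param unit population name (`mode = "population"`) or habitat label
#'   (`mode = "habitat"`). For `mode = "habitat"`, `coastal = TRUE` selects
#'   the coastal-freshwater populations instead of a habitat label.
#' @param mode `"population"` or `"habitat"`.
#' @param coastal with `mode = "habitat"`, pool the coastal-flagged
#'   freshwater populations (ignores `unit`).
#' @param exclude_rare drop alleles below 5% frequency (unit-level) before
#'   estimation; genotypes carrying a dropped allele become missing at that
#'   locus and the remaining copies are renormalised.
#' @param source `"em"`, `"composite"` or `"both"`: which estimator fills
#'   the LD columns.
#' @param tol,max_iter EM controls.
#' @return data.frame with columns `locusA`, `locusB`, `lg`, `distance_mb`,
#'   `dprime`, `r2`, `composite_dprime`, `composite_r2`, `n_alleles_A`,
#'   `n_alleles_B`, `n_ind`.
#' @export
syntenic_ld_scan <- function(ds, map, unit, mode = c("population", "habitat"),
                             coastal = FALSE, exclude_rare = FALSE,
                             source = c("em", "composite", "both"),
                             tol = 1e-8, max_iter = 1000) {
  mode <- match.arg(mode); source <- match.arg(source)
  if (mode == "population") {
    poprec <- gtds_pop(ds, unit)
  } else {
    members <- habitat_members(ds, unit, coastal)
    if (!length(members)) stop("no population matches the habitat unit")
    poprec <- pool_pops(ds, members)
  }
  scan_poprec(poprec, ds$loci, map, exclude_rare = exclude_rare,
              source = source, tol = tol, max_iter = max_iter)
}

#' @rdname syntenic_ld_scan
#' @export
habitat_members <- function(ds, unit = NULL, coastal = FALSE) {
  if (coastal)
    return(names(ds$pops)[vapply(ds$pops, function(p)
      isTRUE(p$coastal) && p$habitat != "marine", logical(1))])
  names(ds$pops)[vapply(ds$pops, function(p) p$habitat == unit, logical(1))]
}

# internal scan over a bare population record
scan_poprec <- function(poprec, loci, map, exclude_rare = FALSE,
                        source = "em", tol = 1e-8, max_iter = 1000) {
  if (exclude_rare) poprec <- mask_rare_alleles(poprec)
  m <- map[map$marker %in% loci, , drop = FALSE]
  if (!nrow(m)) {
    warning("no dataset locus present in the marker map")
    return(empty_ld_records())
  }
  rows <- list()
  for (lg in unique(m$lg)) {
    sub <- m[m$lg == lg, , drop = FALSE]
    if (nrow(sub) < 2) next
    sub <- sub[order(sub$position_mb), , drop = FALSE]
    idx <- match(sub$marker, loci)
    poly <- vapply(idx, function(l) is_polymorphic(poprec, l), logical(1))
    for (i in seq_len(nrow(sub) - 1)) for (j in (i + 1):nrow(sub)) {
      if (!poly[i] || !poly[j]) next
      la <- idx[i]; lb <- idx[j]
      ok <- !is.na(poprec$a1[, la]) & !is.na(poprec$a1[, lb])
      if (sum(ok) < 1) next
      dp <- r2 <- cdp <- cr2 <- NA_real_
      nA <- nB <- NA_integer_
      if (source %in% c("em", "both")) {
        h <- em_pair(poprec, la, lb, sub$marker[i], sub$marker[j],
                     tol = tol, max_iter = max_iter)
        dp <- dprime_multiallelic(h); r2 <- r2_multiallelic(h)
        nA <- nrow(h$freq); nB <- ncol(h$freq)
        if (is.na(dp)) next  # a locus monomorphic among jointly-typed inds
      }
      if (source %in% c("composite", "both")) {
        cp <- composite_pair(poprec, la, lb)
        cdp <- cp$composite_dprime; cr2 <- cp$composite_r2
        if (is.na(nA)) { nA <- length(cp$pA); nB <- length(cp$pB) }
        if (is.na(cdp) && source == "composite") next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        locusA = sub$marker[i], locusB = sub$marker[j], lg = lg,
        distance_mb = abs(sub$position_mb[j] - sub$position_mb[i]),
        dprime = as.numeric(dp), r2 = as.numeric(r2),
        composite_dprime = as.numeric(cdp), composite_r2 = as.numeric(cr2),
        n_alleles_A = nA, n_alleles_B = nB, n_ind = sum(ok),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_ld_records())
  do.call(rbind, rows)
}

empty_ld_records <- function() {
  data.frame(locusA = character(0), locusB = character(0), lg = character(0),
             distance_mb = numeric(0), dprime = numeric(0), r2 = numeric(0),
             composite_dprime = numeric(0), composite_r2 = numeric(0),
             n_alleles_A = integer(0), n_alleles_B = integer(0),
             n_ind = integer(0), stringsAsFactors = FALSE)
}

#' Bin syntenic LD records by physical distance
#'
#' Mean D' (or another value column), estimation error `SD/sqrt(n_pairs)`
#' and pair count per distance bin, with half-open bins closed on the right
#' (`[0, 5], (5, 10], (10, 15], (15, 20], (20, Inf)`) plus an overall row
#' over all syntenic pairs. A bin with a single record reports error 0;
#' empty bins are reported absent (`NA` mean, n = 0).
#'
#' @param records data.frame from [syntenic_ld_scan()].
#' @param value which column to summarise (default `"dprime"`).
#' @param breaks bin edges in Mb.
#' @return data.frame with `bin`, `mean`, `error`, `n_pairs`.
#' @export
bin_ld_by_distance <- function(records, value = "dprime",
                               breaks = c(0, 5, 10, 15, 20, Inf)) {
  if (!nrow(records)) stop("no LD records to bin")
  v <- records[[value]]
  keep <- !is.na(v)
  v <- v[keep]; d <- records$distance_mb[keep]
  labs <- paste0("(", utils::head(breaks, -1), ",", utils::tail(breaks, -1),
                 "]")
  labs[1] <- paste0("[", breaks[1], ",", breaks[2], "]")
  labs[length(labs)] <- paste0(">", breaks[length(breaks) - 1])
  bin <- cut(d, breaks = breaks, labels = labs, include.lowest = TRUE,
             right = TRUE)
  agg <- lapply(levels(bin), function(b) {
    x <- v[bin == b]
    data.frame(bin = b, mean = if (length(x)) mean(x) else NA_real_,
               error = bin_error(x), n_pairs = length(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rbind(out, data.frame(bin = "overall", mean = mean(v),
                        error = bin_error(v), n_pairs = length(v),
                        stringsAsFactors = FALSE))
}

bin_error <- function(x) {
  if (length(x) < 2) return(if (length(x)) 0 else NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Habitat-level binned LD, combined or averaged
#'
#' Two conventions for a habitat summary: `"combined"` pools the member
#' populations' genotypes before estimation, while `"average"` averages the
#' member populations' bin means (error = SD of the population means /
#' sqrt(number of populations)).
#'
#' @inheritParams syntenic_ld_scan
#' @param habitat habitat label (or `coastal = TRUE`).
#' @param convention `"combined"` or `"average"`.
#' @param value column summarised in the bin table.
#' @param ... passed on to [syntenic_ld_scan()].
#' @export
habitat_ld_bins <- function(ds, map, habitat = NULL, coastal = FALSE,
                            convention = c("combined", "average"),
                            value = "dprime", ...) {
  convention <- match.arg(convention)
  if (convention == "combined") {
    rec <- syntenic_ld_scan(ds, map, habitat, mode = "habitat",
                            coastal = coastal, ...)
    return(bin_ld_by_distance(rec, value = value))
  }
  members <- habitat_members(ds, habitat, coastal)
  tabs <- lapply(members, function(p)
    bin_ld_by_distance(syntenic_ld_scan(ds, map, p, ...), value = value))
  bins <- tabs[[1]]$bin
  mat <- vapply(tabs, function(t) t$mean, numeric(length(bins)))
  mat <- matrix(mat, nrow = length(bins))
  data.frame(bin = bins,
             mean = rowMeans(mat, na.rm = TRUE),
             error = apply(mat, 1, function(x) bin_error(x[!is.na(x)])),
             n_pops = rowSums(!is.na(mat)), stringsAsFactors = FALSE)
}

#' Fit the decay of D' with ln(distance)
#'
#' Ordinary least squares of the LD value on the natural log of physical
#' distance (Mb); records at zero distance are excluded. The half-length is
#' the distance at which the fitted line crosses 0.5,
#' `exp((0.5 - intercept)/slope)`, defined only for a negative slope.
#'
#' @param records data.frame from [syntenic_ld_scan()].
#' @param value column to regress (default `"dprime"`).
#' @return list with `intercept`, `slope`, `r_squared`, `p_value`,
#'   `half_length_mb` (NA when undefined), `n`, `degenerate`.
#' @export
fit_ld_decay <- function(records, value = "dprime") {
  keep <- !is.na(records[[value]]) & records$distance_mb > 0
  y <- records[[value]][keep]; x <- log(records$distance_mb[keep])
  if (length(y) < 3) stop("need >= 3 records at positive distance")
  if (stats::var(x) == 0)
    return(list(intercept = NA_real_, slope = NA_real_,
                r_squared = NA_real_, p_value = NA_real_,
                half_length_mb = NA_real_, n = length(y), degenerate = TRUE))
  if (stats::var(y) == 0)
    return(list(intercept = y[1], slope = 0, r_squared = 0, p_value = 1,
                half_length_mb = NA_real_, n = length(y),
                degenerate = FALSE))
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  b0 <- unname(stats::coef(fit)[1]); b1 <- unname(stats::coef(fit)[2])
  pval <- if (nrow(sm$coefficients) >= 2) sm$coefficients[2, 4] else NA_real_
  half <- if (!is.na(b1) && b1 < 0) exp((0.5 - b0) / b1) else NA_real_
  list(intercept = b0, slope = b1, r_squared = sm$r.squared, p_value = pval,
       half_length_mb = half, n = length(y), degenerate = FALSE)
}

#' Correlation between the D' and r2 measures
#'
#' Pearson and Kendall correlations between paired D' and r2 values of a
#' scan.
#'
#' @param records data.frame with `dprime` and `r2` columns (or the
#'   composite ones via `cols`).
#' @param cols length-2 character: the two columns to correlate.
#' @return list with `pearson_r`, `pearson_p`, `kendall_tau`, `kendall_p`.
#' @export
ld_measure_correlation <- function(records, cols = c("dprime", "r2")) {
  x <- records[[cols[1]]]; y <- records[[cols[2]]]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need >= 3 paired records")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(pearson_r = NA_real_, pearson_p = NA_real_,
                kendall_tau = NA_real_, kendall_p = NA_real_,
                undefined = TRUE))
  pe <- stats::cor.test(x, y, method = "pearson")
  ke <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       kendall_tau = unname(ke$estimate), kendall_p = ke$p.value,
       undefined = FALSE)
}
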