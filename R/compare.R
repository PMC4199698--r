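# Statistical comparisons of LD values between habitats and populations:
# Mann-Whitney, Kruskal-Wallis, nested ANCOVA, Bonferroni.

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test on two samples. `U` counts pairs where the
#' first sample exceeds the second (ties count 1/2), `Z` is the
#' tie-corrected normal deviate. The p-value is exact (from the U
#' distribution) for tie-free samples up to 50 per group, otherwise the
#' normal approximation. All values tied across both samples yields
#' `p = 1` with a `tied` flag.
#'
#' @param x,y numeric samples.
#' @return list with `U`, `Z`, `p_value`, `n`, `tied`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- nx * ny / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0)
    return(list(U = U, Z = 0, p_value = 1, n = c(nx, ny), tied = TRUE))
  Z <- (U - nx * ny / 2) / sqrt(sigma2)
  exact <- tie_term == 0 && nx <= 50 && ny <= 50
  p <- if (exact) {
    min(1, 2 * min(stats::pwilcox(U, nx, ny),
                   stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE)))
  } else {
    2 * stats::pnorm(-abs(Z))
  }
  list(U = U, Z = Z, p_value = p, n = c(nx, ny), tied = FALSE)
}

#' Kruskal-Wallis test across groups
#'
#' Tie-corrected H statistic against a chi-square reference with
#' `groups - 1` degrees of freedom (delegates to [stats::kruskal.test()]).
#'
#' @param groups list of numeric vectors, one per group.
#' @return list with `chi2`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need >= 2 groups")
  if (any(!vapply(groups, length, integer(1))))
    stop("every group must be non-empty")
  if (length(unique(unlist(groups))) == 1)
    return(list(chi2 = 0, df = length(groups) - 1, p_value = 1))
  kt <- stats::kruskal.test(groups)
  list(chi2 = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' ANCOVA of LD values on habitat and population with a distance covariate
#'
#' Linear model of D' on the physical-distance covariate, habitat, and
#' population nested within habitat (sequential sums of squares). The
#' habitat effect is tested against the population-within-habitat mean
#' square - the classical expected-mean-squares treatment of a random
#' population factor, exact in balanced designs - while population and the
#' covariate are tested against the residual. Without a habitat column (or
#' with a single habitat) the model reduces to distance + population, both
#' against the residual.
#'
#' @param records data.frame with columns `dprime` (or `value`),
#'   `distance_mb`, `population` and optionally `habitat`.
#' @param value name of the response column.
#' @param log_distance use ln(distance) instead of raw distance as the
#'   covariate (records at non-positive distance are then dropped).
#' @return data.frame F-table: `term`, `df1`, `df2`, `F`, `p`; the habitat
#'   row is `NA` with attribute `untestable` when population is aliased
#'   with habitat (one population per habitat).
#' @export
ancova_ld <- function(records, value = "dprime", log_distance = FALSE) {
  d <- records[!is.na(records[[value]]), , drop = FALSE]
  if (log_distance) d <- d[d$distance_mb > 0, , drop = FALSE]
  y <- d[[value]]
  dist <- if (log_distance) log(d$distance_mb) else d$distance_mb
  pop <- factor(d$population)
  hab <- if ("habitat" %in% names(d)) factor(d$habitat) else NULL
  use_hab <- !is.null(hab) && nlevels(hab) >= 2
  if (use_hab) {
    fit <- stats::lm(y ~ dist + hab + hab:pop)
  } else {
    fit <- stats::lm(y ~ dist + pop)
  }
  an <- stats::anova(fit)
  ms <- an[["Mean Sq"]]; df <- an[["Df"]]
  res_i <- nrow(an)
  ms_res <- ms[res_i]; df_res <- df[res_i]
  rows <- list()
  f_of <- function(i, ms_err, df_err) {
    F <- ms[i] / ms_err
    data.frame(term = rownames(an)[i], df1 = df[i], df2 = df_err, F = F,
               p = stats::pf(F, df[i], df_err, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }
  if (use_hab) {
    pop_i <- which(rownames(an) == "hab:pop")
    hab_i <- which(rownames(an) == "hab")
    untestable <- length(pop_i) == 0 || df[pop_i] == 0
    if (untestable) {
      rows$habitat <- data.frame(term = "habitat", df1 = df[hab_i],
                                 df2 = NA_real_, F = NA_real_, p = NA_real_,
                                 stringsAsFactors = FALSE)
    } else {
      rows$habitat <- f_of(hab_i, ms[pop_i], df[pop_i])
      rows$habitat$term <- "habitat"
    }
    if (length(pop_i) && df[pop_i] > 0) {
      rows$population <- f_of(pop_i, ms_res, df_res)
      rows$population$term <- "population_within_habitat"
    }
    rows$distance <- f_of(1, ms_res, df_res)
    rows$distance$term <- "distance"
    out <- do.call(rbind, rows)
    if (untestable) attr(out, "untestable") <- "habitat"
  } else {
    rows$population <- f_of(which(rownames(an) == "pop"), ms_res, df_res)
    rows$population$term <- "population"
    rows$distance <- f_of(1, ms_res, df_res)
    rows$distance$term <- "distance"
    out <- do.call(rbind, rows)
  }
  attr(out, "distance_slope") <- unname(stats::coef(fit)["dist"])
  rownames(out) <- NULL
  out
}

#' Bonferroni adjustment
#'
#' Each p-value multiplied by the family size and capped at 1; the
#' threshold form `alpha/m` is exposed alongside.
#'
#' @param p_values numeric vector of raw p-values.
#' @param m family size (defaults to `length(p_values)`).
#' @param alpha family-wise level for the threshold form.
#' @return list with `adjusted`, `m`, `threshold`.
#' @export
bonferroni <- function(p_values, m = length(p_values), alpha = 0.05) {
  stopifnot(m >= 1)
  list(adjusted = pmin(1, p_values * m), m = m, threshold = alpha / m)
}

#' Pairwise habitat comparisons of LD values
#'
#' Mann-Whitney tests between every pair of habitats' D' records, with a
#' Bonferroni family over all pairs.
#'
#' @param records_by_unit named list of scan data.frames (one per habitat
#'   or population).
#' @param value column compared.
#' @return data.frame: one row per pair with U, Z, raw and adjusted p.
#' @export
compare_ld_units <- function(records_by_unit, value = "dprime") {
  nm <- names(records_by_unit)
  if (length(nm) < 2) stop("need >= 2 units")
  pairs <- utils::combn(nm, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    mw <- mann_whitney(records_by_unit[[a]][[value]],
                       records_by_unit[[b]][[value]])
    data.frame(unitA = a, unitB = b, U = mw$U, Z = mw$Z,
               p_raw = mw$p_value, nA = mw$n[1], nB = mw$n[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  bf <- bonferroni(out$p_raw)
  out$p_adjusted <- bf$adjusted
  out$m <- bf$m
  out
}
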