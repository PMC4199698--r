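# ---- genotype dataset -------------------------------------------------------

HABITATS <- c("marine", "lake", "pond", "river")

#' Construct a multiallelic genotype dataset
#'
#' The central container of the package: diploid multiallelic genotypes for
#' one or more populations, with missing-data support. Allele codes are
#' positive integers (microsatellite fragment sizes in bp). Missing genotypes
#' are `NA` in both allele slots; a genotype with only one allele missing is
#' treated as fully missing.
#'
#' @param pops named list; each element a list with fields `habitat` (one of
#'   `"marine"`, `"lake"`, `"pond"`, `"river"`), `coastal` (logical) and
#'   `a1`, `a2`: integer matrices (individuals x loci) of allele codes.
#' @param loci character vector of marker ids (column order of `a1`/`a2`).
#' @param motif named numeric vector of per-locus repeat-unit lengths in bp;
#'   loci absent from it default to 4 bp (used only by the M-ratio).
#' @return an object of class `gtds`.
#' @export
gtds <- function(pops, loci, motif = NULL) {
  stopifnot(is.list(pops), length(pops) >= 1, !is.null(names(pops)))
  loci <- as.character(loci)
  if (anyDuplicated(loci)) stop("duplicate locus ids")
  for (nm in names(pops)) {
    p <- pops[[nm]]
    if (is.null(p$habitat) || !p$habitat %in% HABITATS)
      stop(sprintf("population '%s': habitat label missing or invalid", nm))
    if (is.null(p$coastal)) pops[[nm]]$coastal <- FALSE
    a1 <- as.matrix(p$a1); a2 <- as.matrix(p$a2)
    if (!all(dim(a1) == dim(a2)) || ncol(a1) != length(loci))
      stop(sprintf("population '%s': allele matrices malformed", nm))
    if (nrow(a1) < 1) stop(sprintf("population '%s': no individuals", nm))
    # enforce joint missingness of the two allele slots
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    if (any(a1[!is.na(a1)] <= 0) || any(a2[!is.na(a2)] <= 0))
      stop(sprintf("population '%s': allele codes must be positive", nm))
    storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
    colnames(a1) <- colnames(a2) <- loci
    pops[[nm]]$a1 <- a1; pops[[nm]]$a2 <- a2
  }
  m <- rep(4, length(loci)); names(m) <- loci
  if (!is.null(motif)) m[names(motif)[names(motif) %in% loci]] <-
      motif[names(motif) %in% loci]
  structure(list(pops = pops, loci = loci, motif = m), class = "gtds")
}

#' @export
print.gtds <- function(x, ...) {
  cat(sprintf("<gtds> %d loci, %d populations\n", length(x$loci),
              length(x$pops)))
  for (nm in names(x$pops)) {
    p <- x$pops[[nm]]
    cat(sprintf("  %s: n=%d, habitat=%s%s\n", nm, nrow(p$a1), p$habitat,
                if (isTRUE(p$coastal)) " (coastal)" else ""))
  }
  invisible(x)
}

#' @rdname gtds
#' @param ds a `gtds` object.
#' @export
pop_names <- function(ds) names(ds$pops)

# internal: fetch a population record, with a lookup error
gtds_pop <- function(ds, population) {
  if (!population %in% names(ds$pops))
    stop(sprintf("unknown population '%s'", population))
  ds$pops[[population]]
}

# internal: pool several populations' genotypes into one pseudo-population
pool_pops <- function(ds, populations, habitat = NULL) {
  recs <- lapply(populations, function(p) gtds_pop(ds, p))
  list(habitat = habitat %||% recs[[1]]$habitat, coastal = FALSE,
       a1 = do.call(rbind, lapply(recs, `[[`, "a1")),
       a2 = do.call(rbind, lapply(recs, `[[`, "a2")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- GenePop I/O ------------------------------------------------------------

#' Read a GenePop genotype file
#'
#' Accepts both the 4-digit (2 digits per allele) and 6-digit (3 digits per
#' allele) dialects, auto-detected per file. The all-zeros code marks a
#' missing genotype; a half-missing genotype (one allele zero) is treated as
#' fully missing. Population names are recovered from the shared prefix of
#' the individual labels within each population block (`<name>_<i>`), falling
#' back to `pop<k>`.
#'
#' @param path GenePop file.
#' @param habitat_table path to a TSV with columns `population`, `habitat`,
#'   `coastal`, or a data.frame of the same shape. Every population in the
#'   file must be listed.
#' @param motif optional named vector of per-locus motif lengths (bp).
#' @return a [gtds] object.
#' @export
read_genepop <- function(path, habitat_table, motif = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("GenePop file too short: ", path)
  lines <- trimws(lines, which = "right")
  i <- 2
  loci <- character(0)
  while (i <= length(lines) && !grepl("^\\s*pop\\s*$", lines[i],
                                      ignore.case = TRUE)) {
    loci <- c(loci, trimws(strsplit(lines[i], ",")[[1]]))
    i <- i + 1
  }
  loci <- loci[nzchar(loci)]
  if (i > length(lines)) stop("no 'Pop' line found in ", path)
  L <- length(loci)

  pops_raw <- list(); cur <- NULL; cur_ids <- NULL
  flush_pop <- function() {
    if (!is.null(cur) && length(cur))
      pops_raw[[length(pops_raw) + 1L]] <<- list(rows = cur, ids = cur_ids)
  }
  for (j in (i):length(lines)) {
    ln <- lines[j]
    if (!nzchar(trimws(ln))) next
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) {
      flush_pop(); cur <- list(); cur_ids <- character(0)
      next
    }
    if (is.null(cur)) stop("genotype line before first 'Pop' at line ", j)
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2) stop("malformed individual line ", j, ": ", ln)
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != L)
      stop(sprintf("line %d: expected %d genotypes, found %d", j, L,
                   length(toks)))
    if (!all(grepl("^[0-9]+$", toks)))
      stop("malformed allele field at line ", j)
    cur[[length(cur) + 1L]] <- toks
    cur_ids <- c(cur_ids, id)
  }
  flush_pop()
  if (!length(pops_raw)) stop("no populations in ", path)

  all_tok <- unlist(lapply(pops_raw, function(p) unlist(p$rows)))
  wid <- unique(nchar(all_tok))
  if (length(wid) != 1 || !wid %in% c(4L, 6L))
    stop("cannot auto-detect GenePop dialect: genotype widths ",
         paste(sort(wid), collapse = "/"))
  aw <- wid / 2L

  habs <- if (is.data.frame(habitat_table)) habitat_table else
    read_habitat_table(habitat_table)

  pops <- list()
  for (k in seq_along(pops_raw)) {
    pr <- pops_raw[[k]]
    nm <- .infer_pop_name(pr$ids, k)
    g <- do.call(rbind, lapply(pr$rows, function(r) {
      a1 <- as.integer(substr(r, 1, aw))
      a2 <- as.integer(substr(r, aw + 1, 2 * aw))
      c(a1, a2)
    }))
    a1 <- g[, seq_len(L), drop = FALSE]
    a2 <- g[, L + seq_len(L), drop = FALSE]
    miss <- a1 == 0L | a2 == 0L
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    row <- habs[habs$population == nm, , drop = FALSE]
    if (nrow(row) != 1)
      stop(sprintf("population '%s' not listed (once) in habitat table", nm))
    pops[[nm]] <- list(habitat = row$habitat, coastal = isTRUE(row$coastal),
                       a1 = a1, a2 = a2)
  }
  extra <- setdiff(habs$population, names(pops))
  if (length(extra))
    stop("habitat table lists unknown population(s): ",
         paste(extra, collapse = ", "))
  gtds(pops, loci, motif)
}

.infer_pop_name <- function(ids, k) {
  stripped <- sub("_[0-9]+$", "", ids)
  if (length(unique(stripped)) == 1 && nzchar(stripped[1])) stripped[1]
  else paste0("pop", k)
}

#' Write a dataset in GenePop 6-digit format
#'
#' @param ds a [gtds] object.
#' @param path output file.
#' @param title first (comment) line of the file.
#' @export
write_genepop <- function(ds, path, title = "msatLD export") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(ds$loci, con)
  for (nm in names(ds$pops)) {
    p <- ds$pops[[nm]]
    writeLines("Pop", con)
    for (i in seq_len(nrow(p$a1))) {
      a1 <- p$a1[i, ]; a2 <- p$a2[i, ]
      a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
      if (any(c(a1, a2) > 999L)) stop("allele code exceeds 3 digits")
      tok <- paste0(formatC(a1, width = 3, flag = "0"),
                    formatC(a2, width = 3, flag = "0"))
      writeLines(sprintf("%s_%d , %s", nm, i, paste(tok, collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Read / write the population habitat table
#'
#' TSV with columns `population`, `habitat` (marine/lake/pond/river) and
#' `coastal` (TRUE/FALSE).
#' @param path TSV file.
#' @export
read_habitat_table <- function(path) {
  h <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("population", "habitat", "coastal")
  if (!all(need %in% names(h)))
    stop("habitat table must have columns: ", paste(need, collapse = ", "))
  h$coastal <- as.logical(h$coastal)
  if (!all(h$habitat %in% HABITATS))
    stop("invalid habitat label(s): ",
         paste(setdiff(h$habitat, HABITATS), collapse = ", "))
  h
}

#' @rdname read_habitat_table
#' @param ds a [gtds] object (for writing).
#' @export
write_habitat_table <- function(ds, path) {
  h <- data.frame(population = names(ds$pops),
                  habitat = vapply(ds$pops, `[[`, "", "habitat"),
                  coastal = vapply(ds$pops, function(p) isTRUE(p$coastal),
                                   logical(1)))
  utils::write.table(h, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- marker map -------------------------------------------------------------

#' Read a physical marker map
#'
#' TSV with header `marker`, `lg`, `position_mb` and an optional `motif_bp`
#' column. Positions are real-valued megabases within a linkage group.
#'
#' @param path TSV file.
#' @return data.frame of class `marker_map`.
#' @export
read_marker_map <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker", "lg", "position_mb")
  if (!all(need %in% names(m)))
    stop("marker map must have columns: ", paste(need, collapse = ", "))
  marker_map(m)
}

#' @rdname read_marker_map
#' @param entries data.frame with columns `marker`, `lg`, `position_mb`
#'   (and optionally `motif_bp`).
#' @export
marker_map <- function(entries) {
  m <- as.data.frame(entries, stringsAsFactors = FALSE)
  m$marker <- as.character(m$marker)
  m$lg <- as.character(m$lg)
  if (anyDuplicated(m$marker))
    stop("duplicate marker id(s) in map: ",
         paste(unique(m$marker[duplicated(m$marker)]), collapse = ", "))
  if (any(!is.finite(m$position_mb)) || any(m$position_mb < 0))
    stop("marker positions must be non-negative")
  class(m) <- c("marker_map", "data.frame")
  m
}

#' @rdname read_marker_map
#' @param map a `marker_map`.
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Summarise adjacent-marker intervals of a map
#'
#' Mean and median spacing (Mb) between adjacent markers within linkage
#' groups, the quantity usually quoted to describe map density.
#' @param map a `marker_map`.
#' @export
map_interval_summary <- function(map) {
  gaps <- unlist(lapply(split(map$position_mb, map$lg), function(p) {
    if (length(p) < 2) return(numeric(0))
    diff(sort(p))
  }), use.names = FALSE)
  list(mean_mb = mean(gaps), median_mb = stats::median(gaps),
       min_mb = if (length(gaps)) min(gaps) else NA_real_,
       max_mb = if (length(gaps)) max(gaps) else NA_real_,
       n_intervals = length(gaps))
}

# ---- allele frequencies -----------------------------------------------------

#' Per-population allele frequency tables
#'
#' Relative allele frequencies over non-missing gene copies, with the sample
#' gene count (2 x non-missing individuals) per locus. Loci with zero
#' non-missing copies in a population are flagged absent (`NULL` frequency,
#' zero gene count).
#'
#' @param ds a [gtds] object.
#' @return class `aft`: per population, `freq` (list locus -> named numeric)
#'   and `n_gene` (named integer vector).
#' @export
allele_frequencies <- function(ds) {
  out <- lapply(ds$pops, function(p) {
    freq <- vector("list", length(ds$loci)); names(freq) <- ds$loci
    n_gene <- integer(length(ds$loci)); names(n_gene) <- ds$loci
    for (l in seq_along(ds$loci)) {
      al <- c(p$a1[, l], p$a2[, l]); al <- al[!is.na(al)]
      n_gene[l] <- length(al)
      if (length(al)) {
        tab <- table(al)
        freq[[l]] <- stats::setNames(as.numeric(tab) / length(al),
                                     names(tab))
      }
    }
    list(freq = freq, n_gene = n_gene)
  })
  structure(list(pops = out, loci = ds$loci), class = "aft")
}

# internal: locus columns (2n gene copies) of a population record
locus_copies <- function(poprec, l) {
  al <- c(poprec$a1[, l], poprec$a2[, l])
  al[!is.na(al)]
}

# internal: is locus l polymorphic within a population record?
is_polymorphic <- function(poprec, l) {
  al <- locus_copies(poprec, l)
  length(unique(al)) >= 2
}
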