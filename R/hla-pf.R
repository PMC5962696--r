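#' Allele-frequency table
#'
#' Population allele frequencies per locus, with an optional allele-to-group
#' map (e.g. `HLA-A*24:02 -> HLA-A*24`) for group-level queries.
#'
#' @param population,locus,allele Character vectors (recycled to a common
#'   length).
#' @param frequency Numeric in \[0, 1\].
#' @param group_map Optional `data.frame` with columns `allele`, `group`.
#' @return `data.frame` of class `AFTable` with the group map as attribute.
#' @export
af_table <- function(population, locus, allele, frequency, group_map = NULL) {
  df <- data.frame(population = as.character(population),
                   locus = as.character(locus),
                   allele = as.character(allele),
                   frequency = as.numeric(frequency),
                   stringsAsFactors = FALSE)
  if (any(df$frequency < 0 | df$frequency > 1 | !is.finite(df$frequency)))
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  sums <- tapply(df$frequency, interaction(df$population, df$locus, drop = TRUE), sum)
  if (any(sums > 1 + 1e-6))
    stop("per-(population, locus) frequencies sum above 1: ",
         paste(names(sums)[sums > 1 + 1e-6], collapse = ", "), call. = FALSE)
  if (!is.null(group_map)) {
    stopifnot(all(c("allele", "group") %in% names(group_map)))
    attr(df, "group_map") <- group_map[, c("allele", "group")]
  }
  class(df) <- c("AFTable", "data.frame")
  df
}

#' @rdname af_table
#' @param path TSV with columns `population`, `locus`, `allele`, `frequency`.
#' @param group_map_path Optional TSV with columns `allele`, `group`.
#' @export
read_af_table <- function(path, group_map_path = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gm <- if (!is.null(group_map_path))
    utils::read.delim(group_map_path, stringsAsFactors = FALSE) else NULL
  af_table(df$population, df$locus, df$allele, df$frequency, group_map = gm)
}

#' Summed allele frequency of a query set
#'
#' Sum of the frequencies of the query alleles in one population and locus.
#' At `allele_group` level the query names allele groups and every table
#' allele mapping into a queried group contributes. Query members absent
#' from the table contribute 0 and are reported in the `missing` attribute.
#' Sums above 1 are clamped (with a warning: a clamped sum signals an
#' inconsistent table).
#'
#' @param table An [af_table()].
#' @param population,locus Labels present in the table.
#' @param query Non-empty character vector of allele (or group) names.
#' @param level `"allele"` or `"allele_group"`.
#' @return Summed frequency in \[0, 1\], with attribute `missing`.
#' @export
sum_allele_frequencies <- function(table, population, locus, query,
                                   level = c("allele", "allele_group")) {
  level <- match.arg(level)
  stopifnot(length(query) >= 1)
  if (!population %in% table$population)
    stop("unknown population: ", population, call. = FALSE)
  if (!locus %in% table$locus[table$population == population])
    stop("unknown locus '", locus, "' for population ", population, call. = FALSE)
  sub <- table[table$population == population & table$locus == locus, ,
               drop = FALSE]
  if (level == "allele") {
    hit <- sub$allele %in% query
    missing <- setdiff(query, sub$allele)
  } else {
    gm <- attr(table, "group_map")
    if (is.null(gm)) stop("table has no allele-group map", call. = FALSE)
    grp <- gm$group[match(sub$allele, gm$allele)]
    hit <- !is.na(grp) & grp %in% query
    missing <- setdiff(query, grp[!is.na(grp)])
  }
  s <- sum(sub$frequency[hit])
  if (s > 1) {
    warning("summed allele frequency ", format(s),
            " clamped to 1: inconsistent table", call. = FALSE)
    s <- 1
  }
  attr(s, "missing") <- missing
  s
}

#' Phenotype frequency of a diploid carrier
#'
#' Probability that a diploid individual carries at least one allele of a
#' query set with summed allele frequency `sigma_af`:
#' `PF = 1 - (1 - sigma_af)^2`. The squared term assumes the two chromosomes
#' are independent draws from the population allele pool (Hardy-Weinberg).
#'
#' @param sigma_af Summed allele frequency in \[0, 1\] (vectorized).
#' @return Phenotype frequency in \[0, 1\].
#' @export
phenotype_frequency <- function(sigma_af) {
  if (any(!is.finite(sigma_af) | sigma_af < 0 | sigma_af > 1))
    stop("sigma_af must lie in [0, 1]", call. = FALSE)
  1 - (1 - sigma_af)^2
}

#' Default query: the cell line's typed HLA alleles
#'
#' The HLA-A, -B and -DRB3 alleles carried by SV-BR-1-GM (and their allele
#' groups), the default query sets for [pf_report()].
#'
#' @param level `"allele"` or `"allele_group"`.
#' @return Named list locus -> character vector of allele (or group) names.
#' @export
svbr_hla_query <- function(level = c("allele", "allele_group")) {
  level <- match.arg(level)
  if (level == "allele")
    list(`HLA-A` = c("HLA-A*11:01", "HLA-A*24:02"),
         `HLA-B` = c("HLA-B*35:08", "HLA-B*55:01"),
         `HLA-DRB3` = c("HLA-DRB3*01:01", "HLA-DRB3*02:02"))
  else
    list(`HLA-A` = c("HLA-A*11", "HLA-A*24"),
         `HLA-B` = c("HLA-B*35", "HLA-B*55"),
         `HLA-DRB3` = c("HLA-DRB3*01", "HLA-DRB3*02"))
}

#' Per-population, per-locus phenotype-frequency report
#'
#' One row per (population, locus): the summed allele frequency of the query
#' set and the derived phenotype frequency, also expressed as a percentage
#' rounded to 1 decimal (the reporting convention). Per-cell lookup errors
#' are recorded in the `error` column without aborting the rest of the
#' report.
#'
#' @param table An [af_table()].
#' @param query_sets Named list locus -> allele (or group) name vector
#'   (default [svbr_hla_query()] at the requested level).
#' @param populations Populations to report (default: all in the table).
#' @param level `"allele"` or `"allele_group"`.
#' @return `data.frame` with `population`, `locus`, `level`, `sigma_af`,
#'   `pf`, `pf_pct`, `error`.
#' @export
pf_report <- function(table, query_sets = NULL, populations = NULL,
                      level = c("allele", "allele_group")) {
  level <- match.arg(level)
  if (is.null(query_sets)) query_sets <- svbr_hla_query(level)
  if (is.null(populations)) populations <- unique(table$population)
  grid <- expand.grid(population = populations, locus = names(query_sets),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pop <- grid$population[i]; loc <- grid$locus[i]
    out <- data.frame(population = pop, locus = loc, level = level,
                      sigma_af = NA_real_, pf = NA_real_, pf_pct = NA_real_,
                      error = NA_character_, stringsAsFactors = FALSE)
    res <- tryCatch({
      q <- query_sets[[loc]]
      if (length(q) == 0) stop("empty query set for locus ", loc)
      s <- sum_allele_frequencies(table, pop, loc, q, level = level)
      pf <- phenotype_frequency(as.numeric(s))
      list(sigma = as.numeric(s), pf = pf)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error <- conditionMessage(res)
    } else {
      out$sigma_af <- res$sigma
      out$pf <- res$pf
      out$pf_pct <- round_half_up(100 * res$pf, 1)
    }
    out
  })
  do.call(rbind, rows)
}
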