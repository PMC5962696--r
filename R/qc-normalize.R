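#' RNA-integrity quality gate
#'
#' Samples with an RNA integrity number equivalent (RIN^e) strictly below the
#' threshold are excluded; the rule is "less than 7.5", so 7.5 itself passes.
#' Samples without a RIN^e value pass with `rin_pass = NA` (gate not
#' applicable).
#'
#' @param metadata A [sample_metadata()] table.
#' @param threshold Exclusion threshold (default 7.5).
#' @return `data.frame` with `sample_id`, `rin_e`, `rin_pass`.
#' @export
rin_gate <- function(metadata, threshold = 7.5) {
  stopifnot(threshold > 0)
  pass <- ifelse(is.na(metadata$rin_e), NA, metadata$rin_e >= threshold)
  data.frame(sample_id = metadata$sample_id, rin_e = metadata$rin_e,
             rin_pass = pass, stringsAsFactors = FALSE)
}

#' 95th/5th-percentile variability ratio
#'
#' Ratio between a sample's raw intensities at the 95th and 5th percentile
#' (linear interpolation between order statistics). A non-positive 5th
#' percentile makes the ratio undefined: the sample is flagged (`NA`
#' returned), not an error.
#'
#' @param sample_values Non-negative numeric vector of raw intensities
#'   (length >= 2).
#' @return Positive ratio, or `NA_real_` when the 5th percentile is <= 0.
#' @export
variability_ratio <- function(sample_values) {
  stopifnot(length(sample_values) >= 2, all(is.finite(sample_values)))
  p5 <- percentile(sample_values, 0.05)
  if (p5 <= 0) return(NA_real_)
  percentile(sample_values, 0.95) / p5
}

#' Variability quality gate
#'
#' Applied to non-normalized intensities: samples whose 95th/5th-percentile
#' ratio is strictly below `min_ratio` (default 10) are low-variability and
#' excluded; a ratio exactly at the threshold is retained. Undefined ratios
#' (5th percentile <= 0) are excluded and flagged.
#'
#' @param m Raw-scale [expression_matrix()].
#' @param min_ratio Exclusion threshold (default 10).
#' @return `data.frame` with `sample_id`, `variability_ratio`,
#'   `variability_pass`, `excluded`, `reason`.
#' @export
variability_gate <- function(m, min_ratio = 10) {
  stopifnot(inherits(m, "ExpressionMatrix"), min_ratio > 1)
  ratio <- apply(m$values, 2, variability_ratio)
  pass <- !is.na(ratio) & ratio >= min_ratio
  reason <- ifelse(is.na(ratio), "undefined variability ratio (p5 <= 0)",
                   ifelse(pass, "",
                          sprintf("low variability (ratio %.2f < %g)",
                                  ratio, min_ratio)))
  out <- data.frame(sample_id = colnames(m$values), variability_ratio = ratio,
                    variability_pass = pass, excluded = !pass,
                    reason = reason, stringsAsFactors = FALSE, row.names = NULL)
  if (all(out$excluded))
    warning("every sample fails the variability gate: empty cohort",
            call. = FALSE)
  out
}

#' Combined sample QC report
#'
#' Applies the RIN^e gate (where metadata carries RIN^e values) and the
#' variability gate; a sample is excluded if it fails either applicable gate.
#'
#' @inheritParams variability_gate
#' @param metadata [sample_metadata()] covering the matrix's samples.
#' @param min_rin RIN^e threshold (default 7.5).
#' @return `data.frame`, one row per sample, with both gates, the exclusion
#'   flag and a reason string. Carries attribute
#'   `percentile_convention = "linear interpolation (type 7)"`.
#' @export
qc_report <- function(m, metadata, min_rin = 7.5, min_ratio = 10) {
  vg <- variability_gate(m, min_ratio)
  rg <- rin_gate(metadata, min_rin)
  out <- merge(vg, rg, by = "sample_id", all.x = TRUE, sort = FALSE)
  rin_fail <- !is.na(out$rin_pass) & !out$rin_pass
  out$excluded <- out$excluded | rin_fail
  out$reason <- ifelse(rin_fail,
                       trimws(paste(out$reason,
                                    sprintf("RIN^e %.2f < %g", out$rin_e, min_rin),
                                    sep = "; ")),
                       out$reason)
  out$reason <- sub("^; ", "", out$reason)
  attr(out, "percentile_convention") <- "linear interpolation (type 7)"
  out
}

#' Quantile normalization
#'
#' Forces every sample column to share one distribution by replacing values
#' with cross-sample rank means (ties within a column receive the mean of
#' the rank-mean values across their span). Delegates to
#' [limma::normalizeQuantiles()], the standard array implementation.
#'
#' @param m Linear-scale [expression_matrix()] with >= 2 samples; a
#'   single-sample matrix is returned unchanged with a warning.
#' @return Quantile-normalized `ExpressionMatrix` (linear scale).
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale != "linear")
    stop("quantile normalization operates on linear-scale values", call. = FALSE)
  if (ncol(m$values) < 2) {
    warning("single-sample matrix: nothing to normalize", call. = FALSE)
    return(m)
  }
  v <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(v) <- dimnames(m$values)
  expression_matrix(v, platform = m$platform, scale = "linear")
}

#' Log2 transformation
#'
#' `log2(value + offset)`; applied before clustering only, never before
#' screening (all screen thresholds operate on linear quantile-normalized
#' values).
#'
#' @param m Linear-scale [expression_matrix()].
#' @param offset Pseudocount added before the log (default 1).
#' @return `ExpressionMatrix` with `scale = "log2"`.
#' @export
log2_transform <- function(m, offset = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale == "log2")
    stop("matrix is already on the log2 scale", call. = FALSE)
  v <- log2(m$values + offset)
  expression_matrix(v, platform = m$platform, scale = "log2")
}

#' Background cutoff for expressed-gene calling
#'
#' The median quantile-normalized value pooled over all (human RNA-targeting,
#' non-control probe, sample) pairs. After quantile normalization all
#' columns share one distribution, so per-sample medians of the non-control
#' probes coincide with this pooled median by construction.
#'
#' @param m Quantile-normalized [expression_matrix()].
#' @param annotation [probe_annotation()] covering every probe of `m`.
#' @return Object of class `BackgroundCutoff`: `value` (the cutoff),
#'   `n_probes` (non-control probes used), `source_note`.
#' @export
background_cutoff <- function(m, annotation) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  missing <- setdiff(probe_ids(m), annotation$probe_id)
  if (length(missing))
    stop("annotation does not cover probe(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  ctrl <- annotation$probe_id[annotation$is_control]
  keep <- setdiff(probe_ids(m), ctrl)
  if (length(keep) == 0)
    stop("no non-control probes in matrix", call. = FALSE)
  value <- stats::median(m$values[keep, , drop = FALSE])
  structure(
    list(value = value, n_probes = length(keep),
         source_note = sprintf(
           "pooled median over %d non-control probes x %d samples",
           length(keep), ncol(m$values))),
    class = "BackgroundCutoff")
}

#' @export
print.BackgroundCutoff <- function(x, ...) {
  cat(sprintf("BackgroundCutoff: %.4g (%s)\n", x$value, x$source_note))
  invisible(x)
}

#' Expressed-gene call for one gene in one sample
#'
#' A gene is expressed in a sample if at least one of its (non-control)
#' probes has a quantile-normalized value strictly above the background
#' cutoff. A gene without probes in the annotation is not evaluable (`NA`),
#' which is distinct from "not expressed".
#'
#' @param gene Gene symbol.
#' @param m Quantile-normalized [expression_matrix()].
#' @param annotation [probe_annotation()].
#' @param cutoff [background_cutoff()] result.
#' @param sample Sample id.
#' @return `TRUE`, `FALSE`, or `NA` (not evaluable).
#' @export
is_expressed <- function(gene, m, annotation, cutoff, sample) {
  stopifnot(sample %in% sample_ids(m))
  probes <- annotation$probe_id[!annotation$is_control &
                                  !is.na(annotation$gene_symbol) &
                                  annotation$gene_symbol == gene]
  probes <- intersect(probes, probe_ids(m))
  if (length(probes) == 0) return(NA)
  any(m$values[probes, sample] > cutoff$value)
}

#' Average-linkage correlation clustering of samples
#'
#' Agglomerative clustering of sample columns with distance
#' `1 - Pearson correlation` and pairwise average linkage, the standard QC
#' visualization for array cohorts. Deterministic given the input column
#' order (the `stats::hclust` tie behavior).
#'
#' @param m [expression_matrix()] with >= 3 samples; log2 scale recommended
#'   (a warning is issued on linear input).
#' @return An object of class `hclust` over the samples.
#' @export
hierarchical_cluster <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (ncol(m$values) < 3)
    stop("need at least 3 samples to cluster", call. = FALSE)
  if (m$scale != "log2")
    warning("clustering linear-scale values; log2 is recommended", call. = FALSE)
  sds <- apply(m$values, 2, stats::sd)
  if (any(sds == 0))
    stop("constant sample column(s) (undefined correlation): ",
         paste(colnames(m$values)[sds == 0], collapse = ", "), call. = FALSE)
  d <- stats::as.dist(1 - stats::cor(m$values, method = "pearson"))
  stats::hclust(d, method = "average")
}

#' Serialize a dendrogram as Newick
#'
#' Branch lengths are merge-height differences (via [ape::as.phylo()]).
#'
#' @param hc An `hclust` object from [hierarchical_cluster()].
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @return Newick string (invisibly when written to `path`).
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  stopifnot(inherits(hc, "hclust"))
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
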