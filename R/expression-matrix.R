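#' Expression matrix container
#'
#' A rectangular probe-by-sample matrix of intensities with a platform tag
#' and a scale flag. Linear-scale values must be non-negative and complete
#' (no missing values): every downstream representative and screen statistic
#' assumes complete columns, so upstream gaps must be resolved (probe
#' dropped) before construction.
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param platform Platform label, e.g. `"illumina-ht12v4"`, `"synthetic"`.
#' @param scale Either `"linear"` or `"log2"`.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, platform = "unknown", scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry probe ids as rownames and sample ids as colnames",
         call. = FALSE)
  dup_p <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_p))
    stop("duplicate probe id(s): ", paste(dup_p, collapse = ", "), call. = FALSE)
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "), call. = FALSE)
  if (anyNA(values))
    stop("missing values are not permitted; drop incomplete probes first",
         call. = FALSE)
  if (scale == "linear" && any(values < 0))
    stop("negative values are invalid on the linear scale", call. = FALSE)
  structure(
    list(values = values, platform = platform, scale = scale),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples [%s, %s scale]\n",
              nrow(x$values), ncol(x$values), x$platform, x$scale))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

probe_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

#' Merge two expression matrices by shared probes
#'
#' Probes are intersected (keeping the first matrix's order) and sample
#' columns concatenated, mirroring the column-merge step used to combine
#' independently generated array series before joint normalization. Sample-id
#' collisions are resolved by suffixing with a dataset label on both sides
#' rather than rejected, because independently deposited series can share
#' generic column names.
#'
#' @param a,b `ExpressionMatrix` objects on the same scale.
#' @param dataset_a,dataset_b Labels used to disambiguate colliding sample ids.
#' @param allow_cross_platform Permit merging across platform tags.
#' @return Merged `ExpressionMatrix` (platform of `a`, or
#'   `"<a>+<b>"` for cross-platform merges).
#' @export
merge_matrices <- function(a, b, dataset_a = "a", dataset_b = "b",
                           allow_cross_platform = FALSE) {
  stopifnot(inherits(a, "ExpressionMatrix"), inherits(b, "ExpressionMatrix"))
  if (a$scale != b$scale)
    stop("scale mismatch: ", a$scale, " vs ", b$scale, call. = FALSE)
  if (a$platform != b$platform && !allow_cross_platform)
    stop("platform mismatch (", a$platform, " vs ", b$platform,
         "); pass allow_cross_platform = TRUE to override", call. = FALSE)
  common <- intersect(probe_ids(a), probe_ids(b))
  if (length(common) == 0)
    stop("merge error: no probes shared between the two matrices", call. = FALSE)
  common <- probe_ids(a)[probe_ids(a) %in% common]  # a's order
  va <- a$values[common, , drop = FALSE]
  vb <- b$values[common, , drop = FALSE]
  clash <- intersect(colnames(va), colnames(vb))
  if (length(clash)) {
    colnames(va)[colnames(va) %in% clash] <-
      paste0(colnames(va)[colnames(va) %in% clash], "__", dataset_a)
    colnames(vb)[colnames(vb) %in% clash] <-
      paste0(colnames(vb)[colnames(vb) %in% clash], "__", dataset_b)
  }
  platform <- if (a$platform == b$platform) a$platform else
    paste(a$platform, b$platform, sep = "+")
  expression_matrix(cbind(va, vb), platform = platform, scale = a$scale)
}

#' Drop probes from a matrix (and optionally its annotation)
#'
#' Used to remove blacklisted probes (probes judged unreliable, e.g. an
#' HLA-DRB3 probe reporting expression in more samples than allele
#' prevalence permits) before any screening step.
#'
#' @param m `ExpressionMatrix`.
#' @param blacklist Character vector of probe ids to drop (absent ids ignored).
#' @return `ExpressionMatrix` without the blacklisted probes.
#' @export
drop_probes <- function(m, blacklist) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  keep <- !(probe_ids(m) %in% blacklist)
  if (!any(keep)) stop("blacklist removes every probe", call. = FALSE)
  expression_matrix(m$values[keep, , drop = FALSE], m$platform, m$scale)
}
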