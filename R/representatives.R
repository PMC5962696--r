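#' Per-group representative value
#'
#' Collapse a vector of per-sample values into the single value representing
#' a sample group: arithmetic mean, median (mean of the central pair for
#' even n) or 95th percentile (linear interpolation).
#'
#' @param values Non-empty numeric vector.
#' @param method `"mean"`, `"median"` or `"p95"`.
#' @return Length-1 numeric.
#' @export
group_representative <- function(values, method = c("mean", "median", "p95")) {
  method <- match.arg(method)
  if (length(values) == 0) stop("empty value vector", call. = FALSE)
  switch(method,
         mean = mean(values),
         median = stats::median(values),
         p95 = percentile(values, 0.95))
}

#' Single representative SV-BR-1-GM value
#'
#' Each SV-BR-1-GM sample type is first represented by the arithmetic mean of
#' its replicates; the cell line's single representative value is the median
#' of those per-type means.
#'
#' @param per_type_means Named numeric vector of per-sample-type means.
#' @return Length-1 numeric.
#' @export
svbr_representative <- function(per_type_means) {
  stopifnot(length(per_type_means) >= 1)
  stats::median(unname(per_type_means))
}

#' Breast-cancer comparator
#'
#' The 95th percentile over all breast-cancer tissue samples pooled (not
#' grouped). The 95th percentile rather than the maximum is used to
#' accommodate potential outliers, so no maximum variant is offered.
#'
#' @param values Numeric vector over all breast-cancer samples (length >= 2).
#' @return Length-1 numeric.
#' @export
breast_cancer_comparator <- function(values) {
  stopifnot(length(values) >= 2)
  percentile(values, 0.95)
}

#' Normal-tissue comparator
#'
#' For each normal-tissue group take the maximum across its samples, then
#' return the 95th percentile across those group maxima.
#'
#' @param per_group_values List (>= 2 elements) of numeric vectors, one per
#'   tissue group.
#' @return Length-1 numeric.
#' @export
normal_tissue_comparator <- function(per_group_values) {
  stopifnot(is.list(per_group_values), length(per_group_values) >= 2)
  maxima <- vapply(per_group_values, max, numeric(1))
  percentile(maxima, 0.95)
}

#' Per-probe representative table
#'
#' Collapses a merged SV-BR-1-GM + normal-breast matrix into the per-probe
#' representatives all screens consume: per-sample-type representatives for
#' every normal-breast group (medians for non-cultured types, means for
#' cultured sets by default, overridable per group) and the single SV-BR-1-GM
#' representative (median over the per-sample-type arithmetic means).
#'
#' @param m Quantile-normalized [expression_matrix()] whose columns are
#'   covered by `metadata`.
#' @param metadata [sample_metadata()]; roles `svbr`,
#'   `normal_breast_cultured` and `normal_breast_noncultured` are used.
#' @param methods Optional named character vector overriding the
#'   representative method (`mean`/`median`/`p95`) for specific normal-breast
#'   sample types.
#' @return Object of class `RepresentativeTable`: `svbr` (named per-probe
#'   vector), `normal` (probe x group matrix of representatives), `method`
#'   (per-group method used), `nc_groups` (the non-cultured group labels),
#'   `svbr_type_means` (probe x SV-BR-1-GM-type matrix of means).
#' @export
representative_table <- function(m, metadata, methods = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  md <- metadata[metadata$sample_id %in% sample_ids(m), , drop = FALSE]
  sv <- md[md$role == "svbr", , drop = FALSE]
  nb <- md[md$role %in% c("normal_breast_cultured", "normal_breast_noncultured"), ,
           drop = FALSE]
  if (nrow(sv) == 0) stop("no SV-BR-1-GM samples in metadata", call. = FALSE)
  if (nrow(nb) == 0) stop("no normal-breast samples in metadata", call. = FALSE)

  type_mean <- function(types, frame) {
    vapply(types, function(tp) {
      ids <- frame$sample_id[frame$sample_type == tp]
      rowMeans(m$values[, ids, drop = FALSE])
    }, numeric(nrow(m$values)))
  }
  sv_types <- unique(sv$sample_type)
  sv_means <- type_mean(sv_types, sv)          # probe x type
  svbr <- apply(sv_means, 1, stats::median)    # median of per-type means

  nb_types <- unique(nb$sample_type)
  default_method <- vapply(nb_types, function(tp) {
    role <- nb$role[nb$sample_type == tp][1]
    if (role == "normal_breast_noncultured") "median" else "mean"
  }, character(1))
  if (!is.null(methods)) {
    unknown <- setdiff(names(methods), nb_types)
    if (length(unknown))
      stop("method override for unknown group(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    default_method[names(methods)] <- methods
  }
  normal <- vapply(nb_types, function(tp) {
    ids <- nb$sample_id[nb$sample_type == tp]
    apply(m$values[, ids, drop = FALSE], 1, group_representative,
          method = default_method[[tp]])
  }, numeric(nrow(m$values)))
  colnames(normal) <- nb_types

  nc_groups <- nb_types[vapply(nb_types, function(tp)
    nb$role[nb$sample_type == tp][1] == "normal_breast_noncultured",
    logical(1))]

  structure(list(svbr = svbr, normal = normal, method = default_method,
                 nc_groups = nc_groups, svbr_type_means = sv_means),
            class = "RepresentativeTable")
}

#' @export
print.RepresentativeTable <- function(x, ...) {
  cat(sprintf(
    "RepresentativeTable: %d probes; %d normal-breast groups (%d non-cultured); %d SV-BR-1-GM types\n",
    length(x$svbr), ncol(x$normal), length(x$nc_groups), ncol(x$svbr_type_means)))
  invisible(x)
}
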