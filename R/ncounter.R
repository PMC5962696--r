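#' Default nCounter reference genes
#'
#' The eight housekeeping genes used as the reference set for digital-count
#' normalization.
#' @export
NCOUNTER_REFERENCE_GENES <- c("ADRM1", "APTX", "DGUOK", "GNG5", "PSMA4",
                              "RPL38", "TMEM14C", "UBE3C")

#' Digital-count (nCounter-style) run
#'
#' Holds per-lane endogenous counts plus the spiked positive and negative
#' control counts, and the reference-gene list used for the second
#' normalization stage.
#'
#' @param endogenous Gene x lane matrix of non-negative counts (rownames =
#'   gene symbols, colnames = lane ids).
#' @param positive_controls Control x lane matrix of positive-control counts.
#' @param negative_controls Control x lane matrix of negative-control counts.
#' @param reference_genes Reference-gene symbols, a subset of
#'   `rownames(endogenous)` (default [NCOUNTER_REFERENCE_GENES]).
#' @return Object of class `NCounterRun`.
#' @export
ncounter_run <- function(endogenous, positive_controls, negative_controls,
                         reference_genes = NCOUNTER_REFERENCE_GENES) {
  for (nm in c("endogenous", "positive_controls", "negative_controls")) {
    x <- get(nm)
    if (!is.matrix(x) || !is.numeric(x) || any(x < 0) || anyNA(x))
      stop("`", nm, "` must be a non-negative numeric matrix", call. = FALSE)
  }
  if (ncol(endogenous) < 1) stop("need at least one lane", call. = FALSE)
  if (!identical(colnames(endogenous), colnames(positive_controls)) ||
      !identical(colnames(endogenous), colnames(negative_controls)))
    stop("lane ids must agree across endogenous and control matrices",
         call. = FALSE)
  if (nrow(positive_controls) < 1 || nrow(negative_controls) < 1)
    stop("need at least one positive and one negative control per lane",
         call. = FALSE)
  missing_ref <- setdiff(reference_genes, rownames(endogenous))
  if (length(missing_ref))
    stop("reference gene(s) absent from endogenous set: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  structure(list(endogenous = endogenous,
                 positive_controls = positive_controls,
                 negative_controls = negative_controls,
                 reference_genes = reference_genes,
                 background_subtracted = FALSE),
            class = "NCounterRun")
}

#' @export
print.NCounterRun <- function(x, ...) {
  cat(sprintf("NCounterRun: %d genes x %d lanes (%d pos / %d neg controls, %d reference genes)%s\n",
              nrow(x$endogenous), ncol(x$endogenous),
              nrow(x$positive_controls), nrow(x$negative_controls),
              length(x$reference_genes),
              if (x$background_subtracted) ", background-subtracted" else ""))
  invisible(x)
}

#' Read an RCC-like count table
#'
#' TSV with columns `CodeClass` (one of `Endogenous`, `Positive`, `Negative`,
#' `Housekeeping`), `Name`, and one column per lane. `Housekeeping` rows are
#' treated as endogenous genes and become the reference set.
#'
#' @param path File path.
#' @return An [ncounter_run()].
#' @export
read_ncounter <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("CodeClass", "Name")
  if (!all(need %in% names(df)))
    stop("count table needs 'CodeClass' and 'Name' columns", call. = FALSE)
  bad <- setdiff(unique(df$CodeClass),
                 c("Endogenous", "Positive", "Negative", "Housekeeping"))
  if (length(bad))
    stop("unknown CodeClass value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  lanes <- setdiff(names(df), need)
  as_mat <- function(sub) {
    m <- as.matrix(sub[, lanes, drop = FALSE])
    rownames(m) <- sub$Name
    m
  }
  endo <- df$CodeClass %in% c("Endogenous", "Housekeeping")
  ncounter_run(
    endogenous = as_mat(df[endo, , drop = FALSE]),
    positive_controls = as_mat(df[df$CodeClass == "Positive", , drop = FALSE]),
    negative_controls = as_mat(df[df$CodeClass == "Negative", , drop = FALSE]),
    reference_genes = df$Name[df$CodeClass == "Housekeeping"])
}

#' Background subtraction for digital counts
#'
#' Subtracts, from every endogenous count, the maximum negative-control count
#' of its lane (default) or the global maximum across lanes, clipping at 0.
#' Subtraction precedes the scaling stages.
#'
#' @param run An [ncounter_run()].
#' @param method `"per_lane"` (default) or `"global"`.
#' @return The run with background-subtracted endogenous counts.
#' @export
subtract_background <- function(run, method = c("per_lane", "global")) {
  method <- match.arg(method)
  stopifnot(inherits(run, "NCounterRun"))
  bg <- if (method == "per_lane") apply(run$negative_controls, 2, max)
        else rep(max(run$negative_controls), ncol(run$endogenous))
  run$endogenous <- pmax(sweep(run$endogenous, 2, bg, "-"), 0)
  run$background_subtracted <- TRUE
  run
}

#' Two-stage digital-count normalization
#'
#' Stage 1 equalizes the positive-control geometric means across lanes: each
#' lane's scale factor is the arithmetic mean (over lanes) of the per-lane
#' positive-control geometric means divided by that lane's geometric mean.
#' Stage 2 applies the same construction to the reference-gene geometric
#' means of the stage-1 output. After stage 1 the positive-control geometric
#' means agree across lanes; after stage 2 so do the reference-gene ones.
#' Zeros are replaced by 1 before geometric means (see [geometric_mean()]);
#' a lane whose geometric mean is not positive is flagged non-normalizable.
#'
#' @param run A background-subtracted [ncounter_run()] (a warning is issued
#'   otherwise).
#' @return List with `counts` (normalized gene x lane matrix), `factors`
#'   (`data.frame`: lane, `pos_factor`, `ref_factor`, `total_factor`,
#'   `normalizable`).
#' @export
normalize_counts <- function(run) {
  stopifnot(inherits(run, "NCounterRun"))
  if (!isTRUE(run$background_subtracted))
    warning("counts are not background-subtracted; normalizing as-is",
            call. = FALSE)
  lanes <- colnames(run$endogenous)

  stage <- function(counts, control) {
    gm <- apply(control, 2, function(x) as.numeric(geometric_mean(x)))
    ok <- gm > 0
    f <- rep(NA_real_, length(gm))
    f[ok] <- mean(gm[ok]) / gm[ok]
    list(counts = sweep(counts, 2, ifelse(ok, f, 1), "*"), factor = f, ok = ok)
  }
  s1 <- stage(run$endogenous, run$positive_controls)
  ref1 <- s1$counts[run$reference_genes, , drop = FALSE]
  s2 <- stage(s1$counts, ref1)
  normalizable <- s1$ok & s2$ok
  if (!all(normalizable))
    warning("non-normalizable lane(s): ",
            paste(lanes[!normalizable], collapse = ", "), call. = FALSE)
  factors <- data.frame(lane = lanes,
                        pos_factor = s1$factor,
                        ref_factor = s2$factor,
                        total_factor = s1$factor * s2$factor,
                        normalizable = normalizable,
                        stringsAsFactors = FALSE, row.names = NULL)
  list(counts = s2$counts, factors = factors)
}
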