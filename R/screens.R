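#' Screen configuration
#'
#' Thresholds for the three screens. All fold comparisons are strict
#' (`>`/`<`); the verification quotient is inclusive (`>= 3.00`), a cutoff
#' calibrated so that the ERBB2 Affymetrix probe 216836_s_at
#' (quotient 3.95) is retained.
#'
#' @param fold_low Low-stringency fold (default 1.5) over background and over
#'   the maximum normal-breast representative.
#' @param fold_medium Medium-stringency fold over background (default 5).
#' @param fold_cta CTA-screen fold (default 1.5).
#' @param quotient_min Verification quotient cutoff (default 3.00, inclusive).
#' @param calibration_note Free-text provenance of `quotient_min`.
#' @return Object of class `ScreenConfig`.
#' @export
screen_config <- function(fold_low = 1.5, fold_medium = 5.0, fold_cta = 1.5,
                          quotient_min = 3.00,
                          calibration_note = "calibrated to retain an ERBB2 probe at quotient 3.95") {
  stopifnot(fold_low > 1, fold_medium > 1, fold_cta > 1, quotient_min > 0)
  structure(list(fold_low = fold_low, fold_medium = fold_medium,
                 fold_cta = fold_cta, quotient_min = quotient_min,
                 calibration_note = calibration_note),
            class = "ScreenConfig")
}

#' Overexpression ratio score
#'
#' The reported "SV-BR-1-GM / Max" ratio: the representative SV-BR-1-GM value
#' divided by a comparator maximum, rounded half-up to one decimal (the
#' precision at which the scores are reported).
#'
#' @param svbr_value Representative SV-BR-1-GM value.
#' @param max_value Comparator maximum (> 0).
#' @return Ratio rounded half-up to 1 decimal (vectorized).
#' @export
ratio_score <- function(svbr_value, max_value) {
  if (any(max_value <= 0))
    stop("comparator maximum must be positive", call. = FALSE)
  round_half_up(svbr_value / max_value, 1)
}

#' Low-stringency TAA filter
#'
#' Pass iff the representative SV-BR-1-GM value is strictly greater than
#' `fold_low` times the background cutoff AND strictly greater than
#' `fold_low` times the maximum representative value among all normal-breast
#' groups (cultured + non-cultured).
#'
#' @param svbr_value Representative SV-BR-1-GM value(s).
#' @param max_normal_all Maximum normal-breast representative(s), all groups.
#' @param cutoff [background_cutoff()] result (or its numeric value).
#' @param config [screen_config()].
#' @return Logical (vectorized).
#' @export
taa_low_stringency <- function(svbr_value, max_normal_all, cutoff,
                               config = screen_config()) {
  cut <- cutoff_value(cutoff)
  svbr_value > config$fold_low * cut & svbr_value > config$fold_low * max_normal_all
}

#' Medium-stringency TAA filter
#'
#' Pass iff the representative SV-BR-1-GM value strictly exceeds
#' `fold_medium` times the background cutoff.
#'
#' @inheritParams taa_low_stringency
#' @return Logical (vectorized).
#' @export
taa_medium_stringency <- function(svbr_value, cutoff, config = screen_config()) {
  svbr_value > config$fold_medium * cutoff_value(cutoff)
}

#' High-stringency verification quotient
#'
#' Quotient of the breast-cancer comparator (pooled 95th percentile) over the
#' normal-tissue comparator (95th percentile of per-group maxima), reported
#' half-up to two decimals; a probe is verified iff the reported quotient is
#' `>= quotient_min` (inclusive). A non-positive normal comparator makes the
#' quotient not evaluable (`NA`).
#'
#' @param bc_comparator Breast-cancer comparator value(s).
#' @param normal_comparator Normal-tissue comparator value(s).
#' @param config [screen_config()].
#' @return `data.frame` with `quotient` (2 decimals) and `verified`.
#' @export
taa_high_stringency <- function(bc_comparator, normal_comparator,
                                config = screen_config()) {
  q <- ifelse(normal_comparator > 0,
              round_half_up(bc_comparator / normal_comparator, 2), NA_real_)
  data.frame(quotient = q,
             verified = ifelse(is.na(q), NA, q >= config$quotient_min))
}

#' Cancer/testis-antigen overexpression screen
#'
#' Three simultaneous criteria, all strict: the representative SV-BR-1-GM
#' value exceeds `fold_cta` times the background cutoff AND exceeds
#' `fold_cta` times the maximum representative among the non-cultured (NC)
#' normal breast cell types AND that NC maximum is below `fold_cta` times the
#' background cutoff (the antigen must be effectively silent in NC normal
#' breast).
#'
#' @param svbr_value Representative SV-BR-1-GM value(s).
#' @param max_nc_value Maximum NC normal-breast representative(s).
#' @param cutoff [background_cutoff()] result (or numeric value).
#' @param config [screen_config()].
#' @return Logical (vectorized).
#' @export
cta_screen <- function(svbr_value, max_nc_value, cutoff,
                       config = screen_config()) {
  cut <- cutoff_value(cutoff)
  stopifnot(cut > 0)
  svbr_value > config$fold_cta * cut &
    svbr_value > config$fold_cta * max_nc_value &
    max_nc_value < config$fold_cta * cut
}

#' Immune-Signature screen
#'
#' For each queried immunostimulatory gene: tier 1 iff at least one probe has
#' a quantile-normalized value strictly above `fold_low` times the background
#' cutoff in EVERY retained SV-BR-1-GM sample; tier 2 iff at least one probe
#' is above `fold_medium` times the cutoff in every sample. Probes vote
#' independently: the best probe carries the gene.
#'
#' @param m Quantile-normalized [expression_matrix()] restricted to the
#'   retained SV-BR-1-GM samples.
#' @param gene_list Non-empty character vector of gene symbols to screen.
#' @param annotation [probe_annotation()].
#' @param cutoff [background_cutoff()] result.
#' @param config [screen_config()].
#' @return `data.frame` with one row per gene: `gene_symbol`, `n_probes`,
#'   `immune_tier1`, `immune_tier2` (both `NA` when the gene has no probes:
#'   not evaluable).
#' @export
immune_signature_screen <- function(m, gene_list, annotation, cutoff,
                                    config = screen_config()) {
  stopifnot(length(gene_list) >= 1, inherits(m, "ExpressionMatrix"))
  cut <- cutoff_value(cutoff)
  ann <- annotation[!annotation$is_control & !is.na(annotation$gene_symbol) &
                      annotation$probe_id %in% probe_ids(m), , drop = FALSE]
  res <- lapply(gene_list, function(g) {
    probes <- ann$probe_id[ann$gene_symbol == g]
    if (length(probes) == 0)
      return(data.frame(gene_symbol = g, n_probes = 0L,
                        immune_tier1 = NA, immune_tier2 = NA))
    v <- m$values[probes, , drop = FALSE]
    t1 <- apply(v > config$fold_low * cut, 1, all)
    t2 <- apply(v > config$fold_medium * cut, 1, all)
    data.frame(gene_symbol = g, n_probes = length(probes),
               immune_tier1 = any(t1), immune_tier2 = any(t2))
  })
  do.call(rbind, res)
}

cutoff_value <- function(cutoff) {
  v <- if (inherits(cutoff, "BackgroundCutoff")) cutoff$value else cutoff
  stopifnot(is.numeric(v), length(v) == 1, v > 0)
  v
}

#' Probe-level screen records from a representative table
#'
#' Computes, per probe, the comparator maxima, the reported ratio scores and
#' the low/medium/CTA verdicts. The maxima are taken over group
#' representatives (`max_normal_all` over all normal-breast groups,
#' `max_normal_nc` over the non-cultured groups only) -- the deliberate
#' asymmetry of the screens: the CTA comparator excludes cultured cells,
#' whose proliferation program re-expresses several antigens.
#'
#' @param reps [representative_table()].
#' @param annotation [probe_annotation()].
#' @param cutoff [background_cutoff()] result.
#' @param config [screen_config()].
#' @return `data.frame`, one row per non-control annotated probe:
#'   `gene_symbol`, `probe_id`, `svbr_value`, `max_normal_all`,
#'   `max_normal_nc`, `ratio_all`, `ratio_nc`, `low_pass`, `medium_pass`
#'   (serial: requires `low_pass`), `cta_pass`.
#' @export
screen_records <- function(reps, annotation, cutoff, config = screen_config()) {
  stopifnot(inherits(reps, "RepresentativeTable"))
  probes <- names(reps$svbr)
  ann <- annotation[match(probes, annotation$probe_id), , drop = FALSE]
  keep <- !ann$is_control & !is.na(ann$gene_symbol)
  probes <- probes[keep]
  max_all <- apply(reps$normal[probes, , drop = FALSE], 1, max)
  max_nc <- apply(reps$normal[probes, reps$nc_groups, drop = FALSE], 1, max)
  svbr <- reps$svbr[probes]
  low <- taa_low_stringency(svbr, max_all, cutoff, config)
  med <- low & taa_medium_stringency(svbr, cutoff, config)
  data.frame(
    gene_symbol = ann$gene_symbol[keep],
    probe_id = probes,
    svbr_value = unname(svbr),
    max_normal_all = unname(max_all),
    max_normal_nc = unname(max_nc),
    ratio_all = ratio_score(unname(svbr), unname(max_all)),
    ratio_nc = ratio_score(unname(svbr), unname(max_nc)),
    low_pass = unname(low),
    medium_pass = unname(med),
    cta_pass = unname(cta_screen(svbr, max_nc, cutoff, config)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Serial three-tier TAA discovery pipeline
#'
#' Runs the full in-silico antigen search on quantile-normalized inputs:
#' low-stringency filter (over background and over all normal-breast
#' groups), medium-stringency filter (over 5x background), symbol mapping to
#' the verification platform, and the high-stringency breast-cancer /
#' normal-tissue quotient. Filters are applied serially per probe (a probe
#' is evaluated at medium stringency only if it passed low); a gene passes a
#' stage iff at least one of its probes survives to that stage. Genes that
#' pass medium stringency but have no probes on the verification platform
#' are labeled `"unverifiable"`, not rejected.
#'
#' @param svbr_matrix Quantile-normalized [expression_matrix()] of retained
#'   SV-BR-1-GM samples.
#' @param normal_breast_matrix Matching matrix of normal-breast samples
#'   (same platform and probes).
#' @param bc_matrix Breast-cancer tissue matrix on the verification platform.
#' @param normal_tissue_matrix Normal-tissue panel matrix on the verification
#'   platform.
#' @param annotation [probe_annotation()] for the discovery platform.
#' @param metadata [sample_metadata()] covering all samples (SV-BR-1-GM and
#'   normal-breast sample types; `tissue_group` for the normal-tissue panel).
#' @param verification_annotation [probe_annotation()] (or `data.frame` with
#'   `probe_id`, `gene_symbol`) for the verification platform; the
#'   cross-platform gene mapping is by symbol.
#' @param config [screen_config()].
#' @param blacklist Optional probe ids dropped before screening.
#' @return List with `records` (probe-level, discovery platform),
#'   `gene_records` (one row per gene with stage verdicts, `status` in
#'   `rejected_low`/`rejected_medium`/`unverifiable`/`rejected_high`/
#'   `verified`, and the best verification quotient), `verification`
#'   (probe-level quotients on the verification platform), `attrition`
#'   (ordered stage -> probe- and gene-level survivor counts) and `cutoff`.
#' @export
run_taa_pipeline <- function(svbr_matrix, normal_breast_matrix, bc_matrix,
                             normal_tissue_matrix, annotation, metadata,
                             verification_annotation,
                             config = screen_config(), blacklist = NULL) {
  if (nrow(verification_annotation) == 0)
    stop("empty cross-platform mapping", call. = FALSE)
  merged <- merge_matrices(svbr_matrix, normal_breast_matrix,
                           dataset_a = "svbr", dataset_b = "normal_breast",
                           allow_cross_platform = TRUE)
  if (!is.null(blacklist)) merged <- drop_probes(merged, blacklist)
  cutoff <- background_cutoff(merged, annotation)
  reps <- representative_table(merged, metadata)
  rec <- screen_records(reps, annotation, cutoff, config)

  gene_low <- tapply(rec$low_pass, rec$gene_symbol, any)
  gene_med <- tapply(rec$medium_pass, rec$gene_symbol, any)
  genes <- names(gene_low)
  med_genes <- genes[gene_med]

  # high-stringency verification on the second platform, by gene symbol
  vmap <- verification_annotation[!is.na(verification_annotation$gene_symbol), ,
                                  drop = FALSE]
  if ("is_control" %in% names(vmap)) vmap <- vmap[!vmap$is_control, , drop = FALSE]
  vmap <- vmap[vmap$probe_id %in% probe_ids(bc_matrix), , drop = FALSE]
  nt_md <- metadata[metadata$role == "normal_tissue_panel" &
                      metadata$sample_id %in% sample_ids(normal_tissue_matrix), ,
                    drop = FALSE]
  if (nrow(nt_md) == 0) stop("no normal-tissue panel samples in metadata",
                             call. = FALSE)
  groups <- split(nt_md$sample_id, nt_md$tissue_group)

  ver_probes <- vmap[vmap$gene_symbol %in% med_genes, , drop = FALSE]
  verification <- NULL
  gene_quot <- stats::setNames(rep(NA_real_, length(med_genes)), med_genes)
  gene_ver <- stats::setNames(rep(NA, length(med_genes)), med_genes)
  if (nrow(ver_probes) > 0) {
    bc_cmp <- apply(bc_matrix$values[ver_probes$probe_id, , drop = FALSE], 1,
                    breast_cancer_comparator)
    nt_cmp <- apply(normal_tissue_matrix$values[ver_probes$probe_id, , drop = FALSE],
                    1, function(v)
                      normal_tissue_comparator(lapply(groups, function(ids) v[ids])))
    hs <- taa_high_stringency(bc_cmp, nt_cmp, config)
    verification <- data.frame(gene_symbol = ver_probes$gene_symbol,
                               probe_id = ver_probes$probe_id,
                               bc_comparator = unname(bc_cmp),
                               normal_tissue_comparator = unname(nt_cmp),
                               quotient = hs$quotient,
                               verified = hs$verified,
                               stringsAsFactors = FALSE, row.names = NULL)
    gq <- tapply(verification$quotient, verification$gene_symbol,
                 function(q) if (all(is.na(q))) NA_real_ else max(q, na.rm = TRUE))
    gv <- tapply(verification$verified, verification$gene_symbol,
                 function(v) isTRUE(any(v)))
    gene_quot[names(gq)] <- gq
    gene_ver[names(gv)] <- gv
  }
  has_probe <- med_genes %in% ver_probes$gene_symbol
  status <- rep("rejected_low", length(genes))
  names(status) <- genes
  status[gene_low & !gene_med] <- "rejected_medium"
  status[med_genes[!has_probe]] <- "unverifiable"
  status[med_genes[has_probe]] <-
    ifelse(gene_ver[med_genes[has_probe]], "verified", "rejected_high")

  gene_records <- data.frame(
    gene_symbol = genes,
    low_pass = unname(gene_low),
    medium_pass = unname(gene_med),
    quotient = unname(gene_quot[genes]),
    status = unname(status[genes]),
    stringsAsFactors = FALSE, row.names = NULL)

  attrition <- list(
    probes_total = nrow(rec),
    genes_total = length(genes),
    probes_low = sum(rec$low_pass),
    genes_low = sum(gene_low),
    probes_medium = sum(rec$medium_pass),
    genes_medium = sum(gene_med),
    genes_unverifiable = sum(status == "unverifiable"),
    genes_with_verification_probes = sum(has_probe),
    genes_verified = sum(status == "verified"))

  list(records = rec, gene_records = gene_records, verification = verification,
       attrition = attrition, cutoff = cutoff)
}
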