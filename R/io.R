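#' Read an expression matrix from TSV or GCT
#'
#' The canonical TSV dialect has the probe id in column 1 under the header
#' cell `PROBE_ID` and one column per sample. GCT 1.2 (the GenePattern
#' dialect) is accepted as a convenience: a `#1.2` version line, a
#' `rows<TAB>columns` dimension line, then `Name` and `Description` columns
#' ahead of the samples.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"gct"`.
#' @param platform Platform tag stored on the returned matrix.
#' @param scale Scale flag for the returned matrix (`"linear"` default).
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "gct"),
                                   platform = "unknown",
                                   scale = c("linear", "log2")) {
  dialect <- match.arg(dialect)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "tsv") {
    header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    if (length(header) < 2L || header[1] != "PROBE_ID")
      stop("malformed TSV header (line 1): first cell must be 'PROBE_ID', got '",
           header[1], "'", call. = FALSE)
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    vals <- as.matrix(df[, -1, drop = FALSE])
  } else {
    lines <- readLines(path)
    if (length(lines) < 3L || trimws(lines[1]) != "#1.2")
      stop("malformed GCT header (line 1): expected '#1.2', got '",
           lines[1], "'", call. = FALSE)
    dims <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]]))
    if (length(dims) < 2L || anyNA(dims[1:2]))
      stop("malformed GCT dimension line (line 2): '", lines[2], "'",
           call. = FALSE)
    df <- utils::read.delim(text = lines[-(1:2)], check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (!identical(names(df)[1:2], c("Name", "Description")))
      stop("malformed GCT column header (line 3): expected 'Name' and ",
           "'Description' columns", call. = FALSE)
    if (nrow(df) != dims[1] || ncol(df) - 2L != dims[2])
      stop("GCT dimension line says ", dims[1], " x ", dims[2],
           " but table is ", nrow(df), " x ", ncol(df) - 2L, call. = FALSE)
    ids <- as.character(df$Name)
    vals <- as.matrix(df[, -(1:2), drop = FALSE])
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate probe id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  if (!is.numeric(vals))
    stop("non-numeric expression values in ", path, call. = FALSE)
  rownames(vals) <- ids
  expression_matrix(vals, platform = platform, scale = scale)
}

#' Write an expression matrix to TSV or GCT
#'
#' @param m [expression_matrix()].
#' @param path Output path.
#' @param dialect `"tsv"` or `"gct"`.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(m, path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (dialect == "tsv") {
    df <- data.frame(PROBE_ID = rownames(m$values), m$values,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(m$values), ncol(m$values), sep = "\t")), con)
    df <- data.frame(Name = rownames(m$values),
                     Description = rownames(m$values),
                     m$values, check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Construct / read a probe annotation table
#'
#' Maps probe ids to gene symbols and flags control probes. Control probes
#' must not carry a gene symbol (they target no human RNA).
#'
#' @param probe_id Character vector of probe ids (unique within a platform).
#' @param gene_symbol Character vector; `NA` for probes without a symbol.
#' @param is_control Logical vector.
#' @param platform Platform label.
#' @return A `data.frame` of class `ProbeAnnotation`.
#' @export
probe_annotation <- function(probe_id, gene_symbol, is_control = FALSE,
                             platform = "unknown") {
  df <- data.frame(probe_id = as.character(probe_id),
                   gene_symbol = as.character(gene_symbol),
                   is_control = rep_len(as.logical(is_control), length(probe_id)),
                   platform = platform,
                   stringsAsFactors = FALSE)
  dup <- unique(df$probe_id[duplicated(df$probe_id)])
  if (length(dup))
    stop("duplicate probe id(s) in annotation: ", paste(dup, collapse = ", "),
         call. = FALSE)
  bad <- df$is_control & !is.na(df$gene_symbol)
  if (any(bad))
    stop("control probe(s) with a gene symbol: ",
         paste(df$probe_id[bad], collapse = ", "), call. = FALSE)
  class(df) <- c("ProbeAnnotation", "data.frame")
  df
}

#' @rdname probe_annotation
#' @param path TSV with columns `probe_id`, `gene_symbol`, `is_control`
#'   (empty `gene_symbol` read as `NA`).
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  probe_annotation(df$probe_id, df$gene_symbol, as.logical(df$is_control),
                   platform = df$platform[1] %||% "unknown")
}

#' Construct / read sample metadata
#'
#' One row per sample: dataset and sample-type labels, the role the sample
#' plays in the screens, optional tissue group (normal-tissue panel only),
#' optional RNA-integrity score and culture status.
#'
#' @param sample_id Unique sample identifiers.
#' @param dataset Dataset label.
#' @param sample_type Group label (e.g. `"MCB cryo"`, `"ALDH POS"`).
#' @param role One of `svbr`, `normal_breast_cultured`,
#'   `normal_breast_noncultured`, `breast_cancer`, `normal_tissue_panel`,
#'   `other`.
#' @param tissue_group Tissue-group label (normal-tissue panel samples).
#' @param rin_e Optional RNA integrity number equivalent (finite when present).
#' @param culture_status `cultured`, `non_cultured` or `unknown`.
#' @return A `data.frame` of class `SampleMetadata`.
#' @export
sample_metadata <- function(sample_id, dataset = "unknown", sample_type = "unknown",
                            role = "other", tissue_group = NA_character_,
                            rin_e = NA_real_, culture_status = "unknown") {
  roles <- c("svbr", "normal_breast_cultured", "normal_breast_noncultured",
             "breast_cancer", "normal_tissue_panel", "other")
  n <- length(sample_id)
  df <- data.frame(sample_id = as.character(sample_id),
                   dataset = rep_len(dataset, n),
                   sample_type = rep_len(sample_type, n),
                   role = rep_len(role, n),
                   tissue_group = rep_len(as.character(tissue_group), n),
                   rin_e = rep_len(as.numeric(rin_e), n),
                   culture_status = rep_len(culture_status, n),
                   stringsAsFactors = FALSE)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  bad <- !(df$role %in% roles)
  if (any(bad))
    stop("unknown role(s): ", paste(unique(df$role[bad]), collapse = ", "),
         call. = FALSE)
  if (any(!is.na(df$rin_e) & !is.finite(df$rin_e)))
    stop("rin_e must be finite when present", call. = FALSE)
  bad_cs <- !(df$culture_status %in% c("cultured", "non_cultured", "unknown"))
  if (any(bad_cs)) stop("invalid culture_status", call. = FALSE)
  class(df) <- c("SampleMetadata", "data.frame")
  df
}

#' @rdname sample_metadata
#' @param path TSV with the metadata columns.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  sample_metadata(df$sample_id, df$dataset %||% "unknown", df$sample_type,
                  df$role, df$tissue_group %||% NA_character_,
                  df$rin_e %||% NA_real_, df$culture_status %||% "unknown")
}

#' Write / read screen records
#'
#' Tab-separated serialization of a screen-record table (one row per
#' gene-probe pair with all scores and tier flags); reading back reproduces
#' the records exactly.
#'
#' @param records A `data.frame` of screen records.
#' @param path Output path.
#' @return `write_screen_results()` invisibly returns `path`;
#'   `read_screen_results()` returns the `data.frame`.
#' @export
write_screen_results <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_screen_results
#' @export
read_screen_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                    check.names = FALSE)
}
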