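# Small in-code fixtures shared across test files.

make_matrix <- function(values, probes = NULL, samples = NULL,
                        platform = "synthetic", scale = "linear") {
  if (is.null(probes)) probes <- sprintf("P%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(ncol(values)))
  dimnames(values) <- list(probes, samples)
  expression_matrix(values, platform = platform, scale = scale)
}

# 3 probes x 2 samples, the canonical IO fixture
tiny_matrix <- function() {
  make_matrix(matrix(c(1.5, 2, 3, 4, 5.25, 6), nrow = 3, byrow = TRUE),
              probes = c("P1", "P2", "P3"), samples = c("A", "B"))
}

simple_annotation <- function(m, controls = character(0)) {
  ids <- rownames(m$values)
  probe_annotation(ids,
                   ifelse(ids %in% controls, NA_character_, paste0("G_", ids)),
                   is_control = ids %in% controls,
                   platform = m$platform)
}

# Table of printed CTA overexpression scores: SV-BR-1-GM representative,
# maximum nonmalignant representatives (cultured + non-cultured, and
# non-cultured only), and the two published ratio columns.
cta_reference_table <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
gene probe svbr max_cnc max_nc ratio_cnc ratio_nc
PRAME ILMN_1700031 869.1 142.8 114.7 6.1 7.6
PRAME ILMN_2306033 431.9 145.1 112.5 3.0 3.8
PBK ILMN_1673673 663.0 1465.5 107.2 0.5 6.2
CEP55 ILMN_1747016 708.4 3756.0 126.2 0.2 5.6
KIF2C ILMN_1685916 668.0 484.9 130.8 1.4 5.1
PLAC1 ILMN_1754207 415.4 150.1 144.9 2.8 2.9
OIP5 ILMN_1759277 405.9 372.3 167.3 1.1 2.4
CABYR ILMN_2412139 369.6 533.8 179.0 0.7 2.1
SPAG1 ILMN_1712773 289.1 203.7 181.6 1.4 1.6
")
}
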