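test_that("ratio_score reproduces every published overexpression score cell", {
  tab <- cta_reference_table()
  expect_equal(ratio_score(tab$svbr, tab$max_cnc), tab$ratio_cnc)
  expect_equal(ratio_score(tab$svbr, tab$max_nc), tab$ratio_nc)
  expect_equal(ratio_score(100, 100), 1.0)
  expect_error(ratio_score(10, 0), "positive")
})

test_that("low-stringency filter is strict on both arms", {
  cut <- 10
  expect_true(taa_low_stringency(31, 20, cut))
  expect_false(taa_low_stringency(31, 21, cut))   # 31 not > 31.5
  expect_false(taa_low_stringency(14, 1, cut))    # fails the background arm
  expect_false(taa_low_stringency(15, 1, cut))    # boundary: 15 not > 15
})

test_that("medium-stringency filter is strictly above five-fold background", {
  cut <- 10
  expect_true(taa_medium_stringency(51, cut))
  expect_false(taa_medium_stringency(50, cut))
  expect_false(taa_medium_stringency(0, cut))
})

test_that("verification quotient is inclusive at the calibrated cutoff", {
  hs <- taa_high_stringency(c(3.95, 3.00, 2.99), rep(1, 3))
  expect_equal(hs$quotient, c(3.95, 3.00, 2.99))
  expect_identical(hs$verified, c(TRUE, TRUE, FALSE))
  # non-positive normal comparator -> not evaluable, not FALSE
  na <- taa_high_stringency(5, 0)
  expect_true(is.na(na$quotient) && is.na(na$verified))
})

test_that("CTA screen enforces all three strict criteria", {
  cut <- 10
  expect_true(cta_screen(16, 10, cut))    # 16>15, 16>15, 10<15
  expect_false(cta_screen(16, 16, cut))   # NC level not below 1.5x cutoff
  expect_false(cta_screen(15, 5, cut))    # first criterion strict
  expect_false(cta_screen(16, 11, cut))   # 16 not > 16.5
})

test_that("immune screen requires every sample, with probes voting independently", {
  cut <- structure(list(value = 100, n_probes = 5L, source_note = ""),
                   class = "BackgroundCutoff")
  vals <- rbind(
    Pa = c(160, 160, 160),   # G1: > 1.5x in all samples, never > 5x
    Pb = c(160, 160, 140),   # G2: violates the all-samples rule
    Pc = c(600, 550, 900),   # G3 probe 1: tier 2
    Pd = c(100, 100, 100))   # G3 probe 2: below threshold (best probe carries)
  m <- make_matrix(vals, probes = rownames(vals))
  ann <- probe_annotation(rownames(vals), c("G1", "G2", "G3", "G3"))
  res <- immune_signature_screen(m, c("G1", "G2", "G3", "G4"), ann, cut)
  expect_identical(res$immune_tier1, c(TRUE, FALSE, TRUE, NA))
  expect_identical(res$immune_tier2, c(FALSE, FALSE, TRUE, NA))
  expect_identical(res$n_probes, c(1L, 1L, 2L, 0L))
})

test_that("raising any fold threshold never adds a passing gene", {
  set.seed(13)
  for (i in 1:25) {
    svbr <- rlnorm(1, 5, 1); max_all <- rlnorm(1, 5, 1); cut <- rlnorm(1, 4, 0.5)
    f1 <- runif(1, 1.1, 4); f2 <- f1 + runif(1, 0.1, 3)
    lo <- screen_config(fold_low = f1, fold_medium = f1 + 5)
    hi <- screen_config(fold_low = f2, fold_medium = f2 + 5)
    expect_true(taa_low_stringency(svbr, max_all, cut, hi) <=
                  taa_low_stringency(svbr, max_all, cut, lo))
    lo_m <- screen_config(fold_medium = f1 + 1)
    hi_m <- screen_config(fold_medium = f2 + 1)
    expect_true(taa_medium_stringency(svbr, cut, hi_m) <=
                  taa_medium_stringency(svbr, cut, lo_m))
    # CTA pass implies the background arm (first criterion is necessary)
    max_nc <- rlnorm(1, 4.5, 1)
    if (cta_screen(svbr, max_nc, cut)) expect_gt(svbr, 1.5 * cut)
  }
})

test_that("pipeline survivors match a brute-force gene-by-gene re-evaluation", {
  cfg <- study_config(
    n_null_genes = 40,
    planted = data.frame(compartment = c("svbr_only", "cultured_normals_too"),
                         n_genes = c(5L, 2L), fold = c(8, 8)),
    replicates = 2L, two_probe_fraction = 0.1, seed = 303)
  st <- generate_study(cfg)
  res <- run_taa_pipeline(st$svbr, st$normal_breast, st$breast_cancer,
                          st$normal_tissue, st$annotation, st$metadata,
                          st$verification_annotation)

  # independent oracle: explicit loops over the merged matrix
  merged <- cbind(st$svbr$values, st$normal_breast$values)
  md <- st$metadata
  ann <- st$annotation[!st$annotation$is_control, ]
  cut_probes <- setdiff(rownames(merged),
                        st$annotation$probe_id[st$annotation$is_control])
  cutoff <- median(as.vector(merged[cut_probes, ]))
  expect_equal(res$cutoff$value, cutoff)

  oracle_low <- character(0); oracle_med <- character(0)
  for (g in unique(ann$gene_symbol)) {
    probes <- ann$probe_id[ann$gene_symbol == g]
    g_low <- FALSE; g_med <- FALSE
    for (p in probes) {
      sv_types <- unique(md$sample_type[md$role == "svbr"])
      type_means <- sapply(sv_types, function(tp)
        mean(merged[p, md$sample_id[md$sample_type == tp & md$role == "svbr"]]))
      sv <- median(type_means)
      nb <- md[md$role %in% c("normal_breast_cultured",
                              "normal_breast_noncultured"), ]
      grp_rep <- sapply(unique(nb$sample_type), function(tp) {
        ids <- nb$sample_id[nb$sample_type == tp]
        if (nb$role[nb$sample_type == tp][1] == "normal_breast_noncultured")
          median(merged[p, ids]) else mean(merged[p, ids])
      })
      p_low <- sv > 1.5 * cutoff && sv > 1.5 * max(grp_rep)
      p_med <- p_low && sv > 5 * cutoff
      g_low <- g_low || p_low; g_med <- g_med || p_med
    }
    if (g_low) oracle_low <- c(oracle_low, g)
    if (g_med) oracle_med <- c(oracle_med, g)
  }
  gr <- res$gene_records
  expect_setequal(gr$gene_symbol[gr$low_pass], oracle_low)
  expect_setequal(gr$gene_symbol[gr$medium_pass], oracle_med)
})

test_that("genes absent from the verification platform are unverifiable, not rejected", {
  cfg <- study_config(
    n_null_genes = 30,
    planted = data.frame(compartment = "svbr_and_bc", n_genes = 6L, fold = 8),
    replicates = 2L, verification_dropout = 0, seed = 88)
  st <- generate_study(cfg)
  # remove two planted genes from the verification annotation by hand
  va <- st$verification_annotation
  va <- va[!(va$gene_symbol %in% c("TAA_BC_001", "TAA_BC_002")), ]
  res <- run_taa_pipeline(st$svbr, st$normal_breast, st$breast_cancer,
                          st$normal_tissue, st$annotation, st$metadata, va)
  gr <- res$gene_records
  expect_identical(gr$status[gr$gene_symbol == "TAA_BC_001"], "unverifiable")
  expect_identical(gr$status[gr$gene_symbol == "TAA_BC_003"], "verified")
  expect_identical(res$attrition$genes_unverifiable, 2L)
  expect_error(run_taa_pipeline(st$svbr, st$normal_breast, st$breast_cancer,
                                st$normal_tissue, st$annotation, st$metadata,
                                va[0, ]), "empty cross-platform")
})

test_that("raising fold_low above the planted fold empties the screen", {
  cfg <- study_config(
    n_null_genes = 30,
    planted = data.frame(compartment = "svbr_only", n_genes = 5L, fold = 4),
    replicates = 2L, seed = 17)
  st <- generate_study(cfg)
  res <- run_taa_pipeline(st$svbr, st$normal_breast, st$breast_cancer,
                          st$normal_tissue, st$annotation, st$metadata,
                          st$verification_annotation,
                          config = screen_config(fold_low = 6))
  expect_identical(res$attrition$genes_low, 0L)
})

test_that("screen records reproduce their own ratio columns", {
  cfg <- study_config(n_null_genes = 50, replicates = 2L, seed = 23)
  st <- generate_study(cfg)
  res <- run_taa_pipeline(st$svbr, st$normal_breast, st$breast_cancer,
                          st$normal_tissue, st$annotation, st$metadata,
                          st$verification_annotation)
  rec <- res$records
  expect_equal(rec$ratio_all, round_half_up(rec$svbr_value / rec$max_normal_all, 1))
  expect_equal(rec$ratio_nc, round_half_up(rec$svbr_value / rec$max_normal_nc, 1))
  # CTA pass implies the first criterion
  expect_true(all(rec$svbr_value[rec$cta_pass] > 1.5 * res$cutoff$value))
})
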