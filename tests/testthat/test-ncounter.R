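make_run <- function(endo, pos, neg, ref = rownames(endo)[1]) {
  ncounter_run(endo, pos, neg, reference_genes = ref)
}

test_that("background subtraction uses the per-lane negative-control maximum", {
  endo <- matrix(c(110, 5, 200, 50), 2,
                 dimnames = list(c("G1", "G2"), c("L1", "L2")))
  pos <- matrix(c(100, 100), 1, dimnames = list("P", c("L1", "L2")))
  neg <- matrix(c(10, 3, 40, 2), 2, dimnames = list(c("N1", "N2"), c("L1", "L2")))
  run <- subtract_background(make_run(endo, pos, neg))
  expect_equal(unname(run$endogenous),
               matrix(c(100, 0, 160, 10), 2))  # max 10 in L1, 40 in L2; clip at 0
  glob <- subtract_background(make_run(endo, pos, neg), method = "global")
  expect_equal(unname(glob$endogenous), matrix(c(70, 0, 160, 10), 2))
})

test_that("stage factors follow the mean-of-geometric-means construction", {
  endo <- matrix(c(100, 100, 100, 100), 2,
                 dimnames = list(c("R1", "G2"), c("L1", "L2")))
  pos <- matrix(c(100, 400), 1, dimnames = list("P", c("L1", "L2")))
  neg <- matrix(0, 1, 2, dimnames = list("N", c("L1", "L2")))
  run <- subtract_background(make_run(endo, pos, neg, ref = "R1"))
  out <- normalize_counts(run)
  expect_equal(out$factors$pos_factor, c(2.5, 0.625))  # global mean 250
})

test_that("single lane and identical lanes normalize with unit factors", {
  endo <- matrix(c(50, 70), 2, 1, dimnames = list(c("R1", "G2"), "L1"))
  pos <- matrix(100, 1, 1, dimnames = list("P", "L1"))
  neg <- matrix(0, 1, 1, dimnames = list("N", "L1"))
  out <- normalize_counts(subtract_background(make_run(endo, pos, neg, "R1")))
  expect_equal(out$factors$total_factor, 1)
  endo2 <- matrix(rep(c(50, 70), 3), 2, 3,
                  dimnames = list(c("R1", "G2"), c("L1", "L2", "L3")))
  pos2 <- matrix(100, 1, 3, dimnames = list("P", c("L1", "L2", "L3")))
  neg2 <- matrix(0, 1, 3, dimnames = list("N", c("L1", "L2", "L3")))
  out2 <- normalize_counts(subtract_background(make_run(endo2, pos2, neg2, "R1")))
  expect_equal(out2$factors$total_factor, rep(1, 3))
})

test_that("post-normalization geometric means agree across lanes exactly", {
  sim <- generate_ncounter_run(n_genes = 100, n_lanes = 6, lane_scale_spread = 3,
                               seed = 41)
  run <- subtract_background(sim$run)
  out <- normalize_counts(run)
  pos_scaled <- sweep(run$positive_controls, 2, out$factors$pos_factor, "*")
  gm_pos <- apply(pos_scaled, 2, function(x) as.numeric(geometric_mean(x)))
  expect_equal(unname(gm_pos), rep(gm_pos[[1]], 6), tolerance = 1e-12)
  gm_ref <- apply(out$counts[run$reference_genes, ], 2,
                  function(x) as.numeric(geometric_mean(x)))
  expect_equal(unname(gm_ref), rep(gm_ref[[1]], 6), tolerance = 1e-12)
})

test_that("normalization is scale-invariant and idempotent (zero background)", {
  set.seed(6)
  endo <- matrix(rpois(40, 500) + 0, 4, 10,
                 dimnames = list(c("R1", "R2", "G3", "G4"), paste0("L", 1:10)))
  pos <- matrix(rpois(30, 800) + 0, 3, 10,
                dimnames = list(paste0("P", 1:3), paste0("L", 1:10)))
  neg <- matrix(0, 1, 10, dimnames = list("N", paste0("L", 1:10)))
  run <- subtract_background(make_run(endo, pos, neg, ref = c("R1", "R2")))
  out1 <- normalize_counts(run)
  # multiply one lane's raw counts by a constant: the normalized table is
  # unchanged up to the single global level set by the cross-lane mean
  # (relative abundances, the quantity the normalization defines, are intact)
  run2 <- run
  run2$endogenous[, 3] <- run2$endogenous[, 3] * 7
  run2$positive_controls[, 3] <- run2$positive_controls[, 3] * 7
  out2 <- normalize_counts(run2)
  ratio <- out2$counts / out1$counts
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-12)
  # idempotence on already-normalized data
  run3 <- run
  run3$endogenous <- out1$counts
  run3$positive_controls <- sweep(run$positive_controls, 2,
                                  out1$factors$pos_factor, "*")
  out3 <- normalize_counts(run3)
  expect_equal(out3$counts, out1$counts, tolerance = 1e-12)
})

test_that("planted lane scales are recovered from simulated runs", {
  sim <- generate_ncounter_run(n_genes = 500, n_lanes = 12,
                               lane_scale_spread = 2, seed = 77)
  out <- normalize_counts(subtract_background(sim$run))
  expect_gt(cor(out$factors$total_factor, 1 / sim$lane_scale), 0.99)
  # no lane effect -> normalization is the identity within Poisson error
  null_sim <- generate_ncounter_run(n_genes = 300, n_lanes = 6,
                                    lane_scale_spread = 1, seed = 78)
  out0 <- normalize_counts(subtract_background(null_sim$run))
  expect_true(all(abs(out0$factors$total_factor - 1) < 0.05))
})

test_that("RCC-like tables round-trip through the reader", {
  sim <- generate_ncounter_run(n_genes = 20, n_lanes = 3, seed = 50)
  run <- sim$run
  df <- data.frame(
    CodeClass = c(ifelse(rownames(run$endogenous) %in% run$reference_genes,
                         "Housekeeping", "Endogenous"),
                  rep("Positive", nrow(run$positive_controls)),
                  rep("Negative", nrow(run$negative_controls))),
    Name = c(rownames(run$endogenous), rownames(run$positive_controls),
             rownames(run$negative_controls)),
    rbind(run$endogenous, run$positive_controls, run$negative_controls),
    check.names = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_ncounter(path)
  expect_equal(back$endogenous[rownames(run$endogenous), ], run$endogenous)
  expect_setequal(back$reference_genes, run$reference_genes)
  bad <- df; bad$CodeClass[1] <- "Mystery"
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_ncounter(path), "Mystery")
})

test_that("run validation rejects inconsistent control or reference sets", {
  endo <- matrix(1, 2, 2, dimnames = list(c("G1", "G2"), c("L1", "L2")))
  pos <- matrix(1, 1, 2, dimnames = list("P", c("L1", "L2")))
  neg <- matrix(1, 1, 2, dimnames = list("N", c("L1", "L2")))
  expect_error(ncounter_run(endo, pos, neg, reference_genes = "ZZZ"), "absent")
  expect_error(ncounter_run(endo, pos[0, , drop = FALSE], neg, "G1"),
               "at least one positive")
  neg_bad <- neg; colnames(neg_bad) <- c("L1", "LX")
  expect_error(ncounter_run(endo, pos, neg_bad, "G1"), "lane ids")
})
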