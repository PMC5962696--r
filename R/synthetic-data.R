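#' Synthetic-study configuration
#'
#' Defines the cohort structure and planted effects of a generated study.
#' The defaults mirror the cohort the screens were designed around: nine
#' SV-BR-1-GM sample types, six non-cultured normal-breast cell types and
#' three cultured normal-breast sets on the discovery platform, 54
#' breast-cancer tissues and an organ-grouped normal-tissue panel on the
#' verification platform. Intensities are log-normal with multiplicative
#' planted folds (the screens are ratio-based); planted genes sit at the
#' baseline median so the fold is a fold-over-background.
#'
#' Planted compartments:
#' * `svbr_only` -- fold in SV-BR-1-GM samples only (TAA that fails
#'   verification: not elevated in breast-cancer tissue),
#' * `svbr_and_bc` -- fold in SV-BR-1-GM and breast-cancer samples (the
#'   verifiable TAA pattern),
#' * `cultured_normals_too` -- fold also in cultured normal-breast groups
#'   (the proliferation-antigen pattern: fails the cultured+non-cultured
#'   comparison but stands out against non-cultured cells only).
#'
#' @param n_null_genes Number of unplanted background genes.
#' @param planted `data.frame` with columns `compartment`, `n_genes`, `fold`.
#' @param svbr_types SV-BR-1-GM sample-type labels.
#' @param nc_groups Non-cultured normal-breast group labels.
#' @param cultured_groups Cultured normal-breast group labels.
#' @param replicates Replicates per sample type / group.
#' @param n_bc_samples Breast-cancer tissue samples.
#' @param n_tissue_groups Normal-tissue panel groups.
#' @param noise_cv Multiplicative (log-normal) noise coefficient of variation.
#' @param baseline_log_mean,baseline_log_sd Log-normal baseline parameters
#'   (natural log).
#' @param control_fraction Fraction of probes that are near-zero controls.
#' @param two_probe_fraction Fraction of genes carried by two probes.
#' @param verification_dropout Fraction of genes without a verification-platform
#'   probe.
#' @param seed Mandatory integer seed (no implicit randomness).
#' @return Object of class `StudyConfig`.
#' @export
study_config <- function(n_null_genes = 2000,
                         planted = data.frame(
                           compartment = c("svbr_only", "svbr_and_bc",
                                           "cultured_normals_too"),
                           n_genes = c(20L, 20L, 2L),
                           fold = c(8, 8, 8)),
                         svbr_types = c("MCB cryo", "CP Lot IV culture",
                                        "CP Lot IV 4p cryo", "CP Lot IV 4p culture",
                                        "CP Lot V cryo", "CP Lot VIII cryo",
                                        "CP Lot VIII culture 1d",
                                        "CP Lot VIII culture 3d", "RES Lot II cryo"),
                         nc_groups = c("ALDH NEG", "ALDH POS", "ERBB3 NEG",
                                       "NCL", "BASAL", "STROMAL"),
                         cultured_groups = c("HMEC proliferating",
                                             "HMEC senescent", "MCF10A"),
                         replicates = 3L,
                         n_bc_samples = 54L,
                         n_tissue_groups = 30L,
                         noise_cv = 0.2,
                         baseline_log_mean = log(150),
                         baseline_log_sd = 0.5,
                         control_fraction = 0.02,
                         two_probe_fraction = 0.05,
                         verification_dropout = 0.05,
                         seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(all(planted$fold > 0), noise_cv >= 0, replicates >= 1,
            n_null_genes >= 1, n_bc_samples >= 2, n_tissue_groups >= 2,
            all(planted$compartment %in%
                  c("svbr_only", "svbr_and_bc", "cultured_normals_too")))
  structure(as.list(environment()), class = "StudyConfig")
}

lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))  # mean-1 multiplicative noise
}

#' Generate a complete synthetic study with planted ground truth
#'
#' Draws baseline intensities log-normal(`baseline_log_mean`,
#' `baseline_log_sd`), pins planted genes at the baseline median
#' `exp(baseline_log_mean)`, applies the planted folds in their target
#' compartments, multiplies in log-normal noise of the configured CV, and
#' injects near-zero control probes. Fully deterministic given
#' `config$seed`.
#'
#' @param config A [study_config()].
#' @return List: `svbr`, `normal_breast`, `breast_cancer`, `normal_tissue`
#'   ([expression_matrix()] objects), `annotation` and
#'   `verification_annotation` ([probe_annotation()]), `metadata`
#'   ([sample_metadata()]), `truth` (per-gene `data.frame`: `gene_symbol`,
#'   `compartment`, `fold`, `baseline`, `verifiable`, and the noiseless
#'   expected verdicts `expected_low`, `expected_medium`,
#'   `expected_cta`, `expected_verified`), and `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "StudyConfig"))
  set.seed(config$seed)
  cf <- config

  planted_genes <- do.call(rbind, lapply(seq_len(nrow(cf$planted)), function(i) {
    p <- cf$planted[i, ]
    tag <- switch(p$compartment, svbr_only = "TAA_SV", svbr_and_bc = "TAA_BC",
                  cultured_normals_too = "CTA_CULT")
    data.frame(gene_symbol = sprintf("%s_%03d", tag, seq_len(p$n_genes)),
               compartment = p$compartment, fold = p$fold,
               stringsAsFactors = FALSE)
  }))
  null_genes <- data.frame(
    gene_symbol = sprintf("GENE_%05d", seq_len(cf$n_null_genes)),
    compartment = "null", fold = 1, stringsAsFactors = FALSE)
  genes <- rbind(planted_genes, null_genes)
  n_genes <- nrow(genes)

  base <- exp(cf$baseline_log_mean) *
    exp(stats::rnorm(n_genes, 0, cf$baseline_log_sd))
  base[genes$compartment != "null"] <- exp(cf$baseline_log_mean)
  genes$baseline <- base

  # probes: every gene one probe, a fraction two
  n_two <- round(cf$two_probe_fraction * n_genes)
  two <- if (n_two > 0) sample.int(n_genes, n_two) else integer(0)
  probe_gene <- c(seq_len(n_genes), two)
  probe_id <- sprintf("P%06d", seq_along(probe_gene))
  n_ctrl <- max(1L, round(cf$control_fraction * length(probe_id)))
  ctrl_id <- sprintf("CTRL_%04d", seq_len(n_ctrl))

  ann <- probe_annotation(
    probe_id = c(probe_id, ctrl_id),
    gene_symbol = c(genes$gene_symbol[probe_gene], rep(NA_character_, n_ctrl)),
    is_control = c(rep(FALSE, length(probe_id)), rep(TRUE, n_ctrl)),
    platform = "synthetic")

  sim_block <- function(sample_ids, fold_per_gene) {
    n_p <- length(probe_gene) + n_ctrl
    v <- matrix(0, n_p, length(sample_ids),
                dimnames = list(c(probe_id, ctrl_id), sample_ids))
    signal <- genes$baseline[probe_gene] * fold_per_gene[probe_gene]
    for (j in seq_along(sample_ids)) {
      v[seq_along(probe_gene), j] <- signal * lognoise(length(probe_gene), cf$noise_cv)
      v[length(probe_gene) + seq_len(n_ctrl), j] <-
        1 * lognoise(n_ctrl, cf$noise_cv)
    }
    v
  }
  fold_if <- function(compartments) ifelse(genes$compartment %in% compartments,
                                           genes$fold, 1)

  mk_ids <- function(labels, reps) {
    unlist(lapply(labels, function(l)
      paste0(gsub("[^A-Za-z0-9]+", "_", l), "_r", seq_len(reps))))
  }
  sv_ids <- mk_ids(cf$svbr_types, cf$replicates)
  nc_ids <- mk_ids(cf$nc_groups, cf$replicates)
  cu_ids <- mk_ids(cf$cultured_groups, cf$replicates)
  bc_ids <- sprintf("BC_%03d", seq_len(cf$n_bc_samples))
  tissue_groups <- sprintf("organ_%02d", seq_len(cf$n_tissue_groups))
  nt_ids <- mk_ids(tissue_groups, cf$replicates)

  svbr_fold <- fold_if(c("svbr_only", "svbr_and_bc", "cultured_normals_too"))
  svbr <- expression_matrix(sim_block(sv_ids, svbr_fold), "synthetic", "linear")
  nb_vals <- cbind(sim_block(nc_ids, rep(1, n_genes)),
                   sim_block(cu_ids, fold_if("cultured_normals_too")))
  normal_breast <- expression_matrix(nb_vals, "synthetic", "linear")

  # verification platform: one probe per gene, minus a dropout fraction
  n_drop <- round(cf$verification_dropout * n_genes)
  dropped <- if (n_drop > 0) sample.int(n_genes, n_drop) else integer(0)
  vkeep <- setdiff(seq_len(n_genes), dropped)
  vp_id_all <- sprintf("VP_%05d", seq_len(n_genes))
  ver_ann <- probe_annotation(vp_id_all[vkeep], genes$gene_symbol[vkeep],
                              is_control = FALSE,
                              platform = "synthetic-verification")
  sim_ver <- function(sample_ids, fold_per_gene) {
    v <- matrix(0, n_genes, length(sample_ids),
                dimnames = list(vp_id_all, sample_ids))
    signal <- genes$baseline * fold_per_gene
    for (j in seq_along(sample_ids))
      v[, j] <- signal * lognoise(n_genes, cf$noise_cv)
    v
  }
  breast_cancer <- expression_matrix(sim_ver(bc_ids, fold_if("svbr_and_bc")),
                                     "synthetic-verification", "linear")
  normal_tissue <- expression_matrix(sim_ver(nt_ids, rep(1, n_genes)),
                                     "synthetic-verification", "linear")

  metadata <- rbind(
    sample_metadata(sv_ids, dataset = "synthetic-svbr",
                    sample_type = rep(cf$svbr_types, each = cf$replicates),
                    role = "svbr", culture_status = "cultured"),
    sample_metadata(nc_ids, dataset = "synthetic-normal-breast",
                    sample_type = rep(cf$nc_groups, each = cf$replicates),
                    role = "normal_breast_noncultured",
                    culture_status = "non_cultured"),
    sample_metadata(cu_ids, dataset = "synthetic-normal-breast",
                    sample_type = rep(cf$cultured_groups, each = cf$replicates),
                    role = "normal_breast_cultured", culture_status = "cultured"),
    sample_metadata(bc_ids, dataset = "synthetic-breast-cancer",
                    sample_type = "breast cancer tissue", role = "breast_cancer"),
    sample_metadata(nt_ids, dataset = "synthetic-normal-tissue",
                    sample_type = rep(tissue_groups, each = cf$replicates),
                    role = "normal_tissue_panel",
                    tissue_group = rep(tissue_groups, each = cf$replicates)))

  # noiseless expected verdicts against the nominal cutoff exp(baseline_log_mean)
  c0 <- exp(cf$baseline_log_mean)
  sv_val <- genes$baseline *
    ifelse(genes$compartment != "null", genes$fold, 1)
  max_all <- genes$baseline *
    ifelse(genes$compartment == "cultured_normals_too", genes$fold, 1)
  max_nc <- genes$baseline
  cfg <- screen_config()
  truth <- data.frame(
    gene_symbol = genes$gene_symbol,
    compartment = genes$compartment,
    fold = genes$fold,
    baseline = genes$baseline,
    verifiable = !(seq_len(n_genes) %in% dropped),
    expected_low = sv_val > cfg$fold_low * c0 & sv_val > cfg$fold_low * max_all,
    stringsAsFactors = FALSE)
  truth$expected_medium <- truth$expected_low & sv_val > cfg$fold_medium * c0
  truth$expected_cta <- sv_val > cfg$fold_cta * c0 &
    sv_val > cfg$fold_cta * max_nc & max_nc < cfg$fold_cta * c0
  bc_val <- genes$baseline *
    ifelse(genes$compartment == "svbr_and_bc", genes$fold, 1)
  truth$expected_verified <- truth$expected_medium & truth$verifiable &
    (bc_val / genes$baseline >= cfg$quotient_min)

  list(svbr = svbr, normal_breast = normal_breast,
       breast_cancer = breast_cancer, normal_tissue = normal_tissue,
       annotation = ann, verification_annotation = ver_ann,
       metadata = metadata, truth = truth, config = cf)
}

#' Generate a synthetic Immune-Signature cohort
#'
#' An SV-BR-1-GM-only cohort with a queried immunostimulatory gene list in
#' which a chosen number of genes is planted above the tier-1 and tier-2
#' thresholds in every sample. Planted list genes are pinned at the baseline
#' median times their fold; unplanted list genes sit at the baseline median;
#' background (non-list) genes get log-normal baselines and carry the
#' background-cutoff distribution. The default folds (3.5x for tier-1-only,
#' 12x for tier-2 genes) leave more than four noise standard deviations
#' between each planted gene and the nearest threshold at the default noise
#' CV, so the every-sample rule is unambiguous.
#'
#' @param n_list_genes Size of the queried gene list (default 111).
#' @param n_tier1_only Genes planted above tier 1 but not tier 2.
#' @param n_tier2 Genes planted above tier 2 (also tier-1 members).
#' @param tier1_fold,tier2_fold Planted folds over the baseline median.
#' @param n_background_genes Non-list background genes.
#' @param svbr_types,replicates,noise_cv,baseline_log_mean,baseline_log_sd,control_fraction
#'   As in [study_config()].
#' @param seed Mandatory integer seed.
#' @return List: `matrix` ([expression_matrix()]), `annotation`,
#'   `gene_list`, `truth` (`gene_symbol`, `tier` in
#'   `none`/`tier1`/`tier2`), `config` echo.
#' @export
generate_immune_cohort <- function(n_list_genes = 111L, n_tier1_only = 11L,
                                   n_tier2 = 11L, tier1_fold = 3.5,
                                   tier2_fold = 12,
                                   n_background_genes = 2000L,
                                   svbr_types = study_config(seed = 0)$svbr_types,
                                   replicates = 3L, noise_cv = 0.2,
                                   baseline_log_mean = log(150),
                                   baseline_log_sd = 0.5,
                                   control_fraction = 0.02, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_tier1_only + n_tier2 <= n_list_genes, tier1_fold > 1,
            tier2_fold > tier1_fold)
  set.seed(seed)
  list_genes <- sprintf("IMM_%03d", seq_len(n_list_genes))
  tier <- rep("none", n_list_genes)
  tier[seq_len(n_tier2)] <- "tier2"
  tier[n_tier2 + seq_len(n_tier1_only)] <- "tier1"
  bg_genes <- sprintf("BG_%05d", seq_len(n_background_genes))
  genes <- c(list_genes, bg_genes)
  n_genes <- length(genes)

  b0 <- exp(baseline_log_mean)
  level <- c(b0 * ifelse(tier == "tier2", tier2_fold,
                         ifelse(tier == "tier1", tier1_fold, 1)),
             b0 * exp(stats::rnorm(n_background_genes, 0, baseline_log_sd)))

  probe_id <- sprintf("P%06d", seq_len(n_genes))
  n_ctrl <- max(1L, round(control_fraction * n_genes))
  ctrl_id <- sprintf("CTRL_%04d", seq_len(n_ctrl))
  ids <- unlist(lapply(svbr_types, function(l)
    paste0(gsub("[^A-Za-z0-9]+", "_", l), "_r", seq_len(replicates))))
  v <- matrix(0, n_genes + n_ctrl, length(ids),
              dimnames = list(c(probe_id, ctrl_id), ids))
  for (j in seq_along(ids)) {
    v[seq_len(n_genes), j] <- level * lognoise(n_genes, noise_cv)
    v[n_genes + seq_len(n_ctrl), j] <- 1 * lognoise(n_ctrl, noise_cv)
  }
  ann <- probe_annotation(c(probe_id, ctrl_id),
                          c(genes, rep(NA_character_, n_ctrl)),
                          is_control = c(rep(FALSE, n_genes), rep(TRUE, n_ctrl)),
                          platform = "synthetic")
  list(matrix = expression_matrix(v, "synthetic", "linear"),
       annotation = ann, gene_list = list_genes,
       truth = data.frame(gene_symbol = list_genes, tier = tier,
                          stringsAsFactors = FALSE),
       config = list(tier1_fold = tier1_fold, tier2_fold = tier2_fold,
                     noise_cv = noise_cv, replicates = replicates, seed = seed))
}

#' Generate a synthetic allele-frequency table
#'
#' Per (population, locus) frequencies are Dirichlet-distributed over the
#' listed alleles and scaled by `1 - unlisted_mass` (the remainder models
#' unlisted alleles, so sums stay below 1). The listed alleles include the
#' cell line's typed alleles so the default query sets resolve; the
#' allele-group map follows the first field of each allele name.
#'
#' @param n_populations Number of populations.
#' @param n_alleles_per_locus Alleles listed per locus (>= 2).
#' @param seed Mandatory integer seed.
#' @param loci Locus labels.
#' @param unlisted_mass Frequency mass reserved for unlisted alleles.
#' @return An [af_table()] with a group map.
#' @export
generate_af_table <- function(n_populations = 4L, n_alleles_per_locus = 6L,
                              seed, loci = c("HLA-A", "HLA-B", "HLA-DRB3"),
                              unlisted_mass = 0.1) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_populations >= 1, n_alleles_per_locus >= 2,
            unlisted_mass >= 0, unlisted_mass < 1)
  set.seed(seed)
  svbr <- svbr_hla_query("allele")
  pops <- sprintf("POP%02d", seq_len(n_populations))
  rows <- list()
  gm <- list()
  for (loc in loci) {
    fixed <- if (loc %in% names(svbr)) svbr[[loc]] else character(0)
    extra_n <- max(0L, n_alleles_per_locus - length(fixed))
    alleles <- c(fixed, sprintf("%s*90:%02d", loc, seq_len(extra_n)))
    gm[[loc]] <- data.frame(allele = alleles,
                            group = sub(":[^:]*$", "", alleles),
                            stringsAsFactors = FALSE)
    for (pop in pops) {
      g <- stats::rgamma(length(alleles), shape = 1)
      freq <- (1 - unlisted_mass) * g / sum(g)
      rows[[length(rows) + 1L]] <- data.frame(
        population = pop, locus = loc, allele = alleles, frequency = freq,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  af_table(df$population, df$locus, df$allele, df$frequency,
           group_map = do.call(rbind, gm))
}

#' Generate a synthetic digital-count run with planted lane scales
#'
#' Poisson counts around log-normal gene means, multiplied by a per-lane
#' scale drawn log-uniformly within `[1/spread, spread]` (hybridization and
#' loading efficiency); positive and negative control means are fixed and
#' also scaled per lane. The first eight genes are the reference set (named
#' per [NCOUNTER_REFERENCE_GENES]) with means drawn from a narrower, higher
#' band so the reference geometric means are stable.
#'
#' @param n_genes Endogenous genes (>= 8).
#' @param n_lanes Lanes.
#' @param lane_scale_spread Maximum lane-scale fold (1 = no lane effect).
#' @param seed Mandatory integer seed.
#' @param gene_mean_log,gene_mean_sd Log-normal parameters of gene means.
#' @return List: `run` (an [ncounter_run()]), `lane_scale` (the planted
#'   per-lane scale factors, the ground truth for recovery checks).
#' @export
generate_ncounter_run <- function(n_genes = 500L, n_lanes = 12L,
                                  lane_scale_spread = 2, seed,
                                  gene_mean_log = log(500), gene_mean_sd = 1) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_genes >= 8, n_lanes >= 1, lane_scale_spread >= 1)
  set.seed(seed)
  lanes <- sprintf("lane_%02d", seq_len(n_lanes))
  genes <- c(NCOUNTER_REFERENCE_GENES,
             sprintf("GENE_%04d", seq_len(n_genes - 8L)))
  means <- c(exp(stats::runif(8, log(500), log(2000))),
             exp(stats::rnorm(n_genes - 8L, gene_mean_log, gene_mean_sd)))
  scale <- if (lane_scale_spread == 1) rep(1, n_lanes) else
    exp(stats::runif(n_lanes, -log(lane_scale_spread), log(lane_scale_spread)))
  pos_means <- c(8000, 2000, 500, 125, 32, 8)
  neg_mean <- 10

  draw <- function(mu) {
    m <- vapply(scale, function(s) stats::rpois(length(mu), mu * s),
                integer(length(mu)))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(mu))
    colnames(m) <- lanes
    m
  }
  endo <- draw(means); rownames(endo) <- genes
  pos <- draw(pos_means); rownames(pos) <- sprintf("POS_%s", LETTERS[1:6])
  neg <- draw(rep(neg_mean, 8)); rownames(neg) <- sprintf("NEG_%s", LETTERS[1:8])
  list(run = ncounter_run(endo + 0, pos + 0, neg + 0),
       lane_scale = stats::setNames(scale, lanes))
}
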