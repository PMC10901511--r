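# Synthetic MPRA study generator.
#
# Emulates a biallelic targeted STARR-seq library: ~200-nt targets with a
# centered SNP, each synthesized as two allelic constructs that can integrate
# forward or reverse, assayed as RNA counts in two conditions (control,
# caffeine) over replicates, anchored on a sequenced DNA plasmid pool.
# A full ground-truth channel (true allelic log-odds effects per condition,
# true treatment log2 fold-changes, planted motifs) supports calibration,
# FDR, and power studies.

#' Configuration for the synthetic MPRA generator
#'
#' Defaults emulate the assayed study conditions: 43,556 targets of 200 nt
#' with the SNP at the center, ~3.8% negative controls, 6 replicates per
#' condition, and mean sequencing depth of ~450 reads per SNP/direction per
#' replicate (roughly 39M reads per library over 87k constructs). The DNA
#' pool is sequenced `dna_depth_factor` times deeper than one RNA replicate
#' and its reads are binomial (`rho_dna = 0`): the DNA proportion is defined
#' as the pool composition, so overdispersion is a property of RNA relative
#' to that pool.
#'
#' @param n_targets Number of biallelic targets (= SNPs).
#' @param target_length Target length in nt (SNP at 0-based position
#'   `target_length %/% 2`).
#' @param frac_negative_control Fraction of targets that are negative
#'   controls (all true effects exactly 0).
#' @param n_replicates RNA replicates per condition.
#' @param mean_depth Expected total RNA reads per SNP/direction per replicate.
#' @param depth_dispersion Negative-binomial dispersion of per-pair depth
#'   (0 = Poisson).
#' @param dna_proportion_concentration Concentration `c` of the symmetric
#'   Beta(c, c) drawing DNA reference proportions (uneven input pool).
#' @param dna_depth_factor DNA pool depth as a multiple of `mean_depth`.
#' @param rho Beta-binomial overdispersion of RNA allelic counts, in `[0, 1)`.
#' @param rho_dna Overdispersion of DNA pool sequencing (default 0, binomial).
#' @param frac_ase Fraction of SNPs with a shared (both-condition) allelic
#'   effect.
#' @param frac_case Fraction of SNPs with a condition-specific allelic effect
#'   (independent per-condition effects). `frac_ase + frac_case <= 1`.
#' @param effect_sd SD of true allelic log-odds effects.
#' @param direction_specific_effects If `TRUE`, draw independent effects for
#'   the reverse orientation; default shares effects across directions.
#' @param da_frac Fraction of targets with a treatment activity effect.
#' @param da_lfc_sd SD of true treatment log2 fold-changes.
#' @param allele_lfc_sd SD of the per-target allele activity log2
#'   fold-change (the strong allelic axis seen in PCA QC).
#' @param da_baseline_mean Mean baseline activity count per construct per
#'   sample.
#' @param da_baseline_sdlog Log-scale SD of per-target baselines.
#' @param nb_dispersion Negative-binomial dispersion of activity counts.
#' @param size_factor_sdlog Log-scale SD of per-sample size factors.
#' @param motif_set Named list of position frequency matrices to plant
#'   (consensus substitution).
#' @param motif_plant_rate Planting probability per motif in targets without
#'   a true allelic effect.
#' @param motif_ase_multiplier Multiplier on the planting rate in targets
#'   with a true allelic effect (induces motif enrichment); a scalar applied
#'   to every motif, or a named vector keyed by motif ID (unnamed motifs
#'   default to 1).
#' @param seed Integer seed; identical configs give identical outputs.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_targets = 43556,
                       target_length = 200,
                       frac_negative_control = 1676 / 43556,
                       n_replicates = 6,
                       mean_depth = 450,
                       depth_dispersion = 0.5,
                       dna_proportion_concentration = 5,
                       dna_depth_factor = 10,
                       rho = 0.05,
                       rho_dna = 0,
                       frac_ase = 0.05,
                       frac_case = 0.01,
                       effect_sd = 0.5,
                       direction_specific_effects = FALSE,
                       da_frac = 0.05,
                       da_lfc_sd = 0.5,
                       allele_lfc_sd = 0.5,
                       da_baseline_mean = 225,
                       da_baseline_sdlog = 0.5,
                       nb_dispersion = 0.05,
                       size_factor_sdlog = 0.2,
                       motif_set = list(),
                       motif_plant_rate = 0.1,
                       motif_ase_multiplier = 2,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  pos <- c("n_targets", "target_length", "n_replicates", "mean_depth",
           "dna_proportion_concentration", "dna_depth_factor",
           "da_baseline_mean")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      stop("sim_config: '", f, "' must be a positive number")
    }
  }
  fracs <- c("frac_negative_control", "frac_ase", "frac_case",
             "motif_plant_rate")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("sim_config: '", f, "' must lie in [0, 1]")
    }
  }
  if (cfg$frac_ase + cfg$frac_case > 1) {
    stop("sim_config: frac_ase + frac_case must not exceed 1")
  }
  for (f in c("rho", "rho_dna")) {
    if (cfg[[f]] < 0 || cfg[[f]] >= 1) stop("sim_config: '", f, "' must lie in [0, 1)")
  }
  if (cfg$depth_dispersion < 0 || cfg$nb_dispersion < 0) {
    stop("sim_config: dispersions must be non-negative")
  }
  if (cfg$target_length < 10) stop("sim_config: target_length too short")
  invisible(cfg)
}

#' Library combinatorics of a biallelic MPRA design
#'
#' Each target carries one SNP, so it is synthesized as two allelic
#' constructs, and each construct can integrate in the forward or reverse
#' orientation.
#'
#' @param n_targets Number of designed targets (= SNPs).
#' @return List with `n_snps`, `n_targets`, `n_constructs` (`2 * n_targets`;
#'   also the number of SNP/direction pairs), and `n_oriented_constructs`
#'   (`4 * n_targets`).
#' @examples
#' library_combinatorics(43556)
#' @export
library_combinatorics <- function(n_targets) {
  stopifnot(n_targets > 0)
  list(n_snps = n_targets,
       n_targets = n_targets,
       n_constructs = 2L * as.integer(n_targets),
       n_snp_direction_pairs = 2L * as.integer(n_targets),
       n_oriented_constructs = 4L * as.integer(n_targets))
}

BASES <- c("A", "C", "G", "T")

consensus_seq <- function(pfm) {
  paste(rownames(pfm)[apply(pfm, 2, which.max)], collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a biallelic MPRA target library
#'
#' Draws random target sequences with a centered SNP, assigns ground-truth
#' allelic effects (shared, condition-specific, or none), treatment activity
#' effects, DNA pool proportions, and optionally plants motif consensus
#' sequences preferentially into effect-carrying targets.
#'
#' @param config A [sim_config()].
#' @return List with `sequences` (a [Biostrings::DNAStringSet] of
#'   `4 * n_targets` oriented allelic constructs named
#'   `snpID|allele|direction`; reverse direction is the reverse complement)
#'   and `truth` (tibble of per-SNP ground truth: `true_beta_control`,
#'   `true_beta_caffeine`, flags, `dna_ref_proportion`, `true_da_lfc`,
#'   `true_allele_lfc`, `planted_motif_ids`).
#' @export
simulate_library <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_library_impl(config))
}

simulate_library_impl <- function(config) {
  n <- config$n_targets
  L <- config$target_length
  center <- L %/% 2  # 0-based SNP position
  snp_id <- sprintf("snp%05d", seq_len(n))

  seq_mat <- matrix(sample(BASES, n * L, replace = TRUE), nrow = n)
  ref_base <- seq_mat[, center + 1]
  alt_base <- vapply(ref_base, function(b) sample(setdiff(BASES, b), 1), "")

  n_nc <- round(config$frac_negative_control * n)
  is_nc <- rep(FALSE, n)
  if (n_nc > 0) is_nc[sample.int(n, n_nc)] <- TRUE

  effect_pool <- which(!is_nc)
  n_ase <- round(config$frac_ase * n)
  n_case <- round(config$frac_case * n)
  if (n_ase + n_case > length(effect_pool)) {
    stop("frac_ase + frac_case leave too few non-control targets")
  }
  chosen <- if (n_ase + n_case > 0) sample(effect_pool, n_ase + n_case) else integer(0)
  ase_idx <- chosen[seq_len(n_ase)]
  case_idx <- chosen[setdiff(seq_len(n_ase + n_case), seq_len(n_ase))]

  beta_c <- beta_t <- rep(0, n)
  shared <- rnorm(n_ase, 0, config$effect_sd)
  beta_c[ase_idx] <- shared
  beta_t[ase_idx] <- shared
  beta_c[case_idx] <- rnorm(n_case, 0, config$effect_sd)
  beta_t[case_idx] <- rnorm(n_case, 0, config$effect_sd)

  if (config$direction_specific_effects) {
    beta_c_rev <- beta_t_rev <- rep(0, n)
    shared_rev <- rnorm(n_ase, 0, config$effect_sd)
    beta_c_rev[ase_idx] <- shared_rev
    beta_t_rev[ase_idx] <- shared_rev
    beta_c_rev[case_idx] <- rnorm(n_case, 0, config$effect_sd)
    beta_t_rev[case_idx] <- rnorm(n_case, 0, config$effect_sd)
  } else {
    beta_c_rev <- beta_c
    beta_t_rev <- beta_t
  }

  cc <- config$dna_proportion_concentration
  p0 <- rbeta(n, cc, cc)
  p0 <- pmin(pmax(p0, 0.02), 0.98)  # keep pool proportions assayable

  da_lfc <- rep(0, n)
  n_da <- round(config$da_frac * n)
  da_pool <- which(!is_nc)
  if (n_da > length(da_pool)) n_da <- length(da_pool)
  if (n_da > 0) {
    da_idx <- sample(da_pool, n_da)
    da_lfc[da_idx] <- rnorm(n_da, 0, config$da_lfc_sd)
  }
  allele_lfc <- ifelse(is_nc, 0, rnorm(n, 0, config$allele_lfc_sd))

  has_effect <- beta_c != 0 | beta_t != 0
  planted <- rep("", n)
  for (mid in names(config$motif_set)) {
    cons <- consensus_seq(config$motif_set[[mid]])
    ml <- nchar(cons)
    if (ml >= L - 2) stop("motif '", mid, "' too long for target length")
    mult <- config$motif_ase_multiplier
    if (!is.null(names(mult))) mult <- unname(mult[mid])
    if (is.na(mult)) mult <- 1
    rate <- ifelse(has_effect, pmin(1, config$motif_plant_rate * mult),
                   config$motif_plant_rate)
    plant <- runif(n) < rate
    if (!any(plant)) next
    # offsets avoiding the SNP position so both alleles keep the variant
    valid_off <- setdiff(0:(L - ml), (center - ml + 1):center)
    offs <- sample(valid_off, sum(plant), replace = TRUE)
    cons_chars <- strsplit(cons, "")[[1]]
    idx_plant <- which(plant)
    for (j in seq_along(idx_plant)) {
      seq_mat[idx_plant[j], offs[j] + seq_len(ml)] <- cons_chars
    }
    planted[plant] <- ifelse(nzchar(planted[plant]),
                             paste(planted[plant], mid, sep = ","), mid)
  }
  seq_ref <- apply(seq_mat, 1, paste, collapse = "")
  seq_alt_mat <- seq_mat
  seq_alt_mat[, center + 1] <- alt_base
  seq_alt <- apply(seq_alt_mat, 1, paste, collapse = "")

  seqs <- c(seq_ref, seq_alt, revcomp_chr(seq_ref), revcomp_chr(seq_alt))
  names(seqs) <- c(paste0(snp_id, "|ref|fwd"), paste0(snp_id, "|alt|fwd"),
                   paste0(snp_id, "|ref|rev"), paste0(snp_id, "|alt|rev"))
  ord <- order(rep(seq_len(n), 4))
  sequences <- Biostrings::DNAStringSet(seqs[ord])

  truth <- tibble::tibble(
    snp_id = snp_id,
    ref_allele = ref_base,
    alt_allele = alt_base,
    snp_pos = center,
    is_negative_control = is_nc,
    is_ase = seq_len(n) %in% ase_idx,
    is_case = seq_len(n) %in% case_idx,
    true_beta_control = beta_c,
    true_beta_caffeine = beta_t,
    true_beta_control_rev = beta_c_rev,
    true_beta_caffeine_rev = beta_t_rev,
    dna_ref_proportion = p0,
    true_da_lfc = da_lfc,
    true_allele_lfc = allele_lfc,
    planted_motif_ids = planted
  )
  list(sequences = sequences, truth = truth, config = config)
}

#' Simulate the allele-level count table
#'
#' For every SNP/direction/condition/replicate the total depth is drawn
#' negative-binomial around `mean_depth`; the RNA reference count is then
#' beta-binomial with mean `plogis(qlogis(p0) + true_beta_condition)` and
#' overdispersion `rho`. The DNA pool is sequenced once per SNP/direction at
#' `dna_depth_factor * mean_depth` with overdispersion `rho_dna`.
#'
#' @param truth Truth tibble from [simulate_library()].
#' @param config The same [sim_config()].
#' @return Long-form allele count tibble (columns `snp_id`, `direction`,
#'   `allele`, `sample_id`, `condition`, `replicate`, `count`).
#' @export
simulate_allele_counts <- function(truth, config) {
  validate_sim_config(config)
  withr::with_seed(config$seed + 1L, simulate_allele_counts_impl(truth, config))
}

simulate_allele_counts_impl <- function(truth, config) {
  n <- nrow(truth)
  reps <- config$n_replicates
  conditions <- c("control", "caffeine")

  grid <- expand.grid(snp = seq_len(n), direction = c("fwd", "rev"),
                      condition = conditions, replicate = seq_len(reps),
                      stringsAsFactors = FALSE)
  size <- if (config$depth_dispersion > 0) 1 / config$depth_dispersion else Inf
  N <- if (is.finite(size)) {
    rnbinom(nrow(grid), mu = config$mean_depth, size = size)
  } else {
    stats::rpois(nrow(grid), config$mean_depth)
  }
  p0 <- truth$dna_ref_proportion[grid$snp]
  beta <- ifelse(grid$direction == "fwd",
                 ifelse(grid$condition == "control",
                        truth$true_beta_control[grid$snp],
                        truth$true_beta_caffeine[grid$snp]),
                 ifelse(grid$condition == "control",
                        truth$true_beta_control_rev[grid$snp],
                        truth$true_beta_caffeine_rev[grid$snp]))
  mu <- plogis(qlogis(p0) + beta)
  ref <- rbetabinom(nrow(grid), N, mu, config$rho)
  rna <- tibble::tibble(
    snp_id = rep(truth$snp_id[grid$snp], 2),
    direction = rep(grid$direction, 2),
    allele = rep(c("ref", "alt"), each = nrow(grid)),
    sample_id = rep(paste(grid$condition, grid$replicate, sep = "_"), 2),
    condition = rep(grid$condition, 2),
    replicate = rep(grid$replicate, 2),
    count = c(ref, N - ref)
  )

  dgrid <- expand.grid(snp = seq_len(n), direction = c("fwd", "rev"),
                       stringsAsFactors = FALSE)
  dna_mean <- config$mean_depth * config$dna_depth_factor
  Nd <- if (is.finite(size)) {
    rnbinom(nrow(dgrid), mu = dna_mean, size = size)
  } else {
    stats::rpois(nrow(dgrid), dna_mean)
  }
  refd <- rbetabinom(nrow(dgrid), Nd, truth$dna_ref_proportion[dgrid$snp],
                     config$rho_dna)
  dna <- tibble::tibble(
    snp_id = rep(truth$snp_id[dgrid$snp], 2),
    direction = rep(dgrid$direction, 2),
    allele = rep(c("ref", "alt"), each = nrow(dgrid)),
    sample_id = "dna_1",
    condition = "dna",
    replicate = 1L,
    count = c(refd, Nd - refd)
  )
  tab <- dplyr::bind_rows(dna, rna)
  tab <- dplyr::arrange(tab, snp_id, direction, condition, replicate, allele)
  tab$count <- as.integer(tab$count)
  tab
}

#' Simulate the construct-by-sample activity count matrix
#'
#' Counts for each oriented construct (target x allele x direction) in each
#' RNA sample are negative-binomial with mean
#' `baseline * size_factor * 2^(allele_lfc * I[alt] + da_lfc * I[caffeine])`.
#'
#' @param truth Truth tibble from [simulate_library()].
#' @param config The same [sim_config()].
#' @return List with `counts` (integer matrix, rows named
#'   `target|allele|direction`, columns sample IDs) and `samples` (tibble
#'   with `sample_id`, `condition`, `replicate`, `size_factor`).
#' @export
simulate_activity_counts <- function(truth, config) {
  validate_sim_config(config)
  withr::with_seed(config$seed + 2L, simulate_activity_counts_impl(truth, config))
}

simulate_activity_counts_impl <- function(truth, config) {
  n <- nrow(truth)
  reps <- config$n_replicates
  samples <- tibble::tibble(
    sample_id = c(paste0("control_", seq_len(reps)),
                  paste0("caffeine_", seq_len(reps))),
    condition = rep(c("control", "caffeine"), each = reps),
    replicate = rep(seq_len(reps), 2),
    size_factor = rlnorm(2 * reps, 0, config$size_factor_sdlog)
  )
  baseline <- rlnorm(n, log(config$da_baseline_mean) -
                       config$da_baseline_sdlog^2 / 2, config$da_baseline_sdlog)
  rows <- expand.grid(snp = seq_len(n), allele = c("ref", "alt"),
                      direction = c("fwd", "rev"), stringsAsFactors = FALSE)
  row_names <- paste(truth$snp_id[rows$snp], rows$allele, rows$direction, sep = "|")
  lfc_allele <- truth$true_allele_lfc[rows$snp] * (rows$allele == "alt")
  da_lfc <- truth$true_da_lfc[rows$snp]
  base <- baseline[rows$snp]
  nr <- nrow(rows)
  ns <- nrow(samples)
  mu <- outer(base * 2^lfc_allele, samples$size_factor) *
    2^(da_lfc %o% as.numeric(samples$condition == "caffeine"))
  size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
  counts <- if (is.finite(size)) {
    matrix(rnbinom(nr * ns, mu = mu, size = size), nr, ns)
  } else {
    matrix(stats::rpois(nr * ns, mu), nr, ns)
  }
  dimnames(counts) <- list(row_names, samples$sample_id)
  list(counts = counts, samples = samples)
}
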