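# Allele-specific expression: per-replicate beta-binomial effects,
# inverse-variance meta-analysis per condition, z-score against the DNA
# pool proportion, and BH-FDR calls.

# reshape the long allele count table to one row per
# (snp, direction, condition, replicate) with ref/alt columns
counts_to_wide <- function(table) {
  validate_allele_counts(table)
  ref <- table[table$allele == "ref", ]
  alt <- table[table$allele == "alt", ]
  key <- c("snp_id", "direction", "sample_id", "condition", "replicate")
  wide <- dplyr::inner_join(
    dplyr::select(ref, dplyr::all_of(key), ref = count),
    dplyr::select(alt, dplyr::all_of(key), alt = count),
    by = key
  )
  tibble::as_tibble(wide)
}

# DNA reference proportion per (snp, direction), summing DNA replicates
dna_proportions <- function(table, pseudocount = 0.5) {
  dna <- table[table$condition == "dna", ]
  agg <- dna %>%
    dplyr::group_by(snp_id, direction, allele) %>%
    dplyr::summarise(total = sum(count), .groups = "drop")
  ref <- agg[agg$allele == "ref", ]
  alt <- agg[agg$allele == "alt", ]
  out <- dplyr::inner_join(
    dplyr::select(ref, snp_id, direction, dna_ref = total),
    dplyr::select(alt, snp_id, direction, dna_alt = total),
    by = c("snp_id", "direction")
  )
  out$p0 <- estimate_dna_proportion(out$dna_ref, out$dna_alt, pseudocount)
  tibble::as_tibble(out)
}

#' Benjamini--Hochberg adjusted p-values
#'
#' Validating wrapper around [stats::p.adjust()] with `method = "BH"`
#' (step-up with monotonicity enforcement).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   passed through).
#' @return q-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Inverse-variance meta-analysis of per-replicate allelic effects
#'
#' Combines replicate log-odds estimates with weights `1/se^2`; the z-score
#' contrasts the meta-analyzed effect with the DNA pool proportion on the
#' log-odds scale: `z = (beta_meta - logit(p0)) / se_meta`. Records with
#' fewer than `min_replicates` usable replicate fits carry no p-value.
#'
#' @param fits Data frame with columns `beta` and `se` (one row per
#'   replicate; rows with `NA` beta are unusable).
#' @param p0 DNA reference proportion in (0, 1).
#' @param min_replicates Minimum usable replicates for a record to be tested.
#' @return One-row tibble: `beta_meta`, `se_meta`, `dna_logit`, `z`, `p`,
#'   `n_replicates_used`, `tested`.
#' @examples
#' meta_analyze(data.frame(beta = c(0, 2), se = c(1, 1)), p0 = 0.5,
#'              min_replicates = 1)
#' @export
meta_analyze <- function(fits, p0, min_replicates = 4) {
  stopifnot(p0 > 0, p0 < 1)
  if (nrow(fits) == 0) stop("empty fit list")
  use <- !is.na(fits$beta) & !is.na(fits$se) & fits$se > 0
  n_used <- sum(use)
  if (n_used == 0) {
    return(tibble::tibble(beta_meta = NA_real_, se_meta = NA_real_,
                          dna_logit = qlogis(p0), z = NA_real_, p = NA_real_,
                          n_replicates_used = 0L, tested = FALSE))
  }
  w <- 1 / fits$se[use]^2
  beta_meta <- sum(w * fits$beta[use]) / sum(w)
  se_meta <- 1 / sqrt(sum(w))
  z <- (beta_meta - qlogis(p0)) / se_meta
  tested <- n_used >= min_replicates
  tibble::tibble(beta_meta = beta_meta, se_meta = se_meta,
                 dna_logit = qlogis(p0), z = z,
                 p = if (tested) 2 * stats::pnorm(-abs(z)) else NA_real_,
                 n_replicates_used = as.integer(n_used), tested = tested)
}

#' Flag significant ASE at an FDR threshold and summarize
#'
#' @param results ASE meta-analysis results (from [run_ase()]), with `q`.
#' @param fdr FDR threshold (default 0.10).
#' @return `results` with a `significant` column plus a summary attribute;
#'   see [ase_summary()].
#' @export
call_ase <- function(results, fdr = 0.10) {
  results$significant <- !is.na(results$q) & results$q < fdr
  results
}

#' Summarize ASE calls
#'
#' Counts significant SNP/direction pairs and distinct significant SNPs per
#' condition, and the percentage of tested SNPs with significant ASE.
#'
#' @param results ASE results with `significant` (from [call_ase()]).
#' @return Tibble with one row per condition: `n_pairs_tested`,
#'   `n_snps_tested`, `n_pairs_significant`, `n_snps_significant`,
#'   `pct_snps_significant` (on a 0--100 scale, as printed).
#' @export
ase_summary <- function(results) {
  results %>%
    dplyr::filter(tested) %>%
    dplyr::group_by(condition) %>%
    dplyr::summarise(
      n_pairs_tested = dplyr::n(),
      n_snps_tested = dplyr::n_distinct(snp_id),
      n_pairs_significant = sum(significant),
      n_snps_significant = dplyr::n_distinct(snp_id[significant]),
      pct_snps_significant = percent_of(n_snps_significant, n_snps_tested),
      .groups = "drop"
    )
}

#' Percentage of a count over a total, as printed
#'
#' @param count,total Non-negative numbers, `total > 0`.
#' @param digits Decimal places to round to (default 1, reporting style).
#' @return `round(100 * count / total, digits)`.
#' @examples
#' percent_of(665, 30680) # 2.2
#' @export
percent_of <- function(count, total, digits = 1) {
  stopifnot(all(total > 0), all(count >= 0))
  round(100 * count / total, digits)
}

#' Run the full ASE analysis on an allele count table
#'
#' Per condition: estimates (or accepts) the beta-binomial overdispersion,
#' fits every SNP/direction/replicate allelic effect, meta-analyzes
#' replicates with inverse-variance weights, forms z-scores against the DNA
#' pool log-odds, applies BH within condition across all tested
#' SNP/direction pairs (both directions one family), and flags calls at the
#' FDR threshold. Per-replicate weights use score-type standard errors (the
#' beta-binomial information evaluated at the DNA proportion), which keeps
#' the weights independent of the estimates and the null z-scores standard
#' normal; see the methods vignette.
#'
#' @param table Allele count table (see [read_allele_counts()]).
#' @param rho Fixed overdispersion, or `NULL` to estimate per condition via
#'   [estimate_dispersion()].
#' @param min_replicates Minimum usable replicates per record (default 4).
#' @param fdr FDR threshold for significance (default 0.10).
#' @param pseudocount Haldane--Anscombe pseudocount for fits and DNA
#'   proportions.
#' @param min_dna_reads Minimum total DNA reads (ref + alt) for a
#'   SNP/direction pair to be testable (default 100): the DNA proportion is
#'   the null anchor of the z-score and its sampling noise is not propagated,
#'   so pairs with thin DNA coverage carry an unreliable anchor and are
#'   reported untested.
#' @return Tibble with one row per (snp_id, direction, condition):
#'   `beta_meta`, `se_meta`, `dna_logit`, `z`, `p`, `q`,
#'   `n_replicates_used`, `tested`, `significant`, `rho`.
#' @export
run_ase <- function(table, rho = NULL, min_replicates = 4, fdr = 0.10,
                    pseudocount = 0.5, min_dna_reads = 100) {
  wide <- counts_to_wide(table)
  dna <- dna_proportions(table, pseudocount = pseudocount)
  dna$dna_ok <- dna$dna_ref + dna$dna_alt >= min_dna_reads
  out <- list()
  for (cond in c("control", "caffeine")) {
    rna <- wide[wide$condition == cond, ]
    if (nrow(rna) == 0) next
    rho_c <- if (is.null(rho)) {
      estimate_dispersion(table, cond, pseudocount = pseudocount)
    } else {
      rho
    }
    fits <- fit_replicate(rna$ref, rna$alt, rho_c, pseudocount = pseudocount)
    rna$beta <- fits$beta
    # Null-anchored inference: each replicate's standard error and mean bias
    # are the EXACT null moments of the pseudocounted log-odds MLE at the
    # pair's DNA proportion (enumerated on a grid, interpolated). Anchoring
    # at p0 keeps the inverse-variance weights independent of the estimates
    # (curvature-at-MLE standard errors shrink as the estimate drifts toward
    # 0.5, biasing the weighted mean and deflating the cross-condition
    # (delta z)^2 statistic), and the exact-moment correction keeps the null
    # z-scores standard normal at every depth and DNA proportion.
    rna <- dplyr::left_join(rna, dna[, c("snp_id", "direction", "p0")],
                            by = c("snp_id", "direction"))
    n_tot <- rna$ref + rna$alt
    usable <- n_tot > 0
    calib <- bb_null_calibration(rho_c, n_max = max(n_tot),
                                 pseudocount = pseudocount)
    mom <- bb_null_moments(calib, n_tot[usable], rna$p0[usable])
    rna$beta[usable] <- rna$beta[usable] - mom$bias
    rna$se <- NA_real_
    rna$se[usable] <- mom$se
    rna$p0 <- NULL
    meta <- rna %>%
      dplyr::group_by(snp_id, direction) %>%
      dplyr::summarise(
        n_replicates_used = sum(!is.na(beta) & se > 0),
        beta_meta = {
          u <- !is.na(beta) & se > 0
          if (any(u)) sum(beta[u] / se[u]^2) / sum(1 / se[u]^2) else NA_real_
        },
        se_meta = {
          u <- !is.na(beta) & se > 0
          if (any(u)) 1 / sqrt(sum(1 / se[u]^2)) else NA_real_
        },
        .groups = "drop"
      )
    meta <- dplyr::left_join(meta, dna, by = c("snp_id", "direction"))
    meta$condition <- cond
    meta$dna_logit <- qlogis(meta$p0)
    meta$z <- (meta$beta_meta - meta$dna_logit) / meta$se_meta
    meta$tested <- meta$n_replicates_used >= min_replicates & meta$dna_ok
    meta$p <- ifelse(meta$tested, 2 * stats::pnorm(-abs(meta$z)), NA_real_)
    meta$q <- NA_real_
    meta$q[meta$tested] <- bh_adjust(meta$p[meta$tested])
    meta$rho <- rho_c
    out[[cond]] <- meta
  }
  res <- dplyr::bind_rows(out)
  res <- dplyr::select(res, snp_id, direction, condition, beta_meta, se_meta,
                       dna_logit, z, p, q, n_replicates_used, tested, rho)
  call_ase(res, fdr = fdr)
}
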