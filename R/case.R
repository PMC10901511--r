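# Conditional allele-specific expression (GxE): the squared z-score
# difference statistic, genomic-control calibration against chi-squared(1),
# and FDR / nominal follow-up calls.

#' Squared z-score difference statistic for conditional ASE
#'
#' `(z_t - z_c)^2 / 2`: under the null of equal allelic effects in the two
#' conditions (independent standard-normal z-scores) the statistic is
#' chi-squared with 1 degree of freedom.
#'
#' @param z_t,z_c Finite z-scores for the treatment and control condition.
#' @return The statistic, symmetric in its arguments.
#' @examples
#' delta_z_squared(2, -1) # 4.5
#' @export
delta_z_squared <- function(z_t, z_c) {
  if (any(!is.finite(z_t)) || any(!is.finite(z_c))) {
    stop("z-scores must be finite")
  }
  (z_t - z_c)^2 / 2
}

#' Genomic-control inflation factor
#'
#' Ratio of the median observed statistic to the median of the
#' chi-squared(1) distribution (~0.4549, computed from the inverse CDF).
#' Values above 1 indicate inflation; deflation (lambda < 1) is allowed and
#' not floored.
#'
#' @param stats Non-negative finite statistics (at least one).
#' @return The inflation factor `lambda_gc`.
#' @export
genomic_control_lambda <- function(stats) {
  stats <- stats[!is.na(stats)]
  if (length(stats) == 0) stop("no statistics supplied")
  if (any(!is.finite(stats)) || any(stats < 0)) {
    stop("statistics must be finite and non-negative")
  }
  median(stats) / qchisq(0.5, df = 1)
}

#' Calibrated chi-squared p-values for conditional ASE statistics
#'
#' Upper-tail chi-squared(1) probability of each statistic divided by the
#' genomic-control factor.
#'
#' @param stats Non-negative statistics.
#' @param lambda_gc Positive genomic-control factor.
#' @return p-values.
#' @export
case_pvalues <- function(stats, lambda_gc) {
  if (!is.finite(lambda_gc) || lambda_gc <= 0) {
    stop("lambda_gc must be positive")
  }
  pchisq(stats / lambda_gc, df = 1, lower.tail = FALSE)
}

#' Flag conditional ASE at FDR and nominal thresholds
#'
#' @param results Conditional ASE results with `p` and `q` columns.
#' @param fdr FDR threshold (default 0.05).
#' @param nominal_p Nominal p threshold for the relaxed follow-up set
#'   (default 0.0215).
#' @return `results` with `significant_fdr05` and `nominal_followup` flags.
#' @export
call_case <- function(results, fdr = 0.05, nominal_p = 0.0215) {
  results$significant_fdr05 <- !is.na(results$q) & results$q < fdr
  results$nominal_followup <- !is.na(results$p) & results$p < nominal_p
  results
}

#' Summarize conditional ASE calls
#'
#' @param results Results from [run_case()].
#' @return One-row tibble with tested/flagged pair and distinct-SNP counts
#'   at both thresholds, and `lambda_gc`.
#' @export
case_summary <- function(results) {
  tibble::tibble(
    n_pairs_tested = nrow(results),
    n_snps_tested = dplyr::n_distinct(results$snp_id),
    lambda_gc = if (nrow(results)) results$lambda_gc[1] else NA_real_,
    n_pairs_fdr05 = sum(results$significant_fdr05),
    n_snps_fdr05 = dplyr::n_distinct(results$snp_id[results$significant_fdr05]),
    n_pairs_nominal = sum(results$nominal_followup),
    n_snps_nominal = dplyr::n_distinct(results$snp_id[results$nominal_followup])
  )
}

#' Run the conditional ASE (GxE) analysis
#'
#' Joins per-condition ASE meta-analysis results; SNP/direction pairs tested
#' in both conditions are eligible. Computes `(Z_T - Z_C)^2 / 2`, calibrates
#' by genomic control (one lambda per run), derives chi-squared(1) p-values,
#' applies BH across all eligible pairs, and flags calls at the FDR and
#' nominal thresholds.
#'
#' @param ase_results Output of [run_ase()] covering both conditions.
#' @param fdr FDR threshold (default 0.05).
#' @param nominal_p Nominal follow-up threshold (default 0.0215).
#' @return Tibble with one row per eligible (snp_id, direction):
#'   `z_control`, `z_caffeine`, `delta_z_sq`, `lambda_gc`, `p`, `q`,
#'   `significant_fdr05`, `nominal_followup`.
#' @export
run_case <- function(ase_results, fdr = 0.05, nominal_p = 0.0215) {
  tested <- ase_results[ase_results$tested, ]
  ctl <- tested[tested$condition == "control", c("snp_id", "direction", "z")]
  trt <- tested[tested$condition == "caffeine", c("snp_id", "direction", "z")]
  names(ctl)[3] <- "z_control"
  names(trt)[3] <- "z_caffeine"
  eligible <- dplyr::inner_join(ctl, trt, by = c("snp_id", "direction"))
  n_dropped <- nrow(ctl) + nrow(trt) - 2 * nrow(eligible)
  if (n_dropped > 0) {
    message(n_dropped, " SNP/direction records tested in only one condition ",
            "were excluded from conditional ASE")
  }
  if (nrow(eligible) == 0) {
    return(tibble::tibble(snp_id = character(), direction = character(),
                          z_control = numeric(), z_caffeine = numeric(),
                          delta_z_sq = numeric(), lambda_gc = numeric(),
                          p = numeric(), q = numeric(),
                          significant_fdr05 = logical(),
                          nominal_followup = logical()))
  }
  eligible$delta_z_sq <- delta_z_squared(eligible$z_caffeine, eligible$z_control)
  lambda <- genomic_control_lambda(eligible$delta_z_sq)
  eligible$lambda_gc <- lambda
  eligible$p <- case_pvalues(eligible$delta_z_sq, lambda)
  eligible$q <- bh_adjust(eligible$p)
  call_case(eligible, fdr = fdr, nominal_p = nominal_p)
}
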