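# Enrichment tests: per-motif test of proportions against the any-motif
# baseline, interval-overlap annotation, and Fisher's exact enrichment.

#' Test of proportions for one motif against the any-motif baseline
#'
#' The null proportion is the fraction of motif-containing items that are
#' significant across all motifs (`n_a / n_b`); the observed proportion is
#' the same fraction within one motif (`n_c / n_d`). A one-sample
#' chi-squared test of proportion with Yates continuity correction is
#' applied, with a Wilson (continuity-corrected) 95% CI on the observed
#' proportion.
#'
#' @param n_a Significant items within any motif.
#' @param n_b All items within any motif.
#' @param n_c Significant items within this motif.
#' @param n_d All items within this motif (> 0).
#' @param correct Apply continuity correction (default `TRUE`).
#' @return One-row tibble: `n_a`, `n_b`, `n_c`, `n_d`, `null_prop`,
#'   `obs_prop`, `ci_low`, `ci_high`, `p`.
#' @export
proportion_test <- function(n_a, n_b, n_c, n_d, correct = TRUE) {
  if (n_d <= 0 || n_b <= 0) stop("n_d and n_b must be positive")
  if (n_c > n_d || n_a > n_b || n_c > n_a || n_d > n_b) {
    stop("counts must satisfy n_c <= n_d <= n_b and n_c <= n_a <= n_b")
  }
  null_prop <- n_a / n_b
  obs_prop <- n_c / n_d
  if (null_prop <= 0 || null_prop >= 1) {
    # degenerate baseline: the test statistic is undefined
    return(tibble::tibble(n_a = n_a, n_b = n_b, n_c = n_c, n_d = n_d,
                          null_prop = null_prop, obs_prop = obs_prop,
                          ci_low = NA_real_, ci_high = NA_real_,
                          p = if (obs_prop == null_prop) 1 else NA_real_))
  }
  pt <- suppressWarnings(prop.test(n_c, n_d, p = null_prop, correct = correct))
  tibble::tibble(n_a = n_a, n_b = n_b, n_c = n_c, n_d = n_d,
                 null_prop = null_prop, obs_prop = obs_prop,
                 ci_low = pt$conf.int[1], ci_high = pt$conf.int[2],
                 p = pt$p.value)
}

#' Per-motif enrichment of significant items
#'
#' Computes the any-motif baseline and runs [proportion_test()] per motif
#' over the motifs retained by the occurrence filter.
#'
#' @param hits Hit table from [scan_sequences()] for all motifs.
#' @param significant_ids Sequence/target IDs called significant.
#' @param min_occurrence Occurrence filter threshold (default 100).
#' @param strict Strict (>) occurrence filter, see
#'   [filter_motifs_by_occurrence()].
#' @return Tibble with one row per retained motif, sorted by p.
#' @export
motif_enrichment <- function(hits, significant_ids, min_occurrence = 100,
                             strict = FALSE) {
  keep <- filter_motifs_by_occurrence(hits, min_occurrence, strict)
  hits <- hits[hits$motif_id %in% keep, ]
  if (nrow(hits) == 0) {
    return(tibble::tibble(motif_id = character(), n_a = integer(),
                          n_b = integer(), n_c = integer(), n_d = integer(),
                          null_prop = numeric(), obs_prop = numeric(),
                          ci_low = numeric(), ci_high = numeric(),
                          p = numeric()))
  }
  per_target <- dplyr::distinct(hits, motif_id, sequence_id)
  any_motif <- unique(per_target$sequence_id)
  n_b <- length(any_motif)
  n_a <- sum(any_motif %in% significant_ids)
  out <- per_target %>%
    dplyr::group_by(motif_id) %>%
    dplyr::summarise(n_c = sum(sequence_id %in% significant_ids),
                     n_d = dplyr::n(), .groups = "drop")
  res <- dplyr::bind_rows(lapply(seq_len(nrow(out)), function(i) {
    proportion_test(n_a, n_b, out$n_c[i], out$n_d[i])
  }))
  res <- dplyr::bind_cols(tibble::tibble(motif_id = out$motif_id), res)
  dplyr::arrange(res, p)
}

#' Flag variants falling inside genomic intervals
#'
#' Membership uses the BED convention: a variant at 0-based position `pos`
#' is inside `[start, end)` when `start <= pos < end`, chromosome names
#' matched literally.
#'
#' @param variants Data frame with `chrom` and `pos` (0-based) columns.
#' @param intervals Data frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [read_bed()].
#' @return Logical vector, one flag per variant.
#' @export
intersect_variants <- function(variants, intervals) {
  stopifnot(all(c("chrom", "pos") %in% names(variants)),
            all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(variants) == 0) return(logical())
  if (nrow(intervals) == 0) return(rep(FALSE, nrow(variants)))
  # convert to 1-based closed coordinates for IRanges
  v <- GenomicRanges::GRanges(variants$chrom,
                              IRanges::IRanges(variants$pos + 1,
                                               variants$pos + 1))
  iv <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start + 1,
                                                intervals$end))
  # disjoint chromosome sets are legitimate (literal matching): silence the
  # seqlevel mismatch notice and report zero overlap ourselves below
  flags <- suppressWarnings(IRanges::overlapsAny(v, iv))
  if (!any(flags)) {
    warning("no variant overlaps any interval (chromosome names are matched ",
            "literally)")
  }
  flags
}

#' Fisher's exact enrichment of an annotation among significant items
#'
#' Cross-tabulates significance by annotation and reports the two-sided
#' Fisher exact p-value, the conditional-MLE odds ratio, and the fold
#' enrichment (proportion annotated among significant over proportion
#' annotated among non-significant).
#'
#' @param flag_significant,flag_annotation Equal-length logical vectors.
#' @return One-row tibble: `odds_ratio`, `fold_enrichment`, `p`, plus the
#'   2 x 2 counts (`n_sig_ann`, `n_sig_not`, `n_notsig_ann`, `n_notsig_not`).
#' @export
fisher_enrichment <- function(flag_significant, flag_annotation) {
  stopifnot(length(flag_significant) == length(flag_annotation))
  a <- sum(flag_significant & flag_annotation)
  b <- sum(flag_significant & !flag_annotation)
  c_ <- sum(!flag_significant & flag_annotation)
  d <- sum(!flag_significant & !flag_annotation)
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(tibble::tibble(odds_ratio = NA_real_, fold_enrichment = NA_real_,
                          p = 1, n_sig_ann = a, n_sig_not = b,
                          n_notsig_ann = c_, n_notsig_not = d))
  }
  ft <- fisher.test(tab)
  fold <- (a / (a + b)) / (c_ / (c_ + d))
  tibble::tibble(odds_ratio = unname(ft$estimate), fold_enrichment = fold,
                 p = ft$p.value, n_sig_ann = a, n_sig_not = b,
                 n_notsig_ann = c_, n_notsig_not = d)
}
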