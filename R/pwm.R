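# Position weight matrices and motif scanning. Scores are additive log-odds
# in bits (base 2) against a background base composition; a window is a hit
# when its score reaches the threshold (default 10 bits).

#' Convert a position frequency matrix to a log-odds PWM (bits)
#'
#' `entry(b, j) = log2(((count(b, j) + pseudocount) / (colsum_j +
#' 4 * pseudocount)) / background_b)`.
#'
#' @param pfm 4 x L non-negative matrix with rownames A, C, G, T.
#' @param pseudocount Per-cell pseudocount (default 0.25).
#' @param background Base composition, positive and summing to 1 (default
#'   uniform).
#' @param motif_id Identifier carried into hit tables (default `"motif"`).
#' @return List of class `pwm_model`: `motif_id` (taken from the PFM when
#'   available), `mat` (4 x L log-odds in bits), `max_score`.
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 0.25,
                       background = rep(0.25, 4), motif_id = NULL) {
  stopifnot(is.matrix(pfm), nrow(pfm) == 4, all(pfm >= 0))
  if (is.null(rownames(pfm))) rownames(pfm) <- c("A", "C", "G", "T")
  pfm <- pfm[c("A", "C", "G", "T"), , drop = FALSE]
  if (abs(sum(background) - 1) > 1e-8 || any(background <= 0)) {
    stop("background must be positive and sum to 1")
  }
  colsum <- colSums(pfm)
  if (any(colsum + 4 * pseudocount <= 0)) {
    stop("zero column sum with zero pseudocount")
  }
  prob <- sweep(pfm + pseudocount, 2, colsum + 4 * pseudocount, "/")
  mat <- log2(prob / background)
  rownames(mat) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id %||% "motif", mat = mat,
                 max_score = sum(apply(mat, 2, max))),
            class = "pwm_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# reverse-complement a PWM: reverse columns, swap complementary base rows
pwm_revcomp <- function(mat) {
  mat[c("T", "G", "C", "A"), rev(seq_len(ncol(mat))), drop = FALSE]
}

# integer-encode sequences (A=1, C=2, G=3, T=4, anything else NA)
encode_seq <- function(x) {
  code <- setNames(rep(NA_integer_, 255), rawToChar(as.raw(1:255), multiple = TRUE))
  code[c("A", "C", "G", "T", "a", "c", "g", "t")] <- c(1:4, 1:4)
  lapply(strsplit(x, ""), function(ch) unname(code[ch]))
}

scan_one_strand <- function(mat, enc_list, lens, threshold, strand, ids) {
  L <- ncol(mat)
  hits <- list()
  for (len in unique(lens)) {
    if (len < L) next
    sel <- which(lens == len)
    codes <- do.call(rbind, enc_list[sel])  # n x len integer matrix
    n_off <- len - L + 1
    for (off in seq_len(n_off)) {
      score <- rep(0, length(sel))
      for (j in seq_len(L)) {
        score <- score + mat[cbind(codes[, off + j - 1], j)]
      }
      hit <- which(!is.na(score) & score >= threshold)
      if (length(hit) > 0) {
        hits[[length(hits) + 1]] <- tibble::tibble(
          sequence_id = ids[sel][hit], offset = off - 1L,
          strand = strand, score = score[hit])
      }
    }
  }
  if (length(hits) == 0) {
    tibble::tibble(sequence_id = character(), offset = integer(),
                   strand = character(), score = numeric())
  } else {
    dplyr::bind_rows(hits)
  }
}

#' Scan sequences for PWM matches above a bit-score threshold
#'
#' Every window whose additive PWM score reaches `threshold_bits` is
#' reported; windows containing non-ACGT characters are skipped. Minus-strand
#' hits are found by scanning with the reverse-complemented PWM, so offsets
#' are always on the given (forward) sequence, 0-based.
#'
#' @param pwm A `pwm_model` from [pfm_to_pwm()].
#' @param sequences Named character vector or [Biostrings::DNAStringSet].
#' @param threshold_bits Minimum score in bits (default 10).
#' @param both_strands Also scan the reverse complement (default `TRUE`).
#' @return Tibble of hits: `sequence_id`, `motif_id`, `offset` (0-based on
#'   the forward sequence), `strand` (`"+"`/`"-"`), `score`.
#' @export
scan_sequences <- function(pwm, sequences, threshold_bits = 10,
                           both_strands = TRUE) {
  stopifnot(inherits(pwm, "pwm_model"))
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  ids <- names(sequences) %||% as.character(seq_along(sequences))
  enc <- encode_seq(sequences)
  lens <- nchar(sequences)
  out <- scan_one_strand(pwm$mat, enc, lens, threshold_bits, "+", ids)
  if (both_strands) {
    out <- dplyr::bind_rows(
      out, scan_one_strand(pwm_revcomp(pwm$mat), enc, lens, threshold_bits,
                           "-", ids))
  }
  out$motif_id <- rep(pwm$motif_id, nrow(out))
  out[, c("sequence_id", "motif_id", "offset", "strand", "score")]
}

#' Filter motifs by library occurrence
#'
#' Motif occurrence is counted at the target level: a motif counts once per
#' sequence it hits, and motifs hitting fewer targets than the threshold are
#' dropped before enrichment testing.
#'
#' @param hits Hit table from [scan_sequences()] (possibly several motifs).
#' @param min_occurrence Occurrence threshold (default 100; motifs with
#'   occurrence `>= min_occurrence` are retained).
#' @param strict If `TRUE`, require occurrence strictly greater than the
#'   threshold.
#' @return Character vector of retained motif IDs.
#' @export
filter_motifs_by_occurrence <- function(hits, min_occurrence = 100,
                                        strict = FALSE) {
  if (nrow(hits) == 0) return(character())
  occ <- hits %>%
    dplyr::distinct(motif_id, sequence_id) %>%
    dplyr::count(motif_id)
  keep <- if (strict) occ$n > min_occurrence else occ$n >= min_occurrence
  occ$motif_id[keep]
}
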