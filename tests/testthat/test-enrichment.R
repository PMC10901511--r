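# PWM construction and scanning against a brute-force oracle; proportion,
# interval, and Fisher enrichment against enumeration oracles.

test_that("PFM to log-odds conversion matches hand-computed entries", {
  uniform <- matrix(25, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- pfm_to_pwm(uniform, pseudocount = 0.25)
  expect_true(all(abs(pwm$mat) < 0.02))  # only pseudocount dilution

  one <- matrix(c(100, 0, 0, 0), 4, 1,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm1 <- pfm_to_pwm(one, pseudocount = 0.25)
  expect_equal(unname(pwm1$mat["A", 1]), log2((100.25 / 101) / 0.25),
               tolerance = 1e-9)
  expect_equal(unname(pwm1$mat["A", 1]), 1.9893, tolerance = 1e-4)

  # scaling an all-positive PFM by 10 only moves entries through
  # pseudocount dilution (zero-count cells stay pseudocount-dominated)
  pfm <- small_pfm() * 4 + 8
  d <- abs(pfm_to_pwm(10 * pfm)$mat - pfm_to_pwm(pfm)$mat)
  expect_lt(max(d), 0.05)

  expect_error(pfm_to_pwm(matrix(0, 4, 2), pseudocount = 0), "zero column")
  expect_error(pfm_to_pwm(small_pfm(), background = c(0.5, 0.5, 0.2, -0.2)),
               "background")
})

test_that("consensus scores the sum of column maxima; high threshold kills hits", {
  pwm <- pfm_to_pwm(small_pfm(), motif_id = "M1")
  cons <- paste(c("A", "C", "G", "A", "G")[1:5], collapse = "")
  # consensus of small_pfm: A C G (A|C tie -> A from which.max) G
  hits <- scan_sequences(pwm, c(s1 = paste0("TT", cons, "TT")),
                         threshold_bits = pwm$max_score - 1e-9,
                         both_strands = FALSE)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 2L)
  expect_equal(hits$score, pwm$max_score, tolerance = 1e-9)
  none <- scan_sequences(pwm, c(s1 = paste0("TT", cons, "TT")),
                         threshold_bits = pwm$max_score + 0.5)
  expect_equal(nrow(none), 0)
})

test_that("scanner equals the all-windows brute-force oracle exactly", {
  set.seed(99)
  seqs <- setNames(
    vapply(1:300, function(i) {
      paste(sample(c("A", "C", "G", "T", "N"), 60, replace = TRUE,
                   prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    }, ""),
    paste0("seq", 1:300))
  pwm <- pfm_to_pwm(small_pfm(), motif_id = "M1")
  for (thr in c(2, 4, 6)) {
    got <- scan_sequences(pwm, seqs, threshold_bits = thr)
    want <- oracle_scan(pwm$mat, as.list(seqs), thr)
    expect_identical(hit_key(got), hit_key(want))
  }
})

test_that("scanning reverse-complemented input preserves the hit multiset", {
  set.seed(100)
  seqs <- setNames(vapply(1:100, function(i) {
    paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
  }, ""), paste0("s", 1:100))
  pwm <- pfm_to_pwm(small_pfm(), motif_id = "M1")
  rc <- setNames(as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs))), names(seqs))
  a <- scan_sequences(pwm, seqs, threshold_bits = 3)
  b <- scan_sequences(pwm, rc, threshold_bits = 3)
  expect_equal(nrow(a), nrow(b))
  # strand labels swap, scores are preserved as a multiset per sequence
  expect_equal(sort(a$score), sort(b$score), tolerance = 1e-9)
  expect_equal(table(a$strand)[["+"]], table(b$strand)[["-"]])
  # offsets mirror: offset' = len - L - offset
  L <- ncol(pwm$mat)
  key_a <- sort(paste(a$sequence_id, a$offset, a$strand))
  key_b <- sort(paste(b$sequence_id, 40 - L - b$offset,
                      ifelse(b$strand == "+", "-", "+")))
  expect_identical(key_a, key_b)
})

test_that("DNAStringSet input scans identically to character input", {
  seqs <- c(a = "ACGAGACGAGTTTT", b = "TTTTTTTTTTTTTT")
  pwm <- pfm_to_pwm(small_pfm(), motif_id = "M1")
  g1 <- scan_sequences(pwm, seqs, threshold_bits = 3)
  g2 <- scan_sequences(pwm, Biostrings::DNAStringSet(seqs), threshold_bits = 3)
  expect_identical(hit_key(g1), hit_key(g2))
})

test_that("proportion test matches its contracts and a binomial oracle", {
  # observed equal to null: no evidence
  null_eq <- proportion_test(100, 1000, 30, 300)
  expect_gte(null_eq$p, 0.9)
  expect_equal(null_eq$null_prop, 0.1)
  expect_equal(null_eq$obs_prop, 0.1)

  r <- proportion_test(100, 1000, 30, 100)
  # exact binomial tail oracle (two-sided, doubled smaller tail)
  p_hi <- pbinom(29, 100, 0.1, lower.tail = FALSE)
  p_lo <- pbinom(30, 100, 0.1)
  p_exact <- min(1, 2 * min(p_hi, p_lo))
  expect_lt(r$p, p_exact * 2 + 1e-6)
  expect_gt(r$p, p_exact / 2 - 1e-6)
  expect_equal(r$p < 0.05, p_exact < 0.05)
  expect_true(r$ci_low <= 0.3 && 0.3 <= r$ci_high)

  # doubled counts sharpen the same proportions into smaller p
  r2 <- proportion_test(200, 2000, 60, 200)
  expect_lt(r2$p, r$p)

  expect_error(proportion_test(10, 5, 1, 2), "n_a <= n_b")
  expect_error(proportion_test(10, 100, 5, 0), "positive")
})

test_that("occurrence filter keeps motifs at the boundary and drops below", {
  hits <- tibble::tibble(
    motif_id = c(rep("M99", 99), rep("M100", 100), rep("M150", 150)),
    sequence_id = c(paste0("t", 1:99), paste0("t", 1:100), paste0("t", 1:150)))
  expect_setequal(filter_motifs_by_occurrence(hits, 100), c("M100", "M150"))
  expect_setequal(filter_motifs_by_occurrence(hits, 100, strict = TRUE), "M150")
  # duplicates within one target count once
  dup <- tibble::tibble(motif_id = "M1", sequence_id = rep("t1", 200))
  expect_equal(filter_motifs_by_occurrence(dup, 100), character())
  expect_equal(filter_motifs_by_occurrence(dup[0, ], 100), character())
})

test_that("motif enrichment assembles the n_a/n_b/n_c/n_d table correctly", {
  hits <- tibble::tibble(
    motif_id = c(rep("M1", 6), rep("M2", 4)),
    sequence_id = c(paste0("t", 1:6), paste0("t", 5:8)))
  sig <- c("t1", "t2", "t3", "t8")
  res <- motif_enrichment(hits, sig, min_occurrence = 3)
  expect_setequal(res$motif_id, c("M1", "M2"))
  m1 <- res[res$motif_id == "M1", ]
  expect_equal(m1$n_b, 8)   # t1..t8 contain any motif
  expect_equal(m1$n_a, 4)   # all four significant targets contain a motif
  expect_equal(m1$n_d, 6)
  expect_equal(m1$n_c, 3)   # t1,t2,t3
  m2 <- res[res$motif_id == "M2", ]
  expect_equal(m2$n_d, 4)
  expect_equal(m2$n_c, 1)   # t8
})

test_that("variant-in-interval membership is half-open and oracle-exact", {
  iv <- tibble::tibble(chrom = "chr1", start = 10L, end = 20L)
  expect_true(intersect_variants(data.frame(chrom = "chr1", pos = 10), iv))
  expect_false(suppressWarnings(
    intersect_variants(data.frame(chrom = "chr1", pos = 20), iv)))
  expect_false(suppressWarnings(
    intersect_variants(data.frame(chrom = "chr2", pos = 15), iv)))

  set.seed(7)
  variants <- data.frame(
    chrom = sample(paste0("chr", 1:3), 5000, replace = TRUE),
    pos = sample.int(10000, 5000, replace = TRUE) - 1L)
  intervals <- data.frame(
    chrom = sample(paste0("chr", 1:3), 800, replace = TRUE),
    start = sample.int(9900, 800, replace = TRUE) - 1L)
  intervals$end <- intervals$start + sample.int(50, 800, replace = TRUE)
  got <- intersect_variants(variants, intervals)
  expect_identical(got, oracle_intersect(variants, intervals))
  expect_warning(
    intersect_variants(data.frame(chrom = "chrX", pos = 5), iv),
    "no variant overlaps")
})

test_that("Fisher enrichment matches hypergeometric enumeration", {
  # independence: OR = 1, p = 1
  flat <- fisher_enrichment(rep(c(TRUE, FALSE), each = 20),
                            rep(c(TRUE, FALSE), 20))
  expect_equal(flat$p, 1)
  expect_equal(flat$odds_ratio, 1, tolerance = 0.3)

  # table (20, 10; 10, 20) against a brute-force tail sum
  sig <- rep(c(TRUE, FALSE), each = 30)
  ann <- c(rep(TRUE, 20), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 20))
  r <- fisher_enrichment(sig, ann)
  expect_equal(r$p, oracle_fisher_p(20, 10, 10, 20), tolerance = 1e-10)
  expect_equal(r$fold_enrichment, (20 / 30) / (10 / 30))

  # fold enrichment of (30, 70; 10, 90) is 3.0
  sig2 <- rep(c(TRUE, FALSE), each = 100)
  ann2 <- c(rep(TRUE, 30), rep(FALSE, 70), rep(TRUE, 10), rep(FALSE, 90))
  r2 <- fisher_enrichment(sig2, ann2)
  expect_equal(r2$fold_enrichment, 3.0)
  expect_equal(r2$p, oracle_fisher_p(30, 70, 10, 90), tolerance = 1e-10)

  # transposing the table's roles leaves p unchanged
  r3 <- fisher_enrichment(ann2, sig2)
  expect_equal(r3$p, r2$p, tolerance = 1e-12)

  # zero margin: missing odds ratio, p = 1
  r4 <- fisher_enrichment(rep(FALSE, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(r4$p, 1)
  expect_true(is.na(r4$odds_ratio))
})

test_that("a motif planted at double rate in ASE targets is detected", {
  motifs <- planted_motif_set()
  cfg <- sim_config(n_targets = 2000, frac_ase = 0.3, frac_case = 0,
                    frac_negative_control = 0, motif_set = motifs,
                    motif_plant_rate = 0.12,
                    motif_ase_multiplier = c(PLANTED = 2, M2 = 1, M3 = 1),
                    seed = 23)
  lib <- simulate_library(cfg)
  fwd_ref <- lib$sequences[grepl("\\|ref\\|fwd", names(lib$sequences))]
  names(fwd_ref) <- sub("\\|.*", "", names(fwd_ref))
  hits <- dplyr::bind_rows(lapply(names(motifs), function(id) {
    scan_sequences(pfm_to_pwm(motifs[[id]], motif_id = id), fwd_ref,
                   threshold_bits = 10)
  }))
  sig <- lib$truth$snp_id[lib$truth$is_ase]
  res <- motif_enrichment(hits, sig, min_occurrence = 100)
  expect_true(all(c("PLANTED", "M2", "M3") %in% res$motif_id))
  planted <- res[res$motif_id == "PLANTED", ]
  expect_lt(planted$p, 0.05)
  expect_gt(planted$obs_prop, planted$null_prop)
  # the uniformly planted companions are never called enriched (they can
  # appear depleted: the planted motif lifts the any-motif baseline)
  comp <- res[res$motif_id != "PLANTED", ]
  expect_true(all(comp$obs_prop < comp$null_prop | comp$p > 0.05))
})
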