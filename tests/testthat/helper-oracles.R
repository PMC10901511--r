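# Independent oracles used across the suite. These share no code with the
# package's fitting/scanning paths: likelihoods are written out directly and
# optimization is by brute force.

# beta-binomial log-likelihood (full, with the gamma-function binomial
# coefficient so pseudocounted non-integer counts are handled) at mean mu
oracle_bb_loglik <- function(k, n, mu, rho) {
  lcoef <- lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
  if (rho < 1e-10) {
    return(lcoef + k * log(mu) + (n - k) * log1p(-mu))
  }
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  lcoef + lbeta(k + a, n - k + b) - lbeta(a, b)
}

# two-stage grid search MLE over x = logit(mu), final resolution 1e-5
oracle_bb_mle <- function(k, n, rho) {
  coarse <- seq(-10, 10, by = 0.01)
  ll <- oracle_bb_loglik(k, n, plogis(coarse), rho)
  x0 <- coarse[which.max(ll)]
  fine <- seq(max(-10, x0 - 0.02), min(10, x0 + 0.02), by = 1e-5)
  llf <- oracle_bb_loglik(k, n, plogis(fine), rho)
  fine[which.max(llf)]
}

# curvature standard error by central finite differences
oracle_bb_se <- function(k, n, x, rho, h = 1e-4) {
  d2 <- (oracle_bb_loglik(k, n, plogis(x + h), rho) -
           2 * oracle_bb_loglik(k, n, plogis(x), rho) +
           oracle_bb_loglik(k, n, plogis(x - h), rho)) / h^2
  1 / sqrt(-d2)
}

# all-windows PWM scan by explicit double loop over windows and strands
oracle_scan <- function(pwm_mat, sequences, threshold, both_strands = TRUE) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  hits <- list()
  L <- ncol(pwm_mat)
  for (sid in names(sequences)) {
    chars <- strsplit(sequences[[sid]], "")[[1]]
    for (off in 0:(length(chars) - L)) {
      win <- chars[off + seq_len(L)]
      if (any(!win %in% names(comp))) next
      s_plus <- sum(vapply(seq_len(L), function(j) pwm_mat[win[j], j], 0))
      if (s_plus >= threshold) {
        hits[[length(hits) + 1]] <- data.frame(
          sequence_id = sid, offset = off, strand = "+", score = s_plus)
      }
      if (both_strands) {
        rc <- rev(unname(comp[win]))
        s_minus <- sum(vapply(seq_len(L), function(j) pwm_mat[rc[j], j], 0))
        if (s_minus >= threshold) {
          hits[[length(hits) + 1]] <- data.frame(
            sequence_id = sid, offset = off, strand = "-", score = s_minus)
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(sequence_id = character(), offset = integer(),
                      strand = character(), score = numeric()))
  }
  do.call(rbind, hits)
}

# quadratic brute-force interval membership (0-based half-open)
oracle_intersect <- function(variants, intervals) {
  vapply(seq_len(nrow(variants)), function(i) {
    any(intervals$chrom == variants$chrom[i] &
          intervals$start <= variants$pos[i] &
          variants$pos[i] < intervals$end)
  }, logical(1))
}

# two-sided Fisher exact p by hypergeometric enumeration: sum probabilities
# of all tables with the same margins whose probability does not exceed the
# observed table's (with the standard relative tolerance)
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + c_   # annotated total
  n_ <- b + d   # unannotated total
  k <- a + b    # significant total
  x <- max(0, k - n_):min(k, m)
  probs <- dhyper(x, m, n_, k)
  p_obs <- dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# standardized hit key for exact scanner comparisons
hit_key <- function(df) {
  sort(sprintf("%s:%d:%s:%.6f", df$sequence_id, df$offset, df$strand, df$score))
}

small_pfm <- function() {
  m <- rbind(A = c(12, 0, 0, 4, 0), C = c(0, 10, 2, 4, 0),
             G = c(0, 2, 10, 2, 12), T = c(0, 0, 0, 2, 0))
  m
}

# sharp 8-mer PFMs (12 counts on the consensus base): one mismatch costs
# ~5.6 bits, so a 10-bit scan threshold admits only consensus matches
pfm_from_consensus <- function(cons) {
  chars <- strsplit(cons, "")[[1]]
  m <- matrix(0, 4, length(chars), dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(chars, rownames(m)), seq_along(chars))] <- 12
  m
}

planted_motif_set <- function() {
  list(PLANTED = pfm_from_consensus("ACGTACGG"),
       M2 = pfm_from_consensus("GGATCCTA"),
       M3 = pfm_from_consensus("TTGCAAGC"))
}

# base-R reshape of a long count table to ref/alt columns for one condition
counts_subset <- function(tab, condition) {
  rna <- tab[tab$condition == condition, ]
  ref <- rna[rna$allele == "ref", ]
  alt <- rna[rna$allele == "alt", ]
  key <- function(d) paste(d$snp_id, d$direction, d$sample_id)
  alt <- alt[match(key(ref), key(alt)), ]
  data.frame(snp_id = ref$snp_id, direction = ref$direction,
             sample_id = ref$sample_id, replicate = ref$replicate,
             ref = ref$count, alt = alt$count)
}

random_count_table <- function(n_snps = 5, n_reps = 3, seed = 42,
                               depth = 60) {
  withr::with_seed(seed, {
    snp <- sprintf("s%02d", seq_len(n_snps))
    grid <- expand.grid(snp_id = snp, direction = c("fwd", "rev"),
                        condition = c("control", "caffeine"),
                        replicate = seq_len(n_reps), stringsAsFactors = FALSE)
    grid$sample_id <- paste(grid$condition, grid$replicate, sep = "_")
    N <- rpois(nrow(grid), depth)
    ref <- rbinom(nrow(grid), N, 0.5)
    rna <- rbind(
      transform(grid, allele = "ref", count = ref),
      transform(grid, allele = "alt", count = N - ref)
    )
    dg <- expand.grid(snp_id = snp, direction = c("fwd", "rev"),
                      stringsAsFactors = FALSE)
    Nd <- rpois(nrow(dg), depth * 5)
    refd <- rbinom(nrow(dg), Nd, 0.5)
    dna <- rbind(
      data.frame(dg, condition = "dna", replicate = 1L, sample_id = "dna_1",
                 allele = "ref", count = refd),
      data.frame(dg, condition = "dna", replicate = 1L, sample_id = "dna_1",
                 allele = "alt", count = Nd - refd)
    )
    cols <- c("snp_id", "direction", "allele", "sample_id", "condition",
              "replicate", "count")
    tibble::as_tibble(rbind(rna[, cols], dna[, cols]))
  })
}
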