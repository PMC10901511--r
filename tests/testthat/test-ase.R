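# ASE: DNA proportions, beta-binomial replicate fits against grid-search
# oracles, meta-analysis closed forms, BH, dispersion estimation, and the
# allele-swap / null-calibration invariants.

test_that("DNA proportion estimator has the pseudocounted closed form", {
  expect_equal(estimate_dna_proportion(10, 10), 0.5)
  expect_equal(estimate_dna_proportion(0, 0), 0.5)
  expect_equal(estimate_dna_proportion(99, 0), 0.995)
  expect_equal(estimate_dna_proportion(c(10, 99), c(10, 0)), c(0.5, 0.995))
  expect_error(estimate_dna_proportion(-1, 5), "non-negative")
})

test_that("replicate fit matches closed forms in the binomial limit", {
  # symmetric counts: beta = 0
  f <- fit_replicate(5, 5, rho = 1e-8)
  expect_equal(f$beta, 0, tolerance = 1e-6)
  expect_equal(plogis(f$beta), 0.5, tolerance = 1e-6)
  # (8, 2) with pseudocount 0.5: MLE = logit(8.5 / 11)
  f <- fit_replicate(8, 2, rho = 0)
  expect_equal(f$beta, qlogis(8.5 / 11), tolerance = 1e-6)
  expect_equal(f$beta, 1.2238, tolerance = 1e-4)
  # zero totals are flagged missing
  f <- fit_replicate(c(0, 4), c(0, 6), rho = 0.05)
  expect_true(is.na(f$beta[1]) && is.na(f$se[1]))
  expect_false(is.na(f$beta[2]))
  expect_equal(f$n_reads, c(0, 10))
})

test_that("beta-binomial MLE and se match brute-force oracles", {
  # the specific overdispersed example
  f <- fit_replicate(8, 2, rho = 0.1)
  x_star <- oracle_bb_mle(8.5, 11, 0.1)
  expect_equal(f$beta, x_star, tolerance = 1e-3)
  expect_equal(f$se, oracle_bb_se(8.5, 11, x_star, 0.1), tolerance = 1e-3)

  # 200 random count pairs across dispersion regimes
  set.seed(123)
  n_tot <- sample(5:400, 200, replace = TRUE)
  k <- rbinom(200, n_tot, runif(200, 0.05, 0.95))
  rhos <- sample(c(0, 0.01, 0.1, 0.3), 200, replace = TRUE)
  for (rho in unique(rhos)) {
    sel <- which(rhos == rho)
    fit <- fit_replicate(k[sel], n_tot[sel] - k[sel], rho = rho)
    for (j in seq_along(sel)) {
      i <- sel[j]
      x_star <- oracle_bb_mle(k[i] + 0.5, n_tot[i] + 1, rho)
      expect_equal(fit$beta[j], x_star, tolerance = 1e-3)
      expect_equal(fit$se[j], oracle_bb_se(k[i] + 0.5, n_tot[i] + 1, x_star, rho),
                   tolerance = 1e-3)
    }
  }
})

test_that("meta-analysis matches inverse-variance closed forms", {
  one <- meta_analyze(data.frame(beta = 1.5, se = 0.3), p0 = 0.5,
                      min_replicates = 1)
  expect_equal(one$beta_meta, 1.5)
  expect_equal(one$se_meta, 0.3)
  expect_equal(one$z, 5)

  two <- meta_analyze(data.frame(beta = c(0, 2), se = c(1, 1)), p0 = 0.5,
                      min_replicates = 1)
  expect_equal(two$beta_meta, 1)
  expect_equal(two$se_meta, 1 / sqrt(2))
  expect_equal(two$z, sqrt(2), tolerance = 1e-12)

  # the >= 4 usable replicates rule withholds the p-value
  three <- meta_analyze(data.frame(beta = c(0, 1, 2), se = c(1, 1, 1)),
                        p0 = 0.5, min_replicates = 4)
  expect_false(three$tested)
  expect_true(is.na(three$p))
  expect_equal(three$n_replicates_used, 3L)
  expect_error(meta_analyze(data.frame(beta = numeric(), se = numeric()), 0.5),
               "empty")
})

test_that("BH adjustment reproduces the hand-applied step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("dispersion estimation recovers truth and hits the binomial floor", {
  cfg <- sim_config(n_targets = 1500, frac_ase = 0, frac_case = 0,
                    frac_negative_control = 0, rho = 0.05, mean_depth = 200,
                    n_replicates = 2, seed = 31)
  tab <- simulate_allele_counts(simulate_library(cfg)$truth, cfg)
  rho_hat <- estimate_dispersion(tab, "control")
  expect_lt(abs(rho_hat - 0.05), 0.01)

  cfg0 <- sim_config(n_targets = 800, frac_ase = 0, frac_case = 0,
                     frac_negative_control = 0, rho = 0, mean_depth = 200,
                     n_replicates = 2, seed = 32)
  tab0 <- simulate_allele_counts(simulate_library(cfg0)$truth, cfg0)
  expect_lte(estimate_dispersion(tab0, "control"), 1e-3)

  # label symmetry: swapping ref/alt leaves rho unchanged
  swapped <- tab
  swapped$allele <- ifelse(tab$allele == "ref", "alt", "ref")
  expect_equal(estimate_dispersion(swapped, "control"), rho_hat,
               tolerance = 1e-6)
  expect_error(estimate_dispersion(random_count_table(n_snps = 3), "control"),
               "fewer than 50")
})

test_that("allele swap negates effects and z exactly, p unchanged", {
  cfg <- sim_config(n_targets = 120, frac_ase = 0.3, effect_sd = 1,
                    mean_depth = 250, seed = 41)
  tab <- simulate_allele_counts(simulate_library(cfg)$truth, cfg)
  swapped <- tab
  swapped$allele <- ifelse(tab$allele == "ref", "alt", "ref")
  a <- run_ase(tab, rho = 0.05)
  b <- run_ase(swapped, rho = 0.05)
  key <- paste(a$snp_id, a$direction, a$condition)
  b <- b[match(key, paste(b$snp_id, b$direction, b$condition)), ]
  expect_equal(b$z, -a$z, tolerance = 1e-6)
  expect_equal(b$beta_meta - b$dna_logit, -(a$beta_meta - a$dna_logit),
               tolerance = 1e-6)
  expect_equal(b$p, a$p, tolerance = 1e-9)
})

test_that("the replicate filter counts usable replicates", {
  cfg <- sim_config(n_targets = 150, mean_depth = 8, depth_dispersion = 2,
                    frac_ase = 0, frac_case = 0, seed = 51)
  # shallow heavy-tailed depths leave many pairs with < 4 usable replicates
  tab <- simulate_allele_counts(simulate_library(cfg)$truth, cfg)
  res <- run_ase(tab, rho = 0.05, min_dna_reads = 0)
  wide <- counts_subset(tab, "control")
  usable <- tapply(wide$ref + wide$alt > 0,
                   paste(wide$snp_id, wide$direction), sum)
  ctl <- res[res$condition == "control", ]
  expect_equal(ctl$n_replicates_used,
               as.integer(usable[paste(ctl$snp_id, ctl$direction)]))
  expect_identical(ctl$tested, ctl$n_replicates_used >= 4)
  expect_true(all(is.na(ctl$p[!ctl$tested])))
  expect_true(any(!ctl$tested) && any(ctl$tested))
})

test_that("significant-call summary counts pairs and distinct SNPs", {
  res <- tibble::tibble(
    snp_id = c("s1", "s1", "s2", "s2"),
    direction = c("fwd", "rev", "fwd", "rev"),
    condition = "control",
    q = c(0.01, 0.05, 0.5, 0.9),
    p = c(0.001, 0.01, 0.3, 0.8),
    tested = TRUE
  )
  out <- call_ase(res, fdr = 0.10)
  expect_equal(sum(out$significant), 2)
  s <- ase_summary(out)
  expect_equal(s$n_pairs_significant, 2)  # fwd and rev of the same SNP
  expect_equal(s$n_snps_significant, 1)
  expect_equal(s$n_pairs_tested, 4)
  expect_equal(s$n_snps_tested, 2)
  # all q = 1 gives zero significant
  expect_equal(sum(call_ase(transform(res, q = 1))$significant), 0)
})

test_that("printed-count percentage arithmetic matches reporting style", {
  expect_equal(percent_of(665, 30680), 2.2)
  expect_equal(percent_of(0, 10), 0)
})

test_that("power increases with effect size and depth", {
  grid_power <- function(beta, depth, seed) {
    cfg <- sim_config(n_targets = 150, frac_ase = 0, frac_case = 0,
                      frac_negative_control = 0, mean_depth = depth,
                      depth_dispersion = 0, rho = 0.05, seed = seed)
    lib <- simulate_library(cfg)
    lib$truth$true_beta_control <- rep(beta, 150)
    lib$truth$true_beta_control_rev <- rep(beta, 150)
    tab <- simulate_allele_counts(lib$truth, cfg)
    res <- run_ase(tab, rho = 0.05)
    ctl <- res[res$condition == "control" & res$tested, ]
    mean(ctl$p < 0.05)
  }
  p_small <- grid_power(0.2, 150, 61)
  p_mid <- grid_power(0.6, 150, 61)
  p_big <- grid_power(1.2, 150, 61)
  expect_lte(p_small, p_mid + 0.05)
  expect_lte(p_mid, p_big + 0.05)
  expect_gt(p_big, 0.8)
  p_deep <- grid_power(0.6, 600, 62)
  expect_gte(p_deep + 0.05, p_mid)
})
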