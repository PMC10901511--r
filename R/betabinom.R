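# Beta-binomial likelihood machinery for allele-specific expression.
#
# Parameterization: a ref count k out of n reads is BetaBinomial(n, mu, rho)
# with mean n*mu and variance n*mu*(1-mu)*(1 + (n-1)*rho). Internally the
# Beta mixing distribution has shape a = mu*c, b = (1-mu)*c with
# c = (1-rho)/rho, so rho -> 0 recovers the binomial.

# log-likelihood up to terms constant in mu (the lchoose(n, k) term is kept
# out; it cancels in optimization over mu and is constant in rho only through
# k and n, so it is also irrelevant when profiling rho).
bb_loglik <- function(k, n, mu, rho) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  if (length(rho) == 1L && rho < 1e-10) {
    return(k * log(mu) + (n - k) * log1p(-mu))
  }
  cc <- (1 - rho) / rho
  a <- mu * cc
  b <- (1 - mu) * cc
  lbeta(k + a, n - k + b) - lbeta(a, b)
}

# first and second derivatives of bb_loglik with respect to x = logit(mu)
bb_score_logodds <- function(k, n, x, rho) {
  mu <- plogis(x)
  dmu <- mu * (1 - mu)
  if (rho < 1e-10) {
    g <- k - n * mu
    h <- -n * dmu
    return(list(g = g, h = h))
  }
  cc <- (1 - rho) / rho
  a <- mu * cc
  b <- (1 - mu) * cc
  dl_dmu <- cc * (digamma(k + a) - digamma(a) - digamma(n - k + b) + digamma(b))
  d2l_dmu2 <- cc^2 * (trigamma(k + a) - trigamma(a) +
                        trigamma(n - k + b) - trigamma(b))
  g <- dl_dmu * dmu
  h <- d2l_dmu2 * dmu^2 + dl_dmu * dmu * (1 - 2 * mu)
  list(g = g, h = h)
}

# Vectorized safeguarded Newton maximization of the beta-binomial
# log-likelihood over x = logit(mu) in [-10, 10], fixed rho.
# k and n may be non-integer (pseudocounts). Returns beta (MLE of x) and
# the curvature standard error 1/sqrt(-d2l/dx2).
bb_fit_logodds <- function(k, n, rho, bound = 10, tol = 1e-10, max_iter = 100L) {
  stopifnot(length(k) == length(n), all(n > 0), rho >= 0, rho < 1)
  x <- qlogis(pmin(pmax(k / n, 1e-6), 1 - 1e-6))
  x <- pmin(pmax(x, -bound), bound)
  ll <- bb_loglik(k, n, plogis(x), rho)
  active <- rep(TRUE, length(k))
  for (iter in seq_len(max_iter)) {
    if (!any(active)) break
    sc <- bb_score_logodds(k[active], n[active], x[active], rho)
    step <- ifelse(sc$h < -1e-12, -sc$g / sc$h, sign(sc$g) * 0.5)
    step <- pmin(pmax(step, -2), 2)
    xa <- x[active]
    lla <- ll[active]
    for (halve in 1:30) {
      xn <- pmin(pmax(xa + step, -bound), bound)
      lln <- bb_loglik(k[active], n[active], plogis(xn), rho)
      worse <- lln < lla - 1e-12
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    moved <- abs(xn - xa) > tol
    x[active] <- xn
    ll[active] <- lln
    active[active] <- moved
  }
  # fallback for any fit whose gradient is still non-negligible off-boundary
  sc <- bb_score_logodds(k, n, x, rho)
  bad <- which(abs(sc$g) > 1e-5 & abs(x) < bound - 1e-8)
  for (i in bad) {
    opt <- optimize(function(xx) bb_loglik(k[i], n[i], plogis(xx), rho),
                    interval = c(-bound, bound), maximum = TRUE, tol = 1e-9)
    x[i] <- opt$maximum
  }
  h <- bb_score_logodds(k, n, x, rho)$h
  se <- 1 / sqrt(pmax(-h, 1e-12))
  list(beta = x, se = se)
}

# Exact null moments of the pseudocounted beta-binomial log-odds MLE.
#
# With fixed rho the effective information per replicate saturates at 1/rho,
# so the logit nonlinearity never washes out and no first-order standard
# error is exact at any depth. The estimator's null mean and sd are instead
# computed exactly: for a given (N, p0) enumerate k = 0..N, evaluate the
# MLE x(k) once per N, and take moments under the beta-binomial pmf. A grid
# over (N, p0) is enumerated once per run and interpolated (the sd is
# stored as a ratio to a smooth first-order formula, so interpolation error
# is ~1e-3).

bb_se_firstorder <- function(N, p0, rho, pseudocount = 0.5) {
  sqrt((1 + pmax(N - 1, 0) * rho) / (N * p0 * (1 - p0))) *
    N / (N + 2 * pseudocount)
}

bb_pmf <- function(k, N, p0, rho) {
  if (rho < 1e-10) return(stats::dbinom(k, N, p0))
  cc <- (1 - rho) / rho
  a <- p0 * cc
  b <- (1 - p0) * cc
  exp(lchoose(N, k) + lbeta(k + a, N - k + b) - lbeta(a, b))
}

# Enumerate exact null mean bias and sd of the fitted log-odds on a grid of
# depths and DNA proportions, for one dispersion value.
bb_null_calibration <- function(rho, n_max, pseudocount = 0.5,
                                n_p0 = 21, p0_range = c(0.02, 0.98)) {
  n_max <- max(n_max, 16)
  N_grid <- sort(unique(c(1:16, round(exp(seq(log(16), log(n_max),
                                              length.out = 24))))))
  p0_grid <- plogis(seq(qlogis(p0_range[1]), qlogis(p0_range[2]),
                        length.out = n_p0))
  bias <- ratio <- matrix(0, length(N_grid), length(p0_grid))
  for (i in seq_along(N_grid)) {
    N <- N_grid[i]
    k <- 0:N
    xk <- bb_fit_logodds(k + pseudocount, rep(N + 2 * pseudocount, N + 1),
                         rho)$beta
    for (j in seq_along(p0_grid)) {
      w <- bb_pmf(k, N, p0_grid[j], rho)
      w <- w / sum(w)
      m1 <- sum(w * xk)
      sd_exact <- sqrt(max(sum(w * xk^2) - m1^2, 1e-12))
      bias[i, j] <- m1 - qlogis(p0_grid[j])
      ratio[i, j] <- sd_exact / bb_se_firstorder(N, p0_grid[j], rho,
                                                 pseudocount)
    }
  }
  list(rho = rho, pseudocount = pseudocount, log_N = log(N_grid),
       p0 = p0_grid, bias = bias, ratio = ratio)
}

# bilinear interpolation of the calibration surfaces at (N, p0)
bb_null_moments <- function(calib, N, p0) {
  interp2 <- function(mat, x_grid, y_grid, x, y) {
    x <- pmin(pmax(x, x_grid[1]), x_grid[length(x_grid)])
    y <- pmin(pmax(y, y_grid[1]), y_grid[length(y_grid)])
    ix <- pmin(pmax(findInterval(x, x_grid), 1), length(x_grid) - 1)
    iy <- pmin(pmax(findInterval(y, y_grid), 1), length(y_grid) - 1)
    fx <- (x - x_grid[ix]) / (x_grid[ix + 1] - x_grid[ix])
    fy <- (y - y_grid[iy]) / (y_grid[iy + 1] - y_grid[iy])
    mat[cbind(ix, iy)] * (1 - fx) * (1 - fy) +
      mat[cbind(ix + 1, iy)] * fx * (1 - fy) +
      mat[cbind(ix, iy + 1)] * (1 - fx) * fy +
      mat[cbind(ix + 1, iy + 1)] * fx * fy
  }
  lN <- log(pmax(N, 1))
  list(
    bias = interp2(calib$bias, calib$log_N, calib$p0, lN, p0),
    se = bb_se_firstorder(N, p0, calib$rho, calib$pseudocount) *
      interp2(calib$ratio, calib$log_N, calib$p0, lN, p0)
  )
}

# Beta-binomial random draws (rho = 0 degenerates to binomial).
rbetabinom <- function(n_draws, size, mu, rho) {
  if (rho < 1e-12) {
    return(rbinom(n_draws, size, mu))
  }
  cc <- (1 - rho) / rho
  pr <- rbeta(n_draws, mu * cc, (1 - mu) * cc)
  rbinom(n_draws, size, pr)
}

#' Estimate the DNA-library reference-allele proportion
#'
#' The plasmid input library is the null expectation for RNA allelic ratios:
#' a biallelic target with no regulatory effect should produce RNA reads at
#' the same reference fraction as the DNA pool. A Haldane--Anscombe
#' pseudocount keeps the estimate away from 0 and 1 for monoallelic counts.
#'
#' @param dna_ref,dna_alt Non-negative reference/alternate DNA read counts
#'   (vectorized).
#' @param pseudocount Pseudocount added to each allele (default 0.5).
#' @return Reference-allele proportion(s) `p0` in (0, 1):
#'   `(dna_ref + pseudocount) / (dna_ref + dna_alt + 2 * pseudocount)`.
#' @examples
#' estimate_dna_proportion(10, 10) # 0.5
#' estimate_dna_proportion(99, 0)  # 0.995
#' @export
estimate_dna_proportion <- function(dna_ref, dna_alt, pseudocount = 0.5) {
  if (any(dna_ref < 0) || any(dna_alt < 0)) {
    stop("DNA counts must be non-negative")
  }
  (dna_ref + pseudocount) / (dna_ref + dna_alt + 2 * pseudocount)
}

#' Estimate the beta-binomial overdispersion for one condition
#'
#' Pools all SNP/direction/replicate RNA observations of a condition and
#' maximizes the beta-binomial log-likelihood over the overdispersion `rho`,
#' holding each pair's mean fixed at its DNA reference proportion. A single
#' condition-wide `rho` is then used for every per-replicate effect fit.
#'
#' @param table Allele count table (see [read_allele_counts()]).
#' @param condition RNA condition to estimate from (`"control"` or
#'   `"caffeine"`).
#' @param pseudocount Pseudocount for the DNA proportion estimate.
#' @return Estimated `rho` in `[1e-6, 0.999]`.
#' @export
estimate_dispersion <- function(table, condition, pseudocount = 0.5) {
  stopifnot(condition %in% c("control", "caffeine"))
  wide <- counts_to_wide(table)
  dna <- dna_proportions(table, pseudocount = pseudocount)
  rna <- wide[wide$condition == condition & (wide$ref + wide$alt) > 0, ]
  rna <- dplyr::left_join(rna, dna, by = c("snp_id", "direction"))
  n_pairs <- nrow(dplyr::distinct(rna, snp_id, direction))
  if (n_pairs < 50) {
    stop("fewer than 50 SNP/direction pairs with nonzero RNA depth; ",
         "supply a fixed rho instead of estimating it")
  }
  k <- rna$ref
  n <- rna$ref + rna$alt
  mu <- pmin(pmax(rna$p0, 1e-6), 1 - 1e-6)
  negll <- function(rho) -sum(bb_loglik(k, n, mu, rho))
  opt <- optimize(negll, interval = c(1e-6, 0.999), tol = 1e-7)
  # measurement-error correction: the fitted mean is the *estimated* DNA
  # proportion, whose sampling error inflates the apparent overdispersion by
  # ~Var(p0_hat)/(p0 q0) = 1/(N_dna + 1) per pair (binomial DNA sequencing)
  dna_noise <- mean(1 / (rna$dna_ref + rna$dna_alt + 1))
  max(opt$minimum - dna_noise, 1e-6)
}

#' Fit the per-replicate allelic effect under a beta-binomial model
#'
#' Maximum-likelihood estimate of the log-odds of the RNA reference-allele
#' proportion for one replicate, with fixed overdispersion. A pseudocount is
#' added to both allele counts before fitting so monoallelic observations
#' yield finite effects. The standard error is the curvature of the
#' log-likelihood at the optimum.
#'
#' @param rna_ref,rna_alt Non-negative RNA read counts (vectorized; equal
#'   length).
#' @param rho Beta-binomial overdispersion in `[0, 1)`.
#' @param pseudocount Pseudocount added to both counts (default 0.5).
#' @return A tibble with columns `beta` (log-odds MLE), `se`, and `n_reads`
#'   (raw ref + alt). Rows with zero total raw reads get `NA` beta/se and are
#'   excluded from meta-analysis downstream.
#' @examples
#' fit_replicate(8, 2, rho = 0) # beta = logit(8.5/11)
#' @export
fit_replicate <- function(rna_ref, rna_alt, rho, pseudocount = 0.5) {
  stopifnot(length(rna_ref) == length(rna_alt), rho >= 0, rho < 1)
  if (any(rna_ref < 0) || any(rna_alt < 0)) stop("RNA counts must be non-negative")
  n_reads <- rna_ref + rna_alt
  usable <- n_reads > 0
  beta <- se <- rep(NA_real_, length(n_reads))
  if (any(usable)) {
    k <- rna_ref[usable] + pseudocount
    n <- n_reads[usable] + 2 * pseudocount
    fit <- bb_fit_logodds(k, n, rho)
    beta[usable] <- fit$beta
    se[usable] <- fit$se
  }
  tibble::tibble(beta = beta, se = se, n_reads = n_reads)
}
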