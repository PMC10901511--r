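# Differential activity: per-direction negative-binomial Wald test for a
# treatment effect on each target's activity, correcting for allele
# (log mean = offset + intercept + b_allele*I[alt] + b_trt*I[caffeine]).
# Per-target dispersion by profile maximum likelihood (floored), no
# shrinkage, no independent filtering; directions analyzed as separate BH
# families and combined by the either-direction rule.

#' Median-of-ratios size factors
#'
#' For each sample, the median across all-positive rows of the ratio of its
#' count to the row geometric mean, rescaled to geometric mean 1. Falls back
#' to column-total ratios (with a warning) when no row is all-positive.
#'
#' @param matrix Non-negative count matrix (rows constructs, columns
#'   samples).
#' @return Positive per-sample factors (geometric mean 1).
#' @export
size_factors <- function(matrix) {
  stopifnot(is.matrix(matrix), all(matrix >= 0))
  pos <- rowSums(matrix > 0) == ncol(matrix)
  if (!any(pos)) {
    warning("no row with all-positive counts; using column-total ratios")
    f <- colSums(matrix)
    if (any(f == 0)) stop("sample with zero total counts")
    return(f / exp(mean(log(f))))
  }
  m <- matrix[pos, , drop = FALSE]
  log_gm <- rowMeans(log(m))
  f <- apply(m, 2, function(col) median(exp(log(col) - log_gm)))
  f / exp(mean(log(f)))
}

# negative binomial log-likelihood of the 3-coefficient GLM at fixed theta,
# maximized over the coefficients via IRLS (glm.fit with the NB family);
# `adjusted` adds the Cox-Reid term -log det(X'WX)/2, which removes the
# O(p/n) downward bias of the plain dispersion MLE at 2 x n_samples
# observations per target
nb_profile_fit <- function(y, X, offset, theta, adjusted = FALSE) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, offset = offset,
                   family = MASS::negative.binomial(theta = theta, link = "log"))
  )
  ll <- sum(dnbinom(y, size = theta, mu = fit$fitted.values, log = TRUE))
  if (adjusted) {
    mu <- fit$fitted.values
    w <- mu / (1 + mu / theta)
    ll <- ll - 0.5 * determinant(crossprod(X * sqrt(w)))$modulus[1]
  }
  list(fit = fit, loglik = ll)
}

#' Negative-binomial Wald test of treatment on one target's activity
#'
#' Fits `log mean = log size_factor + intercept + b_allele * I[alt] +
#' b_trt * I[caffeine]` to the target's 2-allele by all-samples counts.
#' The per-target NB dispersion (`1/theta`) is profiled by Cox--Reid
#' adjusted maximum likelihood (floored at 1e-8), with no shrinkage across
#' targets; the Wald statistic is `b_trt / se` with
#' the standard error from the expected information `X'WX` at the optimum,
#' referred to a t distribution with residual degrees of freedom
#' (2 x n_samples - 3). A likelihood-ratio alternative is available via
#' `test = "lr"`.
#'
#' @param counts Integer matrix with 2 rows (ref and alt allele of one
#'   target, in that order) and one column per RNA sample.
#' @param condition Character vector per sample, `"control"`/`"caffeine"`.
#' @param sf Per-sample size factors (e.g. from [size_factors()] on the full
#'   matrix).
#' @param target_id Target identifier carried into the result.
#' @param direction Direction label carried into the result.
#' @param test `"wald"` (default) or `"lr"`.
#' @return One-row tibble: `target_id`, `direction`, `lfc_treatment` (log2),
#'   `se_lfc` (log2), `wald`, `p`, `dispersion`, `tested`.
#' @export
fit_nb_da <- function(counts, condition, sf, target_id = "target",
                      direction = "fwd", test = c("wald", "lr")) {
  test <- match.arg(test)
  stopifnot(nrow(counts) == 2, ncol(counts) == length(condition),
            length(sf) == length(condition))
  y <- as.vector(t(counts))  # ref samples then alt samples
  allele <- rep(c(0, 1), each = ncol(counts))
  trt <- rep(as.numeric(condition == "caffeine"), 2)
  untested <- function(reason) {
    tibble::tibble(target_id = target_id, direction = direction,
                   lfc_treatment = NA_real_, se_lfc = NA_real_,
                   wald = NA_real_, p = NA_real_, dispersion = NA_real_,
                   tested = FALSE, reason = reason)
  }
  for (cond in c("control", "caffeine")) {
    if (sum(counts[, condition == cond]) == 0) {
      return(untested(paste0("all-zero counts in ", cond)))
    }
  }
  X <- cbind(1, allele, trt)
  offset <- log(rep(sf, 2))
  prof <- function(log_theta) {
    nb_profile_fit(y, X, offset, exp(log_theta), adjusted = TRUE)$loglik
  }
  opt <- optimize(prof, interval = c(log(0.05), log(1e8)),
                  maximum = TRUE, tol = 1e-4)
  theta <- exp(opt$maximum)
  res <- nb_profile_fit(y, X, offset, theta)
  fit <- res$fit
  mu <- fit$fitted.values
  w <- mu / (1 + mu / theta)       # expected information weights, log link
  info <- crossprod(X * sqrt(w))
  covb <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(covb)) return(untested("singular information matrix"))
  b_trt <- unname(fit$coefficients[3])
  se <- sqrt(covb[3, 3])
  wald <- b_trt / se
  p <- if (test == "wald") {
    # t reference with residual df: the dispersion is estimated per target
    # from 2 x n_samples observations, so a normal reference is liberal
    2 * stats::pt(-abs(wald), df = length(y) - ncol(X))
  } else {
    X0 <- X[, 1:2, drop = FALSE]
    ll0 <- nb_profile_fit(y, X0, offset, theta)$loglik
    pchisq(2 * (res$loglik - ll0), df = 1, lower.tail = FALSE)
  }
  tibble::tibble(target_id = target_id, direction = direction,
                 lfc_treatment = b_trt / log(2), se_lfc = se / log(2),
                 wald = wald, p = p, dispersion = 1 / theta, tested = TRUE,
                 reason = NA_character_)
}

#' Per-direction differential activity analysis
#'
#' Splits the construct-by-sample matrix by direction, computes size factors
#' per direction, fits the NB treatment model per target, and adjusts
#' p-values (BH) within each direction separately.
#'
#' @param counts Integer matrix with rows named `target|allele|direction`
#'   and columns matching `samples$sample_id`.
#' @param samples Tibble with `sample_id` and `condition` per RNA sample.
#' @param test `"wald"` or `"lr"`, see [fit_nb_da()].
#' @return Tibble of per-(target, direction) results with `q`.
#' @export
run_da <- function(counts, samples, test = "wald") {
  stopifnot(all(colnames(counts) == samples$sample_id))
  parts <- strsplit(rownames(counts), "|", fixed = TRUE)
  if (any(lengths(parts) != 3)) {
    stop("row names must be 'target|allele|direction'")
  }
  info <- data.frame(target = vapply(parts, `[`, "", 1),
                     allele = vapply(parts, `[`, "", 2),
                     direction = vapply(parts, `[`, "", 3))
  out <- list()
  for (dir in unique(info$direction)) {
    sel <- info$direction == dir
    m <- counts[sel, , drop = FALSE]
    inf <- info[sel, ]
    sf <- size_factors(m)
    targets <- unique(inf$target)
    ref_rows <- match(paste(targets, "ref", dir), paste(inf$target, inf$allele, inf$direction))
    alt_rows <- match(paste(targets, "alt", dir), paste(inf$target, inf$allele, inf$direction))
    if (any(is.na(ref_rows)) || any(is.na(alt_rows))) {
      stop("direction ", dir, ": some targets lack both allele rows")
    }
    res <- vector("list", length(targets))
    for (i in seq_along(targets)) {
      res[[i]] <- fit_nb_da(m[c(ref_rows[i], alt_rows[i]), , drop = FALSE],
                            samples$condition, sf, target_id = targets[i],
                            direction = dir, test = test)
    }
    res <- dplyr::bind_rows(res)
    res$q <- NA_real_
    res$q[res$tested] <- bh_adjust(res$p[res$tested])
    out[[dir]] <- res
  }
  dplyr::bind_rows(out)
}

#' Target-level differential activity calls (either-direction rule)
#'
#' A target is significant when its BH q-value is below the threshold in the
#' forward OR the reverse direction; the direction of change is the sign of
#' the significant direction's log fold-change (smaller q wins a tie).
#'
#' @param results Per-direction results from [run_da()].
#' @param fdr FDR threshold (default 0.10).
#' @return Tibble with one row per target: `significant`,
#'   `direction_of_change` (`"up"`/`"down"`/`NA`), `lfc_treatment`, `q_min`.
#' @export
da_classify <- function(results, fdr = 0.10) {
  results %>%
    dplyr::filter(tested) %>%
    dplyr::group_by(target_id) %>%
    dplyr::summarise(
      significant = any(q < fdr),
      q_min = min(q),
      lfc_treatment = lfc_treatment[which.min(q)],
      direction_of_change = ifelse(significant,
                                   ifelse(lfc_treatment > 0, "up", "down"),
                                   NA_character_),
      .groups = "drop"
    )
}

#' PCA quality control of an activity matrix
#'
#' Size-factor-normalizes, log2(x + 1) transforms, row-centers, and applies
#' SVD. Sample scores on the leading components expose the dominant axes of
#' variation (in this assay, typically the allele axis before treatment).
#'
#' @param matrix Non-negative count matrix (rows features, columns samples;
#'   at least 3 samples).
#' @return List with `scores` (samples x components) and `var_explained`
#'   (fractions summing to 1).
#' @export
pca_qc <- function(matrix) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 3)
  sf <- size_factors(matrix)
  lg <- log2(sweep(matrix, 2, sf, "/") + 1)
  cx <- lg - rowMeans(lg)
  if (all(abs(cx) < 1e-12)) {
    stop("constant matrix: no variance to decompose")
  }
  sv <- svd(cx)
  scores <- sv$v %*% diag(sv$d, nrow = length(sv$d))
  rownames(scores) <- colnames(matrix)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  list(scores = scores, var_explained = sv$d^2 / sum(sv$d^2))
}
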