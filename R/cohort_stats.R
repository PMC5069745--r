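# Cross-sample statistics: t-tests, concordance, correlation, growth.

#' Pooled-variance two-sample t-test
#'
#' Student's two-sample t-test with pooled variance, the contrast used to
#' compare replicate labeling metrics between time points. Two-tailed by
#' default. Degenerate inputs are handled explicitly: zero pooled variance
#' with equal means gives `t = 0, p = 1`; zero pooled variance with
#' unequal means gives an infinite t and `p = 0` with a warning.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param tails 2 (default) or 1. The one-tailed p is half the two-tailed
#'   p, in the direction of the observed difference.
#' @return One-row tibble: `statistic`, `estimate` (mean difference
#'   a - b), `t`, `p_value`, `df`, `n_a`, `n_b`.
#' @export
pooled_t_test <- function(group_a, group_b, tails = 2) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L,
            tails %in% c(1, 2))
  na <- length(group_a)
  nb <- length(group_b)
  est <- mean(group_a) - mean(group_b)
  s2p <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (s2p == 0) {
    if (est == 0) {
      t_stat <- 0
      p <- 1
    } else {
      warning("zero pooled variance with unequal means: infinite t")
      t_stat <- sign(est) * Inf
      p <- 0
    }
  } else {
    ht <- stats::t.test(group_a, group_b, var.equal = TRUE)
    t_stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  if (tails == 1) p <- p / 2
  tibble(
    statistic = "pooled_t", estimate = est, t = t_stat, p_value = p,
    df = na + nb - 2, n_a = na, n_b = nb
  )
}

#' Lin's concordance correlation coefficient
#'
#' \deqn{\rho_c = \frac{2\,\mathrm{cov}(x,y)}
#'   {\mathrm{var}(x) + \mathrm{var}(y) + (\bar x - \bar y)^2}}
#' with population (n-denominator) moments, the original estimator.
#' Unlike Pearson's r it penalizes location and scale shifts, which makes
#' it the appropriate agreement measure for replicate protein
#' relative-abundance profiles.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return The coefficient in \[-1, 1\], or `NA` with a warning when both
#'   vectors are constant.
#' @export
lin_ccc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  n <- length(x)
  mx <- mean(x)
  my <- mean(y)
  vx <- mean((x - mx)^2)
  vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) {
    warning("concordance undefined for identical constant vectors")
    return(NA_real_)
  }
  2 * cxy / denom
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor()] with explicit degenerate-input
#' handling, used e.g. to relate changes in label frequency to changes in
#' cell counts.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation in \[-1, 1\], or `NA` with a warning on constant
#'   input.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined for constant input")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Growth arithmetic on cell counts
#'
#' `percent_increase` returns `100 * (end/start - 1)`; `fold_change`
#' returns `end/start`. The two are consistent exactly:
#' `100 * (fold_change - 1) == percent_increase`.
#'
#' @param count_start,count_end Positive cell counts (cells per ml).
#' @return A percent (`percent_increase`) or a ratio (`fold_change`).
#' @export
percent_increase <- function(count_start, count_end) {
  if (any(count_start <= 0) || any(count_end <= 0)) {
    stop("cell counts must be positive")
  }
  100 * (count_end / count_start - 1)
}

#' @rdname percent_increase
#' @export
fold_change <- function(count_start, count_end) {
  if (any(count_start <= 0) || any(count_end <= 0)) {
    stop("cell counts must be positive")
  }
  count_end / count_start
}

#' Pairwise replicate concordance of protein relative abundances
#'
#' Computes Lin's concordance correlation coefficient between every pair
#' of samples over the union of their identified proteins (a protein
#' absent from a sample contributes relative abundance 0).
#'
#' @param samples List of [sip_sample()] objects after
#'   [balanced_spectral_counts()].
#' @return Symmetric matrix of concordance coefficients with unit
#'   diagonal, sample ids as dimnames.
#' @export
replicate_concordance <- function(samples) {
  stopifnot(length(samples) >= 2L)
  abund <- lapply(samples, function(s) {
    if (is.null(s$proteins) || !"relative_abundance" %in% names(s$proteins)) {
      stop("sample ", s$sample_id,
           " lacks protein abundances; run balanced_spectral_counts()")
    }
    stats::setNames(s$proteins$relative_abundance, s$proteins$protein_id)
  })
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  all_prot <- sort(unique(unlist(lapply(abund, names))))
  mat <- vapply(abund, function(a) {
    v <- stats::setNames(numeric(length(all_prot)), all_prot)
    v[names(a)] <- a
    v
  }, numeric(length(all_prot)))
  k <- length(samples)
  out <- diag(1, k)
  dimnames(out) <- list(ids, ids)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      out[i, j] <- out[j, i] <- lin_ccc(mat[, i], mat[, j])
    }
  }
  out
}

#' Read a per-sample summary table
#'
#' Reads a tab-delimited replicate summary (columns `sample_id`,
#' `location`, `incubation_h`, `n_psm`, `n_peptides`, `n_proteins`,
#' `label_frequency_pct`, `avg_enrichment_pct`), such as the reference
#' coastal-seawater experiment bundled under
#' `inst/extdata/reference_experiment/`.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_sample_summary <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Read a cell-count series table
#'
#' Columns `location`, `t_h` (hours), `cells_per_ml`. Counts must be
#' positive and time points strictly increasing within a location.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_cell_counts <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  if (any(x$cells_per_ml <= 0)) stop("cell counts must be positive")
  for (loc in unique(x$location)) {
    t <- x$t_h[x$location == loc]
    if (any(diff(t) <= 0)) stop("time points must be strictly ordered")
  }
  x
}
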