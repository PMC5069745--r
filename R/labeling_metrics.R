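# Label frequency, average enrichment, enrichment histograms.

.check_weights <- function(enrichment, weights) {
  if (is.null(weights)) weights <- rep(1, length(enrichment))
  stopifnot(length(weights) == length(enrichment), all(weights >= 0))
  weights
}

#' Label frequency of a PSM subset
#'
#' Percent of (weighted) PSMs whose \eqn{^{13}}C enrichment is at or above
#' the labeling threshold, i.e. above the natural isotope abundance. This
#' measures the breadth of de novo protein synthesis drawing on any carbon
#' source, without distinguishing direct uptake from recycling or
#' cross-feeding.
#'
#' @param enrichment Numeric vector of percent enrichments in \[0, 100\].
#' @param weights Optional non-negative weights (default 1 per PSM).
#' @param threshold Labeling threshold in percent, inclusive (default 2).
#' @return Percent in \[0, 100\], or `NA` with a warning for an empty
#'   subset (an empty subset has no defined frequency; it is not zero).
#' @export
label_frequency <- function(enrichment, weights = NULL,
                            threshold = .default_label_threshold) {
  weights <- .check_weights(enrichment, weights)
  tot <- sum(weights)
  if (length(enrichment) == 0L || tot == 0) {
    warning("label frequency undefined for an empty subset")
    return(NA_real_)
  }
  100 * sum(weights[enrichment >= threshold]) / tot
}

#' Average enrichment of the labeled PSMs in a subset
#'
#' Weighted mean percent \eqn{^{13}}C enrichment over PSMs at or above the
#' labeling threshold. High values indicate direct assimilation of the
#' labeled substrate into newly synthesized protein.
#'
#' @inheritParams label_frequency
#' @return Percent in \[threshold, 100\], or `NA` with a warning when the
#'   subset holds no labeled PSM.
#' @export
average_enrichment <- function(enrichment, weights = NULL,
                               threshold = .default_label_threshold) {
  weights <- .check_weights(enrichment, weights)
  lab <- enrichment >= threshold
  lw <- sum(weights[lab])
  if (lw == 0) {
    warning("average enrichment undefined: no labeled PSMs in subset")
    return(NA_real_)
  }
  sum(weights[lab] * enrichment[lab]) / lw
}

#' Labeling summary for a PSM subset
#'
#' Bundles total weight, labeled weight, label frequency and average
#' enrichment for any weighted subset of PSMs (a sample, a taxon within a
#' sample, a COG category within a taxon, ...).
#'
#' @inheritParams label_frequency
#' @return One-row tibble with columns `n_weight`, `labeled_weight`,
#'   `label_frequency_pct`, `average_enrichment_pct`.
#' @export
summarize_labeling <- function(enrichment, weights = NULL,
                               threshold = .default_label_threshold) {
  weights <- .check_weights(enrichment, weights)
  lab <- enrichment >= threshold
  lw <- sum(weights[lab])
  tot <- sum(weights)
  tibble(
    n_weight = tot,
    labeled_weight = lw,
    label_frequency_pct = if (tot > 0) 100 * lw / tot else NA_real_,
    average_enrichment_pct = if (lw > 0) {
      sum(weights[lab] * enrichment[lab]) / lw
    } else NA_real_
  )
}

#' Histogram of labeled spectra
#'
#' Proportion of total labeled weight falling in half-open 3\%-wide
#' enrichment bins \[4, 7), \[7, 10), ..., \[97, 100). The denominator is
#' the *total* labeled weight, including labeled mass below 4\% (and any
#' exact-100\% values), so the proportions may sum to less than 1.
#'
#' @inheritParams label_frequency
#' @param bin_width Bin width in percent (default 3).
#' @param bin_start Lower edge of the first bin (default 4).
#' @return Tibble with columns `bin_low`, `bin_high`, `proportion`, or an
#'   error when the subset holds no labeled PSM.
#' @export
enrichment_histogram <- function(enrichment, weights = NULL,
                                 threshold = .default_label_threshold,
                                 bin_width = 3, bin_start = 4) {
  weights <- .check_weights(enrichment, weights)
  lab <- enrichment >= threshold
  lw <- sum(weights[lab])
  if (lw == 0) stop("enrichment histogram undefined: no labeled PSMs")
  lo <- seq(bin_start, 100 - bin_width, by = bin_width)
  hi <- lo + bin_width
  e <- enrichment[lab]
  w <- weights[lab]
  prop <- vapply(seq_along(lo), function(i) {
    sum(w[e >= lo[i] & e < hi[i]]) / lw
  }, numeric(1))
  tibble(bin_low = lo, bin_high = hi, proportion = prop)
}

#' Mean and standard deviation over replicate values
#'
#' Arithmetic mean and sample (n-1 denominator) standard deviation, the
#' aggregation used to report replicate label frequency and average
#' enrichment.
#'
#' @param values Numeric vector of replicate percents; must be non-empty.
#' @return Named list with `mean` and `sd` (`sd` is `NA` for a single
#'   value).
#' @export
replicate_mean_sd <- function(values) {
  if (length(values) == 0L) stop("no replicate values supplied")
  list(
    mean = mean(values),
    sd = if (length(values) >= 2L) stats::sd(values) else NA_real_
  )
}

.sample_enr_weights <- function(sample, use_balanced = FALSE) {
  list(
    enrichment = sample$psms$enrichment_pct,
    weights = if (use_balanced) sample$psms$balanced_weight else
      rep(1, nrow(sample$psms))
  )
}

#' Sample-level labeling summary
#'
#' [summarize_labeling()] over all PSMs of a sample, including PSMs
#' orphaned by the two-peptide rule (sample-level spectral metrics are over
#' all spectra, not only those in identified proteins).
#'
#' @param sample A [sip_sample()].
#' @param threshold Labeling threshold in percent.
#' @return One-row tibble prefixed with `sample_id`.
#' @export
sample_labeling_summary <- function(sample,
                                    threshold = .default_label_threshold) {
  stopifnot(inherits(sample, "sip_sample"))
  ew <- .sample_enr_weights(sample)
  out <- summarize_labeling(ew$enrichment, ew$weights, threshold)
  dplyr::bind_cols(tibble(sample_id = sample$sample_id), out)
}

#' Per-group labeling summaries within a sample
#'
#' [summarize_labeling()] for each taxon (or each value of any PSM
#' annotation column) within one sample. PSMs with `NA` in the grouping
#' column are excluded.
#'
#' @param sample A [sip_sample()].
#' @param grouping `"taxon_order"` or `"taxon_genus"`.
#' @param threshold Labeling threshold in percent.
#' @return Tibble with one row per group.
#' @export
group_labeling_summaries <- function(sample,
                                     grouping = c("taxon_order",
                                                  "taxon_genus"),
                                     threshold = .default_label_threshold) {
  stopifnot(inherits(sample, "sip_sample"))
  grouping <- match.arg(grouping)
  g <- sample$psms[[grouping]]
  keep <- !is.na(g)
  idx <- split(which(keep), g[keep])
  dplyr::bind_rows(lapply(names(idx), function(gid) {
    i <- idx[[gid]]
    out <- summarize_labeling(sample$psms$enrichment_pct[i],
                              threshold = threshold)
    dplyr::bind_cols(
      tibble(sample_id = sample$sample_id, group_type = grouping,
             group_id = gid),
      out
    )
  }))
}
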