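# Permutation null distributions matched on spectral counts, Z-scores and
# inner-95% significance calls for taxa and COG categories.

#' Derive a reproducible sub-seed from a master seed and a context key
#'
#' Hashes the context strings with a 31-ary polynomial rolling hash modulo
#' 2^31 - 1 and folds in the master seed. Each (sample, grouping, group)
#' test gets its own stable stream, so adding or removing one group never
#' shifts the draws of the others.
#'
#' @param master_seed Integer master seed.
#' @param ... Context strings (coerced with `as.character`).
#' @return A single integer in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(master_seed, ...) {
  key <- paste(vapply(list(...), as.character, character(1)),
               collapse = "\r")
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 31 + cp) %% 2147483647
  as.integer((h + as.double(master_seed)) %% 2147483647)
}

# One set of permutation draws; both metrics computed per draw so taxon
# tests can share a single resampling pass. Each draw takes PSMs uniformly
# without replacement until the cumulative weight first reaches the target
# (with unit weights this is exact size matching).
.perm_draws <- function(enrichment, weights, target_weight, n_perm, seed,
                        threshold) {
  n <- length(enrichment)
  total <- sum(weights)
  if (!(target_weight > 0) || target_weight >= total) {
    stop("degenerate null: target weight (", target_weight,
         ") must lie strictly between 0 and the pool total (", total, ")")
  }
  lab <- enrichment >= threshold
  freq <- numeric(n_perm)
  avg <- rep(NA_real_, n_perm)
  set.seed(seed)
  if (length(unique(weights)) == 1L) {
    k <- ceiling(target_weight / weights[1])
    use_hash <- k <= n %/% 2 && k < n
    for (j in seq_len(n_perm)) {
      idx <- sample.int(n, k, useHash = use_hash)
      li <- lab[idx]
      nl <- sum(li)
      freq[j] <- 100 * nl / k
      if (nl > 0) avg[j] <- mean(enrichment[idx][li])
    }
  } else {
    for (j in seq_len(n_perm)) {
      p <- sample.int(n)
      k <- which(cumsum(weights[p]) >= target_weight)[1L]
      idx <- p[seq_len(k)]
      wi <- weights[idx]
      li <- lab[idx]
      lw <- sum(wi[li])
      freq[j] <- 100 * lw / sum(wi)
      if (lw > 0) avg[j] <- sum(wi[li] * enrichment[idx][li]) / lw
    }
  }
  list(label_frequency = freq, average_enrichment = avg)
}

.null_from_values <- function(values, metric, seed, target_weight, n_perm,
                              alpha) {
  ok <- values[!is.na(values)]
  q <- if (length(ok) > 0) {
    stats::quantile(ok, c(alpha / 2, 1 - alpha / 2), type = 7,
                    names = FALSE)
  } else c(NA_real_, NA_real_)
  structure(
    list(
      metric = metric, values = values,
      mean = if (length(ok) > 0) mean(ok) else NA_real_,
      sd = if (length(ok) > 1) stats::sd(ok) else NA_real_,
      q025 = q[1], q975 = q[2],
      seed = seed, target_weight = target_weight, n_perm = n_perm,
      alpha = alpha, n_undefined = sum(is.na(values))
    ),
    class = "sip_null"
  )
}

#' @export
print.sip_null <- function(x, ...) {
  cat("<sip_null> ", x$metric, ": ", x$n_perm, " permutations, mean ",
      signif(x$mean, 4), ", sd ", signif(x$sd, 4), ", inner ",
      100 * (1 - x$alpha), "% [", signif(x$q025, 4), ", ",
      signif(x$q975, 4), "]", sep = "")
  if (x$n_undefined > 0) cat(" (", x$n_undefined, " undefined draws)",
                             sep = "")
  cat("\n")
  invisible(x)
}

#' Permutation null distribution for a labeling metric
#'
#' Draws `n_perm` random subsets from a pool of weighted PSMs, each subset
#' accumulated uniformly without replacement until its weight first
#' reaches `target_weight`, and evaluates the metric on every draw. The
#' resulting distribution is the expectation under the null hypothesis
#' that labeling is independent of group membership, matched on spectral
#' counts. Draws where `average_enrichment` is undefined (no labeled PSM)
#' are recorded as `NA` and excluded from the moments; their count is
#' reported as `n_undefined`.
#'
#' @param enrichment,weights The pool's PSM enrichments and weights
#'   (weights default to 1).
#' @param target_weight Weight of the observed group being tested; must be
#'   strictly between 0 and the pool total.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; identical inputs give bit-identical draws.
#' @param metric `"label_frequency"` or `"average_enrichment"`.
#' @param threshold Labeling threshold in percent.
#' @param alpha Two-sided significance level defining the reported
#'   empirical percentiles (default 0.05: 2.5th/97.5th, linear
#'   interpolation).
#' @return A `sip_null` object: the value list plus mean, sd, `q025`,
#'   `q975`, seed, and undefined-draw count.
#' @export
draw_null <- function(enrichment, weights = NULL, target_weight,
                      n_perm = 1000, seed = 1,
                      metric = c("label_frequency", "average_enrichment"),
                      threshold = .default_label_threshold, alpha = 0.05) {
  metric <- match.arg(metric)
  weights <- .check_weights(enrichment, weights)
  draws <- .perm_draws(enrichment, weights, target_weight, n_perm, seed,
                       threshold)
  .null_from_values(draws[[metric]], metric, seed, target_weight, n_perm,
                    alpha)
}

#' Z-score of an observation against a permutation null
#'
#' `(observed - null mean) / null sd`; used to place taxa and COG
#' categories on a common scale for display.
#'
#' @param observed Observed metric value.
#' @param null A `sip_null` from [draw_null()].
#' @return The Z-score, or `NA` with a warning when the null sd is zero
#'   (no score is fabricated for a degenerate null).
#' @export
z_score <- function(observed, null) {
  stopifnot(inherits(null, "sip_null"))
  if (is.na(null$sd) || null$sd == 0) {
    warning("null distribution has zero sd; Z-score undefined")
    return(NA_real_)
  }
  (observed - null$mean) / null$sd
}

# inner-95% call, inclusive: "as extreme or more extreme" than the
# critical percentiles
.sig_call <- function(observed, q_lo, q_hi) {
  if (is.na(observed) || is.na(q_lo) || is.na(q_hi)) return(NA_character_)
  if (observed >= q_hi) "high" else if (observed <= q_lo) "low" else "ns"
}

# empirical two-sided p with add-one correction
.empirical_p <- function(observed, values) {
  ok <- values[!is.na(values)]
  if (is.na(observed) || length(ok) == 0L) return(NA_real_)
  n <- length(ok)
  p_lo <- (1 + sum(ok <= observed)) / (n + 1)
  p_hi <- (1 + sum(ok >= observed)) / (n + 1)
  min(1, 2 * min(p_lo, p_hi))
}

.group_result_row <- function(sample_id, group_type, group_id, obs, draws,
                              seed, n_perm, alpha) {
  null_f <- .null_from_values(draws$label_frequency, "label_frequency",
                              seed, obs$n_weight, n_perm, alpha)
  null_e <- .null_from_values(draws$average_enrichment,
                              "average_enrichment", seed, obs$n_weight,
                              n_perm, alpha)
  zf <- if (!is.na(null_f$sd) && null_f$sd > 0) {
    (obs$label_frequency_pct - null_f$mean) / null_f$sd
  } else NA_real_
  ze <- if (!is.na(null_e$sd) && null_e$sd > 0 &&
            !is.na(obs$average_enrichment_pct)) {
    (obs$average_enrichment_pct - null_e$mean) / null_e$sd
  } else NA_real_
  tibble(
    sample_id = sample_id, group_type = group_type, group_id = group_id,
    n_weight = obs$n_weight,
    label_frequency_pct = obs$label_frequency_pct,
    avg_enrichment_pct = obs$average_enrichment_pct,
    z_freq = zf, z_enrich = ze,
    p_freq = .empirical_p(obs$label_frequency_pct, draws$label_frequency),
    p_enrich = .empirical_p(obs$average_enrichment_pct,
                            draws$average_enrichment),
    call_freq = .sig_call(obs$label_frequency_pct, null_f$q025,
                          null_f$q975),
    call_enrich = .sig_call(obs$average_enrichment_pct, null_e$q025,
                            null_e$q975),
    n_perm = n_perm, seed = seed
  )
}

.run_group_tests <- function(sample_id, pool_enr, pool_w, group_idx,
                             group_type, threshold, n_perm, seed,
                             min_weight, alpha, adjust_p) {
  results <- dplyr::bind_rows(lapply(names(group_idx), function(gid) {
    i <- group_idx[[gid]]
    gw <- sum(pool_w[i])
    if (gw < min_weight) {
      message("skipping ", group_type, " '", gid, "' in ", sample_id,
              ": weight ", round(gw, 2), " < min_weight ", min_weight)
      return(NULL)
    }
    seed_g <- derive_seed(seed, sample_id, group_type, gid)
    obs <- summarize_labeling(pool_enr[i], pool_w[i], threshold)
    draws <- .perm_draws(pool_enr, pool_w, gw, n_perm, seed_g, threshold)
    .group_result_row(sample_id, group_type, gid, obs, draws, seed_g,
                      n_perm, alpha)
  }))
  if (nrow(results) == 0L) {
    warning("no ", group_type, " group in ", sample_id,
            " reaches min_weight = ", min_weight)
    return(results)
  }
  if (adjust_p) {
    results$p_freq_adj <- stats::p.adjust(results$p_freq, method = "BH")
    results$p_enrich_adj <- stats::p.adjust(results$p_enrich,
                                            method = "BH")
  }
  results
}

#' Test taxa within a sample for differential labeling
#'
#' For each taxonomic group in a sample, compares its observed label
#' frequency and average enrichment against a permutation null drawn from
#' the whole sample's spectra at matched spectral count ([draw_null()]).
#' Calls `high`/`low` when the observation is at or beyond the empirical
#' inner-95% critical values, and reports Z-scores against the null mean
#' and sd. No multiple-testing correction is applied by default;
#' `adjust_p = TRUE` adds Benjamini-Hochberg-adjusted empirical p-values.
#'
#' @param sample A [sip_sample()].
#' @param grouping `"taxon_order"` or `"taxon_genus"`.
#' @param threshold Labeling threshold in percent.
#' @param n_perm Permutations per group (default 1000).
#' @param seed Master seed; per-group seeds are derived with
#'   [derive_seed()].
#' @param min_weight Groups below this total weight are skipped
#'   (default 13).
#' @param alpha Two-sided significance level (default 0.05).
#' @param weight_mode `"unit"` (each PSM counts 1) or `"balanced"` (use
#'   `balanced_weight`).
#' @param adjust_p Add BH-adjusted empirical p-values (default `FALSE`).
#' @return Tibble with one row per tested group: observed metrics,
#'   Z-scores, empirical p-values, and `high`/`ns`/`low` calls for both
#'   metrics.
#' @export
test_groups <- function(sample, grouping = c("taxon_order", "taxon_genus"),
                        threshold = .default_label_threshold,
                        n_perm = 1000, seed = 1, min_weight = 13,
                        alpha = 0.05, weight_mode = c("unit", "balanced"),
                        adjust_p = FALSE) {
  stopifnot(inherits(sample, "sip_sample"))
  grouping <- match.arg(grouping)
  weight_mode <- match.arg(weight_mode)
  ew <- .sample_enr_weights(sample, weight_mode == "balanced")
  g <- sample$psms[[grouping]]
  keep <- !is.na(g)
  group_idx <- split(which(keep), g[keep])
  .run_group_tests(sample$sample_id, ew$enrichment, ew$weights, group_idx,
                   grouping, threshold, n_perm, seed, min_weight, alpha,
                   adjust_p)
}

#' Test COG categories within one taxon for differential labeling
#'
#' As [test_groups()], but the null pool is restricted to the taxon's own
#' spectra: the null hypothesis is that enrichment within the taxon is
#' independent of COG category. A PSM carrying several COG letters is a
#' member of each category (membership, not partition).
#'
#' @inheritParams test_groups
#' @param taxon_id The taxon whose spectra form the pool.
#' @param grouping Annotation level of `taxon_id`.
#' @return Tibble with one row per tested COG category; `group_id` is
#'   `"<taxon>:<letter>"`.
#' @export
test_cogs_within_taxon <- function(sample, taxon_id,
                                   grouping = c("taxon_order",
                                                "taxon_genus"),
                                   threshold = .default_label_threshold,
                                   n_perm = 1000, seed = 1,
                                   min_weight = 13, alpha = 0.05,
                                   weight_mode = c("unit", "balanced"),
                                   adjust_p = FALSE) {
  stopifnot(inherits(sample, "sip_sample"))
  grouping <- match.arg(grouping)
  weight_mode <- match.arg(weight_mode)
  in_taxon <- which(!is.na(sample$psms[[grouping]]) &
                      sample$psms[[grouping]] == taxon_id)
  if (length(in_taxon) == 0L) {
    stop("no PSMs for ", grouping, " '", taxon_id, "' in sample ",
         sample$sample_id)
  }
  ew <- .sample_enr_weights(sample, weight_mode == "balanced")
  pool_enr <- ew$enrichment[in_taxon]
  pool_w <- ew$weights[in_taxon]
  cogs <- sample$psms$cog[in_taxon]
  letters_seen <- sort(unique(unlist(cogs)))
  group_idx <- stats::setNames(
    lapply(letters_seen, function(l) {
      which(vapply(cogs, function(v) l %in% v, logical(1)))
    }),
    paste0(taxon_id, ":", letters_seen)
  )
  .run_group_tests(sample$sample_id, pool_enr, pool_w, group_idx,
                   "cog_within_taxon", threshold, n_perm, seed, min_weight,
                   alpha, adjust_p)
}
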