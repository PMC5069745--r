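# Assembled end-to-end runs: resolved configuration, output TSVs with
# reproducibility headers.

#' Pipeline run configuration
#'
#' Defaults follow the analysis the package implements: labeling threshold
#' 2\% (just above natural \eqn{^{13}}C abundance), 1000 permutations,
#' two-sided alpha 0.05 (inner 95\%), minimum group weight 13.
#'
#' @param threshold_pct Labeling threshold in percent (inclusive).
#' @param n_perm Permutations per null distribution.
#' @param alpha Two-sided significance level.
#' @param min_weight Minimum PSM weight for a group to be tested.
#' @param master_seed Master seed for all resampling.
#' @param weight_mode `"unit"` or `"balanced"` (see [test_groups()]).
#' @param cog_taxa Number of highest-weight taxa per sample to test for
#'   COG-level differential labeling.
#' @return A `sip_config` list.
#' @export
sip_config <- function(threshold_pct = 2, n_perm = 1000, alpha = 0.05,
                       min_weight = 13, master_seed = 1,
                       weight_mode = c("unit", "balanced"), cog_taxa = 3) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(threshold_pct > 0, n_perm >= 1, alpha > 0, alpha < 1,
            min_weight >= 0, cog_taxa >= 0)
  if (n_perm < 2 / alpha) {
    warning("n_perm = ", n_perm, " gives the empirical inner-",
            100 * (1 - alpha), "% percentiles a resolution coarser than ",
            "alpha; calls will be degenerate")
  }
  structure(
    list(threshold_pct = threshold_pct, n_perm = n_perm, alpha = alpha,
         min_weight = min_weight, master_seed = master_seed,
         weight_mode = weight_mode, cog_taxa = cog_taxa),
    class = "sip_config"
  )
}

.config_hash <- function(config) {
  key <- paste(names(config), vapply(config, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 31 + cp) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.run_header <- function(config) {
  paste0("proteoSIP ", as.character(packageVersion("proteoSIP")),
         " config=", .config_hash(config),
         " seed=", config$master_seed)
}

.write_with_header <- function(x, path, header) {
  writeLines(paste0("# ", header), path)
  readr::write_tsv(x, path, na = "NA", append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Run the full SIP analysis pipeline
#'
#' For each input sample: applies the two-peptide rule and balanced
#' spectral counting, computes the sample labeling summary and enrichment
#' histogram, tests taxa against the whole-sample permutation null, and
#' tests COG categories within the highest-weight taxa. Across samples it
#' computes the pairwise protein-abundance concordance matrix. All
#' outputs are TSVs carrying a header comment with the package version,
#' a hash of the resolved configuration and the master seed; a rerun with
#' identical inputs reproduces the data rows byte for byte.
#'
#' @param input Either a directory containing `*.psm.tsv` tables, a
#'   single PSM TSV path, or a (possibly named) list of [sip_sample()]
#'   objects.
#' @param out_dir Output directory (created if needed).
#' @param config A [sip_config()].
#' @return Named list of the output tibbles (`summary`, `histograms`,
#'   `taxon_tests`, `cog_tests`, `concordance`), invisibly; files are
#'   written under `out_dir`.
#' @export
run_pipeline <- function(input, out_dir, config = sip_config()) {
  stopifnot(inherits(config, "sip_config"))
  if (is.character(input)) {
    paths <- if (length(input) == 1L && dir.exists(input)) {
      list.files(input, pattern = "\\.psm\\.tsv$", full.names = TRUE)
    } else input
    if (length(paths) == 0L) stop("no *.psm.tsv files found in ", input)
    samples <- do.call(c, lapply(sort(paths), read_psm_table))
  } else {
    samples <- input
    if (inherits(samples, "sip_sample")) samples <- list(samples)
  }
  if (length(samples) == 0L) stop("no input samples")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  header <- .run_header(config)
  thr <- config$threshold_pct

  samples <- lapply(samples, function(s) {
    balanced_spectral_counts(apply_two_peptide_rule(s))
  })

  summary_tbl <- dplyr::bind_rows(lapply(samples, sample_labeling_summary,
                                         threshold = thr))
  hist_tbl <- dplyr::bind_rows(lapply(samples, function(s) {
    ew <- .sample_enr_weights(s)
    tryCatch(
      dplyr::bind_cols(tibble(sample_id = s$sample_id),
                       enrichment_histogram(ew$enrichment, ew$weights, thr)),
      error = function(e) {
        warning("histogram skipped for ", s$sample_id, ": ",
                conditionMessage(e))
        NULL
      }
    )
  }))

  taxon_tbl <- dplyr::bind_rows(lapply(samples, function(s) {
    test_groups(s, "taxon_order", threshold = thr,
                n_perm = config$n_perm, seed = config$master_seed,
                min_weight = config$min_weight, alpha = config$alpha,
                weight_mode = config$weight_mode)
  }))

  cog_tbl <- dplyr::bind_rows(lapply(samples, function(s) {
    g <- s$psms$taxon_order
    w <- tapply(rep(1, nrow(s$psms)), g, sum)
    top <- names(sort(w, decreasing = TRUE))
    top <- top[seq_len(min(config$cog_taxa, length(top)))]
    dplyr::bind_rows(lapply(top, function(tx) {
      tryCatch(
        test_cogs_within_taxon(
          s, tx, "taxon_order", threshold = thr, n_perm = config$n_perm,
          seed = config$master_seed, min_weight = config$min_weight,
          alpha = config$alpha, weight_mode = config$weight_mode
        ),
        error = function(e) {
          warning("COG tests skipped for ", tx, " in ", s$sample_id,
                  ": ", conditionMessage(e))
          NULL
        }
      )
    }))
  }))

  conc_tbl <- NULL
  if (length(samples) >= 2L) {
    m <- replicate_concordance(samples)
    conc_tbl <- as_tibble(as.data.frame(as.table(m)),
                          .name_repair = "minimal")
    names(conc_tbl) <- c("sample_a", "sample_b", "ccc")
    conc_tbl <- filter(conc_tbl,
                       as.character(.data$sample_a) <
                         as.character(.data$sample_b))
    conc_tbl$sample_a <- as.character(conc_tbl$sample_a)
    conc_tbl$sample_b <- as.character(conc_tbl$sample_b)
    conc_tbl <- arrange(conc_tbl, .data$sample_a, .data$sample_b)
  }

  .write_with_header(summary_tbl, file.path(out_dir, "sample_summary.tsv"),
                     header)
  .write_with_header(hist_tbl, file.path(out_dir, "histograms.tsv"),
                     header)
  .write_with_header(taxon_tbl, file.path(out_dir, "taxon_tests.tsv"),
                     header)
  if (nrow(cog_tbl) > 0) {
    .write_with_header(cog_tbl, file.path(out_dir, "cog_tests.tsv"),
                       header)
  }
  write_protein_table(samples, file.path(out_dir, "protein_abundance.tsv"),
                      header_comment = header)
  if (!is.null(conc_tbl)) {
    .write_with_header(conc_tbl, file.path(out_dir, "concordance.tsv"),
                       header)
  }
  resolved <- unclass(config)
  resolved$package_version <- as.character(packageVersion("proteoSIP"))
  resolved$config_hash <- .config_hash(config)
  jsonlite::write_json(resolved, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(summary = summary_tbl, histograms = hist_tbl,
                 taxon_tests = taxon_tbl, cog_tests = cog_tbl,
                 concordance = conc_tbl))
}
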