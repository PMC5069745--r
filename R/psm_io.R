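# PSM table model, readers/writers, two-peptide rule, balanced spectral counts.

.psm_dialect_cols <- c(
  "sample_id", "spectrum_id", "peptide", "proteins", "enrichment_pct",
  "taxon_order", "taxon_genus", "cog"
)

#' Construct a SIP sample
#'
#' A `sip_sample` bundles the PSMs of one mass-spectrometry run with the
#' protein table derived from them and free-form metadata (location label,
#' incubation hours, parse diagnostics).
#'
#' @param sample_id Sample identifier.
#' @param psms Tibble with columns `sample_id`, `spectrum_id`, `peptide`,
#'   `protein_ids` (list of character vectors), `enrichment_pct`,
#'   `taxon_order`, `taxon_genus`, `cog` (list of single-letter character
#'   vectors), `balanced_weight`, `orphaned`.
#' @param proteins Protein table (or `NULL` before
#'   [apply_two_peptide_rule()] has been run).
#' @param metadata Named list.
#' @return An object of class `sip_sample`.
#' @export
sip_sample <- function(sample_id, psms, proteins = NULL, metadata = list()) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  psms <- as_tibble(psms)
  needed <- c("sample_id", "spectrum_id", "peptide", "protein_ids",
              "enrichment_pct", "taxon_order", "taxon_genus", "cog")
  missing <- setdiff(needed, names(psms))
  if (length(missing) > 0) {
    stop("psms is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!"balanced_weight" %in% names(psms)) psms$balanced_weight <- 1
  if (!"orphaned" %in% names(psms)) psms$orphaned <- NA
  if (any(psms$enrichment_pct < 0 | psms$enrichment_pct > 100)) {
    stop("enrichment_pct must lie in [0, 100]")
  }
  if (any(psms$balanced_weight < 0)) stop("balanced_weight must be >= 0")
  if (any(lengths(psms$protein_ids) == 0)) {
    stop("every PSM must map to at least one protein")
  }
  structure(
    list(sample_id = sample_id, psms = psms, proteins = proteins,
         metadata = metadata),
    class = "sip_sample"
  )
}

#' @export
print.sip_sample <- function(x, ...) {
  cat("<sip_sample> ", x$sample_id, ": ", nrow(x$psms), " PSMs", sep = "")
  if (!is.null(x$proteins)) {
    cat(", ", nrow(x$proteins), " identified proteins", sep = "")
  }
  cat("\n")
  invisible(x)
}

.split_cog <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, "")[[1]]
  })
}

.join_cog <- function(x) {
  vapply(x, function(v) paste(v, collapse = ""), character(1))
}

#' Read an annotated PSM table
#'
#' Reads the tab-delimited PSM dialect produced by SIP database searches:
#' one row per PSM with columns `sample_id`, `spectrum_id`, `peptide`,
#' `proteins` (semicolon-joined protein group), `enrichment_pct`,
#' `taxon_order`, `taxon_genus` and `cog` (concatenated single letters,
#' empty or NA for none). Lines starting with `#` are ignored.
#'
#' Rows whose enrichment falls outside \[0, 100\] are rejected with a
#' warning; the count is recorded in each sample's
#' `metadata$n_rejected`. Non-numeric enrichment values are an error that
#' reports the offending line numbers.
#'
#' @param path Path to a TSV file.
#' @return A named list of [sip_sample()] objects, one per distinct
#'   `sample_id` in the file.
#' @export
read_psm_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#", na = "NA", progress = FALSE
  )
  missing <- setdiff(.psm_dialect_cols, names(raw))
  if (length(missing) > 0) {
    stop("PSM table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  enr <- suppressWarnings(as.numeric(raw$enrichment_pct))
  bad_num <- which(is.na(enr) & !is.na(raw$enrichment_pct))
  if (length(bad_num) > 0) {
    stop("non-numeric enrichment_pct at line(s) ",
         paste(bad_num + 1L, collapse = ", "), " of ", path)
  }
  out_of_range <- which(is.na(enr) | enr < 0 | enr > 100)
  if (length(out_of_range) > 0) {
    warning(length(out_of_range), " row(s) rejected: enrichment_pct ",
            "missing or outside [0, 100]")
  }
  keep <- setdiff(seq_len(nrow(raw)), out_of_range)
  psms <- tibble(
    sample_id = raw$sample_id[keep],
    spectrum_id = raw$spectrum_id[keep],
    peptide = raw$peptide[keep],
    protein_ids = strsplit(raw$proteins[keep], ";", fixed = TRUE),
    enrichment_pct = enr[keep],
    taxon_order = raw$taxon_order[keep],
    taxon_genus = raw$taxon_genus[keep],
    cog = .split_cog(raw$cog[keep]),
    balanced_weight = 1,
    orphaned = NA
  )
  n_rej_by <- table(raw$sample_id[out_of_range])
  out <- lapply(split(seq_len(nrow(psms)), psms$sample_id), function(idx) {
    sid <- psms$sample_id[idx[1]]
    sip_sample(
      sample_id = sid,
      psms = psms[idx, , drop = FALSE],
      metadata = list(
        source = path,
        n_rejected = if (sid %in% names(n_rej_by)) {
          as.integer(n_rej_by[[sid]])
        } else 0L,
        natural_abundance_pct = NATURAL_13C_PCT
      )
    )
  })
  out[order(names(out))]
}

#' Write PSM tables in the pipeline's TSV dialect
#'
#' Inverse of [read_psm_table()]: `read_psm_table(write_psm_table(x, f))`
#' reproduces the PSM fields.
#'
#' @param samples A `sip_sample` or list of them.
#' @param path Output TSV path.
#' @param header_comment Optional character vector of comment lines
#'   (written prefixed with `# `).
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(samples, path, header_comment = NULL) {
  if (inherits(samples, "sip_sample")) samples <- list(samples)
  psms <- dplyr::bind_rows(lapply(samples, function(s) s$psms))
  out <- tibble(
    sample_id = psms$sample_id,
    spectrum_id = psms$spectrum_id,
    peptide = psms$peptide,
    proteins = vapply(psms$protein_ids, paste, character(1), collapse = ";"),
    enrichment_pct = psms$enrichment_pct,
    taxon_order = psms$taxon_order,
    taxon_genus = psms$taxon_genus,
    cog = .join_cog(psms$cog)
  )
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), path)
    readr::write_tsv(out, path, na = "NA", append = TRUE, col_names = TRUE,
                     progress = FALSE)
  } else {
    readr::write_tsv(out, path, na = "NA", progress = FALSE)
  }
  invisible(path)
}

# protein -> peptide map derived from the PSMs alone (so the filter is
# idempotent: reapplying recomputes the same map from unchanged PSMs)
.protein_peptide_map <- function(psms) {
  pairs <- tibble(
    peptide = rep(psms$peptide, lengths(psms$protein_ids)),
    protein_id = unlist(psms$protein_ids)
  )
  distinct(pairs)
}

.mode_or_na <- function(x) {
  x <- unique(x[!is.na(x)])
  if (length(x) == 1L) x else NA_character_
}

#' Apply the two-peptide rule
#'
#' A protein is identified only with at least one unique peptide (mapping
#' to no other protein) and at least two distinct peptides in total (one
#' unique plus one more, shared or unique). Builds the protein table from
#' the PSMs, removes failing proteins, and flags PSMs whose whole protein
#' group was removed as `orphaned`. Orphaned PSMs are excluded from
#' protein-level outputs but retained for sample-level labeling metrics.
#'
#' A protein's taxonomy and COG letters are aggregated from its PSMs; a
#' taxonomically mixed protein group gets `NA` taxonomy and the conflict is
#' counted in `metadata$n_taxon_conflicts`.
#'
#' @param sample A [sip_sample()].
#' @return The sample with `proteins` filled in and `psms$orphaned` set.
#' @export
apply_two_peptide_rule <- function(sample) {
  stopifnot(inherits(sample, "sip_sample"))
  psms <- sample$psms
  if (nrow(psms) == 0L) {
    warning("empty PSM table for sample ", sample$sample_id)
    sample$proteins <- tibble(
      protein_id = character(0), taxon_order = character(0),
      taxon_genus = character(0), cog = character(0),
      n_unique_peptides = integer(0), n_total_peptides = integer(0)
    )
    return(sample)
  }
  map <- .protein_peptide_map(psms)
  pep_nprot <- count(map, .data$peptide, name = "n_prot")
  map <- left_join(map, pep_nprot, by = "peptide")
  per_prot <- summarise(
    group_by(map, .data$protein_id),
    n_unique_peptides = sum(.data$n_prot == 1L),
    n_total_peptides = dplyr::n(),
    .groups = "drop"
  )
  per_prot <- filter(per_prot,
                     .data$n_unique_peptides >= 1L,
                     .data$n_total_peptides >= 2L)
  identified <- per_prot$protein_id

  # PSM-derived annotation per protein
  ann_pairs <- tibble(
    protein_id = unlist(psms$protein_ids),
    taxon_order = rep(psms$taxon_order, lengths(psms$protein_ids)),
    taxon_genus = rep(psms$taxon_genus, lengths(psms$protein_ids)),
    cog = rep(.join_cog(psms$cog), lengths(psms$protein_ids))
  )
  ann <- summarise(
    group_by(ann_pairs, .data$protein_id),
    mixed = length(unique(.data$taxon_order[!is.na(.data$taxon_order)])) > 1L,
    taxon_order = .mode_or_na(.data$taxon_order),
    taxon_genus = .mode_or_na(.data$taxon_genus),
    cog = paste(sort(unique(unlist(strsplit(.data$cog, "")))), collapse = ""),
    .groups = "drop"
  )
  proteins <- left_join(per_prot, ann, by = "protein_id")
  sample$metadata$n_taxon_conflicts <-
    sum(proteins$mixed, na.rm = TRUE)
  proteins$mixed <- NULL

  id_set <- identified
  sample$psms$orphaned <- !vapply(
    psms$protein_ids, function(p) any(p %in% id_set), logical(1)
  )
  sample$proteins <- arrange(
    proteins[, c("protein_id", "taxon_order", "taxon_genus", "cog",
                 "n_unique_peptides", "n_total_peptides")],
    .data$protein_id
  )
  sample
}

#' Balanced spectral counting
#'
#' Distributes each non-orphaned PSM's weight (1 by default) over the
#' identified proteins of its group: entirely to one protein when the
#' peptide has a single identified candidate; otherwise proportionally to
#' each candidate's unique-peptide PSM weight, or equally when all
#' candidates lack unique PSMs. Adds `balanced_count` and
#' `relative_abundance` columns to the protein table; orphaned weight is
#' accumulated in `metadata$unassigned_weight`. The per-PSM
#' `balanced_weight` used by sample-level metrics is left untouched.
#'
#' @param sample A [sip_sample()] after [apply_two_peptide_rule()].
#' @return The sample with protein abundances filled in.
#' @export
balanced_spectral_counts <- function(sample) {
  stopifnot(inherits(sample, "sip_sample"))
  if (is.null(sample$proteins)) {
    stop("apply_two_peptide_rule() must be run before ",
         "balanced_spectral_counts()")
  }
  psms <- sample$psms
  proteins <- sample$proteins
  id_set <- proteins$protein_id
  counts <- stats::setNames(numeric(length(id_set)), id_set)

  cand <- lapply(psms$protein_ids, function(p) p[p %in% id_set])
  n_cand <- lengths(cand)
  w <- psms$balanced_weight

  # pass 1: PSMs with a single identified candidate define unique counts
  uniq_idx <- which(n_cand == 1L)
  if (length(uniq_idx) > 0) {
    uc <- tapply(w[uniq_idx], unlist(cand[uniq_idx]), sum)
    counts[names(uc)] <- counts[names(uc)] + as.numeric(uc)
  }
  unique_counts <- counts

  # pass 2: shared PSMs split proportionally to unique counts
  for (i in which(n_cand > 1L)) {
    p <- cand[[i]]
    u <- unique_counts[p]
    share <- if (sum(u) > 0) u / sum(u) else rep(1 / length(p), length(p))
    counts[p] <- counts[p] + w[i] * share
  }

  unassigned <- sum(w[n_cand == 0L])
  proteins$balanced_count <- as.numeric(counts[proteins$protein_id])
  total <- sum(proteins$balanced_count)
  proteins$relative_abundance <-
    if (total > 0) proteins$balanced_count / total else 0
  sample$proteins <- proteins
  sample$metadata$unassigned_weight <- unassigned
  if (unassigned > 0) {
    message(sample$sample_id, ": ", round(unassigned, 3),
            " PSM weight unassigned (orphaned protein groups)")
  }
  sample
}

#' Write the protein-level output table
#'
#' @param samples A `sip_sample` or list of them, after
#'   [balanced_spectral_counts()].
#' @param path Output TSV path.
#' @param header_comment Optional comment lines.
#' @return `path`, invisibly.
#' @export
write_protein_table <- function(samples, path, header_comment = NULL) {
  if (inherits(samples, "sip_sample")) samples <- list(samples)
  out <- dplyr::bind_rows(lapply(samples, function(s) {
    p <- s$proteins
    tibble(
      sample_id = s$sample_id, protein_id = p$protein_id,
      taxon_order = p$taxon_order, taxon_genus = p$taxon_genus,
      cog = p$cog, n_unique_peptides = p$n_unique_peptides,
      n_total_peptides = p$n_total_peptides,
      balanced_count = p$balanced_count,
      relative_abundance = p$relative_abundance
    )
  }))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), path)
    readr::write_tsv(out, path, na = "NA", append = TRUE, col_names = TRUE,
                     progress = FALSE)
  } else {
    readr::write_tsv(out, path, na = "NA", progress = FALSE)
  }
  invisible(path)
}
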