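# In-code fixtures.

# Build a sip_sample from parallel vectors; proteins as ";"-joined strings,
# cog as concatenated letters.
make_sample <- function(sample_id = "S1", peptide, proteins, enrichment,
                        taxon_order = NA_character_,
                        taxon_genus = NA_character_, cog = "",
                        weight = 1) {
  n <- length(enrichment)
  psms <- tibble::tibble(
    sample_id = sample_id,
    spectrum_id = sprintf("sc%03d", seq_len(n)),
    peptide = rep_len(peptide, n),
    protein_ids = strsplit(rep_len(proteins, n), ";", fixed = TRUE),
    enrichment_pct = enrichment,
    taxon_order = rep_len(taxon_order, n),
    taxon_genus = rep_len(taxon_genus, n),
    cog = lapply(rep_len(cog, n), function(s) {
      if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, "")[[1]]
    }),
    balanced_weight = rep_len(weight, n),
    orphaned = NA
  )
  sip_sample(sample_id, psms)
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

psm_header <- paste("sample_id", "spectrum_id", "peptide", "proteins",
                    "enrichment_pct", "taxon_order", "taxon_genus", "cog",
                    sep = "\t")

psm_line <- function(sample, spectrum, peptide, proteins, enr,
                     order = "NA", genus = "NA", cog = "") {
  paste(sample, spectrum, peptide, proteins, enr, order, genus, cog,
        sep = "\t")
}
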