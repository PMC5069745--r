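test_that("PSM tables parse, reject out-of-range rows, and flag bad input", {
  path <- write_tsv_lines(c(
    psm_header,
    psm_line("A", "s1", "PEPTIDEK", "P1", 1.1, "Rhodobacterales",
             "Roseobacter", "J"),
    psm_line("A", "s2", "PEPTIDER", "P1;P2", 35, "Rhodobacterales", "NA",
             "EJ"),
    psm_line("A", "s3", "AKAKAKAK", "P2", 0, "NA", "NA", "")
  ))
  samples <- read_psm_table(path)
  expect_length(samples, 1L)
  s <- samples[["A"]]
  expect_s3_class(s, "sip_sample")
  expect_equal(nrow(s$psms), 3L)
  expect_equal(s$psms$protein_ids[[2]], c("P1", "P2"))
  expect_equal(s$psms$cog[[2]], c("E", "J"))
  expect_equal(s$psms$cog[[3]], character(0))
  expect_true(is.na(s$psms$taxon_order[3]))
  expect_equal(s$metadata$n_rejected, 0L)

  # enrichment outside [0, 100] -> row rejected, counted
  path2 <- write_tsv_lines(c(
    psm_header,
    psm_line("A", "s1", "PEPK", "P1", 101),
    psm_line("A", "s2", "PEPR", "P1", 50)
  ))
  expect_warning(samples2 <- read_psm_table(path2), "rejected")
  expect_equal(nrow(samples2[["A"]]$psms), 1L)
  expect_equal(samples2[["A"]]$metadata$n_rejected, 1L)

  # non-numeric enrichment -> error naming the line
  path3 <- write_tsv_lines(c(
    psm_header,
    psm_line("A", "s1", "PEPK", "P1", 50),
    psm_line("A", "s2", "PEPR", "P1", "lots")
  ))
  expect_error(read_psm_table(path3), "line\\(s\\) 3")

  # missing required column -> error naming the column
  path4 <- write_tsv_lines(c(
    "sample_id\tspectrum_id\tpeptide\tproteins\ttaxon_order\ttaxon_genus\tcog",
    "A\ts1\tPEPK\tP1\tNA\tNA\t"
  ))
  expect_error(read_psm_table(path4), "enrichment_pct")
})

test_that("write/read round-trip is the identity on a synthetic table", {
  cfg <- synthetic_config(default_community(), n_psm = 50, seed = 11)
  s <- generate_sample(cfg, "RT1")$sample
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(s, path)
  back <- read_psm_table(path)[["RT1"]]
  for (col in c("sample_id", "spectrum_id", "peptide", "enrichment_pct",
                "taxon_order", "taxon_genus")) {
    expect_equal(back$psms[[col]], s$psms[[col]], info = col)
  }
  expect_equal(back$psms$protein_ids, s$psms$protein_ids)
  expect_equal(back$psms$cog, s$psms$cog)
  expect_equal(back$metadata$n_rejected, 0L)
})

test_that("two-peptide rule keeps unique+shared proteins and drops singletons", {
  # A: two unique peptides -> kept; B: one unique, nothing else -> dropped;
  # C: one unique + one peptide shared with A -> kept
  s <- make_sample(
    peptide = c("AAA", "BBB", "CCC", "DDD", "EEE"),
    proteins = c("A", "A", "B", "C", "C;A"),
    enrichment = c(1, 1, 1, 1, 1)
  )
  s <- apply_two_peptide_rule(s)
  expect_setequal(s$proteins$protein_id, c("A", "C"))
  expect_equal(s$proteins$n_unique_peptides[s$proteins$protein_id == "C"], 1L)
  # B's only PSM is orphaned; kept in the PSM table
  expect_equal(sum(s$psms$orphaned), 1L)
  expect_equal(s$psms$peptide[s$psms$orphaned], "CCC")

  # idempotence
  s2 <- apply_two_peptide_rule(s)
  expect_identical(s$proteins, s2$proteins)
  expect_identical(s$psms$orphaned, s2$psms$orphaned)

  # taxonomically mixed protein group -> NA taxonomy, conflict counted
  m <- make_sample(
    peptide = c("AAA", "BBB"),
    proteins = c("X", "X"),
    enrichment = c(1, 1),
    taxon_order = c("Rhodobacterales", "SAR11")
  )
  m <- apply_two_peptide_rule(m)
  expect_true(is.na(m$proteins$taxon_order))
  expect_equal(m$metadata$n_taxon_conflicts, 1L)

  e <- make_sample(peptide = character(0), proteins = character(0),
                   enrichment = numeric(0))
  expect_warning(apply_two_peptide_rule(e), "empty")
})

test_that("balanced spectral counting distributes shared weight proportionally", {
  # A has 4 unique-peptide PSMs, B has 1; the shared PSM splits 0.8/0.2
  s <- make_sample(
    peptide = c("A1", "A1", "A2", "A2", "B1", "SH"),
    proteins = c("A", "A", "A", "A", "B", "A;B"),
    enrichment = rep(1, 6)
  )
  s <- balanced_spectral_counts(apply_two_peptide_rule(s))
  bc <- setNames(s$proteins$balanced_count, s$proteins$protein_id)
  expect_equal(unname(bc["A"]), 4 + 0.8)
  expect_equal(unname(bc["B"]), 1 + 0.2)
  # conservation and normalization
  expect_equal(sum(bc) + s$metadata$unassigned_weight, nrow(s$psms))
  expect_equal(sum(s$proteins$relative_abundance), 1, tolerance = 1e-9)

  # all-zero unique-PSM weight -> equal split of shared weight
  s0 <- make_sample(
    peptide = c("U1", "S1", "U2", "S1"),
    proteins = c("P", "P;Q", "Q", "P;Q"),
    enrichment = rep(1, 4),
    weight = c(0, 1, 0, 1)
  )
  s0 <- balanced_spectral_counts(apply_two_peptide_rule(s0))
  bc0 <- setNames(s0$proteins$balanced_count, s0$proteins$protein_id)
  expect_equal(unname(bc0["P"]), 1)
  expect_equal(unname(bc0["Q"]), 1)

  # weight of orphaned PSMs lands in the unassigned bucket
  so <- make_sample(
    peptide = c("A1", "A2", "L1"),
    proteins = c("A", "A", "LONE"),
    enrichment = rep(1, 3)
  )
  expect_message(
    so <- balanced_spectral_counts(apply_two_peptide_rule(so)),
    "unassigned"
  )
  expect_equal(so$metadata$unassigned_weight, 1)
  expect_equal(sum(so$proteins$balanced_count), 2)
})

test_that("conservation holds on a larger synthetic sample", {
  cfg <- synthetic_config(default_community(), n_psm = 2000, seed = 5)
  s <- generate_sample(cfg, "CONS")$sample
  s <- balanced_spectral_counts(apply_two_peptide_rule(s))
  expect_equal(sum(s$proteins$balanced_count) + s$metadata$unassigned_weight,
               nrow(s$psms), tolerance = 1e-9)
  expect_equal(sum(s$proteins$relative_abundance), 1, tolerance = 1e-9)
})
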