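# Ground-truthed synthetic PSM tables emulating SIP search output: a
# dominant unlabeled mass near natural 13C abundance, labeled enrichment
# mixtures on the 1% search grid, taxon/COG structure and shared peptides.

#' Describe one taxon of a synthetic community
#'
#' @param taxon_order,taxon_genus Taxonomy labels (`taxon_genus` may be
#'   `NA`).
#' @param proportion Fraction of community PSMs from this taxon.
#' @param p_label Probability that one of its PSMs is labeled.
#' @param mixture Data frame with columns `weight`, `mode`, `spread`
#'   describing the labeled-enrichment mixture: each component is a normal
#'   with mean `mode` and sd `spread`, truncated to
#'   \[threshold, 100\] and snapped to the 1\% search grid. Weights must
#'   sum to 1.
#' @param cog_probs Named numeric vector of per-letter COG probabilities
#'   for this taxon's proteins; may sum to less than 1 (remainder = no
#'   category assigned).
#' @param n_proteins Number of proteins in the taxon's reference set.
#' @param shared_peptide_fraction Fraction of PSMs drawn from peptides
#'   shared by two proteins of the taxon, in \[0, 1).
#' @return A `taxon_profile` list.
#' @export
taxon_profile <- function(taxon_order, taxon_genus = NA_character_,
                          proportion, p_label,
                          mixture = data.frame(weight = 1, mode = 35,
                                               spread = 8),
                          cog_probs = c(J = 0.25, C = 0.15, P = 0.12,
                                        E = 0.12, G = 0.10, O = 0.06,
                                        S = 0.08),
                          n_proteins = 60,
                          shared_peptide_fraction = 0.2) {
  stopifnot(proportion >= 0, proportion <= 1, p_label >= 0, p_label <= 1,
            n_proteins >= 2,
            shared_peptide_fraction >= 0, shared_peptide_fraction < 1)
  mixture <- as.data.frame(mixture)
  if (!all(c("weight", "mode", "spread") %in% names(mixture))) {
    stop("mixture needs columns weight, mode, spread")
  }
  if (abs(sum(mixture$weight) - 1) > 1e-8) {
    stop("mixture weights must sum to 1")
  }
  if (sum(cog_probs) > 1 + 1e-8) stop("cog_probs must sum to <= 1")
  structure(
    list(taxon_order = taxon_order, taxon_genus = taxon_genus,
         proportion = proportion, p_label = p_label, mixture = mixture,
         cog_probs = cog_probs, n_proteins = n_proteins,
         shared_peptide_fraction = shared_peptide_fraction),
    class = "taxon_profile"
  )
}

#' Configuration of a synthetic sample
#'
#' @param profiles List of [taxon_profile()]s; proportions must sum to 1.
#' @param n_psm PSMs per sample (default 20000).
#' @param threshold Labeling threshold in percent.
#' @param seed Master seed; all downstream draws derive from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(profiles, n_psm = 20000,
                             threshold = .default_label_threshold,
                             seed = 1) {
  stopifnot(n_psm > 0)
  if (inherits(profiles, "taxon_profile")) profiles <- list(profiles)
  props <- vapply(profiles, function(p) p$proportion, numeric(1))
  if (abs(sum(props) - 1) > 1e-8) {
    stop("taxon proportions must sum to 1 (got ", sum(props), ")")
  }
  structure(
    list(profiles = profiles, n_psm = n_psm, threshold = threshold,
         seed = seed),
    class = "synthetic_config"
  )
}

#' Draw enrichment values for one taxon
#'
#' Unlabeled PSMs sit at natural abundance (1.109\%) plus uniform jitter
#' of half a percent, always strictly below the threshold. Labeled PSMs
#' are drawn from the profile's truncated-normal mixture, rounded to the
#' 1\% search grid and clipped to \[threshold, 100\]. Uses the current RNG
#' state; callers seed it.
#'
#' @param profile A [taxon_profile()].
#' @param labeled Logical vector (one flag per draw).
#' @param threshold Labeling threshold in percent.
#' @return Numeric vector of percent enrichments, `length(labeled)` long.
#' @export
sample_enrichment <- function(profile, labeled,
                              threshold = .default_label_threshold) {
  n <- length(labeled)
  out <- numeric(n)
  n_un <- sum(!labeled)
  if (n_un > 0) {
    u <- NATURAL_13C_PCT + runif(n_un, -0.5, 0.5)
    while (any(u >= threshold)) {
      redo <- u >= threshold
      u[redo] <- NATURAL_13C_PCT + runif(sum(redo), -0.5, 0.5)
    }
    out[!labeled] <- u
  }
  n_lab <- sum(labeled)
  if (n_lab > 0) {
    mix <- profile$mixture
    comp <- sample.int(nrow(mix), n_lab, replace = TRUE,
                       prob = mix$weight)
    v <- rnorm(n_lab, mean = mix$mode[comp], sd = mix$spread[comp])
    v <- round(v)
    v <- pmin(pmax(v, ceiling(threshold)), 100)
    out[labeled] <- v
  }
  out
}

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.random_peptides <- function(n, min_len = 9, max_len = 16) {
  lens <- sample(seq(min_len, max_len), n, replace = TRUE)
  peps <- vapply(lens, function(l) {
    paste(sample(.AA, l, replace = TRUE), collapse = "")
  }, character(1))
  while (anyDuplicated(peps)) {
    dup <- which(duplicated(peps))
    peps[dup] <- vapply(lens[dup] + 1L, function(l) {
      paste(sample(.AA, l, replace = TRUE), collapse = "")
    }, character(1))
  }
  peps
}

.taxon_tag <- function(taxon_order, i) {
  paste0(gsub("[^A-Za-z0-9]", "", substr(taxon_order, 1, 6)), i)
}

# Fixed protein/peptide repertoire shared by all samples generated from
# one config, so replicates overlap in protein identifications.
.build_repertoire <- function(config) {
  set.seed(derive_seed(config$seed, "repertoire"))
  lapply(seq_along(config$profiles), function(t) {
    pr <- config$profiles[[t]]
    np <- pr$n_proteins
    tag <- .taxon_tag(pr$taxon_order, t)
    protein_id <- sprintf("%s_P%03d", tag, seq_len(np))
    # one COG letter (or none) per protein
    letters_p <- names(pr$cog_probs)
    probs <- c(pr$cog_probs, none = max(0, 1 - sum(pr$cog_probs)))
    drawn <- sample(c(letters_p, ""), np, replace = TRUE, prob = probs)
    n_unique <- 3L
    unique_pep <- .random_peptides(np * n_unique)
    n_shared <- if (pr$shared_peptide_fraction > 0) {
      max(1L, round(np * pr$shared_peptide_fraction))
    } else 0L
    shared_pep <- character(0)
    shared_pair <- matrix(integer(0), ncol = 2)
    if (n_shared > 0) {
      shared_pep <- .random_peptides(n_shared, min_len = 17, max_len = 24)
      shared_pair <- t(vapply(seq_len(n_shared), function(i) {
        sort(sample.int(np, 2))
      }, integer(2)))
    }
    shared_by_prot <- lapply(seq_len(np), function(p) {
      which(shared_pair[, 1] == p | shared_pair[, 2] == p)
    })
    # long-tailed per-protein abundance propensities (log-normal), fixed in
    # the repertoire so replicate samples share true protein abundances
    prot_prob <- stats::rlnorm(np, meanlog = 0, sdlog = 1)
    prot_prob <- prot_prob / sum(prot_prob)
    list(profile = pr, protein_id = protein_id, cog = drawn,
         n_unique = n_unique, unique_pep = unique_pep,
         shared_pep = shared_pep, shared_pair = shared_pair,
         shared_by_prot = shared_by_prot, prot_prob = prot_prob)
  })
}

.mixture_spec <- function(mixture) {
  paste(sprintf("%g@%g±%g", mixture$weight, mixture$mode,
                mixture$spread), collapse = "|")
}

#' Generate one synthetic sample
#'
#' Draws `n_psm` PSMs: taxa from the configured proportions, labeled flags
#' Bernoulli(`p_label`), enrichments via [sample_enrichment()], peptides
#' and protein groups from a repertoire fixed by the config seed (so
#' samples generated from one config share proteins). Deterministic given
#' the config seed and `sample_id`.
#'
#' @param config A [synthetic_config()].
#' @param sample_id Sample identifier (also seeds the sample's stream).
#' @param metadata Extra metadata stored on the sample.
#' @param repertoire Optional pre-built repertoire (internal; built from
#'   the config when `NULL`).
#' @return List with `sample` (a [sip_sample()]) and `truth` (tibble of
#'   per-taxon true proportions, `p_label` and mixture specs).
#' @export
generate_sample <- function(config, sample_id, metadata = list(),
                            repertoire = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(repertoire)) repertoire <- .build_repertoire(config)
  set.seed(derive_seed(config$seed, "sample", sample_id))
  n <- config$n_psm
  props <- vapply(config$profiles, function(p) p$proportion, numeric(1))
  taxon_of <- sample.int(length(props), n, replace = TRUE, prob = props)

  parts <- lapply(seq_along(config$profiles), function(t) {
    rows <- which(taxon_of == t)
    nt <- length(rows)
    if (nt == 0L) return(NULL)
    rep_t <- repertoire[[t]]
    pr <- config$profiles[[t]]  # repertoire fixes structure, not labeling
    np <- length(rep_t$protein_id)
    prot <- sample.int(np, nt, replace = TRUE, prob = rep_t$prot_prob)
    labeled <- runif(nt) < pr$p_label
    enr <- sample_enrichment(pr, labeled, config$threshold)
    can_share <- lengths(rep_t$shared_by_prot)[prot] > 0
    use_shared <- can_share & (runif(nt) < pr$shared_peptide_fraction)
    pep <- character(nt)
    groups <- vector("list", nt)
    cogs <- vector("list", nt)
    u_idx <- which(!use_shared)
    if (length(u_idx) > 0) {
      slot <- sample.int(rep_t$n_unique, length(u_idx), replace = TRUE)
      pep[u_idx] <- rep_t$unique_pep[(prot[u_idx] - 1L) * rep_t$n_unique +
                                       slot]
      groups[u_idx] <- as.list(rep_t$protein_id[prot[u_idx]])
      cogs[u_idx] <- lapply(rep_t$cog[prot[u_idx]], function(l) {
        if (nzchar(l)) l else character(0)
      })
    }
    s_idx <- which(use_shared)
    if (length(s_idx) > 0) {
      sp <- vapply(prot[s_idx], function(p) {
        cand <- rep_t$shared_by_prot[[p]]
        cand[sample.int(length(cand), 1)]
      }, integer(1))
      pep[s_idx] <- rep_t$shared_pep[sp]
      groups[s_idx] <- lapply(sp, function(i) {
        rep_t$protein_id[rep_t$shared_pair[i, ]]
      })
      cogs[s_idx] <- lapply(sp, function(i) {
        l <- rep_t$cog[rep_t$shared_pair[i, ]]
        sort(unique(l[nzchar(l)]))
      })
    }
    tibble(
      row = rows, peptide = pep, protein_ids = groups,
      enrichment_pct = enr, taxon_order = pr$taxon_order,
      taxon_genus = pr$taxon_genus, cog = cogs
    )
  })
  psms <- dplyr::bind_rows(parts)
  psms <- psms[order(psms$row), , drop = FALSE]
  psms$row <- NULL
  psms <- dplyr::bind_cols(
    tibble(sample_id = sample_id,
           spectrum_id = sprintf("scan_%06d", seq_len(n))),
    psms
  )
  psms$balanced_weight <- 1
  psms$orphaned <- NA

  truth <- dplyr::bind_rows(lapply(config$profiles, function(pr) {
    tibble(sample_id = sample_id, taxon_order = pr$taxon_order,
           taxon_genus = pr$taxon_genus, proportion = pr$proportion,
           p_label = pr$p_label, mixture = .mixture_spec(pr$mixture))
  }))
  list(
    sample = sip_sample(sample_id, psms,
                        metadata = c(metadata,
                                     list(threshold = config$threshold,
                                          seed = config$seed))),
    truth = truth
  )
}

.scale_p_label <- function(profiles, factor) {
  lapply(profiles, function(p) {
    p$p_label <- min(1, p$p_label * factor)
    p
  })
}

.set_mixture <- function(profiles, mixture) {
  lapply(profiles, function(p) {
    p$mixture <- mixture
    p
  })
}

#' Default synthetic community
#'
#' Eight marine bacterioplankton taxa with abundances and labeling
#' probabilities chosen so the community label frequency at the first time
#' point is about 2.4\%, dominated by fast-assimilating Alteromonadales
#' and Rhodobacterales and a large weakly-labeled Flavobacteriales
#' fraction; the labeled-enrichment mixture is unimodal near 35\%.
#'
#' @param mixture Labeled-enrichment mixture applied to every taxon.
#' @return List of [taxon_profile()]s with proportions summing to 1.
#' @export
default_community <- function(mixture = data.frame(weight = 1, mode = 35,
                                                   spread = 8)) {
  specs <- list(
    list("Flavobacteriales", "Polaribacter", 0.30, 0.010),
    list("Rhodobacterales", "Roseobacter", 0.20, 0.045),
    list("SAR11", "Pelagibacter", 0.15, 0.005),
    list("Alteromonadales", "Alteromonas", 0.10, 0.070),
    list("Oceanospirillales", "Oceanospirillum", 0.05, 0.030),
    list("SAR86", NA_character_, 0.10, 0.008),
    list("Methylophilales", "Methylophilus", 0.05, 0.015),
    list("Other", NA_character_, 0.05, 0.020)
  )
  lapply(specs, function(s) {
    taxon_profile(taxon_order = s[[1]], taxon_genus = s[[2]],
                  proportion = s[[3]], p_label = s[[4]],
                  mixture = mixture)
  })
}

.bimodal_mixture <- data.frame(weight = c(0.5, 0.5), mode = c(17, 60),
                               spread = c(4, 8))

#' Default experiment design
#'
#' Emulates the study design the analysis targets: two coastal locations,
#' two incubation time points (15 h and 32 h). The first location (MB) has
#' three replicates per time point (MB1a-c, MB2a-c), the second (OR) a
#' single sample per time point (OR1, OR2). Between time points labeling
#' probabilities roughly double at MB, and the labeled-enrichment mixture
#' shifts from unimodal (mode 35\%) to bimodal (modes 17\% and 60\%); the
#' OR community is labeled about four times more heavily and bimodal at
#' both time points.
#'
#' @param seed Master seed.
#' @param n_psm PSMs per sample (default 20000).
#' @return List with `samples` (tibble: `sample_id`, `location`,
#'   `incubation_h`, `profile_set`), `profile_sets`, `n_psm`, `threshold`,
#'   `seed`.
#' @export
default_experiment_config <- function(seed = 1, n_psm = 20000) {
  base <- default_community()
  profile_sets <- list(
    mb_t1 = base,
    mb_t2 = .set_mixture(.scale_p_label(base, 2.0), .bimodal_mixture),
    or_t1 = .set_mixture(.scale_p_label(base, 3.9), .bimodal_mixture),
    or_t2 = .set_mixture(.scale_p_label(base, 4.3), .bimodal_mixture)
  )
  samples <- tibble(
    sample_id = c("MB1a", "MB1b", "MB1c", "MB2a", "MB2b", "MB2c",
                  "OR1", "OR2"),
    location = c(rep("MB", 6), "OR", "OR"),
    incubation_h = c(15, 15, 15, 32, 32, 32, 15, 32),
    profile_set = c(rep("mb_t1", 3), rep("mb_t2", 3), "or_t1", "or_t2")
  )
  list(samples = samples, profile_sets = profile_sets, n_psm = n_psm,
       threshold = .default_label_threshold, seed = seed)
}

#' Generate a full synthetic experiment
#'
#' Generates every sample of an experiment design
#' ([default_experiment_config()] by default) from a single protein
#' repertoire, so replicates share protein identifications. Deterministic
#' given the design's seed.
#'
#' @param config An experiment design list (see
#'   [default_experiment_config()]).
#' @return List with `samples` (named list of [sip_sample()]), `truth`
#'   (tibble over all samples), and `config`.
#' @export
generate_experiment <- function(config = default_experiment_config()) {
  base_cfg <- synthetic_config(config$profile_sets[[1]],
                               n_psm = config$n_psm,
                               threshold = config$threshold,
                               seed = config$seed)
  repertoire <- .build_repertoire(base_cfg)
  out <- lapply(seq_len(nrow(config$samples)), function(i) {
    row <- config$samples[i, ]
    cfg_i <- synthetic_config(config$profile_sets[[row$profile_set]],
                              n_psm = config$n_psm,
                              threshold = config$threshold,
                              seed = config$seed)
    generate_sample(cfg_i, row$sample_id,
                    metadata = list(location = row$location,
                                    incubation_h = row$incubation_h),
                    repertoire = repertoire)
  })
  samples <- lapply(out, function(x) x$sample)
  names(samples) <- config$samples$sample_id
  truth <- dplyr::bind_rows(lapply(out, function(x) x$truth))
  list(samples = samples, truth = truth, config = config)
}

#' Write a synthetic experiment to disk
#'
#' One PSM TSV per sample (`<sample_id>.psm.tsv`, the [read_psm_table()]
#' dialect) plus `ground_truth.tsv`. Byte-identical across runs with the
#' same design.
#'
#' @param experiment Output of [generate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in experiment$samples) {
    write_psm_table(s, file.path(dir, paste0(s$sample_id, ".psm.tsv")))
  }
  readr::write_tsv(experiment$truth, file.path(dir, "ground_truth.tsv"),
                   na = "NA", progress = FALSE)
  invisible(dir)
}
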