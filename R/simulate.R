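#' Configuration for a synthetic FMT trial
#'
#' Defaults describe a four-arm capsule FMT trial in IBS-D: ~11 subjects
#' per arm, six stool donors shared across the FMT arms, stool sampled at
#' baseline, during antibiotics (antibiotic arms only), week 1 and week 10,
#' sequenced to 10,000 reads per sample. Community profiles are log-normal
#' relative abundances over three OTU pools: recipient-only, shared
#' (present in donors and recipients — these can never count as engrafted),
#' and donor-unique (the identifiable engraftment signal). Post-FMT
#' profiles mix a fraction `transfer_fraction[arm]` of donor-unique
#' material into the recovered recipient community, so the expected
#' abundance-mode engraftment equals that fraction exactly.
#'
#' @param n_per_arm Subjects per arm (default 11).
#' @param arms Arm labels; `transfer_fraction` must be named by these.
#' @param transfer_fraction Named per-arm donor-unique abundance fraction
#'   mixed into post-FMT samples (defaults 0.15, 0.05, 0.02, 0).
#' @param abx_arms Arms receiving antibiotic pretreatment (these get a
#'   `during_abx` sample and the depletion applied).
#' @param n_donors Number of donors (default 6).
#' @param n_otus_recipient,n_otus_shared,n_otus_donor_unique Pool sizes.
#' @param abx_depletion Multiplicative depletion factor in (0, 1] applied
#'   to affected taxa during antibiotics (default 0.1).
#' @param abx_affected_fraction Fraction of a subject's taxa affected
#'   (default 0.5).
#' @param lost_fraction Fraction of depleted taxa permanently lost at the
#'   post-FMT timepoints (default 0: full recovery toward baseline).
#' @param depth Multinomial reads per sample (default 10000).
#' @param lognormal_sigma Log-scale SD of relative-abundance profiles
#'   (default 1).
#' @param clinical_effect Named per-arm shift added to the mean IBS-SSS
#'   change (default all 0: arm-independent, i.e. a null clinical effect).
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_arm = 11,
                       arms = c("FMT", "R-FMT", "CM-FMT", "placebo"),
                       transfer_fraction = c("FMT" = 0.15, "R-FMT" = 0.05,
                                             "CM-FMT" = 0.02, "placebo" = 0),
                       abx_arms = c("R-FMT", "CM-FMT"),
                       n_donors = 6,
                       n_otus_recipient = 120,
                       n_otus_shared = 60,
                       n_otus_donor_unique = 60,
                       abx_depletion = 0.1,
                       abx_affected_fraction = 0.5,
                       lost_fraction = 0,
                       depth = 10000,
                       lognormal_sigma = 1,
                       clinical_effect = NULL,
                       seed) {
  if (missing(seed)) abort("sim_config requires an explicit seed")
  if (!all(arms %in% names(transfer_fraction))) {
    abort("transfer_fraction must be named for every arm")
  }
  transfer_fraction <- transfer_fraction[arms]
  if (any(transfer_fraction < 0 | transfer_fraction > 1)) {
    abort("transfer fractions must lie in [0, 1]")
  }
  if (abx_depletion <= 0 || abx_depletion > 1) {
    abort("abx_depletion must lie in (0, 1]")
  }
  if (any(transfer_fraction > 0) && n_otus_donor_unique < 1) {
    abort("donor-unique pool is empty but a transfer fraction is positive")
  }
  if (depth < 1) abort("depth must be >= 1")
  clinical_effect <- clinical_effect %||% setNames(rep(0, length(arms)), arms)
  structure(list(
    n_per_arm = n_per_arm, arms = arms,
    transfer_fraction = transfer_fraction, abx_arms = abx_arms,
    n_donors = n_donors, n_otus_recipient = n_otus_recipient,
    n_otus_shared = n_otus_shared, n_otus_donor_unique = n_otus_donor_unique,
    abx_depletion = abx_depletion,
    abx_affected_fraction = abx_affected_fraction,
    lost_fraction = lost_fraction, depth = depth,
    lognormal_sigma = lognormal_sigma,
    clinical_effect = clinical_effect[arms], seed = as.integer(seed)),
    class = "sim_config")
}

lognormal_profile <- function(n, sigma) {
  w <- rlnorm(n, meanlog = 0, sdlog = sigma)
  w / sum(w)
}

SYNTH_ORDERS <- c("Clostridiales", "Bacteroidales", "Lactobacillales",
                  "Bifidobacteriales", "Enterobacterales")

#' Simulate a complete synthetic FMT trial
#'
#' Generates donor stool samples, recipient samples at every scheduled
#' timepoint, ground-truth engraftment per subject, and clinical records.
#' Construction guarantees: donor-unique OTUs have probability zero in
#' every baseline profile (so any observed engrafted donor-unique OTU is a
#' true transfer); the during-antibiotics profile is the baseline with the
#' depletion factor applied to the affected taxa and renormalised (Shannon
#' decreases in expectation); post-FMT profiles are
#' `(1 - f) * recovered baseline + f * donor-unique mixture`, so the
#' expected engrafted abundance share equals `f`. All samples are drawn
#' multinomially at the configured depth. Identical seeds give
#' bit-identical datasets.
#'
#' @param config A [sim_config()].
#' @return A list of class `fmt_sim`: `table` (an [otu_table] with
#'   synthetic order-level taxonomy), `meta` (sample metadata), `truth`
#'   (per-subject tibble: arm, transfer fraction, transferred OTU ids,
#'   expected engrafted share), `clinical` (per-subject records), `config`.
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  withr::with_seed(cf$seed, {
    otu_rec <- sprintf("OTU_R%03d", seq_len(cf$n_otus_recipient))
    otu_shr <- if (cf$n_otus_shared > 0) {
      sprintf("OTU_S%03d", seq_len(cf$n_otus_shared))
    } else character()
    otu_don <- if (cf$n_otus_donor_unique > 0) {
      sprintf("OTU_D%03d", seq_len(cf$n_otus_donor_unique))
    } else character()
    all_otus <- c(otu_rec, otu_shr, otu_don)

    # donor communities over shared + donor-unique pools
    donor_ids <- sprintf("D%02d", seq_len(cf$n_donors))
    donor_profiles <- lapply(donor_ids, function(d) {
      p <- lognormal_profile(length(otu_shr) + length(otu_don),
                             cf$lognormal_sigma)
      setNames(p, c(otu_shr, otu_don))
    })
    names(donor_profiles) <- donor_ids
    # capsule pool: donor-unique component of the admixed material
    donor_mix <- Reduce(`+`, donor_profiles) / length(donor_profiles)
    unique_mix <- donor_mix[otu_don]
    if (length(unique_mix)) unique_mix <- unique_mix / sum(unique_mix)

    counts <- list(); meta <- list(); truth <- list(); clin <- list()
    draw <- function(profile) {
      full <- setNames(numeric(length(all_otus)), all_otus)
      full[names(profile)] <- profile
      as.integer(rmultinom(1, cf$depth, full))
    }
    for (d in donor_ids) {
      counts[[d]] <- draw(donor_profiles[[d]])
      meta[[d]] <- tibble(sample_id = d, subject_id = d, arm = "donor",
                          timepoint = "donor", donor_ids = NA_character_)
    }

    subj_id <- 0
    for (arm in cf$arms) {
      f <- cf$transfer_fraction[[arm]]
      for (i in seq_len(cf$n_per_arm)) {
        subj_id <- subj_id + 1
        sub <- sprintf("P%03d", subj_id)
        base_otus <- c(otu_rec, otu_shr)
        base <- setNames(lognormal_profile(length(base_otus),
                                           cf$lognormal_sigma), base_otus)
        tps <- list(baseline = base)
        recovered <- base
        if (arm %in% cf$abx_arms) {
          affected <- runif(length(base)) < cf$abx_affected_fraction
          abx <- base
          abx[affected] <- abx[affected] * cf$abx_depletion
          tps$during_abx <- abx / sum(abx)
          lost <- affected & runif(length(base)) < cf$lost_fraction
          recovered <- base
          recovered[lost] <- 0
          recovered <- recovered / sum(recovered)
        }
        post <- (1 - f) * recovered
        if (f > 0) {
          post <- c(post, f * unique_mix)
        }
        tps$week1 <- post
        tps$week10 <- post
        for (tp in names(tps)) {
          sid <- paste0(sub, "_", tp)
          counts[[sid]] <- draw(tps[[tp]])
          meta[[sid]] <- tibble(sample_id = sid, subject_id = sub, arm = arm,
                                timepoint = tp,
                                donor_ids = if (arm == "placebo") "" else
                                  paste(donor_ids, collapse = ";"))
        }
        truth[[sub]] <- tibble(
          subject_id = sub, arm = arm, transfer_fraction = f,
          transferred_otus = list(if (f > 0) otu_don else character()),
          expected_share_week1 = 100 * f, expected_share_week10 = 100 * f)

        eff <- cf$clinical_effect[[arm]]
        sss0 <- min(500, max(175, round(rnorm(1, 310, 60))))
        sss10 <- min(500, max(0, round(sss0 + rnorm(1, -80 + eff, 110))))
        qol0 <- min(100, max(0, round(rnorm(1, 48, 18), 1)))
        qol10 <- min(100, max(0, round(qol0 + rnorm(1, 11, 20), 1)))
        clin[[sub]] <- tibble(
          subject_id = sub, arm = arm,
          ibs_sss_baseline = sss0, ibs_sss_week10 = sss10,
          ibs_qol_baseline = qol0, ibs_qol_week10 = qol10,
          gis_week10 = sample(1:7, 1, prob = c(1, 1, 2, 4, 4, 3, 2)),
          adequate_relief_week10 = runif(1) < 0.4)
      }
    }

    m <- do.call(rbind, counts)
    rownames(m) <- names(counts); colnames(m) <- all_otus
    taxonomy <- tibble(
      otu_id = all_otus,
      domain = "Bacteria",
      phylum = NA_character_, class = NA_character_,
      order = sample(c(SYNTH_ORDERS, NA_character_), length(all_otus),
                     replace = TRUE, prob = c(0.35, 0.25, 0.12, 0.08, 0.1, 0.1)),
      family = NA_character_, genus = NA_character_)
    structure(list(
      table = otu_table(m, taxonomy = taxonomy),
      meta = dplyr::bind_rows(meta),
      truth = dplyr::bind_rows(truth),
      clinical = dplyr::bind_rows(clin),
      config = cf), class = "fmt_sim")
  })
}

#' @export
print.fmt_sim <- function(x, ...) {
  cat(sprintf(
    "# synthetic FMT trial: %d arms x %d subjects, %d donors, %d OTUs, depth %d, seed %d\n",
    length(x$config$arms), x$config$n_per_arm, x$config$n_donors,
    length(otu_ids(x$table)), x$config$depth, x$config$seed))
  invisible(x)
}

#' Write a simulated trial to a fixture directory
#'
#' Emits `otu_table.tsv` (QIIME-classic orientation), `metadata.tsv`,
#' `taxonomy.tsv` (semicolon lineages), `clinical.tsv` and
#' `ground_truth.json`. Regenerating with the same seed reproduces the
#' files byte for byte.
#'
#' @param sim An `fmt_sim` from [simulate_trial()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(sim, out_dir) {
  stopifnot(inherits(sim, "fmt_sim"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(sim$table, file.path(out_dir, "otu_table.tsv"))
  readr::write_tsv(sim$meta, file.path(out_dir, "metadata.tsv"),
                   progress = FALSE)
  tax <- otu_taxonomy(sim$table)
  lineage <- apply(as.matrix(tax[TAXONOMY_RANKS]), 1, function(r) {
    paste(dplyr::coalesce(r, ""), collapse = ";")
  })
  writeLines(paste(tax$otu_id, lineage, sep = "\t"),
             file.path(out_dir, "taxonomy.tsv"), useBytes = TRUE)
  readr::write_tsv(sim$clinical, file.path(out_dir, "clinical.tsv"),
                   progress = FALSE)
  truth <- sim$truth
  jsonlite::write_json(
    lapply(seq_len(nrow(truth)), function(i) list(
      subject_id = truth$subject_id[i], arm = truth$arm[i],
      transfer_fraction = truth$transfer_fraction[i],
      transferred_otus = truth$transferred_otus[[i]],
      expected_share_week1 = truth$expected_share_week1[i],
      expected_share_week10 = truth$expected_share_week10[i])),
    file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
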