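#' Donor OTUs engrafted in a recipient
#'
#' An OTU counts as engrafted when it is present in the donor material and
#' in the recipient's post-FMT sample but absent from the recipient's
#' pre-FMT baseline sample (collected before any antibiotics):
#' `(donor intersect post) setminus pre`.
#'
#' @param donor_present,pre_present,post_present Character vectors of OTU
#'   ids present in the donor pool, the baseline sample, and the post-FMT
#'   sample.
#' @return Character vector of engrafted OTU ids.
#' @export
#' @examples
#' engrafted_otus(c("A", "B", "C"), c("C", "D"), c("A", "C", "D"))
engrafted_otus <- function(donor_present, pre_present, post_present) {
  setdiff(intersect(unique(donor_present), unique(post_present)),
          unique(pre_present))
}

#' Engraftment as a percentage
#'
#' Three denominators are offered because trial reports rarely state one:
#' * `"abundance"` (default): share of post-FMT reads carried by engrafted
#'   OTUs — scale-free and robust to sequencing depth;
#' * `"donor_richness"`: engrafted OTUs as a fraction of the donor OTU set;
#' * `"post_richness"`: engrafted OTUs as a fraction of OTUs present
#'   post-FMT.
#'
#' @param engrafted Character vector of engrafted OTU ids (a subset of
#'   `donor_present`).
#' @param donor_present Character vector, the donor OTU set.
#' @param post_counts Named integer vector of post-FMT sample counts
#'   (names are OTU ids); total must be positive.
#' @param mode Denominator, see above.
#' @return A percentage in \[0, 100\], or `NA` (with a warning) for
#'   `donor_richness` with an empty donor set.
#' @export
engraftment_percent <- function(engrafted, donor_present, post_counts,
                                mode = c("abundance", "donor_richness",
                                         "post_richness")) {
  mode <- match.arg(mode)
  if (length(setdiff(engrafted, donor_present))) {
    abort("engrafted OTUs must be a subset of the donor set")
  }
  if (mode == "abundance") {
    total <- sum(post_counts)
    if (total <= 0) abort("post-FMT sample has zero total count")
    return(100 * sum(post_counts[names(post_counts) %in% engrafted]) / total)
  }
  if (mode == "donor_richness") {
    if (length(donor_present) == 0) {
      warn("empty donor set: donor_richness engraftment undefined")
      return(NA_real_)
    }
    return(100 * length(engrafted) / length(unique(donor_present)))
  }
  post_present <- names(post_counts)[post_counts > 0]
  if (length(post_present) == 0) abort("post-FMT sample has zero total count")
  100 * length(engrafted) / length(post_present)
}

#' Average engraftment over the two post-FMT timepoints
#'
#' The primary engraftment outcome is the mean of the week-1 and week-10
#' percentages. A subject with only one post-FMT sample keeps that single
#' value, flagged; a subject with neither is missing.
#'
#' @param percent_w1,percent_w10 Numeric vectors of per-timepoint
#'   percentages (`NA` for a missing sample); recycled to common length.
#' @return A tibble: `percent_avg`, `n_timepoints`, `single_timepoint`.
#' @export
average_engraftment <- function(percent_w1, percent_w10) {
  k <- max(length(percent_w1), length(percent_w10))
  w1 <- rep_len(as.numeric(percent_w1), k)
  w10 <- rep_len(as.numeric(percent_w10), k)
  n <- (!is.na(w1)) + (!is.na(w10))
  avg <- ifelse(n == 0, NA_real_,
                (dplyr::coalesce(w1, 0) + dplyr::coalesce(w10, 0)) / pmax(n, 1))
  tibble(percent_avg = avg, n_timepoints = n, single_timepoint = n == 1)
}

subject_donor_set <- function(meta, subject, donor_sets,
                              donor_policy = c("union", "listed")) {
  donor_policy <- match.arg(donor_policy)
  if (donor_policy == "union") return(unique(unlist(donor_sets)))
  ids <- meta$donor_ids[meta$subject_id == subject & meta$timepoint != "donor"]
  ids <- unique(unlist(strsplit(ids[!is.na(ids) & nzchar(ids)], ";", fixed = TRUE)))
  unique(unlist(donor_sets[intersect(names(donor_sets), ids)]))
}

#' Per-subject engraftment from an OTU table and sample metadata
#'
#' For each recipient subject, forms the donor, baseline-presence and
#' post-FMT presence sets from the (filtered) OTU table and computes the
#' week-1, week-10 and averaged engraftment percentages.
#'
#' Metadata must carry one row per sample: `sample_id`, `subject_id`, `arm`,
#' `timepoint` (one of `baseline`, `during_abx`, `week1`, `week10`,
#' `donor`), and optionally `donor_ids` (semicolon-delimited donor subject
#' ids administered to the subject). Donor samples are rows with
#' `timepoint == "donor"`. Subjects lacking a baseline sample, or lacking
#' both post-FMT samples, are excluded with a warning.
#'
#' @param table A filtered [otu_table].
#' @param meta Sample metadata tibble (see Details).
#' @param mode Engraftment denominator, see [engraftment_percent()].
#' @param presence_floor Optional within-sample relative-abundance floor for
#'   presence calls (default 0: any nonzero count).
#' @param donor_policy `"union"` (default; the donor set is the union over
#'   all donor samples, matching a pooled-donor capsule program) or
#'   `"listed"` (union over the donors named in the subject's `donor_ids`).
#' @return A tibble of class `tbl_engraftment`, one row per analysable
#'   subject: `subject_id`, `arm`, `n_engrafted_w1`, `n_engrafted_w10`,
#'   `percent_w1`, `percent_w10`, `percent_avg`, `single_timepoint`, `mode`.
#'   Excluded subjects and reasons are in the `"exclusions"` attribute.
#' @export
compute_engraftment <- function(table, meta,
                                mode = c("abundance", "donor_richness",
                                         "post_richness"),
                                presence_floor = 0,
                                donor_policy = c("union", "listed")) {
  mode <- match.arg(mode)
  donor_policy <- match.arg(donor_policy)
  meta <- as_tibble(meta)
  meta <- dplyr::filter(meta, .data$sample_id %in% otu_samples(table))
  pres <- presence_sets(table, presence_floor = presence_floor)
  counts_by_sample <- split(setNames(table$count, table$otu_id),
                            factor(table$sample_id, levels = otu_samples(table)))

  donor_meta <- dplyr::filter(meta, .data$timepoint == "donor")
  donor_sets <- setNames(pres[donor_meta$sample_id], donor_meta$subject_id)

  recip <- dplyr::filter(meta, .data$timepoint != "donor")
  subjects <- unique(recip$subject_id)
  exclusions <- tibble(subject_id = character(), reason = character())
  rows <- purrr::map(subjects, function(sub) {
    sm <- dplyr::filter(recip, .data$subject_id == sub)
    base_id <- sm$sample_id[sm$timepoint == "baseline"]
    if (length(base_id) != 1) {
      exclusions <<- dplyr::add_row(exclusions, subject_id = sub,
                                    reason = "no unique baseline sample")
      return(NULL)
    }
    donor_set <- subject_donor_set(meta, sub, donor_sets, donor_policy)
    pre_set <- pres[[base_id]]
    one_tp <- function(tp) {
      sid <- sm$sample_id[sm$timepoint == tp]
      if (length(sid) != 1) return(list(n = NA_integer_, pct = NA_real_))
      eng <- engrafted_otus(donor_set, pre_set, pres[[sid]])
      stopifnot(length(intersect(eng, pre_set)) == 0)  # invariant
      pct <- engraftment_percent(eng, donor_set, counts_by_sample[[sid]],
                                 mode = mode)
      list(n = length(eng), pct = pct)
    }
    w1 <- one_tp("week1"); w10 <- one_tp("week10")
    if (is.na(w1$pct) && is.na(w10$pct)) {
      exclusions <<- dplyr::add_row(exclusions, subject_id = sub,
                                    reason = "no post-FMT stool sample")
      return(NULL)
    }
    avg <- average_engraftment(w1$pct, w10$pct)
    tibble(subject_id = sub, arm = sm$arm[1],
           n_engrafted_w1 = w1$n, n_engrafted_w10 = w10$n,
           percent_w1 = w1$pct, percent_w10 = w10$pct,
           percent_avg = avg$percent_avg,
           single_timepoint = avg$single_timepoint, mode = mode)
  })
  if (nrow(exclusions)) {
    warn(sprintf("excluded %d subject(s) from engraftment: %s",
                 nrow(exclusions),
                 paste(exclusions$subject_id, exclusions$reason,
                       sep = ": ", collapse = "; ")))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "exclusions") <- exclusions
  class(out) <- c("tbl_engraftment", class(out))
  out
}

FMT_ARMS <- c("FMT", "R-FMT", "CM-FMT")

#' Compare engraftment across FMT arms
#'
#' Kruskal-Wallis omnibus test on the averaged engraftment percentages over
#' the (by default three) FMT arms, followed by Dunn's pairwise posttest
#' (unadjusted, two-sided). Arms with fewer than 2 subjects are dropped
#' with a warning.
#'
#' @param results A `tbl_engraftment` (or any data frame with `arm` and
#'   `percent_avg`).
#' @param arms Arms to compare (default the three FMT arms; placebo is not
#'   part of the engraftment contrast).
#' @param adjust Dunn p-value adjustment, `"none"` (default) or
#'   `"bonferroni"`.
#' @return An object of class `engraft_arm_test` with elements `omnibus`
#'   (tibble: H, df, p), `pairwise` (Dunn results) and `medians` (per-arm n
#'   and median). [tidy()] returns the pairwise table, [glance()] the
#'   omnibus row.
#' @export
compare_engraftment_by_arm <- function(results, arms = FMT_ARMS,
                                       adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  d <- results |>
    as_tibble() |>
    dplyr::filter(.data$arm %in% arms, !is.na(.data$percent_avg))
  sizes <- d |> dplyr::count(.data$arm)
  small <- sizes$arm[sizes$n < 2]
  if (length(small)) {
    warn(sprintf("arm(s) with < 2 subjects excluded: %s",
                 paste(small, collapse = ", ")))
    d <- dplyr::filter(d, !.data$arm %in% small)
  }
  if (dplyr::n_distinct(d$arm) < 2) abort("need >= 2 arms with >= 2 subjects")
  medians <- d |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(n = dplyr::n(), median = median(.data$percent_avg),
                     .groups = "drop")
  omni <- kruskal_wallis(d$percent_avg, d$arm)
  pairwise <- if (dplyr::n_distinct(d$arm) >= 3) {
    dunn_posttest(d$percent_avg, d$arm, adjust = adjust)
  } else {
    tibble(group1 = character(), group2 = character(),
           statistic = numeric(), p.value = numeric())
  }
  structure(list(omnibus = omni, pairwise = pairwise, medians = medians),
            class = "engraft_arm_test")
}

#' @export
print.engraft_arm_test <- function(x, ...) {
  cat("Engraftment comparison across arms\n")
  cat(sprintf("  Kruskal-Wallis H = %.3f, df = %d, p = %.4g\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p.value))
  cat("  Medians:\n")
  for (i in seq_len(nrow(x$medians))) {
    cat(sprintf("    %-8s n = %2d  median = %.2f%%\n",
                x$medians$arm[i], x$medians$n[i], x$medians$median[i]))
  }
  if (nrow(x$pairwise)) {
    cat("  Dunn posttest (two-sided, unadjusted unless requested):\n")
    for (i in seq_len(nrow(x$pairwise))) {
      cat(sprintf("    %s vs %s: z = %.3f, p = %.4g\n",
                  x$pairwise$group1[i], x$pairwise$group2[i],
                  x$pairwise$statistic[i], x$pairwise$p.value[i]))
    }
  }
  invisible(x)
}

#' @export
tidy.engraft_arm_test <- function(x, ...) x$pairwise

#' @export
glance.engraft_arm_test <- function(x, ...) x$omnibus

#' Compare engraftment between clinical responders and non-responders
#'
#' Two-sided Mann-Whitney U test on the averaged engraftment percentage.
#'
#' @param results A `tbl_engraftment`.
#' @param responders A data frame with `subject_id` and a logical
#'   `responder` column (or a named logical vector).
#' @return A one-row tibble: `statistic` (U), `p.value`, `method`,
#'   `n_responder`, `n_nonresponder`, `median_responder`,
#'   `median_nonresponder`; all-`NA` with a warning when a class is empty.
#' @export
compare_engraftment_by_response <- function(results, responders) {
  d <- as_tibble(results)
  if (!is.data.frame(responders)) {
    responders <- tibble(subject_id = names(responders),
                         responder = as.logical(responders))
  }
  d <- d |>
    dplyr::inner_join(as_tibble(responders), by = "subject_id") |>
    dplyr::filter(!is.na(.data$percent_avg), !is.na(.data$responder))
  a <- d$percent_avg[d$responder]
  b <- d$percent_avg[!d$responder]
  if (length(a) == 0 || length(b) == 0) {
    warn("a response class is empty; comparison undefined")
    return(tibble(statistic = NA_real_, p.value = NA_real_,
                  method = NA_character_,
                  n_responder = length(a), n_nonresponder = length(b),
                  median_responder = median(a), median_nonresponder = median(b)))
  }
  mw <- mann_whitney_u(a, b)
  tibble(mw, n_responder = length(a), n_nonresponder = length(b),
         median_responder = median(a), median_nonresponder = median(b))
}

#' @export
autoplot.tbl_engraftment <- function(object, ...) {
  d <- dplyr::filter(as_tibble(object), !is.na(.data$percent_avg))
  ggplot(d, aes(x = .data$arm, y = .data$percent_avg)) +
    geom_boxplot(outlier.shape = NA, fill = "grey90") +
    geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    labs(x = NULL, y = "Engraftment (% of post-FMT reads)",
         title = "Donor-OTU engraftment averaged over week 1 and week 10") +
    theme_minimal()
}
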