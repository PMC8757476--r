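#' Shannon diversity index
#'
#' \eqn{H = -\sum_i p_i \ln p_i} over taxa with nonzero counts, in nats.
#' Zero counts contribute nothing; an all-zero vector is an error.
#'
#' @param counts Non-negative numeric vector of taxon counts.
#' @return Shannon index in nats, in `[0, ln(richness)]`.
#' @export
#' @examples
#' shannon(c(25, 25, 25, 25))  # ln 4
shannon <- function(counts) {
  if (any(counts < 0)) abort("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) abort("all-zero count vector: Shannon undefined")
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Per-sample Shannon diversity joined with sample metadata
#'
#' @param table An [otu_table].
#' @param meta Sample metadata (`sample_id`, `subject_id`, `arm`,
#'   `timepoint`).
#' @param min_depth Optional minimum total reads; shallower samples are
#'   dropped with a warning (off by default — no depth correction is applied
#'   anywhere unless requested).
#' @return A tibble of class `tbl_diversity`: `sample_id`, `subject_id`,
#'   `arm`, `timepoint`, `depth`, `shannon`.
#' @export
sample_diversity <- function(table, meta, min_depth = 0) {
  div <- table |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(depth = sum(.data$count),
                     shannon = shannon(.data$count), .groups = "drop")
  if (min_depth > 0) {
    shallow <- div$sample_id[div$depth < min_depth]
    if (length(shallow)) {
      warn(sprintf("dropping %d sample(s) below %d reads: %s",
                   length(shallow), min_depth, paste(shallow, collapse = ", ")))
      div <- dplyr::filter(div, .data$depth >= min_depth)
    }
  }
  out <- as_tibble(meta) |>
    dplyr::select("sample_id", "subject_id", "arm", "timepoint") |>
    dplyr::inner_join(div, by = "sample_id")
  class(out) <- c("tbl_diversity", class(out))
  out
}

#' Paired comparison of diversity between two timepoints
#'
#' Two-sided paired t-test on within-subject Shannon differences
#' (`timepoint_b` minus `timepoint_a`). Subjects missing either timepoint
#' are excluded and counted. When every within-subject difference is zero
#' the t statistic is undefined; the result is reported non-significant
#' with a `zero_variance` flag.
#'
#' @param diversity A `tbl_diversity` from [sample_diversity()].
#' @param timepoint_a,timepoint_b Timepoint labels to compare.
#' @param arms Optional subset of arms.
#' @return A one-row tibble: `estimate` (mean difference b - a),
#'   `statistic`, `df`, `p.value`, `n_pairs`, `n_excluded`, `zero_variance`.
#' @export
compare_diversity <- function(diversity, timepoint_a, timepoint_b,
                              arms = NULL) {
  d <- as_tibble(diversity)
  if (!is.null(arms)) d <- dplyr::filter(d, .data$arm %in% arms)
  wide <- d |>
    dplyr::filter(.data$timepoint %in% c(timepoint_a, timepoint_b)) |>
    dplyr::select("subject_id", "timepoint", "shannon") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "shannon")
  for (tp in c(timepoint_a, timepoint_b)) {
    if (!tp %in% names(wide)) wide[[tp]] <- NA_real_
  }
  complete <- !is.na(wide[[timepoint_a]]) & !is.na(wide[[timepoint_b]])
  n_excluded <- sum(!complete)
  diffs <- wide[[timepoint_b]][complete] - wide[[timepoint_a]][complete]
  n <- length(diffs)
  if (n < 2) {
    warn("fewer than 2 complete subject pairs; comparison undefined")
    return(tibble(estimate = NA_real_, statistic = NA_real_, df = NA_real_,
                  p.value = NA_real_, n_pairs = n, n_excluded = n_excluded,
                  zero_variance = NA))
  }
  if (sd(diffs) == 0) {
    return(tibble(estimate = mean(diffs), statistic = NA_real_, df = n - 1,
                  p.value = if (all(diffs == 0)) 1 else NA_real_,
                  n_pairs = n, n_excluded = n_excluded, zero_variance = TRUE))
  }
  tt <- stats::t.test(diffs)
  tibble(estimate = mean(diffs), statistic = unname(tt$statistic),
         df = unname(tt$parameter), p.value = tt$p.value,
         n_pairs = n, n_excluded = n_excluded, zero_variance = FALSE)
}

#' @export
autoplot.tbl_diversity <- function(object, ...) {
  d <- as_tibble(object)
  d$timepoint <- factor(d$timepoint,
                        levels = c("donor", "baseline", "during_abx",
                                   "week1", "week10"))
  ggplot(d, aes(x = .data$timepoint, y = .data$shannon)) +
    geom_boxplot(outlier.shape = NA, fill = "grey90") +
    geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    facet_wrap(~arm) +
    labs(x = NULL, y = "Shannon index (nats)",
         title = "Alpha diversity by timepoint") +
    theme_minimal()
}
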