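#' IBS-QoL summary score from 34 Likert items
#'
#' The 34-item quality-of-life instrument is scored 1-5 per item and
#' linearly transformed to 0-100, higher = better quality of life:
#' `100 * (170 - sum(items)) / 136` when higher item responses indicate
#' worse interference (the instrument's native orientation), or the mirror
#' transform when items are coded higher = better.
#'
#' @param items Numeric vector of exactly 34 responses in 1..5, or a matrix
#'   / data frame with 34 columns (one row per subject).
#' @param item_orientation `"higher_worse"` (default, native coding) or
#'   `"higher_better"`.
#' @return Numeric score(s) in \[0, 100\].
#' @export
#' @examples
#' qol_score(rep(1, 34))  # 100
#' qol_score(rep(3, 34))  # 50
qol_score <- function(items, item_orientation = c("higher_worse",
                                                  "higher_better")) {
  item_orientation <- match.arg(item_orientation)
  if (is.data.frame(items)) items <- as.matrix(items)
  if (!is.matrix(items)) items <- matrix(items, nrow = 1)
  if (ncol(items) != 34) {
    abort(sprintf("expected 34 items, got %d", ncol(items)))
  }
  if (anyNA(items)) abort("missing item responses; no imputation is applied")
  if (any(items < 1 | items > 5 | items != trunc(items))) {
    abort("item responses must be integers in 1..5")
  }
  if (item_orientation == "higher_better") items <- 6 - items
  s <- rowSums(items)
  out <- 100 * (170 - s) / 136
  if (nrow(items) == 1) out[[1]] else out
}

#' Responder classification from clinical records
#'
#' One row per subject with (any of) the columns `ibs_sss_baseline`,
#' `ibs_sss_week10`, `ibs_qol_baseline`, `ibs_qol_week10`, `gis_week10`
#' (global improvement, 1-7), `adequate_relief_week10` (logical or
#' `"yes"`/`"no"`). Flags:
#' * `responder_sss`: IBS-SSS decreased by at least 50 points (inclusive);
#' * `responder_qol`: IBS-QoL improved by at least 12 points (inclusive);
#' * `responder_gis`: moderately (6) or substantially (7) improved;
#' * `responder_relief`: reported adequate relief.
#' Missing inputs propagate to missing flags.
#'
#' @param records A data frame of clinical records.
#' @return The input tibble with change scores (`change_sss`, `change_qol`)
#'   and the four responder flags appended.
#' @export
classify_responders <- function(records) {
  d <- as_tibble(records)
  col <- function(nm) if (nm %in% names(d)) d[[nm]] else NA_real_
  for (nm in c("ibs_sss_baseline", "ibs_sss_week10")) {
    v <- col(nm)
    if (any(!is.na(v) & (v < 0 | v > 500))) abort(sprintf("%s outside 0-500", nm))
  }
  for (nm in c("ibs_qol_baseline", "ibs_qol_week10")) {
    v <- col(nm)
    if (any(!is.na(v) & (v < 0 | v > 100))) abort(sprintf("%s outside 0-100", nm))
  }
  gis <- col("gis_week10")
  if (any(!is.na(gis) & !gis %in% 1:7)) abort("gis_week10 outside 1..7")
  relief <- col("adequate_relief_week10")
  if (is.character(relief)) {
    relief <- dplyr::case_when(is.na(relief) ~ NA,
                               tolower(relief) == "yes" ~ TRUE,
                               .default = FALSE)
  }
  d |>
    dplyr::mutate(
      change_sss = col("ibs_sss_week10") - col("ibs_sss_baseline"),
      change_qol = col("ibs_qol_week10") - col("ibs_qol_baseline"),
      responder_sss = -.data$change_sss >= 50,
      responder_qol = .data$change_qol >= 12,
      responder_gis = gis >= 6,
      responder_relief = as.logical(relief)
    )
}

arm_counts <- function(d, flag) {
  d |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(yes = sum(.data[[flag]], na.rm = TRUE),
                     no = sum(!.data[[flag]], na.rm = TRUE), .groups = "drop")
}

#' Trial outcome tables with omnibus and combined-arm tests
#'
#' Reproduces the structure of a four-arm clinical outcome table and its
#' combined FMT-vs-placebo companion: per-arm mean (sd) change in IBS-SSS
#' and IBS-QoL with a one-way ANOVA p, responder counts with a
#' Freeman-Halton exact p, and the three FMT arms pooled against placebo
#' (pooled-variance t-test; 2x2 Fisher exact).
#'
#' @param records Clinical records as for [classify_responders()] (flags are
#'   computed internally), with an `arm` column.
#' @param placebo_arm Label of the placebo arm (default `"placebo"`).
#' @return An object of class `fmt_outcomes`: `by_arm` (per-arm summaries),
#'   `tests` (omnibus p per outcome), `combined` (FMT-combined vs placebo).
#'   [tidy()] returns `by_arm`, [glance()] the test tables bound together.
#' @export
outcomes_table <- function(records, placebo_arm = "placebo") {
  d <- classify_responders(records)
  empty <- setdiff(unique(d$arm), unique(d$arm[!is.na(d$change_sss) |
                                                 !is.na(d$responder_relief)]))
  if (length(empty)) warn(sprintf("arm(s) with no analysable records: %s",
                                  paste(empty, collapse = ", ")))
  arms <- unique(d$arm)
  if (length(arms) < 2) abort("need >= 2 arms")

  cont <- function(var) {
    d |>
      dplyr::filter(!is.na(.data[[var]])) |>
      dplyr::group_by(.data$arm) |>
      dplyr::summarise(n = dplyr::n(), mean = mean(.data[[var]]),
                       sd = sd(.data[[var]]), .groups = "drop")
  }
  sss <- cont("change_sss"); qol <- cont("change_qol")
  dich <- function(flag) arm_counts(dplyr::filter(d, !is.na(.data[[flag]])), flag)
  relief <- dich("responder_relief"); gis <- dich("responder_gis")
  rsss <- dich("responder_sss"); rqol <- dich("responder_qol")

  by_arm <- sss |>
    dplyr::rename(n_sss = "n", mean_change_sss = "mean", sd_change_sss = "sd") |>
    dplyr::full_join(qol |> dplyr::rename(n_qol = "n", mean_change_qol = "mean",
                                          sd_change_qol = "sd"), by = "arm") |>
    dplyr::full_join(relief |> dplyr::rename(n_adequate_relief = "yes",
                                             n_no_relief = "no"), by = "arm") |>
    dplyr::full_join(gis |> dplyr::rename(n_global_improvement = "yes",
                                          n_no_improvement = "no"), by = "arm") |>
    dplyr::full_join(rsss |> dplyr::rename(n_sss_responder = "yes",
                                           n_sss_nonresponder = "no"), by = "arm") |>
    dplyr::full_join(rqol |> dplyr::rename(n_qol_responder = "yes",
                                           n_qol_nonresponder = "no"), by = "arm")

  fh <- function(counts) {
    tab <- rbind(counts$yes, counts$no)
    if (ncol(tab) < 2 || any(colSums(tab) == 0)) return(NA_real_)
    fisher_exact(tab)$p.value
  }
  tests <- tibble(
    outcome = c("change_sss", "change_qol", "adequate_relief",
                "global_improvement", "responder_sss", "responder_qol"),
    test = c("anova", "anova", rep("freeman-halton", 4)),
    p.value = c(
      if (nrow(sss) >= 2) anova_oneway_summary(sss)$p.value else NA_real_,
      if (nrow(qol) >= 2) anova_oneway_summary(qol)$p.value else NA_real_,
      fh(relief), fh(gis), fh(rsss), fh(rqol)))

  combined <- NULL
  if (placebo_arm %in% arms) {
    pool <- function(var) {
      dd <- dplyr::filter(d, !is.na(.data[[var]]))
      grp <- ifelse(dd$arm == placebo_arm, "placebo", "FMT combined")
      s <- tibble(label = grp, x = dd[[var]]) |>
        dplyr::group_by(.data$label) |>
        dplyr::summarise(n = dplyr::n(), mean = mean(.data$x),
                         sd = sd(.data$x), .groups = "drop")
      if (nrow(s) < 2 || any(s$n < 2)) return(NA_real_)
      t_test_summary(s[s$label == "FMT combined", ],
                     s[s$label == "placebo", ], variant = "pooled")$p.value
    }
    pool_fisher <- function(flag) {
      dd <- dplyr::filter(d, !is.na(.data[[flag]]))
      tab <- table(factor(dd$arm == placebo_arm, levels = c(FALSE, TRUE)),
                   factor(dd[[flag]], levels = c(TRUE, FALSE)))
      if (any(dim(tab) < 2)) return(NA_real_)
      fisher_exact(unclass(tab))$p.value
    }
    combined <- tibble(
      outcome = tests$outcome,
      test = c("pooled t", "pooled t", rep("fisher 2x2", 4)),
      p.value = c(pool("change_sss"), pool("change_qol"),
                  pool_fisher("responder_relief"), pool_fisher("responder_gis"),
                  pool_fisher("responder_sss"), pool_fisher("responder_qol")))
  }
  structure(list(by_arm = by_arm, tests = tests, combined = combined),
            class = "fmt_outcomes")
}

#' @export
print.fmt_outcomes <- function(x, ...) {
  cat("Clinical outcomes by arm\n")
  print(x$by_arm)
  cat("\nOmnibus tests across arms\n")
  print(x$tests)
  if (!is.null(x$combined)) {
    cat("\nFMT arms combined vs placebo\n")
    print(x$combined)
  }
  invisible(x)
}

#' @export
tidy.fmt_outcomes <- function(x, ...) x$by_arm

#' @export
glance.fmt_outcomes <- function(x, ...) {
  out <- dplyr::mutate(x$tests, comparison = "four arms")
  if (!is.null(x$combined)) {
    out <- dplyr::bind_rows(
      out, dplyr::mutate(x$combined, comparison = "FMT combined vs placebo"))
  }
  out
}
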