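#' Pipeline run configuration
#'
#' Collects and validates everything one end-to-end analysis needs. Either
#' point it at files on disk (an OTU table, sample metadata, and optionally
#' taxonomy and clinical TSVs, e.g. a directory written by
#' [write_fixture()]), or load it from a YAML file with the same field
#' names.
#'
#' @param otu_table,metadata Paths to the OTU count table and sample
#'   metadata TSVs (required).
#' @param taxonomy,clinical Optional paths to taxonomy and clinical TSVs.
#' @param out_dir Output directory for report artifacts.
#' @param mode Engraftment denominator (see [engraftment_percent()]).
#' @param presence_floor Relative-abundance presence floor (default 0).
#' @param donor_policy Donor-set policy (see [compute_engraftment()]).
#' @param min_samples,min_total_reads OTU filter thresholds
#'   (see [filter_otus()]).
#' @param seed Integer seed recorded in the report (the analysis itself is
#'   deterministic; the seed feeds any Monte-Carlo test fallback).
#' @return A `run_config` list.
#' @export
run_config <- function(otu_table, metadata, taxonomy = NULL, clinical = NULL,
                       out_dir = tempfile("engraftr_run_"),
                       mode = "abundance", presence_floor = 0,
                       donor_policy = "union",
                       min_samples = 2, min_total_reads = 10, seed = 1) {
  for (p in c(otu_table, metadata, taxonomy, clinical)) {
    if (!is.null(p) && !file.exists(p)) abort(sprintf("file not found: %s", p))
  }
  mode <- match.arg(mode, c("abundance", "donor_richness", "post_richness"))
  donor_policy <- match.arg(donor_policy, c("union", "listed"))
  structure(list(otu_table = otu_table, metadata = metadata,
                 taxonomy = taxonomy, clinical = clinical, out_dir = out_dir,
                 mode = mode, presence_floor = presence_floor,
                 donor_policy = donor_policy, min_samples = min_samples,
                 min_total_reads = min_total_reads, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML file whose keys are `run_config()` arguments.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  cf <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (k in c("otu_table", "metadata", "taxonomy", "clinical")) {
    if (!is.null(cf[[k]]) && !file.exists(cf[[k]])) {
      cf[[k]] <- file.path(base, cf[[k]])
    }
  }
  do.call(run_config, cf)
}

#' Run the full engraftment analysis pipeline
#'
#' Executes filter -> engraftment -> diversity -> order-level composition
#' -> arm comparisons -> clinical outcomes on the configured inputs, writes
#' TSV/JSON artifacts plus a plain-text log to `out_dir`, and returns the
#' report invisibly. Every excluded sample or subject is logged with a
#' reason. Subjects without a week-10 stool sample are excluded from
#' engraftment but kept for clinical outcomes when questionnaire data
#' exist (per-protocol semantics).
#'
#' @param config A [run_config()] (or a path to a YAML config).
#' @return Invisibly, a list: `engraftment` (per-subject tibble),
#'   `arm_test`, `diversity`, `diversity_tests`, `composition`,
#'   `outcomes`, `files` (paths written).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("engraftr pipeline")
  for (k in c("otu_table", "metadata", "taxonomy", "clinical", "mode",
              "presence_floor", "donor_policy", "min_samples",
              "min_total_reads", "seed")) {
    logf("  %s: %s", k, config[[k]] %||% "(none)")
  }

  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      logf("FAILED at stage '%s': %s", name, conditionMessage(e))
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  tab <- step("read", read_otu_table(config$otu_table,
                                     taxonomy = config$taxonomy))
  meta <- step("read", as_tibble(readr::read_tsv(config$metadata,
                                                 col_types = readr::cols(),
                                                 progress = FALSE)))
  n0 <- length(otu_ids(tab))
  tab <- step("filter", filter_otus(tab, config$min_samples,
                                    config$min_total_reads))
  logf("filter: %d of %d OTUs retained", length(otu_ids(tab)), n0)

  eng <- step("engraftment", withCallingHandlers(
    compute_engraftment(tab, meta, mode = config$mode,
                        presence_floor = config$presence_floor,
                        donor_policy = config$donor_policy),
    warning = function(w) { logf("engraftment: %s", conditionMessage(w))
                            invokeRestart("muffleWarning") }))
  excl <- attr(eng, "exclusions")
  if (!is.null(excl)) for (i in seq_len(nrow(excl))) {
    logf("excluded subject %s: %s", excl$subject_id[i], excl$reason[i])
  }
  readr::write_tsv(as_tibble(eng), file.path(config$out_dir, "engraftment.tsv"),
                   progress = FALSE)

  arm_test <- step("engraftment", tryCatch(
    withCallingHandlers(
      compare_engraftment_by_arm(eng),
      warning = function(w) { logf("arm comparison: %s", conditionMessage(w))
                              invokeRestart("muffleWarning") }),
    error = function(e) { logf("arm comparison skipped: %s",
                               conditionMessage(e)); NULL }))

  div <- step("diversity", sample_diversity(tab, meta))
  readr::write_tsv(as_tibble(div), file.path(config$out_dir, "diversity.tsv"),
                   progress = FALSE)
  div_tests <- step("diversity", {
    pairs <- list(c("baseline", "during_abx"), c("baseline", "week1"),
                  c("baseline", "week10"))
    purrr::map_dfr(pairs, function(pr) {
      if (!all(pr %in% div$timepoint)) return(NULL)
      res <- withCallingHandlers(
        compare_diversity(div, pr[1], pr[2]),
        warning = function(w) { logf("diversity %s-%s: %s", pr[1], pr[2],
                                     conditionMessage(w))
                                invokeRestart("muffleWarning") })
      dplyr::mutate(res, timepoint_a = pr[1], timepoint_b = pr[2],
                    .before = 1)
    })
  })

  comp <- step("composition", {
    if (is.null(otu_taxonomy(tab))) NULL else {
      aggregate_by_rank(tab, "order") |>
        relative_abundance() |>
        dplyr::rename(taxon = "otu_id") |>
        dplyr::left_join(dplyr::select(meta, "sample_id", "arm", "timepoint"),
                         by = "sample_id")
    }
  })
  if (!is.null(comp)) {
    readr::write_tsv(comp, file.path(config$out_dir, "composition_order.tsv"),
                     progress = FALSE)
  }

  outcomes <- step("clinical", {
    if (is.null(config$clinical)) NULL else {
      rec <- readr::read_tsv(config$clinical, col_types = readr::cols(),
                             progress = FALSE)
      withCallingHandlers(
        outcomes_table(rec),
        warning = function(w) { logf("outcomes: %s", conditionMessage(w))
                                invokeRestart("muffleWarning") })
    }
  })

  report <- list(
    engraftment_medians = if (!is.null(arm_test)) arm_test$medians,
    kruskal_wallis = if (!is.null(arm_test)) arm_test$omnibus,
    dunn = if (!is.null(arm_test)) arm_test$pairwise,
    diversity_tests = div_tests,
    outcome_tests = if (!is.null(outcomes)) glance(outcomes))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")

  summary_path <- file.path(config$out_dir, "summary.txt")
  con <- file(summary_path, "w")
  sink(con)
  on.exit({ sink(); close(con) }, add = TRUE)
  cat("engraftr pipeline summary\n=========================\n\n")
  if (!is.null(arm_test)) print(arm_test)
  cat("\nDiversity comparisons (paired t, b - a):\n")
  print(as.data.frame(div_tests))
  if (!is.null(outcomes)) { cat("\n"); print(outcomes) }
  sink(); close(con); on.exit()

  logf("done")
  invisible(list(engraftment = eng, arm_test = arm_test, diversity = div,
                 diversity_tests = div_tests, composition = comp,
                 outcomes = outcomes,
                 files = list.files(config$out_dir, full.names = TRUE)))
}
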