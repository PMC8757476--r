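#' OTU count tables as tidy tibbles
#'
#' An `otu_table` is a long tibble with one row per (sample, OTU) pair and
#' columns `sample_id`, `otu_id`, `count`. The grid is complete: every
#' sample/OTU combination is present, zeros included, so that the on-disk
#' wide representation round-trips exactly. An optional taxonomy (a tibble
#' with `otu_id` plus rank columns `domain` ... `genus`) travels along as the
#' `"taxonomy"` attribute.
#'
#' @param counts A data frame with columns `sample_id`, `otu_id`, `count`,
#'   or a numeric matrix (samples x OTUs) with dimnames.
#' @param taxonomy Optional taxonomy tibble (`otu_id` plus rank columns).
#'
#' @return A tibble of class `otu_table`.
#' @export
#' @examples
#' m <- matrix(c(30L, 50L, 20L, 0L, 10L, 90L), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("otuA", "otuB", "otuC")))
#' otu_table(m)
otu_table <- function(counts, taxonomy = NULL) {
  if (is.matrix(counts)) {
    rn <- rownames(counts) %||% character(0)
    cn <- colnames(counts) %||% character(0)
    if ((nrow(counts) > 0 && !length(rn)) || (ncol(counts) > 0 && !length(cn))) {
      abort("count matrix must have sample (row) and OTU (column) names")
    }
    counts <- tibble(
      sample_id = rep(rn, times = ncol(counts)),
      otu_id    = rep(cn, each = nrow(counts)),
      count     = as.vector(counts)
    )
  }
  counts <- as_tibble(counts)
  tbl <- validate_otu_table(counts)
  attr(tbl, "taxonomy") <- validate_taxonomy(taxonomy)
  class(tbl) <- c("otu_table", class(tibble()))
  tbl
}

TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

validate_taxonomy <- function(taxonomy) {
  if (is.null(taxonomy)) return(NULL)
  taxonomy <- as_tibble(taxonomy)
  if (!"otu_id" %in% names(taxonomy)) abort("taxonomy must have an 'otu_id' column")
  if (anyDuplicated(taxonomy$otu_id)) abort("taxonomy has duplicated otu_id entries")
  taxonomy
}

validate_otu_table <- function(tbl) {
  need <- c("sample_id", "otu_id", "count")
  if (!all(need %in% names(tbl))) {
    abort(paste0("otu_table needs columns ", paste(need, collapse = ", ")))
  }
  tbl <- tbl[need]
  if (anyNA(tbl$count)) abort("counts contain missing values")
  if (any(tbl$count < 0)) abort("counts must be non-negative")
  if (any(tbl$count != trunc(tbl$count))) {
    bad <- which(tbl$count != trunc(tbl$count))[1]
    abort(sprintf("non-integer count %s at sample '%s', OTU '%s'",
                  format(tbl$count[bad]), tbl$sample_id[bad], tbl$otu_id[bad]))
  }
  tbl$count <- as.integer(tbl$count)
  if (anyDuplicated(tbl[c("sample_id", "otu_id")])) {
    abort("duplicated (sample_id, otu_id) pair in otu_table")
  }
  # complete grid so zeros are explicit and round-trips are lossless
  tbl <- tidyr::complete(tbl,
    sample_id = unique(tbl$sample_id), otu_id = unique(tbl$otu_id),
    fill = list(count = 0L))
  dplyr::arrange(tbl, match(.data$sample_id, unique(.data$sample_id)),
                 match(.data$otu_id, unique(.data$otu_id)))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("# otu_table: %d samples x %d OTUs (%s taxonomy)\n",
              dplyr::n_distinct(x$sample_id), dplyr::n_distinct(x$otu_id),
              if (is.null(attr(x, "taxonomy"))) "no" else "with"))
  NextMethod()
}

#' Accessors for otu_table components
#'
#' @param table An [otu_table].
#' @return `otu_samples()` and `otu_ids()` return character vectors;
#'   `otu_taxonomy()` the taxonomy tibble or `NULL`; `otu_matrix()` the
#'   samples x OTUs integer count matrix.
#' @export
otu_samples <- function(table) unique(table$sample_id)

#' @rdname otu_samples
#' @export
otu_ids <- function(table) unique(table$otu_id)

#' @rdname otu_samples
#' @export
otu_taxonomy <- function(table) attr(table, "taxonomy")

#' @rdname otu_samples
#' @export
otu_matrix <- function(table) {
  samples <- otu_samples(table)
  otus <- otu_ids(table)
  m <- matrix(0L, length(samples), length(otus), dimnames = list(samples, otus))
  m[cbind(table$sample_id, table$otu_id)] <- table$count
  m
}

#' Read an OTU count table from TSV
#'
#' Reads the classic QIIME-style tab-separated OTU table. Orientation is
#' detected from the header: a leading `#OTU ID` cell means OTUs are rows and
#' samples are columns; a leading `sample_id` cell means samples are rows.
#' A leading comment line `# Constructed from biom file` (BIOM TSV export)
#' is skipped.
#'
#' @param path Path to a TSV file.
#' @param taxonomy Optional path to a taxonomy TSV (columns: OTU id and a
#'   semicolon-delimited lineage `domain;phylum;...;genus`).
#'
#' @return An [otu_table].
#' @export
read_otu_table <- function(path, taxonomy = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^# Constructed from biom", lines)]
  if (!length(lines)) abort(sprintf("empty file: %s", path))
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 1 || !nzchar(header[1])) {
    abort(sprintf("malformed header in %s: empty leading field", path))
  }
  otus_as_rows <- identical(header[1], "#OTU ID")
  if (!otus_as_rows && !identical(header[1], "sample_id")) {
    abort(sprintf(
      "malformed header in %s: expected leading '#OTU ID' or 'sample_id', got '%s'",
      path, header[1]))
  }
  ids <- header[-1]
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate identifier '%s' in header of %s",
                  ids[duplicated(ids)][1], path))
  }
  body <- lines[-1]
  cells <- lapply(body, function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  row_ids <- vapply(cells, `[`, character(1), 1)
  if (anyDuplicated(row_ids)) {
    abort(sprintf("duplicate identifier '%s' in first column of %s",
                  row_ids[duplicated(row_ids)][1], path))
  }
  counts <- matrix(0L, length(row_ids), length(ids),
                   dimnames = list(row_ids, ids))
  for (i in seq_along(cells)) {
    vals <- cells[[i]][-1]
    if (length(vals) != length(ids)) {
      abort(sprintf("row '%s' of %s has %d fields, expected %d",
                    row_ids[i], path, length(vals), length(ids)))
    }
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(num) | num != trunc(num) | num < 0)
    if (length(bad)) {
      abort(sprintf("non-integer count '%s' at row '%s', column '%s' in %s",
                    vals[bad[1]], row_ids[i], ids[bad[1]], path))
    }
    counts[i, ] <- as.integer(num)
  }
  if (otus_as_rows) counts <- t(counts)
  tax <- if (!is.null(taxonomy)) read_taxonomy(taxonomy)
  otu_table(counts, taxonomy = tax)
}

#' @rdname read_otu_table
#' @param table An [otu_table] to write.
#' @param orientation `"otus"` (default; OTUs as rows, `#OTU ID` header) or
#'   `"samples"` (samples as rows, `sample_id` header).
#' @export
write_otu_table <- function(table, path, orientation = c("otus", "samples")) {
  orientation <- match.arg(orientation)
  m <- otu_matrix(table)
  if (orientation == "otus") {
    m <- t(m)
    header <- c("#OTU ID", colnames(m))
  } else {
    header <- c("sample_id", colnames(m))
  }
  lines <- c(paste(header, collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], m[i, ]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a taxonomy TSV
#'
#' Expects two tab-separated columns: OTU id and a semicolon-delimited
#' lineage from domain down to genus (shorter lineages are padded with `NA`).
#'
#' @param path Path to the taxonomy TSV (a header line is optional).
#' @return A tibble with columns `otu_id`, `domain`, ..., `genus`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, col_names = FALSE, col_types = "cc",
                        progress = FALSE)
  if (identical(tolower(df[[1]][1]), "otu_id")) df <- df[-1, ]
  ranks <- strsplit(df[[2]], ";", fixed = TRUE)
  lev <- lapply(seq_along(TAXONOMY_RANKS), function(i) {
    vapply(ranks, function(r) {
      v <- if (length(r) >= i) trimws(r[i]) else NA_character_
      if (!is.na(v) && !nzchar(v)) NA_character_ else v
    }, character(1))
  })
  names(lev) <- TAXONOMY_RANKS
  validate_taxonomy(tibble(otu_id = df[[1]], !!!lev))
}

#' Filter OTUs by prevalence and total reads
#'
#' Discards OTUs seen in fewer than `min_samples` distinct samples or with
#' fewer than `min_total_reads` reads summed across all samples (both
#' boundaries inclusive: exactly 2 samples and exactly 10 reads are kept
#' under the defaults). The sample set is unchanged, so samples left with
#' zero counts are retained. The operation is idempotent.
#'
#' @param table An [otu_table].
#' @param min_samples Minimum number of distinct samples with a nonzero
#'   count (default 2).
#' @param min_total_reads Minimum total reads across all samples (default 10).
#'
#' @return A filtered [otu_table]; taxonomy, if present, is subset to the
#'   retained OTUs.
#' @export
filter_otus <- function(table, min_samples = 2, min_total_reads = 10) {
  if (!is.numeric(min_samples) || min_samples < 1) {
    abort("min_samples must be >= 1")
  }
  if (!is.numeric(min_total_reads) || min_total_reads < 0) {
    abort("min_total_reads must be >= 0")
  }
  keep <- table |>
    dplyr::group_by(.data$otu_id) |>
    dplyr::summarise(n_samples = sum(.data$count > 0),
                     total = sum(.data$count), .groups = "drop") |>
    dplyr::filter(.data$n_samples >= min_samples,
                  .data$total >= min_total_reads) |>
    dplyr::pull(.data$otu_id)
  out <- dplyr::filter(table, .data$otu_id %in% keep)
  # keep the full sample set even if a sample lost all its counts
  missing_samples <- setdiff(otu_samples(table), unique(out$sample_id))
  if (length(keep) == 0L && length(missing_samples)) {
    # degenerate: no OTUs left; represent samples with an empty grid
    out <- out[0, ]
  }
  tax <- otu_taxonomy(table)
  if (!is.null(tax)) tax <- dplyr::filter(tax, .data$otu_id %in% keep)
  res <- otu_table(out, taxonomy = tax)
  attr(res, "all_samples") <- otu_samples(table)
  res
}

#' Per-sample relative abundances
#'
#' @param table An [otu_table].
#' @return A tibble `sample_id`, `otu_id`, `rel_abund`; abundances within a
#'   sample sum to 1.
#' @export
relative_abundance <- function(table) {
  totals <- table |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  zero <- totals$sample_id[totals$total == 0]
  if (length(zero)) {
    abort(sprintf("sample(s) with zero total count: %s",
                  paste(zero, collapse = ", ")))
  }
  table |>
    dplyr::left_join(totals, by = "sample_id") |>
    dplyr::mutate(rel_abund = .data$count / .data$total) |>
    dplyr::select("sample_id", "otu_id", "rel_abund")
}

#' Aggregate an OTU table at a taxonomic rank
#'
#' Sums counts over all OTUs sharing a taxon at the given rank; OTUs with no
#' assignment at that rank are pooled under `"unclassified"`. Per-sample
#' totals are conserved exactly.
#'
#' @param table An [otu_table] with taxonomy.
#' @param rank One of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return An [otu_table] whose `otu_id` values are taxon names at `rank`.
#' @export
aggregate_by_rank <- function(table, rank) {
  if (!is.character(rank) || length(rank) != 1 || !rank %in% TAXONOMY_RANKS) {
    abort(sprintf("unknown rank '%s'; expected one of %s",
                  paste(rank, collapse = ","), paste(TAXONOMY_RANKS, collapse = ", ")))
  }
  tax <- otu_taxonomy(table)
  if (is.null(tax)) abort("otu_table has no taxonomy; cannot aggregate")
  lineage <- tax[[rank]] %||% rep(NA_character_, nrow(tax))
  key <- tibble(otu_id = tax$otu_id,
                taxon = dplyr::coalesce(lineage, "unclassified"))
  agg <- table |>
    dplyr::left_join(key, by = "otu_id") |>
    dplyr::mutate(taxon = dplyr::coalesce(.data$taxon, "unclassified")) |>
    dplyr::group_by(.data$sample_id, .data$taxon) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::rename(otu_id = "taxon")
  otu_table(agg)
}

#' Rarefy an OTU table to even depth
#'
#' Optional depth normalisation by subsampling reads without replacement.
#' Off by default throughout the package: the engraftment and diversity
#' analyses operate on raw filtered counts.
#'
#' @param table An [otu_table].
#' @param depth Target reads per sample; samples below `depth` are dropped
#'   with a warning.
#' @param seed Integer seed (subsampling is random).
#' @return A rarefied [otu_table].
#' @export
rarefy_otu_table <- function(table, depth, seed) {
  if (missing(seed)) abort("rarefy_otu_table requires an explicit seed")
  m <- otu_matrix(table)
  keep <- rowSums(m) >= depth
  if (any(!keep)) {
    warn(sprintf("dropping %d sample(s) below depth %d: %s",
                 sum(!keep), depth,
                 paste(rownames(m)[!keep], collapse = ", ")))
    m <- m[keep, , drop = FALSE]
  }
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(nrow(m))) {
      reads <- rep.int(seq_len(ncol(m)), m[i, ])
      sub <- sample(reads, depth)
      m[i, ] <- tabulate(sub, nbins = ncol(m))
    }
  })
  otu_table(m, taxonomy = otu_taxonomy(table))
}

#' Presence sets per sample
#'
#' OTUs counted as present in a sample: count >= 1, with an optional
#' relative-abundance floor.
#'
#' @param table An [otu_table].
#' @param sample_ids Samples to extract (default all).
#' @param presence_floor Minimum within-sample relative abundance for a
#'   nonzero OTU to count as present (default 0, i.e. any nonzero count).
#' @return A named list of character vectors of OTU ids.
#' @export
presence_sets <- function(table, sample_ids = NULL, presence_floor = 0) {
  sample_ids <- sample_ids %||% otu_samples(table)
  sub <- dplyr::filter(table, .data$sample_id %in% sample_ids, .data$count > 0)
  if (presence_floor > 0) {
    sub <- sub |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::mutate(rel = .data$count / sum(.data$count)) |>
      dplyr::ungroup() |>
      dplyr::filter(.data$rel >= presence_floor)
  }
  sets <- split(sub$otu_id, factor(sub$sample_id, levels = sample_ids))
  lapply(sets, as.character)
}
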