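#' Order-level composition bar plot
#'
#' Stacked relative-abundance bars per sample, faceted by arm and
#' timepoint, from the long composition table produced by
#' [aggregate_by_rank()] + [relative_abundance()] (or by [run_pipeline()]).
#'
#' @param composition A tibble with `sample_id`, `taxon`, `rel_abund` and
#'   optionally `arm`, `timepoint`.
#' @return A ggplot object.
#' @export
plot_composition <- function(composition) {
  d <- as_tibble(composition)
  p <- ggplot(d, aes(x = .data$sample_id, y = .data$rel_abund,
                     fill = .data$taxon)) +
    geom_col(width = 1) +
    labs(x = NULL, y = "Relative abundance", fill = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_blank(), panel.grid = element_blank())
  if (all(c("arm", "timepoint") %in% names(d))) {
    p <- p + facet_grid(arm ~ timepoint, scales = "free_x", space = "free_x")
  }
  p
}
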