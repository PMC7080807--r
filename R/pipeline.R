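## End-to-end wiring: correct -> collapse -> (optionally) quantify.

#' Run correction and collapse on a set of reads
#'
#' @param reads raw reads table (all samples).
#' @param sites valid-site set from [build_valid_sites()].
#' @param window splice-site correction / matching window (default 10).
#' @param max_gap indel gap-fill threshold (default 30).
#' @param end_window TSS/TES clustering window (default 100).
#' @param min_support minimum uniquely assigned reads per isoform
#'   (default 3).
#' @param end_slack assignment end tolerance (default 200).
#' @return list: `correction` (full [correct_reads()] output), `parts`
#'   (read partition), `isoforms` (final filtered set), `assignment`.
#' @export
collapse_pipeline <- function(reads, sites, window = 10L, max_gap = 30L,
                              end_window = 100L, min_support = 3L,
                              end_slack = 200L) {
  filled <- fill_small_gaps_reads(reads, max_gap)
  corr <- correct_reads(filled, sites, window)
  parts <- partition_reads(corr)
  groups <- group_by_chain(parts$corrected)
  fp <- first_pass(groups, end_window)
  fp <- consolidate_isoforms(fp, window, end_slack)
  allr <- rbind(parts$corrected, parts$uncorrected, parts$unspliced)
  asn <- assign_reads(allr, fp, window, end_slack)
  iso <- filter_isoforms(fp, asn, min_support)
  list(correction = corr, parts = parts, isoforms = iso, assignment = asn)
}

#' Full pipeline: correct, collapse, annotate and count
#'
#' @inheritParams collapse_pipeline
#' @param annotation annotation from [read_gtf()].
#' @param support optional short-read junction support.
#' @param ... passed to [collapse_pipeline()].
#' @return the [collapse_pipeline()] list plus `counts` (isoform x sample
#'   matrix) and annotated/categorized `isoforms`.
#' @export
run_pipeline <- function(reads, annotation, support = NULL, ...) {
  sites <- build_valid_sites(annotation, support)
  res <- collapse_pipeline(reads, sites, ...)
  if (nrow(res$isoforms)) {
    res$isoforms <- assign_genes(res$isoforms, annotation)
    res$isoforms <- categorize_vs_annotation(res$isoforms, annotation)
  }
  res$counts <- count_matrix(res$assignment, res$isoforms,
                             samples = unique(reads$sample_id))
  res
}
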