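## Per-sample isoform counting, upper-quartile normalization over
## protein-coding genes, fold changes, and summary statistics.

#' Build the isoform-by-sample counts matrix
#'
#' Entry (i, s) is the number of reads of sample s uniquely assigned to
#' isoform i; ambiguous/unassigned reads contribute nothing.
#'
#' @param assignment output of [assign_reads()].
#' @param isoforms final isoform table (rows of the matrix).
#' @param samples sample ids for the columns (default: those present in
#'   the assignment).
#' @return integer matrix with isoform ids as rownames.
#' @export
count_matrix <- function(assignment, isoforms, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(assignment$sample_id))
  m <- matrix(0L, nrow = nrow(isoforms), ncol = length(samples),
              dimnames = list(isoforms$isoform_id, samples))
  a <- assignment[reason == "unique" & isoform_id %in% isoforms$isoform_id]
  if (nrow(a)) {
    tab <- a[, .N, by = .(isoform_id, sample_id)]
    m[cbind(match(tab$isoform_id, rownames(m)),
            match(tab$sample_id, samples))] <- tab$N
  }
  m
}

#' Upper-quartile normalization over protein-coding genes
#'
#' Per sample, isoform counts are summed to gene level for protein-coding
#' genes; the normalization factor is the 75th percentile
#' (linear-interpolation quantile) of the nonzero coding-gene counts, and
#' every entry is divided by it.
#'
#' @param counts counts matrix from [count_matrix()].
#' @param gene_map named character vector isoform_id -> gene_id.
#' @param gene_biotype named character vector gene_id -> biotype; genes
#'   labeled `"protein_coding"` enter the quantile.
#' @param include_zero include zero-count coding genes in the quantile
#'   (default FALSE).
#' @return list: `norm` (matrix), `factors` (per-sample UQ factor).
#' @export
upper_quartile_normalize <- function(counts, gene_map, gene_biotype,
                                     include_zero = FALSE) {
  genes <- gene_map[rownames(counts)]
  coding <- names(gene_biotype)[gene_biotype == "protein_coding"]
  factors <- vapply(colnames(counts), function(s) {
    gsum <- tapply(counts[, s], genes, sum)
    gsum <- gsum[names(gsum) %in% coding]
    if (!include_zero) gsum <- gsum[gsum > 0]
    if (length(gsum) == 0L)
      stop("sample ", s, ": no protein-coding gene with nonzero count")
    f <- as.numeric(quantile(gsum, 0.75, type = 7))
    if (f <= 0) stop("sample ", s, ": upper-quartile factor is zero")
    f
  }, 1.0)
  list(norm = sweep(counts, 2L, factors, "/"), factors = factors)
}

#' Condition fold changes from normalized counts
#'
#' Per isoform, the ratio of the median normalized count in `cond_a` over
#' `cond_b` (log2). Isoforms with both condition medians below
#' `min_median` are excluded, as are zero-denominator ratios.
#'
#' @param norm normalized matrix (e.g. `upper_quartile_normalize()$norm`).
#' @param manifest sample manifest ([read_manifest()]).
#' @param cond_a,cond_b condition labels (numerator / denominator).
#' @param min_median expression filter (default 10).
#' @return data.table `isoform_id`, `median_a`, `median_b`, `log2fc`,
#'   `kept`, `reason`.
#' @export
fold_change <- function(norm, manifest, cond_a, cond_b, min_median = 10) {
  if (!all(c(cond_a, cond_b) %in% manifest$condition))
    stop("unknown condition label")
  sa <- manifest[condition == cond_a, sample_id]
  sb <- manifest[condition == cond_b, sample_id]
  ma <- apply(norm[, sa, drop = FALSE], 1L, median)
  mb <- apply(norm[, sb, drop = FALSE], 1L, median)
  out <- data.table(isoform_id = rownames(norm), median_a = ma, median_b = mb)
  out[, reason := fifelse(pmax(median_a, median_b) < min_median, "low_expression",
                          fifelse(median_b == 0, "zero_denominator", "ok"))]
  out[, kept := reason == "ok"]
  out[, log2fc := fifelse(kept, log2(median_a / median_b), NA_real_)]
  out[]
}

#' Per-sample full-length read fraction
#'
#' A read is full-length when its exonic overlap with its assigned
#' isoform's exons covers at least `threshold` of the isoform's spliced
#' length.
#'
#' @param reads reads table (post gap-fill / correction).
#' @param assignment output of [assign_reads()].
#' @param isoforms isoform table.
#' @param threshold coverage fraction (default 0.8).
#' @return data.table `sample_id`, `assigned`, `full_length`, `fraction`.
#' @export
full_length_stats <- function(reads, assignment, isoforms, threshold = 0.8) {
  a <- assignment[reason == "unique"]
  a <- a[isoform_id %in% isoforms$isoform_id]
  ridx <- match(a$read_id, reads$read_id)
  iidx <- match(a$isoform_id, isoforms$isoform_id)
  ilen <- vapply(isoforms$blocks, blocks_len, 1L)
  cov <- vapply(seq_len(nrow(a)), function(k)
    blocks_overlap(reads$blocks[[ridx[k]]], isoforms$blocks[[iidx[k]]]) /
      ilen[iidx[k]], 1.0)
  a[, fl := cov >= threshold]
  a[, .(assigned = .N, full_length = sum(fl),
        fraction = sum(fl) / .N), by = sample_id]
}

#' Genes detected and fraction alternatively spliced
#'
#' Genes with at least one expressed isoform count as detected; those with
#' two or more are alternatively spliced.
#'
#' @param isoforms isoform table with `gene_id`.
#' @param counts optional counts matrix; when given, only isoforms with a
#'   nonzero total count are considered expressed.
#' @return list `genes_detected`, `as_fraction`.
#' @export
gene_summary <- function(isoforms, counts = NULL) {
  iso <- isoforms
  if (!is.null(counts)) {
    expressed <- rownames(counts)[rowSums(counts) > 0]
    iso <- iso[isoform_id %in% expressed]
  }
  if (nrow(iso) == 0L) return(list(genes_detected = 0L, as_fraction = NA_real_))
  per_gene <- iso[, .N, by = gene_id]
  list(genes_detected = nrow(per_gene),
       as_fraction = mean(per_gene$N >= 2L))
}
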