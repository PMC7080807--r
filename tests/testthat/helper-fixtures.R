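## Fixture builders shared across the suite. Everything is constructed in
## code; no data files.

library(data.table)

## Build an annotation object directly (same shape as read_gtf()).
## tx_list: named list, each element list(gene, chrom, strand, blocks,
## biotype = "protein_coding", start_codon = NULL, cds = NULL).
make_annotation <- function(tx_list) {
  tx <- rbindlist(lapply(names(tx_list), function(id) {
    t <- tx_list[[id]]
    data.table(transcript_id = id, gene_id = t$gene, chrom = t$chrom,
               strand = t$strand, blocks = list(t$blocks))
  }))
  jx <- unique(rbindlist(lapply(names(tx_list), function(id) {
    t <- tx_list[[id]]
    j <- blocks_to_junctions(t$blocks)
    if (nrow(j) == 0L) return(NULL)
    data.table(chrom = t$chrom, start = j[, 1L], end = j[, 2L],
               strand = t$strand)
  })))
  if (is.null(jx) || nrow(jx) == 0L)
    jx <- data.table(chrom = character(), start = integer(),
                     end = integer(), strand = character())
  feat <- function(field) {
    rows <- lapply(names(tx_list), function(id) {
      t <- tx_list[[id]]
      if (is.null(t[[field]])) return(NULL)
      data.table(transcript_id = id, chrom = t$chrom, strand = t$strand,
                 blocks = list(t[[field]]))
    })
    out <- rbindlist(rows)
    if (is.null(out) || nrow(out) == 0L)
      out <- data.table(transcript_id = character(), chrom = character(),
                        strand = character(), blocks = list())
    out
  }
  bt <- vapply(tx_list, function(t)
    if (is.null(t$biotype)) "protein_coding" else t$biotype, "")
  genes <- vapply(tx_list, `[[`, "", "gene")
  bt_by_gene <- tapply(bt, genes, function(v) v[1L])
  structure(list(transcripts = tx, junctions = jx,
                 start_codons = feat("start_codon"), cds = feat("cds"),
                 gene_biotype = setNames(as.character(bt_by_gene),
                                         names(bt_by_gene))),
            class = "ls_annotation")
}

## Quick reads-table constructor.
make_reads <- function(blocks_list, chrom = "chr1", strand = "+",
                       sample_id = "s1", ids = NULL) {
  n <- length(blocks_list)
  if (is.null(ids)) ids <- sprintf("r%03d", seq_len(n))
  data.table(read_id = ids, chrom = rep_len(chrom, n),
             strand = rep_len(strand, n),
             sample_id = rep_len(sample_id, n), blocks = blocks_list)
}

## Isoform-table constructor from block matrices.
make_isoforms <- function(blocks_list, chrom = "chr1", strand = "+",
                          gene = "g1", ids = NULL) {
  n <- length(blocks_list)
  if (is.null(ids)) ids <- sprintf("I%02d", seq_len(n))
  data.table(isoform_id = ids, chrom = rep_len(chrom, n),
             strand = rep_len(strand, n),
             chain = lapply(blocks_list, blocks_to_junctions),
             blocks = blocks_list,
             start = vapply(blocks_list, function(b) b[1L, 1L], 1L),
             end = vapply(blocks_list, function(b) b[nrow(b), 2L], 1L),
             gene_id = rep_len(gene, n))
}

## Random sorted non-overlapping block matrix (for property tests).
random_blocks <- function(n_blocks, gap_range = c(1L, 400L),
                          len_range = c(5L, 200L), origin = 100L) {
  lens <- sample(len_range[1L]:len_range[2L], n_blocks, replace = TRUE)
  gaps <- sample(gap_range[1L]:gap_range[2L], n_blocks, replace = TRUE)
  starts <- origin + cumsum(gaps) + cumsum(c(0L, head(lens, -1L)))
  cbind(start = as.integer(starts), end = as.integer(starts + lens))
}

## A genome (DNAStringSet) built from a transcript sequence placed on
## given exon blocks; off-exon positions are filled with "C".
## Returns the genome; `tx_seq` must have nchar == total exonic length.
genome_from_tx <- function(tx_seq, blocks, strand, chrom = "chr1",
                           pad = 50L) {
  glen <- blocks[nrow(blocks), 2L] + pad
  g <- rep("C", glen)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (t in seq_len(nchar(tx_seq)) - 1L) {
    gpos <- longsplice:::tx_to_genomic(blocks, strand, t)
    base <- substr(tx_seq, t + 1L, t + 1L)
    g[gpos + 1L] <- if (strand == "-") comp[[base]] else base
  }
  Biostrings::DNAStringSet(setNames(paste(g, collapse = ""), chrom))
}

## Transcript sequence with ATG at 0, non-stop codons elsewhere, and a
## planted stop codon starting at tx position `stop_at` (multiple of 3),
## or no stop when stop_at is NA.
orf_tx_seq <- function(len, stop_at = NA) {
  n_cod <- ceiling(len / 3)
  cods <- rep("AAA", n_cod)
  cods[1L] <- "ATG"
  if (!is.na(stop_at)) cods[stop_at / 3 + 1L] <- "TAA"
  substr(paste(cods, collapse = ""), 1L, len)
}
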