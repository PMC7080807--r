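## Readers/writers for BED12, GTF, FASTA, junction tables, counts matrices
## and the sample manifest. All coordinate normalization happens here:
## everything downstream is 0-based half-open.

#' Read spliced read alignments from BED12
#'
#' Each line is one read; blocks are reconstructed as absolute genomic
#' intervals. Strand "." is kept as unknown and such reads are excluded from
#' strand-dependent analyses unless a strand can be inherited during
#' correction.
#'
#' @param path BED12 file.
#' @param sample_id sample of origin attached to every read (default: file
#'   name without extension).
#' @return a `data.table` with columns `read_id`, `chrom`, `strand`,
#'   `sample_id` and a list-column `blocks` of start/end matrices.
#' @export
read_bed12 <- function(path, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_reads())
  parse_line <- function(i) {
    f <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(f) < 12L)
      stop(sprintf("%s line %d: expected 12 BED fields, got %d",
                   path, i, length(f)))
    cs <- suppressWarnings(as.integer(f[2])); ce <- suppressWarnings(as.integer(f[3]))
    nb <- suppressWarnings(as.integer(f[10]))
    if (anyNA(c(cs, ce, nb)))
      stop(sprintf("%s line %d: non-numeric coordinate fields", path, i))
    sizes  <- suppressWarnings(as.integer(strsplit(f[11], ",")[[1]]))
    starts <- suppressWarnings(as.integer(strsplit(f[12], ",")[[1]]))
    if (anyNA(sizes) || anyNA(starts) ||
        length(sizes) != nb || length(starts) != nb)
      stop(sprintf("%s line %d: blockCount %d does not match blockSizes/blockStarts",
                   path, i, nb))
    bs <- cs + starts
    be <- bs + sizes
    if (starts[1L] != 0L || be[nb] != ce)
      stop(sprintf("%s line %d: blocks inconsistent with chromStart/chromEnd",
                   path, i))
    blocks <- cbind(start = bs, end = be)
    validate_blocks(blocks)
    list(read_id = f[4], chrom = f[1],
         strand = if (f[6] %in% c("+", "-")) f[6] else ".",
         blocks = blocks)
  }
  recs <- lapply(seq_along(lines), parse_line)
  data.table(
    read_id = vapply(recs, `[[`, "", "read_id"),
    chrom   = vapply(recs, `[[`, "", "chrom"),
    strand  = vapply(recs, `[[`, "", "strand"),
    sample_id = sample_id,
    blocks  = lapply(recs, `[[`, "blocks")
  )
}

empty_reads <- function() {
  data.table(read_id = character(), chrom = character(),
             strand = character(), sample_id = character(),
             blocks = list())
}

#' Write reads or isoforms as BED12
#'
#' @param x a `data.table` with `chrom`, `strand`, `blocks` and a name
#'   column (`read_id` or `isoform_id`); an optional `support` column is
#'   written to the score field.
#' @param path output file.
#' @export
write_bed12 <- function(x, path) {
  if (nrow(x) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  name_col <- if ("isoform_id" %in% names(x)) "isoform_id" else "read_id"
  score <- if ("support" %in% names(x)) x$support else rep(0L, nrow(x))
  lines <- vapply(seq_len(nrow(x)), function(i) {
    b <- x$blocks[[i]]
    cs <- b[1L, 1L]; ce <- b[nrow(b), 2L]
    paste(x$chrom[i], cs, ce, x[[name_col]][i], score[i],
          if (x$strand[i] %in% c("+", "-")) x$strand[i] else ".",
          cs, ce, "0", nrow(b),
          paste0(paste(b[, 2L] - b[, 1L], collapse = ","), ","),
          paste0(paste(b[, 1L] - cs, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation from GTF
#'
#' Coordinates are converted from GTF 1-based closed to 0-based half-open.
#' Junctions are derived from consecutive exons of each transcript;
#' single-exon transcripts contribute none.
#'
#' @param path GTF file with `exon` (and optionally `start_codon`, `CDS`)
#'   features carrying `transcript_id`/`gene_id` attributes.
#' @return an annotation object: a list with elements `transcripts`
#'   (data.table: transcript_id, gene_id, chrom, strand, blocks),
#'   `junctions` (data.table: chrom, start, end, strand), `start_codons`
#'   (data.table: transcript_id, chrom, strand, blocks), `cds` (same shape)
#'   and `gene_biotype` (named character vector).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.table(gr)
  if (!"type" %in% names(df)) stop("GTF has no feature type column")
  ex <- df[type == "exon"]
  if (nrow(ex) > 0L && (!"transcript_id" %in% names(ex) ||
                        anyNA(ex$transcript_id)))
    stop("exon feature without transcript_id")
  ## 1-based closed -> 0-based half-open
  ex[, `:=`(start = start - 1L)]
  setorder(ex, transcript_id, start)
  tx <- ex[, {
    b <- cbind(start = as.integer(start), end = as.integer(end))
    if (nrow(b) > 1L && any(b[-1L, 1L] < b[-nrow(b), 2L]))
      stop(sprintf("transcript %s: overlapping exons", .BY[[1]]))
    list(gene_id = gene_id[1L], chrom = as.character(seqnames[1L]),
         strand = as.character(strand[1L]), blocks = list(b))
  }, by = transcript_id]
  jx <- tx[, {
    j <- blocks_to_junctions(blocks[[1L]])
    if (nrow(j) == 0L) NULL
    else list(chrom = chrom, start = j[, 1L], end = j[, 2L], strand = strand)
  }, by = transcript_id][, transcript_id := NULL]
  jx <- if (nrow(jx) == 0L) empty_junctions() else
    unique(jx[, .(chrom, start, end, strand)])
  feat_blocks <- function(what) {
    fb <- df[type == what]
    if (nrow(fb) == 0L)
      return(data.table(transcript_id = character(), chrom = character(),
                        strand = character(), blocks = list()))
    fb[, start := start - 1L]
    setorder(fb, transcript_id, start)
    fb[, .(chrom = as.character(seqnames[1L]),
           strand = as.character(strand[1L]),
           blocks = list(cbind(start = as.integer(start),
                               end = as.integer(end)))),
       by = transcript_id]
  }
  bt_col <- intersect(c("gene_biotype", "gene_type"), names(df))
  gene_biotype <- if (length(bt_col)) {
    g <- df[!is.na(gene_id), .(bt = {
      v <- stats::na.omit(.SD[[bt_col[1L]]]); if (length(v)) v[1L] else "other"
    }), by = gene_id]
    setNames(g$bt, g$gene_id)
  } else setNames(rep("other", uniqueN(tx$gene_id)), unique(tx$gene_id))
  structure(list(transcripts = tx, junctions = jx,
                 start_codons = feat_blocks("start_codon"),
                 cds = feat_blocks("CDS"),
                 gene_biotype = gene_biotype),
            class = "ls_annotation")
}

empty_junctions <- function() {
  data.table(chrom = character(), start = integer(), end = integer(),
             strand = character())
}

#' Read a short-read splice-junction support table
#'
#' Tab-delimited columns: chrom, intron start, intron end, strand,
#' unique-read count. The default dialect is STAR-style 1-based closed
#' intron coordinates, converted on read.
#'
#' @param path junction table.
#' @param min_unique junctions supported by fewer uniquely mapping short
#'   reads are dropped (default 3).
#' @param dialect coordinate dialect of the file.
#' @return data.table chrom, start, end, strand, unique_reads (internal
#'   0-based half-open coordinates).
#' @export
read_junction_tab <- function(path, min_unique = 3L,
                              dialect = c("one_based_closed",
                                          "zero_based_half_open")) {
  dialect <- match.arg(dialect)
  dt <- fread(path, header = FALSE,
              col.names = c("chrom", "start", "end", "strand",
                            "unique_reads")[1:5])
  if (nrow(dt) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      unique_reads = integer()))
  if (any(dt$unique_reads < 0L)) stop("negative junction read counts")
  if (!all(dt$strand %in% c("+", "-"))) stop("junction strand must be + or -")
  if (dialect == "one_based_closed") dt[, start := start - 1L]
  dt[unique_reads >= min_unique][order(chrom, start, end)]
}

#' Write an isoform set as BED12 or GTF
#'
#' @param isoforms isoform table (see [filter_isoforms()]).
#' @param path output file.
#' @param format `"bed12"` or `"gtf"`.
#' @export
write_isoforms <- function(isoforms, path, format = c("bed12", "gtf")) {
  format <- match.arg(format)
  if (format == "bed12") return(write_bed12(isoforms, path))
  if (nrow(isoforms) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  lines <- unlist(lapply(seq_len(nrow(isoforms)), function(i) {
    b <- isoforms$blocks[[i]]
    gid <- if ("gene_id" %in% names(isoforms) && !is.na(isoforms$gene_id[i]))
      isoforms$gene_id[i] else isoforms$isoform_id[i]
    attr_str <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                        gid, isoforms$isoform_id[i],
                        if ("gene_biotype" %in% names(isoforms))
                          isoforms$gene_biotype[i] else "protein_coding")
    ## 0-based half-open -> 1-based closed
    tx_line <- paste(isoforms$chrom[i], "longsplice", "transcript",
                     b[1L, 1L] + 1L, b[nrow(b), 2L], ".",
                     isoforms$strand[i], ".", attr_str, sep = "\t")
    ex_lines <- vapply(seq_len(nrow(b)), function(k)
      paste(isoforms$chrom[i], "longsplice", "exon",
            b[k, 1L] + 1L, b[k, 2L], ".", isoforms$strand[i], ".",
            attr_str, sep = "\t"), character(1))
    c(tx_line, ex_lines)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return a `Biostrings::DNAStringSet` named by the first whitespace token
#'   of each header.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract the spliced (exonic) sequence of a transcript
#'
#' Exon block sequences are concatenated in genomic order and
#' reverse-complemented for minus-strand transcripts, so the result reads
#' 5' to 3'.
#'
#' @param genome `DNAStringSet` (or path to FASTA).
#' @param chrom chromosome name.
#' @param blocks exon block matrix, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @return a character scalar of length `sum(block lengths)`.
#' @export
extract_spliced_sequence <- function(genome, chrom, blocks, strand = "+") {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_genome(genome)
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  contig <- genome[[chrom]]
  if (any(blocks[, 2L] > length(contig)) || any(blocks[, 1L] < 0L))
    stop("block beyond contig bounds on ", chrom)
  parts <- lapply(seq_len(nrow(blocks)), function(i)
    Biostrings::subseq(contig, start = blocks[i, 1L] + 1L, end = blocks[i, 2L]))
  s <- do.call(Biostrings::xscat, parts)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Read the sample manifest
#'
#' Tab-delimited with header columns `sample_id`, `condition` and optional
#' `batch` (defaults to a single batch).
#'
#' @param path manifest TSV.
#' @export
read_manifest <- function(path) {
  m <- fread(path, header = TRUE, colClasses = "character")
  if (!all(c("sample_id", "condition") %in% names(m)))
    stop("manifest needs sample_id and condition columns")
  if (!"batch" %in% names(m)) m[, batch := "1"]
  m[, .(sample_id, condition, batch)]
}

#' Write / read an isoform-by-sample counts matrix as TSV
#'
#' @param counts numeric matrix, rows = isoform ids, columns = sample ids.
#' @param path file path.
#' @export
write_counts <- function(counts, path) {
  dt <- data.table(isoform_id = rownames(counts))
  for (s in colnames(counts)) dt[[s]] <- counts[, s]
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  dt <- fread(path, header = TRUE)
  m <- as.matrix(dt[, -1L])
  rownames(m) <- dt[[1L]]
  m
}
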