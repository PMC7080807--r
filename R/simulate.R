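## Deterministic synthetic-data generator: multi-isoform genes with
## alternative 3'/5' splice sites, cassette exons and retained introns; a
## random genome with canonical GT..AG splice motifs; and noisy long reads
## with splice-site jitter and 5' truncation, all with recorded ground
## truth.

#' Simulation configuration
#'
#' Defaults describe a desk-scale nanopore-like experiment: 20 genes of
#' 4-8 exons (80-300 nt) and 200-1000 nt introns, 2-4 isoforms per gene
#' differing by cassette exons, alternative 3'/5' splice sites (shifts of
#' 12-40 nt) or retained introns; reads get independent uniform splice-site
#' jitter up to 5 nt per junction endpoint and, with probability 0.3, a 5'
#' truncation of up to half the transcript, capped so that the retained
#' structure still identifies the generating isoform.
#'
#' @param seed RNG seed (all randomness in the generator derives from it).
#' @param n_genes number of genes.
#' @param isoforms_per_gene integer range `c(min, max)`.
#' @param n_exons integer range for exons of the base isoform.
#' @param exon_len,intron_len integer ranges in nt.
#' @param alt_delta range of alternative splice-site shifts in nt.
#' @param jitter per-endpoint splice-site jitter: a scalar `j` draws
#'   uniform integers on `[-j, j]`; a range `c(lo, hi)` draws a magnitude
#'   uniformly on `lo:hi` with a random sign.
#' @param trunc_prob probability a read is 5'-truncated.
#' @param trunc_max_frac maximum truncated fraction of transcript length.
#' @param keep_discriminating cap truncation so every read remains
#'   uniquely assignable to its generating isoform.
#' @param reads_per_isoform default per-sample read count per isoform.
#' @param fixed_counts if `TRUE` abundances are exact counts; otherwise
#'   Poisson draws.
#' @param event_types event repertoire used to derive extra isoforms.
#' @param chrom chromosome name.
#' @return a config list.
#' @export
sim_config <- function(seed = 1L, n_genes = 20L,
                       isoforms_per_gene = c(2L, 4L),
                       n_exons = c(4L, 8L), exon_len = c(80L, 300L),
                       intron_len = c(200L, 1000L), alt_delta = c(12L, 40L),
                       jitter = 5L, trunc_prob = 0.3, trunc_max_frac = 0.5,
                       keep_discriminating = TRUE, reads_per_isoform = 10L,
                       fixed_counts = TRUE,
                       event_types = c("es", "a3", "a5", "ir"),
                       chrom = "chrS") {
  as.list(environment())
}

rint <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(range[1L]:range[2L], n, replace = TRUE)
}

#' Generate a synthetic genome, annotation and truth isoform set
#'
#' Genes are laid out on one chromosome with 2 kb spacing, alternating
#' strands. Isoform 1 of each gene is the base exon chain; further
#' isoforms apply one planted event each (cassette skip, alternative
#' 3'/5' splice site, or intron retention). The genome is uniform random
#' nucleotides with canonical splice motifs (GT donors, AG acceptors,
#' strand-aware) planted at every annotated junction. Deterministic given
#' `config$seed`.
#'
#' @param config from [sim_config()].
#' @return list `genome` (DNAStringSet), `annotation` (as [read_gtf()]),
#'   `isoforms` (truth isoform table), `events` (planted event table).
#' @export
make_locus_set <- function(config = sim_config()) {
  set.seed(config$seed)
  offset <- 1000L
  iso_rows <- list()
  planted <- list()
  for (g in seq_len(config$n_genes)) {
    gene <- sprintf("gene%02d", g)
    strand <- if (g %% 2L == 1L) "+" else "-"
    ne <- rint(1L, config$n_exons)
    elens <- rint(ne, config$exon_len)
    ilens <- rint(max(0L, ne - 1L), config$intron_len)
    starts <- offset + cumsum(c(0L, head(elens, -1L) + ilens))
    base <- cbind(start = as.integer(starts),
                  end = as.integer(starts + elens))
    k <- rint(1L, config$isoforms_per_gene)
    variants <- list(base)
    ev_types <- rep(config$event_types, length.out = max(0L, k - 1L))
    used_introns <- integer(0)
    for (m in seq_len(k - 1L)) {
      v <- plant_variant(base, strand, ev_types[m], config, used_introns)
      if (is.null(v)) next
      used_introns <- c(used_introns, v$intron_idx)
      variants[[length(variants) + 1L]] <- v$blocks
      planted[[length(planted) + 1L]] <- data.table(
        gene_id = gene, type = v$type,
        iso_base = sprintf("tx_%02d_1", g),
        iso_alt = sprintf("tx_%02d_%d", g, length(variants)),
        detail = list(v$detail))
    }
    for (m in seq_along(variants)) {
      iso_rows[[length(iso_rows) + 1L]] <- data.table(
        isoform_id = sprintf("tx_%02d_%d", g, m),
        chrom = config$chrom, strand = strand,
        chain = list(blocks_to_junctions(variants[[m]])),
        blocks = list(variants[[m]]),
        start = variants[[m]][1L, 1L],
        end = variants[[m]][nrow(variants[[m]]), 2L],
        gene_id = gene)
    }
    offset <- max(vapply(variants, function(b) b[nrow(b), 2L], 1L)) + 2000L
  }
  truth <- rbindlist(iso_rows)
  glen <- max(truth$end) + 500L
  seq <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
               collapse = "")
  tx <- truth[, .(transcript_id = isoform_id, gene_id, chrom, strand, blocks)]
  jx <- unique(rbindlist(lapply(seq_len(nrow(truth)), function(i) {
    j <- truth$chain[[i]]
    if (nrow(j) == 0L) return(NULL)
    data.table(chrom = truth$chrom[i], start = j[, 1L], end = j[, 2L],
               strand = truth$strand[i])
  })))
  if (is.null(jx) || nrow(jx) == 0L) jx <- empty_junctions()
  seq <- plant_splice_motifs(seq, jx)
  genome <- Biostrings::DNAStringSet(setNames(seq, config$chrom))
  ann <- structure(list(
    transcripts = tx, junctions = jx,
    start_codons = data.table(transcript_id = character(),
                              chrom = character(), strand = character(),
                              blocks = list()),
    cds = data.table(transcript_id = character(), chrom = character(),
                     strand = character(), blocks = list()),
    gene_biotype = setNames(rep("protein_coding", uniqueN(truth$gene_id)),
                            unique(truth$gene_id))),
    class = "ls_annotation")
  events <- if (length(planted)) rbindlist(planted) else
    data.table(gene_id = character(), type = character(),
               iso_base = character(), iso_alt = character(),
               detail = list())
  list(genome = genome, annotation = ann, isoforms = truth, events = events,
       config = config)
}

## One structural variant of a base exon chain. Returns NULL when the
## requested event is infeasible for this gene.
plant_variant <- function(base, strand, type, config, used_introns) {
  ne <- nrow(base)
  if (ne < 3L) return(NULL)
  internal <- 2L:(ne - 1L)
  introns <- setdiff(seq_len(ne - 1L), used_introns)
  if (type == "es") {
    e <- sample(internal, 1L)
    list(type = "es", blocks = base[-e, , drop = FALSE], intron_idx = c(e - 1L, e),
         detail = c(exon_start = unname(base[e, 1L]),
                    exon_end = unname(base[e, 2L])))
  } else if (type == "ir") {
    if (!length(introns)) return(NULL)
    j <- sample(introns, 1L)
    blocks <- base
    blocks[j, 2L] <- blocks[j + 1L, 2L]
    blocks <- blocks[-(j + 1L), , drop = FALSE]
    list(type = "ir", blocks = blocks, intron_idx = j,
         detail = c(intron_start = unname(base[j, 2L]),
                    intron_end = unname(base[j + 1L, 1L])))
  } else if (type %in% c("a3", "a5")) {
    if (!length(introns)) return(NULL)
    j <- sample(introns, 1L)
    delta <- rint(1L, config$alt_delta)
    intron_len <- base[j + 1L, 1L] - base[j, 2L]
    if (intron_len <= delta + 30L) return(NULL)
    blocks <- base
    ## acceptor is the transcript-downstream intron boundary
    move_right_boundary <- (strand == "+") == (type == "a3")
    if (move_right_boundary) blocks[j + 1L, 1L] <- blocks[j + 1L, 1L] - delta
    else blocks[j, 2L] <- blocks[j, 2L] + delta
    list(type = type, blocks = blocks, intron_idx = j,
         detail = c(junction = j, delta = delta))
  } else NULL
}

## Plant GT (donor) / AG (acceptor) dinucleotides, strand-aware, at every
## junction; 0-based intron [start, end).
plant_splice_motifs <- function(seq, junctions) {
  s <- strsplit(seq, "")[[1L]]
  for (k in seq_len(nrow(junctions))) {
    a <- junctions$start[k]; b <- junctions$end[k]
    if (junctions$strand[k] == "+") {
      s[a + 1L] <- "G"; s[a + 2L] <- "T"      # first two intronic bases
      s[b - 1L] <- "A"; s[b] <- "G"           # last two intronic bases
    } else {
      s[a + 1L] <- "C"; s[a + 2L] <- "T"      # revcomp AG
      s[b - 1L] <- "A"; s[b] <- "C"           # revcomp GT
    }
  }
  paste(s, collapse = "")
}

## Jitter draws: scalar j -> uniform on [-j, j]; range c(lo, hi) ->
## magnitude uniform on lo:hi with random sign.
draw_jitter <- function(n, jitter) {
  if (length(jitter) == 1L)
    return(sample(seq(-jitter, jitter), n, replace = TRUE))
  mag <- sample(jitter[1L]:jitter[2L], n, replace = TRUE)
  as.integer(mag * sample(c(-1L, 1L), n, replace = TRUE))
}

## Remove `t` nt from the transcript 5' end of a block matrix.
truncate_blocks <- function(blocks, strand, t) {
  if (t <= 0L) return(blocks)
  lens <- blocks[, 2L] - blocks[, 1L]
  if (strand == "+") {
    cs <- cumsum(lens)
    m <- which(t < cs)[1L]
    off <- t - (if (m > 1L) cs[m - 1L] else 0L)
    out <- blocks[m:nrow(blocks), , drop = FALSE]
    out[1L, 1L] <- out[1L, 1L] + off
  } else {
    cs <- cumsum(rev(lens))
    mr <- which(t < cs)[1L]
    m <- nrow(blocks) - mr + 1L
    off <- t - (if (mr > 1L) cs[mr - 1L] else 0L)
    out <- blocks[1L:m, , drop = FALSE]
    out[nrow(out), 2L] <- out[nrow(out), 2L] - off
  }
  out
}

## Largest 5' truncation (tx nt) keeping the read uniquely structurally
## compatible with its generating isoform among the truth set.
max_unique_truncation <- function(iso_idx, truth, window = 10L,
                                  end_slack = 200L, margin = 15L) {
  bl <- truth$blocks[[iso_idx]]
  strand <- truth$strand[iso_idx]
  ne <- nrow(bl)
  if (ne == 1L) return(0L)
  lens <- if (strand == "+") bl[, 2L] - bl[, 1L] else rev(bl[, 2L] - bl[, 1L])
  cs <- cumsum(lens)
  unique_at <- function(t) {
    rb <- truncate_blocks(bl, strand, t)
    hits <- sum(vapply(seq_len(nrow(truth)), function(j)
      truth$chrom[j] == truth$chrom[iso_idx] &&
        read_compatible(rb, strand, truth[j], window, end_slack),
      logical(1)))
    hits == 1L
  }
  for (m in (ne - 1L):1L) {      # truncation point inside tx exon m
    deep <- cs[m] - margin
    if (deep > 0L && unique_at(deep)) return(as.integer(deep))
    shallow <- if (m > 1L) cs[m - 1L] else 0L
    if (unique_at(shallow)) return(as.integer(shallow))
  }
  0L
}

#' Simulate noisy long reads from a truth isoform set
#'
#' Per sample and isoform, the requested number of reads is emitted (or
#' Poisson-drawn when `fixed_counts` is off). Each read is 5'-truncated in
#' transcript space with probability `trunc_prob` (capped to keep the read
#' uniquely assignable when `keep_discriminating`), mapped back to genomic
#' blocks, and every remaining junction endpoint is jittered independently
#' by a uniform integer in `[-jitter, jitter]`. 3' ends are exact.
#'
#' @param locus output of [make_locus_set()] (or a compatible list with
#'   `isoforms`).
#' @param config from [sim_config()]; the read stream is seeded with
#'   `config$seed + 7919`.
#' @param abundance optional isoform-by-sample matrix of read counts;
#'   defaults to `reads_per_isoform` everywhere.
#' @param manifest sample manifest; defaults to one sample, one condition.
#' @return list `reads` (reads table, all samples), `read_truth`
#'   (per-read: generating isoform, truncation, jitter matrix),
#'   `manifest`, `planned_counts`.
#' @export
simulate_reads <- function(locus, config = locus$config, abundance = NULL,
                           manifest = NULL) {
  truth <- locus$isoforms
  if (is.null(manifest))
    manifest <- data.table(sample_id = "s1", condition = "A", batch = "1")
  if (is.null(abundance)) {
    abundance <- matrix(config$reads_per_isoform, nrow = nrow(truth),
                        ncol = nrow(manifest),
                        dimnames = list(truth$isoform_id,
                                        manifest$sample_id))
  }
  set.seed(config$seed + 7919L)
  tmax <- if (config$keep_discriminating && config$trunc_prob > 0)
    vapply(seq_len(nrow(truth)), function(i)
      max_unique_truncation(i, truth, margin = 2L * max(config$jitter) + 5L),
      1L)
  else rep(.Machine$integer.max, nrow(truth))
  margin <- 2L * max(config$jitter) + 5L
  read_rows <- list(); truth_rows <- list()
  counter <- 0L
  planned <- abundance
  for (s in manifest$sample_id) {
    for (i in seq_len(nrow(truth))) {
      n <- abundance[truth$isoform_id[i], s]
      if (!config$fixed_counts) n <- rpois(1L, n)
      planned[truth$isoform_id[i], s] <- n
      if (n == 0L) next
      bl <- truth$blocks[[i]]
      txlen <- blocks_len(bl)
      for (r in seq_len(n)) {
        counter <- counter + 1L
        t <- 0L
        if (config$trunc_prob > 0 && runif(1L) < config$trunc_prob) {
          t <- as.integer(floor(runif(1L) * config$trunc_max_frac * txlen))
          t <- min(t, tmax[i], txlen - margin)
          t <- max(t, 0L)
        }
        rb <- truncate_blocks(bl, truth$strand[i], t)
        ## keep the 5'-terminal exon remnant clear of the jitter window
        first_len <- if (truth$strand[i] == "+") rb[1L, 2L] - rb[1L, 1L]
        else rb[nrow(rb), 2L] - rb[nrow(rb), 1L]
        if (nrow(rb) > 1L && first_len < margin) {
          t <- max(0L, t - (margin - first_len))
          rb <- truncate_blocks(bl, truth$strand[i], t)
        }
        jx <- blocks_to_junctions(rb)
        jit <- matrix(0L, nrow = nrow(jx), ncol = 2L)
        if (max(config$jitter) > 0L && nrow(jx) > 0L) {
          jit <- matrix(draw_jitter(2L * nrow(jx), config$jitter),
                        ncol = 2L)
          jxj <- jx + jit
          rb <- junctions_to_blocks(jxj, rb[1L, 1L], rb[nrow(rb), 2L])
        }
        rid <- sprintf("r_%s_%06d", s, counter)
        read_rows[[counter]] <- data.table(
          read_id = rid, chrom = truth$chrom[i],
          strand = truth$strand[i], sample_id = s, blocks = list(rb))
        truth_rows[[counter]] <- data.table(
          read_id = rid, sample_id = s, isoform_id = truth$isoform_id[i],
          truncation = t, true_chain = list(jx), jitter = list(jit))
      }
    }
  }
  list(reads = if (counter) rbindlist(read_rows) else empty_reads(),
       read_truth = if (counter) rbindlist(truth_rows) else data.table(),
       manifest = manifest, planned_counts = planned)
}
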