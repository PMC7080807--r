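## Collapse fully corrected reads into a first-pass isoform set keyed by
## splice-junction chains, call representative TSS/TES from read-end
## density, consolidate truncation-explainable subchain groups, reassign
## all reads under a unique-best-match contract, and keep isoforms with
## >= min_support uniquely assigned reads.

#' Group fully corrected reads by their splice-junction chains
#'
#' Spliced reads group by exact chain equality; single-exon reads group by
#' overlapping locus (single-linkage interval overlap per chrom/strand).
#'
#' @param reads fully corrected reads table.
#' @return data.table with one row per group: `chrom`, `strand`, `chain`
#'   (list-column), `read_ids` (list-column), `starts`, `ends`
#'   (list-columns of read outer coordinates), `n_reads`.
#' @export
group_by_chain <- function(reads) {
  if (nrow(reads) == 0L)
    return(data.table(chrom = character(), strand = character(),
                      chain = list(), read_ids = list(), starts = list(),
                      ends = list(), n_reads = integer()))
  chains <- lapply(reads$blocks, blocks_to_junctions)
  keys <- vapply(seq_len(nrow(reads)), function(i)
    chain_key(reads$chrom[i], reads$strand[i], chains[[i]]), character(1))
  spliced <- vapply(chains, nrow, 1L) > 0L
  out <- list()
  if (any(spliced)) {
    idx <- split(which(spliced), keys[spliced])
    out <- lapply(idx, function(ii) {
      data.table(chrom = reads$chrom[ii[1L]], strand = reads$strand[ii[1L]],
                 chain = list(chains[[ii[1L]]]),
                 read_ids = list(reads$read_id[ii]),
                 starts = list(vapply(reads$blocks[ii], function(b) b[1L, 1L], 1L)),
                 ends = list(vapply(reads$blocks[ii], function(b) b[nrow(b), 2L], 1L)),
                 n_reads = length(ii))
    })
  }
  if (any(!spliced)) {
    se <- data.table(i = which(!spliced),
                     chrom = reads$chrom[!spliced],
                     strand = reads$strand[!spliced],
                     start = vapply(reads$blocks[!spliced], function(b) b[1L, 1L], 1L),
                     end = vapply(reads$blocks[!spliced], function(b) b[1L, 2L], 1L))
    setorder(se, chrom, strand, start)
    se[, grp := {
      g <- integer(.N); cur <- 1L; maxend <- end[1L]
      if (.N) g[1L] <- 1L
      for (k in seq_len(.N)[-1L]) {
        if (start[k] >= maxend) cur <- cur + 1L
        maxend <- max(maxend, end[k]); g[k] <- cur
      }
      g
    }, by = .(chrom, strand)]
    se_groups <- se[, .(ii = list(i)), by = .(chrom, strand, grp)]
    out <- c(out, lapply(seq_len(nrow(se_groups)), function(r) {
      ii <- se_groups$ii[[r]]
      data.table(chrom = se_groups$chrom[r], strand = se_groups$strand[r],
                 chain = list(blocks_to_junctions(reads$blocks[[ii[1L]]])),
                 read_ids = list(reads$read_id[ii]),
                 starts = list(vapply(reads$blocks[ii], function(b) b[1L, 1L], 1L)),
                 ends = list(vapply(reads$blocks[ii], function(b) b[nrow(b), 2L], 1L)),
                 n_reads = length(ii))
    }))
  }
  rbindlist(out)
}

#' Call representative transcript ends from read end-coordinate density
#'
#' Coordinates are clustered by single-linkage within `end_window`; the
#' cluster with most reads wins and its modal coordinate is returned.
#' Ties favor the longer transcript: equal-size clusters pick the cluster
#' whose mode is outward-most, and equal-frequency modes pick the
#' outward-most coordinate (5'-most for the start side, 3'-most for the
#' end side, which is outward on both strands).
#'
#' @param starts,ends genomic outer coordinates of the group's reads.
#' @param end_window single-linkage distance (default 100 nt).
#' @return `c(left, right)` representative genomic outer coordinates.
#' @export
call_ends <- function(starts, ends, end_window = 100L) {
  c(call_end_1d(starts, end_window, outward = "min"),
    call_end_1d(ends, end_window, outward = "max"))
}

call_end_1d <- function(x, end_window, outward = c("min", "max")) {
  outward <- match.arg(outward)
  pick_out <- if (outward == "min") min else max
  xs <- sort(x)
  brk <- cumsum(c(1L, as.integer(diff(xs) > end_window)))
  clusters <- split(xs, brk)
  sizes <- lengths(clusters)
  modes <- vapply(clusters, function(v) {
    tb <- table(v)
    cand <- as.integer(names(tb)[tb == max(tb)])
    pick_out(cand)
  }, 1)
  win <- which(sizes == max(sizes))
  if (length(win) > 1L) win <- win[which(modes[win] == pick_out(modes[win]))[1L]]
  as.integer(modes[win[1L]])
}

#' Build the first-pass isoform set (one isoform per junction chain)
#'
#' @param groups output of [group_by_chain()].
#' @param end_window passed to [call_ends()].
#' @return isoform table: `isoform_id`, `chrom`, `strand`, `chain`,
#'   `blocks`, `start`, `end`, `n_reads`.
#' @export
first_pass <- function(groups, end_window = 100L) {
  if (nrow(groups) == 0L)
    return(empty_isoforms())
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    ends <- call_ends(groups$starts[[i]], groups$ends[[i]], end_window)
    chain <- groups$chain[[i]]
    data.table(chrom = groups$chrom[i], strand = groups$strand[i],
               chain = list(chain),
               blocks = list(junctions_to_blocks(chain, ends[1L], ends[2L])),
               start = ends[1L], end = ends[2L],
               n_reads = groups$n_reads[i])
  })
  iso <- rbindlist(rows)
  setorder(iso, chrom, start, end)
  iso[, isoform_id := sprintf("iso_%04d", .I)]
  setcolorder(iso, "isoform_id")
  iso[]
}

empty_isoforms <- function() {
  data.table(isoform_id = character(), chrom = character(),
             strand = character(), chain = list(), blocks = list(),
             start = integer(), end = integer(), n_reads = integer())
}

## TRUE if chain `sub` equals a contiguous run of `full` starting at
## offset o (1-based junction index), within +/- window per coordinate.
chain_match_at <- function(sub, full, o, window) {
  k <- nrow(sub)
  seg <- full[o:(o + k - 1L), , drop = FALSE]
  all(abs(seg - sub) <= window)
}

## Offsets (1-based) at which `sub` is a contiguous subchain of `full`.
subchain_offsets <- function(sub, full, window) {
  k <- nrow(sub); m <- nrow(full)
  if (k == 0L || k > m) return(integer(0))
  Filter(function(o) chain_match_at(sub, full, o, window), seq_len(m - k + 1L))
}

#' Consolidate truncation-explainable first-pass isoforms
#'
#' Nanopore cDNA reads lose 5' sequence, so 5'-truncated reads of isoform J
#' form their own chain groups whose chains are strand-aware 5' suffixes of
#' J's chain. A spliced first-pass isoform is removed when (i) its chain is
#' a proper contiguous 5'-side subchain of another isoform's chain, (ii)
#' its 5' outer coordinate lies inside the corresponding exon of the longer
#' isoform (distinguishing truncation from genuine retained first introns),
#' and (iii) its 3' outer end matches the longer isoform's within
#' `end_slack`. A single-exon first-pass isoform is removed when its block
#' lies inside the exon footprint of a spliced isoform. Reads of removed
#' groups are recovered (or judged ambiguous) by [assign_reads()].
#'
#' @param isoforms first-pass isoform table.
#' @param window junction coordinate tolerance (default 10).
#' @param end_slack tolerance on outer ends (default 200).
#' @return filtered isoform table.
#' @export
consolidate_isoforms <- function(isoforms, window = 10L, end_slack = 200L) {
  n <- nrow(isoforms)
  if (n < 2L) return(isoforms)
  nj <- vapply(isoforms$chain, nrow, 1L)
  drop <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (nj[i] == 0L) next
    for (j in seq_len(n)) {
      if (i == j || nj[j] <= nj[i]) next
      if (isoforms$chrom[i] != isoforms$chrom[j] ||
          isoforms$strand[i] != isoforms$strand[j]) next
      ci <- isoforms$chain[[i]]; cj <- isoforms$chain[[j]]
      k <- nj[i]; m <- nj[j]
      if (isoforms$strand[i] == "+") {
        ## 5' truncation removes leading (genomically left) junctions
        if (!chain_match_at(ci, cj, m - k + 1L, window)) next
        prev_intron_end <- cj[m - k, 2L]
        if (isoforms$start[i] < prev_intron_end - window) next
        if (abs(isoforms$end[i] - isoforms$end[j]) > end_slack) next
      } else {
        if (!chain_match_at(ci, cj, 1L, window)) next
        next_intron_start <- cj[k + 1L, 1L]
        if (isoforms$end[i] > next_intron_start + window) next
        if (abs(isoforms$start[i] - isoforms$start[j]) > end_slack) next
      }
      drop[i] <- TRUE
      break
    }
  }
  ## single-exon groups explainable as truncation of a spliced isoform
  for (i in seq_len(n)) {
    if (nj[i] > 0L || drop[i]) next
    for (j in seq_len(n)) {
      if (nj[j] == 0L || drop[j]) next
      if (isoforms$chrom[i] != isoforms$chrom[j]) next
      bj <- isoforms$blocks[[j]]
      q <- nrow(bj)
      tol_l <- c(end_slack, rep(window, q - 1L))
      tol_r <- c(rep(window, q - 1L), end_slack)
      if (any(isoforms$start[i] >= bj[, 1L] - tol_l &
              isoforms$end[i] <= bj[, 2L] + tol_r)) {
        drop[i] <- TRUE; break
      }
    }
  }
  isoforms[!drop]
}

## Structural compatibility of one read with one isoform.
## A spliced read is compatible iff its chain matches a contiguous subchain
## of the isoform's chain (each coordinate within +/- window) and its outer
## blocks stay inside the matched exons: beyond the matched subchain the
## read may extend only to the isoform's neighboring intron boundary
## (+ window), or past the isoform's terminal exon by end_slack.
## A single-exon read must lie inside one exon of the isoform (terminal
## exon edges relaxed by end_slack).
read_compatible <- function(rblocks, rstrand, iso_row, window, end_slack) {
  if (rstrand %in% c("+", "-") && rstrand != iso_row$strand) return(FALSE)
  rch <- blocks_to_junctions(rblocks)
  ich <- iso_row$chain[[1L]]
  rs <- rblocks[1L, 1L]; re <- rblocks[nrow(rblocks), 2L]
  if (nrow(rch) == 0L) {
    bj <- iso_row$blocks[[1L]]
    q <- nrow(bj)
    tol_l <- c(end_slack, rep(window, max(0L, q - 1L)))
    tol_r <- c(rep(window, max(0L, q - 1L)), end_slack)
    return(any(rs >= bj[, 1L] - tol_l & re <= bj[, 2L] + tol_r))
  }
  m <- nrow(ich); k <- nrow(rch)
  if (k > m) return(FALSE)
  for (o in subchain_offsets(rch, ich, window)) {
    left_ok <- if (o == 1L) rs >= iso_row$start - end_slack
    else rs >= ich[o - 1L, 2L] - window
    right_ok <- if (o + k - 1L == m) re <= iso_row$end + end_slack
    else re <= ich[o + k, 1L] + window
    if (left_ok && right_ok) return(TRUE)
  }
  FALSE
}

#' Assign all reads (including uncorrected and unspliced) to isoforms
#'
#' A read compatible with exactly one isoform is assigned (`unique`);
#' compatibility with more than one leaves it unassigned (`ambiguous`,
#' mirroring a MAPQ < 1 multi-mapper), with none, `no_match`. Reads whose
#' exonic length falls below `min_exonic` are `too_short`.
#'
#' @param reads reads table (use corrected blocks where available).
#' @param isoforms isoform table.
#' @param window junction coordinate tolerance (default 10).
#' @param end_slack allowed overhang past isoform terminal exons
#'   (default 200).
#' @param min_exonic minimum read exonic length (default 0).
#' @return data.table `read_id`, `sample_id`, `isoform_id` (NA when
#'   unassigned), `reason`.
#' @export
assign_reads <- function(reads, isoforms, window = 10L, end_slack = 200L,
                         min_exonic = 0L) {
  n <- nrow(reads)
  iso_id <- rep(NA_character_, n)
  reason <- rep("no_match", n)
  if (nrow(isoforms) == 0L || n == 0L)
    return(data.table(read_id = reads$read_id, sample_id = reads$sample_id,
                      isoform_id = iso_id, reason = reason))
  by_chrom <- split(seq_len(nrow(isoforms)), isoforms$chrom)
  for (i in seq_len(n)) {
    b <- reads$blocks[[i]]
    if (blocks_len(b) < min_exonic) { reason[i] <- "too_short"; next }
    cand <- by_chrom[[reads$chrom[i]]]
    if (is.null(cand)) next
    rs <- b[1L, 1L]; re <- b[nrow(b), 2L]
    cand <- cand[isoforms$start[cand] - end_slack <= rs &
                   isoforms$end[cand] + end_slack >= re]
    hits <- cand[vapply(cand, function(j)
      read_compatible(b, reads$strand[i], isoforms[j], window, end_slack),
      logical(1))]
    if (length(hits) == 1L) {
      iso_id[i] <- isoforms$isoform_id[hits]; reason[i] <- "unique"
    } else if (length(hits) > 1L) reason[i] <- "ambiguous"
  }
  data.table(read_id = reads$read_id, sample_id = reads$sample_id,
             isoform_id = iso_id, reason = reason)
}

#' Keep isoforms with enough uniquely assigned supporting reads
#'
#' @param isoforms isoform table.
#' @param assignment output of [assign_reads()].
#' @param min_support minimum uniquely assigned reads (default 3).
#' @return isoform table with an updated `support` column.
#' @export
filter_isoforms <- function(isoforms, assignment, min_support = 3L) {
  sup <- assignment[reason == "unique", .N, by = isoform_id]
  out <- copy(isoforms)
  out[, support := 0L]
  out[sup, support := i.N, on = "isoform_id"]
  out[support >= min_support]
}

#' Assign isoforms to annotated genes
#'
#' The gene sharing the most splice junctions wins; ties break by exonic
#' overlap; isoforms matching no annotated gene get a synthetic locus id.
#'
#' @param isoforms isoform table.
#' @param annotation annotation from [read_gtf()].
#' @return isoform table with a `gene_id` column.
#' @export
assign_genes <- function(isoforms, annotation) {
  tx <- annotation$transcripts
  out <- copy(isoforms)
  out[, gene_id := NA_character_]
  if (nrow(tx) == 0L || nrow(out) == 0L) {
    out[, gene_id := paste0("locus:", chrom, ":", start)]
    return(out)
  }
  gene_tbl <- tx[, .(gene_id = gene_id[1L], chrom = chrom[1L],
                     strand = strand[1L], blocks = blocks), by = transcript_id]
  for (i in seq_len(nrow(out))) {
    same <- gene_tbl[chrom == out$chrom[i] & strand == out$strand[i]]
    if (nrow(same) == 0L) next
    ich <- out$chain[[i]]
    ikey <- if (nrow(ich)) paste(ich[, 1L], ich[, 2L]) else character(0)
    shared <- vapply(same$blocks, function(b) {
      jj <- blocks_to_junctions(b)
      if (nrow(jj) == 0L) return(0L)
      sum(paste(jj[, 1L], jj[, 2L]) %in% ikey)
    }, 1L)
    ovl <- vapply(same$blocks, function(b)
      blocks_overlap(out$blocks[[i]], b), 1L)
    score <- data.table(gene_id = same$gene_id, shared = shared, ovl = ovl)
    score <- score[, .(shared = max(shared), ovl = max(ovl)), by = gene_id]
    score <- score[shared > 0L | ovl > 0L]
    if (nrow(score) == 0L) next
    setorder(score, -shared, -ovl, gene_id)
    out$gene_id[i] <- score$gene_id[1L]
  }
  out[is.na(gene_id), gene_id := paste0("locus:", chrom, ":", start)]
  out[]
}

#' Categorize an isoform against the annotation
#'
#' Precedence: `annotated` (chain equals an annotated transcript's chain)
#' > `novel_site` (a junction endpoint absent from annotation) >
#' `retained_intron` (an annotated same-gene junction fully inside one
#' exon) > `novel_exon` (an exon overlapping no annotated exon of the
#' gene) > `novel_combination`.
#'
#' @param isoforms isoform table with `gene_id`.
#' @param annotation annotation from [read_gtf()].
#' @return isoform table with a `category` column.
#' @export
categorize_vs_annotation <- function(isoforms, annotation) {
  tx <- annotation$transcripts
  out <- copy(isoforms)
  out[, category := NA_character_]
  ann_keys <- vapply(seq_len(nrow(tx)), function(i)
    chain_key(tx$chrom[i], tx$strand[i],
              blocks_to_junctions(tx$blocks[[i]])), character(1))
  ann_sites <- annotation$junctions[, .(pos = c(start, end)),
                                    by = .(chrom, strand)]
  for (i in seq_len(nrow(out))) {
    ich <- out$chain[[i]]
    g <- out$gene_id[i]
    gtx <- tx[gene_id == g]
    if (nrow(ich) == 0L) {
      se_match <- nrow(gtx) > 0L && any(vapply(gtx$blocks, function(b)
        nrow(b) == 1L && b[1L, 2L] > out$start[i] && b[1L, 1L] < out$end[i],
        logical(1)))
      out$category[i] <- if (se_match) "annotated" else "novel_combination"
      next
    }
    key <- chain_key(out$chrom[i], out$strand[i], ich)
    if (key %in% ann_keys) { out$category[i] <- "annotated"; next }
    known <- ann_sites[chrom == out$chrom[i] & strand == out$strand[i], pos]
    if (!all(c(ich[, 1L], ich[, 2L]) %in% known)) {
      out$category[i] <- "novel_site"; next
    }
    gj <- if (nrow(gtx)) unique(rbindlist(lapply(gtx$blocks, function(b) {
      j <- blocks_to_junctions(b)
      if (nrow(j)) data.table(start = j[, 1L], end = j[, 2L]) else NULL
    }))) else data.table(start = integer(), end = integer())
    bi <- out$blocks[[i]]
    ri <- nrow(gj) > 0L && any(vapply(seq_len(nrow(gj)), function(k)
      any(bi[, 1L] <= gj$start[k] & gj$end[k] <= bi[, 2L]), logical(1)))
    if (ri) { out$category[i] <- "retained_intron"; next }
    gex <- if (nrow(gtx)) do.call(rbind, gtx$blocks) else
      matrix(integer(0), ncol = 2L)
    ne <- any(vapply(seq_len(nrow(bi)), function(k)
      nrow(gex) == 0L ||
        !any(gex[, 1L] < bi[k, 2L] & gex[, 2L] > bi[k, 1L]), logical(1)))
    out$category[i] <- if (ne) "novel_exon" else "novel_combination"
  }
  out[]
}

#' Isoform saturation curve by read subsampling
#'
#' Reads are subsampled without replacement at each depth (RNG seeded once
#' with `seed`, depths processed in order) and the correct + collapse
#' pipeline is re-run.
#'
#' @param reads raw reads table.
#' @param depths read depths to evaluate.
#' @param sites valid-site set for correction.
#' @param seed RNG seed.
#' @param ... passed to [collapse_pipeline()].
#' @return data.table `depth`, `n_isoforms`.
#' @export
saturation_curve <- function(reads, depths, sites, seed = 1L, ...) {
  stopifnot(all(depths <= nrow(reads)))
  set.seed(seed)
  res <- lapply(depths, function(d) {
    sub <- reads[sample.int(nrow(reads), d)]
    n <- if (d == 0L) 0L else nrow(collapse_pipeline(sub, sites, ...)$isoforms)
    data.table(depth = d, n_isoforms = n)
  })
  rbindlist(res)
}
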