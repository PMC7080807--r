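## Splice-site correction: fill indel-scale alignment gaps, then snap each
## read splice site to the nearest valid site (annotated and/or
## short-read-supported) within a fixed window. Reads whose junctions are
## all valid after snapping are "fully corrected"; novel splice sites are
## never invented.

#' Merge alignment blocks separated by indel-scale gaps
#'
#' Adjacent blocks separated by a gap strictly smaller than `max_gap` are
#' merged into one exon; larger gaps are kept as candidate introns. The
#' operation is idempotent.
#'
#' @param blocks exon block matrix (sorted, non-overlapping).
#' @param max_gap gaps `< max_gap` nt are filled (default 30).
#' @return merged block matrix.
#' @export
fill_small_gaps <- function(blocks, max_gap = 30L) {
  n <- nrow(blocks)
  if (n < 2L || max_gap <= 0L) return(blocks)
  gaps <- blocks[-1L, 1L] - blocks[-n, 2L]
  grp <- cumsum(c(1L, as.integer(gaps >= max_gap)))
  starts <- tapply(blocks[, 1L], grp, min)
  ends <- tapply(blocks[, 2L], grp, max)
  cbind(start = as.integer(starts), end = as.integer(ends))
}

#' @rdname fill_small_gaps
#' @param reads a reads table ([read_bed12()]).
#' @export
fill_small_gaps_reads <- function(reads, max_gap = 30L) {
  out <- copy(reads)
  out[, blocks := lapply(blocks, fill_small_gaps, max_gap = max_gap)]
  out
}

#' Build the set of valid splice sites
#'
#' Union of annotation-derived and (filtered) short-read-derived donor and
#' acceptor coordinates, keyed by chromosome, strand and side, with
#' provenance (`annotation`, `short_read` or `both`) per site.
#'
#' @param annotation annotation from [read_gtf()] (or `NULL`).
#' @param support junction support from [read_junction_tab()] (or `NULL`).
#' @return a `ls_valid_sites` object.
#' @export
build_valid_sites <- function(annotation = NULL, support = NULL) {
  ann_j <- if (!is.null(annotation)) copy(annotation$junctions) else
    empty_junctions()
  sr_j <- if (!is.null(support) && nrow(support))
    support[, .(chrom, start, end, strand)] else empty_junctions()
  if (nrow(ann_j) + nrow(sr_j) == 0L)
    stop("no valid splice sites: correction impossible")
  ann_j[, src := 1L]   # bit 1 = annotation
  if (nrow(sr_j)) sr_j[, src := 2L]  # bit 2 = short read
  jx <- rbind(ann_j, if (nrow(sr_j)) sr_j)
  jx <- jx[, .(src = sum(unique(src))), by = .(chrom, start, end, strand)]
  jx[, prov := c("annotation", "short_read", "both")[src]]
  ## donor = 5'SS (intron start on +, intron end on -); acceptor = 3'SS.
  donors <- jx[, .(chrom, strand, side = "donor",
                   pos = fifelse(strand == "+", start, end), src)]
  accept <- jx[, .(chrom, strand, side = "acceptor",
                   pos = fifelse(strand == "+", end, start), src)]
  sites <- rbind(donors, accept)[, .(src = sum(unique(src))),
                                 by = .(chrom, strand, side, pos)]
  sites[, src := fifelse(src > 3L, 3L, src)]
  sites[, prov := c("annotation", "short_read", "both")[src]]
  setorder(sites, chrom, strand, side, pos)
  idx <- split(sites, paste(sites$chrom, sites$strand, sites$side, sep = "|"))
  structure(list(sites = sites[, .(chrom, strand, side, pos, prov)],
                 junctions = jx[, .(chrom, start, end, strand, prov)],
                 index = idx),
            class = "ls_valid_sites")
}

## Snap one coordinate to the nearest valid site within `window`.
## Tie-break: provenance both > annotation > short_read, then smaller
## coordinate. Returns NA if no site is in range.
snap_site <- function(pos, tbl, window) {
  if (is.null(tbl) || nrow(tbl) == 0L) return(NA_integer_)
  d <- abs(tbl$pos - pos)
  inw <- which(d <= window)
  if (!length(inw)) return(NA_integer_)
  cand <- inw[d[inw] == min(d[inw])]
  if (length(cand) > 1L) {
    rank <- c(annotation = 2L, short_read = 1L, both = 3L)[tbl$prov[cand]]
    cand <- cand[rank == max(rank)]
    cand <- cand[which.min(tbl$pos[cand])]
  }
  tbl$pos[cand[1L]]
}

#' Correct the splice sites of reads against a valid-site set
#'
#' Each junction endpoint already equal to a valid site is untouched;
#' otherwise it is replaced by the nearest valid site of the same
#' side/strand within `window` nt. A junction with no reachable valid site,
#' or whose correction would create an empty/inverted exon, is marked
#' uncorrectable and the read is not fully corrected. Donor and acceptor
#' are corrected independently. Reads with unknown strand inherit the
#' strand of the first junction exactly matching a valid junction.
#'
#' @param reads gap-filled reads table.
#' @param sites valid-site set from [build_valid_sites()].
#' @param window maximum snap distance in nt (default 10).
#' @return list with `reads` (corrected blocks, plus `status`) and
#'   `junctions` (per-read, per-junction outcome table with signed deltas).
#' @export
correct_reads <- function(reads, sites, window = 10L) {
  n <- nrow(reads)
  status <- character(n)
  new_blocks <- vector("list", n)
  strands <- reads$strand
  jrec <- vector("list", n)
  for (i in seq_len(n)) {
    b <- reads$blocks[[i]]
    if (nrow(b) == 1L) {
      status[i] <- "unspliced"; new_blocks[[i]] <- b
      next
    }
    jx <- blocks_to_junctions(b)
    strand <- strands[i]
    if (!strand %in% c("+", "-")) {
      strand <- infer_strand(reads$chrom[i], jx, sites)
      strands[i] <- strand
    }
    if (!strand %in% c("+", "-")) {
      status[i] <- "partially_corrected"; new_blocks[[i]] <- b
      jrec[[i]] <- data.table(read_id = reads$read_id[i],
                              junction = seq_len(nrow(jx)),
                              outcome = "uncorrectable",
                              delta_donor = NA_integer_,
                              delta_acceptor = NA_integer_)
      next
    }
    don_tbl <- sites$index[[paste(reads$chrom[i], strand, "donor", sep = "|")]]
    acc_tbl <- sites$index[[paste(reads$chrom[i], strand, "acceptor", sep = "|")]]
    nj <- nrow(jx)
    prop <- jx
    d_don <- d_acc <- rep(NA_integer_, nj)
    ok <- rep(TRUE, nj)
    for (k in seq_len(nj)) {
      ## genomic left endpoint = intron start, right = intron end
      left_is_donor <- strand == "+"
      sl <- snap_site(jx[k, 1L], if (left_is_donor) don_tbl else acc_tbl, window)
      sr <- snap_site(jx[k, 2L], if (left_is_donor) acc_tbl else don_tbl, window)
      if (is.na(sl) || is.na(sr)) { ok[k] <- FALSE; next }
      prop[k, 1L] <- sl; prop[k, 2L] <- sr
      if (left_is_donor) { d_don[k] <- sl - jx[k, 1L]; d_acc[k] <- sr - jx[k, 2L] }
      else { d_acc[k] <- sl - jx[k, 1L]; d_don[k] <- sr - jx[k, 2L] }
    }
    ## geometry pass: accepted junctions must keep exons >= 1 nt and
    ## introns >= 1 nt; violators revert to original coords, uncorrectable
    acc <- jx
    prev_end <- b[1L, 1L]   # left boundary of current exon
    for (k in seq_len(nj)) {
      cand <- if (ok[k]) prop[k, ] else jx[k, ]
      nxt <- if (k < nj) min(prop[k + 1L, 1L], jx[k + 1L, 1L]) else b[nrow(b), 2L]
      good <- cand[1L] > prev_end && cand[2L] > cand[1L] && cand[2L] < nxt
      if (ok[k] && !good) { ok[k] <- FALSE; cand <- jx[k, ] }
      acc[k, ] <- cand
      prev_end <- acc[k, 2L]
    }
    outcome <- ifelse(!ok, "uncorrectable",
                      ifelse(d_don == 0L & d_acc == 0L, "already_valid",
                             "snapped"))
    jrec[[i]] <- data.table(read_id = reads$read_id[i],
                            junction = seq_len(nj), outcome = outcome,
                            delta_donor = d_don, delta_acceptor = d_acc)
    new_blocks[[i]] <- junctions_to_blocks(acc, b[1L, 1L], b[nrow(b), 2L])
    status[i] <- if (all(ok)) "fully_corrected" else "partially_corrected"
  }
  out <- copy(reads)
  out[, `:=`(blocks = new_blocks, strand = strands, status = status)]
  junctions <- if (length(jrec)) rbindlist(jrec[!vapply(jrec, is.null, TRUE)])
  else NULL
  if (is.null(junctions) || nrow(junctions) == 0L)
    junctions <- data.table(read_id = character(), junction = integer(),
                            outcome = character(), delta_donor = integer(),
                            delta_acceptor = integer())
  list(reads = out, junctions = junctions)
}

## Strand inheritance for unknown-strand reads: strand of the first read
## junction exactly matching a valid junction; "." if none or ambiguous.
infer_strand <- function(chrom_, jx, sites) {
  for (k in seq_len(nrow(jx))) {
    hit <- sites$junctions[chrom == chrom_ & start == jx[k, 1L] &
                             end == jx[k, 2L]]
    if (nrow(hit) == 1L) return(hit$strand)
    if (nrow(hit) > 1L) next  # both strands annotated: ambiguous
  }
  "."
}

#' Partition correction results into corrected / uncorrected / unspliced
#'
#' @param corrected output of [correct_reads()].
#' @return list of three disjoint reads tables covering all input reads.
#' @export
partition_reads <- function(corrected) {
  r <- corrected$reads
  list(corrected  = r[status == "fully_corrected"],
       uncorrected = r[status == "partially_corrected"],
       unspliced  = r[status == "unspliced"])
}
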