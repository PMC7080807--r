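## Productivity classification under the 55-nt premature-termination-codon
## rule: translate each isoform from annotated start codons and call it
## unproductive when the stop codon ends 55 nt or more upstream of the
## last splice junction (the classic NMD heuristic).

STOP_CODONS <- c("TAA", "TAG", "TGA")

## Transcript coordinate (0-based, 5'->3') of the last splice junction =
## number of exonic nt 5' of it; NA for single-exon isoforms.
last_junction_tx <- function(blocks, strand) {
  n <- nrow(blocks)
  if (n < 2L) return(NA_integer_)
  total <- blocks_len(blocks)
  term_len <- if (strand == "-") blocks[1L, 2L] - blocks[1L, 1L]
  else blocks[n, 2L] - blocks[n, 1L]
  as.integer(total - term_len)
}

## Project an annotated start codon (possibly split across exons) onto an
## isoform: all bases must land inside exons, be consecutive in transcript
## space, and the spliced trinucleotide must still read ATG.
project_start <- function(iso_blocks, strand, tx_seq, sc_blocks, sc_strand) {
  if (sc_strand != strand) return(NA_integer_)
  gpos <- unlist(lapply(seq_len(nrow(sc_blocks)), function(i)
    seq(sc_blocks[i, 1L], sc_blocks[i, 2L] - 1L)))
  if (length(gpos) != 3L) return(NA_integer_)
  tpos <- vapply(gpos, function(g) genomic_to_tx(iso_blocks, strand, g),
                 NA_integer_)
  if (anyNA(tpos)) return(NA_integer_)
  tpos <- sort(tpos)
  if (!identical(tpos, tpos[1L] + 0:2)) return(NA_integer_)
  if (substr(tx_seq, tpos[1L] + 1L, tpos[1L] + 3L) != "ATG")
    return(NA_integer_)
  tpos[1L]
}

## First in-frame stop from tx position `from` (0-based); returns the
## 0-based tx position of the stop codon's first base, or NA.
first_stop <- function(tx_seq, from) {
  len <- nchar(tx_seq)
  pos <- from
  while (pos + 3L <= len) {
    if (substr(tx_seq, pos + 1L, pos + 3L) %in% STOP_CODONS)
      return(as.integer(pos))
    pos <- pos + 3L
  }
  NA_integer_
}

#' Classify isoform productivity via the 55-nt PTC rule
#'
#' Annotated start codons overlapping each isoform's exons are projected
#' to transcript coordinates (they must land wholly in exons with the ATG
#' preserved). When several starts project, two strategies are evaluated:
#' (1) the 5'-most start and (2) the start yielding the longest open
#' reading frame; if they disagree on productivity the isoform is
#' `ambiguous_excluded`. Translation scans codons to the first stop;
#' `ptc_distance` is the number of nt between the last base of the stop
#' and the last splice junction, and the call is `unproductive` when it
#' is `>= ptc_min`. Isoforms with no usable start or no in-frame stop are
#' `no_start_stop`; single-exon isoforms with an ORF are productive (the
#' rule is undefined without a junction).
#'
#' @param isoforms isoform table.
#' @param annotation annotation with `start_codons` ([read_gtf()]).
#' @param genome `DNAStringSet`.
#' @param ptc_min PTC distance threshold in nt (default 55).
#' @return data.table `isoform_id`, `call`, `start_tx`, `stop_tx` (tx
#'   coordinate of the stop codon's first base), `last_junction_tx`,
#'   `ptc_distance`.
#' @export
classify_productivity <- function(isoforms, annotation, genome,
                                  ptc_min = 55L) {
  sc <- annotation$start_codons
  rows <- lapply(seq_len(nrow(isoforms)), function(i) {
    bl <- isoforms$blocks[[i]]
    strand <- isoforms$strand[i]
    tx_seq <- extract_spliced_sequence(genome, isoforms$chrom[i], bl, strand)
    lj <- last_junction_tx(bl, strand)
    base <- data.table(isoform_id = isoforms$isoform_id[i],
                       call = "no_start_stop", start_tx = NA_integer_,
                       stop_tx = NA_integer_, last_junction_tx = lj,
                       ptc_distance = NA_integer_)
    cand <- sc[chrom == isoforms$chrom[i] & strand == isoforms$strand[i]]
    starts <- unique(stats::na.omit(vapply(seq_len(nrow(cand)), function(k)
      project_start(bl, strand, tx_seq, cand$blocks[[k]], cand$strand[k]),
      NA_integer_)))
    if (length(starts) == 0L) return(base)
    eval_start <- function(s) {
      stop_pos <- first_stop(tx_seq, s)
      if (is.na(stop_pos))
        return(list(call = "no_start_stop", stop_tx = NA_integer_,
                    ptc = NA_integer_, orf = nchar(tx_seq) - s))
      ptc <- if (is.na(lj)) NA_integer_ else lj - (stop_pos + 3L)
      call <- if (is.na(lj)) "productive"
      else if (ptc >= ptc_min) "unproductive" else "productive"
      list(call = call, stop_tx = stop_pos, ptc = ptc, orf = stop_pos + 3L - s)
    }
    s1 <- min(starts)                              # 5'-most
    evs <- lapply(starts, eval_start)
    orf_len <- vapply(evs, function(e) e$orf, 1)
    s2 <- starts[orf_len == max(orf_len)]
    s2 <- min(s2)                                  # tie -> 5'-most
    e1 <- evs[[which(starts == s1)]]
    e2 <- evs[[which(starts == s2)]]
    if (e1$call != e2$call) {
      base$call <- "ambiguous_excluded"
      return(base)
    }
    base$call <- e1$call
    base$start_tx <- s1
    base$stop_tx <- e1$stop_tx
    base$ptc_distance <- e1$ptc
    base
  })
  rbindlist(rows)
}

#' Cross-tabulate productivity with intron-retention status
#'
#' Isoforms are labeled IR when they belong to the inclusion (retaining)
#' set of at least one IR event; productive/unproductive labels come from
#' [classify_productivity()]. Per-category log2 fold-change distributions
#' (focal over reference condition medians, [fold_change()]) and pairwise
#' Mann-Whitney U tests are returned.
#'
#' @param isoforms isoform table.
#' @param prod_calls output of [classify_productivity()].
#' @param ir_events output of [call_ir()].
#' @param norm normalized counts matrix.
#' @param manifest sample manifest.
#' @param cond_focal,cond_ref condition labels.
#' @param min_median [fold_change()] filter (default 10).
#' @return list `categories` (isoform_id -> category table), `fc` (named
#'   list of log2 FC vectors), `tests` (pairwise U tests).
#' @export
ir_productivity_crosstab <- function(isoforms, prod_calls, ir_events, norm,
                                     manifest, cond_focal, cond_ref,
                                     min_median = 10) {
  ir_iso <- unique(unlist(ir_events$inclusion_isoforms))
  cat_tbl <- merge(isoforms[, .(isoform_id)],
                   prod_calls[, .(isoform_id, call)], by = "isoform_id")
  cat_tbl <- cat_tbl[call %in% c("productive", "unproductive")]
  cat_tbl[, ir := isoform_id %in% ir_iso]
  cat_tbl[, category := paste0(call, "_", fifelse(ir, "IR", "spliced"))]
  fc <- fold_change(norm, manifest, cond_focal, cond_ref, min_median)
  cat_tbl <- merge(cat_tbl, fc[kept == TRUE, .(isoform_id, log2fc)],
                   by = "isoform_id", all.x = TRUE)
  cats <- c("productive_spliced", "productive_IR",
            "unproductive_spliced", "unproductive_IR")
  fc_by_cat <- lapply(setNames(cats, cats), function(cc)
    cat_tbl[category == cc & !is.na(log2fc), log2fc])
  pairs <- combn(cats, 2L)
  tests <- rbindlist(lapply(seq_len(ncol(pairs)), function(k) {
    a <- fc_by_cat[[pairs[1L, k]]]; b <- fc_by_cat[[pairs[2L, k]]]
    if (length(a) == 0L || length(b) == 0L)
      return(data.table(cat_a = pairs[1L, k], cat_b = pairs[2L, k],
                        U = NA_real_, p = NA_real_))
    mw <- mann_whitney_u(a, b, exact_max = 12L)
    data.table(cat_a = pairs[1L, k], cat_b = pairs[2L, k], U = mw$U, p = mw$p)
  }))
  list(categories = cat_tbl, fc = fc_by_cat, tests = tests)
}

#' Frame-preservation table for alternative 3' splice-site events
#'
#' For A3SS events whose proximal site is preferred in the focal condition
#' (more focal-condition reads on proximal than distal isoforms), isoforms
#' using the proximal site with at least `min_counts` reads summed across
#' focal-condition samples are tallied by productivity call.
#' `multiple_of_3` records whether the proximal/distal shift preserves
#' frame. Only events with both alternative sites inside the CDS span of
#' an annotated coding transcript are included (when the annotation
#' carries CDS features).
#'
#' @param a3ss_events A3SS event table.
#' @param prod_calls output of [classify_productivity()].
#' @param counts counts matrix.
#' @param manifest sample manifest.
#' @param cond_focal focal condition label.
#' @param annotation annotation (for CDS spans); optional.
#' @param min_counts minimum focal-condition counts per isoform
#'   (default 20).
#' @return data.table per event: `event_id`, `delta`, `multiple_of_3`,
#'   `productive`, `unproductive`, `no_start_stop`.
#' @export
alt3_frame_table <- function(a3ss_events, prod_calls, counts, manifest,
                             cond_focal, annotation = NULL,
                             min_counts = 20L) {
  focal_samples <- manifest[condition == cond_focal, sample_id]
  cds_spans <- NULL
  if (!is.null(annotation) && nrow(annotation$cds) > 0L)
    cds_spans <- annotation$cds[, .(chrom = chrom,
                                    start = vapply(blocks, function(b) b[1L, 1L], 1L),
                                    end = vapply(blocks, function(b) b[nrow(b), 2L], 1L))]
  rows <- lapply(seq_len(nrow(a3ss_events)), function(k) {
    e <- a3ss_events[k]
    prox <- e$inclusion_def[[1L]]["ss"]; dist <- e$exclusion_def[[1L]]["ss"]
    if (!is.null(cds_spans)) {
      inside <- cds_spans[chrom == e$chrom & start <= min(prox, dist) &
                            end >= max(prox, dist)]
      if (nrow(inside) == 0L) return(NULL)
    }
    inc_iso <- intersect(e$inclusion_isoforms[[1L]], rownames(counts))
    exc_iso <- intersect(e$exclusion_isoforms[[1L]], rownames(counts))
    focal_inc <- sum(counts[inc_iso, focal_samples, drop = FALSE])
    focal_exc <- sum(counts[exc_iso, focal_samples, drop = FALSE])
    if (focal_inc <= focal_exc) return(NULL)  # proximal not preferred
    per_iso <- rowSums(counts[inc_iso, focal_samples, drop = FALSE])
    keep <- names(per_iso)[per_iso >= min_counts]
    calls <- prod_calls[isoform_id %in% keep, call]
    data.table(event_id = e$event_id,
               delta = abs(as.integer(prox) - as.integer(dist)),
               multiple_of_3 = (abs(prox - dist) %% 3L) == 0L,
               productive = sum(calls == "productive"),
               unproductive = sum(calls == "unproductive"),
               no_start_stop = sum(calls == "no_start_stop"))
  })
  out <- rbindlist(rows)
  if (nrow(out) == 0L)
    out <- data.table(event_id = character(), delta = integer(),
                      multiple_of_3 = logical(), productive = integer(),
                      unproductive = integer(), no_start_stop = integer())
  out
}
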