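## Alternative-splicing event calling from the final isoform set, PSI
## quantification, coverage filters, and splice-site sequence summaries.

event_skeleton <- function() {
  data.table(event_id = character(), type = character(), chrom = character(),
             strand = character(), gene_id = character(),
             inclusion_def = list(), exclusion_def = list(),
             inclusion_isoforms = list(), exclusion_isoforms = list(),
             exempt = logical())
}

## All junctions of an isoform table, one row per (isoform, junction).
iso_junction_table <- function(isoforms) {
  rows <- lapply(seq_len(nrow(isoforms)), function(i) {
    j <- isoforms$chain[[i]]
    if (nrow(j) == 0L) return(NULL)
    data.table(isoform_id = isoforms$isoform_id[i], chrom = isoforms$chrom[i],
               strand = isoforms$strand[i], gene_id = isoforms$gene_id[i],
               start = j[, 1L], end = j[, 2L])
  })
  out <- rbindlist(rows)
  if (nrow(out) == 0L)
    out <- data.table(isoform_id = character(), chrom = character(),
                      strand = character(), gene_id = character(),
                      start = integer(), end = integer())
  out
}

#' Call intron-retention events
#'
#' An IR event is any isoform intron completely spanned by another
#' same-gene isoform's exon. Inclusion isoforms retain the intron (exon
#' spans it); exclusion isoforms splice it. Duplicate events merge by
#' intron coordinates.
#'
#' @param isoforms final isoform table with `gene_id`.
#' @return event table (see [call_alt_ss()] for columns).
#' @export
call_ir <- function(isoforms) {
  jt <- iso_junction_table(isoforms)
  if (nrow(jt) == 0L) return(event_skeleton())
  introns <- unique(jt[, .(chrom, strand, gene_id, start, end)])
  ev <- lapply(seq_len(nrow(introns)), function(k) {
    g <- introns$gene_id[k]; a <- introns$start[k]; b <- introns$end[k]
    gi <- which(isoforms$gene_id == g)
    spanning <- gi[vapply(gi, function(i) {
      bl <- isoforms$blocks[[i]]
      any(bl[, 1L] <= a & b <= bl[, 2L])
    }, logical(1))]
    if (!length(spanning)) return(NULL)
    splicing <- jt[gene_id == g & start == a & end == b, unique(isoform_id)]
    data.table(event_id = sprintf("IR:%s:%d-%d", introns$chrom[k], a, b),
               type = "IR", chrom = introns$chrom[k],
               strand = introns$strand[k], gene_id = g,
               inclusion_def = list(c(a, b)), exclusion_def = list(c(a, b)),
               inclusion_isoforms = list(isoforms$isoform_id[spanning]),
               exclusion_isoforms = list(splicing),
               exempt = FALSE)
  })
  out <- rbindlist(ev)
  if (nrow(out) == 0L) return(event_skeleton())
  unique(out, by = "event_id")
}

## Exon adjacent to a junction on the alternative side.
## For 3prime (acceptor) the exon transcript-downstream of the junction;
## for 5prime (donor) the exon transcript-upstream.
adjacent_exon <- function(blocks, jstart, jend, strand, side) {
  n <- nrow(blocks)
  k <- which(blocks[-n, 2L] == jstart & blocks[-1L, 1L] == jend)
  if (length(k) != 1L) return(NULL)
  downstream_genomic_right <- (strand == "+") == (side == "3prime")
  if (downstream_genomic_right) blocks[k + 1L, ] else blocks[k, ]
}

#' Call alternative 3' / 5' splice-site events
#'
#' Junctions of the same gene sharing the non-alternative splice site and
#' whose alternative-side sites sit in overlapping exons form one event
#' per alternative pair. Proximal = closer to the shared site along the
#' transcript. Pairs whose alternative sites are within `exempt_dist` bp
#' are flagged `exempt` (reported but not tested).
#'
#' @param isoforms final isoform table with `gene_id`.
#' @param side `"3prime"` (alternative acceptors) or `"5prime"`
#'   (alternative donors).
#' @param exempt_dist statistical-test exemption distance (default 10).
#' @return event table with list-columns `inclusion_def`/`exclusion_def`
#'   = `(shared SS, proximal SS)` / `(shared SS, distal SS)` and isoform
#'   id sets; inclusion = proximal.
#' @export
call_alt_ss <- function(isoforms, side = c("3prime", "5prime"),
                        exempt_dist = 10L) {
  side <- match.arg(side)
  jt <- iso_junction_table(isoforms)
  if (nrow(jt) == 0L) return(event_skeleton())
  ## shared coordinate: donor for A3SS, acceptor for A5SS
  jt[, shared := if (side == "3prime")
    fifelse(strand == "+", start, end) else fifelse(strand == "+", end, start)]
  jt[, alt := fifelse(shared == start, end, start)]
  type_lab <- if (side == "3prime") "A3SS" else "A5SS"
  groups <- split(jt, by = c("gene_id", "strand", "shared"))
  ev <- lapply(groups, function(g) {
    alts <- sort(unique(g$alt))
    if (length(alts) < 2L) return(NULL)
    pairs <- combn(alts, 2L)
    rows <- lapply(seq_len(ncol(pairs)), function(pc) {
      a1 <- pairs[1L, pc]; a2 <- pairs[2L, pc]
      iso1 <- unique(g[alt == a1, isoform_id])
      iso2 <- unique(g[alt == a2, isoform_id])
      ## alternative-side exons must overlap between the two isoform sets
      ex1 <- exons_for(isoforms, iso1, g, a1, side)
      ex2 <- exons_for(isoforms, iso2, g, a2, side)
      if (is.null(ex1) || is.null(ex2) ||
          !any(outer(ex1[, 1L], ex2[, 2L], `<`) &
               outer(ex1[, 2L], ex2[, 1L], `>`)))
        return(NULL)
      shared_ss <- g$shared[1L]
      ## proximal = smaller |alt - shared|
      d1 <- abs(a1 - shared_ss); d2 <- abs(a2 - shared_ss)
      prox <- if (d1 <= d2) a1 else a2
      dist <- if (d1 <= d2) a2 else a1
      inc_iso <- if (prox == a1) iso1 else iso2
      exc_iso <- if (prox == a1) iso2 else iso1
      data.table(event_id = sprintf("%s:%s:%d:%d-%d", type_lab,
                                    g$chrom[1L], shared_ss, prox, dist),
                 type = type_lab, chrom = g$chrom[1L], strand = g$strand[1L],
                 gene_id = g$gene_id[1L],
                 inclusion_def = list(c(shared = shared_ss, ss = prox)),
                 exclusion_def = list(c(shared = shared_ss, ss = dist)),
                 inclusion_isoforms = list(inc_iso),
                 exclusion_isoforms = list(exc_iso),
                 exempt = abs(a1 - a2) <= exempt_dist)
    })
    rbindlist(rows)
  })
  out <- rbindlist(ev)
  if (nrow(out) == 0L) return(event_skeleton())
  unique(out, by = "event_id")
}

## Exons adjacent (alternative side) to junctions with the given alt
## coordinate, over the listed isoforms.
exons_for <- function(isoforms, iso_ids, g, a, side) {
  res <- lapply(iso_ids, function(id) {
    i <- which(isoforms$isoform_id == id)
    jrow <- g[isoform_id == id & alt == a][1L]
    js <- min(jrow$start, jrow$end); je <- max(jrow$start, jrow$end)
    adjacent_exon(isoforms$blocks[[i]], js, je, jrow$strand, side)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

#' Call cassette-exon (exon-skipping) events
#'
#' An internal exon flanked by junctions (a, s) and (t, b) in some isoform
#' is a cassette event when another same-gene isoform contains the exact
#' spanning junction (a, b). Inclusion isoforms carry both flanking
#' junctions; exclusion isoforms carry the spanning junction.
#'
#' @param isoforms final isoform table with `gene_id`.
#' @return event table.
#' @export
call_es <- function(isoforms) {
  jt <- iso_junction_table(isoforms)
  if (nrow(jt) == 0L) return(event_skeleton())
  ev <- list()
  for (i in seq_len(nrow(isoforms))) {
    bl <- isoforms$blocks[[i]]
    n <- nrow(bl)
    if (n < 3L) next
    g <- isoforms$gene_id[i]
    for (k in 2L:(n - 1L)) {
      a <- bl[k - 1L, 2L]; s <- bl[k, 1L]; t <- bl[k, 2L]; b <- bl[k + 1L, 1L]
      exc <- jt[gene_id == g & start == a & end == b, unique(isoform_id)]
      if (!length(exc)) next
      inc <- jt[gene_id == g & start == a & end == s, unique(isoform_id)]
      inc2 <- jt[gene_id == g & start == t & end == b, unique(isoform_id)]
      inc <- intersect(inc, inc2)
      ev[[length(ev) + 1L]] <- data.table(
        event_id = sprintf("ES:%s:%d-%d|%d-%d", isoforms$chrom[i], a, s, t, b),
        type = "ES", chrom = isoforms$chrom[i], strand = isoforms$strand[i],
        gene_id = g,
        inclusion_def = list(c(a = a, exon_start = s, exon_end = t, b = b)),
        exclusion_def = list(c(a = a, b = b)),
        inclusion_isoforms = list(inc), exclusion_isoforms = list(exc),
        exempt = FALSE)
    }
  }
  out <- rbindlist(ev)
  if (nrow(out) == 0L) return(event_skeleton())
  unique(out, by = "event_id")
}

#' Quantify events: per-sample inclusion/exclusion counts, PSI and dPSI
#'
#' PSI = 100 * (inc + pc) / (inc + exc + 2 pc) with pseudocount pc; dPSI
#' is the difference of per-condition mean PSI, focal minus reference.
#'
#' @param events event table.
#' @param counts counts matrix from [count_matrix()].
#' @param manifest sample manifest.
#' @param cond_focal,cond_ref condition labels; dPSI = PSI(focal) -
#'   PSI(ref).
#' @param pseudocount default 1.
#' @return list: `quants` (long table event x sample with inc, exc, psi),
#'   `summary` (per event: mean PSI per condition, dpsi).
#' @export
quantify_events <- function(events, counts, manifest, cond_focal, cond_ref,
                            pseudocount = 1) {
  if (nrow(events) == 0L)
    return(list(quants = data.table(), summary = data.table()))
  samples <- manifest$sample_id
  qs <- lapply(seq_len(nrow(events)), function(k) {
    inc_iso <- intersect(events$inclusion_isoforms[[k]], rownames(counts))
    exc_iso <- intersect(events$exclusion_isoforms[[k]], rownames(counts))
    if (length(inc_iso) + length(exc_iso) == 0L)
      stop("event ", events$event_id[k], " has no isoforms in the counts matrix")
    inc <- colSums(counts[inc_iso, samples, drop = FALSE])
    exc <- colSums(counts[exc_iso, samples, drop = FALSE])
    data.table(event_id = events$event_id[k], sample_id = samples,
               inc = as.numeric(inc), exc = as.numeric(exc),
               psi = 100 * (inc + pseudocount) /
                 (inc + exc + 2 * pseudocount))
  })
  quants <- rbindlist(qs)
  quants <- merge(quants, manifest[, .(sample_id, condition)],
                  by = "sample_id", sort = FALSE)
  summ <- quants[, .(psi_focal = mean(psi[condition == cond_focal]),
                     psi_ref = mean(psi[condition == cond_ref])),
                 by = event_id]
  summ[, dpsi := psi_focal - psi_ref]
  list(quants = quants, summary = summ)
}

#' Coverage filter for testable events
#'
#' An event is testable when at least `min_samples` samples cover it with
#' `min_cov` or more reads (inclusion + exclusion, raw counts) and each
#' condition contributes at least `min_per_cond` of those samples. Events
#' flagged exempt are removed here.
#'
#' @param quants long quant table from [quantify_events()] (has
#'   `condition`).
#' @param events event table (for the exempt flag).
#' @param min_cov minimum per-sample coverage (default 25).
#' @param min_samples minimum covered samples (default 4).
#' @param min_per_cond minimum covered samples per condition (default 2).
#' @return character vector of testable event ids.
#' @export
filter_events <- function(quants, events, min_cov = 25L, min_samples = 4L,
                          min_per_cond = 2L) {
  if (nrow(quants) == 0L) return(character(0))
  cov <- quants[, .(covered = inc + exc >= min_cov), by = .(event_id, condition, sample_id)]
  keep <- cov[, {
    nc <- sum(covered)
    per <- tapply(covered, condition, sum)
    list(ok = nc >= min_samples && length(per) >= 2L && all(per >= min_per_cond))
  }, by = event_id][ok == TRUE, event_id]
  exempt_ids <- events[exempt == TRUE, event_id]
  setdiff(keep, exempt_ids)
}

#' Run differential splicing tests over quantified events
#'
#' With exactly one sample per condition a two-sided Fisher's exact test
#' on raw counts is used; with replicates, the beta-binomial LRT
#' ([bb_lrt()]). BH correction and significance flags are applied within
#' event type via [correct_and_flag()].
#'
#' @param events event table.
#' @param quant output of [quantify_events()].
#' @param manifest sample manifest.
#' @param cond_focal,cond_ref condition labels.
#' @param testable event ids to test (from [filter_events()]); defaults to
#'   all non-exempt events.
#' @param alpha,dpsi_min significance thresholds (defaults 0.1, 10).
#' @param pseudocount for the beta-binomial counts (default 1).
#' @return event-level results table.
#' @export
diffsplice_test <- function(events, quant, manifest, cond_focal, cond_ref,
                            testable = NULL, alpha = 0.1, dpsi_min = 10,
                            pseudocount = 1) {
  if (nrow(events) == 0L) return(data.table())
  if (is.null(testable)) testable <- events[exempt == FALSE, event_id]
  q <- quant$quants
  n_per <- manifest[condition %in% c(cond_focal, cond_ref), .N, by = condition]
  replicated <- all(n_per$N >= 2L)
  res <- events[, .(event_id, type, chrom, strand, gene_id, exempt)]
  res[, raw_p := NA_real_]
  for (eid in intersect(testable, res$event_id)) {
    qq <- q[event_id == eid]
    if (replicated) {
      fit <- bb_lrt(qq$inc, qq$exc,
                    ifelse(qq$condition == cond_focal, "focal", "ref"),
                    pseudocount = pseudocount)
      res[event_id == eid, raw_p := fit$p]
    } else {
      qa <- qq[condition == cond_focal]; qb <- qq[condition == cond_ref]
      res[event_id == eid,
          raw_p := fisher_test(sum(qa$inc), sum(qa$exc),
                               sum(qb$inc), sum(qb$exc))]
    }
  }
  res <- merge(res, quant$summary, by = "event_id", sort = FALSE)
  res[, dpsi := psi_focal - psi_ref]
  correct_and_flag(res, alpha = alpha, dpsi_min = dpsi_min)
}

#' Distances from alternative to canonical 3' splice sites, with a
#' sequence-based control
#'
#' Observed distances are signed, measured transcript 5'->3' (negative =
#' upstream), from each A3SS event's alternative acceptor to its canonical
#' acceptor (the annotated one when exactly one is annotated, else the
#' distal). The control takes, for each canonical annotated 3'SS, the
#' distance to the nearest upstream AG-ending trimer that is not GAG,
#' within `control_window` nt. The two distributions are compared with a
#' two-sided Mann-Whitney U test.
#'
#' @param a3ss_events A3SS event table.
#' @param annotation annotation ([read_gtf()]).
#' @param genome `DNAStringSet`.
#' @param control_window upstream scan window (default 100).
#' @return list `observed`, `control`, `U`, `p`.
#' @export
ss_distance_distribution <- function(a3ss_events, annotation, genome,
                                     control_window = 100L) {
  ann_acc <- annotation$junctions[, .(chrom, strand,
                                      pos = fifelse(strand == "+", end, start))]
  observed <- numeric(0)
  for (k in seq_len(nrow(a3ss_events))) {
    e <- a3ss_events[k]
    ss <- c(e$inclusion_def[[1L]]["ss"], e$exclusion_def[[1L]]["ss"])
    is_ann <- vapply(ss, function(p)
      nrow(ann_acc[chrom == e$chrom & strand == e$strand & pos == p]) > 0L,
      logical(1))
    canon <- if (sum(is_ann) == 1L) ss[is_ann] else ss[2L]  # distal fallback
    alt <- setdiff(ss, canon)[1L]
    if (is.na(alt)) next
    d <- if (e$strand == "+") alt - canon else canon - alt
    observed <- c(observed, unname(d))
  }
  control <- numeric(0)
  uacc <- unique(ann_acc)
  for (k in seq_len(nrow(uacc))) {
    d <- nearest_nongag_ag(genome, uacc$chrom[k], uacc$pos[k],
                           uacc$strand[k], control_window)
    if (!is.na(d)) control <- c(control, d)
  }
  mw <- if (length(observed) && length(control))
    mann_whitney_u(observed, control) else list(U = NA_real_, p = NA_real_)
  list(observed = observed, control = control, U = mw$U, p = mw$p)
}

## Signed distance (negative, upstream) from a canonical acceptor to the
## nearest candidate acceptor whose trimer ends in AG and is not GAG.
## `pos` is the acceptor coordinate as stored on junctions (intron end on
## "+", intron start on "-"); candidate offsets are in transcript
## orientation.
nearest_nongag_ag <- function(genome, chrom, pos, strand, window) {
  contig <- genome[[chrom]]
  if (is.null(contig)) return(NA_real_)
  if (strand == "+") {
    lo <- max(0L, pos - window - 3L)
    seq <- as.character(Biostrings::subseq(contig, lo + 1L, min(length(contig), pos)))
    ## candidate acceptor q (0-based, q < pos): trimer at [q-3, q)
    for (off in 1L:window) {
      q <- pos - off
      i <- q - lo          # trimer occupies seq[i-2..i]
      if (i < 3L) break
      tri <- substr(seq, i - 2L, i)
      if (substr(tri, 2L, 3L) == "AG" && tri != "GAG") return(-off)
    }
  } else {
    ## transcript-upstream sequence 5'->3'; its last base sits at upstream
    ## distance 1 (genomic position `pos`, the first intronic base)
    hi <- min(length(contig), pos + window + 3L)
    ups <- as.character(Biostrings::reverseComplement(
      Biostrings::subseq(contig, pos + 1L, hi)))
    L <- nchar(ups)
    for (off in 1L:window) {
      i <- L - off          # trimer at upstream distances off+3 .. off+1
      if (i < 3L) break
      tri <- substr(ups, i - 2L, i)
      if (substr(tri, 2L, 3L) == "AG" && tri != "GAG") return(-off)
    }
  }
  NA_real_
}

#' Position frequency matrix around 3' splice sites
#'
#' Strand-oriented windows covering positions -up .. +down relative to the
#' first exonic base of each acceptor (position 0); minus-strand windows
#' are reverse-complemented before counting. Each column (position) sums
#' to 1.
#'
#' @param sites data.table `chrom`, `pos`, `strand` where `pos` is the
#'   acceptor coordinate as stored on junctions (intron end on "+",
#'   intron start on "-").
#' @param genome `DNAStringSet`.
#' @param up,down window extent (defaults 25, 3).
#' @return 4 x (up+down+1) matrix, rows A/C/G/T.
#' @export
motif_matrix <- function(sites, genome, up = 25L, down = 3L) {
  width <- up + down + 1L
  counts <- matrix(0, nrow = 4L, ncol = width,
                   dimnames = list(c("A", "C", "G", "T"),
                                   as.character(seq(-up, down))))
  n_used <- 0L
  for (k in seq_len(nrow(sites))) {
    contig <- genome[[sites$chrom[k]]]
    if (is.null(contig)) next
    if (sites$strand[k] == "+") {
      s <- sites$pos[k] - up; e <- sites$pos[k] + down
      if (s < 0L || e + 1L > length(contig)) next
      win <- Biostrings::subseq(contig, s + 1L, e + 1L)
    } else {
      ## first exonic base is pos - 1 (genomic); upstream is genomically right
      s <- sites$pos[k] - 1L - down; e <- sites$pos[k] - 1L + up
      if (s < 0L || e + 1L > length(contig)) next
      win <- Biostrings::reverseComplement(
        Biostrings::subseq(contig, s + 1L, e + 1L))
    }
    ch <- strsplit(as.character(win), "")[[1L]]
    if (length(ch) != width || !all(ch %in% rownames(counts))) next
    counts[cbind(match(ch, rownames(counts)), seq_len(width))] <-
      counts[cbind(match(ch, rownames(counts)), seq_len(width))] + 1
    n_used <- n_used + 1L
  }
  if (n_used == 0L) return(counts)
  sweep(counts, 2L, colSums(counts), "/")
}

#' Differential isoform usage (isoform vs rest of gene)
#'
#' Genes with at least `min_cov` reads in at least `min_samples` samples
#' are tested; within each, every isoform is contrasted against the rest
#' of the gene with the beta-binomial LRT. BH correction is applied across
#' all tested isoforms; significance additionally requires a usage shift
#' above `dusage_min` percentage points. Single-isoform genes are skipped.
#'
#' @param counts counts matrix.
#' @param gene_map named vector isoform_id -> gene_id.
#' @param manifest sample manifest.
#' @param cond_focal,cond_ref condition labels.
#' @param min_cov,min_samples gene coverage rule (defaults 25, 4).
#' @param alpha,dusage_min significance thresholds (defaults 0.1, 10).
#' @param pseudocount for usage reporting and the LRT (default 1).
#' @return per-isoform results table.
#' @export
diff_isoform_usage <- function(counts, gene_map, manifest, cond_focal,
                               cond_ref, min_cov = 25L, min_samples = 4L,
                               alpha = 0.1, dusage_min = 10,
                               pseudocount = 1) {
  samples <- manifest$sample_id
  genes <- gene_map[rownames(counts)]
  res <- list()
  for (g in unique(genes)) {
    iso <- rownames(counts)[genes == g]
    if (length(iso) < 2L) next
    gcount <- colSums(counts[iso, samples, drop = FALSE])
    if (sum(gcount >= min_cov) < min_samples) next
    for (id in iso) {
      inc <- counts[id, samples]
      exc <- gcount - inc
      cond <- manifest$condition[match(samples, manifest$sample_id)]
      fit <- bb_lrt(inc, exc, ifelse(cond == cond_focal, "focal", "ref"),
                    pseudocount = pseudocount)
      usage <- 100 * (inc + pseudocount) / (gcount + 2 * pseudocount)
      d_usage <- mean(usage[cond == cond_focal]) - mean(usage[cond == cond_ref])
      res[[length(res) + 1L]] <- data.table(
        isoform_id = id, gene_id = g, raw_p = fit$p, d_usage = d_usage)
    }
  }
  out <- rbindlist(res)
  if (nrow(out) == 0L) return(out)
  out[, corrected_p := NA_real_]
  out[!is.na(raw_p), corrected_p := p.adjust(raw_p, method = "BH")]
  out[, significant := !is.na(corrected_p) & corrected_p < alpha &
        abs(d_usage) > dusage_min]
  out[]
}
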