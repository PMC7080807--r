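## Independent oracles and fixture builders shared across test files.

## Exhaustive hypergeometric oracle for the two-sided Fisher p on a 2x2
## table with margins fixed (same relative-error convention as the
## conditional exact test).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  dens <- exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  sum(dens[dens <= dens[x == a] * (1 + 1e-7)])
}


## Brute-force event-calling oracles used by several tests. These work
## directly on block matrices, independently of the package's grouping
## logic.

ir_oracle <- function(iso) {
  hits <- list()
  for (i in seq_len(nrow(iso))) {
    j <- blocks_to_junctions(iso$blocks[[i]])
    for (r in seq_len(nrow(j))) {
      a <- j[r, 1]; b <- j[r, 2]
      for (k in seq_len(nrow(iso))) {
        if (iso$gene_id[k] != iso$gene_id[i]) next
        bl <- iso$blocks[[k]]
        if (any(bl[, 1] <= a & b <= bl[, 2]))
          hits[[length(hits) + 1]] <- c(a, b)
      }
    }
  }
  unique(do.call(rbind, c(hits, list(matrix(numeric(0), ncol = 2)))))
}

es_oracle <- function(iso) {
  out <- list()
  for (i in seq_len(nrow(iso))) {
    bl <- iso$blocks[[i]]
    if (nrow(bl) < 3) next
    for (k in 2:(nrow(bl) - 1)) {
      a <- bl[k - 1, 2]; s <- bl[k, 1]; t <- bl[k, 2]; b <- bl[k + 1, 1]
      for (m in seq_len(nrow(iso))) {
        if (m == i || iso$gene_id[m] != iso$gene_id[i]) next
        jm <- blocks_to_junctions(iso$blocks[[m]])
        if (any(jm[, 1] == a & jm[, 2] == b))
          out[[length(out) + 1]] <- c(a, s, t, b)
      }
    }
  }
  unique(do.call(rbind, c(out, list(matrix(numeric(0), ncol = 4)))))
}

## Alternative-SS oracle: pairs of junctions sharing the non-alternative
## SS whose alternative-side adjacent exons overlap between the isoforms.
alt_ss_oracle <- function(iso, side) {
  recs <- list()
  for (i in seq_len(nrow(iso))) {
    bl <- iso$blocks[[i]]
    j <- blocks_to_junctions(bl)
    for (r in seq_len(nrow(j))) {
      plus <- iso$strand[i] == "+"
      shared <- if ((side == "3prime") == plus) j[r, 1] else j[r, 2]
      alt <- if (shared == j[r, 1]) j[r, 2] else j[r, 1]
      down_right <- plus == (side == "3prime")
      ex <- if (down_right) bl[r + 1, ] else bl[r, ]
      recs[[length(recs) + 1]] <- data.table(
        gene = iso$gene_id[i], strand = iso$strand[i], shared = shared,
        alt = alt, ex_s = ex[1], ex_e = ex[2])
    }
  }
  recs <- rbindlist(recs)
  pairs <- list()
  for (gkey in split(recs, by = c("gene", "strand", "shared"))) {
    alts <- sort(unique(gkey$alt))
    if (length(alts) < 2) next
    for (x in seq_along(alts)) for (y in seq_along(alts)) {
      if (x >= y) next
      e1 <- gkey[alt == alts[x]]; e2 <- gkey[alt == alts[y]]
      if (any(outer(e1$ex_s, e2$ex_e, `<`) & outer(e1$ex_e, e2$ex_s, `>`)))
        pairs[[length(pairs) + 1]] <- data.table(
          gene = gkey$gene[1], shared = gkey$shared[1],
          ss1 = alts[x], ss2 = alts[y])
    }
  }
  out <- rbindlist(pairs)
  if (is.null(out) || nrow(out) == 0)
    out <- data.table(gene = character(), shared = numeric(),
                      ss1 = numeric(), ss2 = numeric())
  unique(out)
}

## Random same-gene isoform sets rich in shared splice sites.
random_isoform_set <- function(n_iso, strand = NULL) {
  if (is.null(strand)) strand <- sample(c("+", "-"), 1)
  base <- random_blocks(sample(4:6, 1), gap_range = c(80L, 300L),
                        len_range = c(60L, 150L))
  blocks <- list(base)
  for (i in seq_len(n_iso - 1)) {
    b <- base
    op <- sample(c("skip", "shift", "retain", "none"), 1)
    if (op == "skip" && nrow(b) >= 3) {
      b <- b[-sample(2:(nrow(b) - 1), 1), , drop = FALSE]
    } else if (op == "shift") {
      r <- sample(nrow(b) - 1, 1)
      d <- sample(c(5L, 8L, 15L, 30L), 1)
      if (runif(1) < 0.5) b[r, 2] <- b[r, 2] + d    # donor-side boundary
      else b[r + 1, 1] <- b[r + 1, 1] - d
      if (b[r + 1, 1] - b[r, 2] < 5) b <- base
    } else if (op == "retain" && nrow(b) >= 2) {
      r <- sample(nrow(b) - 1, 1)
      b[r, 2] <- b[r + 1, 2]
      b <- b[-(r + 1), , drop = FALSE]
    }
    blocks[[length(blocks) + 1]] <- b
  }
  blocks <- unique(blocks)
  make_isoforms(blocks, strand = strand,
                ids = sprintf("I%02d", seq_along(blocks)))
}


## Hand-built ORF fixtures: a transcript sequence placed on exon blocks
## via genome_from_tx(); start codons annotated explicitly.

two_exon_fixture <- function(L1, stop_at, strand = "+", L2 = 100L,
                             extra_seq = NULL) {
  ## L1 = transcript 5' exon length (junction at tx L1); on the minus
  ## strand the 5' exon is the genomically right block
  lens <- if (strand == "-") c(L2, L1) else c(L1, L2)
  blocks <- cbind(start = c(100L, 100L + lens[1L] + 500L),
                  end = c(100L + lens[1L], 100L + lens[1L] + 500L + lens[2L]))
  tx_seq <- if (is.null(extra_seq)) orf_tx_seq(L1 + L2, stop_at) else extra_seq
  genome <- genome_from_tx(tx_seq, blocks, strand)
  sc_g <- vapply(0:2, function(t)
    longsplice:::tx_to_genomic(blocks, strand, t), 1L)
  sc_blocks <- cbind(start = min(sc_g), end = max(sc_g) + 1L)
  ann <- make_annotation(list(
    t1 = list(gene = "g1", chrom = "chr1", strand = strand, blocks = blocks,
              start_codon = sc_blocks)))
  iso <- make_isoforms(list(blocks), strand = strand)
  list(iso = iso, ann = ann, genome = genome, blocks = blocks)
}


## Enumeration oracle for the Mann-Whitney U: counting definition of U and
## full enumeration of group assignments of the pooled values.
mwu_oracle <- function(a, b) {
  count_u <- function(x, y)
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pooled <- c(a, b); na <- length(a)
  U <- count_u(a, b)
  combos <- combn(length(pooled), na)
  Us <- apply(combos, 2, function(ix) count_u(pooled[ix], pooled[-ix]))
  p <- min(1, 2 * min(mean(Us <= U + 1e-9), mean(Us >= U - 1e-9)))
  list(U = U, p = p)
}

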