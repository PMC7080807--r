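## Event-calling oracles live in helper-oracles.R

test_that("call_ir matches the containment definition", {
  iso <- make_isoforms(list(
    cbind(c(100L, 300L), c(200L, 400L)),     # intron (200,300)
    cbind(c(150L), c(350L)),                 # exon spans it
    cbind(c(210L), c(350L))))                # partial overlap, no event
  ev <- call_ir(iso)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$inclusion_def[[1]], c(200L, 300L))
  expect_true("I02" %in% ev$inclusion_isoforms[[1]])
  expect_true("I01" %in% ev$exclusion_isoforms[[1]])
  expect_false("I03" %in% ev$inclusion_isoforms[[1]])
})

test_that("call_es finds cassette exons via the spanning junction", {
  iso <- make_isoforms(list(
    cbind(c(50L, 200L, 300L), c(100L, 250L, 400L)),  # inclusion
    cbind(c(50L, 300L), c(100L, 400L))))             # exclusion (100,300)
  ev <- call_es(iso)
  expect_equal(nrow(ev), 1L)
  expect_equal(unname(ev$inclusion_def[[1]]), c(100L, 200L, 250L, 300L))
  expect_equal(ev$inclusion_isoforms[[1]], "I01")
  expect_equal(ev$exclusion_isoforms[[1]], "I02")
  ## no spanning junction -> no event
  iso2 <- make_isoforms(list(
    cbind(c(50L, 200L, 300L), c(100L, 250L, 400L)),
    cbind(c(50L, 320L), c(100L, 400L))))
  expect_equal(nrow(call_es(iso2)), 0L)
})

test_that("call_alt_ss labels proximal/distal and the 10-bp exemption", {
  iso <- make_isoforms(list(
    cbind(c(500L, 2000L), c(1000L, 2400L)),
    cbind(c(500L, 2020L), c(1000L, 2400L))))
  ev <- call_alt_ss(iso, side = "3prime")
  expect_equal(nrow(ev), 1L)
  expect_equal(unname(ev$inclusion_def[[1]]["ss"]), 2000L)  # proximal
  expect_equal(unname(ev$exclusion_def[[1]]["ss"]), 2020L)  # distal
  expect_false(ev$exempt)          # delta 20 > 10
  iso2 <- make_isoforms(list(
    cbind(c(500L, 2000L), c(1000L, 2400L)),
    cbind(c(500L, 2008L), c(1000L, 2400L))))
  ev2 <- call_alt_ss(iso2, side = "3prime")
  expect_true(ev2$exempt)          # delta 8 <= 10
})

test_that("event callers equal brute-force oracles on random isoform sets", {
  set.seed(19)
  for (k in 1:40) {
    iso <- random_isoform_set(sample(2:6, 1))
    ## IR
    got_ir <- call_ir(iso)
    want_ir <- ir_oracle(iso)
    got_coords <- unique(do.call(rbind, c(got_ir$inclusion_def,
                                          list(matrix(numeric(0), ncol = 2)))))
    ord2 <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]
    expect_equal(ord2(got_coords), ord2(want_ir), ignore_attr = TRUE)
    ## ES
    got_es <- call_es(iso)
    want_es <- es_oracle(iso)
    got_es_m <- unique(do.call(rbind, c(lapply(got_es$inclusion_def, unname),
                                        list(matrix(numeric(0), ncol = 4)))))
    ord <- function(m) m[order(m[, 1], m[, 2], m[, 3], m[, 4]), , drop = FALSE]
    expect_equal(ord(got_es_m), ord(want_es), ignore_attr = TRUE)
    ## alternative splice sites, both sides
    for (sd in c("3prime", "5prime")) {
      got <- call_alt_ss(iso, side = sd)
      want <- alt_ss_oracle(iso, sd)
      got_pairs <- if (nrow(got)) data.table(
        gene = got$gene_id, shared = sapply(got$inclusion_def, `[[`, "shared"),
        ss1 = pmin(sapply(got$inclusion_def, `[[`, "ss"),
                   sapply(got$exclusion_def, `[[`, "ss")),
        ss2 = pmax(sapply(got$inclusion_def, `[[`, "ss"),
                   sapply(got$exclusion_def, `[[`, "ss")))
      else data.table(gene = character(), shared = numeric(),
                      ss1 = numeric(), ss2 = numeric())
      setkey(got_pairs, gene, shared, ss1, ss2)
      want[, `:=`(ss1 = pmin(ss1, ss2), ss2 = pmax(ss1, ss2))]
      setkey(want, gene, shared, ss1, ss2)
      expect_equal(unique(got_pairs), unique(want), ignore_attr = TRUE)
    }
  }
})

test_that("quantify_events applies the pseudocount PSI formula", {
  iso <- make_isoforms(list(cbind(0L, 100L), cbind(200L, 300L)))
  ev <- data.table(event_id = "e1", type = "IR", chrom = "chr1",
                   strand = "+", gene_id = "g1",
                   inclusion_def = list(c(0, 1)), exclusion_def = list(c(0, 1)),
                   inclusion_isoforms = list("I01"),
                   exclusion_isoforms = list("I02"), exempt = FALSE)
  counts <- matrix(c(9L, 5L, 0L, 5L), 2, 2, byrow = TRUE,
                   dimnames = list(c("I01", "I02"), c("sA", "sB")))
  mani <- data.table(sample_id = c("sA", "sB"), condition = c("MT", "WT"),
                     batch = "1")
  q <- quantify_events(ev, counts, mani, "MT", "WT")
  expect_equal(q$quants[sample_id == "sA", psi], 100 * 10 / 11)
  expect_equal(q$quants[sample_id == "sB", psi], 50)       # inc == exc
  expect_equal(q$summary$dpsi, 100 * 10 / 11 - 50)
  ## PSI stays in [0, 100] on random counts and matches the formula
  set.seed(23)
  cm <- matrix(rpois(20, 20), 2, 10,
               dimnames = list(c("I01", "I02"), paste0("s", 1:10)))
  mani2 <- data.table(sample_id = paste0("s", 1:10),
                      condition = rep(c("MT", "WT"), 5), batch = "1")
  q2 <- quantify_events(ev, cm, mani2, "MT", "WT")$quants
  expect_true(all(q2$psi >= 0 & q2$psi <= 100))
  expect_equal(q2$psi, 100 * (q2$inc + 1) / (q2$inc + q2$exc + 2))
})

test_that("filter_events matches the exhaustively enumerated rule", {
  ev <- data.table(event_id = "e1", type = "IR", chrom = "c", strand = "+",
                   gene_id = "g", inclusion_def = list(1), exclusion_def = list(1),
                   inclusion_isoforms = list("I01"),
                   exclusion_isoforms = list("I02"), exempt = FALSE)
  mani <- data.table(sample_id = paste0("s", 1:6),
                     condition = rep(c("MT", "WT"), each = 3), batch = "1")
  covs <- expand.grid(rep(list(c(0L, 25L, 30L)), 6))
  for (r in seq_len(nrow(covs))) {
    cv <- as.integer(covs[r, ])
    quants <- data.table(event_id = "e1", sample_id = mani$sample_id,
                         inc = cv, exc = 0L,
                         psi = 100, condition = mani$condition)
    kept <- length(filter_events(quants, ev, min_cov = 25L,
                                 min_samples = 4L, min_per_cond = 2L)) == 1L
    covered <- cv >= 25L
    want <- sum(covered) >= 4L &&
      sum(covered & mani$condition == "MT") >= 2L &&
      sum(covered & mani$condition == "WT") >= 2L
    expect_equal(kept, want)
  }
  ## exempt events are removed even with full coverage
  ev2 <- copy(ev)[, exempt := TRUE]
  quants <- data.table(event_id = "e1", sample_id = mani$sample_id,
                       inc = 100L, exc = 100L, psi = 50,
                       condition = mani$condition)
  expect_length(filter_events(quants, ev2), 0L)
})

## empty A3SS event table with the right columns (control-only runs)
event_skeleton_for_test <- function() {
  data.table(event_id = character(), type = character(), chrom = character(),
             strand = character(), gene_id = character(),
             inclusion_def = list(), exclusion_def = list(),
             inclusion_isoforms = list(), exclusion_isoforms = list(),
             exempt = logical())
}

test_that("ss_distance_distribution signs distances and scans controls", {
  ## alternative acceptor 20 nt upstream of canonical on +
  iso <- make_isoforms(list(
    cbind(c(500L, 2000L), c(1000L, 2400L)),     # canonical acceptor 2020? no:
    cbind(c(500L, 2020L), c(1000L, 2400L))))
  ann <- make_annotation(list(
    t1 = list(gene = "g1", chrom = "chr1", strand = "+",
              blocks = cbind(c(500L, 2020L), c(1000L, 2400L)))))
  ev <- call_alt_ss(iso, side = "3prime")
  ## genome: all C, with AG planted so the control has a known answer:
  ## canonical acceptor at 2020 -> bases 2018-2019 are its AG; nearest
  ## upstream non-GAG AG trimer planted ending at 2000 (offset -20)
  g <- rep("C", 3000)
  g[2019:2020] <- c("A", "G")                  # canonical AG (1-based string)
  g[1998:2000] <- c("T", "A", "G")             # TAG trimer at offset -20
  genome <- Biostrings::DNAStringSet(setNames(paste(g, collapse = ""), "chr1"))
  res <- ss_distance_distribution(ev, ann, genome, control_window = 100L)
  expect_equal(res$observed, -20)              # alt (2000) upstream of canonical
  expect_equal(res$control, -20)               # planted TAG
  ## GAG trimers are skipped in the control scan
  g2 <- g
  g2[2008:2010] <- c("G", "A", "G")            # closer but GAG -> ignored
  genome2 <- Biostrings::DNAStringSet(setNames(paste(g2, collapse = ""), "chr1"))
  res2 <- ss_distance_distribution(ev, ann, genome2, control_window = 100L)
  expect_equal(res2$control, -20)
  ## random-sequence control equals a naive scan oracle (plus strand)
  set.seed(29)
  for (k in 1:20) {
    seqc <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
    gg <- Biostrings::DNAStringSet(setNames(seqc, "chr1"))
    pos <- 300L
    annk <- make_annotation(list(
      t1 = list(gene = "g1", chrom = "chr1", strand = "+",
                blocks = cbind(c(10L, pos), c(100L, 380L)))))
    rk <- ss_distance_distribution(event_skeleton_for_test(), annk, gg,
                                   control_window = 100L)
    want <- NA
    for (off in 1:100) {
      tri <- substr(seqc, pos - off - 2, pos - off)
      if (substr(tri, 2, 3) == "AG" && tri != "GAG") { want <- -off; break }
    }
    if (is.na(want)) expect_length(rk$control, 0)
    else expect_equal(rk$control, want)
  }
})

test_that("motif_matrix counts strand-oriented windows", {
  seqc <- paste(c(rep("C", 100), "T", "A", "G", rep("A", 50)), collapse = "")
  genome <- Biostrings::DNAStringSet(setNames(seqc, "chr1"))
  ## + acceptor at pos 103 (0-based): AG at 101-102, exon starts at 103
  sites <- data.table(chrom = "chr1", pos = 103L, strand = "+")
  m <- motif_matrix(sites, genome, up = 3L, down = 1L)
  expect_equal(dim(m), c(4L, 5L))
  expect_equal(unname(m[, "-2"]), c(1, 0, 0, 0))   # A
  expect_equal(unname(m[, "-1"]), c(0, 0, 1, 0))   # G
  expect_equal(unname(m[, "0"]), c(1, 0, 0, 0))    # first exon base A
  expect_true(all(abs(colSums(m) - 1) < 1e-12))
  ## a minus-strand acceptor over the reverse-complement context
  seqm <- paste(c(rep("T", 50), "C", "T", "A", rep("G", 100)), collapse = "")
  genomem <- Biostrings::DNAStringSet(setNames(seqm, "chr1"))
  ## "-" acceptor with junction start 50 (0-based): exon base at 49 ("T"->A)
  sitesm <- data.table(chrom = "chr1", pos = 50L, strand = "-")
  mm <- motif_matrix(sitesm, genomem, up = 3L, down = 1L)
  expect_equal(unname(mm[, "0"]), c(1, 0, 0, 0))   # revcomp of T = A
  expect_equal(unname(mm[, "-1"]), c(0, 0, 1, 0))  # revcomp of C = G
  ## random sites match a direct tally oracle
  set.seed(31)
  seqr <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  gr <- Biostrings::DNAStringSet(setNames(seqr, "chr1"))
  pos <- sample(100:1900, 100L)
  st <- data.table(chrom = "chr1", pos = pos, strand = "+")
  got <- motif_matrix(st, gr, up = 5L, down = 2L)
  tal <- matrix(0, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (p in pos) {
    w <- substr(seqr, p - 5 + 1, p + 2 + 1)
    ch <- strsplit(w, "")[[1]]
    for (j in seq_along(ch)) tal[ch[j], j] <- tal[ch[j], j] + 1
  }
  tal <- sweep(tal, 2, colSums(tal), "/")
  expect_equal(unname(got), unname(tal))
})

test_that("diff_isoform_usage applies the gene coverage rule and finds planted usage shifts", {
  mani <- data.table(sample_id = paste0("s", 1:6),
                     condition = rep(c("MT", "WT"), each = 3), batch = "1")
  ## gene below coverage in 3 samples only -> untested
  cm_low <- matrix(c(30, 30, 30, 0, 0, 0,
                     30, 30, 30, 0, 0, 0), 2, 6, byrow = TRUE,
                   dimnames = list(c("i1", "i2"), mani$sample_id))
  gm <- c(i1 = "g1", i2 = "g1")
  expect_equal(nrow(diff_isoform_usage(cm_low / 2, gm, mani, "MT", "WT")), 0L)
  ## planted 90/10 vs 10/90 usage at high coverage -> significant
  set.seed(33)
  cm <- rbind(i1 = c(180, 175, 185, 20, 25, 15),
              i2 = c(20, 25, 15, 180, 175, 185))
  colnames(cm) <- mani$sample_id
  res <- diff_isoform_usage(cm, gm, mani, "MT", "WT")
  expect_equal(nrow(res), 2L)
  expect_true(all(res$significant))
  expect_gt(res[isoform_id == "i1", d_usage], 50)
  ## single-isoform genes are skipped
  gm2 <- c(i1 = "g1", i2 = "g2")
  expect_equal(nrow(diff_isoform_usage(cm, gm2, mani, "MT", "WT")), 0L)
})

test_that("diffsplice_test picks Fisher for 1v1 and bb_lrt for replicates", {
  iso <- make_isoforms(list(cbind(0L, 100L), cbind(200L, 300L)))
  ev <- data.table(event_id = "e1", type = "A3SS", chrom = "chr1",
                   strand = "+", gene_id = "g1",
                   inclusion_def = list(c(shared = 0, ss = 1)),
                   exclusion_def = list(c(shared = 0, ss = 2)),
                   inclusion_isoforms = list("I01"),
                   exclusion_isoforms = list("I02"), exempt = FALSE)
  counts <- matrix(c(40L, 5L, 10L, 45L), 2, 2, byrow = TRUE,
                   dimnames = list(c("I01", "I02"), c("sA", "sB")))
  mani <- data.table(sample_id = c("sA", "sB"), condition = c("MT", "WT"),
                     batch = "1")
  q <- quantify_events(ev, counts, mani, "MT", "WT")
  res <- diffsplice_test(ev, q, mani, "MT", "WT", testable = "e1")
  expect_equal(res$raw_p, fisher_test(40, 10, 5, 45))
  expect_true(res$significant)
})
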