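## Block / junction arithmetic shared across modules.
## Blocks are integer matrices with columns (start, end), 0-based half-open,
## sorted and non-overlapping. A junction chain is the matrix of introns
## between consecutive blocks, same convention.

#' Validate an exon block matrix
#'
#' @param blocks integer matrix with columns start, end (0-based half-open).
#' @return invisibly `TRUE`; errors otherwise.
#' @keywords internal
validate_blocks <- function(blocks) {
  if (!is.matrix(blocks) || ncol(blocks) != 2L || nrow(blocks) < 1L)
    stop("blocks must be a matrix with >= 1 row and 2 columns")
  if (any(blocks[, 2L] <= blocks[, 1L]))
    stop("each block must have end > start")
  if (nrow(blocks) > 1L) {
    if (is.unsorted(blocks[, 1L], strictly = TRUE))
      stop("blocks must be sorted by start")
    if (any(blocks[-1L, 1L] < blocks[-nrow(blocks), 2L]))
      stop("blocks must not overlap")
  }
  invisible(TRUE)
}

#' Introns between consecutive exon blocks
#'
#' @param blocks exon block matrix.
#' @return matrix with columns start, end; 0 rows for single-exon input.
#' @export
blocks_to_junctions <- function(blocks) {
  n <- nrow(blocks)
  if (n < 2L) return(matrix(integer(0), ncol = 2L,
                            dimnames = list(NULL, c("start", "end"))))
  cbind(start = blocks[-n, 2L], end = blocks[-1L, 1L])
}

#' Rebuild exon blocks from a junction chain and outer ends
#'
#' @param chain junction matrix (possibly 0 rows).
#' @param left,right outermost genomic start / end of the transcript.
#' @export
junctions_to_blocks <- function(chain, left, right) {
  if (nrow(chain) == 0L)
    return(matrix(c(left, right), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  matrix(c(unname(c(left, chain[, 2L])), unname(c(chain[, 1L], right))),
         ncol = 2L, dimnames = list(NULL, c("start", "end")))
}

## String key identifying a junction chain (chrom + strand + coordinates).
chain_key <- function(chrom, strand, chain) {
  if (nrow(chain) == 0L) return(paste0(chrom, "|", strand, "|."))
  paste0(chrom, "|", strand, "|",
         paste(chain[, 1L], chain[, 2L], sep = "-", collapse = ","))
}

## Total exonic length of a block matrix.
blocks_len <- function(blocks) sum(blocks[, 2L] - blocks[, 1L])

## Exonic overlap (nt) between two block matrices on the same chromosome.
blocks_overlap <- function(a, b) {
  tot <- 0L
  for (i in seq_len(nrow(a))) {
    s <- pmax(a[i, 1L], b[, 1L]); e <- pmin(a[i, 2L], b[, 2L])
    tot <- tot + sum(pmax(0L, e - s))
  }
  tot
}

## Map a genomic position (0-based, must lie inside a block) to the
## transcript coordinate (0-based, 5'->3' on `strand`).
genomic_to_tx <- function(blocks, strand, gpos) {
  w <- which(gpos >= blocks[, 1L] & gpos < blocks[, 2L])
  if (length(w) != 1L) return(NA_integer_)
  lens <- blocks[, 2L] - blocks[, 1L]
  tx_plus <- (if (w > 1L) sum(lens[seq_len(w - 1L)]) else 0L) +
    (gpos - blocks[w, 1L])
  if (strand == "-") sum(lens) - 1L - tx_plus else as.integer(tx_plus)
}

## Inverse of genomic_to_tx: transcript coordinate -> genomic position.
tx_to_genomic <- function(blocks, strand, tpos) {
  lens <- blocks[, 2L] - blocks[, 1L]
  total <- sum(lens)
  if (tpos < 0L || tpos >= total) return(NA_integer_)
  p <- if (strand == "-") total - 1L - tpos else tpos
  cs <- cumsum(lens)
  w <- which(p < cs)[1L]
  off <- p - (if (w > 1L) cs[w - 1L] else 0L)
  as.integer(blocks[w, 1L] + off)
}
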