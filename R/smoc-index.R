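## Short-read screening by exact match of a very large k-mer, and the
## position weight matrix built from the 3'-side overhangs of anchored
## reads. These are the two primitives of the seed-extension curation
## algorithm.

#' Build a large-k-mer screen over short reads
#'
#' Indexes every k-mer of every read on both strands (the reverse
#' complement of each read is indexed explicitly, so queries are looked
#' up verbatim and matches on either strand are found). Lookup of the
#' 3'-terminal k-mer of a growing consensus is an O(1)-expected keyed
#' search.
#'
#' @param reads named character vector of short reads.
#' @param k k-mer size; "extremely large" relative to usual assembly
#'   k-mers. The default 72 keeps the anchor essentially unique in a
#'   genome while leaving enough of a 150 nt read as overhang that the
#'   expected per-column support at 30x coverage is about three times
#'   the default acceptance depth. Must not exceed the longest read.
#' @param min_overhang minimum useful 3' overhang, documentation only.
#' @return object of class `kmer_index`.
#' @export
build_kmer_screen <- function(reads, k = 72L, min_overhang = 20L) {
  k <- as.integer(k)
  if (!length(reads)) stop("no reads supplied")
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  lens <- nchar(reads)
  if (k > max(lens)) stop("k (", k, ") exceeds the longest read (",
                          max(lens), ")")
  if (k < 16L) warning("k < 16 defeats the purpose of a large-k-mer screen")
  fwd <- unname(reads)
  rev <- revcomp(fwd)
  n_pos <- pmax(lens - k + 1L, 0L)
  idx <- rep.int(seq_along(fwd), n_pos)
  off <- sequence(n_pos)
  tab <- data.table::data.table(
    kmer = c(substring(fwd[idx], off, off + k - 1L),
             substring(rev[idx], off, off + k - 1L)),
    read = c(idx, idx),
    offset = c(off, off),
    strand = rep(c("+", "-"), each = length(idx))
  )
  data.table::setkey(tab, kmer)
  structure(list(k = k, table = tab, fwd = fwd, rev = rev,
                 read_names = names(reads), min_overhang = min_overhang),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: k=%d, %d reads, %d indexed positions (both strands)\n",
              x$k, length(x$fwd), nrow(x$table)))
  invisible(x)
}

#' Recruit reads matching a k-mer and align their 3' overhangs
#'
#' Reads containing an exact match of `kmer` are anchored at the match;
#' the sequence 3' of the anchor (in the orientation that matches the
#' query) is the overhang. Anchoring is exact and gap-free: overhang
#' column j of every recruited read is homologous to consensus position
#' `|kmer| + j`. Reads ending exactly at the k-mer are recruited but
#' contribute no columns.
#'
#' @param kmer query k-mer (length must equal the index k).
#' @param index a [build_kmer_screen()] index.
#' @return list with `overhangs` (character vector, possibly
#'   zero-length strings) and `hits` (data.table read/offset/strand).
#' @export
recruit_and_align <- function(kmer, index) {
  stopifnot(inherits(index, "kmer_index"))
  if (nchar(kmer) != index$k)
    stop("query length ", nchar(kmer), " != index k ", index$k)
  .query_kmer <- kmer
  hits <- index$table[.(.query_kmer), nomatch = NULL]
  if (!nrow(hits))
    return(list(overhangs = character(0), hits = hits))
  src <- ifelse(hits$strand == "+", index$fwd[hits$read],
                index$rev[hits$read])
  ov <- substring(src, hits$offset + index$k, nchar(src))
  list(overhangs = ov, hits = hits)
}

#' Position weight matrix over aligned overhangs
#'
#' Column j counts the bases observed at overhang position j. The
#' conservation invariant holds by construction: each column's counts
#' sum to the number of recruited reads long enough to cover it.
#'
#' @param overhangs character vector of gap-free aligned overhangs.
#' @return object of class `pwm`: list with `counts` (4 x L matrix, rows
#'   A/C/G/T), `support` (reads per column), `consensus` (argmax string,
#'   ties broken A<C<G<T) and `purity` (dominant-base fraction).
#' @export
pwm_from_overhangs <- function(overhangs) {
  L <- if (length(overhangs)) max(nchar(overhangs)) else 0L
  counts <- matrix(0L, nrow = 4L, ncol = L,
                   dimnames = list(.BASES, NULL))
  if (L > 0L) {
    for (j in seq_len(L)) {
      ch <- substr(overhangs, j, j)
      ch <- ch[ch != ""]
      if (length(ch))
        counts[, j] <- tabulate(factor(ch, levels = .BASES), nbins = 4L)
    }
  }
  support <- colSums(counts)
  cons_idx <- if (L > 0L) apply(counts, 2L, which.max) else integer(0)
  consensus <- c2s(.BASES[cons_idx])
  purity <- ifelse(support > 0, apply(counts, 2L, max) / support, 0)
  structure(list(counts = counts, support = support,
                 consensus = consensus, purity = as.numeric(purity),
                 n_reads = length(overhangs)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm: %d columns from %d overhangs; consensus %s%s\n",
              ncol(x$counts), x$n_reads,
              substr(x$consensus, 1, 40),
              if (nchar(x$consensus) > 40) "..." else ""))
  invisible(x)
}
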