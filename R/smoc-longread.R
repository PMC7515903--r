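## Long-read mapping of the curated components and repeat iteration
## counting. Matching is approximate (nanopore-scale error), using local
## pairwise alignment of terminal-domain anchors and tiling alignment of
## a repeat-unit anchor across the inter-terminal region.

.nt_submat <- function() {
  if (is.null(.pkg_env$ntmat))
    .pkg_env$ntmat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE)
  .pkg_env$ntmat
}

## Local alignment of a short anchor against a read; identity is
## matches / anchor length, robust to clipping. `window` optionally
## restricts the search to the read head ("head") or tail ("tail") of
## the given size, falling back to the whole read on a miss.
.locate_anchor <- function(anchor, read, window = NULL,
                           window_size = 5000L, min_identity = 0) {
  run <- function(sq, off) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = anchor, subject = sq, type = "local",
      substitutionMatrix = .nt_submat(), gapOpening = 1,
      gapExtension = 1)
    sr <- Biostrings::subject(aln)
    list(start = off + Biostrings::start(sr),
         end = off + Biostrings::end(sr),
         identity = Biostrings::nmatch(aln) / nchar(anchor))
  }
  n <- nchar(read)
  if (!is.null(window) && n > window_size) {
    res <- if (window == "head")
      run(substr(read, 1L, window_size), 0L)
    else run(substr(read, n - window_size + 1L, n), n - window_size)
    if (res$identity >= min_identity) return(res)
  }
  run(read, 0L)
}

## Count unit copies between region coordinates by tiling an anchor of
## the unit at expected offsets, re-anchoring on each match so indel
## drift does not accumulate. Returns matched/missed tile counts.
.tile_units <- function(region, unit, anchor_len = 150L,
                        min_identity = 0.75) {
  ulen <- nchar(unit)
  a_len <- min(anchor_len, ulen)
  anchor <- substr(unit, 1L, a_len)
  rlen <- nchar(region)
  slack <- max(60L, round(0.25 * ulen))
  s <- 1L
  outcome <- logical(0)
  while (s + a_len - 1L <= rlen + slack) {
    lo <- max(1L, s - slack)
    hi <- min(rlen, s + a_len + slack)
    if (hi - lo + 1L < a_len * 0.6) break
    win <- substr(region, lo, hi)
    aln <- Biostrings::pairwiseAlignment(
      pattern = anchor, subject = win, type = "global-local",
      substitutionMatrix = .nt_submat(), gapOpening = 1, gapExtension = 1)
    idd <- Biostrings::nmatch(aln) / a_len
    if (idd >= min_identity) {
      outcome <- c(outcome, TRUE)
      hit_start <- lo - 1L + Biostrings::start(Biostrings::subject(aln))
      s <- hit_start + ulen
    } else {
      outcome <- c(outcome, FALSE)
      s <- s + ulen
    }
  }
  matched <- sum(outcome)
  ## misses after the last match are beyond the array, not failed copies
  interior_missed <- if (matched) sum(!outcome[seq_len(max(which(outcome)))])
                     else 0L
  list(matched = matched, missed = interior_missed)
}

#' Estimate repeat iteration number from long reads
#'
#' For each long read, the 3' end of the NTD and the 5' end of the CTD
#' are located by approximate matching (local alignment, identity at
#' least `long_map_id`); between them, repeat-unit copies are counted by
#' tiling alignment of a unit anchor. The copy-number estimate is the
#' mode over spanning reads (ties broken towards the larger value).
#' Continuity is validated when at least one read carries NTD, one or
#' more repeat copies, and CTD in that order on one strand.
#'
#' @param ntd,unit,ctd curated nucleotide sequences (NTD may be `NULL`
#'   if only partially curated; spanning then cannot be validated).
#' @param long_reads named character vector of long reads.
#' @param long_map_id identity threshold for approximate matching
#'   (default 0.75, appropriate for ~10 percent read error).
#' @param anchor_len terminal-domain anchor length (nt).
#' @param max_spanning stop after this many spanning reads have been
#'   evaluated (the mode stabilises quickly).
#' @return list with `n_copies_estimate`, `spanning_read_ids`,
#'   `continuity_validated`, `low_confidence` and `per_read` detail.
#' @export
estimate_iterations <- function(ntd, unit, ctd, long_reads,
                                long_map_id = 0.75, anchor_len = 400L,
                                max_spanning = 8L) {
  if (is.null(unit) || !nchar(unit)) stop("repeat unit must be non-empty")
  if (!length(long_reads)) stop("no long reads supplied")
  if (is.null(names(long_reads)))
    names(long_reads) <- paste0("lr", seq_along(long_reads))
  ulen <- nchar(unit)
  ntd_anchor <- if (!is.null(ntd) && nchar(ntd) >= 50L)
    substr(ntd, max(1L, nchar(ntd) - anchor_len + 1L), nchar(ntd)) else NULL
  ctd_anchor <- if (!is.null(ctd) && nchar(ctd) >= 50L)
    substr(ctd, 1L, min(anchor_len, nchar(ctd))) else NULL
  min_span_len <- sum(nchar(ntd_anchor), nchar(ctd_anchor)) + 2L * ulen
  ord <- order(nchar(long_reads), decreasing = TRUE)
  per_read <- list()
  spanning <- character(0)
  estimates <- integer(0)
  partial_best <- 0L
  n_span_eval <- 0L
  for (ri in ord) {
    if (n_span_eval >= max_spanning) break
    rd <- long_reads[[ri]]
    nm <- names(long_reads)[ri]
    if (nchar(rd) < min_span_len) next
    hit <- NULL
    for (orient in c("+", "-")) {
      sq <- if (orient == "+") rd else revcomp(rd)
      if (!is.null(ntd_anchor)) {
        ln <- .locate_anchor(ntd_anchor, sq, window = "head",
                             min_identity = long_map_id)
        if (ln$identity < long_map_id) next
        region_from <- ln$end + 1L
      } else {
        ln <- NULL
        region_from <- 1L
      }
      if (!is.null(ctd_anchor)) {
        tail_sq <- substr(sq, region_from, nchar(sq))
        lc <- .locate_anchor(ctd_anchor, tail_sq, window = "tail",
                             min_identity = long_map_id)
        if (lc$identity < long_map_id) {
          if (!is.null(ln)) {  # NTD found but no CTD: partial span
            region <- substr(sq, region_from, nchar(sq))
            tl <- .tile_units(region, unit, min_identity = long_map_id)
            partial_best <- max(partial_best, tl$matched)
            per_read[[length(per_read) + 1L]] <- data.frame(
              read = nm, orient = orient, spanning = FALSE,
              n_tiles = tl$matched + tl$missed, matched = tl$matched)
          }
          next
        }
        region_to <- region_from + lc$start - 2L
      } else {
        region_to <- nchar(sq)
        lc <- NULL
      }
      if (region_to <= region_from) next
      region <- substr(sq, region_from, region_to)
      tl <- .tile_units(region, unit, min_identity = long_map_id)
      n_est <- tl$matched + tl$missed
      hit <- data.frame(read = nm, orient = orient,
                        spanning = !is.null(ln) && !is.null(lc),
                        n_tiles = n_est, matched = tl$matched)
      per_read[[length(per_read) + 1L]] <- hit
      if (hit$spanning && tl$matched >= 1L) {
        spanning <- c(spanning, nm)
        estimates <- c(estimates, n_est)
        n_span_eval <- n_span_eval + 1L
      }
      break
    }
  }
  per_read <- if (length(per_read)) do.call(rbind, per_read) else
    data.frame(read = character(0), orient = character(0),
               spanning = logical(0), n_tiles = integer(0),
               matched = integer(0))
  if (length(estimates)) {
    tab <- table(estimates)
    best <- max(as.integer(names(tab)[tab == max(tab)]))
    list(n_copies_estimate = best, spanning_read_ids = spanning,
         continuity_validated = TRUE, low_confidence = FALSE,
         per_read = per_read)
  } else {
    list(n_copies_estimate = max(partial_best, 1L),
         spanning_read_ids = character(0),
         continuity_validated = FALSE, low_confidence = TRUE,
         per_read = per_read)
  }
}
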