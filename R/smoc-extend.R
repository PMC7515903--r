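## Consensus extension and tandem-period detection.

#' Detect the tandem repeat unit at the 3' end of a sequence
#'
#' Finds the smallest period p such that a trailing window aligns to
#' itself shifted by p with identity at or above `id_threshold`. The
#' window is `window_mult * p` characters when that much sequence is
#' available; the minimal two-copy window `2p` is also accepted, so
#' two complete trailing copies are sufficient evidence. The returned
#' unit is a per-column majority consensus over the complete trailing
#' copies, phased so the unit ends at the sequence end.
#'
#' @param sequence character scalar.
#' @param min_period,max_period period search range; `max_period`
#'   defaults to half the (tail) length.
#' @param id_threshold self-alignment identity required (default 0.9).
#' @param window_mult trailing window size in units of p (default 3).
#' @param tail_window optionally restrict the scan to the trailing
#'   `tail_window` characters (used during extension to bound cost).
#' @param prefilter skip periods whose final character does not repeat
#'   at lag p. This is a fast heuristic used by the extension loop
#'   (where a missed check is retried a few bases later); it can miss a
#'   qualifying period whose last column mismatches, so it is off by
#'   default.
#' @return `NULL` if no period qualifies, else a list with `unit`,
#'   `period`, `phase` (`nchar(sequence) %% period`), `identity` and
#'   `n_window_copies`.
#' @export
detect_repeat_unit <- function(sequence, min_period = 1L,
                               max_period = NULL, id_threshold = 0.9,
                               window_mult = 3, tail_window = NULL,
                               prefilter = FALSE) {
  full_n <- nchar(sequence)
  tail_s <- if (!is.null(tail_window) && tail_window < full_n)
    substr(sequence, full_n - tail_window + 1L, full_n) else sequence
  raw <- charToRaw(tail_s)
  n <- length(raw)
  maxp <- min(if (is.null(max_period)) n %/% 2L else max_period, n %/% 2L)
  if (maxp < min_period) return(NULL)
  last <- raw[n]
  for (p in seq.int(min_period, maxp)) {
    ## cheap precheck: the final character must repeat at lag p
    if (prefilter && raw[n - p] != last) next
    ## candidate windows: the full window_mult*p window when that many
    ## copies are present, else the minimal two-copy window 2p (two
    ## complete trailing copies are sufficient evidence)
    ws <- unique(pmin(c(round(window_mult * p), 2L * p), n))
    ws <- sort(ws[ws >= 2L * p], decreasing = TRUE)
    idd <- -1
    w <- 0L
    for (wc in ws) {
      x <- raw[(n - wc + 1L):(n - p)]
      y <- raw[(n - wc + 1L + p):n]
      ic <- mean(x == y)
      if (ic >= id_threshold) { idd <- ic; w <- wc; break }
      if (ic > idd) { idd <- ic; w <- wc }
    }
    if (idd >= id_threshold) {
      k <- w %/% p
      m <- vapply(seq_len(k), function(i)
        raw[(n - i * p + 1L):(n - (i - 1L) * p)], raw(p))
      cons <- raw(p)
      cnt_best <- integer(p)
      for (b in charToRaw(c2s(.BASES))) {
        cnt <- rowSums(m == b)
        upd <- cnt > cnt_best
        cons[upd] <- b
        cnt_best[upd] <- cnt[upd]
      }
      return(list(unit = rawToChar(cons), period = p,
                  phase = full_n %% p, identity = idd,
                  n_window_copies = k))
    }
  }
  NULL
}

#' Extend a seed through PWM consensus until repeats appear
#'
#' Iteratively takes the 3'-terminal k-mer of the growing consensus,
#' recruits short reads containing it exactly, builds a PWM over their
#' 3' overhangs, and accepts consensus bases column by column while the
#' column support is at least `min_depth` reads and the dominant-base
#' fraction is at least `min_purity`. Ties at the column maximum are
#' broken lexicographically (A<C<G<T) only when the purity threshold is
#' met; otherwise extension stops. Extension terminates when the
#' consensus tail becomes periodic with at least two complete trailing
#' copies (`repeat_detected`), when no column passes
#' (`support_exhausted`), or at `max_length`.
#'
#' @param seed seed sequence (length >= k).
#' @param index a [build_kmer_screen()] index over the short reads.
#' @param min_depth minimum reads supporting an accepted column.
#' @param min_purity minimum dominant-base fraction.
#' @param poly_support_factor,poly_purity_floor secondary acceptance
#'   rule for polymorphic tandem copies: inside a repeat array the
#'   recruited reads come from every copy at once, so a position where
#'   a minority of copies diverged shows a genuine mixed column. Such a
#'   column is still accepted when its support is at least
#'   `poly_support_factor * min_depth`, its purity at least
#'   `poly_purity_floor`, and the majority base is strict. The accepted
#'   base is then the across-copy majority, which is exactly the repeat
#'   unit consensus being sought.
#' @param max_length hard cap on consensus length.
#' @param min_period,max_unit,repeat_id_threshold,repeat_window
#'   periodicity detection parameters (see [detect_repeat_unit()]);
#'   `repeat_window` bounds the scanned tail and `max_unit` the largest
#'   period considered.
#' @param check_every run the periodicity check every this many steps.
#' @param fallback_index optional second [build_kmer_screen()] index at
#'   a smaller (still large) k. Used only when the primary anchor
#'   recruits no acceptable column: low-complexity repeat units can
#'   lack any read carrying the full-length majority k-mer in a given
#'   window, while a shorter anchor still recruits specifically. A
#'   step rescued this way is marked in the log.
#' @return object of class `extension_state`: list with `consensus`,
#'   `seed_length`, `steps` (per-step log: kmer, reads recruited, bases
#'   accepted), `stop_reason` and `repeat_unit` (from
#'   [detect_repeat_unit()], or NULL).
#' @export
extend_consensus <- function(seed, index, min_depth = 5L,
                             min_purity = 0.8,
                             poly_support_factor = 3,
                             poly_purity_floor = 0.5,
                             max_length = 50000L,
                             min_period = 50L, max_unit = 1500L,
                             repeat_id_threshold = 0.9,
                             repeat_window = 6000L, check_every = 2L,
                             fallback_index = NULL) {
  stopifnot(inherits(index, "kmer_index"))
  k <- index$k
  if (nchar(seed) < k) stop("seed shorter than k")
  accept_cols <- function(pw) {
    n_cols <- ncol(pw$counts)
    acc <- 0L
    while (acc < n_cols) {
      j <- acc + 1L
      s <- pw$support[j]
      if (s < min_depth) break
      if (pw$purity[j] < min_purity) {
        srt <- sort(pw$counts[, j], decreasing = TRUE)
        strict <- srt[1L] > srt[2L]
        if (!(s >= poly_support_factor * min_depth &&
              pw$purity[j] >= poly_purity_floor && strict)) break
      }
      acc <- j
    }
    acc
  }
  try_step <- function(consensus, idx) {
    len <- nchar(consensus)
    kq <- substr(consensus, len - idx$k + 1L, len)
    rec <- recruit_and_align(kq, idx)
    if (!length(rec$overhangs))
      return(list(kmer = kq, reads = 0L, acc = 0L, accepted = ""))
    pw <- pwm_from_overhangs(rec$overhangs)
    acc <- accept_cols(pw)
    list(kmer = kq, reads = length(rec$overhangs), acc = acc,
         accepted = if (acc > 0L) substr(pw$consensus, 1L, acc) else "")
  }
  consensus <- seed
  seed_len <- nchar(seed)
  steps <- list()
  stop_reason <- NULL
  rep_unit <- NULL
  step <- 0L
  repeat {
    step <- step + 1L
    len <- nchar(consensus)
    if (len >= max_length) { stop_reason <- "max_length"; break }
    st <- try_step(consensus, index)
    fallback <- FALSE
    if (st$acc == 0L && !is.null(fallback_index)) {
      st2 <- try_step(consensus, fallback_index)
      if (st2$acc > 0L) { st <- st2; fallback <- TRUE }
    }
    steps[[step]] <- data.frame(step = step, kmer = st$kmer,
                                reads = st$reads, accepted = st$acc,
                                fallback = fallback)
    if (st$acc == 0L) { stop_reason <- "support_exhausted"; break }
    consensus <- paste0(consensus, st$accepted)
    grown <- nchar(consensus) - seed_len
    if (grown >= 2L * min_period && step %% check_every == 0L) {
      ru <- detect_repeat_unit(consensus, min_period = min_period,
                               max_period = max_unit,
                               id_threshold = repeat_id_threshold,
                               tail_window = min(repeat_window,
                                                 nchar(consensus)),
                               prefilter = TRUE)
      if (!is.null(ru)) {
        stop_reason <- "repeat_detected"
        rep_unit <- ru
        break
      }
    }
  }
  if (is.null(rep_unit) && identical(stop_reason, "support_exhausted")) {
    ## a final check: support may die right after the array is complete
    ru <- detect_repeat_unit(consensus, min_period = min_period,
                             max_period = max_unit,
                             id_threshold = repeat_id_threshold,
                             tail_window = min(repeat_window,
                                               nchar(consensus)))
    if (!is.null(ru)) rep_unit <- ru
  }
  structure(list(
    consensus = consensus, seed_length = seed_len,
    steps = if (length(steps)) do.call(rbind, steps) else
      data.frame(step = integer(0), kmer = character(0),
                 reads = integer(0), accepted = integer(0),
                 fallback = logical(0)),
    stop_reason = stop_reason, repeat_unit = rep_unit
  ), class = "extension_state")
}

#' @export
print.extension_state <- function(x, ...) {
  cat(sprintf("extension_state: %d nt (seed %d), %d steps, stopped: %s%s\n",
              nchar(x$consensus), x$seed_length, nrow(x$steps),
              x$stop_reason,
              if (!is.null(x$repeat_unit))
                sprintf(" (period %d)", x$repeat_unit$period) else ""))
  invisible(x)
}

## Leftmost start of the p-periodic tail of `sequence`: walks agreement
## seq[i] == seq[i+p] leftwards and stops where a 30-nt window drops
## below `min_agree`. Returns the 1-based start of the periodic region.
periodic_boundary <- function(sequence, p, min_agree = 0.8,
                              window = 30L) {
  raw <- charToRaw(sequence)
  n <- length(raw)
  if (n <= p) return(n + 1L)
  agree <- raw[seq_len(n - p)] == raw[(p + 1L):n]
  b <- n - p + 1L
  i <- n - p
  while (i >= 1L) {
    lo <- max(1L, i - window + 1L)
    if (mean(agree[lo:i]) < min_agree) break
    b <- i
    i <- i - 1L
  }
  ## refine to the exact edge: walk single positions past the window
  ## break, then trim any leading disagreements
  while (b > 1L && agree[b - 1L]) b <- b - 1L
  while (b <= n - p && !agree[b]) b <- b + 1L
  b
}
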