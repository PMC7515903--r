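## Seed discovery on contigs and the end-to-end curation driver.

.aa_submat <- function() {
  if (is.null(.pkg_env$blosum)) {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    .pkg_env$blosum <- get("BLOSUM62", envir = environment())
  }
  .pkg_env$blosum
}

#' Find terminal-domain and repeat seeds on contigs
#'
#' Translates each contig in all six frames and searches the amino-acid
#' query profiles by local alignment (BLOSUM62). A hit requires an
#' alignment of at least `min_hit_len` aligned residues at identity
#' `min_identity` or better. Coordinates are reported on the original
#' contig (1-based, inclusive), with the matching strand.
#'
#' @param contigs named character vector of nucleotide contigs, or a
#'   FASTA path.
#' @param profiles data.frame with columns `name`, `category` (one of
#'   NTD/CTD/repeat) and `sequence` (amino acids).
#' @param min_identity minimum alignment identity (matches / alignment
#'   length).
#' @param min_hit_len minimum alignment length in residues.
#' @return data.frame of hits: contig, profile, category, strand, frame,
#'   start, end (nt), identity, coverage.
#' @export
find_seeds <- function(contigs, profiles, min_identity = 0.75,
                       min_hit_len = 30L) {
  if (is.character(contigs) && length(contigs) == 1L &&
      file.exists(contigs)) contigs <- read_fasta(contigs)
  if (!length(contigs)) return(.empty_seeds())
  if (!all(c("name", "category", "sequence") %in% names(profiles)))
    stop("profiles must have columns name, category, sequence")
  if (!nrow(profiles)) stop("no query profiles supplied")
  if (is.null(names(contigs)))
    names(contigs) <- paste0("contig", seq_along(contigs))
  mat <- .aa_submat()
  hits <- list()
  for (cn in names(contigs)) {
    fwd <- contigs[[cn]]
    L <- nchar(fwd)
    for (strand in c("+", "-")) {
      sq <- if (strand == "+") fwd else revcomp(fwd)
      for (f in 0:2) {
        aa <- translate_nt(substr(sq, f + 1L, L))
        if (nchar(aa) < min_hit_len) next
        aa <- gsub("\\*", "X", aa)  # keep frame intact across stops
        for (pi in seq_len(nrow(profiles))) {
          aln <- Biostrings::pairwiseAlignment(
            pattern = profiles$sequence[pi], subject = aa,
            type = "local", substitutionMatrix = mat,
            gapOpening = 10, gapExtension = 0.5)
          alen <- Biostrings::nchar(aln)
          if (alen < min_hit_len) next
          idd <- Biostrings::nmatch(aln) / alen
          if (idd < min_identity) next
          sr <- Biostrings::subject(aln)
          nt_s <- f + 3L * (Biostrings::start(sr) - 1L) + 1L
          nt_e <- f + 3L * Biostrings::end(sr)
          if (strand == "-") {
            tmp <- nt_s
            nt_s <- L - nt_e + 1L
            nt_e <- L - tmp + 1L
          }
          hits[[length(hits) + 1L]] <- data.frame(
            contig = cn, profile = profiles$name[pi],
            category = profiles$category[pi], strand = strand,
            frame = f, start = nt_s, end = nt_e, identity = idd,
            coverage = alen / nchar(profiles$sequence[pi]))
        }
      }
    }
  }
  if (!length(hits)) return(.empty_seeds())
  do.call(rbind, hits)
}

.empty_seeds <- function() {
  data.frame(contig = character(0), profile = character(0),
             category = character(0), strand = character(0),
             frame = integer(0), start = integer(0), end = integer(0),
             identity = numeric(0), coverage = numeric(0))
}

#' Build query profiles from gene records
#'
#' Convenience for synthetic runs: translates the NTD and CTD of each
#' gene into amino-acid query profiles for [find_seeds()].
#' @param genes list of `gene_record`s.
#' @return profiles data.frame (name, category, sequence).
#' @export
profiles_from_genes <- function(genes) {
  if (inherits(genes, "gene_record")) genes <- list(genes)
  do.call(rbind, lapply(genes, function(g) {
    data.frame(
      name = paste0(g$gene_id, c("_NTD", "_CTD")),
      category = c("NTD", "CTD"),
      sequence = c(translate_nt(g$ntd_nt), translate_nt(g$ctd_nt)))
  }))
}

#' Best rotational identity between two repeat units
#'
#' Tandem-repeat units are defined only up to rotation (and, when
#' detected from opposite ends, differ in phase); this returns the best
#' identity over all circular shifts of `b` against `a`. Units of
#' unequal length are compared at the shorter length after tandem
#' doubling the longer.
#' @param a,b unit sequences.
#' @return identity in `[0, 1]`.
#' @export
rotational_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    ## compare at the shorter length after tandem-doubling the longer
    n <- min(nchar(a), nchar(b))
    a <- substr(a, 1L, n); b <- substr(strrep(b, 2L), 1L, n)
  }
  n <- nchar(a)
  bb <- paste0(b, b)
  best <- 0
  for (s in 0:(n - 1L)) {
    idd <- str_identity(a, substr(bb, s + 1L, s + n))
    if (idd > best) best <- idd
    if (best == 1) break
  }
  best
}

#' Polish a repeat-unit consensus against the short reads
#'
#' The first bases of a unit walked out of a terminal domain are
#' anchored at a single copy and may carry that copy's private variants.
#' Polishing replaces every unit position by the majority base of a
#' k-mer-anchored pileup taken in cyclic (tandem-array) space, i.e. the
#' across-copy majority. Positions with pileup support below
#' `min_depth` are left unchanged.
#'
#' @param unit unit consensus to polish.
#' @param index short-read [build_kmer_screen()] index.
#' @param min_depth minimum pileup support to override a position.
#' @param repair_index optional smaller-k index used for the
#'   low-support rescue: a shorter anchor is clean in more copies, so
#'   the across-copy vote at a rescued position rests on more loci.
#' @return polished unit string.
#' @export
polish_unit <- function(unit, index, min_depth = 5L,
                        repair_index = NULL) {
  p <- nchar(unit)
  k <- index$k
  if (p < 10L) return(unit)
  COMP <- c(A = "T", C = "G", G = "C", T = "A")
  pileup <- function(anchors) {
    ## counts of the base immediately following each anchor, per position
    qry <- data.table::data.table(kmer = anchors, pos = seq_len(p))
    hits <- index$table[qry, on = "kmer", nomatch = NULL,
                        allow.cartesian = TRUE]
    cnt <- matrix(0L, nrow = p, ncol = 4L,
                  dimnames = list(NULL, .BASES))
    if (!nrow(hits)) return(cnt)
    src <- ifelse(hits$strand == "+", index$fwd[hits$read],
                  index$rev[hits$read])
    base <- substr(src, hits$offset + k, hits$offset + k)
    keep <- base != ""
    if (!any(keep)) return(cnt)
    tab <- table(pos = factor(hits$pos[keep], levels = seq_len(p)),
                 base = factor(base[keep], levels = .BASES))
    cnt + unclass(tab)
  }
  ## tandem-tile the unit so both anchors stay in range for any k/p
  m <- p * (ceiling(k / p) + 1L)           # offset of the focal copy
  tiled <- strrep(unit, (m + p + k) %/% p + 1L)
  ends <- m + seq_len(p) - 1L
  ## forward: anchor = k bases cyclically preceding position i
  fwd_anchors <- substring(tiled, ends - k + 1L, ends)
  cnt <- pileup(fwd_anchors)
  ## reverse: anchor = reverse complement of the k bases following i,
  ## whose 3' overhang starts with the complement of position i. This
  ## rescues positions whose upstream context carries a variant.
  starts <- m + seq_len(p) + 1L
  rev_anchors <- revcomp(substring(tiled, starts, starts + k - 1L))
  cnt_rev <- pileup(rev_anchors)
  cnt <- cnt + cnt_rev[, COMP[.BASES], drop = FALSE]
  support <- rowSums(cnt)
  maj <- .BASES[max.col(cnt, ties.method = "first")]
  out <- s2c(unit)
  upd <- support >= min_depth
  out[upd] <- maj[upd]
  ## Low-support rescue: a cluster of first-copy variants spaced within
  ## the anchor length contaminates every anchor that covers it, so the
  ## pileup only recruits that copy (support ~ 1/n_copies of typical)
  ## and the majority vote cannot escape. For such positions, try all
  ## four bases and keep the one whose covering anchor recruits the
  ## most reads; repairing left to right unravels the chain.
  ## Recruitment-count repair: the pileup vote above can be confounded
  ## when, by chance, only one copy besides the variant-carrying one is
  ## clean over the anchor window. For every position and every base,
  ## count the reads recruited by the anchor ending at that position
  ## with that base substituted (one batch join), and flip a base only
  ## on a clear recruitment majority. Iterating the polish lets chains
  ## of first-copy variants unravel one link per round.
  ridx <- if (!is.null(repair_index)) repair_index else index
  rk <- ridx$k
  m2 <- p * (ceiling(rk / p) + 1L)
  ends2 <- m2 + seq_len(p)            # tiled index of unit position i
  for (round in 1:8) {
    tiled2 <- strrep(c2s(out), (m2 + p + rk) %/% p + 1L)
    prefix <- substring(tiled2, ends2 - rk + 1L, ends2 - 1L)
    qry2 <- data.table::data.table(
      kmer = paste0(rep(prefix, each = 4L), .BASES),
      pos = rep(seq_len(p), each = 4L),
      base = rep(.BASES, p))
    hits2 <- ridx$table[qry2, on = "kmer", nomatch = NULL,
                        allow.cartesian = TRUE]
    if (!nrow(hits2)) break
    rc <- table(pos = factor(hits2$pos, levels = seq_len(p)),
                base = factor(hits2$base, levels = .BASES))
    best_i <- max.col(rc, ties.method = "first")
    best_n <- rc[cbind(seq_len(p), best_i)]
    cur_n <- rc[cbind(seq_len(p), match(out, .BASES))]
    flip <- .BASES[best_i] != out & best_n >= min_depth &
      best_n > 1.5 * cur_n
    if (!any(flip)) break
    out[flip] <- .BASES[best_i[flip]]
  }
  c2s(out)
}

## Extract oriented seed sequence for a hit row.
.seed_sequence <- function(contigs, hit) {
  sq <- substr(contigs[[hit$contig]], hit$start, hit$end)
  if (hit$strand == "-") revcomp(sq) else sq
}

#' Curate one spidroin gene from contigs, short reads and long reads
#'
#' Runs the full seed-extension curation for a single locus: seed
#' discovery on the contigs, large-k-mer PWM extension from the NTD seed
#' (3' direction) and from the reverse complement of the CTD seed, repeat
#' unit extraction with phase anchored at the NTD/repeat boundary, a
#' consistency check between the two independently extended units, and
#' copy-number estimation from the long reads.
#'
#' @param contigs named character vector (or FASTA path).
#' @param short_reads named character vector of short reads (both mates
#'   pooled; orientation is handled by the two-strand k-mer index).
#' @param long_reads named character vector of long reads.
#' @param profiles seed query profiles (see [find_seeds()]).
#' @param gene_id identifier for the curated record.
#' @param k,min_depth,min_purity extension parameters
#'   (see [extend_consensus()]).
#' @param fallback_k smaller anchor size used only when the primary
#'   k-mer stalls (see `fallback_index` in [extend_consensus()]);
#'   NULL disables the fallback.
#' @param min_period minimum repeat period considered (nt).
#' @param long_map_id long-read approximate-match identity threshold.
#' @param unit_conflict_id minimum rotational identity tolerated between
#'   the NTD-side and CTD-side unit consensuses before curation aborts.
#' @return object of class `curated_gene`.
#' @export
curate_gene <- function(contigs, short_reads, long_reads, profiles,
                        gene_id = "gene1", k = 72L, fallback_k = 44L,
                        min_depth = 5L,
                        min_purity = 0.8, min_period = 50L,
                        long_map_id = 0.75, unit_conflict_id = 0.9) {
  if (is.character(contigs) && length(contigs) == 1L &&
      file.exists(contigs)) contigs <- read_fasta(contigs)
  seeds <- find_seeds(contigs, profiles)
  index <- build_kmer_screen(short_reads, k = k)
  fb_index <- if (!is.null(fallback_k) && fallback_k < k)
    build_kmer_screen(short_reads, k = fallback_k) else NULL
  pick <- function(cat) {
    h <- seeds[seeds$category == cat, , drop = FALSE]
    if (!nrow(h)) return(NULL)
    h[order(-h$identity * h$coverage), , drop = FALSE][1L, , drop = FALSE]
  }
  ntd_hit <- pick("NTD")
  ctd_hit <- pick("CTD")
  if (is.null(ntd_hit) && is.null(ctd_hit))
    stop("no terminal-domain seeds found on the contigs")

  extend_side <- function(seed) {
    if (nchar(seed) < k) return(NULL)
    ext <- extend_consensus(seed, index, min_depth = min_depth,
                            min_purity = min_purity,
                            min_period = min_period,
                            fallback_index = fb_index)
    if (is.null(ext$repeat_unit))
      ## no periodicity reached from this side: keep the seed region as
      ## the curated terminal, contribute no unit
      return(list(ext = ext, unit = NULL,
                  flank = substr(ext$consensus, 1L, nchar(seed))))
    p <- ext$repeat_unit$period
    b <- periodic_boundary(ext$consensus, p)
    list(ext = ext, period = p, boundary = b,
         flank = substr(ext$consensus, 1L, b - 1L),
         unit = substr(ext$consensus, b, min(b + p - 1L,
                                             nchar(ext$consensus))))
  }

  ntd_side <- if (!is.null(ntd_hit))
    extend_side(.seed_sequence(contigs, ntd_hit)) else NULL
  ctd_side <- if (!is.null(ctd_hit))
    extend_side(revcomp(.seed_sequence(contigs, ctd_hit))) else NULL

  unit_n <- if (!is.null(ntd_side$unit)) ntd_side$unit else NULL
  unit_c <- if (!is.null(ctd_side$unit)) revcomp(ctd_side$unit) else NULL
  if (!is.null(unit_n) && !is.null(unit_c)) {
    rid <- rotational_identity(unit_n, unit_c)
    if (rid < unit_conflict_id)
      stop(sprintf(paste0(
        "conflicting repeat units from NTD-side and CTD-side extension ",
        "(rotational identity %.3f):\n  NTD-side: %s...\n  CTD-side: %s..."),
        rid, substr(unit_n, 1, 40), substr(unit_c, 1, 40)))
  }
  unit <- if (!is.null(unit_n)) unit_n else unit_c
  if (is.null(unit))
    stop("extension did not reach a repeat region from either terminal")
  ## iterate: polishing improves the anchors, which improves the
  ## pileup; chained variants resolve one link per round
  for (it in 1:8) {
    polished <- polish_unit(unit, index, min_depth = min_depth,
                            repair_index = fb_index)
    if (identical(polished, unit)) break
    unit <- polished
  }

  ntd_nt <- if (!is.null(ntd_side)) ntd_side$flank else NULL
  ctd_nt <- if (!is.null(ctd_side)) revcomp(ctd_side$flank) else NULL
  est <- estimate_iterations(ntd_nt, unit, ctd_nt, long_reads,
                             long_map_id = long_map_id)
  assemble_curated_gene(gene_id, seeds, ntd_side, ctd_side, unit, est,
                        ntd_hit, ctd_hit)
}

#' Assemble a curated gene record
#'
#' Merges the two extension results, the repeat unit and the long-read
#' iteration estimate into one record; terminals whose seed was absent
#' or whose profile coverage fell below 0.8 are flagged partial.
#'
#' @param gene_id identifier.
#' @param seeds seed table from [find_seeds()].
#' @param ntd_side,ctd_side extension summaries (internal structure from
#'   [curate_gene()]); may be NULL.
#' @param unit final repeat-unit consensus (coding strand).
#' @param est result of [estimate_iterations()].
#' @param ntd_hit,ctd_hit the chosen seed rows (may be NULL).
#' @return object of class `curated_gene`.
#' @export
assemble_curated_gene <- function(gene_id, seeds, ntd_side, ctd_side,
                                  unit, est, ntd_hit = NULL,
                                  ctd_hit = NULL) {
  flag <- function(hit, side) {
    if (is.null(hit) || is.null(side)) "partial"
    else if (hit$coverage < 0.8) "partial" else "complete"
  }
  structure(list(
    gene_id = gene_id,
    family_label = NA_character_,
    ntd_nt = if (!is.null(ntd_side)) ntd_side$flank else NA_character_,
    ctd_nt = if (!is.null(ctd_side)) revcomp(ctd_side$flank)
             else NA_character_,
    repeat_unit_nt = unit,
    n_copies_estimate = max(1L, est$n_copies_estimate),
    confidence = if (est$low_confidence) "low" else "spanning-read mode",
    spanning_long_read_ids = est$spanning_read_ids,
    continuity_validated = est$continuity_validated,
    ntd_flag = flag(ntd_hit, ntd_side),
    ctd_flag = flag(ctd_hit, ctd_side),
    seeds = seeds,
    per_read = est$per_read
  ), class = "curated_gene")
}

#' @export
print.curated_gene <- function(x, ...) {
  cat(sprintf(
    "curated_gene %s: NTD %s nt [%s], unit %d nt x %d (%s), CTD %s nt [%s]\n  continuity validated: %s (%d spanning reads)\n",
    x$gene_id,
    if (is.na(x$ntd_nt)) "?" else nchar(x$ntd_nt), x$ntd_flag,
    nchar(x$repeat_unit_nt), x$n_copies_estimate, x$confidence,
    if (is.na(x$ctd_nt)) "?" else nchar(x$ctd_nt), x$ctd_flag,
    x$continuity_validated, length(x$spanning_long_read_ids)))
  invisible(x)
}

#' Write curated genes as a TSV catalogue and per-domain FASTA
#'
#' @param curated list of `curated_gene`s.
#' @param tsv_path catalogue TSV path (gene_id, family, ntd_len,
#'   unit_len, ctd_len, n_copies, flags).
#' @param fasta_path optional FASTA of domain records with suffixes
#'   `_NTD`, `_RTD_unit`, `_CTD`.
#' @return the catalogue data.frame, invisibly.
#' @export
write_curated_catalog <- function(curated, tsv_path, fasta_path = NULL) {
  if (inherits(curated, "curated_gene")) curated <- list(curated)
  cat_df <- do.call(rbind, lapply(curated, function(g) data.frame(
    gene_id = g$gene_id,
    family = g$family_label,
    ntd_len = if (is.na(g$ntd_nt)) NA_integer_ else nchar(g$ntd_nt),
    unit_len = nchar(g$repeat_unit_nt),
    ctd_len = if (is.na(g$ctd_nt)) NA_integer_ else nchar(g$ctd_nt),
    n_copies = g$n_copies_estimate,
    continuity = g$continuity_validated,
    flags = paste0("ntd:", g$ntd_flag, ";ctd:", g$ctd_flag))))
  write.table(cat_df, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(fasta_path)) {
    seqs <- unlist(lapply(curated, function(g) {
      out <- c()
      if (!is.na(g$ntd_nt)) out[paste0(g$gene_id, "_NTD")] <- g$ntd_nt
      out[paste0(g$gene_id, "_RTD_unit")] <- g$repeat_unit_nt
      if (!is.na(g$ctd_nt)) out[paste0(g$gene_id, "_CTD")] <- g$ctd_nt
      out
    }))
    write_fasta(seqs, fasta_path)
  }
  invisible(cat_df)
}
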