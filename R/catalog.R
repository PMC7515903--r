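## Annotation of spidroin sequences: start-codon selection by Kozak
## context plus a signal-peptide hydropathy heuristic, domain
## segmentation against terminal profiles, tandem decomposition and
## silk-motif scanning.

## Kyte-Doolittle hydropathy index.
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2)

#' Signal-peptide likelihood heuristic
#'
#' A lightweight, deterministic stand-in for a dedicated signal-peptide
#' predictor: the maximum sliding-window (width 9) mean Kyte-Doolittle
#' hydropathy over residues 1-30, rescaled to `[0, 1]`, plus a bonus for
#' a positively charged residue (K/R) among the first five. The score is
#' bounded in `[0, 1]` and invariant to sequence beyond residue 30.
#'
#' @param protein_nterm amino-acid string (only the first 30 residues
#'   are used).
#' @param window hydropathy window width.
#' @return numeric score in `[0, 1]`.
#' @export
signal_peptide_score <- function(protein_nterm, window = 9L) {
  aa <- s2c(toupper(substr(protein_nterm, 1L, 30L)))
  h <- unname(.KD[aa])
  h[is.na(h)] <- 0
  n <- length(h)
  if (n < window) {
    win_max <- if (n) mean(h) else -4.5
  } else {
    cs <- cumsum(c(0, h))
    win_max <- max((cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) /
                     window)
  }
  hydro <- (win_max + 4.5) / 9
  hydro <- min(max(hydro, 0), 1)
  charged <- any(aa[seq_len(min(5L, length(aa)))] %in% c("K", "R"))
  0.8 * hydro + 0.2 * as.numeric(charged)
}

## Kozak context score for an ATG at nt position pos (1-based):
## purine at -3 weighted 2, G at +4 weighted 1.
.kozak_score <- function(cdna, pos) {
  up <- if (pos >= 4L) substr(cdna, pos - 3L, pos - 3L) else ""
  dn <- substr(cdna, pos + 3L, pos + 3L)
  2 * (up %in% c("A", "G")) + 1 * (dn == "G")
}

#' Select the translation start codon of a cDNA
#'
#' Scores every ATG that opens an ORF of at least `min_orf_aa` codons by
#' Kozak context (purine at -3, G at +4) combined with the
#' signal-peptide heuristic on the first 30 encoded residues, and
#' returns the best-scoring candidate. All candidates are reported for
#' auditability.
#'
#' @param cdna nucleotide string.
#' @param min_orf_aa minimum open reading frame length (codons).
#' @param sp_weight weight of the signal-peptide score (it is bounded by
#'   1, so with the default it acts as a tie-break between equal Kozak
#'   contexts).
#' @return list with `position` (1-based nt offset of the A of ATG),
#'   `score`, and `candidates` (data.frame position/orf_aa/kozak/
#'   sp_score/score).
#' @export
select_start_codon <- function(cdna, min_orf_aa = 50L, sp_weight = 1) {
  cdna <- toupper(cdna)
  starts <- gregexpr("ATG", cdna, fixed = TRUE)[[1L]]
  if (starts[1L] == -1L) stop("no ATG found")
  rows <- lapply(as.integer(starts), function(pos) {
    orf_nt <- substr(cdna, pos, nchar(cdna))
    aa <- translate_nt(orf_nt)
    stop_at <- regexpr("*", aa, fixed = TRUE)
    orf_aa <- if (stop_at == -1L) nchar(aa) else stop_at - 1L
    if (orf_aa < min_orf_aa) return(NULL)
    sp <- signal_peptide_score(substr(aa, 1L, 30L))
    kz <- .kozak_score(cdna, pos)
    data.frame(position = pos, orf_aa = orf_aa, kozak = kz,
               sp_score = sp, score = kz + sp_weight * sp)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || !nrow(rows))
    stop("no ATG opens an ORF of at least ", min_orf_aa, " codons")
  best <- rows[order(-rows$score, rows$position), ][1L, ]
  list(position = best$position, score = best$score, candidates = rows)
}

#' Segment a spidroin sequence into NTD / RTD / CTD
#'
#' Locates the terminal domains by best local alignment of the sequence
#' (translated in six frames) to family terminal profiles, takes the
#' interval between them as the repetitive domain, and decomposes it
#' into tandem copies with [detect_repeat_unit()]. A terminal whose
#' alignment covers less than 80 percent of its profile is flagged
#' partial.
#'
#' @param sequence nucleotide string (the gene/cDNA on its coding
#'   strand).
#' @param terminal_profiles profiles data.frame (name, category in
#'   NTD/CTD, sequence) as for [find_seeds()].
#' @param gene_id identifier carried into the annotation.
#' @param min_period minimum repeat period considered.
#' @return object of class `domain_annotation`: list with `gene_id`,
#'   nt intervals `ntd`, `rtd`, `ctd` (1-based, inclusive),
#'   `unit_len_mean`, `n_copies`, `partial` flags and the repeat unit.
#' @export
segment_domains <- function(sequence, terminal_profiles,
                            gene_id = "gene1", min_period = 50L) {
  hits <- find_seeds(setNames(sequence, "x"), terminal_profiles)
  pick <- function(cat) {
    h <- hits[hits$category == cat & hits$strand == "+", , drop = FALSE]
    if (!nrow(h)) return(NULL)
    h[order(-h$identity * h$coverage), , drop = FALSE][1L, , drop = FALSE]
  }
  nh <- pick("NTD"); ch <- pick("CTD")
  n <- nchar(sequence)
  ntd <- if (!is.null(nh)) c(1L, nh$end) else NULL
  ctd <- if (!is.null(ch)) c(ch$start, n) else NULL
  rtd <- c(if (!is.null(ntd)) ntd[2L] + 1L else 1L,
           if (!is.null(ctd)) ctd[1L] - 1L else n)
  if (rtd[2L] <= rtd[1L]) stop("no repetitive interval between terminals")
  rtd_seq <- substr(sequence, rtd[1L], rtd[2L])
  ru <- detect_repeat_unit(rtd_seq, min_period = min_period)
  rtd_len <- rtd[2L] - rtd[1L] + 1L
  if (!is.null(ru)) {
    n_copies <- max(1L, round(rtd_len / ru$period))
    unit_len_mean <- rtd_len / n_copies
  } else {
    n_copies <- NA_integer_; unit_len_mean <- NA_real_
  }
  structure(list(
    gene_id = gene_id,
    ntd = ntd, rtd = rtd, ctd = ctd,
    unit_len_mean = unit_len_mean, n_copies = n_copies,
    repeat_unit = if (!is.null(ru)) ru$unit else NA_character_,
    partial = c(ntd = is.null(nh) || nh$coverage < 0.8,
                ctd = is.null(ch) || ch$coverage < 0.8)
  ), class = "domain_annotation")
}

#' @export
print.domain_annotation <- function(x, ...) {
  iv <- function(v) if (is.null(v)) "absent" else
    sprintf("%d-%d", v[1L], v[2L])
  cat(sprintf(
    "domain_annotation %s: NTD %s | RTD %s (unit ~%.0f nt x %s) | CTD %s\n",
    x$gene_id, iv(x$ntd), iv(x$rtd), x$unit_len_mean,
    x$n_copies, iv(x$ctd)))
  invisible(x)
}

#' Packaged terminal-domain query profiles
#'
#' Loads the synthetic terminal-domain amino-acid profiles shipped with
#' the package (one NTD and one CTD profile per spidroin family,
#' generated from the family architecture defaults). They are
#' placeholders for user-supplied profiles of curated real sequences:
#' pass your own data.frame of the same shape to [find_seeds()] or
#' [segment_domains()] to annotate real data.
#'
#' @return profiles data.frame (name, category, sequence).
#' @export
default_terminal_profiles <- function() {
  path <- system.file("extdata", "synthetic_terminal_profiles.fasta",
                      package = "silkforge")
  x <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(x), " ", fixed = TRUE)
  data.frame(
    name = vapply(parts, `[[`, "", 1L),
    category = vapply(parts, `[[`, "", 2L),
    sequence = unname(as.character(x)))
}

.MOTIF_CLASSES <- c("polyA", "GPGGX", "GPSS", "GGX", "QQ", "TT", "SS")

#' Scan silk motifs in an amino-acid sequence
#'
#' Greedy non-overlapping left-to-right scan. Glycine motifs are matched
#' with longer-motif precedence (GPGGX > GPSS > GGX); dipeptide classes
#' (QQ, TT, SS) are counted as `floor(run / 2)` over maximal
#' same-residue runs of positions not consumed by a glycine motif;
#' poly-alanine counts maximal A-runs of at least `min_run` residues
#' (one count per run).
#'
#' @param aa_sequence amino-acid string.
#' @param min_run minimum poly-A run length (default 4).
#' @return object of class `motif_profile`: named integer vector of
#'   counts with attribute `consumed` (logical mask).
#' @export
scan_motifs <- function(aa_sequence, min_run = 4L) {
  x <- s2c(toupper(aa_sequence))
  n <- length(x)
  counts <- setNames(integer(length(.MOTIF_CLASSES)), .MOTIF_CLASSES)
  consumed <- rep(FALSE, n)
  i <- 1L
  while (i <= n) {
    if (i + 4L <= n && x[i] == "G" && x[i + 1L] == "P" &&
        x[i + 2L] == "G" && x[i + 3L] == "G") {
      counts["GPGGX"] <- counts["GPGGX"] + 1L
      consumed[i:(i + 4L)] <- TRUE
      i <- i + 5L
    } else if (i + 3L <= n && x[i] == "G" && x[i + 1L] == "P" &&
               x[i + 2L] == "S" && x[i + 3L] == "S") {
      counts["GPSS"] <- counts["GPSS"] + 1L
      consumed[i:(i + 3L)] <- TRUE
      i <- i + 4L
    } else if (i + 2L <= n && x[i] == "G" && x[i + 1L] == "G") {
      counts["GGX"] <- counts["GGX"] + 1L
      consumed[i:(i + 2L)] <- TRUE
      i <- i + 3L
    } else i <- i + 1L
  }
  ## runs over unconsumed positions
  run_counts <- function(res) {
    hits <- which(x == res & !consumed)
    if (!length(hits)) return(integer(0))
    breaks <- c(0L, which(diff(hits) != 1L), length(hits))
    diff(breaks)  # lengths of maximal runs
  }
  for (res in c(Q = "Q", T = "T", S = "S")) {
    cls <- paste0(res, res)
    counts[cls] <- sum(run_counts(res) %/% 2L)
  }
  a_runs <- run_counts("A")
  counts["polyA"] <- sum(a_runs >= min_run)
  structure(counts, consumed = consumed, class = "motif_profile")
}

#' @export
print.motif_profile <- function(x, ...) {
  cat("motif_profile:",
      paste(names(x), unclass(x), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Annotate a gene end to end
#'
#' Convenience wrapper: domain segmentation plus motif scanning of the
#' translated repetitive domain.
#' @param gene a `gene_record` or nucleotide string.
#' @param profiles terminal profiles; defaults to profiles built from
#'   the gene record itself (useful on synthetic data).
#' @param family family label carried into the row.
#' @inheritParams segment_domains
#' @return `domain_annotation` with `motifs` and `family` fields added.
#' @export
annotate_gene <- function(gene, profiles = NULL, family = NA_character_,
                          min_period = 50L) {
  if (inherits(gene, "gene_record")) {
    if (is.null(profiles)) profiles <- profiles_from_genes(gene)
    if (is.na(family)) family <- gene$family
    sequence <- gene$cds
    gene_id <- gene$gene_id
  } else {
    sequence <- gene
    gene_id <- "gene1"
    if (is.null(profiles)) stop("profiles required for a bare sequence")
  }
  ann <- segment_domains(sequence, profiles, gene_id = gene_id,
                         min_period = min_period)
  rtd_aa <- translate_nt(substr(sequence, ann$rtd[1L], ann$rtd[2L]))
  ann$motifs <- scan_motifs(gsub("\\*", "", rtd_aa))
  ann$family <- family
  ann
}

#' Architecture catalogue table
#'
#' One row per gene (family, domain lengths, copy number, flags) plus
#' per-family means across species.
#'
#' @param annotations list of annotated genes ([annotate_gene()]).
#' @param path optional TSV output (gene table; family means are written
#'   to `<path base>_family_means.tsv`).
#' @return list with data.frames `genes` and `family_means`.
#' @export
catalog_table <- function(annotations, path = NULL) {
  ilen <- function(v) if (is.null(v)) NA_integer_ else v[2L] - v[1L] + 1L
  genes <- if (length(annotations)) do.call(rbind, lapply(
    annotations, function(a) data.frame(
      gene_id = a$gene_id,
      family = if (!is.null(a$family)) a$family else NA_character_,
      ntd_len = ilen(a$ntd), unit_len_mean = a$unit_len_mean,
      n_copies = a$n_copies, ctd_len = ilen(a$ctd),
      flags = paste0(ifelse(a$partial["ntd"], "ntd:partial", ""),
                     ifelse(a$partial["ctd"], ";ctd:partial", ""))))) else
    data.frame(gene_id = character(0), family = character(0),
               ntd_len = integer(0), unit_len_mean = numeric(0),
               n_copies = integer(0), ctd_len = integer(0),
               flags = character(0))
  fam <- if (nrow(genes)) {
    ag <- aggregate(genes[c("ntd_len", "unit_len_mean", "n_copies",
                            "ctd_len")],
                    by = list(family = genes$family), FUN = mean,
                    na.rm = TRUE)
    ag
  } else data.frame(family = character(0), ntd_len = numeric(0),
                    unit_len_mean = numeric(0), n_copies = numeric(0),
                    ctd_len = numeric(0))
  if (!is.null(path)) {
    write.table(genes, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(fam, sub("\\.tsv$", "_family_means.tsv", path),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(genes = genes, family_means = fam)
}
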