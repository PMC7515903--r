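## Synthetic spidroin gene models: ground-truth generator for the pipeline.

## Default family architectures. Lengths are nucleotides of the coding
## sequence; CrSp carries the long (>2 kb) N-terminal domain, a 1009 nt
## repeat unit and a 962 nt C-terminal domain with 11 tandem copies;
## AcSp carries the 1124 nt unit; Pflag the short ~200 nt unit. Motif
## vocabularies are amino-acid level and family-specific (poly-A and
## spacer TT/SS for CrSp; GGX/GPGGX-type glycine motifs plus GPSS/QQ for
## the flagelliform-like families).
.FAMILY_DEFAULTS <- list(
  MaSp  = list(ntd = 501, unit = 300,  ctd = 300, n_copies = 10,
               motifs = c("AAAAAA", "GGA", "GGQ")),
  MiSp  = list(ntd = 501, unit = 300,  ctd = 300, n_copies = 12,
               motifs = c("GGA", "GAGA", "GGQ")),
  AcSp  = list(ntd = 501, unit = 1124, ctd = 300, n_copies = 8,
               motifs = c("SSAA", "QQ", "SQSA")),
  CySp  = list(ntd = 501, unit = 600,  ctd = 300, n_copies = 10,
               motifs = c("SSSS", "AASS", "SA")),
  PySp  = list(ntd = 501, unit = 600,  ctd = 300, n_copies = 10,
               motifs = c("QQ", "PP", "QPQ")),
  AgSp  = list(ntd = 501, unit = 600,  ctd = 399, n_copies = 10,
               motifs = c("QQ", "TT", "EE")),
  CrSp  = list(ntd = 2100, unit = 1009, ctd = 962, n_copies = 11,
               motifs = c("AAAAA", "TT", "SS")),
  Pflag = list(ntd = 501, unit = 201,  ctd = 300, n_copies = 12,
               motifs = c("GGA", "GPSS", "QQ", "GPGGA")),
  Flag  = list(ntd = 501, unit = 441,  ctd = 300, n_copies = 15,
               motifs = c("GGA", "GPGGA", "GPGGS"))
)

.FAMILIES <- names(.FAMILY_DEFAULTS)

#' Built-in spidroin family architecture defaults
#' @return data.frame of per-family NTD/unit/CTD lengths (nt), default
#'   copy numbers and motif vocabularies.
#' @export
spidroin_families <- function() {
  data.frame(
    family = .FAMILIES,
    ntd_len = vapply(.FAMILY_DEFAULTS, `[[`, 1, "ntd"),
    unit_len = vapply(.FAMILY_DEFAULTS, `[[`, 1, "unit"),
    ctd_len = vapply(.FAMILY_DEFAULTS, `[[`, 1, "ctd"),
    n_copies = vapply(.FAMILY_DEFAULTS, `[[`, 1, "n_copies"),
    motifs = vapply(.FAMILY_DEFAULTS, function(x)
      paste(x$motifs, collapse = ","), character(1)),
    row.names = NULL
  )
}

## Amino-acid template for a repeat unit: motif vocabulary interleaved
## with short filler stretches, long enough to cover len_aa residues.
.unit_aa_template <- function(len_aa, motifs, motif_density = 0.5) {
  parts <- character(0)
  total <- 0L
  while (total < len_aa) {
    if (length(motifs) && runif(1) < motif_density) {
      m <- motifs[[sample.int(length(motifs), 1L)]]
    } else {
      m <- random_aa(sample(3:8, 1L))
    }
    parts <- c(parts, m)
    total <- total + nchar(m)
  }
  substr(c2s(parts), 1L, len_aa)
}

.check_motifs <- function(motifs) {
  bad <- motifs[grepl("[^A-Z]", motifs) |
                  grepl("[CMWY*]", motifs)]
  if (length(bad))
    stop("motifs containing residues with stop-encoding codon contexts ",
         "(C/M/W/Y) are not allowed: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Construct a spidroin gene model
#'
#' A gene model is the generative description of one intronless spidroin
#' gene: concrete NTD/CTD nucleotide sequences, a repeat-unit sequence, a
#' copy number and a per-copy substitution rate. The coding sequence
#' implied by a model is `ntd_nt + n_copies mutated copies of
#' repeat_unit_nt + ctd_nt`. Sequences are built from stop-safe codons so
#' the reading frame stays open for any unit length, including lengths
#' that are not multiples of three.
#'
#' @param family family label, one of MaSp, MiSp, AcSp, CySp, PySp, CrSp,
#'   Pflag, Flag, AgSp.
#' @param ntd_len,unit_len,ctd_len domain lengths in nucleotides; default
#'   from the per-family architecture table ([spidroin_families()]).
#' @param n_copies number of tandem repeat copies (>= 2).
#' @param per_copy_divergence substitution rate in `[0, 0.1]` applied
#'   independently to each repeat copy.
#' @param motifs amino-acid motif vocabulary seeded into the repeat unit.
#' @param seed RNG seed for sequence construction.
#' @return object of class `spidroin_gene_model`.
#' @export
spidroin_gene_model <- function(family = "CrSp",
                                ntd_len = NULL, unit_len = NULL,
                                ctd_len = NULL, n_copies = NULL,
                                per_copy_divergence = 0.01,
                                motifs = NULL, seed = NULL) {
  family <- match.arg(family, .FAMILIES)
  def <- .FAMILY_DEFAULTS[[family]]
  ntd_len <- if (is.null(ntd_len)) def$ntd else as.integer(ntd_len)
  unit_len <- if (is.null(unit_len)) def$unit else as.integer(unit_len)
  ctd_len <- if (is.null(ctd_len)) def$ctd else as.integer(ctd_len)
  n_copies <- if (is.null(n_copies)) def$n_copies else as.integer(n_copies)
  motifs <- if (is.null(motifs)) def$motifs else motifs
  if (n_copies < 2L)
    stop("n_copies must be >= 2: repeat detection is undefined below that")
  if (per_copy_divergence < 0 || per_copy_divergence > 0.1)
    stop("per_copy_divergence must lie in [0, 0.1]")
  if (ntd_len < 30L || unit_len < 9L || ctd_len < 9L)
    stop("domain lengths too short to be meaningful")
  .check_motifs(motifs)
  with_seed(seed, {
    ## NTD: fixed start ATG + Arg(CGC), then a hydrophobic signal-peptide
    ## stretch and filler. The CGC pins CDS base 4 away from A so the
    ## start codon cannot seed a TGA in a shifted frame.
    n_rest <- ntd_len - 6L
    sp <- "FLLALVALLA"
    ntd_aa_rest <- paste0(sp, random_aa(ceiling(n_rest / 3) + 2L -
                                          nchar(sp)))
    ntd_nt <- paste0("ATGCGC", safe_nt_segment(ntd_aa_rest, n_rest))
    unit_aa <- .unit_aa_template(ceiling(unit_len / 3) + 2L, motifs)
    unit_nt <- safe_nt_segment(unit_aa, unit_len)
    ctd_nt <- safe_nt_segment(random_aa(ceiling(ctd_len / 3) + 2L), ctd_len)
    structure(list(
      family_label = family,
      ntd_nt = ntd_nt, ctd_nt = ctd_nt, repeat_unit_nt = unit_nt,
      n_copies = n_copies, per_copy_divergence = per_copy_divergence,
      motif_vocabulary = motifs
    ), class = "spidroin_gene_model")
  })
}

#' @export
print.spidroin_gene_model <- function(x, ...) {
  cat(sprintf("spidroin gene model [%s]: NTD %d nt + %d x %d nt + CTD %d nt (div %.3f)\n",
              x$family_label, nchar(x$ntd_nt), x$n_copies,
              nchar(x$repeat_unit_nt), nchar(x$ctd_nt),
              x$per_copy_divergence))
  invisible(x)
}

#' Realise a gene model into a coding sequence with ground truth
#'
#' Assembles `NTD + n_copies mutated unit copies + CTD`, applies the
#' per-copy substitution divergence, and returns the CDS together with a
#' truth table of domain boundaries (0-based, half-open) used by the
#' recovery tests. The translated frame is verified to be open.
#'
#' @param model a [spidroin_gene_model()].
#' @param seed RNG seed controlling the per-copy mutations.
#' @param gene_id identifier; default `<family>_g1`.
#' @return object of class `gene_record`: list with `cds`, `protein`,
#'   `copies`, `truth` (data.frame gene_id/domain/start/end/n_copies) and
#'   the model fields.
#' @export
generate_gene <- function(model, seed = NULL,
                          gene_id = paste0(model$family_label, "_g1")) {
  stopifnot(inherits(model, "spidroin_gene_model"))
  if (model$n_copies < 2L) stop("n_copies must be >= 2")
  with_seed(seed, {
    copies <- vapply(seq_len(model$n_copies), function(i)
      mutate_stopfree(model$repeat_unit_nt,
                      model$per_copy_divergence)$seq, character(1))
    cds <- paste0(model$ntd_nt, paste(copies, collapse = ""), model$ctd_nt)
    nl <- nchar(model$ntd_nt)
    rl <- nchar(model$repeat_unit_nt) * model$n_copies
    cl <- nchar(model$ctd_nt)
    truth <- data.frame(
      gene_id = gene_id,
      domain = c("NTD", "RTD", "CTD"),
      start = c(0L, nl, nl + rl),
      end = c(nl, nl + rl, nl + rl + cl),
      n_copies = model$n_copies
    )
    prot <- translate_nt(cds)
    if (grepl("\\*", substr(prot, 1L, nchar(prot) - 1L)))
      stop("internal error: stop codon inside generated CDS")
    structure(list(
      gene_id = gene_id, family = model$family_label,
      cds = cds, protein = prot,
      ntd_nt = model$ntd_nt, ctd_nt = model$ctd_nt,
      repeat_unit_nt = model$repeat_unit_nt, copies = copies,
      n_copies = model$n_copies, truth = truth
    ), class = "gene_record")
  })
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("gene_record %s [%s]: CDS %d nt, %d copies of %d nt unit\n",
              x$gene_id, x$family, nchar(x$cds), x$n_copies,
              nchar(x$repeat_unit_nt)))
  invisible(x)
}

#' Prepend/append untranslated regions to a gene CDS
#'
#' Useful to exercise start-codon selection: the default 5' UTR ends in a
#' favourable Kozak context (purine at -3).
#' @param gene a `gene_record` or a CDS string.
#' @param utr5,utr3 untranslated flanks.
#' @return cDNA string.
#' @export
make_cdna <- function(gene, utr5 = "GGCAGCCACC", utr3 = "GCACCAGCAC") {
  cds <- if (inherits(gene, "gene_record")) gene$cds else gene
  paste0(utr5, cds, utr3)
}

#' Generate a multi-species set of orthologous gene models
#'
#' Emulates species-level divergence within each spidroin family: each
#' species' model is the family base model with substitutions applied
#' independently to NTD, unit and CTD at the given rate.
#'
#' @param families character vector of family labels (default all nine).
#' @param n_species number of species.
#' @param divergence per-site substitution rate between the family base
#'   and each species.
#' @param seed RNG seed.
#' @param ... passed to [spidroin_gene_model()] (e.g. `per_copy_divergence`).
#' @return nested list `genes[[family]][[species]]` of `gene_record`s.
#' @export
make_species_set <- function(families = .FAMILIES, n_species = 6,
                             divergence = 0.05, seed = 1, ...) {
  with_seed(seed, {
    out <- lapply(families, function(fam) {
      base <- spidroin_gene_model(fam, ...)
      sp <- lapply(seq_len(n_species), function(i) {
        m <- base
        m$ntd_nt <- mutate_stopfree(base$ntd_nt, divergence, protect = 6L)$seq
        m$repeat_unit_nt <- mutate_stopfree(base$repeat_unit_nt, divergence)$seq
        m$ctd_nt <- mutate_stopfree(base$ctd_nt, divergence)$seq
        generate_gene(m, gene_id = sprintf("%s_sp%02d", fam, i))
      })
      names(sp) <- sprintf("sp%02d", seq_len(n_species))
      sp
    })
    names(out) <- families
    out
  })
}

#' Write domain truth tables as TSV
#'
#' Columns `gene_id, domain, start, end, n_copies`; coordinates 0-based,
#' half-open.
#' @param genes list of `gene_record`s.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(genes, path) {
  tt <- do.call(rbind, lapply(genes, `[[`, "truth"))
  write.table(tt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Simple amino-acid substitution process over the 20-letter alphabet
## (used for terminal-domain phylogeny simulations; no codon constraints).
.AA20 <- s2c("ACDEFGHIKLMNPQRSTVWY")
aa_mutate <- function(aa, rate) {
  x <- s2c(aa)
  k <- rbinom(1L, length(x), rate)
  if (k > 0L) {
    pos <- sample.int(length(x), k)
    x[pos] <- vapply(x[pos], function(a)
      sample(setdiff(.AA20, a), 1L), character(1))
  }
  c2s(x)
}

#' Simulate terminal-domain sequences for a family phylogeny
#'
#' Generates amino-acid terminal domains for `n_families` families and
#' `n_species` species per family: a random root sequence diverges into
#' family ancestors (rate `between`) and each ancestor into species
#' sequences (rate `within`). With `between` well above `within`, family
#' members form clearly supported clades.
#'
#' @param n_families,n_species dataset shape.
#' @param len residues per sequence (90 for N-terminal sets, 80 for
#'   C-terminal sets).
#' @param within,between per-site substitution rates.
#' @param end "N" or "C", recorded in the output labels.
#' @param seed RNG seed.
#' @return data.frame (taxon, family, end, sequence).
#' @export
simulate_terminal_domains <- function(n_families = 9, n_species = 6,
                                      len = 90, within = 0.02,
                                      between = 0.3, end = "N", seed = 1) {
  with_seed(seed, {
    fams <- if (n_families <= length(.FAMILIES))
      .FAMILIES[seq_len(n_families)]
    else paste0("fam", seq_len(n_families))
    root <- c2s(sample(.AA20, len, replace = TRUE))
    rows <- lapply(fams, function(fam) {
      anc <- aa_mutate(root, between)
      data.frame(
        taxon = sprintf("%s_sp%02d", fam, seq_len(n_species)),
        family = fam, end = end,
        sequence = vapply(seq_len(n_species), function(i)
          aa_mutate(anc, within), character(1))
      )
    })
    do.call(rbind, rows)
  })
}
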