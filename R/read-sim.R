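## Read simulators: 150 bp paired-end short reads with substitution
## errors, and long noisy reads with an indel-biased i.i.d. edit process.
## Every simulator writes an exact error log so audits of the error model
## are deterministic, not statistical.

#' Read-simulation configuration
#'
#' @param short_read_len short read length (nt).
#' @param insert_mean,insert_sd fragment (insert) size distribution.
#' @param short_error_rate per-base substitution probability for short
#'   reads (substitution-only error model).
#' @param long_len_mean,long_len_sd length distribution of non-spanning
#'   long reads.
#' @param long_error_rate combined per-base error rate for long reads.
#' @param indel_bias fraction of long-read errors that are indels
#'   (default 0.8, i.e. indel:substitution = 4:1; insertions and
#'   deletions equally likely).
#' @param span_fraction fraction of long reads forced to span their full
#'   reference, as required for repeat iteration counting.
#' @param coverage_short,coverage_long requested fold coverage.
#' @param rng_seed integer seed; identical seed + config gives
#'   byte-identical output.
#' @return object of class `read_sim_config`.
#' @export
read_sim_config <- function(short_read_len = 150L,
                            insert_mean = 400, insert_sd = 40,
                            short_error_rate = 0.001,
                            long_len_mean = 12000, long_len_sd = 3000,
                            long_error_rate = 0.10,
                            indel_bias = 0.8,
                            span_fraction = 0.5,
                            coverage_short = 30, coverage_long = 20,
                            rng_seed = 1L) {
  structure(list(
    short_read_len = as.integer(short_read_len),
    insert_mean = insert_mean, insert_sd = insert_sd,
    short_error_rate = short_error_rate,
    long_len_mean = long_len_mean, long_len_sd = long_len_sd,
    long_error_rate = long_error_rate, indel_bias = indel_bias,
    span_fraction = span_fraction,
    coverage_short = coverage_short, coverage_long = coverage_long,
    rng_seed = as.integer(rng_seed)
  ), class = "read_sim_config")
}

## substitute bases at `pos` in char vector x with uniformly drawn
## different bases; returns list(x, to)
.substitute_bases <- function(x, pos) {
  to <- vapply(x[pos], function(b)
    sample(setdiff(.BASES, b), 1L), character(1), USE.NAMES = FALSE)
  x[pos] <- to
  list(x = x, to = to)
}

#' Simulate paired-end short reads
#'
#' Fragments are drawn uniformly from either strand of each reference
#' with normally distributed insert sizes; mates are read inward from the
#' fragment ends (FR orientation). Errors are substitutions only. Read
#' names encode mate pairing as `<ref>_p<i>/1` and `/2`.
#'
#' @param refs named character vector of reference sequences.
#' @param cfg a [read_sim_config()].
#' @param prefix optional file prefix; when given, writes
#'   `<prefix>_R1.fastq`, `<prefix>_R2.fastq` and `<prefix>_errors.tsv`.
#' @return list with `r1`, `r2` (named character vectors), `log`
#'   (data.frame read/pos/from/to) and, when written, the file paths.
#' @export
simulate_short_reads <- function(refs, cfg = read_sim_config(),
                                 prefix = NULL) {
  if (length(refs) == 0L) stop("no reference sequences supplied")
  if (is.null(names(refs))) names(refs) <- paste0("ref", seq_along(refs))
  rl <- cfg$short_read_len
  with_seed(cfg$rng_seed, {
    r1 <- r2 <- character(0)
    log <- list()
    for (rn in names(refs)) {
      ref <- refs[[rn]]
      len <- nchar(ref)
      if (len < cfg$insert_mean) {
        warning("reference ", rn, " shorter than mean insert; skipped")
        next
      }
      rc <- revcomp(ref)
      n_pairs <- max(1L, round(cfg$coverage_short * len / (2 * rl)))
      ins <- pmin(pmax(round(rnorm(n_pairs, cfg$insert_mean,
                                   cfg$insert_sd)), rl), len)
      start <- vapply(ins, function(i)
        sample.int(len - i + 1L, 1L), integer(1))
      strand <- sample(c("+", "-"), n_pairs, replace = TRUE)
      st <- ifelse(strand == "+", start, len - (start + ins - 1L) + 1L)
      frag <- ifelse(strand == "+",
                     substring(ref, st, st + ins - 1L),
                     substring(rc, st, st + ins - 1L))
      a <- substring(frag, 1L, rl)
      b <- revcomp(substring(frag, ins - rl + 1L, ins))
      nm <- sprintf("%s_p%06d", rn, seq_len(n_pairs))
      reads <- setNames(c(a, b),
                        c(paste0(nm, "/1"), paste0(nm, "/2")))
      if (cfg$short_error_rate > 0) {
        nerr <- rbinom(length(reads), nchar(reads),
                       cfg$short_error_rate)
        for (i in which(nerr > 0L)) {
          x <- s2c(reads[[i]])
          pos <- sort(sample.int(length(x), nerr[i]))
          from <- x[pos]
          sub <- .substitute_bases(x, pos)
          log[[length(log) + 1L]] <- data.frame(
            read = names(reads)[i], pos = pos, from = from,
            to = sub$to)
          reads[[i]] <- c2s(sub$x)
        }
      }
      r1 <- c(r1, reads[seq_len(n_pairs)])
      r2 <- c(r2, reads[n_pairs + seq_len(n_pairs)])
    }
    log <- if (length(log)) do.call(rbind, log) else
      data.frame(read = character(0), pos = integer(0),
                 from = character(0), to = character(0))
    out <- list(r1 = r1, r2 = r2, log = log)
    if (!is.null(prefix)) {
      out$r1_path <- write_fastq(r1, paste0(prefix, "_R1.fastq"))
      out$r2_path <- write_fastq(r2, paste0(prefix, "_R2.fastq"))
      out$log_path <- paste0(prefix, "_errors.tsv")
      write.table(log, out$log_path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    out
  })
}

## apply the long-read edit process to one sequence; returns
## list(seq, log rows)
.long_edit <- function(sq, name, rate, indel_bias) {
  if (rate <= 0) return(list(seq = sq, log = NULL))
  x <- s2c(sq)
  k <- rbinom(1L, length(x), rate)
  if (k == 0L) return(list(seq = sq, log = NULL))
  pos <- sort(sample.int(length(x), k))
  type <- ifelse(runif(k) < indel_bias,
                 ifelse(runif(k) < 0.5, "ins", "del"), "sub")
  from <- x[pos]
  to <- character(k)
  ## substitutions in place (vectorized)
  is_sub <- type == "sub"
  if (any(is_sub)) {
    s <- .substitute_bases(x, pos[is_sub])
    x <- s$x
    to[is_sub] <- s$to
  }
  to[type == "del"] <- "-"
  n_ins <- sum(type == "ins")
  if (n_ins) to[type == "ins"] <- sample(.BASES, n_ins, replace = TRUE)
  ## deletions and insertions in one indexed rebuild: insertions are
  ## placed just before their reference position
  keep <- setdiff(seq_along(x), pos[type == "del"])
  vals <- c(x[keep], to[type == "ins"])
  ord <- order(c(keep, pos[type == "ins"] - 0.5))
  list(seq = c2s(vals[ord]),
       log = data.frame(read = name, pos = pos, type = type,
                        from = from, to = to))
}

#' Simulate long noisy reads
#'
#' A configurable fraction of reads spans its full reference (needed for
#' repeat iteration counting); the remainder follow the configured length
#' distribution. Errors are an i.i.d. edit process, indel-biased
#' (default 4:1 indel:substitution).
#'
#' @inheritParams simulate_short_reads
#' @return list with `reads` (named character vector), `log`
#'   (read/pos/type/from/to, reference coordinates) and optional paths.
#' @export
simulate_long_reads <- function(refs, cfg = read_sim_config(),
                                prefix = NULL) {
  if (length(refs) == 0L) stop("no reference sequences supplied")
  if (is.null(names(refs))) names(refs) <- paste0("ref", seq_along(refs))
  with_seed(cfg$rng_seed + 1L, {
    reads <- character(0)
    log <- list()
    for (rn in names(refs)) {
      ref <- refs[[rn]]
      len <- nchar(ref)
      rc <- revcomp(ref)
      n_reads <- max(2L, round(cfg$coverage_long * len /
                                 min(cfg$long_len_mean, len)))
      for (i in seq_len(n_reads)) {
        span <- runif(1) < cfg$span_fraction
        if (span) {
          st <- 1L; rdlen <- len
        } else {
          rdlen <- min(len, max(200L, round(rnorm(1, cfg$long_len_mean,
                                                  cfg$long_len_sd))))
          st <- sample.int(len - rdlen + 1L, 1L)
        }
        strand <- sample(c("+", "-"), 1L)
        src <- if (strand == "+") ref else rc
        st2 <- if (strand == "+") st else len - (st + rdlen - 1L) + 1L
        sq <- substr(src, st2, st2 + rdlen - 1L)
        nm <- sprintf("%s_L%05d_%s%s", rn, i, strand,
                      if (span) "_span" else "")
        ed <- .long_edit(sq, nm, cfg$long_error_rate, cfg$indel_bias)
        reads[[nm]] <- ed$seq
        if (!is.null(ed$log)) log[[length(log) + 1L]] <- ed$log
      }
    }
    log <- if (length(log)) do.call(rbind, log) else
      data.frame(read = character(0), pos = integer(0),
                 type = character(0), from = character(0),
                 to = character(0))
    out <- list(reads = reads, log = log)
    if (!is.null(prefix)) {
      out$path <- write_fastq(reads, paste0(prefix, "_long.fastq"))
      out$log_path <- paste0(prefix, "_long_errors.tsv")
      write.table(log, out$log_path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    out
  })
}

#' Embed a gene in random genomic flanks
#'
#' Read simulation from a bare CDS under-covers the gene termini
#' (fragments must fit inside the reference); genomic DNA reads extend
#' past the gene, so a realistic reference carries flanking sequence.
#' @param gene a `gene_record` or nucleotide string.
#' @param flank flank length on each side (nt).
#' @param seed RNG seed for the random flanks.
#' @return list with `ref` (flanked sequence) and `offset` (0-based
#'   start of the gene within it).
#' @export
flanked_reference <- function(gene, flank = 400L, seed = 1L) {
  cds <- if (inherits(gene, "gene_record")) gene$cds else gene
  with_seed(seed, {
    f5 <- c2s(sample(.BASES, flank, replace = TRUE))
    f3 <- c2s(sample(.BASES, flank, replace = TRUE))
    list(ref = paste0(f5, cds, f3), offset = flank)
  })
}

#' Build contig fixtures mimicking assembler behaviour on repeats
#'
#' De novo assemblers truncate or collapse long tandem arrays; this
#' fixture generator emits the corresponding contig shapes from ground
#' truth genes.
#'
#' @param genes list of `gene_record`s.
#' @param policy `"perfect"` (full CDS), `"repeat_collapse"` (terminals
#'   flanking at most two unit copies) or `"terminal_only"` (NTD and CTD
#'   fragments only).
#' @param path optional FASTA output path.
#' @return named character vector of contigs.
#' @export
make_contig_fixtures <- function(genes,
                                 policy = c("perfect", "repeat_collapse",
                                            "terminal_only"),
                                 path = NULL) {
  policy <- match.arg(policy)
  if (inherits(genes, "gene_record")) genes <- list(genes)
  out <- character(0)
  for (g in genes) {
    switch(policy,
      perfect = {
        out[paste0(g$gene_id, "_full")] <- g$cds
      },
      repeat_collapse = {
        out[paste0(g$gene_id, "_collapsed")] <-
          paste0(g$ntd_nt, strrep(g$repeat_unit_nt, 2L), g$ctd_nt)
      },
      terminal_only = {
        out[paste0(g$gene_id, "_NTD")] <- g$ntd_nt
        out[paste0(g$gene_id, "_CTD")] <- g$ctd_nt
      })
  }
  if (!is.null(path)) write_fasta(out, path)
  out
}
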