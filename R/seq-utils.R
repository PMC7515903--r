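## Low-level sequence helpers shared across modules.

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

## Amino acids usable by the gene generator. C, M, W and Y are excluded
## because none of their codons satisfy the stop-free construction rule
## below; silk repeat and terminal domains are modelled without them.
.GEN_AA <- c("A", "R", "N", "D", "Q", "E", "G", "H", "I", "L",
             "K", "F", "P", "S", "T", "V")

.pkg_env <- new.env(parent = emptyenv())

## Codon tables derived from the standard genetic code.
##  - full: all synonymous codons per amino acid.
##  - safe: codons with no TA/TG dinucleotide and not ending in T. A
##    sequence built only from safe codons contains no TA or TG
##    dinucleotide anywhere, hence no stop triplet in ANY reading frame and
##    across any concatenation or truncation junction. This is what lets
##    the generator build tandem arrays whose unit length is not a multiple
##    of three while keeping the translated frame open end to end.
.codon_tables <- function() {
  if (!is.null(.pkg_env$codons)) return(.pkg_env$codons)
  gc <- Biostrings::GENETIC_CODE
  full <- split(names(gc), unname(gc))
  full[["*"]] <- NULL
  safe <- lapply(full, function(cs) {
    cs[!grepl("TA|TG", cs) & substr(cs, 3, 3) != "T"]
  })
  safe <- safe[vapply(safe, length, 1L) > 0L]
  .pkg_env$codons <- list(full = full, safe = safe)
  .pkg_env$codons
}

## Evaluate expr under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Reverse complement of a nucleotide string
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate a nucleotide sequence (frame 1)
#'
#' Trailing bases that do not fill a codon are dropped.
#' @param nt character vector of DNA sequences.
#' @return character vector of amino-acid sequences.
#' @export
translate_nt <- function(nt) {
  nt <- substr(nt, 1L, (nchar(nt) %/% 3L) * 3L)
  as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAStringSet(nt),
                          if.fuzzy.codon = "X")))
}

## Split a string into a character vector of single characters.
s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]
c2s <- function(x) paste(x, collapse = "")

## Fraction of equal characters between two equal-length strings.
str_identity <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  if (length(ra) == 0L) return(1)
  mean(ra == rb)
}

## Reverse-translate an amino-acid string using only stop-safe codons,
## sampling uniformly among the allowed synonymous codons.
reverse_translate_safe <- function(aa) {
  tab <- .codon_tables()$safe
  res <- s2c(aa)
  bad <- setdiff(unique(res), names(tab))
  if (length(bad))
    stop("residues not representable by stop-safe codons: ",
         paste(bad, collapse = ", "))
  codons <- vapply(res, function(a) {
    cs <- tab[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1))
  c2s(codons)
}

## Random filler amino-acid string over the generator alphabet.
random_aa <- function(n, alphabet = .GEN_AA) {
  c2s(sample(alphabet, n, replace = TRUE))
}

## Build a nucleotide segment of EXACTLY len_nt bases that encodes `aa`
## motifs/filler and contains no TA/TG dinucleotide. When len_nt is not a
## multiple of 3 the tail codon is truncated; the cut must not leave a
## trailing T (which could form TA/TG at a downstream junction), so the
## last codon is resampled if needed.
safe_nt_segment <- function(aa, len_nt) {
  nt <- reverse_translate_safe(aa)
  if (nchar(nt) < len_nt)
    stop("amino-acid template too short for requested length")
  out <- substr(nt, 1L, len_nt)
  if (substr(out, len_nt, len_nt) == "T") {
    ## patch the cut codon with an alanine codon: GC prefixes cannot end
    ## in T, so the truncation stays junction-safe
    ci <- (len_nt - 1L) %/% 3L + 1L  # codon index containing the cut
    repl <- sample(c("GCA", "GCC", "GCG"), 1L)
    substr(nt, (ci - 1L) * 3L + 1L, ci * 3L) <- repl
    out <- substr(nt, 1L, len_nt)
  }
  out
}

## Substitution mutation preserving the no-TA/TG property (so mutated
## genes stay stop-free in every frame). `protect` shields a 5' prefix
## (e.g. the start codon). Returns list(seq, n_subs, positions).
mutate_stopfree <- function(nt, rate, protect = 0L) {
  n <- nchar(nt)
  if (rate <= 0 || n <= protect)
    return(list(seq = nt, n_subs = 0L, positions = integer(0)))
  x <- s2c(nt)
  eligible <- seq.int(protect + 1L, n)
  k <- rbinom(1L, length(eligible), rate)
  if (k == 0L) return(list(seq = nt, n_subs = 0L, positions = integer(0)))
  pos <- sort(sample(eligible, k))
  done <- integer(0)
  for (i in pos) {
    alts <- setdiff(.BASES, x[i])
    ## boundary positions use worst-case neighbours so mutated segments
    ## stay junction-safe when concatenated into tandem arrays
    left <- if (i > 1L) x[i - 1L] else "T"
    right <- if (i < n) x[i + 1L] else "A"
    ok <- !(left == "T" & alts %in% c("A", "G")) &
      !(alts == "T" & right %in% c("A", "G"))
    alts <- alts[ok]
    if (!length(alts)) next
    x[i] <- alts[sample.int(length(alts), 1L)]
    done <- c(done, i)
  }
  list(seq = c2s(x), n_subs = length(done), positions = done)
}

## FASTA / FASTQ I/O -------------------------------------------------------

#' Write named sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ## BStringSet accepts both nucleotide and amino-acid alphabets
  x <- Biostrings::BStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

## FASTQ with a constant Phred+33 quality character (the simulators encode
## truth in a separate error log, not in quality strings).
write_fastq <- function(seqs, path, qual_char = "I") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(seqs))
    writeLines(paste0("@", names(seqs), "\n", seqs, "\n+\n",
                      vapply(nchar(seqs), function(n)
                        strrep(qual_char, n), character(1))), con)
  invisible(path)
}

#' Read FASTQ sequences
#' @param path FASTQ file (Phred+33).
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
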