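## Terminal-domain phylogenetics: trimming, alignment, Poisson-corrected
## distances, neighbor-joining trees, bootstrap support and per-family
## monophyly tests. Distance/NJ is used in place of full maximum
## likelihood: the properties read off these trees (family monophyly)
## are topological and robust to the inference method.

#' Trim proteins to their terminal domains
#'
#' N-terminal sets keep the first 90 residues, C-terminal sets the last
#' 80; sequences shorter than the window are kept whole and flagged.
#'
#' @param proteins named character vector of amino-acid sequences, or a
#'   data.frame with columns `taxon`, `sequence` (and optionally
#'   `family`).
#' @param end `"N"` or `"C"`.
#' @param n_len,c_len window sizes (defaults 90 and 80).
#' @param family optional family labels (recycled against proteins).
#' @return data.frame of class `terminal_domain_set`: taxon, family,
#'   end, sequence, short (logical).
#' @export
trim_terminals <- function(proteins, end = c("N", "C"), n_len = 90L,
                           c_len = 80L, family = NA_character_) {
  end <- match.arg(end)
  if (is.data.frame(proteins)) {
    taxa <- proteins$taxon
    seqs <- proteins$sequence
    if ("family" %in% names(proteins)) family <- proteins$family
  } else {
    taxa <- names(proteins)
    if (is.null(taxa)) taxa <- paste0("t", seq_along(proteins))
    seqs <- unname(proteins)
  }
  if (any(!nchar(seqs))) stop("empty sequence in input")
  w <- if (end == "N") n_len else c_len
  trimmed <- if (end == "N") substr(seqs, 1L, w) else
    substr(seqs, pmax(1L, nchar(seqs) - w + 1L), nchar(seqs))
  out <- data.frame(taxon = taxa,
                    family = rep_len(family, length(taxa)),
                    end = end, sequence = trimmed,
                    short = nchar(seqs) < w)
  class(out) <- c("terminal_domain_set", class(out))
  out
}

#' Align terminal domains (MAFFT)
#'
#' Produces a multiple sequence alignment via the MAFFT executable
#' (`--auto`). Contract: all rows have equal length and removing gaps
#' from any row returns its input. A single sequence is returned
#' unchanged.
#'
#' @param set a `terminal_domain_set` or named character vector.
#' @return named character vector of aligned rows (upper case).
#' @export
align_terminals <- function(set) {
  seqs <- if (is.data.frame(set)) setNames(set$sequence, set$taxon)
          else set
  if (is.null(names(seqs))) names(seqs) <- paste0("t", seq_along(seqs))
  if (length(seqs) <= 1L) return(seqs)
  if (Sys.which("mafft") == "")
    stop("mafft executable not found on PATH")
  tin <- tempfile(fileext = ".fa"); tout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(tin, tout)))
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, tin)
  status <- system2("mafft", c("--auto", "--anysymbol", "--quiet", tin),
                    stdout = tout)
  if (status != 0L) stop("mafft failed with status ", status)
  aln <- Biostrings::readAAStringSet(tout)
  out <- toupper(setNames(as.character(aln), names(aln)))
  out[names(seqs)]
}

## alignment (named char vector) -> character matrix rows=taxa
.msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(unname(msa), "", fixed = TRUE))
  rownames(m) <- names(msa)
  m
}

#' Pairwise distances from a multiple alignment
#'
#' Default model: mismatch proportion p over ungapped column pairs
#' (pairwise deletion), Poisson-corrected as `d = -ln(1 - p)`; values
#' with `p` at or beyond saturation are capped at `max_dist`.
#'
#' @param msa named character vector of aligned rows, or a character
#'   matrix.
#' @param model `"poisson"` or `"raw"` (uncorrected p-distance).
#' @param max_dist saturation cap.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(msa, model = c("poisson", "raw"),
                            max_dist = 5) {
  model <- match.arg(model)
  m <- if (is.matrix(msa)) msa else .msa_matrix(msa)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  gap <- m == "-" | m == "." | m == "X"
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq.int(i + 1L, n)) {
      ok <- !gap[i, ] & !gap[j, ]
      nv <- sum(ok)
      p <- if (nv) sum(m[i, ok] != m[j, ok]) / nv else 1
      d <- if (model == "raw") p else {
        if (p >= 1 - exp(-max_dist)) max_dist else -log(1 - p)
      }
      D[i, j] <- D[j, i] <- min(d, max_dist)
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Canonical neighbor-joining on a distance matrix; on additive
#' distances it recovers the generating topology and branch lengths.
#'
#' @param D symmetric distance matrix with labelled rows.
#' @return object of class `support_tree`: list with `tree` (ape
#'   `phylo`) and `supports` (NULL until bootstrapped).
#' @export
nj_tree <- function(D) {
  tree <- ape::nj(as.dist(D))
  structure(list(tree = tree, supports = NULL, reps = 0L),
            class = "support_tree")
}

#' @export
print.support_tree <- function(x, ...) {
  cat(sprintf("support_tree: %d tips%s\n", length(x$tree$tip.label),
              if (!is.null(x$supports))
                sprintf(", bootstrap supports from %d replicates", x$reps)
              else ""))
  invisible(x)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' distance/NJ tree per replicate, and reports for each internal edge of
#' the original tree the percentage of replicate trees containing the
#' same bipartition. Deterministic under a fixed seed.
#'
#' @param msa named character vector of aligned rows (or matrix).
#' @param reps bootstrap replicates (0 leaves supports unset).
#' @param seed RNG seed.
#' @inheritParams distance_matrix
#' @return `support_tree` with `supports` (per internal node, percent)
#'   stored in `tree$node.label`.
#' @export
bootstrap_tree <- function(msa, reps = 100L, seed = 1L,
                           model = "poisson", max_dist = 5) {
  m <- if (is.matrix(msa)) msa else .msa_matrix(msa)
  base <- nj_tree(distance_matrix(m, model = model,
                                  max_dist = max_dist))
  if (reps <= 0L) return(base)
  L <- ncol(m)
  boots <- with_seed(seed, lapply(seq_len(reps), function(r) {
    cols <- sample.int(L, L, replace = TRUE)
    ape::nj(as.dist(distance_matrix(m[, cols, drop = FALSE],
                                    model = model,
                                    max_dist = max_dist)))
  }))
  cnt <- ape::prop.clades(base$tree, boots, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  supports <- round(100 * cnt / reps)
  tree <- base$tree
  tree$node.label <- as.character(supports)
  structure(list(tree = tree, supports = supports, reps = reps),
            class = "support_tree")
}

## canonical bipartitions (tip-label sets) of an unrooted phylo tree:
## for each internal edge, the side not containing the reference tip.
tree_bipartitions <- function(tree) {
  if (inherits(tree, "support_tree")) tree <- tree$tree
  labs <- tree$tip.label
  pp <- ape::prop.part(tree)
  sides <- lapply(pp, function(ix) labs[ix])
  canon <- lapply(sides, function(s) {
    if (labs[1L] %in% s) sort(setdiff(labs, s)) else sort(s)
  })
  unique(canon[vapply(canon, length, 1L) > 0L])
}

#' Per-family monophyly report
#'
#' A family is monophyletic when some edge bipartition of the tree
#' separates exactly its members from everything else (single-member
#' families are trivially monophyletic).
#'
#' @param tree a `support_tree`, `phylo`, or Newick string.
#' @param labels named character vector: tip label -> family.
#' @return data.frame (family, n, monophyletic).
#' @export
monophyly_report <- function(tree, labels) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (inherits(tree, "support_tree")) tree <- tree$tree
  labs <- tree$tip.label
  if (!all(labs %in% names(labels)))
    stop("labels missing for some tips")
  bips <- tree_bipartitions(tree)
  keys <- vapply(bips, paste, character(1), collapse = "|")
  all_sorted <- sort(labs)
  fams <- split(names(labels)[match(labs, names(labels))],
                unname(labels[labs]))
  rows <- lapply(names(fams), function(f) {
    mem <- sort(fams[[f]])
    mono <- if (length(mem) <= 1L || length(mem) >= length(labs) - 1L)
      TRUE
    else {
      k1 <- paste(mem, collapse = "|")
      k2 <- paste(sort(setdiff(all_sorted, mem)), collapse = "|")
      (k1 %in% keys) || (k2 %in% keys)
    }
    data.frame(family = f, n = length(fams[[f]]), monophyletic = mono)
  })
  do.call(rbind, rows)
}

#' Write a support tree as Newick
#' @param x `support_tree` or `phylo`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_support_tree <- function(x, path) {
  if (inherits(x, "support_tree")) x <- x$tree
  ape::write.tree(x, file = path)
  invisible(path)
}
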