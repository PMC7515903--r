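## Amino-acid composition of repetitive domains: frequency vectors,
## Pearson correlation and average-linkage hierarchical clustering.

#' Amino-acid frequency vector
#'
#' Frequencies over the 20 canonical residues; non-standard characters
#' are excluded from the denominator.
#' @param repeat_domain_aa amino-acid string (non-empty).
#' @return named numeric vector of length 20, summing to 1.
#' @export
aa_frequencies <- function(repeat_domain_aa) {
  if (!nchar(repeat_domain_aa)) stop("empty amino-acid sequence")
  x <- s2c(toupper(repeat_domain_aa))
  x <- x[x %in% .AA20]
  if (!length(x)) stop("no canonical residues in sequence")
  tab <- table(factor(x, levels = .AA20))
  setNames(as.numeric(tab) / length(x), .AA20)
}

#' Build a composition matrix from repetitive-domain sequences
#'
#' @param seqs named character vector of repetitive-domain amino-acid
#'   sequences; names become row labels (conventionally
#'   `<species>_<family>`).
#' @return matrix rows = sequences, columns = 20 residue frequencies.
#' @export
composition_matrix <- function(seqs) {
  m <- t(vapply(seqs, aa_frequencies, numeric(20L)))
  colnames(m) <- .AA20
  m
}

#' Pearson correlation matrix of compositions
#'
#' @param M composition matrix (rows = samples).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(M) {
  r <- cor(t(M))
  diag(r) <- 1
  r
}

#' Hierarchical clustering of repetitive-domain compositions
#'
#' Distance is `1 - Pearson r`, linkage is average (UPGMA) by default;
#' both configurable. The dendrogram is deterministic given the input
#' (ties resolved by `hclust`'s fixed merge order). Flat groups are
#' reported at `cut_height` alongside the full dendrogram.
#'
#' @param M composition matrix (rows = samples) or named character
#'   vector of sequences.
#' @param linkage linkage method for [stats::hclust()].
#' @param cut_height dendrogram cut for flat groups (distance scale,
#'   default 0.5).
#' @return list with `hclust`, `groups` (named integers), `newick`
#'   (dendrogram as a Newick string), `cor` (correlation matrix) and
#'   `dist`.
#' @export
cluster_composition <- function(M, linkage = "average",
                                cut_height = 0.5) {
  if (is.character(M)) M <- composition_matrix(M)
  if (nrow(M) < 2L) {
    return(list(hclust = NULL,
                groups = setNames(1L, rownames(M)),
                newick = paste0("(", rownames(M), ");"),
                cor = matrix(1, 1, 1, dimnames = list(rownames(M),
                                                      rownames(M))),
                dist = NULL))
  }
  r <- correlation_matrix(M)
  d <- as.dist(1 - r)
  hc <- hclust(d, method = linkage)
  groups <- cutree(hc, h = cut_height)
  phy <- ape::as.phylo(hc)
  list(hclust = hc, groups = groups,
       newick = ape::write.tree(phy), cor = r, dist = d)
}

#' Is each label group a clade of the dendrogram?
#'
#' A group forms a clade when all its members merge with each other
#' before any of them merges with a non-member (equivalently, the group
#' is monophyletic in the dendrogram read as a rooted tree).
#'
#' @param hc an `hclust` object (or result of [cluster_composition()]).
#' @param labels named character vector mapping row labels to group
#'   labels.
#' @return named logical vector per group.
#' @export
dendrogram_groups_intact <- function(hc, labels) {
  if (is.list(hc) && !inherits(hc, "hclust")) hc <- hc$hclust
  stopifnot(inherits(hc, "hclust"))
  phy <- ape::as.phylo(hc)
  groups <- split(names(labels), unname(labels))
  vapply(groups, function(members) {
    if (length(members) <= 1L) return(TRUE)
    .is_clade(phy, members)
  }, logical(1))
}

## rooted clade check on a phylo object
.is_clade <- function(phy, members) {
  tips <- match(members, phy$tip.label)
  if (anyNA(tips)) stop("members not in tree")
  anc <- ape::getMRCA(phy, tips)
  clade_tips <- .tips_under(phy, anc)
  setequal(clade_tips, tips)
}

.tips_under <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  kids <- phy$edge[phy$edge[, 1L] == node, 2L]
  unlist(lapply(kids, .tips_under, phy = phy))
}

#' Plot a composition correlation heatmap
#'
#' Thin wrapper around pheatmap when installed; writes to `file` if
#' given.
#' @param cl result of [cluster_composition()].
#' @param file optional PNG path.
#' @return invisibly, the pheatmap object or NULL when pheatmap is
#'   unavailable.
#' @export
plot_composition_heatmap <- function(cl, file = NULL) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    message("pheatmap not installed; skipping heatmap")
    return(invisible(NULL))
  }
  if (!is.null(file)) grDevices::png(file, width = 900, height = 800)
  p <- pheatmap::pheatmap(cl$cor,
                          clustering_distance_rows = cl$dist,
                          clustering_distance_cols = cl$dist,
                          clustering_method = "average")
  if (!is.null(file)) grDevices::dev.off()
  invisible(p)
}
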