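# Strain trees: SNV and gene-content distances, neighbour joining,
# Newick round trips.

#' Normalised Hamming distance between aligned haplotypes
#'
#' Pairwise mismatch fraction over positions where both rows are
#' unambiguous (not in `ambiguous`). Rows must have equal length; a pair
#' with zero comparable positions is an error.
#'
#' @param haplotypes Character matrix (rows = haplotypes, columns = sites)
#'   or a character vector of equal-length strings, named by genome/sample.
#' @param ambiguous Characters treated as missing (default `N`, `-`, `.`).
#' @return A `dist_matrix` (metric `"snv"`).
#' @export
snv_distance_matrix <- function(haplotypes, ambiguous = c("N", "-", ".")) {
  if (is.character(haplotypes) && !is.matrix(haplotypes)) {
    if (length(unique(nchar(haplotypes))) != 1) {
      stop("haplotype strings must have equal length")
    }
    nm <- names(haplotypes) %||% as.character(seq_along(haplotypes))
    haplotypes <- do.call(rbind, strsplit(toupper(haplotypes), ""))
    rownames(haplotypes) <- nm
  }
  stopifnot(is.matrix(haplotypes))
  n <- nrow(haplotypes)
  ok <- !(haplotypes %in% ambiguous)
  dim(ok) <- dim(haplotypes)
  m <- matrix(0, n, n, dimnames = list(rownames(haplotypes),
                                       rownames(haplotypes)))
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      comp <- ok[i, ] & ok[j, ]
      if (!any(comp)) stop("no comparable positions between rows ", i,
                           " and ", j)
      m[i, j] <- m[j, i] <- mean(haplotypes[i, comp] != haplotypes[j, comp])
    }
  }
  new_dist_matrix(m, "snv")
}

#' Jaccard distance on gene content
#'
#' `1 - |intersection| / |union|` of the gene sets of each genome pair,
#' from a binary genes x genomes presence/absence matrix. Jaccard (rather
#' than Hamming) is robust to genome-size differences from incomplete MAGs.
#'
#' @param gpm A [gene_presence_matrix()] or a binary matrix (genes in rows,
#'   genomes in columns).
#' @return A `dist_matrix` (metric `"gene_jaccard"`).
#' @export
gene_content_distance <- function(gpm) {
  m <- if (inherits(gpm, "gene_presence_matrix")) gpm$matrix else gpm
  stopifnot(is.matrix(m), all(m %in% c(0, 1)))
  if (any(colSums(m) == 0)) stop("genome with zero genes")
  storage.mode(m) <- "numeric"
  inter <- crossprod(m)               # |A & B|
  size <- colSums(m)
  uni <- outer(size, size, "+") - inter
  d <- 1 - inter / uni
  dimnames(d) <- list(colnames(m), colnames(m))
  new_dist_matrix(d, "gene_jaccard")
}

#' Neighbour-joining strain tree
#'
#' Builds an unrooted NJ tree ([ape::nj()]) from a distance matrix;
#' negative branch lengths (an NJ artefact on non-additive input) are
#' clamped to zero with the deficit transferred to the adjacent edge, so
#' path lengths are preserved as closely as possible.
#'
#' @param dm A `dist_matrix` with at least 3 leaves.
#' @param annotations Optional data frame with a column matching the leaf
#'   labels (`genome_id` or `sample_id`) plus metadata (infant, group,
#'   probiotic use); stored on the tree for downstream scans.
#' @return An object of class `strain_tree`: an [ape::phylo] tree with an
#'   `annotations` attribute.
#' @export
build_tree <- function(dm, annotations = NULL) {
  stopifnot(inherits(dm, "dist_matrix"))
  if (nrow(dm$matrix) < 3) stop("need at least 3 leaves")
  tr <- ape::nj(stats::as.dist(dm$matrix))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    # transfer the negative length to the sibling edge sharing the child
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sib <- which(tr$edge[, 1] == parent & seq_along(tr$edge[, 1]) != e)
    if (length(sib)) {
      tr$edge.length[sib[1]] <- max(0, tr$edge.length[sib[1]] + deficit)
    }
  }
  as_strain_tree(tr, annotations)
}

#' Attach leaf annotations to a phylo tree
#'
#' @param tree An [ape::phylo] object.
#' @param annotations Optional data frame; the first of `genome_id`,
#'   `sample_id`, `leaf` found is used as the label key.
#' @return A `strain_tree`.
#' @export
as_strain_tree <- function(tree, annotations = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  if (!is.null(annotations)) {
    key <- intersect(c("genome_id", "sample_id", "leaf"), names(annotations))
    if (!length(key)) stop("annotations need a genome_id/sample_id/leaf column")
    key <- key[1]
    if (!all(tree$tip.label %in% annotations[[key]])) {
      stop("every leaf label must appear in the annotation map")
    }
    annotations <- annotations[match(tree$tip.label, annotations[[key]]), ]
    attr(tree, "annotations") <- annotations
  }
  class(tree) <- c("strain_tree", "phylo")
  tree
}

#' Read / write Newick strain trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that enforce
#' unique leaf labels and return `strain_tree` objects. The round trip
#' preserves topology, labels, and branch lengths (to float precision).
#'
#' @param path File path (for `read_newick`) or output path.
#' @param tree A `strain_tree` or `phylo` object.
#' @param annotations Optional annotation data frame attached on read.
#' @return `read_newick` returns a `strain_tree`; `write_newick` the path,
#'   invisibly.
#' @export
read_newick <- function(path, annotations = NULL) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("malformed Newick in ", path)
  as_strain_tree(tr, annotations)
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
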