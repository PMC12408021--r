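# Phylogenetic clade disease-enrichment scan, infant-oriented clade
# flagging, clade-unique gene extraction, and generic term enrichment.

# tip index sets below every node (internal nodes included), via one
# post-order pass over the edge matrix
node_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  sets <- vector("list", n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(ord))) {
    parent <- ord[e, 1]; child <- ord[e, 2]
    sets[[parent]] <- c(sets[[parent]], sets[[child]])
  }
  sets
}

#' Scan every clade of a strain tree for case/control enrichment
#'
#' For each internal node with at least `min_leaves` leaves, tests the
#' case/control split of its leaves against the expected case fraction
#' with a 1-df chi-square goodness-of-fit test (no continuity correction):
#' `X2 = (n_case - E)^2/E + (n_control - (n-E))^2/(n-E)` with
#' `E = n * expected_case_fraction`. Whether a clade is *infant-oriented*
#' (all leaves from one infant) is recorded for every node regardless of
#' size. No multiple-testing correction is applied by default (the
#' per-node p < 0.05 convention); set `adjust = TRUE` for BH q-values
#' across tested nodes.
#'
#' @param tree A `strain_tree` (or `phylo`) whose leaves are all present in
#'   `labels`.
#' @param labels Data frame with columns `leaf` (or `genome_id` /
#'   `sample_id`), `infant_id`, `group` ("case"/"control"). Defaults to the
#'   tree's attached annotations.
#' @param expected_case_fraction Expected case share under no enrichment.
#'   `NULL` (default) uses the observed leaf-set fraction; pass `0.5` to
#'   force the even-split null appropriate for balanced case-control
#'   selections.
#' @param min_leaves Smallest clade size tested (>= 2).
#' @param adjust Add BH q-values across tested nodes.
#' @param maximal Keep only significant nodes whose parent is not
#'   significant (de-duplicates nested signals).
#' @param alpha Significance threshold used for the `significant` flag and
#'   the `maximal` filter.
#' @return Data frame of class `clade_scan`, one row per tested node,
#'   sorted by p then node id: node, n_leaves, n_case, n_control,
#'   expected_case_fraction, chisq, p_value, infant_oriented, n_infants,
#'   significant (and q_value if `adjust`). Leaf index sets are attached as
#'   attribute `"tip_sets"` keyed by node id.
#' @export
scan_tree <- function(tree, labels = NULL, expected_case_fraction = NULL,
                      min_leaves = 6, adjust = FALSE, maximal = FALSE,
                      alpha = 0.05) {
  stopifnot(inherits(tree, "phylo"))
  if (min_leaves < 2) stop("min_leaves must be >= 2")
  if (is.null(labels)) labels <- attr(tree, "annotations")
  if (is.null(labels)) stop("no leaf labels supplied or attached")
  key <- intersect(c("leaf", "genome_id", "sample_id"), names(labels))[1]
  if (is.na(key)) stop("labels need a leaf/genome_id/sample_id column")
  stopifnot(all(c("infant_id", "group") %in% names(labels)))
  idx <- match(tree$tip.label, labels[[key]])
  if (any(is.na(idx))) stop("unlabelled leaf: ",
                            tree$tip.label[which(is.na(idx))[1]])
  grp <- labels$group[idx]
  infant <- as.character(labels$infant_id[idx])
  stopifnot(all(grp %in% c("case", "control")))
  n_tip <- length(tree$tip.label)
  if (is.null(expected_case_fraction)) {
    expected_case_fraction <- mean(grp == "case")
  }
  if (expected_case_fraction <= 0 || expected_case_fraction >= 1) {
    stop("expected case fraction must lie in (0, 1)")
  }
  sets <- node_tip_sets(tree)
  internal <- (n_tip + 1L):(n_tip + tree$Nnode)
  rows <- lapply(internal, function(nd) {
    tips <- sets[[nd]]
    n <- length(tips)
    nc <- sum(grp[tips] == "case")
    e <- n * expected_case_fraction
    chisq <- (nc - e)^2 / e + ((n - nc) - (n - e))^2 / (n - e)
    data.frame(node = nd, n_leaves = n, n_case = nc, n_control = n - nc,
               expected_case_fraction = expected_case_fraction,
               chisq = chisq,
               p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
               infant_oriented = length(unique(infant[tips])) == 1L,
               n_infants = length(unique(infant[tips])))
  })
  out <- do.call(rbind, rows)
  tested <- out$n_leaves >= min_leaves
  out$chisq[!tested] <- NA_real_
  out$p_value[!tested] <- NA_real_
  if (adjust) {
    out$q_value <- NA_real_
    out$q_value[tested] <- bh_adjust(out$p_value[tested])
  }
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  if (maximal) {
    parent <- integer(nrow(out))
    pmatch_ <- tree$edge
    parent_of <- stats::setNames(pmatch_[, 1], pmatch_[, 2])
    keep <- vapply(seq_len(nrow(out)), function(i) {
      if (!out$significant[i]) return(FALSE)
      p <- parent_of[as.character(out$node[i])]
      if (is.na(p)) return(TRUE)  # root
      !isTRUE(out$significant[match(p, out$node)])
    }, TRUE)
    out <- out[keep, , drop = FALSE]
  }
  ord <- order(out$p_value, out$node, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tip_sets") <- stats::setNames(
    lapply(internal, function(nd) tree$tip.label[sets[[nd]]]), internal)
  class(out) <- c("clade_scan", "data.frame")
  out
}

#' Is a clade infant-oriented?
#'
#' TRUE iff every leaf below `node` derives from a single infant. A
#' single-leaf node is infant-oriented by definition.
#'
#' @param tree A `strain_tree` / `phylo`.
#' @param node Node number (tip or internal, ape numbering).
#' @param labels Leaf annotation data frame (see [scan_tree()]); defaults
#'   to the tree's attached annotations.
#' @return Logical.
#' @export
infant_oriented <- function(tree, node, labels = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(labels)) labels <- attr(tree, "annotations")
  key <- intersect(c("leaf", "genome_id", "sample_id"), names(labels))[1]
  sets <- node_tip_sets(tree)
  tips <- tree$tip.label[sets[[node]]]
  infants <- labels$infant_id[match(tips, labels[[key]])]
  length(unique(infants)) == 1L
}

#' Genes unique to a clade
#'
#' From a binary gene presence/absence matrix, returns the genes present
#' in at least `in_min` of the clade's genomes and at most `out_max` of
#' the remaining genomes. The tolerance (rather than strict 100%/0%)
#' absorbs MAG incompleteness and contamination.
#'
#' @param gpm A [gene_presence_matrix()] or binary genes x genomes matrix.
#' @param clade_genomes Character vector of genome ids forming the clade;
#'   must be a proper, non-empty subset of the matrix columns.
#' @param in_min,out_max Presence-fraction thresholds.
#' @return List of class `unique_gene_set`: `genes`, `in_fraction`,
#'   `out_fraction` (named by gene), `clade_genomes`.
#' @export
clade_unique_genes <- function(gpm, clade_genomes, in_min = 0.95,
                               out_max = 0.05) {
  m <- if (inherits(gpm, "gene_presence_matrix")) gpm$matrix else gpm
  stopifnot(is.matrix(m), all(m %in% c(0, 1)))
  clade_genomes <- as.character(clade_genomes)
  if (!all(clade_genomes %in% colnames(m))) stop("unknown clade genome")
  out_genomes <- setdiff(colnames(m), clade_genomes)
  if (length(clade_genomes) == 0) stop("empty clade")
  if (length(out_genomes) == 0) stop("clade spans all genomes")
  in_frac <- rowMeans(m[, clade_genomes, drop = FALSE])
  out_frac <- rowMeans(m[, out_genomes, drop = FALSE])
  sel <- in_frac >= in_min & out_frac <= out_max
  structure(list(genes = rownames(m)[sel],
                 in_fraction = in_frac[sel],
                 out_fraction = out_frac[sel],
                 clade_genomes = clade_genomes),
            class = "unique_gene_set")
}

#' @export
print.unique_gene_set <- function(x, ...) {
  cat(sprintf("<unique_gene_set> %d genes unique to a %d-genome clade\n",
              length(x$genes), length(x$clade_genomes)))
  invisible(x)
}

#' Term over-representation test for a gene set
#'
#' One-sided hypergeometric (Fisher) over-representation test of the query
#' gene set against each term of a user-supplied gene-to-term annotation,
#' with BH correction across terms. Terms with zero query overlap get
#' p = 1 under the one-sided convention.
#'
#' @param genes Character vector of query gene ids, or a
#'   `unique_gene_set`.
#' @param annotation Data frame with columns `gene`, `term` (one row per
#'   gene-term link), or a named list term -> gene vector.
#' @param background Character vector: the gene universe. Defaults to all
#'   annotated genes.
#' @return Data frame sorted by p: term, n_term, n_query, overlap,
#'   p_value, q_value.
#' @export
term_enrichment <- function(genes, annotation, background = NULL) {
  if (inherits(genes, "unique_gene_set")) genes <- genes$genes
  if (is.data.frame(annotation)) {
    stopifnot(all(c("gene", "term") %in% names(annotation)))
    ann <- split(as.character(annotation$gene), annotation$term)
  } else {
    ann <- lapply(annotation, as.character)
  }
  if (is.null(background)) background <- unique(unlist(ann))
  background <- unique(as.character(background))
  if (!length(background)) stop("empty background")
  genes <- intersect(unique(as.character(genes)), background)
  if (!length(genes)) stop("annotation/background cover no query gene")
  n_bg <- length(background)
  n_q <- length(genes)
  rows <- lapply(names(ann), function(tm) {
    term_genes <- intersect(ann[[tm]], background)
    k <- length(intersect(term_genes, genes))
    m <- length(term_genes)
    # P(X >= k), X ~ Hypergeom(m term genes, n_bg - m others, n_q draws)
    p <- stats::phyper(k - 1, m, n_bg - m, n_q, lower.tail = FALSE)
    data.frame(term = tm, n_term = m, n_query = n_q, overlap = k,
               p_value = p)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$term), ]
  rownames(out) <- NULL
  out
}
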