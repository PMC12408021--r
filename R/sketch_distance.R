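# MinHash genome sketches, Mash-formula distances, and the stratified
# related/unrelated x case/control comparison of within-species MAG
# distances.

#' MinHash sketch of a genome
#'
#' Bottom-`s` MinHash signature over canonical k-mers (lexicographic
#' minimum of a k-mer and its reverse complement). Hashing uses a fixed
#' 64-bit mixing function (splitmix64) truncated to 53 bits so sketches are
#' deterministic across platforms and exactly representable in R doubles;
#' k-mers containing ambiguous bases are skipped. Defaults follow the usual
#' genome-sketching parameters k = 21, s = 1000.
#'
#' @param sequences Character vector of DNA sequences (contigs of one
#'   genome), or a single path to an uncompressed FASTA file.
#' @param k K-mer length (1-32).
#' @param s Sketch size (number of retained minimum hashes).
#' @param genome_id Identifier stored in the sketch.
#' @return Object of class `minhash_sketch`: list with `hashes` (ascending),
#'   `k`, `s`, `genome_id`.
#' @export
sketch <- function(sequences, k = 21, s = 1000, genome_id = "genome") {
  if (length(sequences) == 1 && nchar(sequences) < 500 &&
      file.exists(sequences)) {
    sequences <- read_fasta(sequences)
  }
  sequences <- as.character(sequences)
  if (all(nchar(sequences) < k)) stop("all sequences shorter than k")
  h <- .sketch_hashes(sequences, as.integer(k), as.integer(s))
  if (length(h) == 0) stop("no valid k-mers (ambiguous bases only?)")
  structure(list(hashes = h, k = as.integer(k), s = as.integer(s),
                 genome_id = genome_id),
            class = "minhash_sketch")
}

#' @export
print.minhash_sketch <- function(x, ...) {
  cat(sprintf("<minhash_sketch> %s: k=%d, s=%d, %d hashes\n",
              x$genome_id, x$k, x$s, length(x$hashes)))
  invisible(x)
}

#' Mash distance between two sketches
#'
#' Estimates the k-mer Jaccard index `j` from the `s` smallest hashes of
#' the union of the two sketches (the Mash estimator), then converts it to
#' a mutation-rate distance `d = -(1/k) log(2j / (1 + j))`. Sketches with
#' no shared hashes saturate at `d = 1`.
#'
#' @param a,b `minhash_sketch` objects with equal `k`.
#' @return Single distance value.
#' @export
mash_distance <- function(a, b) {
  stopifnot(inherits(a, "minhash_sketch"), inherits(b, "minhash_sketch"))
  if (a$k != b$k) stop("sketches have mismatched k")
  j <- sketch_jaccard(a, b)
  if (j == 0) return(1)
  -(1 / a$k) * log(2 * j / (1 + j))
}

#' MinHash Jaccard estimate between two sketches
#'
#' Shared-hash fraction among the `s` smallest distinct hashes of the union
#' of the two sketches.
#'
#' @param a,b `minhash_sketch` objects with equal `k`.
#' @return Jaccard estimate in `[0, 1]`.
#' @export
sketch_jaccard <- function(a, b) {
  stopifnot(inherits(a, "minhash_sketch"), inherits(b, "minhash_sketch"))
  if (a$k != b$k) stop("sketches have mismatched k")
  s <- min(a$s, b$s)
  u <- sort(unique(c(a$hashes, b$hashes)))
  u <- u[seq_len(min(s, length(u)))]
  shared <- sum(u %in% a$hashes & u %in% b$hashes)
  shared / length(u)
}

#' Pairwise Mash distance matrix
#'
#' @param sketches List of `minhash_sketch` objects (named, or names taken
#'   from `genome_id`).
#' @return A `dist_matrix` (metric `"mash"`).
#' @export
mash_distance_matrix <- function(sketches) {
  ids <- names(sketches) %||%
    vapply(sketches, function(x) x$genome_id, "")
  n <- length(sketches)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- mash_distance(sketches[[i]], sketches[[j]])
    }
  }
  new_dist_matrix(m, "mash")
}

#' Stratified comparison of within-species MAG distances
#'
#' For each of the species with the most MAGs (ties broken
#' lexicographically), splits pairwise distances into *related* (the two
#' genomes come from samples of the same infant) and *unrelated* pairs, and
#' tests (i) related vs unrelated and (ii) within the related pairs, case
#' infants vs control infants, both with two-sided Mann-Whitney U tests.
#' Tests whose strata are empty are reported `NA`.
#'
#' @param dm A `dist_matrix` over genomes (e.g. from
#'   [mash_distance_matrix()]).
#' @param genome_map Data frame with columns `genome_id`, `infant_id`,
#'   `group`, `species` covering the matrix ids.
#' @param top_n_species How many species (ranked by MAG count) to test.
#' @return Data frame: species, n_mags, n_related, n_unrelated, medians per
#'   stratum, `p_related_vs_unrelated`, `p_case_vs_control` (within related
#'   pairs).
#' @export
stratified_comparison <- function(dm, genome_map, top_n_species = 20) {
  stopifnot(inherits(dm, "dist_matrix"), is.data.frame(genome_map))
  req <- c("genome_id", "infant_id", "group", "species")
  stopifnot(all(req %in% names(genome_map)))
  ids <- dm$sample_ids
  gm <- genome_map[match(ids, genome_map$genome_id), ]
  if (any(is.na(gm$genome_id))) stop("genome absent from genome_map")
  counts <- sort(table(gm$species), decreasing = TRUE)
  ord <- names(counts)[order(-as.integer(counts), names(counts))]
  species <- utils::head(ord, top_n_species)
  rows <- list()
  for (sp in species) {
    sel <- which(gm$species == sp)
    if (length(sel) < 2) next
    pairs <- utils::combn(sel, 2)
    d <- dm$matrix[cbind(pairs[1, ], pairs[2, ])]
    same_inf <- gm$infant_id[pairs[1, ]] == gm$infant_id[pairs[2, ]]
    related <- d[same_inf]
    unrelated <- d[!same_inf]
    p_ru <- if (length(related) >= 1 && length(unrelated) >= 1) {
      tidy_wilcox_p(related, unrelated)
    } else NA_real_
    rel_grp <- gm$group[pairs[1, ]][same_inf]  # same infant => same group
    rc <- related[rel_grp == "case"]
    rn <- related[rel_grp == "control"]
    p_cc <- if (length(rc) >= 1 && length(rn) >= 1) {
      tidy_wilcox_p(rc, rn)
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      species = sp, n_mags = length(sel),
      n_related = length(related), n_unrelated = length(unrelated),
      median_related = stats::median(related),
      median_unrelated = stats::median(unrelated),
      median_related_case = if (length(rc)) stats::median(rc) else NA_real_,
      median_related_control = if (length(rn)) stats::median(rn) else NA_real_,
      p_related_vs_unrelated = p_ru,
      p_case_vs_control = p_cc)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# two-sided Mann-Whitney U p; completely tied samples carry no evidence of
# a difference, so the NaN that arises from zero rank variance maps to 1
tidy_wilcox_p <- function(a, b) {
  p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
  if (is.nan(p)) 1 else p
}

#' Save / load sketches as JSON
#'
#' Hash values are written as decimal strings (they are 53-bit integers, so
#' the round trip through character is exact).
#'
#' @param sketches List of `minhash_sketch` objects.
#' @param path File path.
#' @return `read_sketches` returns the list of sketches.
#' @export
write_sketches <- function(sketches, path) {
  payload <- lapply(sketches, function(sk) {
    list(genome_id = sk$genome_id, k = sk$k, s = sk$s,
         hashes = sprintf("%.0f", sk$hashes))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sketches
#' @export
read_sketches <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(payload, function(x) {
    structure(list(hashes = as.numeric(unlist(x$hashes)),
                   k = as.integer(x$k), s = as.integer(x$s),
                   genome_id = x$genome_id),
              class = "minhash_sketch")
  })
}

#' Exact k-mer Jaccard between two small genomes
#'
#' Full k-mer-set Jaccard (no sketching); intended as a reference for
#' validating the MinHash estimate on small inputs.
#'
#' @param a,b Character vectors of DNA sequences.
#' @param k K-mer length.
#' @return Exact Jaccard index.
#' @export
kmer_jaccard <- function(a, b, k = 21) {
  .kmer_jaccard_exact(as.character(a), as.character(b), as.integer(k))
}
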