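# Readers/writers for the external formats (taxonomic profiler TSV,
# pangenome CSV, metadata CSV, FASTA, Newick, JSON) and the umbrella
# pipeline driver.

#' Gene presence/absence matrix
#'
#' Binary genes x genomes matrix plus an optional genome -> sample/infant
#' mapping.
#'
#' @param matrix Binary numeric matrix, genes in rows, genomes in columns,
#'   both dimnames set.
#' @param genome_map Optional data frame with `genome_id` and any of
#'   `sample_id`, `infant_id`, `group`, `species`.
#' @param gene_annotation Optional data frame of per-gene metadata
#'   (rownames or a `gene` column matching the matrix rows).
#' @return Object of class `gene_presence_matrix`.
#' @export
gene_presence_matrix <- function(matrix, genome_map = NULL,
                                 gene_annotation = NULL) {
  stopifnot(is.matrix(matrix), all(matrix %in% c(0, 1)),
            !is.null(rownames(matrix)), !is.null(colnames(matrix)))
  if (!is.null(genome_map)) {
    stopifnot("genome_id" %in% names(genome_map))
    if (!all(colnames(matrix) %in% genome_map$genome_id)) {
      stop("genome_map does not cover all genomes")
    }
  }
  structure(list(matrix = matrix, genome_map = genome_map,
                 gene_annotation = gene_annotation),
            class = "gene_presence_matrix")
}

#' @export
print.gene_presence_matrix <- function(x, ...) {
  cat(sprintf("<gene_presence_matrix> %d genes x %d genomes\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Read a merged taxonomic-profiler table
#'
#' Parses the usual merged profiler output: a TSV whose first column holds
#' pipe-delimited clade strings (`k__...|p__...|...|s__...`) and whose
#' remaining columns are per-sample percentages. Rows whose deepest rank
#' matches `level` are extracted, values are rescaled from percentages to
#' proportions (raw per-sample sums are validated to be <= 100 + tol), and
#' the result is renormalised to sum to 1 per sample.
#'
#' @param path TSV path. A leading comment line (`#...`) is tolerated.
#' @param level `"species"` or `"genus"`.
#' @return A relative `feature_table` with the full clade strings in
#'   `$taxonomy`.
#' @export
read_metaphlan_table <- function(path, level = c("species", "genus")) {
  level <- match.arg(level)
  prefix <- if (level == "species") "s__" else "g__"
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  clade <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric abundance cell in ", path)
  if (anyDuplicated(clade)) {
    stop("duplicate clade rows: ", clade[duplicated(clade)][1])
  }
  last <- vapply(strsplit(clade, "|", fixed = TRUE),
                 function(p) p[length(p)], "")
  bad <- !grepl("^[a-z]__", last)
  if (any(bad)) stop("malformed clade string: ", clade[bad][1])
  sel <- startsWith(last, prefix)
  if (!any(sel)) stop("no rows at level ", level)
  m <- vals[sel, , drop = FALSE] / 100
  rownames(m) <- sub(prefix, "", last[sel], fixed = TRUE)
  sums <- colSums(m)
  if (any(sums > 1 + 1e-6)) {
    stop("per-sample abundances exceed 100%: max ", max(sums) * 100)
  }
  feature_table(m, type = "relative", level = level,
                taxonomy = clade[sel], normalise = TRUE)
}

#' Write a feature table in merged-profiler dialect
#'
#' Emits species-level clade strings (a generic lineage derived from the
#' genus part of each feature name when no taxonomy is attached) and
#' percentage values.
#'
#' @param table A relative `feature_table`.
#' @param path Output TSV path.
#' @export
write_metaphlan_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"), table$type == "relative")
  clade <- table$taxonomy
  if (is.null(clade)) {
    genus <- sub("_.*$", "", rownames(table$values))
    prefix <- if (table$level == "species") {
      paste0("k__Bacteria|p__Unknown|c__Unknown|o__Unknown|f__Unknown|g__",
             genus, "|s__", rownames(table$values))
    } else {
      paste0("k__Bacteria|p__Unknown|c__Unknown|o__Unknown|f__Unknown|g__",
             rownames(table$values))
    }
    clade <- prefix
  }
  out <- data.frame(clade_name = clade, 100 * table$values,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# canonical leading metadata columns of the pangenome CSV dialect
.roary_meta_cols <- c("Gene", "Non-unique Gene name", "Annotation",
                      "No. isolates", "No. sequences",
                      "Avg sequences per isolate", "Genome Fragment",
                      "Order within Fragment", "Accessory Fragment",
                      "Accessory Order with Fragment", "QC",
                      "Min group size nuc", "Max group size nuc",
                      "Avg group size nuc")

#' Read a pangenome gene presence/absence CSV
#'
#' Consumes the common pangenome-pipeline dialect: one row per gene
#' cluster, a block of metadata columns, then one column per genome where
#' presence is any non-empty cell (the cell normally holds the member gene
#' id). Quoted commas are handled by the CSV parser.
#'
#' @param path CSV path.
#' @return A [gene_presence_matrix()] with gene metadata retained.
#' @export
read_gene_presence_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"Gene" %in% names(df)) stop("no 'Gene' column; not a pangenome CSV")
  meta_cols <- intersect(.roary_meta_cols, names(df))
  genome_cols <- setdiff(names(df), meta_cols)
  if (!length(genome_cols)) stop("no genome columns detected")
  m <- vapply(genome_cols, function(g) {
    as.numeric(!is.na(df[[g]]) & df[[g]] != "")
  }, numeric(nrow(df)))
  rownames(m) <- df$Gene
  gene_presence_matrix(m, gene_annotation = df[meta_cols])
}

#' Write a gene presence/absence CSV
#'
#' @param gpm A [gene_presence_matrix()].
#' @param path Output path.
#' @export
write_gene_presence_csv <- function(gpm, path) {
  stopifnot(inherits(gpm, "gene_presence_matrix"))
  m <- gpm$matrix
  cells <- matrix("", nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    present <- m[, j] == 1
    cells[present, j] <- paste0(rownames(m)[present], "_", colnames(m)[j])
  }
  out <- data.frame(Gene = rownames(m),
                    `Non-unique Gene name` = "", Annotation = "",
                    cells, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read / write per-sample clinical metadata CSV
#'
#' One row per sample with the infant-level covariates repeated:
#' `sample_id, infant_id, age_months, symptom_state, group, sex,
#' delivery_mode, initial_feeding, probiotic_first_year` (optional
#' `onset_age`, `resolution_age`). A missing required column is a named
#' schema error.
#'
#' @param path CSV path.
#' @param cohort A [cohort_table()] (for writing).
#' @return `read_metadata_csv` returns a [cohort_table()].
#' @export
read_metadata_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "infant_id", "age_months", "symptom_state", "group",
           "sex", "delivery_mode", "initial_feeding", "probiotic_first_year")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("metadata schema error; missing column(s): ",
         paste(missing, collapse = ", "))
  }
  inf_cols <- c("infant_id", "group", "sex", "delivery_mode",
                "initial_feeding", "probiotic_first_year",
                intersect(c("onset_age", "resolution_age"), names(df)))
  infants <- unique(df[inf_cols])
  if (anyDuplicated(infants$infant_id)) {
    stop("inconsistent infant-level covariates across samples")
  }
  cohort_table(infants,
               df[c("sample_id", "infant_id", "age_months", "symptom_state")])
}

#' @rdname read_metadata_csv
#' @export
write_metadata_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  df <- merge(cohort$samples, cohort$infants, by = "infant_id", sort = FALSE)
  df <- df[order(df$infant_id, df$age_months, df$sample_id), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers over Biostrings returning plain named character vectors.
#'
#' @param path FASTA path.
#' @param sequences Named character vector (or coercible list) of
#'   sequences.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(unlist(sequences))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes the stages in dependency order on a simulated dataset:
#' simulate -> subsets/matching -> diversity & stability -> differential
#' model -> MAG tiers -> sketches & stratified Mash comparison -> strain
#' tree -> clade scan + unique genes -> classifier. Each stage can be
#' switched off. All file outputs land under `out_dir`; a JSON manifest
#' records the config, seed, package version and md5 of every written
#' file.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stage names to run (default all):
#'   `simulate` is always implied.
#' @return The manifest, invisibly; results are also returned in
#'   `$results`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("apmicro_"),
                         stages = c("subsets", "diversity", "stability",
                                    "differential", "mags", "sketch",
                                    "tree", "cladescan", "classify")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  res <- list()
  cohort <- generate_cohort(config)
  ab <- generate_abundances(cohort, config)
  write_metadata_csv(cohort, file.path(out_dir, "metadata.csv"))
  write_metaphlan_table(ab$relative, file.path(out_dir, "abundance.tsv"))
  res$cohort <- cohort
  res$abundance <- ab
  if ("subsets" %in% stages) {
    res$subsets <- select_state_subsets(cohort)
    sub <- res$subsets$first_symptomatic
    ctrl <- cohort$samples[
      cohort$infants$group[match(cohort$samples$infant_id,
                                 cohort$infants$infant_id)] == "control", ]
    res$match <- match_by_age(
      stats::setNames(sub$age_months, sub$sample_id),
      stats::setNames(ctrl$age_months, ctrl$sample_id))
  }
  if ("diversity" %in% stages) {
    res$age_correlation <- age_diversity_correlation(ab$counts, cohort)
    dm <- aitchison(ab$relative)
    s_inf <- cohort$samples$infant_id[match(colnames(ab$relative$values),
                                            cohort$samples$sample_id)]
    grp <- cohort$infants$group[match(s_inf, cohort$infants$infant_id)]
    res$pcoa <- pcoa_ordination(dm, n_axes = 2, groups = grp)
  }
  if ("stability" %in% stages) {
    res$stability <- stability_analysis(ab$relative, cohort)
  }
  if ("differential" %in% stages) {
    res$differential <- fit_associations(ab$relative, cohort,
                                         aggregate_window = c(0, 2))
    utils::write.table(res$differential,
                       file.path(out_dir, "differential.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if ("mags" %in% stages) {
    res$mags <- generate_mags(cohort, config)
    res$tier_summary <- tier_summary(res$mags,
                                     n_samples_total = nrow(cohort$samples))
  }
  strain <- NULL
  if (any(c("sketch", "tree", "cladescan") %in% stages)) {
    strain <- generate_strain_data(cohort, config)
    res$strain <- strain
  }
  if ("sketch" %in% stages) {
    sks <- lapply(names(strain$genomes), function(g) {
      sketch(strain$genomes[[g]], genome_id = g)
    })
    names(sks) <- names(strain$genomes)
    dm <- mash_distance_matrix(sks)
    res$mash <- stratified_comparison(dm, strain$genome_map,
                                      top_n_species = 20)
  }
  if ("tree" %in% stages || "cladescan" %in% stages) {
    gd <- gene_content_distance(strain$gpm)
    res$tree <- build_tree(gd, annotations = strain$genome_map)
    write_newick(res$tree, file.path(out_dir, "strain_tree.nwk"))
  }
  if ("cladescan" %in% stages) {
    res$clade_scan <- scan_tree(res$tree, expected_case_fraction = 0.5)
    top_node <- res$clade_scan$node[1]
    leaves <- attr(res$clade_scan, "tip_sets")[[as.character(top_node)]]
    res$unique_genes <- clade_unique_genes(strain$gpm, leaves)
  }
  if ("classify" %in% stages) {
    pf <- prepare_features(ab$relative, cohort,
                           exclude = "Lacticaseibacillus_rhamnosus")
    res$classifier <- train_evaluate(pf$x, pf$y, seed = config$seed)
  }
  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("apmicro")),
    seed = config$seed,
    stages = stages,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$results <- res
  invisible(manifest)
}
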