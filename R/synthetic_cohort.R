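# Synthetic cohort generator: clinical metadata, Dirichlet-multinomial
# abundance tables with age maturation and planted effects, strain data
# (marker SNVs, pangenome gene matrix, genome sequences), and MAG quality
# records. Every stage downstream of sequencing is exercisable on its
# output with no external data.

#' Simulation configuration
#'
#' All knobs of the synthetic cohort in one validated object. Defaults
#' emulate a two-arm infant cohort with scheduled visits across the first
#' year: 163 infants with an 84/163 case share, visits at roughly birth,
#' 2 weeks, 1, 2, 4, 6, 9 and 12 months with Gaussian jitter, a bit over
#' half of visits attended so each infant contributes a median of about
#' four samples, a case-enriched *Escherichia coli* effect planted in the 0-2
#' month window, a near-clonal probiotic *Lacticaseibacillus rhamnosus*
#' lineage in probiotic-exposed infants, and a planted case-enriched
#' *E. coli* clade carrying 223 clade-unique genes.
#'
#' @param n_infants Number of infants.
#' @param case_fraction Case share in (0,1); case count is
#'   `round(n_infants * case_fraction)`.
#' @param visit_ages_months Strictly increasing scheduled visit ages.
#' @param age_jitter_sd SD (months) of Gaussian jitter around each visit,
#'   truncated at 0.
#' @param attendance Probability a scheduled visit yields a sample.
#' @param n_taxa Number of species in the abundance tables.
#' @param planted_effects List of planted differential-abundance effects;
#'   each element a list with `taxon`, `group` ("case"/"control"),
#'   `window` (c(lo, hi) months), `log_effect` (added to the taxon's
#'   log Dirichlet weight in that group/window).
#' @param probiotic_log_effect Log-weight boost of the probiotic species in
#'   probiotic-exposed infants.
#' @param overdispersion Dirichlet concentration (smaller = noisier).
#' @param infant_effect_sd SD of per-infant, per-taxon log-weight random
#'   intercepts (drives within-infant stability).
#' @param sequencing_depth Reads (count total) per sample.
#' @param probiotic_strain_divergence Per-site mutation probability of the
#'   probiotic-species haplotype in carriers *without* reported probiotic
#'   use (community-acquired lineage).
#' @param probiotic_clonal_divergence Per-site mutation probability in
#'   probiotic-exposed carriers (near-clonal product strain).
#' @param carrier_rate_unexposed Fraction of non-probiotic infants that
#'   nonetheless carry the probiotic species.
#' @param snv_sites Marker haplotype length (sites).
#' @param planted_clade List: `species`, `n_unique_genes`,
#'   `clade_case_fraction`, `clade_size`.
#' @param strain_n_genomes Genomes (one per selected sample) in the
#'   planted-clade species' pangenome and tree.
#' @param strain_n_infants Infants those genomes are drawn from (up to 2
#'   samples per infant, so related same-infant pairs exist).
#' @param n_core_genes,n_accessory_genes Pangenome structure; accessory
#'   genes are present per genome with probability `accessory_rate`.
#' @param accessory_rate See above.
#' @param genome_length Length (bp) of the synthetic genome backbone
#'   emitted for sketching.
#' @param lineage_divergence,related_divergence Per-site mutation
#'   probabilities of a genome relative to the species backbone
#'   (between-infant lineages) and relative to the infant lineage
#'   (same-infant genomes).
#' @param mag_mean_per_sample Poisson mean of MAGs recovered per yielding
#'   sample.
#' @param sample_yield_prob Probability a sample yields any MAG.
#' @param completeness_shape Two Beta shape parameters for completeness/100.
#' @param contamination_shape Two Beta shape parameters for
#'   contamination/100.
#' @param seed Integer master seed; every generator derives its stream
#'   from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_infants = 163,
                       case_fraction = 84 / 163,
                       visit_ages_months = c(0.1, 0.5, 1, 2, 4, 6, 9, 12),
                       age_jitter_sd = 0.15,
                       attendance = 0.57,
                       n_taxa = 60,
                       planted_effects = list(
                         list(taxon = "Escherichia_coli", group = "case",
                              window = c(0, 2), log_effect = log(2))),
                       probiotic_log_effect = log(50),
                       overdispersion = 50,
                       infant_effect_sd = 0.5,
                       sequencing_depth = 5e4,
                       probiotic_strain_divergence = 0.02,
                       probiotic_clonal_divergence = 5e-4,
                       carrier_rate_unexposed = 0.15,
                       snv_sites = 1000,
                       planted_clade = list(species = "Escherichia_coli",
                                            n_unique_genes = 223,
                                            clade_case_fraction = 1.0,
                                            clade_size = 12),
                       strain_n_genomes = 120,
                       strain_n_infants = 72,
                       n_core_genes = 1000,
                       n_accessory_genes = 600,
                       accessory_rate = 0.35,
                       genome_length = 50000,
                       lineage_divergence = 0.01,
                       related_divergence = 0.001,
                       mag_mean_per_sample = 12.4,
                       sample_yield_prob = 0.984,
                       completeness_shape = c(1.227, 0.397),
                       contamination_shape = c(1, 24),
                       seed = 1) {
  cfg <- as.list(environment())
  if (cfg$n_infants < 1) stop("n_infants must be positive")
  if (cfg$case_fraction <= 0 || cfg$case_fraction >= 1) {
    stop("case_fraction must lie strictly in (0, 1)")
  }
  if (is.unsorted(cfg$visit_ages_months, strictly = TRUE)) {
    stop("visit ages must be strictly increasing")
  }
  probs <- c(cfg$attendance, cfg$probiotic_strain_divergence,
             cfg$probiotic_clonal_divergence, cfg$carrier_rate_unexposed,
             cfg$accessory_rate, cfg$lineage_divergence,
             cfg$related_divergence, cfg$sample_yield_prob)
  if (any(probs < 0 | probs > 1)) stop("rates/probabilities must lie in [0,1]")
  if (cfg$age_jitter_sd < 0) stop("age_jitter_sd must be >= 0")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

# derive independent sub-streams from the master seed; offsets keep the
# generators decoupled so e.g. regenerating abundances does not shift the
# strain data
sub_seed <- function(config, stream) {
  offsets <- c(cohort = 11L, taxa = 23L, abundance = 37L, strain = 53L,
               mags = 71L)
  (config$seed * 97L + offsets[[stream]]) %% .Machine$integer.max
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

# realistic infant-gut species names for the head of the rank curve; the
# tail is generic
taxa_names <- function(n) {
  head_names <- c("Bifidobacterium_longum", "Escherichia_coli",
                  "Bifidobacterium_breve", "Bacteroides_fragilis",
                  "Klebsiella_pneumoniae", "Bifidobacterium_bifidum",
                  "Clostridium_paraputrificum", "Klebsiella_michiganensis",
                  "Lacticaseibacillus_rhamnosus", "Enterococcus_faecalis",
                  "Staphylococcus_epidermidis", "Streptococcus_salivarius",
                  "Veillonella_parvula", "Bacteroides_vulgatus",
                  "Ruminococcus_gnavus")
  if (n <= length(head_names)) return(head_names[seq_len(n)])
  c(head_names, sprintf("Species_%03d", seq_len(n - length(head_names))))
}

#' Generate a synthetic cohort
#'
#' Draws infant-level covariates (sex, delivery mode, initial feeding,
#' first-year probiotic use — with probiotic use far more frequent in
#' cases, mirroring therapeutic exposure), assigns case infants a symptom
#' onset age (log-normal, median 0.5 months) and a resolution age, and
#' realises per-visit samples with jittered collection ages. Symptom state
#' per sample is derived from the onset/resolution ages (onset-day samples
#' count as symptomatic).
#'
#' @param config A [sim_config()].
#' @return A [cohort_table()]; onset/resolution ages are kept in
#'   `$infants`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(sub_seed(config, "cohort"), {
    n <- config$n_infants
    n_case <- round(n * config$case_fraction)
    if (n_case == 0 || n_case == n) stop("degenerate case_fraction for this n")
    infant_id <- sprintf("I%03d", seq_len(n))
    group <- rep(c("case", "control"), c(n_case, n - n_case))
    probiotic <- ifelse(group == "case",
                        stats::runif(n) < 0.857, stats::runif(n) < 0.203)
    infants <- data.frame(
      infant_id = infant_id,
      group = group,
      sex = sample(c("female", "male"), n, TRUE, prob = c(0.45, 0.55)),
      delivery_mode = sample(c("vaginal", "cesarean"), n, TRUE,
                             prob = c(0.65, 0.35)),
      initial_feeding = sample(c("exclusive", "partial", "formula"), n, TRUE,
                               prob = c(0.63, 0.27, 0.10)),
      probiotic_first_year = probiotic)
    onset <- rep(NA_real_, n)
    resolution <- rep(NA_real_, n)
    onset[group == "case"] <- stats::rlnorm(n_case, log(0.5), 0.81)
    resolution[group == "case"] <- onset[group == "case"] +
      stats::rlnorm(n_case, log(5), 0.45)
    infants$onset_age <- onset
    infants$resolution_age <- resolution
    visits <- config$visit_ages_months
    rows <- list()
    for (i in seq_len(n)) {
      attended <- which(stats::runif(length(visits)) < config$attendance)
      if (!length(attended)) attended <- sample(seq_along(visits), 1)
      age <- visits[attended] +
        stats::rnorm(length(attended), 0, config$age_jitter_sd)
      age <- pmin(pmax(age, 0), 13.99)
      state <- if (group[i] == "control") {
        rep("control", length(age))
      } else {
        ifelse(age < onset[i], "pre_symptomatic",
               ifelse(age < resolution[i], "symptomatic", "resolved"))
      }
      rows[[i]] <- data.frame(
        sample_id = sprintf("%s_V%02d", infant_id[i], attended),
        infant_id = infant_id[i], age_months = age, symptom_state = state)
    }
    cohort_table(infants, do.call(rbind, rows))
  })
}

# per-taxon baseline log-weights and age slopes; a handful of founder taxa
# dominate at birth, the rest rise with age so richness and evenness grow
taxa_params <- function(config) {
  with_seed(sub_seed(config, "taxa"), {
    n <- config$n_taxa
    nm <- taxa_names(n)
    founder <- seq_len(min(6, n))
    b <- stats::rnorm(n, -4, 1.5)
    b[founder] <- stats::rnorm(length(founder), 2, 0.5)
    m <- stats::runif(n, 1.0, 1.8)
    m[founder] <- stats::runif(length(founder), -0.6, 0.2)
    list(names = nm, base = b, slope = m)
  })
}

#' Generate synthetic abundance tables
#'
#' Per-sample counts follow a Dirichlet-multinomial whose log Dirichlet
#' weights combine a taxon baseline, an age-maturation slope (on
#' `log1p(age)`), a per-infant per-taxon random intercept, the configured
#' planted case/control effects within their age windows, and a probiotic
#' boost of the probiotic species in exposed infants.
#'
#' @param cohort A [generate_cohort()] result.
#' @param config The same [sim_config()].
#' @return List: `counts` and `relative` `feature_table`s (taxa x samples).
#' @export
generate_abundances <- function(cohort, config = sim_config()) {
  stopifnot(inherits(cohort, "cohort"), inherits(config, "sim_config"))
  tp <- taxa_params(config)
  for (pe in config$planted_effects) {
    if (!pe$taxon %in% tp$names) stop("planted taxon not simulated: ",
                                      pe$taxon)
  }
  with_seed(sub_seed(config, "abundance"), {
    s <- cohort$samples
    inf_ids <- cohort$infants$infant_id
    n_taxa <- config$n_taxa
    u <- matrix(stats::rnorm(length(inf_ids) * n_taxa, 0,
                             config$infant_effect_sd),
                length(inf_ids), n_taxa, dimnames = list(inf_ids, NULL))
    grp <- cohort$infants$group[match(s$infant_id, inf_ids)]
    prob_use <- cohort$infants$probiotic_first_year[match(s$infant_id,
                                                          inf_ids)]
    probiotic_taxon <- match("Lacticaseibacillus_rhamnosus", tp$names)
    counts <- matrix(0L, n_taxa, nrow(s),
                     dimnames = list(tp$names, s$sample_id))
    for (k in seq_len(nrow(s))) {
      lw <- tp$base + tp$slope * log1p(s$age_months[k]) + u[s$infant_id[k], ]
      for (pe in config$planted_effects) {
        if (grp[k] == pe$group && s$age_months[k] >= pe$window[1] &&
            s$age_months[k] < pe$window[2]) {
          j <- match(pe$taxon, tp$names)
          lw[j] <- lw[j] + pe$log_effect
        }
      }
      if (!is.na(probiotic_taxon) && isTRUE(prob_use[k])) {
        lw[probiotic_taxon] <- lw[probiotic_taxon] +
          config$probiotic_log_effect
      }
      w <- exp(lw - max(lw))
      alpha <- config$overdispersion * w / sum(w)
      g <- stats::rgamma(n_taxa, shape = alpha, rate = 1)
      if (sum(g) == 0) g[which.max(alpha)] <- 1
      counts[, k] <- stats::rmultinom(1, config$sequencing_depth, g / sum(g))
    }
    ct <- feature_table(counts, type = "counts", level = "species")
    list(counts = ct, relative = relative_abundance(ct))
  })
}

mutate_seq <- function(x, rate, alphabet = c("A", "C", "G", "T")) {
  if (rate <= 0) return(x)
  hit <- which(stats::runif(length(x)) < rate)
  if (length(hit)) {
    # substitute with a different base
    cur <- x[hit]
    sub <- vapply(cur, function(b) sample(setdiff(alphabet, b), 1), "")
    x[hit] <- sub
  }
  x
}

#' Generate synthetic strain-level data
#'
#' Three coupled artefacts for the strain analyses:
#'
#' * a marker-SNV haplotype matrix for the probiotic species —
#'   probiotic-exposed carrier infants receive near-clonal haplotypes
#'   (per-site divergence `probiotic_clonal_divergence`), unexposed
#'   carriers diverge at `probiotic_strain_divergence`;
#' * a binary gene presence/absence matrix for the planted-clade species —
#'   core genes in every genome, random accessory genes, and
#'   `n_unique_genes` present in every clade genome and absent elsewhere,
#'   with the clade drawn predominantly from case samples
#'   (`clade_case_fraction`);
#' * genome sequences for every genome (a shared backbone with
#'   between-infant lineage SNVs and smaller within-infant divergence) so
#'   MinHash sketches and Mash distances can be computed, with same-infant
#'   genome pairs more similar than different-infant pairs.
#'
#' @param cohort A [generate_cohort()] result.
#' @param config The same [sim_config()].
#' @return List: `snv` (haplotype character matrix, rows = carrier
#'   infants), `snv_exposed` (logical per row), `gpm` (a
#'   [gene_presence_matrix()]), `genome_map` (data frame genome_id,
#'   sample_id, infant_id, group, species), `clade_genomes`,
#'   `unique_genes`, `genomes` (named list of sequence strings).
#' @export
generate_strain_data <- function(cohort, config = sim_config()) {
  stopifnot(inherits(cohort, "cohort"), inherits(config, "sim_config"))
  pc <- config$planted_clade
  if (pc$clade_size < 2) stop("clade size must be >= 2")
  with_seed(sub_seed(config, "strain"), {
    inf <- cohort$infants
    ## --- probiotic-species marker haplotypes (one per carrier infant) ---
    exposed <- inf$infant_id[inf$probiotic_first_year]
    unexposed_pool <- inf$infant_id[!inf$probiotic_first_year]
    n_unexp <- round(config$carrier_rate_unexposed * length(unexposed_pool))
    unexposed <- if (n_unexp > 0) sample(unexposed_pool, n_unexp) else
      character()
    carriers <- c(exposed, unexposed)
    ref <- sample(c("A", "C", "G", "T"), config$snv_sites, TRUE)
    hap <- t(vapply(carriers, function(id) {
      rate <- if (id %in% exposed) config$probiotic_clonal_divergence else
        config$probiotic_strain_divergence
      mutate_seq(ref, rate)
    }, character(config$snv_sites)))
    rownames(hap) <- carriers
    ## --- planted-clade species: genomes from ~balanced case/control samples
    s <- cohort$samples
    s$group <- inf$group[match(s$infant_id, inf$infant_id)]
    pick_side <- function(g, n_inf) {
      ids <- unique(s$infant_id[s$group == g])
      ids <- sample(ids, min(n_inf, length(ids)))
      out <- list()
      for (id in ids) {
        smp <- s$sample_id[s$infant_id == id]
        out[[id]] <- sample(smp, min(2, length(smp)))
      }
      unlist(out, use.names = FALSE)
    }
    n_inf_side <- ceiling(config$strain_n_infants / 2)
    sel <- c(pick_side("case", n_inf_side), pick_side("control", n_inf_side))
    # trim to strain_n_genomes keeping the case/control balance
    selgrp <- s$group[match(sel, s$sample_id)]
    keep <- c(which(selgrp == "case")[seq_len(min(config$strain_n_genomes / 2,
                                                  sum(selgrp == "case")))],
              which(selgrp == "control")[
                seq_len(min(config$strain_n_genomes / 2,
                            sum(selgrp == "control")))])
    sel <- sel[sort(keep)]
    genome_map <- data.frame(
      genome_id = paste0("g_", sel),
      sample_id = sel,
      infant_id = s$infant_id[match(sel, s$sample_id)],
      group = s$group[match(sel, s$sample_id)],
      species = pc$species)
    ## clade membership: clade_case_fraction of clade genomes from cases
    n_clade_case <- round(pc$clade_size * pc$clade_case_fraction)
    n_clade_ctrl <- pc$clade_size - n_clade_case
    case_g <- genome_map$genome_id[genome_map$group == "case"]
    ctrl_g <- genome_map$genome_id[genome_map$group == "control"]
    if (length(case_g) < n_clade_case || length(ctrl_g) < n_clade_ctrl) {
      stop("not enough genomes to form the planted clade")
    }
    clade <- c(sample(case_g, n_clade_case),
               if (n_clade_ctrl > 0) sample(ctrl_g, n_clade_ctrl))
    ## gene presence/absence
    n_gen <- nrow(genome_map)
    core <- matrix(1, config$n_core_genes, n_gen)
    acc <- matrix(stats::rbinom(config$n_accessory_genes * n_gen, 1,
                                config$accessory_rate),
                  config$n_accessory_genes, n_gen)
    uniq <- matrix(0, pc$n_unique_genes, n_gen)
    uniq[, genome_map$genome_id %in% clade] <- 1
    m <- rbind(core, acc, uniq)
    rownames(m) <- c(sprintf("core_%04d", seq_len(config$n_core_genes)),
                     sprintf("acc_%04d", seq_len(config$n_accessory_genes)),
                     sprintf("uniq_%04d", seq_len(pc$n_unique_genes)))
    colnames(m) <- genome_map$genome_id
    gpm <- gene_presence_matrix(m, genome_map)
    ## genome sequences: backbone + per-infant lineage + per-genome noise
    backbone <- sample(c("A", "C", "G", "T"), config$genome_length, TRUE)
    lineages <- list()
    genomes <- stats::setNames(vector("list", n_gen), genome_map$genome_id)
    for (i in seq_len(n_gen)) {
      iid <- genome_map$infant_id[i]
      if (is.null(lineages[[iid]])) {
        lineages[[iid]] <- mutate_seq(backbone, config$lineage_divergence)
      }
      genomes[[i]] <- paste(mutate_seq(lineages[[iid]],
                                       config$related_divergence),
                            collapse = "")
    }
    list(snv = hap,
         snv_exposed = carriers %in% exposed,
         gpm = gpm,
         genome_map = genome_map,
         clade_genomes = clade,
         unique_genes = rownames(m)[grepl("^uniq_", rownames(m))],
         genomes = genomes)
  })
}

#' Generate synthetic MAG quality records
#'
#' Each sample yields MAGs with probability `sample_yield_prob`; yielding
#' samples produce a zero-truncated Poisson number of MAGs whose
#' completeness and contamination are drawn from the configured Beta
#' distributions (defaults calibrated so the high/medium/low tier split is
#' roughly 37/21/43%). Species labels follow a geometric rank-abundance
#' pull so a few species dominate, as in real binning runs.
#'
#' @param cohort A [generate_cohort()] result.
#' @param config The same [sim_config()].
#' @return Data frame: mag_id, sample_id, infant_id, species,
#'   completeness, contamination, tier.
#' @export
generate_mags <- function(cohort, config = sim_config()) {
  stopifnot(inherits(cohort, "cohort"), inherits(config, "sim_config"))
  with_seed(sub_seed(config, "mags"), {
    s <- cohort$samples
    yields <- stats::runif(nrow(s)) < config$sample_yield_prob
    n_mags <- ifelse(yields,
                     pmax(1L, stats::rpois(nrow(s),
                                           config$mag_mean_per_sample)), 0L)
    total <- sum(n_mags)
    sample_id <- rep(s$sample_id, n_mags)
    species_pool <- taxa_names(config$n_taxa)
    sp_prob <- 0.85^seq_along(species_pool)
    rec <- data.frame(
      mag_id = sprintf("MAG_%05d", seq_len(total)),
      sample_id = sample_id,
      infant_id = rep(s$infant_id, n_mags),
      species = sample(species_pool, total, TRUE, prob = sp_prob),
      completeness = 100 * stats::rbeta(total, config$completeness_shape[1],
                                        config$completeness_shape[2]),
      contamination = 100 * stats::rbeta(total, config$contamination_shape[1],
                                         config$contamination_shape[2]))
    rec$tier <- assign_tier(rec$completeness, rec$contamination)
    rec
  })
}
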