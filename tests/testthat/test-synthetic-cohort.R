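test_that("configuration is validated", {
  expect_error(sim_config(n_infants = 0), "positive")
  expect_error(sim_config(case_fraction = 1), "strictly")
  expect_error(sim_config(visit_ages_months = c(2, 1)), "increasing")
  expect_error(sim_config(attendance = 1.5), "\\[0,1\\]")
})

test_that("cohort generation honours counts, jitter and determinism", {
  cfg <- sim_config(seed = 9)
  co1 <- generate_cohort(cfg)
  expect_equal(sum(co1$infants$group == "case"), 84)
  expect_equal(sum(co1$infants$group == "control"), 79)
  # byte-identical rerun under the same seed
  co2 <- generate_cohort(cfg)
  expect_identical(co1, co2)
  # zero jitter: every age equals a scheduled visit age
  cfg0 <- sim_config(seed = 9, age_jitter_sd = 0)
  co0 <- generate_cohort(cfg0)
  expect_true(all(co0$samples$age_months %in% cfg0$visit_ages_months))
  # probiotic use concentrated in cases
  pr <- tapply(co1$infants$probiotic_first_year, co1$infants$group, mean)
  expect_gt(pr["case"], pr["control"])
  # symptom states consistent with onset/resolution ages
  ons <- co1$infants$onset_age[match(co1$samples$infant_id,
                                     co1$infants$infant_id)]
  pre <- co1$samples$symptom_state == "pre_symptomatic"
  expect_true(all(co1$samples$age_months[pre] < ons[pre]))
})

test_that("abundance tables close to 1 and respect planted effects", {
  fx <- default_fixture()
  rel <- fx$relative$values
  expect_true(all(abs(colSums(rel) - 1) < 1e-9))
  expect_true(all(fx$counts$values >= 0))
  expect_true(all(colSums(fx$counts$values) == fx$cfg$sequencing_depth))
  # regeneration is deterministic
  ab2 <- generate_abundances(fx$cohort, fx$cfg)
  expect_identical(ab2$relative$values, rel)
  # unknown planted taxon is refused
  cfg_bad <- sim_config(planted_effects = list(
    list(taxon = "Not_a_species", group = "case", window = c(0, 2),
         log_effect = 1)))
  expect_error(generate_abundances(fx$cohort, cfg_bad), "not simulated")
})

test_that("a planted 2-fold case effect raises case means in its window", {
  # sign check across independent seeds (Monte-Carlo, small n of seeds)
  hits <- 0
  for (s in 1:5) {
    cfg <- sim_config(seed = 300 + s, n_infants = 200, case_fraction = 0.5)
    co <- generate_cohort(cfg)
    ab <- generate_abundances(co, cfg)
    sel <- co$samples$age_months < 2
    grp <- co$infants$group[match(co$samples$infant_id,
                                  co$infants$infant_id)]
    x <- ab$relative$values["Escherichia_coli", ]
    hits <- hits + (mean(x[sel & grp == "case"]) >
                      mean(x[sel & grp == "control"]))
  }
  expect_gte(hits, 5 * 0.95 - 1)  # sign holds in essentially all seeds
})

test_that("null generator yields uniform group p-values across taxa", {
  cfg <- sim_config(seed = 42, planted_effects = list(),
                    probiotic_log_effect = 0)
  co <- generate_cohort(cfg)
  ab <- generate_abundances(co, cfg)
  res <- fit_associations(ab$relative, co, fixed_effects = "group",
                          aggregate_window = c(0, 14))
  p <- res$p_value[grepl("^group", res$covariate)]
  ks <- ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("strain data honours divergence settings and clade construction", {
  fx <- default_fixture()
  st <- generate_strain_data(fx$cohort, fx$cfg)
  # clade drawn per configured case share
  grp <- st$genome_map$group[match(st$clade_genomes,
                                   st$genome_map$genome_id)]
  expect_equal(mean(grp == "case"),
               fx$cfg$planted_clade$clade_case_fraction)
  # unique genes present in-clade, absent out-clade
  m <- st$gpm$matrix
  inb <- colnames(m) %in% st$clade_genomes
  expect_true(all(m[st$unique_genes, inb] == 1))
  expect_true(all(m[st$unique_genes, !inb] == 0))
  # zero divergence for both carrier classes: identical haplotypes
  cfg0 <- sim_config(seed = 7, probiotic_strain_divergence = 0,
                     probiotic_clonal_divergence = 0)
  co0 <- generate_cohort(cfg0)
  st0 <- generate_strain_data(co0, cfg0)
  expect_equal(snv_distance_matrix(apply(st0$snv, 1, paste,
                                         collapse = ""))$matrix,
               matrix(0, nrow(st0$snv), nrow(st0$snv),
                      dimnames = list(rownames(st0$snv),
                                      rownames(st0$snv))))
  # exposed carriers near-clonal, unexposed more diverse
  d <- snv_distance_matrix(apply(st$snv, 1, paste, collapse = ""))$matrix
  exp_ids <- rownames(st$snv)[st$snv_exposed]
  unexp_ids <- rownames(st$snv)[!st$snv_exposed]
  mean_within <- function(ids) {
    if (length(ids) < 2) return(NA_real_)
    sub <- d[ids, ids]
    mean(sub[upper.tri(sub)])
  }
  expect_lt(mean_within(exp_ids), 0.005)
  expect_gt(mean_within(unexp_ids), mean_within(exp_ids))
  # determinism
  st2 <- generate_strain_data(fx$cohort, fx$cfg)
  expect_identical(st$gpm$matrix, st2$gpm$matrix)
  expect_identical(st$genomes, st2$genomes)
})

test_that("clade of size below 2 is refused", {
  fx <- default_fixture()
  cfg <- sim_config(planted_clade = list(species = "Escherichia_coli",
                                         n_unique_genes = 10,
                                         clade_case_fraction = 1,
                                         clade_size = 1))
  expect_error(generate_strain_data(fx$cohort, cfg), "clade size")
})
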