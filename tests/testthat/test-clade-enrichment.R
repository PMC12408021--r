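# helper: balanced caterpillar tree over n case + n control leaves with a
# pure-case clade of the first k leaves
make_labelled_tree <- function(n_case, n_control, seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  labs <- c(sprintf("case%02d", seq_len(n_case)),
            sprintf("ctrl%02d", seq_len(n_control)))
  tr <- ape::rtree(n, tip.label = labs)
  ann <- data.frame(leaf = labs,
                    infant_id = labs,  # one sample per infant
                    group = rep(c("case", "control"), c(n_case, n_control)))
  as_strain_tree(tr, ann)
}

test_that("clade chi-square matches its 1-df closed form", {
  # 10 case / 0 control vs even split: X2 = 10
  labs <- data.frame(leaf = paste0("t", 1:20),
                     infant_id = paste0("i", 1:20),
                     group = rep(c("case", "control"), each = 10))
  tr <- ape::read.tree(text = paste0(
    "(((((((((t1,t2),t3),t4),t5),t6),t7),t8),(t9,t10)),",
    "(((((((((t11,t12),t13),t14),t15),t16),t17),t18),t19),t20));"))
  sc <- scan_tree(as_strain_tree(tr, labs), expected_case_fraction = 0.5,
                  min_leaves = 6)
  pure10 <- sc[sc$n_leaves == 10 & sc$n_case == 10, ]
  expect_equal(pure10$chisq[1], 10)
  expect_equal(pure10$p_value[1], pchisq(10, 1, lower.tail = FALSE))
  expect_equal(pure10$p_value[1], 0.001565, tolerance = 1e-3)
  pure6 <- sc[sc$n_leaves == 6 & sc$n_case == 6, ]
  expect_equal(pure6$chisq[1], 6)
  expect_equal(pure6$p_value[1], 0.0143, tolerance = 1e-3)
  expect_true(pure6$significant[1])
  # balanced node: X2 = 0, p = 1
  bal <- sc[sc$n_case == sc$n_control & !is.na(sc$p_value), ]
  expect_true(all(bal$chisq == 0) && all(bal$p_value == 1))
})

test_that("parent case/control counts equal the sum over children", {
  tr <- make_labelled_tree(10, 10, seed = 3)
  sc <- scan_tree(tr, min_leaves = 2)
  sets <- attr(sc, "tip_sets")
  edge <- tr$edge
  n_tip <- length(tr$tip.label)
  for (nd in sc$node) {
    kids <- edge[edge[, 1] == nd, 2]
    kid_case <- sum(vapply(kids, function(k) {
      if (k <= n_tip) as.integer(startsWith(tr$tip.label[k], "case"))
      else sc$n_case[match(k, sc$node)]
    }, 1L))
    expect_equal(sc$n_case[match(nd, sc$node)], kid_case)
  }
})

test_that("label permutation keeps the significant-node fraction near 0.05", {
  # permute case/control labels on a generator strain tree; the fraction of
  # tested nodes below 0.05 stays near nominal (chi-square is approximate
  # at clade sizes near min_leaves, hence the 3-point band)
  pvals <- c()
  set.seed(61)
  for (cfg_seed in c(101, 202, 303)) {
    cfg <- sim_config(seed = cfg_seed)
    co <- generate_cohort(cfg)
    st <- generate_strain_data(co, cfg)
    tr <- build_tree(gene_content_distance(st$gpm),
                     annotations = st$genome_map)
    for (s in 1:30) {
      gm <- st$genome_map
      gm$group <- sample(gm$group)
      sc <- scan_tree(tr, labels = gm, expected_case_fraction = 0.5,
                      min_leaves = 6)
      pvals <- c(pvals, sc$p_value[!is.na(sc$p_value)])
    }
  }
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.03)
})

test_that("infant-oriented flags clades drawn from one infant", {
  labs <- data.frame(leaf = c("a1", "a2", "a3", "b1"),
                     infant_id = c("A", "A", "A", "B"),
                     group = c("case", "case", "case", "control"))
  tr <- ape::read.tree(text = "(((a1,a2),a3),b1);")
  st <- as_strain_tree(tr, labs)
  n_tip <- 4
  # node numbering: root = 5, (a1,a2,a3) = 6, (a1,a2) = 7
  expect_false(infant_oriented(st, 5))
  expect_true(infant_oriented(st, 6))
  expect_true(infant_oriented(st, 7))
  expect_true(infant_oriented(st, 1))  # single leaf
  sc <- scan_tree(st, min_leaves = 2, expected_case_fraction = 0.5)
  expect_equal(sc$infant_oriented[match(6, sc$node)], TRUE)
  expect_equal(sc$infant_oriented[match(5, sc$node)], FALSE)
})

test_that("clade-unique gene extraction honours the in/out thresholds", {
  m <- rbind(core = rep(1, 10),
             uniq = c(rep(1, 4), rep(0, 6)),
             near = c(1, 1, 1, 0, rep(0, 6)),
             leak = c(rep(1, 4), 1, rep(0, 5)))
  colnames(m) <- paste0("g", 1:10)
  clade <- paste0("g", 1:4)
  ug <- clade_unique_genes(m, clade, in_min = 0.95, out_max = 0.05)
  expect_equal(ug$genes, "uniq")       # core fails out_max, near fails in_min,
                                       # leak fails out_max (1/6 > 0.05)
  ug2 <- clade_unique_genes(m, clade, in_min = 0.7, out_max = 0.2)
  expect_setequal(ug2$genes, c("uniq", "near", "leak"))
  expect_error(clade_unique_genes(m, colnames(m)), "all genomes")
  expect_error(clade_unique_genes(m, "nope"), "unknown")
})

test_that("planted clade and its 223 unique genes are recovered from synthetic data", {
  fx <- default_fixture()
  st <- generate_strain_data(fx$cohort, fx$cfg)
  ug <- clade_unique_genes(st$gpm, st$clade_genomes)
  expect_equal(length(ug$genes), 223)
  expect_setequal(ug$genes, st$unique_genes)
  tr <- build_tree(gene_content_distance(st$gpm),
                   annotations = st$genome_map)
  sc <- scan_tree(tr, expected_case_fraction = 0.5)
  top <- attr(sc, "tip_sets")[[as.character(sc$node[1])]]
  extra <- length(setdiff(top, st$clade_genomes)) +
    length(setdiff(st$clade_genomes, top))
  expect_lte(extra, 1)
})

test_that("term enrichment ranks a fully-enriched term first and is one-sided", {
  ann <- data.frame(gene = c(paste0("g", 1:5), paste0("g", 6:50)),
                    term = c(rep("adhesion", 5), rep("other", 45)))
  res <- term_enrichment(paste0("g", 1:5), ann)
  expect_equal(res$term[1], "adhesion")
  expect_lt(res$p_value[1], 1e-5)
  # zero-overlap term: p = 1 under the one-sided convention
  expect_equal(res$p_value[res$term == "other"], 1)
  # random queries give roughly uniform p
  set.seed(77)
  ps <- replicate(200, {
    q <- sample(paste0("g", 1:50), 5)
    term_enrichment(q, ann)$p_value[1]
  })
  expect_gt(mean(ps > 0.2), 0.5)  # not systematically small
  expect_error(term_enrichment("gX", ann), "no query gene")
})
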