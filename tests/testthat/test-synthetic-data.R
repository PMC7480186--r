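test_that("identical seeds give bit-identical studies and truth", {
  s1 <- generate_dual_study(small_config(seed = 7))
  s2 <- generate_dual_study(small_config(seed = 7))
  expect_identical(s1$array$values, s2$array$values)
  expect_identical(s1$rnaseq$values, s2$rnaseq$values)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_dual_study(small_config(seed = 8))
  expect_false(identical(s1$array$values, s3$array$values))
})

test_that("platform structure matches the generating model", {
  sim <- generate_dual_study(small_config(seed = 2))
  expect_true(all(sim$array$values >= 0))
  expect_identical(sim$rnaseq$values, round(sim$rnaseq$values))
  expect_identical(rownames(sim$array$values), rownames(sim$rnaseq$values))
  expect_setequal(unique(sim$array$samples$group), c("case", "control"))
  expect_equal(table(sim$rnaseq$samples$group)[["case"]], 8)
  expect_equal(table(sim$rnaseq$samples$group)[["control"]], 12)
  expect_equal(unique(sim$array$samples$study), "array_study")
})

test_that("truth bookkeeping follows the configured rates", {
  cfg <- small_config(seed = 3, n_genes = 20000, de_fraction = 0.2,
                      discordant_fraction = 0.1)
  sim <- generate_dual_study(cfg)
  tr <- sim$truth
  nde <- sum(tr$is_de)
  # binomial error around the configured fraction
  se <- sqrt(0.2 * 0.8 / cfg$n_genes)
  expect_lt(abs(nde / cfg$n_genes - 0.2), 4 * se)
  # non-DE genes carry zero effect on both platforms
  expect_true(all(tr$true_lfc_array[!tr$is_de] == 0))
  expect_true(all(tr$true_lfc_rnaseq[!tr$is_de] == 0))
  # every DE gene has a nonzero effect on at least one platform
  expect_true(all(tr$true_lfc_array[tr$is_de] != 0 |
                    tr$true_lfc_rnaseq[tr$is_de] != 0))
  # discordance rate among DE genes
  disc <- sign(tr$true_lfc_array[tr$is_de]) != sign(tr$true_lfc_rnaseq[tr$is_de])
  se_d <- sqrt(0.1 * 0.9 / nde)
  expect_lt(abs(mean(disc) - 0.1), 4 * se_d)
  # mean |lfc| of DE genes close to the configured mean
  m <- mean(abs(tr$true_lfc_array[tr$is_de]))
  expect_lt(abs(m - cfg$lfc_mean), 3 * cfg$lfc_sd / sqrt(nde) + 0.01)
})

test_that("a null configuration yields no DE truth and uniform p-values", {
  cfg <- simulation_config(n_genes = 10000, de_fraction = 0, seed = 11)
  sim <- generate_dual_study(cfg)
  expect_equal(sum(sim$truth$is_de), 0)
  f <- filter_absent(sim$array, sim$rnaseq)
  de_arr <- run_de(vst_array(f$a))
  de_rna <- run_de(log_cpm(f$b))
  expect_gt(stats::ks.test(de_arr$p, "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(de_rna$p, "punif")$p.value, 0.01)
})

test_that("degenerate simulator inputs are rejected", {
  expect_error(simulation_config(group_sizes = c(1, 10, 8, 12)), ">= 2")
  expect_error(simulation_config(de_fraction = 1.5), "proportions")
  expect_error(simulation_config(nb_dispersion = NaN), "finite")
  expect_error(simulation_config(group_sizes = c(8, 10, 8)), "length 4")
})

test_that("dropout genes are absent in more than 80% of pooled samples", {
  cfg <- small_config(seed = 5, dropout_fraction = 0.02)
  sim <- generate_dual_study(cfg)
  pooled_zero <- rowMeans(cbind(sim$array$values == 0,
                                sim$rnaseq$values == 0))
  expect_gte(sum(pooled_zero > 0.8), round(0.02 * cfg$n_genes))
})

test_that("gene-set generator honours sizes and planted enrichment odds", {
  univ <- sprintf("u%04d", 1:100)
  gs <- generate_gene_sets(univ, n_sets = 8, set_size_range = c(10, 10),
                           seed = 4)
  expect_true(all(lengths(gs$sets) == 10))
  expect_error(generate_gene_sets(univ, enrichment_odds = 0), "odds")
  expect_error(generate_gene_sets(univ, set_size_range = c(10, 500)),
               "exceed")

  # odds 20 at 50% DE prevalence -> expected DE share near 20/21
  univ2 <- sprintf("u%04d", 1:2000)
  truth <- data.frame(gene = univ2, is_de = rep(c(TRUE, FALSE), 1000))
  gs2 <- generate_gene_sets(univ2, n_sets = 40, set_size_range = c(50, 50),
                            enrich_truth = truth, enriched_sets = 40,
                            enrichment_odds = 20, seed = 6)
  share <- mean(vapply(gs2$sets, function(s)
    mean(s %in% truth$gene[truth$is_de]), numeric(1)))
  expect_lt(abs(share - 20 / 21), 0.02)
})

test_that("gene-set generator is deterministic and GMT-serializable", {
  univ <- sprintf("u%03d", 1:50)
  g1 <- generate_gene_sets(univ, n_sets = 5, set_size_range = c(5, 15),
                           seed = 9)
  g2 <- generate_gene_sets(univ, n_sets = 5, set_size_range = c(5, 15),
                           seed = 9)
  expect_identical(g1$sets, g2$sets)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(g1, path)
  back <- read_gmt(path)
  expect_identical(back$sets, g1$sets)
})

test_that("PPI generator produces connected scale-free-style graphs", {
  univ <- sprintf("u%04d", 1:500)
  tree <- generate_ppi(univ, attachment = 1, seed = 3)
  expect_equal(nrow(tree$edges), length(univ) - 1)
  g <- igraph::graph_from_data_frame(tree$edges, directed = FALSE)
  expect_true(igraph::is_connected(g))

  net <- generate_ppi(univ, attachment = 3, seed = 3)
  g3 <- igraph::graph_from_data_frame(net$edges, directed = FALSE)
  expect_true(igraph::is_connected(g3))
  expect_gte(max(igraph::degree(g3)), 3)
  expect_identical(generate_ppi(univ, attachment = 3, seed = 3)$edges,
                   net$edges)
  expect_error(generate_ppi(character(0)), "empty")
  expect_error(generate_ppi(univ[1:2], attachment = 2), "larger")
})

test_that("preferential attachment is heavier-tailed than an ER graph", {
  univ <- sprintf("u%04d", 1:1000)
  pa <- generate_ppi(univ, attachment = 2, seed = 9)
  deg_pa <- sort(table(c(pa$edges$from, pa$edges$to)), decreasing = TRUE)
  share_pa <- sum(utils::head(deg_pa, 10)) / sum(deg_pa)
  set.seed(10)
  shares_er <- replicate(5, {
    er <- igraph::sample_gnm(1000, nrow(pa$edges))
    dg <- sort(igraph::degree(er), decreasing = TRUE)
    sum(utils::head(dg, 10)) / sum(dg)
  })
  expect_gt(share_pa, max(shares_er))
})
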