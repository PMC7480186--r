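# Minimal DEResult stand-in for join/direction tests.
fake_de <- function(gene, p, direction) {
  data.frame(gene = gene, p = p, direction = direction,
             stringsAsFactors = FALSE)
}

test_that("the Fisher statistic and its chi-square(4) tail are exact", {
  fc <- fisher_combine(matrix(c(0.05, 0.05), 1, 2))
  expect_equal(fc$F_abs, -4 * log(0.05))
  expect_equal(fc$F_abs, 11.98293, tolerance = 1e-6)
  expect_equal(fc$p_comb, 0.01748, tolerance = 1e-4)

  f <- c(0, 0.5, 2, 11.98293, 40.355, 83.5)
  expect_equal(fisher_tail_2study(f),
               stats::pchisq(f, df = 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(fisher_tail_2study(-1), "non-negative")
  expect_error(fisher_combine(matrix(c(0, 0.5), 1, 2)), "\\(0, 1\\]")
})

test_that("stronger per-study evidence gives stronger combined evidence", {
  p <- cbind(seq(0.001, 0.9, length.out = 50), 0.3)
  fc <- fisher_combine(p)
  expect_true(all(diff(fc$F_abs) < 0))
  expect_true(all(diff(fc$p_comb) > 0))
})

test_that("study join keeps shared genes and floors zero p-values", {
  d1 <- fake_de(c("a", "b", "c"), c(0.1, 0.2, 0.3), c("up", "up", "down"))
  d2 <- fake_de(c("b", "c", "d"), c(0.4, 0.5, 0.6), c("up", "down", "up"))
  pv <- study_pvalues(d1, d2)
  expect_identical(pv$gene, c("b", "c"))
  expect_equal(attr(pv, "n_excluded"), 2L)
  expect_equal(pv$p, cbind(c(0.2, 0.3), c(0.4, 0.5)))

  d1z <- fake_de("a", 0, "up")
  d2z <- fake_de("a", 0.5, "up")
  expect_warning(pvz <- study_pvalues(d1z, d2z), "floored")
  expect_equal(pvz$p[1, 1], 1e-300)
  expect_error(study_pvalues(d1, fake_de("zz", 0.1, "up")), "shared")
})

test_that("consensus direction follows the smaller-p rule and sign convention", {
  d1 <- fake_de(c("a", "b", "c", "d"), c(0.01, 0.50, 0.20, 0.30),
                c("up", "up", "down", "up"))
  d2 <- fake_de(c("a", "b", "c", "d"), c(0.20, 0.01, 0.20, 0.30),
                c("up", "down", "down", "down"))
  pv <- study_pvalues(d1, d2)
  fc <- fisher_combine(pv)
  expect_message(dir <- assign_direction(pv, fc$F_abs), "ambiguous")
  # a: concordant up; b: discordant, study 2 wins (down); c: concordant
  # down; d: discordant with exactly tied p -> ambiguous
  expect_identical(dir$effect, c("Up-regulated", "Down-regulated",
                                 "Down-regulated", "ambiguous"))
  expect_identical(dir$concordant, c(TRUE, FALSE, TRUE, FALSE))
  # up-regulated genes carry negative signed statistics
  expect_lt(dir$F_g[1], 0)
  expect_gt(dir$F_g[2], 0)
  expect_true(is.na(dir$F_g[4]))
  expect_equal(abs(dir$F_g[1:3]), fc$F_abs[1:3])
})

test_that("meta records chain combination, direction and BH coherently", {
  set.seed(1)
  g <- sprintf("g%03d", 1:200)
  d1 <- fake_de(g, runif(200), sample(c("up", "down"), 200, TRUE))
  d2 <- fake_de(g, runif(200), sample(c("up", "down"), 200, TRUE))
  rec <- meta_records(d1, d2)
  expect_equal(rec$p_comb_adj, bh_adjust(rec$p_comb))
  expect_equal(rec$p_comb, fisher_tail_2study(rec$F_abs), tolerance = 1e-12)
  expect_true(all(abs(rec$F_g[rec$effect != "ambiguous"]) ==
                    rec$F_abs[rec$effect != "ambiguous"]))

  sig <- call_meta_genes(rec, alpha = 0.5)
  expect_true(all(sig$p_comb_adj < 0.5))
  expect_true(!is.unsorted(sig$p_comb_adj))
  raw <- call_meta_genes(rec, alpha = 0.5, use_adjusted = FALSE)
  expect_true(all(raw$p_comb < 0.5))
  expect_gte(nrow(raw), nrow(sig))
})

test_that("combined p-values are calibrated under the two-study null", {
  set.seed(11)
  p <- matrix(runif(20000), 10000, 2)
  fc <- fisher_combine(p)
  expect_lt(abs(mean(fc$p_comb < 0.05) - 0.05), 0.007)
  ks <- stats::ks.test(fc$F_abs, stats::pchisq, df = 4)
  expect_gt(ks$p.value, 0.01)
})

test_that("overlap bookkeeping partitions the union of the three sets", {
  vc <- venn_counts(c("a", "b", "c"), c("b", "c", "d"),
                    c("c", "d", "e", "f"))
  expect_equal(vc$only1, 1)        # a
  expect_equal(vc$only2, 0)
  expect_equal(vc$only_meta, 2)    # e, f
  expect_equal(vc$s1_s2, 1)        # b
  expect_equal(vc$s1_meta, 0)
  expect_equal(vc$s2_meta, 1)      # d
  expect_equal(vc$all3, 1)         # c
  total <- vc$only1 + vc$only2 + vc$only_meta + vc$s1_s2 + vc$s1_meta +
    vc$s2_meta + vc$all3
  expect_equal(total, 6)           # |{a..f}|
  expect_equal(vc$newly_detected, 2)
})

test_that("meta tables round-trip through write_meta_table", {
  set.seed(2)
  g <- sprintf("g%03d", 1:50)
  d1 <- fake_de(g, runif(50), sample(c("up", "down"), 50, TRUE))
  d2 <- fake_de(g, runif(50), sample(c("up", "down"), 50, TRUE))
  rec <- meta_records(d1, d2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_meta_table(rec, path, comments = "demo")
  back <- utils::read.delim(path, comment.char = "#")
  expect_identical(back$gene, rec$gene)
  expect_equal(back$p_comb, rec$p_comb, tolerance = 1e-4)
})

test_that("printed-precision helpers parse both decimal and E formats", {
  expect_equal(printed_ulp(c("1.72E-05", "0.00019", "0.00287", "9.48E-10")),
               c(1e-7, 1e-5, 1e-5, 1e-12))
  expect_equal(round_to_printed(0.0001934, "0.00019"), 0.00019)
  expect_equal(round_to_printed(1.7249e-5, "1.72E-05"), 1.72e-5)
})

test_that("top-rank BH reconstruction matches full-table BH", {
  set.seed(3)
  p1 <- runif(5000)^2
  F_abs <- -2 * (log(p1) + log(runif(5000)))
  o <- order(-F_abs)
  full <- bh_adjust(fisher_tail_2study(F_abs))
  # supplying the complete sorted table reproduces the step-up exactly
  expect_equal(bh_from_fisher_top(F_abs[o], 5000), full[o],
               tolerance = 1e-12)
  expect_error(bh_from_fisher_top(c(1, 2), 100), "descending")
})

test_that("the effective test count is recoverable from printed triples", {
  set.seed(4)
  m_true <- 5000
  F_all <- sort(-2 * rowSums(log(matrix(runif(2 * m_true), m_true))),
                decreasing = TRUE)
  # separate the top 20 clearly, as in a real outlier-dominated table, so
  # the full-table step-up is determined locally at these ranks
  F_all[1:20] <- F_all[1:20] + seq(40, 4, length.out = 20)
  adj <- bh_adjust(fisher_tail_2study(F_all))[1:20]
  printed <- sprintf("%.3G", adj)
  fit <- infer_effective_tests(F_all[1:20], printed,
                               m_range = c(4000L, 6000L))
  expect_equal(fit$n_matched, 20)
  expect_lt(abs(fit$m - m_true), 150)
  expect_gte(fit$m_candidates[1], 4000)
})

test_that("the bundled published tables have the documented shape", {
  for (region in c("macular", "nonmacular")) {
    tb <- published_meta_top20(region)
    expect_equal(nrow(tb), 20)
    expect_identical(tb$rank, 1:20)
    expect_true(!is.unsorted(rev(tb$F_abs)))
    expect_true(all(tb$effect %in% c("Up-regulated", "Down-regulated")))
    expect_true(all((tb$F_g < 0) == (tb$effect == "Up-regulated")))
    expect_false(any(is.na(as.numeric(tb$p_printed))))
  }
})
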