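test_that("fit_groups matches the per-gene lm oracle", {
  set.seed(1)
  x <- matrix(rnorm(50 * 9, 8), 50, 9)
  grp <- rep(c("case", "control"), c(4, 5))
  st <- make_study(x, groups = grp)
  fg <- fit_groups(st)
  for (g in c(1, 17, 50)) {
    fit <- stats::lm(x[g, ] ~ factor(grp, levels = c("control", "case")))
    expect_equal(fg$effect[g], unname(stats::coef(fit)[2]), tolerance = 1e-12)
    expect_equal(fg$s2[g], summary(fit)$sigma^2, tolerance = 1e-12)
  }
  expect_equal(unique(fg$df), 7)
  expect_identical(attr(fg, "n_case"), 4L)
  expect_identical(attr(fg, "n_control"), 5L)
  expect_error(fit_groups(make_study(x, groups = rep(c("case", "control"),
                                                     c(1, 8)))),
               ">= 2")
})

test_that("a zero-weight prior reproduces the ordinary pooled t-test", {
  set.seed(2)
  x <- matrix(rnorm(20 * 10), 20, 10)
  grp <- rep(c("case", "control"), each = 5)
  fg <- fit_groups(make_study(x, groups = grp))
  mt <- moderated_test(fg$effect, fg$s2, fg$df[1],
                       structure(list(d0 = 0, s0sq = 1), class = "EBPrior"),
                       5, 5)
  for (g in c(3, 11)) {
    tt <- stats::t.test(x[g, grp == "case"], x[g, grp == "control"],
                        var.equal = TRUE)
    expect_equal(mt$t_mod[g], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(mt$p[g], tt$p.value, tolerance = 1e-12)
  }
})

test_that("variance shrinkage follows the posterior formula", {
  prior <- structure(list(d0 = 4, s0sq = 2), class = "EBPrior")
  mt <- moderated_test(effect = 1, s2 = 6, df = 8, prior,
                       n_case = 5, n_control = 5)
  s2_post <- (4 * 2 + 8 * 6) / 12
  expect_equal(mt$t_mod, 1 / sqrt(s2_post * 0.4))
  expect_equal(mt$p, 2 * stats::pt(-abs(mt$t_mod), df = 12))

  # infinite prior weight: all variances collapse to s0sq, normal reference
  pr_inf <- structure(list(d0 = Inf, s0sq = 2), class = "EBPrior")
  mt_inf <- moderated_test(1, 6, 8, pr_inf, 5, 5)
  expect_equal(mt_inf$t_mod, 1 / sqrt(2 * 0.4))
  expect_equal(mt_inf$p, 2 * stats::pnorm(-abs(mt_inf$t_mod)))

  expect_error(moderated_test(1, 6, 8, list(d0 = -1, s0sq = 2), 5, 5),
               "prior")
})

test_that("prior estimation handles point masses and scales correctly", {
  pm <- estimate_prior(rep(2.5, 100), df = 6)
  expect_identical(pm$d0, Inf)
  expect_equal(pm$s0sq, 2.5)

  set.seed(3)
  s2 <- 2 * rchisq(5000, 8) / 8 * (4 / rchisq(5000, 4))
  p1 <- estimate_prior(s2, df = 8)
  p2 <- estimate_prior(2 * s2, df = 8)
  expect_equal(p2$d0, p1$d0, tolerance = 1e-10)
  expect_equal(p2$s0sq, 2 * p1$s0sq, tolerance = 1e-10)

  expect_error(estimate_prior(rep(1, 5), df = 6), ">= 10")
  expect_error(estimate_prior(rep(1, 100), df = 0.5), "df")
  expect_error(estimate_prior(rep(0, 100), df = 6), "zero")
})

test_that("the prior hyperparameters are recovered from a known hierarchy", {
  set.seed(4)
  n <- 20000; d0 <- 4; s0sq <- 2; df <- 10
  sigma2 <- s0sq * d0 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, df) / df
  pr <- estimate_prior(s2, df)
  expect_gt(pr$d0, 3.4); expect_lt(pr$d0, 4.6)
  expect_gt(pr$s0sq, 1.8); expect_lt(pr$s0sq, 2.2)
})

test_that("the full moderated pipeline agrees with the limma reference", {
  set.seed(42)
  n <- 3000; n1 <- 6; n2 <- 8
  x <- matrix(rnorm(n * (n1 + n2), 8, sqrt(rchisq(n, 4) / 4)), n, n1 + n2)
  rownames(x) <- sprintf("g%04d", 1:n)
  grp <- rep(c("case", "control"), c(n1, n2))
  de <- run_de(make_study(x, groups = grp))
  design <- stats::model.matrix(~ 0 + factor(grp, levels = c("control",
                                                             "case")))
  colnames(design) <- c("control", "case")
  fit <- limma::lmFit(x, design)
  fit <- limma::contrasts.fit(fit, limma::makeContrasts(case - control,
                                                        levels = design))
  fit <- limma::eBayes(fit)
  pr <- attr(de, "prior")
  expect_equal(pr$d0, fit$df.prior, tolerance = 1e-8)
  expect_equal(pr$s0sq, fit$s2.prior, tolerance = 1e-8)
  expect_equal(de$t_mod, unname(fit$t[, 1]), tolerance = 1e-10)
  expect_equal(de$p, unname(fit$p.value[, 1]), tolerance = 1e-10)
  expect_equal(de$p_adj, unname(stats::p.adjust(fit$p.value[, 1], "BH")),
               tolerance = 1e-10)
})

test_that("BH adjustment matches the quadratic-time step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-14)
  }
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_true(all(bh_adjust(runif(100)) <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("BH is monotone: ordering of adjusted follows ordering of raw", {
  set.seed(6)
  p <- runif(200)
  q <- bh_adjust(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
  expect_true(all(q >= p - 1e-15))
})

test_that("directions track the effect sign and zero effects warn", {
  set.seed(7)
  x <- matrix(rnorm(30 * 8), 30, 8)
  grp <- rep(c("case", "control"), each = 4)
  de <- run_de(make_study(x, groups = grp))
  expect_identical(de$direction, ifelse(de$effect > 0, "up", "down"))
  expect_true(all(de$p_adj >= de$p - 1e-15))

  x0 <- x
  x0[1, ] <- 5  # constant gene: zero effect
  expect_warning(de0 <- run_de(make_study(x0, groups = grp)), "zero effect")
  expect_identical(de0$direction[1], "down")
})

test_that("DE tables round-trip through write_de", {
  set.seed(8)
  x <- matrix(rnorm(20 * 8), 20, 8)
  de <- run_de(make_study(x, groups = rep(c("case", "control"), each = 4)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_de(de, path)
  back <- utils::read.delim(path)
  expect_identical(back$gene, de$gene)
  expect_equal(back$p_adj, de$p_adj, tolerance = 1e-10)
})
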