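#' Per-gene two-group summary statistics
#'
#' Fits the standard two-group linear model gene by gene on the normalized
#' scale: effect = mean(case) - mean(control), pooled within-group
#' variance, and residual degrees of freedom `n_case + n_control - 2`.
#'
#' @param study a normalized [expression_study()].
#' @param contrast length-2 character vector `(case_label, control_label)`
#'   matched against `study$samples$group`.
#' @return data frame with columns `gene`, `effect`, `s2`, `df`, plus
#'   attributes `n_case` and `n_control`.
#' @export
fit_groups <- function(study, contrast = c("case", "control")) {
  stopifnot(inherits(study, "ExpressionStudy"))
  grp <- study$samples$group
  i1 <- which(grp == contrast[1])
  i2 <- which(grp == contrast[2])
  if (length(i1) < 2 || length(i2) < 2)
    stop("each group needs >= 2 samples (found ", length(i1), " and ",
         length(i2), ")")
  x1 <- study$values[, i1, drop = FALSE]
  x2 <- study$values[, i2, drop = FALSE]
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2
  out <- data.frame(gene = rownames(study$values), effect = m1 - m2,
                    s2 = (ss1 + ss2) / df, df = df,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_case") <- n1
  attr(out, "n_control") <- n2
  out
}

## Newton solve of trigamma(y) = x (x > 0), vectorized; used by the
## moment-matching prior estimator.
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Estimate the empirical-Bayes variance prior
#'
#' Moment-matching of `log s^2` against the scaled-F model underlying
#' variance moderation: the empirical variance of `log s^2` in excess of
#' `trigamma(df/2)` determines the prior degrees of freedom `d0` through
#' the trigamma function, and the mean determines the prior variance
#' `s0sq` after digamma bias correction. When the empirical spread does
#' not exceed the pure sampling contribution `trigamma(df/2)`, `d0 = Inf`
#' is returned (all genes share one variance).
#'
#' @param s2 per-gene residual variances (>= 10 values).
#' @param df residual degrees of freedom (scalar, >= 1).
#' @return list of class `EBPrior` with elements `d0` and `s0sq`.
#' @export
estimate_prior <- function(s2, df) {
  if (length(s2) < 10) stop("need >= 10 genes to estimate the prior")
  if (df < 1) stop("df must be >= 1")
  if (all(s2 == 0)) stop("all residual variances are zero")
  pos <- s2 > 0
  z <- log(s2[pos])
  if (max(z) - min(z) < 1e-12) {
    ## exact point mass: no spread at all, so no sampling-noise correction
    return(structure(list(d0 = Inf, s0sq = exp(z[1])), class = "EBPrior"))
  }
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (evar <= 0) {
    d0 <- Inf
    s0sq <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0sq = s0sq), class = "EBPrior")
}

#' Moderated t-test
#'
#' Shrinks each gene's variance toward the prior,
#' `s2_post = (d0 * s0sq + df * s2) / (d0 + df)`, forms
#' `t = effect / sqrt(s2_post * (1/n1 + 1/n2))` and refers it to a t
#' distribution with `d0 + df` degrees of freedom (a normal reference when
#' `d0 = Inf`). `d0 = 0` reproduces the ordinary pooled two-sample t-test.
#'
#' @param effect,s2,df per-gene output of [fit_groups()].
#' @param prior an `EBPrior` from [estimate_prior()].
#' @param n_case,n_control group sizes.
#' @return data frame with columns `t_mod` and `p` (two-sided).
#' @export
moderated_test <- function(effect, s2, df, prior, n_case, n_control) {
  d0 <- prior$d0; s0sq <- prior$s0sq
  if (is.null(d0) || is.null(s0sq) || d0 < 0 || s0sq <= 0)
    stop("invalid prior")
  s2_post <- if (is.infinite(d0)) rep(s0sq, length(s2))
             else (d0 * s0sq + df * s2) / (d0 + df)
  se <- sqrt(s2_post * (1 / n_case + 1 / n_control))
  t_mod <- effect / se
  df_tot <- d0 + df
  p <- if (is.infinite(df_tot)) 2 * stats::pnorm(-abs(t_mod))
       else 2 * stats::pt(-abs(t_mod), df = df_tot)
  data.frame(t_mod = t_mod, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1, returned in the input
#' order.
#'
#' @param p raw p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1 | !is.finite(p)))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Per-study differential expression with variance moderation
#'
#' Convenience wrapper chaining [fit_groups()], [estimate_prior()],
#' [moderated_test()] and [bh_adjust()] into one per-gene table. Genes with
#' effect exactly zero are assigned direction `"down"` (a deterministic tie
#' rule that only arises on degenerate input) with a warning.
#'
#' @param study a normalized [expression_study()].
#' @param contrast `(case_label, control_label)`.
#' @return data frame of class `DEResult`: `gene`, `effect`, `s2`, `df`,
#'   `t_mod`, `p`, `p_adj`, `direction`; the prior is attached as attribute
#'   `prior`.
#' @export
run_de <- function(study, contrast = c("case", "control")) {
  fg <- fit_groups(study, contrast)
  prior <- estimate_prior(fg$s2, fg$df[1])
  mt <- moderated_test(fg$effect, fg$s2, fg$df[1], prior,
                       attr(fg, "n_case"), attr(fg, "n_control"))
  if (any(fg$effect == 0))
    warning(sum(fg$effect == 0),
            " gene(s) with zero effect assigned direction 'down'")
  out <- data.frame(fg, t_mod = mt$t_mod, p = mt$p,
                    p_adj = bh_adjust(mt$p),
                    direction = ifelse(fg$effect > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  attr(out, "prior") <- prior
  attr(out, "n_case") <- attr(fg, "n_case")
  attr(out, "n_control") <- attr(fg, "n_control")
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Write a per-study DE table
#' @param de a `DEResult`.
#' @param path output TSV path.
#' @export
write_de <- function(de, path) {
  utils::write.table(de[, c("gene", "effect", "t_mod", "p", "p_adj",
                            "direction")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
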