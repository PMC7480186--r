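#' Assemble per-study p-values and directions for meta-analysis
#'
#' Joins two per-study DE tables on gene id; genes missing from either
#' study are excluded (their count is attached as attribute `n_excluded`).
#' Raw p-values of exactly zero are floored at 1e-300 with a warning so the
#' Fisher log never sees zero.
#'
#' @param de1,de2 `DEResult` tables from [run_de()].
#' @return list of class `StudyPValueMatrix`: `gene`, `p` (genes x 2
#'   matrix), `direction` (genes x 2 character matrix), `S = 2`.
#' @export
study_pvalues <- function(de1, de2) {
  common <- intersect(de1$gene, de2$gene)
  n_excluded <- length(union(de1$gene, de2$gene)) - length(common)
  if (length(common) == 0) stop("no genes shared between the DE tables")
  i1 <- match(common, de1$gene)
  i2 <- match(common, de2$gene)
  p <- cbind(de1$p[i1], de2$p[i2])
  if (any(p == 0)) {
    warning(sum(p == 0), " zero p-value(s) floored at 1e-300")
    p[p == 0] <- 1e-300
  }
  if (any(p < 0 | p > 1)) stop("p-values outside [0, 1]")
  out <- list(gene = common, p = p,
              direction = cbind(de1$direction[i1], de2$direction[i2]),
              S = 2L)
  attr(out, "n_excluded") <- n_excluded
  class(out) <- "StudyPValueMatrix"
  out
}

#' Fisher combination of per-study p-values
#'
#' `|F_g| = -2 * sum_s ln(P_gs)`, referred to the upper tail of the
#' chi-square distribution with `2S` degrees of freedom.
#'
#' @param pvals a `StudyPValueMatrix` (or a plain numeric matrix of
#'   per-study p-values in `(0, 1]`).
#' @return data frame with `gene` (when available), `F_abs` and `p_comb`.
#' @export
fisher_combine <- function(pvals) {
  p <- if (inherits(pvals, "StudyPValueMatrix")) pvals$p else as.matrix(pvals)
  if (any(p <= 0 | p > 1)) stop("per-study p-values must lie in (0, 1]")
  F_abs <- -2 * rowSums(log(p))
  p_comb <- stats::pchisq(F_abs, df = 2 * ncol(p), lower.tail = FALSE)
  out <- data.frame(F_abs = F_abs, p_comb = p_comb)
  if (inherits(pvals, "StudyPValueMatrix")) out <- cbind(gene = pvals$gene, out)
  out
}

#' Closed-form chi-square(4) upper tail
#'
#' For two studies the Fisher statistic is chi-square with 4 degrees of
#' freedom, whose upper tail has the closed form
#' `(1 + F/2) * exp(-F/2)`.
#'
#' @param F_abs non-negative Fisher statistic(s).
#' @return upper-tail probabilities.
#' @export
fisher_tail_2study <- function(F_abs) {
  if (any(F_abs < 0)) stop("F must be non-negative")
  (1 + F_abs / 2) * exp(-F_abs / 2)
}

#' Consensus direction and signed Fisher statistic
#'
#' When the studies agree the shared direction is used (`concordant =
#' TRUE`); when they disagree the direction of the study with the smaller
#' raw p wins (`concordant = FALSE`). Exactly tied p-values with opposite
#' directions are marked `"ambiguous"` (such genes are excluded from
#' pathway and network stages). The reporting convention signs the Fisher
#' statistic negative for up-regulated genes and positive for
#' down-regulated ones.
#'
#' @param pvals a `StudyPValueMatrix`.
#' @param F_abs unsigned Fisher statistics aligned with `pvals$gene`.
#' @return data frame: `gene`, `effect` (`"Up-regulated"`,
#'   `"Down-regulated"` or `"ambiguous"`), `concordant`, `F_g` (signed; NA
#'   for ambiguous genes).
#' @export
assign_direction <- function(pvals, F_abs) {
  stopifnot(inherits(pvals, "StudyPValueMatrix"))
  d <- pvals$direction
  p <- pvals$p
  agree <- d[, 1] == d[, 2]
  winner <- ifelse(p[, 1] <= p[, 2], d[, 1], d[, 2])
  cons <- ifelse(agree, d[, 1], winner)
  ambiguous <- !agree & p[, 1] == p[, 2]
  effect <- ifelse(ambiguous, "ambiguous",
                   ifelse(cons == "up", "Up-regulated", "Down-regulated"))
  if (any(ambiguous))
    message(sum(ambiguous),
            " gene(s) with tied opposite evidence marked ambiguous")
  F_g <- ifelse(effect == "Up-regulated", -F_abs,
                ifelse(effect == "Down-regulated", F_abs, NA_real_))
  data.frame(gene = pvals$gene, effect = effect, concordant = agree,
             F_g = F_g, stringsAsFactors = FALSE)
}

#' Build the full meta-gene record table
#'
#' Combines [fisher_combine()], [assign_direction()] and [bh_adjust()].
#'
#' @param de1,de2 per-study `DEResult` tables.
#' @return data frame of class `MetaGeneTable`: `gene`, `F_g` (signed),
#'   `F_abs`, `p_comb`, `p_comb_adj`, `effect`, `concordant`.
#' @export
meta_records <- function(de1, de2) {
  pv <- study_pvalues(de1, de2)
  fc <- fisher_combine(pv)
  dir <- assign_direction(pv, fc$F_abs)
  out <- data.frame(gene = pv$gene, F_g = dir$F_g, F_abs = fc$F_abs,
                    p_comb = fc$p_comb, p_comb_adj = bh_adjust(fc$p_comb),
                    effect = dir$effect, concordant = dir$concordant,
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- attr(pv, "n_excluded")
  class(out) <- c("MetaGeneTable", "data.frame")
  out
}

#' Call significant meta-genes
#'
#' Genes whose (BH-adjusted, by default) combined p-value falls below
#' `alpha`, sorted by adjusted p ascending and `|F_g|` descending. The
#' printed values of published meta-gene tables of this design are
#' BH-adjusted, hence `use_adjusted = TRUE` by default; set `FALSE` for
#' the raw-p reading of the 0.05 rule.
#'
#' @param records a `MetaGeneTable` from [meta_records()].
#' @param alpha significance threshold.
#' @param use_adjusted compare `alpha` against adjusted (TRUE) or raw
#'   combined p-values.
#' @return the significant subset, sorted.
#' @export
call_meta_genes <- function(records, alpha = 0.05, use_adjusted = TRUE) {
  pcol <- if (use_adjusted) records$p_comb_adj else records$p_comb
  sig <- records[pcol < alpha, , drop = FALSE]
  sig[order(if (use_adjusted) sig$p_comb_adj else sig$p_comb, -sig$F_abs), ]
}

#' Three-set overlap bookkeeping
#'
#' Region sizes of the Venn diagram over the two per-study DE sets and the
#' meta-gene set, plus the count of meta-genes detected by neither single
#' study.
#'
#' @param study1_de,study2_de,meta_set character vectors of gene ids.
#' @return list of class `OverlapCounts` with the seven region sizes
#'   (`only1`, `only2`, `only_meta`, `s1_s2`, `s1_meta`, `s2_meta`, `all3`)
#'   and `newly_detected`.
#' @export
venn_counts <- function(study1_de, study2_de, meta_set) {
  s1 <- unique(study1_de); s2 <- unique(study2_de); mm <- unique(meta_set)
  in1 <- function(g) g %in% s1
  in2 <- function(g) g %in% s2
  inm <- function(g) g %in% mm
  univ <- unique(c(s1, s2, mm))
  r <- c(only1 = sum(in1(univ) & !in2(univ) & !inm(univ)),
         only2 = sum(!in1(univ) & in2(univ) & !inm(univ)),
         only_meta = sum(!in1(univ) & !in2(univ) & inm(univ)),
         s1_s2 = sum(in1(univ) & in2(univ) & !inm(univ)),
         s1_meta = sum(in1(univ) & !in2(univ) & inm(univ)),
         s2_meta = sum(!in1(univ) & in2(univ) & inm(univ)),
         all3 = sum(in1(univ) & in2(univ) & inm(univ)))
  structure(c(as.list(r),
              list(newly_detected = length(setdiff(mm, union(s1, s2))))),
            class = "OverlapCounts")
}

#' Write a meta-gene table as TSV
#' @param records a `MetaGeneTable` (or its significant subset).
#' @param path output path.
#' @param comments optional `#` comment lines.
#' @export
write_meta_table <- function(records, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  cols <- c("gene", "F_g", "p_comb", "p_comb_adj", "effect", "concordant")
  writeLines(paste(cols, collapse = "\t"), con)
  body <- as.matrix(format(records[, cols], trim = TRUE, digits = 6))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}
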