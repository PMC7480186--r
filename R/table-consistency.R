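#' Published top-20 AMD RPE/choroid meta-gene tables
#'
#' Returns the printed top-20 meta-gene table for the macular or
#' non-macular AMD-vs-control contrast bundled with the package: Entrez id,
#' symbol, signed Fisher statistic and the BH-adjusted combined p-value as
#' printed. Rows are returned sorted by `|F_g|` descending, i.e. by raw
#' combined p ascending, which is the rank order of the underlying full
#' table.
#'
#' @param region `"macular"` or `"nonmacular"`.
#' @return data frame: `entrez`, `symbol`, `F_g`, `F_abs`, `p_printed`
#'   (character, preserving the printed format), `effect`, `rank`.
#' @export
published_meta_top20 <- function(region = c("macular", "nonmacular")) {
  region <- match.arg(region)
  path <- system.file("extdata",
                      sprintf("amd_meta_top20_%s.tsv", region),
                      package = "transmeta", mustWork = TRUE)
  tb <- utils::read.delim(path, comment.char = "#",
                          colClasses = c(p_printed = "character"),
                          stringsAsFactors = FALSE)
  tb$F_abs <- abs(tb$F_g)
  tb <- tb[order(-tb$F_abs), ]
  tb$rank <- seq_len(nrow(tb))
  rownames(tb) <- NULL
  tb
}

#' Unit in the last printed significant digit
#'
#' For a printed number such as `"1.72E-05"` or `"0.00019"`, the magnitude
#' of one unit of its last significant digit — the natural agreement
#' tolerance for values reproduced at printed precision.
#'
#' @param s character vector of printed numbers.
#' @return numeric vector of last-digit units.
#' @export
printed_ulp <- function(s) {
  vapply(s, function(x) {
    x <- toupper(trimws(x))
    if (grepl("E", x, fixed = TRUE)) {
      parts <- strsplit(x, "E", fixed = TRUE)[[1]]
      mant <- parts[1]
      ex <- as.numeric(gsub(" ", "", parts[2]))
      dec <- if (grepl(".", mant, fixed = TRUE))
        nchar(strsplit(mant, ".", fixed = TRUE)[[1]][2]) else 0
      10^(ex - dec)
    } else {
      dec <- if (grepl(".", x, fixed = TRUE))
        nchar(strsplit(x, ".", fixed = TRUE)[[1]][2]) else 0
      10^(-dec)
    }
  }, numeric(1), USE.NAMES = FALSE)
}

#' Round a value to the precision of a printed number
#'
#' @param x numeric value(s).
#' @param printed printed string(s) defining the precision (recycled).
#' @return `x` rounded to the printed number's last significant digit.
#' @export
round_to_printed <- function(x, printed) {
  u <- printed_ulp(printed)
  round(x / u) * u
}

#' BH step-up adjusted values from top-ranked Fisher statistics
#'
#' Given the `k` largest two-study Fisher statistics of a table of `m`
#' genes (so their ranks are 1..k), computes the BH-adjusted combined
#' p-values `min_{j >= i} m * p_raw(F_j) / j`, where
#' `p_raw(F) = (1 + F/2) exp(-F/2)` is the chi-square(4) upper tail. The
#' running minimum is taken over the supplied ranks only; for the last
#' supplied rank this is an upper bound, since unprinted genes at ranks
#' `> k` with nearly tied raw p can pull the true step-up value further
#' down (by at most a factor `k / (k + 1)` per following near-tie).
#'
#' @param F_abs unsigned Fisher statistics, sorted descending.
#' @param m effective number of tests in the full table.
#' @return adjusted p-values for ranks `1..length(F_abs)`.
#' @export
bh_from_fisher_top <- function(F_abs, m) {
  if (is.unsorted(rev(F_abs))) stop("F_abs must be sorted descending")
  p <- fisher_tail_2study(F_abs)
  k <- seq_along(p)
  pmin(rev(cummin(rev(m * p / k))), 1)
}

#' Infer the effective test count behind a printed meta-gene table
#'
#' A published top-k meta-gene table prints BH-adjusted combined p-values
#' but not the number of genes m that entered the adjustment. Because the
#' step-up values are `m * p_raw / rank`, m can be recovered from the
#' printed (rank, F, adjusted-p) triples themselves: this routine scans an
#' integer range and returns the m that maximizes the number of rows whose
#' recomputed step-up value agrees with the printed value to within one
#' unit of its last printed digit. The final printed row is granted a
#' one-rank truncation allowance (its printed value may have been pulled
#' down by the first unprinted, nearly tied gene), making the match
#' criterion `m * p / (k+1) - ulp <= printed <= fitted + ulp` there.
#'
#' @param F_abs unsigned Fisher statistics sorted descending (ranks 1..k).
#' @param printed printed adjusted p-values as character strings, aligned
#'   with `F_abs`.
#' @param m_range length-2 integer vector, inclusive scan bounds.
#' @param exclude optional row indices ignored when scoring (e.g. to infer
#'   m without the row under test).
#' @return list: `m` (best effective test count), `n_matched`, `matched`
#'   (logical per row at the best m), `fitted` (adjusted values at the best
#'   m).
#' @export
infer_effective_tests <- function(F_abs, printed,
                                  m_range = c(17000L, 19000L),
                                  exclude = NULL) {
  stopifnot(length(F_abs) == length(printed))
  pr_num <- as.numeric(printed)
  ulp <- printed_ulp(printed)
  n <- length(F_abs)
  p_raw <- fisher_tail_2study(F_abs)
  score_m <- function(m) {
    fitted <- bh_from_fisher_top(F_abs, m)
    ok <- abs(fitted - pr_num) <= ulp + 1e-12
    ## truncation allowance for the final printed row
    low <- m * p_raw[n] / (n + 1)
    ok[n] <- ok[n] || (pr_num[n] >= low - ulp[n] - 1e-12 &&
                         pr_num[n] <= fitted[n] + ulp[n] + 1e-12)
    if (!is.null(exclude)) ok[exclude] <- NA
    ok
  }
  ms <- seq(m_range[1], m_range[2])
  best <- NULL
  for (m in ms) {
    ok <- score_m(m)
    nm <- sum(ok, na.rm = TRUE)
    if (is.null(best) || nm > best$n_matched) {
      best <- list(m = m, n_matched = nm, matched = ok,
                   fitted = bh_from_fisher_top(F_abs, m))
    }
  }
  ## prefer the central m among the equally best: rescan for the range
  ties <- ms[vapply(ms, function(m) sum(score_m(m), na.rm = TRUE),
                    numeric(1)) == best$n_matched]
  m_mid <- ties[ceiling(length(ties) / 2)]
  list(m = m_mid, n_matched = best$n_matched, matched = score_m(m_mid),
       fitted = bh_from_fisher_top(F_abs, m_mid),
       m_candidates = range(ties))
}
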