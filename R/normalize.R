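#' Normalization parameters
#'
#' @param array_method `"glog_quantile"` (generalized-log transform then
#'   quantile normalization, the default) or `"log2_offset_quantile"`
#'   (plain `log2(y + offset)` then quantile normalization, provided for
#'   sensitivity analysis).
#' @param glog_c positive glog calibration constant, or `"auto"` (the 5th
#'   percentile of positive intensities).
#' @param log_offset offset for the `log2_offset_quantile` path.
#' @param cpm_prior prior count added before the log2-CPM transform.
#' @return list of class `NormalizationConfig`.
#' @export
normalization_config <- function(array_method = c("glog_quantile",
                                                  "log2_offset_quantile"),
                                 glog_c = "auto", log_offset = 8,
                                 cpm_prior = 0.5) {
  array_method <- match.arg(array_method)
  if (!identical(glog_c, "auto") && (!is.numeric(glog_c) || glog_c <= 0))
    stop("glog_c must be positive or \"auto\"")
  if (log_offset <= 0 || cpm_prior <= 0)
    stop("log_offset and cpm_prior must be positive")
  structure(list(array_method = array_method, glog_c = glog_c,
                 log_offset = log_offset, cpm_prior = cpm_prior),
            class = "NormalizationConfig")
}

#' Generalized-log transform
#'
#' `glog2(y) = log2((y + sqrt(y^2 + c^2)) / 2)`: behaves like `log2(y)` for
#' `y >> c` but remains defined and variance-stabilizing near zero
#' (`glog2(0) = log2(c/2)`).
#'
#' @param y non-negative numeric values.
#' @param c positive calibration constant.
#' @return transformed values.
#' @export
glog2 <- function(y, c) {
  if (any(y < 0)) stop("glog2 expects non-negative values")
  if (c <= 0) stop("glog constant must be positive")
  log2((y + sqrt(y^2 + c^2)) / 2)
}

## Quantile-normalize columns of a matrix: each column's sorted values are
## replaced by the row-wise mean of the sorted columns; tied values within a
## column all receive the mean of the reference values at their tied ranks.
quantile_normalize <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    o <- order(col)
    v <- numeric(length(col))
    v[o] <- ref
    # ties: average the reference values occupying the tied ranks
    if (anyDuplicated(col)) v <- stats::ave(v, match(col, col))
    out[, j] <- v
  }
  out
}

#' Variance-stabilizing transform for array intensities
#'
#' Applies the generalized-log transform element-wise (with `c` either
#' fixed or set to the 5th percentile of positive intensities) and then
#' quantile normalization across samples, yielding log2-scale intensities
#' with identical column distributions.
#'
#' @param study a microarray [expression_study()] with non-negative values.
#' @param config a [normalization_config()].
#' @return the normalized `ExpressionStudy`; attribute `method` records the
#'   transform and its parameters.
#' @export
vst_array <- function(study, config = normalization_config()) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (study$platform != "microarray")
    stop("vst_array expects a microarray study")
  if (any(study$values < 0)) stop("negative intensities")
  if (config$array_method == "glog_quantile") {
    cc <- config$glog_c
    if (identical(cc, "auto")) {
      pos <- study$values[study$values > 0]
      cc <- as.numeric(stats::quantile(pos, 0.05))
    }
    tv <- glog2(study$values, cc)
    method <- sprintf("glog_quantile(c=%.6g)", cc)
  } else {
    tv <- log2(study$values + config$log_offset)
    method <- sprintf("log2_offset_quantile(offset=%g)", config$log_offset)
  }
  study$values <- quantile_normalize(tv)
  attr(study, "method") <- method
  study
}

#' Log2 counts-per-million transform
#'
#' `log2((count + prior) / (library_size + 2 * prior) * 1e6)` with the
#' library size taken as the column sum, placing RNA-seq counts on a
#' log2 scale comparable with normalized array intensities.
#'
#' @param study an RNA-seq [expression_study()] (integer counts).
#' @param config a [normalization_config()]; `cpm_prior` is the prior
#'   count.
#' @return the transformed `ExpressionStudy` (platform tag preserved);
#'   attribute `method` records the parameters.
#' @export
log_cpm <- function(study, config = normalization_config()) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (study$platform != "rnaseq")
    stop("log_cpm expects an rnaseq study")
  lib <- colSums(study$values)
  if (any(lib == 0)) stop("zero library size in sample(s): ",
                          paste(colnames(study$values)[lib == 0],
                                collapse = ", "))
  pr <- config$cpm_prior
  vals <- log2(sweep(study$values + pr, 2, lib + 2 * pr, `/`) * 1e6)
  out <- study
  out$values <- vals
  attr(out, "method") <- sprintf("log_cpm(prior=%g)", pr)
  out
}
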