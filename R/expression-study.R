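#' Expression study container
#'
#' A light-weight container for one platform's gene-by-sample expression
#' matrix together with its sample annotations, modelled on the plain
#' matrix-plus-targets idiom of classic differential-expression workflows.
#'
#' @param values numeric matrix, genes in rows and samples in columns. Row
#'   names are gene (or probe) identifiers, column names are sample
#'   identifiers. For `platform = "rnaseq"` the matrix must hold non-negative
#'   integers (counts).
#' @param platform `"microarray"` or `"rnaseq"`.
#' @param samples data frame of per-sample annotations with one row per
#'   column of `values`; must contain columns `sample`, `study`, `group`
#'   (values `"case"`/`"control"`) and `region` (`"macular"`/`"nonmacular"`).
#'
#' @return An object of class `ExpressionStudy`: a list with elements
#'   `values`, `platform` and `samples`.
#' @export
expression_study <- function(values, platform = c("microarray", "rnaseq"),
                             samples) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry gene row names and sample column names")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (!is.data.frame(samples))
    stop("'samples' must be a data frame")
  req <- c("sample", "study", "group", "region")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("'samples' lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stop("'samples' has ", nrow(samples), " rows but 'values' has ",
         ncol(values), " columns")
  if (!identical(as.character(samples$sample), colnames(values)))
    stop("'samples$sample' must match the column names of 'values' in order")
  if (any(!is.finite(values)))
    stop("'values' contains non-finite entries")
  if (platform == "rnaseq") {
    if (any(values < 0))
      stop("count matrix contains negative values")
    if (any(values != round(values)))
      stop("count matrix contains non-integer values")
  }
  structure(list(values = values, platform = platform,
                 samples = as.data.frame(samples)),
            class = "ExpressionStudy")
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat(sprintf("ExpressionStudy (%s): %d genes x %d samples\n",
              x$platform, nrow(x$values), ncol(x$values)))
  tb <- table(x$samples$group)
  cat("  groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.ExpressionStudy <- function(x) dim(x$values)

#' Restrict a study to a set of genes
#'
#' @param study an [expression_study()] object.
#' @param genes character vector of gene identifiers to keep; must all be
#'   present. The output follows the order of `genes`.
#' @return the restricted `ExpressionStudy`.
#' @export
subset_genes <- function(study, genes) {
  stopifnot(inherits(study, "ExpressionStudy"))
  miss <- setdiff(genes, rownames(study$values))
  if (length(miss))
    stop("genes absent from study: ", paste(utils::head(miss, 5), collapse = ", "))
  study$values <- study$values[genes, , drop = FALSE]
  study
}

gene_ids <- function(study) rownames(study$values)
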