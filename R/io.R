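#' Read a gene-by-sample expression table
#'
#' Expects tab-separated text with a header row; the first column holds
#' gene (or probe) identifiers and the remaining columns one sample each.
#' Count matrices (`platform = "rnaseq"`) are validated as non-negative
#' integers.
#'
#' @param path path to a TSV file.
#' @param platform `"microarray"` or `"rnaseq"`.
#' @param samples optional per-sample annotation data frame (columns
#'   `sample`, `study`, `group`, `region`); when omitted, placeholder
#'   annotations are attached and should be replaced via
#'   [read_sample_metadata()].
#' @return an [expression_study()].
#' @export
read_expression <- function(path, platform = c("microarray", "rnaseq"),
                            samples = NULL) {
  platform <- match.arg(platform)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2) stop("expression file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  body <- fields[-1]
  nc <- lengths(body)
  if (any(nc != length(header)))
    stop("ragged row(s) at line(s): ",
         paste(utils::head(which(nc != length(header)) + 1, 5), collapse = ", "))
  ids <- vapply(body, `[[`, "", 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(length(sample_ids))))
  vals <- if (length(sample_ids) == 1L) matrix(vals, nrow = length(body))
          else t(vals)
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at data row %d, column '%s'",
                 bad[1], sample_ids[bad[2]]))
  }
  rownames(vals) <- ids
  colnames(vals) <- sample_ids
  if (is.null(samples))
    samples <- data.frame(sample = sample_ids, study = "unknown",
                          group = "control", region = "macular",
                          stringsAsFactors = FALSE)
  expression_study(vals, platform, samples)
}

#' Write an expression matrix as TSV
#'
#' First column `gene`, one column per sample. Optional `#`-prefixed
#' provenance comment lines are written before the header.
#'
#' @param study an [expression_study()].
#' @param path output path.
#' @param comments character vector of comment lines (without the leading
#'   `#`).
#' @export
write_expression <- function(study, path, comments = character()) {
  stopifnot(inherits(study, "ExpressionStudy"))
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  writeLines(paste(c("gene", colnames(study$values)), collapse = "\t"), con)
  body <- cbind(rownames(study$values),
                format(study$values, trim = TRUE, digits = 15,
                       scientific = FALSE))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read/write sample metadata
#'
#' Four-column TSV: `sample`, `study`, `group`, `region`.
#' @param path file path.
#' @return data frame of sample annotations.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("sample", "study", "group", "region")
  miss <- setdiff(req, names(md))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  md
}

#' @rdname read_sample_metadata
#' @param metadata data frame to write.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a probe/transcript-to-gene identifier map
#'
#' Two-column TSV (`source`, `gene`). Many sources may map to one gene; a
#' source id mapping to more than one gene is an error.
#'
#' @param path file path.
#' @return data frame with columns `source` and `gene`.
#' @export
read_id_map <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(m) < 2) stop("id map must have two columns: source, gene")
  names(m)[1:2] <- c("source", "gene")
  if (anyDuplicated(m$source))
    stop("source id(s) map to more than one gene: ",
         paste(utils::head(unique(m$source[duplicated(m$source)]), 5),
               collapse = ", "))
  m[, 1:2]
}

#' Collapse probe-level rows to gene-level rows
#'
#' Rows are re-keyed through the id map; rows without a mapping are dropped
#' (their count is recorded in attribute `n_unmapped`). When several rows
#' map to the same gene, the row with maximal mean expression is kept, ties
#' broken lexicographically by source id — a common deterministic
#' convention for probe sets.
#'
#' @param study an [expression_study()] keyed by source (probe) ids.
#' @param idmap data frame from [read_id_map()].
#' @return an `ExpressionStudy` keyed by gene ids (lexicographic order),
#'   with attribute `n_unmapped`.
#' @export
collapse_to_genes <- function(study, idmap) {
  stopifnot(inherits(study, "ExpressionStudy"))
  src <- rownames(study$values)
  gene <- idmap$gene[match(src, idmap$source)]
  mapped <- !is.na(gene)
  n_unmapped <- sum(!mapped)
  if (!any(mapped)) stop("no rows could be mapped to gene ids")
  vals <- study$values[mapped, , drop = FALSE]
  gene <- gene[mapped]
  ## keep, per gene, the probe with maximal mean; ties -> smallest probe id
  rm <- rowMeans(vals)
  ord <- order(gene, -rm, rownames(vals))
  keep <- ord[!duplicated(gene[ord])]
  keep <- keep[order(gene[keep])]
  out <- vals[keep, , drop = FALSE]
  rownames(out) <- gene[keep]
  res <- expression_study(out, study$platform, study$samples)
  attr(res, "n_unmapped") <- n_unmapped
  res
}

#' Restrict two studies to their common gene universe
#'
#' Both studies are subset to the sorted intersection of their gene ids,
#' in identical (lexicographic) order. Symmetric in its arguments.
#'
#' @param a,b gene-keyed [expression_study()] objects.
#' @return list with elements `a` and `b`.
#' @export
intersect_universe <- function(a, b) {
  common <- sort(intersect(gene_ids(a), gene_ids(b)))
  if (length(common) == 0) stop("studies share no gene identifiers")
  list(a = subset_genes(a, common), b = subset_genes(b, common))
}

#' Remove genes absent in more than a given fraction of pooled samples
#'
#' A gene is "absent" in a sample when its count is zero (RNA-seq) or its
#' intensity is at or below the platform floor, defined as the study's
#' matrix minimum (microarray). Absence is pooled over all samples of both
#' studies; a gene is removed from both studies when its pooled absence
#' fraction is strictly greater than `threshold` ("more than 80 percent"
#' at the default).
#'
#' @param a,b two studies over the same gene universe (same order).
#' @param threshold absence fraction in (0, 1]; default 0.8.
#' @return list with elements `a`, `b` (filtered) and `removed` (gene ids).
#' @export
filter_absent <- function(a, b, threshold = 0.8) {
  stopifnot(identical(gene_ids(a), gene_ids(b)))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  absent_in <- function(s) {
    floorv <- if (s$platform == "rnaseq") 0 else min(s$values)
    s$values <= floorv
  }
  abs_mat <- cbind(absent_in(a), absent_in(b))
  frac <- rowMeans(abs_mat)
  removed <- gene_ids(a)[frac > threshold]
  keep <- setdiff(gene_ids(a), removed)
  if (length(keep) == 0) stop("absence filter removed every gene")
  list(a = subset_genes(a, keep), b = subset_genes(b, keep),
       removed = removed)
}

#' Write the simulator's outputs to a directory
#'
#' Writes the two expression matrices, pooled sample metadata, the truth
#' table, a GMT gene-set collection and a PPI edge list as plain text.
#'
#' @param sim result of [generate_dual_study()].
#' @param outdir output directory (created if needed).
#' @param gene_sets optional `GeneSetCollection` to write as GMT.
#' @param network optional [interaction_network()] to write as edge list.
#' @return invisibly, the vector of paths written.
#' @export
write_simulation <- function(sim, outdir, gene_sets = NULL, network = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    array = file.path(outdir, "array_expression.tsv"),
    rnaseq = file.path(outdir, "rnaseq_counts.tsv"),
    metadata = file.path(outdir, "sample_metadata.tsv"),
    truth = file.path(outdir, "truth.tsv"))
  write_expression(sim$array, paths["array"])
  write_expression(sim$rnaseq, paths["rnaseq"])
  write_sample_metadata(rbind(sim$array$samples, sim$rnaseq$samples),
                        paths["metadata"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(gene_sets)) {
    paths["gmt"] <- file.path(outdir, "gene_sets.gmt")
    write_gmt(gene_sets, paths["gmt"])
  }
  if (!is.null(network)) {
    paths["edges"] <- file.path(outdir, "ppi_edges.tsv")
    write_edge_list(network, paths["edges"])
  }
  invisible(paths)
}
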