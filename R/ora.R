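#' Gene-set collection
#'
#' @param sets named list of character vectors (gene ids).
#' @param universe background universe of gene ids.
#' @return list of class `GeneSetCollection` with deduplicated members.
#' @export
gene_set_collection <- function(sets, universe) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every gene set must be named")
  if (anyDuplicated(universe)) stop("universe ids must be unique")
  sets <- lapply(sets, unique)
  structure(list(sets = sets, universe = universe),
            class = "GeneSetCollection")
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then member ids, tab-separated.
#' Duplicate members are collapsed; empty sets are dropped with a warning.
#'
#' @param path GMT file path.
#' @param universe optional background universe; defaults to the union of
#'   all members.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop("malformed GMT line(s) (need name, description, >=1 member): ",
         paste(utils::head(bad, 5), collapse = ", "))
  nm <- vapply(fields, `[[`, "", 1L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- nm
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty set(s)")
    sets <- sets[!empty]
  }
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  gene_set_collection(sets, universe)
}

#' Write a GMT gene-set file
#' @param collection a `GeneSetCollection`.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  sets <- collection$sets
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, ds, members)
    paste(c(nm, ds, members), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query list overlaps it more than
#' chance given the background universe: exact upper hypergeometric tail
#' `P(X >= k)` with `k` hits among a list of size `n`, a set of size `K`
#' within a universe of size `N`, followed by BH adjustment across the
#' tested sets. Sets are intersected with the universe first; sets outside
#' `size_range` (after intersection) are excluded before adjustment.
#'
#' @param meta_set character vector of query gene ids (e.g. significant
#'   meta-genes). Ids outside the universe are dropped with a message.
#' @param collection a `GeneSetCollection`.
#' @param universe optional override of the collection's universe.
#' @param size_range length-2 vector: minimum and maximum within-universe
#'   set size tested (defaults 5 and 2000).
#' @return data frame of class `ORAResult`, sorted by p ascending: `set`,
#'   `k`, `K`, `n`, `N`, `p`, `fdr`, `hits` (semicolon-joined ids).
#' @export
ora_test <- function(meta_set, collection, universe = NULL,
                     size_range = c(5, 2000)) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (is.null(universe)) universe <- collection$universe
  if (length(universe) == 0) stop("empty universe")
  meta_set <- unique(meta_set)
  out_univ <- setdiff(meta_set, universe)
  if (length(out_univ)) {
    message(length(out_univ), " query gene(s) outside the universe dropped")
    meta_set <- intersect(meta_set, universe)
  }
  if (length(meta_set) == 0) stop("empty query list")
  N <- length(universe)
  n <- length(meta_set)
  sets <- lapply(collection$sets, intersect, universe)
  Ks <- lengths(sets)
  keep <- Ks >= size_range[1] & Ks <= size_range[2]
  sets <- sets[keep]
  if (length(sets) == 0) stop("no gene sets within the size bounds")
  rows <- lapply(names(sets), function(nm) {
    members <- sets[[nm]]
    hits <- intersect(meta_set, members)
    k <- length(hits); K <- length(members)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               hits = paste(sort(hits), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- bh_adjust(res$p)
  res <- res[order(res$p, res$set), c("set", "k", "K", "n", "N", "p",
                                      "fdr", "hits")]
  rownames(res) <- NULL
  class(res) <- c("ORAResult", "data.frame")
  res
}

#' Write an ORA result table
#' @param res an `ORAResult`.
#' @param path output TSV path.
#' @param top_k optional number of top rows to keep (by p).
#' @param comments optional `#` comment lines (parameters are recorded by
#'   the pipeline driver).
#' @export
write_ora <- function(res, path, top_k = NULL, comments = character()) {
  if (!is.null(top_k)) res <- utils::head(res, top_k)
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  writeLines(paste(names(res), collapse = "\t"), con)
  writeLines(apply(as.matrix(format(res, trim = TRUE, digits = 6)), 1,
                   paste, collapse = "\t"), con)
  invisible(path)
}
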