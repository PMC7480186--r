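#' Undirected interaction network
#'
#' Stores a deduplicated, self-loop-free undirected edge list plus the node
#' set (which covers all edge endpoints and may include extra isolated
#' nodes).
#'
#' @param edges data frame with character columns `from` and `to`.
#' @param nodes optional node id vector; defaults to the edge endpoints.
#' @return list of class `InteractionNetwork` with `edges` and `nodes`.
#' @export
interaction_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges <- edges[edges$from != edges$to, c("from", "to")]
  key <- ifelse(edges$from < edges$to,
                paste(edges$from, edges$to, sep = "\r"),
                paste(edges$to, edges$from, sep = "\r"))
  edges <- edges[!duplicated(key), ]
  rownames(edges) <- NULL
  endpoints <- unique(c(edges$from, edges$to))
  if (is.null(nodes)) nodes <- endpoints
  else if (!all(endpoints %in% nodes))
    stop("edge endpoints missing from the node set")
  structure(list(edges = edges, nodes = sort(unique(nodes))),
            class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat(sprintf("InteractionNetwork: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  g
}

#' Read a PPI edge list
#'
#' Two-column TSV (`from`, `to`); an optional third numeric column is
#' treated as an interaction confidence score and can be thresholded with
#' `min_score`.
#'
#' @param path edge-list file.
#' @param min_score optional minimum score; rows below it are dropped
#'   (requires a third column).
#' @return an [interaction_network()].
#' @export
read_edge_list <- function(path, min_score = NULL) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(e) < 2) stop("edge list needs at least two columns")
  names(e)[1:2] <- c("from", "to")
  if (!is.null(min_score)) {
    if (ncol(e) < 3) stop("min_score given but the file has no score column")
    e <- e[e[[3]] >= min_score, ]
  }
  interaction_network(e[, 1:2])
}

#' Write an edge list as TSV
#' @param net an `InteractionNetwork`.
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Zero- or first-order subnetwork around seed genes
#'
#' Zero order: the subgraph induced on the seeds themselves, with isolated
#' (degree-0) nodes removed. First order: the subgraph induced on the seeds
#' plus all of their direct neighbors.
#'
#' @param seeds character vector of seed gene ids.
#' @param reference an [interaction_network()] (e.g. a STRING-style edge
#'   list).
#' @param order `"zero"` or `"first"`.
#' @return an `InteractionNetwork`; may be empty for zero order when no two
#'   seeds interact. Node annotation `seed` marks seed membership.
#' @export
build_subnetwork <- function(seeds, reference, order = c("zero", "first")) {
  order <- match.arg(order)
  stopifnot(inherits(reference, "InteractionNetwork"))
  if (length(seeds) == 0) stop("empty seed list")
  seeds <- unique(seeds)
  mapped <- intersect(seeds, reference$nodes)
  if (length(mapped) == 0)
    stop("no seed maps into the reference network; unmapped: ",
         paste(utils::head(seeds, 10), collapse = ", "))
  g <- as_igraph(reference)
  keep <- if (order == "zero") mapped else {
    nb <- unique(unlist(lapply(igraph::adjacent_vertices(g, mapped), names),
                        use.names = FALSE))
    union(mapped, nb)
  }
  sub <- igraph::induced_subgraph(g, keep)
  if (order == "zero")
    sub <- igraph::delete_vertices(sub, igraph::V(sub)[igraph::degree(sub) == 0])
  el <- igraph::as_edgelist(sub)
  net <- interaction_network(
    data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE),
    nodes = igraph::V(sub)$name)
  attr(net, "seeds") <- intersect(net$nodes, mapped)
  net
}

## Random walk with restart on the column-normalized adjacency: at each step
## the walker follows a uniform random edge with probability (1 - restart)
## and teleports to the uniform seed distribution with probability
## `restart`; columns with no outgoing edges redistribute their mass to the
## restart vector. Power iteration to max |delta| < 1e-10.
rwr_scores <- function(g, seeds, restart) {
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  deg <- colSums(A)
  e <- as.numeric(nodes %in% seeds)
  if (sum(e) == 0) e <- rep(1, n)
  e <- e / sum(e)
  v <- e
  for (iter in seq_len(10000)) {
    walk <- as.numeric(A %*% (ifelse(deg > 0, v / deg, 0)))
    dangling <- sum(v[deg == 0])
    v_new <- (1 - restart) * (walk + dangling * e) + restart * e
    if (max(abs(v_new - v)) < 1e-10) {
      v <- v_new
      break
    }
    v <- v_new
  }
  stats::setNames(v, nodes)
}

#' Node statistics: degree, betweenness, random-walk score
#'
#' Degree from the edge list; exact (unnormalized) shortest-path
#' betweenness; and the stationary visiting probability of a random walk
#' restarting at the seed set (scores sum to one).
#'
#' @param net an [interaction_network()].
#' @param seeds seed gene ids for the restart vector (defaults to the
#'   subnetwork's recorded seeds, else all nodes).
#' @param restart restart probability in (0, 1]; `restart = 1` returns the
#'   uniform seed vector itself.
#' @return data frame of class `NodeStats`: `node`, `seed`, `degree`,
#'   `betweenness`, `rwr_score`.
#' @export
node_stats <- function(net, seeds = NULL, restart = 0.5) {
  stopifnot(inherits(net, "InteractionNetwork"))
  if (length(net$nodes) == 0) stop("empty network")
  if (restart <= 0 || restart > 1) stop("restart must be in (0, 1]")
  if (is.null(seeds)) seeds <- attr(net, "seeds")
  if (is.null(seeds)) seeds <- net$nodes
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  rwr <- if (restart == 1) {
    e <- as.numeric(net$nodes %in% seeds)
    if (sum(e) == 0) e <- rep(1, length(net$nodes))
    stats::setNames(e / sum(e), igraph::V(g)$name)[net$nodes]
  } else rwr_scores(g, seeds, restart)
  out <- data.frame(node = igraph::V(g)$name,
                    seed = igraph::V(g)$name %in% seeds,
                    degree = as.numeric(deg),
                    betweenness = as.numeric(btw),
                    rwr_score = as.numeric(rwr[igraph::V(g)$name]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$node), ]
  rownames(out) <- NULL
  class(out) <- c("NodeStats", "data.frame")
  out
}

#' Rank hub candidates
#'
#' Degree descending, ties by betweenness descending, remaining ties
#' lexicographically by node id.
#'
#' @param stats a `NodeStats` table.
#' @param top_k number of rows to return (default all).
#' @return the ranked subset of `stats`.
#' @export
rank_hubs <- function(stats, top_k = nrow(stats)) {
  o <- order(-stats$degree, -stats$betweenness, stats$node)
  out <- stats[o, , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}
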