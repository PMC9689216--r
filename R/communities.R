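#' Degree and eigenvector centrality of every node
#'
#' Eigenvector centrality is the leading eigenvector of the 0/1 adjacency
#' matrix, computed by power iteration from a positive start (tolerance
#' 1e-10, at most 10,000 iterations) and max-normalized so the most
#' central node scores 1. On a disconnected graph the Perron vector
#' concentrates on the component with the largest adjacency eigenvalue;
#' nodes outside it receive (near-)zero scores, which matches a single
#' global hub ranking.
#'
#' @param net a [build_network()] object with at least one edge.
#' @return Object of class `centrality_table`: data.frame with columns
#'   `keyword`, `degree`, `eigenvector`, plus attribute `eigenvalue`.
#' @export
centralities <- function(net) {
  stopifnot(inherits(net, "keyword_network"))
  if (net$q < 1) stop("centralities undefined for an edgeless graph")
  A <- net$adjacency
  # iterate on A + I: same eigenvectors, but a strictly dominant leading
  # eigenvalue even on bipartite graphs (where A alone has +/- lambda_max
  # and plain power iteration oscillates)
  x <- rep(1, net$n)
  for (i in seq_len(10000)) {
    y <- drop(A %*% x) + x
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) < 1e-10) { x <- y; break }
    x <- y
  }
  lam <- drop(crossprod(x, A %*% x))   # Rayleigh quotient for A itself
  ev <- x / max(x)
  out <- data.frame(keyword = net$nodes, degree = .degrees(net),
                    eigenvector = ev, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "eigenvalue") <- lam
  class(out) <- c("centrality_table", class(out))
  out
}

#' Top network hubs by a centrality measure
#'
#' @param table a [centralities()] result.
#' @param k number of hubs (default 5).
#' @param measure `"degree"` or `"eigenvector"`.
#' @return Character vector of the top-k keywords, ties broken
#'   lexicographically; all keywords (with a warning) when k exceeds n.
#' @export
top_hubs <- function(table, k = 5, measure = c("degree", "eigenvector")) {
  measure <- match.arg(measure)
  stopifnot(k >= 1)
  if (k > nrow(table)) {
    warning("k exceeds the number of nodes; returning all")
    k <- nrow(table)
  }
  ord <- order(-table[[measure]], table$keyword)
  table$keyword[ord][seq_len(k)]
}

#' Modularity of a node partition, with resolution
#'
#' \deqn{Q(c) = \frac{1}{2l}\sum_{ij}\Big[A_{ij} -
#'   \lambda\frac{k_i k_j}{2l}\Big]\,\delta_{ij}(c),}
#' the sum running over ordered node pairs, with \eqn{\delta_{ij}(c)=1}
#' iff i and j share a module and resolution parameter \eqn{\lambda}
#' weighting the expected-edge term.
#'
#' @param net a [build_network()] object with at least one edge.
#' @param assignment integer (or factor) module id per node, covering all
#'   nodes.
#' @param resolution the resolution parameter (default 1).
#' @return Scalar Q.
#' @export
modularity_score <- function(net, assignment, resolution = 1) {
  stopifnot(inherits(net, "keyword_network"))
  if (net$q < 1) stop("modularity undefined for an edgeless graph")
  if (length(assignment) != net$n || anyNA(assignment))
    stop("assignment must cover all ", net$n, " nodes")
  a <- as.integer(factor(assignment))
  k <- .degrees(net)
  l <- net$q
  same <- outer(a, a, "==")
  sum((net$adjacency - resolution * outer(k, k) / (2 * l)) * same) / (2 * l)
}

#' Louvain module detection
#'
#' Standard two-phase Louvain maximization of [modularity_score()] at the
#' given resolution (local moving until no gain, then graph aggregation,
#' repeated over the full hierarchy), deterministic given the seed.
#'
#' @param net a [build_network()] object with at least one edge.
#' @param resolution resolution parameter (default 1).
#' @param seed integer seed for the node-order shuffling (default 0).
#' @return Object of class `module_partition`: list with `assignment`
#'   (named integer vector, module ids contiguous from 1), `modularity`,
#'   `resolution`, `seed`, `sizes`, and `omitted` (filled by
#'   [filter_small_modules()], initially all FALSE).
#' @export
louvain <- function(net, resolution = 1, seed = 0) {
  stopifnot(inherits(net, "keyword_network"))
  if (net$q < 1) stop("module detection undefined for an edgeless graph")
  cl <- .with_seed(seed,
    igraph::cluster_louvain(net$graph, resolution = resolution))
  memb <- igraph::membership(cl)
  a <- as.integer(factor(memb, levels = sort(unique(as.integer(memb)))))
  names(a) <- net$nodes
  q_single <- modularity_score(net, seq_len(net$n), resolution)
  q_found <- modularity_score(net, a, resolution)
  if (q_found < q_single) {     # never return worse than singletons
    a <- stats::setNames(seq_len(net$n), net$nodes)
    q_found <- q_single
  }
  structure(list(assignment = a, modularity = q_found,
                 resolution = resolution, seed = seed,
                 sizes = as.integer(table(a)),
                 omitted = rep(FALSE, length(unique(a)))),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules (sizes %s), Q = %.3f at resolution %.2f\n",
              length(x$sizes), paste(x$sizes, collapse = ", "),
              x$modularity, x$resolution))
  invisible(x)
}

#' Flag modules below a minimum size as omitted
#'
#' Small modules are marked omitted (for presentation) but their nodes are
#' retained in the assignment, not reassigned.
#'
#' @param partition a [louvain()] result.
#' @param min_size smallest module size kept (default 3).
#' @return The partition with its `omitted` flags updated.
#' @export
filter_small_modules <- function(partition, min_size = 3) {
  stopifnot(inherits(partition, "module_partition"), min_size >= 1)
  partition$omitted <- partition$sizes < min_size
  partition
}

#' Module sizes as percentages of the node set
#'
#' @param partition a [louvain()] result.
#' @return data.frame with `module`, `size`, `share_pct` (percent of all
#'   nodes, summing to 100), `omitted`.
#' @export
module_shares <- function(partition) {
  stopifnot(inherits(partition, "module_partition"))
  n <- length(partition$assignment)
  data.frame(module = seq_along(partition$sizes), size = partition$sizes,
             share_pct = 100 * partition$sizes / n,
             omitted = partition$omitted)
}
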