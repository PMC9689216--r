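#' Keyword network from an estimated precision matrix
#'
#' Nodes are keywords; an edge joins keywords i and j iff the off-diagonal
#' precision entry exceeds `threshold` in absolute value — i.e., iff the
#' model estimates a conditional dependence between them. The lasso
#' produces exact zeros, so the default threshold is only a numerical
#' guard.
#'
#' @param theta_hat symmetric p x p matrix (a precision estimate); an
#'   asymmetry beyond 1e-8 is an error.
#' @param threshold absolute-value edge threshold (default 1e-8).
#' @param labels optional node labels; defaults to `colnames(theta_hat)`
#'   or `V1..Vp`.
#' @return Object of class `keyword_network`: `nodes`, `adjacency` (0/1
#'   symmetric, no self-loops), `weights` (absolute precision entries on
#'   edges), `graph` (an igraph object), `q` (edge count), `n` (node
#'   count).
#' @export
build_network <- function(theta_hat, threshold = 1e-8, labels = NULL) {
  theta_hat <- as.matrix(theta_hat)
  p <- nrow(theta_hat)
  if (ncol(theta_hat) != p) stop("theta_hat must be square")
  if (max(abs(theta_hat - t(theta_hat))) > 1e-8)
    stop("theta_hat is not symmetric (beyond 1e-8)")
  if (is.null(labels))
    labels <- if (!is.null(colnames(theta_hat))) colnames(theta_hat)
              else sprintf("V%d", seq_len(p))
  A <- (abs(theta_hat) > threshold) * 1
  diag(A) <- 0
  dimnames(A) <- list(labels, labels)
  W <- abs(theta_hat) * A
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  structure(list(nodes = labels, adjacency = A, weights = W, graph = g,
                 q = sum(A) / 2, n = p),
            class = "keyword_network")
}

#' @export
print.keyword_network <- function(x, ...) {
  cat(sprintf("keyword_network: n = %d nodes, q = %d edges, %d isolated\n",
              x$n, x$q, sum(rowSums(x$adjacency) == 0)))
  invisible(x)
}

.degrees <- function(net) rowSums(net$adjacency)

#' Average degree over all nodes
#'
#' `2q / n`, with isolated nodes included in the denominator.
#'
#' @param net a [build_network()] object.
#' @return Scalar.
#' @export
average_degree <- function(net) {
  stopifnot(inherits(net, "keyword_network"))
  if (net$n == 0) stop("network has no nodes")
  2 * net$q / net$n
}

#' Average shortest-path length
#'
#' Mean of the shortest-path length over unordered node pairs at finite
#' distance (pairs within the same connected component of size >= 2);
#' cross-component pairs are excluded rather than treated as infinite.
#'
#' @param net a [build_network()] object with at least one edge.
#' @return Scalar.
#' @export
aspl <- function(net) {
  stopifnot(inherits(net, "keyword_network"))
  if (net$q < 1) stop("ASPL undefined for an edgeless graph")
  igraph::mean_distance(net$graph, unconnected = TRUE)
}

#' Mean local clustering coefficient
#'
#' Each node contributes \eqn{q_i / \binom{k_i}{2}} (the fraction of
#' realized edges among its neighbors) when \eqn{k_i \ge 2} and 0 when
#' \eqn{k_i = 1}; the average is over non-isolated nodes.
#'
#' @param net a [build_network()] object.
#' @return Scalar in [0, 1].
#' @export
clustering_coefficient <- function(net) {
  stopifnot(inherits(net, "keyword_network"))
  k <- .degrees(net)
  active <- k > 0
  if (!any(active)) stop("all nodes isolated: clustering undefined")
  loc <- igraph::transitivity(net$graph, type = "local", isolates = "zero")
  mean(loc[active])
}

#' Erdos-Renyi baselines for ASPL and clustering
#'
#' For a random graph with `n_active` nodes and `q` edges:
#' \eqn{ASPL_r \approx \ln(n)/(\ln(2q) - \ln(n))} and
#' \eqn{CC_r \approx 2q / (n(n-1))}, evaluated with `n` equal to the
#' number of non-isolated nodes of the observed network.
#'
#' @param n_active number of non-isolated nodes (>= 2).
#' @param q number of edges (>= 1); `2q` must differ from `n_active`.
#' @return List with `aspl_r` and `cc_r`.
#' @export
er_baselines <- function(n_active, q) {
  if (n_active < 2) stop("degenerate case: fewer than 2 active nodes")
  if (q < 1) stop("degenerate case: no edges")
  if (2 * q == n_active)
    stop("degenerate case: 2q = n_active makes the ASPL baseline undefined")
  list(aspl_r = log(n_active) / (log(2 * q) - log(n_active)),
       cc_r = 2 * q / (n_active * (n_active - 1)))
}

#' Small-world coefficient
#'
#' \eqn{\sigma = (CC/CC_r) / (ASPL/ASPL_r)}; values above 1 indicate
#' small-world structure (more clustered than random at comparable path
#' lengths). Defined as 0 when CC = 0.
#'
#' @param cc,cc_r clustering coefficient and its random baseline.
#' @param aspl,aspl_r average shortest-path length and its baseline.
#' @return Scalar.
#' @export
small_world_sigma <- function(cc, cc_r, aspl, aspl_r) {
  if (cc_r <= 0 || aspl_r <= 0) stop("baselines must be positive")
  if (cc == 0) return(0)
  stopifnot(cc > 0, aspl > 0)
  (cc / cc_r) / (aspl / aspl_r)
}

#' Discrete power-law exponent of the degree distribution
#'
#' Maximum-likelihood fit of \eqn{P(k) \propto k^{-\gamma}} with
#' \eqn{x_{\min} = 1} to the positive degrees (zeros excluded), maximizing
#' the zeta-normalized log-likelihood
#' \eqn{-n\log\zeta(\gamma) - \gamma \sum \log k_i} numerically. An
#' optional parametric bootstrap Kolmogorov-Smirnov test flags degree
#' sequences the power law fits poorly.
#'
#' @param degrees integer degree sequence; at least 5 positive entries.
#' @param gof run the bootstrap goodness-of-fit test (default FALSE).
#' @param gof_reps bootstrap replicates (default 100).
#' @param gof_seed seed for the bootstrap.
#' @return List with `gamma` (the MLE), `n_tail` (positive degrees used),
#'   `degenerate` (TRUE when all positive degrees are equal, where the
#'   likelihood is maximized at the search boundary), and, when
#'   `gof = TRUE`, `ks_stat`, `p_value` and `plausible` (p >= 0.1).
#' @export
powerlaw_gamma <- function(degrees, gof = FALSE, gof_reps = 100,
                           gof_seed = 1) {
  k <- degrees[degrees >= 1]
  if (length(k) < 5) stop("insufficient tail: fewer than 5 positive degrees")
  fitone <- function(kv) {
    nll <- function(g) length(kv) * log(pracma::zeta(g)) + g * sum(log(kv))
    stats::optimize(nll, c(1.01, 20))$minimum
  }
  gam <- fitone(k)
  degenerate <- length(unique(k)) == 1
  out <- list(gamma = gam, n_tail = length(k), degenerate = degenerate)
  if (gof) {
    ks_stat <- function(kv, g) {
      kk <- seq_len(max(kv))
      cdf <- cumsum(kk^(-g)) / pracma::zeta(g)
      emp <- stats::ecdf(kv)(kk)
      max(abs(emp - cdf))
    }
    obs <- ks_stat(k, gam)
    boots <- .with_seed(gof_seed, {
      seeds <- sample.int(.Machine$integer.max, gof_reps)
      vapply(seq_len(gof_reps), function(b) {
        kb <- sample_powerlaw(length(k), gam, seed = seeds[b])
        ks_stat(kb, fitone(kb))
      }, 0)
    })
    out$ks_stat <- obs
    out$p_value <- mean(boots >= obs)
    out$plausible <- out$p_value >= 0.1
  }
  out
}

#' All Table-style indicators of a keyword network
#'
#' Bundles [average_degree()], [aspl()], [clustering_coefficient()],
#' [er_baselines()] (on the non-isolated node count), the small-world
#' coefficient and the power-law degree exponent. Indicators that are
#' undefined on the given graph (e.g., ASPL of an edgeless network) are
#' returned as `NA`.
#'
#' @param net a [build_network()] object.
#' @param gof pass-through to [powerlaw_gamma()].
#' @return One-row data.frame with columns `n`, `n_active`, `q`,
#'   `avg_degree`, `aspl`, `aspl_r`, `cc`, `cc_r`, `sigma`, `gamma`,
#'   `gamma_plausible`.
#' @export
network_indicators <- function(net, gof = FALSE) {
  stopifnot(inherits(net, "keyword_network"))
  k <- .degrees(net)
  n_active <- sum(k > 0)
  sfe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  a <- sfe(aspl(net))
  cc <- sfe(clustering_coefficient(net))
  er <- tryCatch(er_baselines(n_active, net$q),
                 error = function(e) list(aspl_r = NA_real_,
                                          cc_r = NA_real_))
  sg <- sfe(small_world_sigma(cc, er$cc_r, a, er$aspl_r))
  pl <- tryCatch(powerlaw_gamma(k, gof = gof),
                 error = function(e) list(gamma = NA_real_,
                                          plausible = NA))
  data.frame(n = net$n, n_active = n_active, q = net$q,
             avg_degree = average_degree(net), aspl = a,
             aspl_r = er$aspl_r, cc = cc, cc_r = er$cc_r, sigma = sg,
             gamma = pl$gamma,
             gamma_plausible = if (gof) pl$plausible else NA)
}
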