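# Network families used to span the amplifier/suppressor axis, plus graph
# validation, amplification-factor estimation, degree-preserving
# randomization and synthetic ductal-like tree fixtures. All generators
# return simple, undirected, connected igraph objects and are deterministic
# given a seed.

#' Validate a population graph
#'
#' @param graph igraph object.
#' @return Invisibly `TRUE`; errors if the graph is not simple, undirected,
#'   connected, or has fewer than two nodes.
#' @export
validate_graph <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::is_directed(graph)) stop("graph must be undirected")
  if (igraph::vcount(graph) < 2) stop("graph must have at least 2 nodes")
  if (any(igraph::which_loop(graph))) stop("graph must have no self-loops")
  if (any(igraph::which_multiple(graph))) stop("graph must have no multi-edges")
  if (!igraph::is_connected(graph)) stop("graph must be connected")
  invisible(TRUE)
}

.retry_connected <- function(gen, retries = 50L) {
  for (k in seq_len(retries)) {
    g <- gen()
    if (igraph::is_connected(g)) return(g)
  }
  stop("could not sample a connected graph in ", retries, " attempts")
}

# sequential preferential attachment: each new node links to m existing
# nodes with probability proportional to degree^beta (beta may be negative;
# beta = 0 is uniform attachment)
.pa_power <- function(n, m, beta) {
  m0 <- max(m, 2L)
  edges <- utils::combn(seq_len(m0), 2)  # complete seed graph
  deg <- integer(n)
  deg[seq_len(m0)] <- m0 - 1L
  el <- t(edges)
  for (v in (m0 + 1L):n) {
    existing <- seq_len(v - 1L)
    w <- pmax(deg[existing], 1L)^beta
    tgt <- sample(existing, size = min(m, v - 1L), prob = w / sum(w))
    el <- rbind(el, cbind(v, tgt))
    deg[tgt] <- deg[tgt] + 1L
    deg[v] <- deg[v] + length(tgt)
  }
  igraph::graph_from_edgelist(el, directed = FALSE)
}

.pa_star <- function(n, i) {
  stopifnot(i >= 1, i <= n - 1)
  core <- seq_len(i)
  leaves <- if (i < n) (i + 1L):n else integer(0)
  el <- NULL
  if (i >= 2) el <- t(utils::combn(core, 2))
  if (length(leaves)) {
    el <- rbind(el, as.matrix(expand.grid(core, leaves)))
  }
  g <- igraph::graph_from_edgelist(as.matrix(el), directed = FALSE)
  igraph::add_vertices(g, n - igraph::vcount(g))  # no-op when complete
}

.detour <- function(n1, n2, seed_rng) {
  g <- igraph::make_full_graph(n1)
  e <- igraph::E(g)[sample(igraph::ecount(g), 1)]
  uv <- igraph::ends(g, e)[1, ]
  g <- igraph::delete_edges(g, e)
  g <- igraph::add_vertices(g, n2)
  path_nodes <- n1 + seq_len(n2)
  chain <- c(uv[1], path_nodes, uv[2])
  g <- igraph::add_edges(g, as.vector(rbind(chain[-length(chain)], chain[-1])))
  g
}

.modified_star <- function(n, m) {
  g <- igraph::make_star(n, mode = "undirected", center = 1)
  missing <- which(upper.tri(matrix(0, n, n)) &
                     !(as.matrix(igraph::as_adjacency_matrix(g)) > 0),
                   arr.ind = TRUE)
  pick <- missing[sample(nrow(missing), min(m, nrow(missing))), , drop = FALSE]
  igraph::add_edges(g, as.vector(t(pick)))
}

.random_geometric <- function(n = 100L, cluster_means = c(0, 3),
                              sd = 0.5, radius = NULL) {
  half <- n %/% 2L
  x <- c(stats::rnorm(half, cluster_means[1], sd),
         stats::rnorm(n - half, cluster_means[2], sd))
  y <- stats::rnorm(n, 0, sd)
  dmat <- as.matrix(stats::dist(cbind(x, y)))
  if (is.null(radius)) {
    # smallest radius yielding connectivity = longest Euclidean MST edge
    full <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                                weighted = TRUE)
    mst <- igraph::mst(full)
    radius <- max(igraph::E(mst)$weight) * (1 + 1e-12)
  }
  adj <- dmat <= radius
  diag(adj) <- FALSE
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

.random_tree <- function(n, max_children = 3L) {
  parent <- integer(n)
  children <- integer(n)
  for (v in 2:n) {
    open <- which(children[seq_len(v - 1L)] < max_children)
    p <- if (length(open) == 1L) open else sample(open, 1L)
    parent[v] <- p
    children[p] <- children[p] + 1L
  }
  igraph::graph_from_edgelist(cbind(2:n, parent[2:n]), directed = FALSE)
}

#' Generate a graph from a named family
#'
#' Families and their parameters:
#' \describe{
#'   \item{complete}{none.}
#'   \item{star}{none (hub is node 1).}
#'   \item{modified_star}{`m` random extra edges added to a star.}
#'   \item{k_regular}{`k` neighbors per node (`n * k` even).}
#'   \item{erdos_renyi}{edge probability `p`; resampled until connected.}
#'   \item{small_world}{ring lattice of degree `k` rewired with probability
#'     `p` (Watts-Strogatz).}
#'   \item{bipartite}{complete bipartite with parts `n1`, `n2` (`n = n1+n2`).}
#'   \item{random_geometric}{`n` points in two x-clusters (means 0 and 3,
#'     sd 0.5 in both coordinates); nodes within the cut-off `radius` are
#'     linked, defaulting to the smallest radius yielding connectivity.}
#'   \item{preferential_attachment}{`m` links per new node, attachment
#'     kernel degree^`beta`.}
#'   \item{pa_star}{`i` fully connected core nodes; `n - i` leaves attached
#'     to every core node. `i = 1` is the star, `i = n - 1` the complete
#'     graph.}
#'   \item{detour}{complete graph on `n1` nodes with one edge replaced by a
#'     path through `n2` new nodes (`n = n1 + n2`).}
#'   \item{random_tree}{growing random tree with at most `max_children`
#'     children per node (`max_children = 1` gives the path graph).}
#' }
#'
#' @param family Family name (see above).
#' @param n Number of nodes.
#' @param ... Family-specific parameters.
#' @param seed RNG seed; the same seed reproduces the same graph.
#' @return A connected simple undirected igraph object.
#' @export
graph_family <- function(family, n, ..., seed = NULL) {
  args <- list(...)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  g <- switch(
    family,
    complete = igraph::make_full_graph(n),
    star = igraph::make_star(n, mode = "undirected", center = 1),
    modified_star = .modified_star(n, args$m %||% 50L),
    k_regular = {
      k <- args$k %||% 4L
      if ((n * k) %% 2 != 0) stop("k-regular needs n * k even")
      .retry_connected(function() igraph::sample_k_regular(n, k))
    },
    erdos_renyi = .retry_connected(function()
      igraph::sample_gnp(n, args$p %||% (2 * log(n) / n))),
    small_world = .retry_connected(function()
      igraph::sample_smallworld(1, n, (args$k %||% 8L) / 2, args$p %||% 0.1)),
    bipartite = {
      n1 <- args$n1 %||% (n %/% 2L)
      igraph::make_full_bipartite_graph(n1, n - n1)
    },
    random_geometric = .retry_connected(function()
      .random_geometric(n, radius = args$radius)),
    preferential_attachment = .pa_power(n, args$m %||% 3L, args$beta %||% 1),
    pa_star = .pa_star(n, args$i %||% 1L),
    detour = {
      n1 <- args$n1 %||% (n - 1L)
      .detour(n1, n - n1)
    },
    random_tree = .random_tree(n, args$max_children %||% 3L),
    stop("unknown graph family: ", family)
  )
  g <- igraph::simplify(g)
  validate_graph(g)
  igraph::as_undirected(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic ductal-like random tree
#'
#' A random growing tree standing in for imaging-derived ductal networks:
#' branching tissue architectures are acyclic and strongly spatially
#' constrained. The `max_children` parameter bounds the branching factor;
#' `max_children = 1` degenerates to the path graph.
#'
#' @param n_nodes Number of nodes.
#' @param max_children Maximum children per node.
#' @param seed RNG seed.
#' @return A tree (igraph) with `n_nodes - 1` edges.
#' @export
random_ductal_tree <- function(n_nodes, max_children = 3L, seed = NULL) {
  graph_family("random_tree", n_nodes, max_children = max_children,
               seed = seed)
}

#' Degree-preserving randomization by double edge swaps
#'
#' Repeatedly picks two edges (a,b), (c,d) and rewires them to (a,d), (c,b);
#' swaps that would create self-loops, multi-edges, or disconnect the graph
#' are rejected. The degree sequence is invariant.
#'
#' @param graph igraph object.
#' @param n_swaps Number of attempted swaps.
#' @param seed RNG seed.
#' @return A connected simple graph with the same degree sequence.
#' @export
degree_preserving_randomize <- function(graph, n_swaps, seed = NULL) {
  validate_graph(graph)
  if (!is.null(seed)) set.seed(seed)
  g <- graph
  for (k in seq_len(n_swaps)) {
    m <- igraph::ecount(g)
    ee <- sample(m, 2)
    ends <- igraph::ends(g, ee)
    a <- ends[1, 1]; b <- ends[1, 2]; c <- ends[2, 1]; d <- ends[2, 2]
    if (length(unique(c(a, b, c, d))) < 4) next
    if (igraph::are_adjacent(g, a, d) || igraph::are_adjacent(g, c, b)) next
    g2 <- igraph::delete_edges(g, ee)
    g2 <- igraph::add_edges(g2, c(a, d, c, b))
    if (!igraph::is_connected(g2)) next
    g <- g2
  }
  g
}

#' Empirical amplification factor of a graph
#'
#' Runs the constant-selection Birth-death process (no ecological selection,
#' mutant fitness `1 + s_probe`), estimates the fixation probability `Phi`
#' by Monte Carlo, and solves the defining relation
#' `Phi = (1 - (1+s)^(-a)) / (1 - (1+s)^(-aN))`
#' for the amplification factor `a`. `method = "weak_linear"` instead uses
#' the weak-selection linearization `a = 2 (Phi - 1/N) / s_probe`.
#'
#' @param graph igraph object.
#' @param s_probe Probe selection coefficient (> 0, small).
#' @param replicates Monte-Carlo replicates (>= 1e4 recommended).
#' @param seed Master seed.
#' @param method `"empirical_eq20"` (root solve of the defining relation) or
#'   `"weak_linear"`.
#' @param a_max Upper end of the root bracket.
#' @return List with `a_bd`, `phi`, `se`, `method`.
#' @export
estimate_amplification <- function(graph, s_probe = 0.005,
                                   replicates = 1e5, seed = 1,
                                   method = c("empirical_eq20", "weak_linear"),
                                   a_max = 20) {
  method <- match.arg(method)
  stopifnot(s_probe > 0)
  N <- igraph::vcount(graph)
  params <- eco_params(N, s_probe, alpha = 0.5)
  est <- estimate_fixation(graph, params,
                           sim_config(replicates = replicates, seed = seed))
  phi <- est$p_fix
  if (phi <= 0 || phi >= 1) {
    stop("fixation estimate ", phi, " unusable for amplification estimation")
  }
  a_bd <- if (method == "weak_linear") {
    2 * (phi - 1 / N) / s_probe
  } else {
    g <- function(a) (1 - (1 + s_probe)^(-a)) / (1 - (1 + s_probe)^(-a * N)) - phi
    lo <- 1e-3
    if (g(lo) * g(a_max) > 0) stop("no amplification root in (", lo, ", ", a_max, "]")
    stats::uniroot(g, c(lo, a_max), tol = 1e-10)$root
  }
  list(a_bd = a_bd, phi = phi, se = est$p_fix_se, method = method,
       s_probe = s_probe, replicates = replicates)
}
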