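#' Global regression of structure time courses
#'
#' Removes the strong global response shared by all structures: the global
#' mean trace (mean over structures) is regressed out of every structure's
#' trace by OLS (intercept + global mean), leaving the residuals. If the
#' global mean has zero variance the traces are only mean-centered (with a
#' warning).
#'
#' @param traces Matrix (n_structures x n_timepoints) of structure traces.
#' @return Matrix of residual traces, same shape; the global mean trace is
#'   attached as attribute `global_mean`.
#' @export
global_regression <- function(traces) {
  stopifnot(is.matrix(traces), nrow(traces) >= 2)
  g <- colMeans(traces)
  if (stats::sd(g) == 0) {
    warning("global mean has zero variance; mean-centering only")
    out <- traces - rowMeans(traces)
    attr(out, "global_mean") <- g
    return(out)
  }
  X <- cbind(intercept = 1, global = g)
  B <- solve(crossprod(X), crossprod(X, t(traces)))  # 2 x n_structures
  out <- traces - t(X %*% B)
  attr(out, "global_mean") <- g
  out
}

#' Fisher-z adjacency matrix from structure traces
#'
#' Pairwise Pearson correlation between all structure traces, transformed
#' to Fisher z = atanh(r) (|r| clipped at 1 - 1e-7 so degenerate traces
#' stay finite). Constant traces yield undefined rows/columns (NA) and are
#' listed in attribute `excluded`.
#'
#' @param traces Matrix (n_structures x n_timepoints), typically residuals
#'   from [global_regression()]. At least 3 time points.
#' @param nodes Optional node ids (default: row order).
#' @return N x N symmetric matrix of Fisher-z values (class
#'   `adjacency_matrix`), NA diagonal.
#' @export
build_adjacency <- function(traces, nodes = NULL) {
  stopifnot(is.matrix(traces), ncol(traces) >= 3)
  n <- nrow(traces)
  if (is.null(nodes)) nodes <- rownames(traces) %||% as.character(seq_len(n))
  sds <- apply(traces, 1, stats::sd)
  excluded <- which(sds == 0 | !is.finite(sds))
  if (length(excluded))
    warning("constant trace(s) excluded from adjacency: ",
            paste(nodes[excluded], collapse = ", "))
  r <- suppressWarnings(stats::cor(t(traces)))
  z <- fisher_z(r)
  if (length(excluded)) z[excluded, ] <- z[, excluded] <- NA_real_
  diag(z) <- NA_real_
  dimnames(z) <- list(nodes, nodes)
  attr(z, "excluded") <- excluded
  class(z) <- c("adjacency_matrix", class(z))
  z
}

#' Element-wise mean of adjacency matrices
#'
#' The group-level matrix: element-wise mean of per-animal Fisher-z
#' matrices (NAs removed per element).
#'
#' @param mats List of N x N matrices with identical node sets.
#' @export
adjacency_group_mean <- function(mats) {
  stopifnot(length(mats) >= 1)
  A <- Reduce(`+`, lapply(mats, function(m) {
    m[is.na(m)] <- 0
    m
  }))
  Wn <- Reduce(`+`, lapply(mats, function(m) !is.na(m)))
  out <- A / pmax(Wn, 1)
  out[Wn == 0] <- NA_real_
  dimnames(out) <- dimnames(mats[[1]])
  class(out) <- c("adjacency_matrix", "matrix", "array")
  out
}

#' k-standardize an adjacency matrix into a brain network
#'
#' Retains exactly the m strongest positive connections, m = N*k/2 for a
#' symmetric matrix (each undirected pair counted once) or N*k for a
#' directed one, so that every network carries the same number of edges
#' (mean degree k) regardless of its overall correlation level. Ties are
#' broken deterministically by ascending (i, j) index. If fewer positive
#' entries exist than requested, all are kept with a warning.
#'
#' @param mat N x N matrix of Fisher-z (or r) values; NA entries ignored.
#' @param k Target mean degree (default 10).
#' @param mode `"symmetric"` (uses the upper triangle) or `"directed"`.
#' @param node_info Optional data.frame with per-node metadata (must have
#'   N rows; e.g. functional_group, x/y/z positions).
#' @return An object of class `brain_network`: list with `edges`
#'   (data.frame: from, to, weight (z), weight_r), `nodes`, `n_nodes`, `k`,
#'   `mode`, `node_info`.
#' @export
k_standardize <- function(mat, k = 10, mode = c("symmetric", "directed"),
                          node_info = NULL) {
  mode <- match.arg(mode)
  if (k <= 0) stop("k must be positive")
  n <- nrow(mat)
  stopifnot(n == ncol(mat))
  nodes <- rownames(mat) %||% as.character(seq_len(n))
  if (mode == "symmetric") {
    m_target <- round(n * k / 2)
    idx <- which(upper.tri(mat), arr.ind = TRUE)
  } else {
    m_target <- round(n * k)
    idx <- which(row(mat) != col(mat), arr.ind = TRUE)
  }
  w <- mat[idx]
  pos <- which(!is.na(w) & w > 0)
  if (length(pos) < m_target)
    warning("only ", length(pos), " positive connections available; ",
            "requested ", m_target)
  ord <- pos[order(-w[pos], idx[pos, 1], idx[pos, 2])]
  keep <- ord[seq_len(min(m_target, length(ord)))]
  edges <- data.frame(from = idx[keep, 1], to = idx[keep, 2],
                      weight = w[keep], weight_r = tanh(w[keep]))
  structure(list(edges = edges, nodes = nodes, n_nodes = n, k = k,
                 mode = mode, node_info = node_info),
            class = "brain_network")
}

#' @export
print.brain_network <- function(x, ...) {
  cat(sprintf("Brain network: %d nodes, %d %s edges (k = %g)\n",
              x$n_nodes, nrow(x$edges), x$mode, x$k))
  invisible(x)
}

#' Number of edges
#' @param network A `brain_network`.
#' @export
n_edges <- function(network) nrow(network$edges)

# igraph view of a brain network (binarized topology or weighted).
as_igraph <- function(network, weighted = FALSE) {
  g <- igraph::make_empty_graph(n = network$n_nodes,
                                directed = network$mode == "directed")
  if (nrow(network$edges) > 0) {
    g <- igraph::add_edges(g, rbind(network$edges$from, network$edges$to))
    if (weighted) igraph::E(g)$weight <- network$edges$weight
  }
  igraph::V(g)$name <- network$nodes
  g
}

#' Small-world metrics
#'
#' Computes the binary clustering coefficient C (mean local clustering,
#' nodes with degree < 2 contributing 0) and characteristic path length L
#' (mean shortest path over connected ordered pairs) of the k-standardized
#' network, normalizes them against the means of `n_random` uniform random
#' graphs with the same node and edge count, and reports
#' gamma = C / <C_rand>, lambda = L / <L_rand> and the small-world index
#' sigma = gamma / lambda.
#'
#' @param network A `brain_network` (binarized for topology).
#' @param n_random Number of random reference graphs.
#' @param seed Seed for the random references.
#' @param reference Null model: uniform `"gnm"` graphs with matched node
#'   and edge count (default) or degree-preserving `"rewire"` of the
#'   network itself.
#' @return List with `gamma`, `lambda`, `sigma`, `C`, `L`, `C_rand`,
#'   `L_rand`, `n_random`, `seed`, `connected` (is the graph connected?).
#' @export
small_world <- function(network, n_random = 100, seed = 1,
                        reference = c("gnm", "rewire")) {
  reference <- match.arg(reference)
  if (n_edges(network) == 0) stop("small-world metrics undefined on an empty graph")
  g <- igraph::as_undirected(as_igraph(network), mode = "collapse")
  C <- clustering_coefficient(g)
  L <- igraph::mean_distance(g, unconnected = TRUE)
  nv <- igraph::vcount(g)
  ne <- igraph::ecount(g)
  rng <- local_rng(seed)
  Cr <- Lr <- numeric(n_random)
  for (i in seq_len(n_random)) {
    gr <- if (reference == "gnm") igraph::sample_gnm(nv, ne) else
      igraph::rewire(g, igraph::keeping_degseq(niter = 20 * ne))
    Cr[i] <- clustering_coefficient(gr)
    Lr[i] <- igraph::mean_distance(gr, unconnected = TRUE)
  }
  gamma <- C / mean(Cr)
  lambda <- L / mean(Lr)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       C = C, L = L, C_rand = mean(Cr), L_rand = mean(Lr),
       n_random = n_random, seed = seed,
       connected = igraph::is_connected(g))
}

# Mean local clustering coefficient; degree < 2 nodes count as 0.
clustering_coefficient <- function(g) {
  lc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  lc[is.na(lc)] <- 0
  mean(lc)
}

#' Louvain (Blondel) community detection
#'
#' Greedy modularity optimization on the edge weights of the network;
#' deterministic under a fixed seed.
#'
#' @param network A `brain_network` with at least one edge.
#' @param seed RNG seed.
#' @return List with `membership` (named integer vector), `modularity`,
#'   `n_communities`, `seed`.
#' @export
blondel_communities <- function(network, seed = 1) {
  if (n_edges(network) == 0) stop("community detection needs at least one edge")
  g <- igraph::as_undirected(as_igraph(network, weighted = TRUE),
                             mode = "collapse", edge.attr.comb = "mean")
  rng <- local_rng(seed)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  mem <- igraph::membership(cl)
  list(membership = stats::setNames(as.integer(mem), network$nodes),
       modularity = igraph::modularity(cl),
       n_communities = length(unique(as.integer(mem))),
       seed = seed)
}

#' Condense a network by functional group
#'
#' Merges structures into their functional groups: condensed node degree is
#' the sum of member degrees and condensed edge weight the sum of the
#' member edges' Pearson r. With `respect_communities`, structures are
#' merged per (functional group, community) pair so that e.g. the two
#' hemispheres' sensory cortices stay separate when Louvain splits them.
#' Edges inside one condensed node are kept as self-loops so total edge
#' weight is conserved.
#'
#' @param network A `brain_network`.
#' @param structure_table data.frame with label_id and functional_group
#'   covering every node.
#' @param respect_communities Merge within communities only?
#' @param communities Result of [blondel_communities()] (required when
#'   `respect_communities`).
#' @param positions Optional n_nodes x 3 matrix of node positions; the
#'   condensed node position is the member mean (center of gravity).
#' @return List with `nodes` (data.frame: id, functional_group, community,
#'   degree, n_members, x, y, z), `edges` (data.frame: from, to, weight_r,
#'   n_member_edges).
#' @export
aggregate_functional_groups <- function(network, structure_table,
                                        respect_communities = FALSE,
                                        communities = NULL,
                                        positions = NULL) {
  fg <- structure_table$functional_group[
    match(network$nodes, as.character(structure_table$label_id))]
  if (any(is.na(fg))) stop("unknown functional group for node(s): ",
                           paste(network$nodes[is.na(fg)], collapse = ", "))
  comm <- if (respect_communities) {
    if (is.null(communities)) stop("communities required")
    communities$membership[network$nodes]
  } else rep(1L, network$n_nodes)
  key <- paste(fg, comm, sep = "@")
  ids <- unique(key)
  gidx <- match(key, ids)
  ed <- network$edges
  deg <- tabulate(c(ed$from, ed$to), nbins = network$n_nodes)
  degsum <- rowsum(deg, gidx)  # rows ordered by group index
  nodes <- data.frame(
    id = ids,
    functional_group = sub("@.*$", "", ids),
    community = as.integer(sub("^.*@", "", ids)),
    degree = as.integer(degsum[as.character(seq_along(ids)), ]),
    n_members = as.integer(table(factor(gidx, seq_along(ids)))))
  if (!is.null(positions)) {
    pos <- rowsum(positions, gidx) / as.numeric(table(factor(gidx,
                                                             seq_along(ids))))
    nodes$x <- pos[, 1]; nodes$y <- pos[, 2]; nodes$z <- pos[, 3]
  }
  ef <- gidx[ed$from]; et <- gidx[ed$to]
  lo <- pmin(ef, et); hi <- pmax(ef, et)
  ekey <- paste(lo, hi)
  agg <- rowsum(cbind(weight_r = ed$weight_r, n = 1), ekey)
  parts <- do.call(rbind, strsplit(rownames(agg), " "))
  edges <- data.frame(from = ids[as.integer(parts[, 1])],
                      to = ids[as.integer(parts[, 2])],
                      weight_r = agg[, 1],
                      n_member_edges = as.integer(agg[, 2]))
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

#' Kamada-Kawai 2D layout of a network
#'
#' @param network A `brain_network`.
#' @param seed RNG seed (layout initialization).
#' @return data.frame (node, x, y).
#' @export
layout_kamada_kawai <- function(network, seed = 1) {
  g <- as_igraph(network, weighted = TRUE)
  rng <- local_rng(seed)
  xy <- igraph::layout_with_kk(igraph::as_undirected(g, mode = "collapse"))
  data.frame(node = network$nodes, x = xy[, 1], y = xy[, 2])
}

#' Write an adjacency matrix / network edge list as TSV
#'
#' @param mat Adjacency matrix (node-id header preserved).
#' @param path Output path.
#' @param provenance Optional list written as a JSON sidecar.
#' @export
write_adjacency_tsv <- function(mat, path, provenance = NULL) {
  df <- data.frame(node = rownames(mat), as.data.frame(unclass(mat)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(provenance))
    jsonlite::write_json(provenance, sub("\\.tsv$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_adjacency_tsv
#' @param network A `brain_network`.
#' @export
write_network_tsv <- function(network, path, provenance = NULL) {
  ed <- network$edges
  ed$node_i <- network$nodes[ed$from]
  ed$node_j <- network$nodes[ed$to]
  utils::write.table(ed[, c("node_i", "node_j", "weight", "weight_r")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(provenance))
    jsonlite::write_json(provenance, sub("\\.tsv$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}
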