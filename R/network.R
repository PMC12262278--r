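# Interaction network layer: genomic bins are vertices (named by their
# 0-based start coordinate), desert-filtered significant contacts are edges.
# Community detection and all module statistics run on induced subgraphs.

#' Build the interaction network from filtered significant contacts
#'
#' One vertex per distinct bin, one edge per distinct bin pair; self pairs
#' and parallel edges are dropped (simple undirected graph). Edge attributes
#' `probability` and `count` are carried over when present.
#'
#' @param significant filtered significant contacts.
#' @param chrom chromosome name stored as a graph attribute.
#' @param resolution bin width in bp, stored as a graph attribute.
#' @return an undirected `igraph` graph.
#' @export
build_network <- function(significant, chrom = NULL, resolution = NULL) {
  sig <- significant[significant$start1 != significant$start2, , drop = FALSE]
  if (nrow(sig) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    el <- data.frame(from = as.character(sig$start1),
                     to = as.character(sig$start2))
    if (!is.null(sig$probability)) el$probability <- sig$probability
    if (!is.null(sig$count)) el$count <- sig$count
    g <- igraph::graph_from_data_frame(el, directed = FALSE)
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                          edge.attr.comb = "first")
  }
  g <- igraph::set_graph_attr(g, "chrom",
                              chrom %||% unique(significant$chrom)[1])
  g <- igraph::set_graph_attr(g, "resolution", resolution)
  g
}

# eigenvector centrality per connected component, each component scaled so
# its maximum score is 1; isolated vertices score 1 trivially
eigencentrality_by_component <- function(g) {
  scores <- stats::setNames(numeric(igraph::vcount(g)),
                            igraph::V(g)$name)
  comp <- igraph::components(g)
  for (c_id in seq_len(comp$no)) {
    vs <- names(comp$membership)[comp$membership == c_id]
    if (length(vs) == 1L) {
      scores[vs] <- 1
    } else {
      sub <- igraph::induced_subgraph(g, vs)
      ec <- igraph::eigen_centrality(sub)$vector  # max-scaled by igraph
      scores[names(ec)] <- ec
    }
  }
  scores
}

new_chromatin_modules <- function(df, nodes, centrality, chrom, resolution) {
  attr(df, "nodes") <- nodes
  attr(df, "centrality") <- centrality
  attr(df, "chrom") <- chrom
  attr(df, "resolution") <- resolution
  class(df) <- c("chromatin_modules", "data.frame")
  df
}

empty_modules <- function(chrom = NA_character_, resolution = NULL) {
  df <- data.frame(module_id = character(), chrom = character(),
                   span_start = numeric(), span_end = numeric(),
                   n_nodes = integer(), connectivity = integer(),
                   transitivity = numeric(),
                   central_node_start = numeric(),
                   central_node_score = numeric())
  new_chromatin_modules(df, list(), list(), chrom, resolution)
}

#' Detect chromatin interaction modules
#'
#' Partitions the interaction network into communities by label propagation
#' (default, order-dependent hence seeded) or Louvain clustering, discards
#' communities with fewer than `min_nodes` nodes, and scores each retained
#' module: connectivity (induced edge count), global transitivity of the
#' induced subgraph (0 when no connected triplet exists), and eigenvector
#' centrality normalized to a maximum of 1, with the central node being the
#' top-scoring node (ties broken toward the smallest genomic coordinate).
#'
#' @param net interaction network from [build_network()].
#' @param method `"label_prop"` or `"louvain"`.
#' @param min_nodes minimum module size (default 4, i.e. more than 3 nodes).
#' @param seed RNG seed making the clustering reproducible.
#' @return a `chromatin_modules` data.frame (one row per module, ordered by
#'   genomic span) with per-module node sets and centrality maps attached as
#'   attributes; see [module_nodes()].
#' @export
detect_modules <- function(net, method = c("label_prop", "louvain"),
                           min_nodes = 4L, seed = 42L) {
  method <- match.arg(method)
  chrom <- igraph::graph_attr(net, "chrom")
  resolution <- igraph::graph_attr(net, "resolution")
  if (igraph::vcount(net) == 0L) return(empty_modules(chrom, resolution))
  set.seed(seed)
  comm <- switch(method,
                 label_prop = igraph::cluster_label_prop(net),
                 louvain = igraph::cluster_louvain(net))
  memb <- igraph::membership(comm)
  groups <- split(names(memb), as.integer(memb))
  groups <- groups[vapply(groups, length, integer(1)) >= min_nodes]
  if (length(groups) == 0L) return(empty_modules(chrom, resolution))
  groups <- groups[order(vapply(groups,
                                function(v) min(as.numeric(v)), numeric(1)))]
  res <- resolution %||% 0
  rows <- vector("list", length(groups))
  cents <- vector("list", length(groups))
  for (m in seq_along(groups)) {
    nodes <- groups[[m]]
    starts <- as.numeric(nodes)
    sub <- igraph::induced_subgraph(net, nodes)
    tr <- igraph::transitivity(sub, type = "global")
    if (is.nan(tr)) tr <- 0
    cen <- eigencentrality_by_component(sub)
    top <- names(cen)[cen >= max(cen) - 1e-10]
    central <- min(as.numeric(top))
    rows[[m]] <- data.frame(
      module_id = sprintf("%s_M%03d", chrom %||% "mod", m),
      chrom = chrom %||% NA_character_,
      span_start = min(starts),
      span_end = max(starts) + res,
      n_nodes = length(nodes),
      connectivity = igraph::ecount(sub),
      transitivity = tr,
      central_node_start = central,
      central_node_score = unname(cen[as.character(central)]))
    cents[[m]] <- cen
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  names(groups) <- df$module_id
  names(cents) <- df$module_id
  new_chromatin_modules(df, groups, cents, chrom, resolution)
}

#' Node membership of detected modules
#'
#' @param modules a `chromatin_modules` object.
#' @param id optional module id; when given, returns that module's node names
#'   (bin start coordinates as character), otherwise the full named list.
#' @export
module_nodes <- function(modules, id = NULL) {
  nodes <- attr(modules, "nodes")
  if (is.null(id)) nodes else nodes[[id]]
}

#' @export
print.chromatin_modules <- function(x, ...) {
  cat(nrow(x), "chromatin interaction module(s) on",
      attr(x, "chrom") %||% "?", "\n")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  invisible(x)
}

#' Connectivity of a node set: induced edge count
#'
#' @param net interaction network.
#' @param nodes character (or numeric) vertex names.
#' @return number of network edges with both endpoints in `nodes`.
#' @export
module_connectivity <- function(net, nodes) {
  nodes <- intersect(as.character(nodes), igraph::V(net)$name)
  igraph::ecount(igraph::induced_subgraph(net, nodes))
}

#' Global transitivity of a node set's induced subgraph
#'
#' 3 x triangles / connected triplets; 0 when the induced subgraph has no
#' connected triplet.
#'
#' @inheritParams module_connectivity
#' @export
module_transitivity <- function(net, nodes) {
  nodes <- intersect(as.character(nodes), igraph::V(net)$name)
  tr <- igraph::transitivity(igraph::induced_subgraph(net, nodes),
                             type = "global")
  if (is.nan(tr)) 0 else tr
}

#' Eigenvector centrality of a node set's induced subgraph
#'
#' Principal-eigenvector scores of the induced adjacency matrix, computed per
#' connected component and normalized so the maximum score is 1. On an
#' undirected graph these coincide with igraph's authority scores.
#'
#' @inheritParams module_connectivity
#' @return list with `scores` (named vector) and `central_node` (numeric bin
#'   start of the top-scoring node, ties broken toward the smallest
#'   coordinate).
#' @export
module_centrality <- function(net, nodes) {
  nodes <- intersect(as.character(nodes), igraph::V(net)$name)
  cen <- eigencentrality_by_component(igraph::induced_subgraph(net, nodes))
  top <- names(cen)[cen >= max(cen) - 1e-10]
  list(scores = cen, central_node = min(as.numeric(top)))
}

#' Node degree distribution of a network
#'
#' @param net interaction network.
#' @return data.frame with `degree`, `count` (summing to the node count),
#'   `density`, and `log_density` (natural log; `NA` for zero densities).
#' @export
degree_distribution <- function(net) {
  deg <- igraph::degree(net)
  tab <- table(deg)
  count <- as.integer(tab)
  density <- count / igraph::vcount(net)
  data.frame(degree = as.integer(names(tab)), count = count,
             density = density,
             log_density = ifelse(density > 0, log(density), NA_real_))
}
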