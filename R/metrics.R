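#' Census of connected components
#'
#' Partitions the network into its giant component (GC), lexical islands
#' (components of size >= 2 other than the GC), and isolates ("lexical
#' hermits", degree-0 nodes). Ties for the largest component are broken
#' deterministically in favour of the component containing the
#' lexicographically smallest node name. On an edgeless graph the GC is a
#' single node by convention.
#'
#' @param network An igraph.
#' @return A `component_census`: list with `sizes` (component size
#'   vector), `membership`, `gc_nodes` (character vector of names),
#'   `gc_size`, `n_isolates`, `n_islands`, `island_words` (node count in
#'   islands), and `n_nodes`.
#' @export
component_census <- function(network) {
  stopifnot(igraph::is_igraph(network))
  comp <- igraph::components(network)
  nm <- igraph::V(network)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(network)))
  gc_size <- max(comp$csize)
  cand <- which(comp$csize == gc_size)
  if (length(cand) > 1L) {
    first_name <- vapply(cand, function(ci) min(nm[comp$membership == ci]), "")
    cand <- cand[order(first_name)[1L]]
  }
  gc_id <- cand[1L]
  gc_nodes <- nm[comp$membership == gc_id]
  deg <- igraph::degree(network)
  n_isolates <- sum(deg == 0L)
  island_ids <- setdiff(which(comp$csize >= 2L), gc_id)
  structure(
    list(sizes = comp$csize, membership = comp$membership,
         gc_nodes = gc_nodes, gc_size = gc_size,
         n_isolates = n_isolates,
         n_islands = length(island_ids),
         island_words = sum(comp$csize[island_ids]),
         n_nodes = igraph::vcount(network)),
    class = "component_census"
  )
}

#' @export
print.component_census <- function(x, ...) {
  cat(sprintf(
    "component_census: %d nodes | GC %d (%.0f%%) | isolates %d (%.0f%%) | %d islands (%d words)\n",
    x$n_nodes, x$gc_size, 100 * x$gc_size / x$n_nodes,
    x$n_isolates, 100 * x$n_isolates / x$n_nodes,
    x$n_islands, x$island_words))
  invisible(x)
}

# Extract the giant-component subgraph.
gc_subgraph <- function(network, census = component_census(network)) {
  igraph::induced_subgraph(network, census$gc_nodes)
}

#' Detect communities and modularity in a connected subgraph
#'
#' Louvain-style greedy modularity maximisation (resolution 1 by default),
#' seeded for reproducibility. Q is the Newman-Girvan modularity of the
#' returned partition.
#'
#' @param subgraph A connected igraph (typically the giant component).
#' @param resolution Resolution parameter of the Louvain objective.
#' @param seed Integer seed for the (stochastic) heuristic.
#' @return List with `membership`, `n_communities`, `modularity`.
#' @export
detect_communities <- function(subgraph, resolution = 1, seed = 1L) {
  stopifnot(igraph::is_igraph(subgraph))
  cl <- with_rng_seed(seed,
    igraph::cluster_louvain(subgraph, resolution = resolution))
  membership <- igraph::membership(cl)
  list(membership = membership,
       n_communities = length(unique(membership)),
       modularity = igraph::modularity(subgraph, membership))
}

#' Average local clustering coefficient of a subgraph
#'
#' Mean over all nodes of the proportion of a node's neighbor pairs that
#' are themselves connected. Nodes with degree < 2 contribute 0 (they
#' have no neighbor pairs).
#'
#' @param subgraph An igraph (typically the giant component).
#' @return Numeric in \[0, 1\].
#' @export
avg_clustering <- function(subgraph) {
  if (igraph::vcount(subgraph) == 0L) return(NA_real_)
  mean(igraph::transitivity(subgraph, type = "local", isolates = "zero"))
}

#' Average shortest path length of a connected subgraph
#'
#' Exact breadth-first mean distance over unordered node pairs; errors on
#' disconnected input (use [component_census()] to supply the giant
#' component).
#'
#' @param subgraph A connected igraph.
#' @return Numeric >= 1 when the subgraph has >= 2 nodes; NA for a single
#'   node.
#' @export
aspl <- function(subgraph) {
  n <- igraph::vcount(subgraph)
  if (n <= 1L) return(NA_real_)
  if (!igraph::is_connected(subgraph)) {
    stop("subgraph is disconnected; pass the giant component")
  }
  igraph::mean_distance(subgraph, directed = FALSE)
}

#' Resilience flag from the 1.5x ASPL heuristic
#'
#' Point estimates of ASPL across damage stages admit no inferential
#' test, so a network is flagged as having lost resilience when its ASPL
#' is at least 1.5 times the intact network's ASPL.
#'
#' @param aspl_value ASPL of the (possibly damaged) network.
#' @param intact_aspl ASPL of the intact network.
#' @return Logical: `TRUE` when `aspl_value >= 1.5 * intact_aspl`.
#' @examples
#' resilience_flag(11.93, 6.05) # TRUE: 11.93 >= 9.075
#' resilience_flag(6.12, 6.05)  # FALSE
#' @export
resilience_flag <- function(aspl_value, intact_aspl) {
  stopifnot(aspl_value > 0, intact_aspl > 0)
  aspl_value >= 1.5 * intact_aspl
}

#' Structural metric panel for one network
#'
#' Computes the full descriptive panel: edge count, giant component size
#' and percentage, isolate count and percentage, island count and word
#' total, communities and modularity in the GC, average degree (whole
#' network and GC), average clustering in the GC, ASPL in the GC, and the
#' resilience flag relative to a reference (intact) ASPL.
#'
#' @param network An igraph.
#' @param intact_aspl Reference ASPL for the resilience flag; `NULL`
#'   (e.g. for the intact network itself) gives flag `FALSE`.
#' @param community_seed Seed for community detection.
#' @return One-row data frame.
#' @export
network_panel <- function(network, intact_aspl = NULL, community_seed = 1L) {
  census <- component_census(network)
  gc <- gc_subgraph(network, census)
  n <- census$n_nodes
  comm <- if (igraph::ecount(gc) > 0L) {
    detect_communities(gc, seed = community_seed)
  } else {
    list(n_communities = NA_integer_, modularity = NA_real_)
  }
  aspl_value <- aspl(gc)
  flagged <- if (is.null(intact_aspl) || is.na(aspl_value)) FALSE else {
    resilience_flag(aspl_value, intact_aspl)
  }
  data.frame(
    n_nodes = n,
    n_edges = igraph::ecount(network),
    gc_size = census$gc_size,
    gc_pct = 100 * census$gc_size / n,
    n_isolates = census$n_isolates,
    isolate_pct = 100 * census$n_isolates / n,
    n_islands = census$n_islands,
    island_words = census$island_words,
    n_communities = comm$n_communities,
    modularity = comm$modularity,
    avg_degree = 2 * igraph::ecount(network) / n,
    avg_degree_gc = 2 * igraph::ecount(gc) / max(1L, igraph::vcount(gc)),
    avg_clustering_gc = avg_clustering(gc),
    aspl_gc = aspl_value,
    resilience_lost = flagged
  )
}

#' Metric panels along a damage trajectory
#'
#' One [network_panel()] row per stage, intact network first; resilience
#' flags are computed against the intact network's ASPL.
#'
#' @param trajectory A `damage_trajectory`.
#' @param community_seed Seed for community detection, shared across
#'   stages.
#' @return Data frame with one row per stage and a leading
#'   `fraction_removed` column.
#' @export
summarize_trajectory <- function(trajectory, community_seed = 1L) {
  stopifnot(inherits(trajectory, "damage_trajectory"))
  intact_census <- component_census(trajectory$stages[[1L]])
  intact_aspl <- aspl(gc_subgraph(trajectory$stages[[1L]], intact_census))
  rows <- lapply(seq_along(trajectory$stages), function(k) {
    ref <- if (k == 1L) NULL else intact_aspl
    cbind(fraction_removed = trajectory$fractions[k],
          network_panel(trajectory$stages[[k]], intact_aspl = ref,
                        community_seed = community_seed))
  })
  do.call(rbind, rows)
}
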