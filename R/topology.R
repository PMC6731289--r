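#' Detect network modules
#'
#' Community detection by deterministic greedy modularity maximization
#' (igraph's fast-greedy algorithm) on the unsigned, unweighted skeleton
#' of the graph. Isolated nodes and singleton components form their own
#' modules. The result is deterministic; `seed` is accepted for interface
#' stability.
#'
#' @param graph an undirected igraph (edge signs, if any, are ignored).
#' @param seed integer seed.
#' @return named integer vector: module id per node.
#' @export
detect_modules <- function(graph, seed = 1) {
  stopifnot(igraph::vcount(graph) > 0)
  g <- igraph::simplify(igraph::as_undirected(graph, mode = "collapse"))
  igraph::edge_attr(g) <- list()
  memb <- with_seed(seed, {
    if (igraph::ecount(g) == 0) seq_len(igraph::vcount(g))
    else {
      fg <- igraph::membership(igraph::cluster_fast_greedy(g))
      ## guard against the greedy merge path stopping short of the
      ## whole-component community (visible on bare cliques): fall back
      ## to connected components when they score at least as well
      comp <- igraph::components(g)$membership
      if (igraph::modularity(g, comp) >= igraph::modularity(g, fg)) comp
      else fg
    }
  })
  out <- as.integer(memb)
  names(out) <- igraph::V(g)$name
  out
}

#' Within-module degree z and participation coefficient
#'
#' Guimera-Amaral connectivity statistics on the unsigned skeleton.
#' z_i standardizes the node's within-own-module degree against the
#' distribution of within-module degrees in its module (zero spread or an
#' isolated node gives z = 0, so role assignment is total);
#' P_i = 1 - sum_s (k_is / k_i)^2 measures how evenly the node's links
#' spread over modules (isolated nodes get P = 0).
#'
#' @param graph an undirected igraph.
#' @param modules named integer vector from [detect_modules()] covering
#'   all nodes.
#' @return data.frame with columns `node_id`, `module_id`, `degree`,
#'   `within_degree`, `z`, `participation`.
#' @export
connectivity_stats <- function(graph, modules) {
  g <- igraph::simplify(igraph::as_undirected(graph, mode = "collapse"))
  nodes <- igraph::V(g)$name
  stopifnot(all(nodes %in% names(modules)))
  mod <- modules[nodes]
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  k <- rowSums(adj)
  mods <- sort(unique(mod))
  ## k_is: links of node i into module s
  kis <- sapply(mods, function(s) rowSums(adj[, mod == s, drop = FALSE]))
  kis <- matrix(kis, nrow = length(nodes), dimnames = list(nodes, mods))
  kown <- kis[cbind(seq_along(nodes), match(mod, mods))]
  z <- numeric(length(nodes))
  for (s in mods) {
    in_s <- mod == s
    mu <- mean(kown[in_s])
    sd_s <- stats::sd(kown[in_s])
    z[in_s] <- if (is.na(sd_s) || sd_s == 0) 0 else (kown[in_s] - mu) / sd_s
  }
  P <- ifelse(k == 0, 0, 1 - rowSums((kis / pmax(k, 1))^2))
  data.frame(node_id = nodes, module_id = as.integer(mod), degree = k,
             within_degree = kown, z = z, participation = P,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign Guimera-Amaral topological roles
#'
#' Peripheral (specialist): z <= z_thresh and P <= p_thresh; connector:
#' z <= z_thresh and P > p_thresh; module hub: z > z_thresh and
#' P <= p_thresh; network hub: z > z_thresh and P > p_thresh.
#'
#' @param z within-module degree z-score(s).
#' @param participation participation coefficient(s) in \[0, 1).
#' @param z_thresh hub threshold on z (default 2.5).
#' @param p_thresh connector threshold on P (default 0.62).
#' @return character vector of roles.
#' @export
assign_role <- function(z, participation, z_thresh = 2.5, p_thresh = 0.62) {
  ifelse(z <= z_thresh,
         ifelse(participation <= p_thresh, "peripheral", "connector"),
         ifelse(participation <= p_thresh, "module_hub", "network_hub"))
}

#' Full topological-role table for a network
#'
#' Runs module detection, connectivity statistics and role assignment.
#'
#' @param net a `cooccurrence_network` or an igraph.
#' @param seed seed for [detect_modules()].
#' @param z_thresh,p_thresh role thresholds, see [assign_role()].
#' @return data.frame (role table): `node_id`, `module_id`, `degree`,
#'   `within_degree`, `z`, `participation`, `role`.
#' @export
role_table <- function(net, seed = 1, z_thresh = 2.5, p_thresh = 0.62) {
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  modules <- detect_modules(g, seed = seed)
  stats <- connectivity_stats(g, modules)
  stats$role <- assign_role(stats$z, stats$participation,
                            z_thresh = z_thresh, p_thresh = p_thresh)
  stats
}

#' Network summary counts
#'
#' Node, signed-edge, module-membership and role counts for one inferred
#' network (the per-pathway summary layout used for digester
#' metaproteome networks). An edge is in-module iff both endpoints share
#' a module.
#'
#' @param net a `cooccurrence_network` from [infer_network()].
#' @param roles role table from [role_table()] for the same network.
#' @return one-row data.frame: `nodes`, `edges_positive`,
#'   `edges_negative`, `edges_in_module`, `edges_outside_module`,
#'   `edges_total`, `n_modules`, `connectors`, `module_hubs`,
#'   `network_hubs`, `peripherals`.
#' @export
summarize_network <- function(net, roles) {
  g <- net$graph
  mod <- stats::setNames(roles$module_id, roles$node_id)
  el <- igraph::as_edgelist(g)
  signs <- if (igraph::ecount(g)) igraph::E(g)$sign else integer(0)
  in_mod <- if (nrow(el)) mod[el[, 1]] == mod[el[, 2]] else logical(0)
  data.frame(
    nodes = igraph::vcount(g),
    edges_positive = sum(signs > 0),
    edges_negative = sum(signs < 0),
    edges_in_module = sum(in_mod),
    edges_outside_module = sum(!in_mod),
    edges_total = igraph::ecount(g),
    n_modules = length(unique(roles$module_id)),
    connectors = sum(roles$role == "connector"),
    module_hubs = sum(roles$role == "module_hub"),
    network_hubs = sum(roles$role == "network_hub"),
    peripherals = sum(roles$role == "peripheral"))
}
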