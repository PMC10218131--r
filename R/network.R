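#' Typed two-role networks
#'
#' The game runs on an undirected network whose nodes carry a role:
#' `"GRS"` (government resource subject) or `"SRS"` (social resource
#' subject). `typed_network()` builds and validates such a network from a
#' node table and an edge table; the result is an [igraph][igraph::graph]
#' object with a `role` vertex attribute and class `typed_network`, so all
#' igraph tooling applies.
#'
#' Validation rejects self-loops, duplicate edges, duplicate node ids,
#' unknown role labels, and edges whose endpoints are not in the node
#' table, naming the offending entry. Disconnectedness is *not* an error
#' here (see [network_report()]), only in the generator, which guarantees
#' connectivity by construction.
#'
#' @param nodes Data frame with columns `id` (unique character) and `role`
#'   (`"GRS"` or `"SRS"`).
#' @param edges Data frame with columns `source` and `target` (node ids).
#'   May have zero rows.
#' @return A `typed_network` (igraph) object. Vertices are ordered by
#'   sorted id so that node iteration order is reproducible.
#' @seealso [generate_network()], [read_network()], [network_report()]
#' @export
typed_network <- function(nodes, edges) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  if (!all(c("id", "role") %in% names(nodes)))
    stop("node table must have columns 'id' and 'role'", call. = FALSE)
  if (nrow(edges) > 0 && !all(c("source", "target") %in% names(edges)))
    stop("edge table must have columns 'source' and 'target'", call. = FALSE)
  nodes$id <- as.character(nodes$id)
  nodes$role <- as.character(nodes$role)
  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup))
    stop("duplicate node id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad_role <- !nodes$role %in% c("GRS", "SRS")
  if (any(bad_role))
    stop("unknown role label(s) for node(s) ",
         paste(nodes$id[bad_role], collapse = ", "),
         " (must be \"GRS\" or \"SRS\")", call. = FALSE)
  nodes <- nodes[order(nodes$id), c("id", "role")]
  if (nrow(edges) > 0) {
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    missing_ep <- !(edges$source %in% nodes$id) | !(edges$target %in% nodes$id)
    if (any(missing_ep)) {
      i <- which(missing_ep)[1]
      stop("edge ", edges$source[i], " -- ", edges$target[i],
           " (row ", i, ") references a node not in the node table",
           call. = FALSE)
    }
    loops <- edges$source == edges$target
    if (any(loops))
      stop("self-loop on node ", edges$source[which(loops)[1]],
           " (edge row ", which(loops)[1], ")", call. = FALSE)
    key <- paste(pmin(edges$source, edges$target),
                 pmax(edges$source, edges$target))
    if (anyDuplicated(key)) {
      i <- which(duplicated(key))[1]
      stop("duplicate edge ", edges$source[i], " -- ", edges$target[i],
           " (row ", i, ")", call. = FALSE)
    }
  }
  if (nrow(edges) == 0)
    edges <- data.frame(source = character(0), target = character(0))
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = nodes$id, role = nodes$role))
  class(g) <- c("typed_network", class(g))
  g
}

#' @export
print.typed_network <- function(x, ...) {
  r <- node_roles(x)
  cat(sprintf("Typed network: %d GRS + %d SRS nodes, %d edges, %s\n",
              sum(r == "GRS"), sum(r == "SRS"), igraph::ecount(x),
              if (igraph::is_connected(x)) "connected" else "disconnected"))
  invisible(x)
}

#' Node roles of a typed network
#'
#' @param net A [typed_network()].
#' @return Named character vector of `"GRS"`/`"SRS"` per node, in vertex
#'   order (sorted id for networks built by this package).
#' @export
node_roles <- function(net) {
  r <- igraph::vertex_attr(net, "role")
  names(r) <- igraph::V(net)$name
  r
}

#' Synthetic generator configuration
#'
#' Configuration for [generate_network()]. The defaults emulate the size
#' and composition of an empirical city-level emergency resource support
#' network: 19 GRS and 49 SRS nodes, connected, with both cross-type
#' (GRS--SRS) and same-type cooperative ties, cross-type ties dominant.
#'
#' @param n_grs,n_srs Node counts per role (each at least 1).
#' @param mean_degree Target mean degree; the total edge count is
#'   `round(mean_degree * n / 2)`. Must be at least `2 * (1 - 1/n)`
#'   (a spanning tree) and at most `n - 1` (the complete graph).
#' @param p_same_type Probability that a generated edge joins two nodes of
#'   the same role.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_grs = 19, n_srs = 49, mean_degree = 4,
                             p_same_type = 0.3, seed = 1L) {
  stopifnot(is.numeric(n_grs), n_grs >= 1, n_grs == round(n_grs),
            is.numeric(n_srs), n_srs >= 1, n_srs == round(n_srs),
            is.numeric(mean_degree), is.numeric(p_same_type),
            p_same_type >= 0, p_same_type <= 1,
            is.numeric(seed), is.finite(seed))
  n <- n_grs + n_srs
  if (mean_degree < 2 * (1 - 1 / n))
    stop("mean_degree ", mean_degree, " is below the spanning-tree minimum ",
         format(2 * (1 - 1 / n)), " for ", n, " nodes", call. = FALSE)
  if (mean_degree > n - 1)
    stop("mean_degree ", mean_degree, " exceeds the complete-graph maximum ",
         n - 1, " for ", n, " nodes", call. = FALSE)
  structure(list(n_grs = as.integer(n_grs), n_srs = as.integer(n_srs),
                 mean_degree = as.numeric(mean_degree),
                 p_same_type = as.numeric(p_same_type),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic two-role support network
#'
#' Builds a connected network of `n_grs` GRS and `n_srs` SRS nodes:
#' first a random spanning tree (each node attaches to a random earlier
#' node, the partner's role chosen same-type with probability
#' `p_same_type`), then additional random edges with the same same-/cross-
#' type mixture until `round(mean_degree * n / 2)` edges exist. The result
#' is connected by construction and deterministic for a fixed seed.
#'
#' This generator emulates the size, two-type composition and mixing of an
#' empirical case network whose exact topology is not published; its
#' parameters are exposed configuration, not constants.
#'
#' @param config A [generator_config()].
#' @return A [typed_network()] with node ids `G01..` (GRS) and `S01..`
#'   (SRS).
#' @examples
#' net <- generate_network(generator_config(seed = 42))
#' network_report(net)
#' @export
generate_network <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_grs + config$n_srs
  ids <- c(sprintf("G%0*d", max(2, nchar(config$n_grs)), seq_len(config$n_grs)),
           sprintf("S%0*d", max(2, nchar(config$n_srs)), seq_len(config$n_srs)))
  roles <- rep(c("GRS", "SRS"), c(config$n_grs, config$n_srs))
  n_edges_target <- round(config$mean_degree * n / 2)
  if (n_edges_target > choose(n, 2))
    stop("edge target ", n_edges_target, " exceeds the ", choose(n, 2),
         " possible edges", call. = FALSE)

  with_seed(config$seed, {
    # random attachment order mixes the two roles
    ord <- sample.int(n)
    src <- integer(0); dst <- integer(0)
    edge_seen <- new.env(hash = TRUE, parent = emptyenv())
    add_edge <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (a == b || !is.null(edge_seen[[key]])) return(FALSE)
      edge_seen[[key]] <- TRUE
      src <<- c(src, a); dst <<- c(dst, b)
      TRUE
    }
    pick_partner <- function(node, pool, want_same) {
      # honour the edge's same-/cross-type intent when the pool allows it
      same <- pool[roles[pool] == roles[node]]
      cross <- pool[roles[pool] != roles[node]]
      cand <- if (want_same) same else cross
      if (!length(cand)) cand <- if (want_same) cross else same
      cand[sample.int(length(cand), 1L)]
    }
    # commit the same-type intent per edge up front with exact counts, so the
    # realized same-type fraction concentrates tightly around p_same_type
    n_same <- round(config$p_same_type * n_edges_target)
    want <- sample(rep(c(TRUE, FALSE), c(n_same, n_edges_target - n_same)))
    for (k in 2:n) {                       # spanning tree: guarantees connectivity
      node <- ord[k]
      add_edge(node, pick_partner(node, ord[seq_len(k - 1L)], want[k - 1L]))
    }
    all_idx <- seq_len(n)
    guard <- 0L
    while (length(src) < n_edges_target) {
      a <- all_idx[sample.int(n, 1L)]
      b <- pick_partner(a, setdiff(all_idx, a), want[length(src) + 1L])
      if (!add_edge(a, b)) {
        guard <- guard + 1L
        if (guard > 1000L * n_edges_target)
          stop("could not reach the edge target; the same-/cross-type pool ",
               "is exhausted for this configuration", call. = FALSE)
      }
    }
    typed_network(data.frame(id = ids, role = roles),
                  data.frame(source = ids[src], target = ids[dst]))
  })
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Structural summary of a typed network
#'
#' @param net A [typed_network()].
#' @return A list: node counts per role, edge count, same-type edge
#'   fraction, connectivity flag, and ids of isolated nodes.
#' @export
network_report <- function(net) {
  r <- node_roles(net)
  el <- igraph::as_edgelist(net, names = TRUE)
  same <- if (nrow(el)) mean(r[el[, 1]] == r[el[, 2]]) else NA_real_
  deg <- igraph::degree(net)
  list(n_grs = sum(r == "GRS"), n_srs = sum(r == "SRS"),
       n_edges = igraph::ecount(net),
       mean_degree = mean(deg),
       same_type_fraction = same,
       connected = igraph::is_connected(net),
       isolated = names(deg)[deg == 0])
}

#' Read / write typed networks
#'
#' CSV form: a node file with columns `id,role` and an edge file with
#' columns `source,target`. GraphML form: a single file with a `role`
#' vertex attribute ([read_network_graphml()], [write_network_graphml()]).
#' Writing then reading is an identity on the node and edge sets. All
#' readers run the full [typed_network()] validation, so malformed input
#' (unknown role, dangling endpoint, duplicate id or edge) is rejected
#' with the offending entry named.
#'
#' @param node_file,edge_file CSV paths.
#' @param net A [typed_network()].
#' @param path GraphML path.
#' @return Readers return a `typed_network`; writers return the path(s)
#'   invisibly.
#' @export
read_network <- function(node_file, edge_file) {
  nodes <- utils::read.csv(node_file, colClasses = "character")
  edges <- utils::read.csv(edge_file, colClasses = "character")
  typed_network(nodes, edges)
}

#' @rdname read_network
#' @export
write_network <- function(net, node_file, edge_file) {
  r <- node_roles(net)
  utils::write.csv(data.frame(id = names(r), role = unname(r)),
                   node_file, row.names = FALSE, quote = FALSE)
  el <- igraph::as_edgelist(net, names = TRUE)
  utils::write.csv(data.frame(source = el[, 1], target = el[, 2]),
                   edge_file, row.names = FALSE, quote = FALSE)
  invisible(c(node_file, edge_file))
}

#' @rdname read_network
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (!"role" %in% igraph::vertex_attr_names(g))
    stop("GraphML file has no 'role' vertex attribute", call. = FALSE)
  if (!"name" %in% igraph::vertex_attr_names(g))
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = TRUE)
  typed_network(
    data.frame(id = igraph::V(g)$name, role = igraph::V(g)$role),
    data.frame(source = el[, 1], target = el[, 2]))
}

#' @rdname read_network
#' @export
write_network_graphml <- function(net, path) {
  g <- net
  class(g) <- "igraph"
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
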