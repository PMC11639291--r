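#' Directed relation graphs and causal DAGs
#'
#' A relation graph holds scored directed edges over disease codes, at most
#' one per ordered pair and without self-loops; it may contain cycles
#' (including antiparallel edge pairs). A causal DAG is the acyclic graph
#' produced by [build_dag()], which additionally records the edges removed
#' during cycle breaking.
#'
#' @param edges data frame with columns `cause`, `effect`, `score` (extra
#'   measure columns are carried through).
#' @param nodes optional character vector of node ids; defaults to the union
#'   of edge endpoints.
#' @return An object of class `relation_graph` with elements `nodes` and
#'   `edges`.
#' @export
relation_graph <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("cause", "effect", "score") %in% names(edges)))
  edges$cause <- as.character(edges$cause)
  edges$effect <- as.character(edges$effect)
  edges$score <- as.numeric(edges$score)
  if (any(!is.finite(edges$score))) abort("edge scores must be finite")
  if (any(edges$cause == edges$effect)) abort("self-loops are not allowed")
  if (anyDuplicated(paste(edges$cause, edges$effect))) {
    abort("duplicate directed edges")
  }
  nodes <- sort(unique(c(nodes, edges$cause, edges$effect)))
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "relation_graph")
}

#' @export
print.relation_graph <- function(x, ...) {
  cat(sprintf("<%s> %d nodes, %d edges", class(x)[1], length(x$nodes),
              nrow(x$edges)))
  if (inherits(x, "causal_dag")) {
    cat(sprintf(", %d removed during cycle breaking", nrow(x$removed)))
  }
  cat("\n")
  invisible(x)
}

#' Build a DAG by score-descending greedy insertion
#'
#' Edges are sorted by descending score (ties broken lexicographically by
#' (cause, effect), making the build deterministic) and inserted one at a
#' time. Whenever inserting an edge would close a directed cycle, the edge
#' with the lowest score in that cycle is removed; under descending-order
#' insertion every edge already present scores at least as high as the
#' newcomer, so the newcomer itself is discarded and recorded. The retained
#' set is the greedy-maximal acyclic subset under this ordering.
#'
#' @param graph a [relation_graph()] (or a bare scored edge data frame).
#' @return An object of class `causal_dag`/`relation_graph` with the
#'   acyclic `edges`, all `nodes` of the input (including any isolated by
#'   removals), and the `removed` edges in removal order.
#' @export
build_dag <- function(graph) {
  if (is.data.frame(graph)) graph <- relation_graph(graph)
  stopifnot(inherits(graph, "relation_graph"))
  e <- graph$edges
  ord <- order(-e$score, e$cause, e$effect)
  e <- e[ord, , drop = FALSE]
  adj <- new.env(parent = emptyenv())
  keep <- logical(nrow(e))
  for (i in seq_len(nrow(e))) {
    u <- e$cause[i]; v <- e$effect[i]
    if (reaches(adj, v, u)) next  # would close a cycle: drop the newcomer
    keep[i] <- TRUE
    assign(u, c(adj_get(adj, u), v), envir = adj)
  }
  kept <- e[keep, , drop = FALSE]
  removed <- e[!keep, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  structure(list(nodes = graph$nodes, edges = kept, removed = removed),
            class = c("causal_dag", "relation_graph"))
}

adj_get <- function(adj, key) {
  if (exists(key, envir = adj, inherits = FALSE)) get(key, envir = adj)
  else character(0)
}

# iterative DFS: is `to` reachable from `from` along the adjacency list?
reaches <- function(adj, from, to) {
  if (from == to) return(TRUE)
  stack <- from
  seen <- new.env(parent = emptyenv())
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (exists(node, envir = seen, inherits = FALSE)) next
    assign(node, TRUE, envir = seen)
    nxt <- adj_get(adj, node)
    if (to %in% nxt) return(TRUE)
    stack <- c(stack, nxt)
  }
  FALSE
}

# igraph view of a relation graph (internal)
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("cause", "effect"), drop = FALSE],
    directed = TRUE, vertices = graph$nodes)
}

#' Test whether a relation graph is acyclic
#' @param graph a [relation_graph()] or `causal_dag`.
#' @return `TRUE` iff the directed graph has no cycle.
#' @export
is_acyclic <- function(graph) {
  stopifnot(inherits(graph, "relation_graph"))
  if (nrow(graph$edges) == 0) return(TRUE)
  igraph::is_dag(as_igraph(graph))
}

#' Parent set of a node
#'
#' The directly connected causative diseases of `node`: all `x` with an
#' edge `x -> node`.
#'
#' @param dag a `causal_dag` (any [relation_graph()] accepted).
#' @param node a node id present in the graph.
#' @return Character vector of parent codes (possibly empty), sorted.
#' @export
dag_parents <- function(dag, node) {
  stopifnot(inherits(dag, "relation_graph"), is_string(node))
  if (!node %in% dag$nodes) abort("unknown node: %s", node)
  sort(unique(dag$edges$cause[dag$edges$effect == node]))
}

#' Directed reachability between two nodes
#'
#' @param dag a [relation_graph()] or `causal_dag`.
#' @param x,y node ids present in the graph.
#' @return `TRUE` iff a directed path (length >= 1) from `x` to `y` exists.
#' @export
has_directed_path <- function(dag, x, y) {
  stopifnot(inherits(dag, "relation_graph"))
  if (!all(c(x, y) %in% dag$nodes)) abort("unknown node(s)")
  adj <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(dag$edges))) {
    u <- dag$edges$cause[i]
    assign(u, c(adj_get(adj, u), dag$edges$effect[i]), envir = adj)
  }
  if (x == y) {
    # a path of length >= 1 back to itself would be a cycle through x
    return(any(vapply(adj_get(adj, x), function(s) reaches(adj, s, x), TRUE)))
  }
  reaches(adj, x, y)
}

#' All descendants of a node
#' @param dag a [relation_graph()] or `causal_dag`.
#' @param node a node id.
#' @return Character vector of nodes reachable from `node` (excluding it
#'   unless it lies on a cycle).
#' @export
dag_descendants <- function(dag, node) {
  stopifnot(inherits(dag, "relation_graph"))
  if (!node %in% dag$nodes) abort("unknown node: %s", node)
  g <- as_igraph(dag)
  out <- igraph::subcomponent(g, node, mode = "out")
  setdiff(names(out), node)
}

#' Write a DAG (or relation graph) as edge-list TSV
#'
#' Writes the retained edges to `path`; for a `causal_dag` the removed
#' edges go to a sibling file `<path>.removed.tsv` unless `removed_path`
#' says otherwise.
#'
#' @param dag the graph.
#' @param path output TSV path.
#' @param removed_path optional path for the removed-edge table.
#' @return `path`, invisibly.
#' @export
write_dag <- function(dag, path, removed_path = NULL) {
  stopifnot(inherits(dag, "relation_graph"))
  utils::write.table(dag$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (inherits(dag, "causal_dag")) {
    rp <- removed_path %||% paste0(path, ".removed.tsv")
    utils::write.table(dag$removed, rp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a scored edge list into a relation graph
#' @param path TSV with columns `cause`, `effect`, `score`.
#' @return A [relation_graph()].
#' @export
read_graph <- function(path) {
  relation_graph(utils::read.delim(path, header = TRUE, sep = "\t",
                                   quote = "", stringsAsFactors = FALSE))
}

#' Export a graph in GraphViz DOT format
#' @param dag the graph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dot <- function(dag, path) {
  stopifnot(inherits(dag, "relation_graph"))
  lines <- c("digraph causal {",
             sprintf("  \"%s\" -> \"%s\" [label=\"%.3f\"];",
                     dag$edges$cause, dag$edges$effect, dag$edges$score),
             "}")
  writeLines(lines, path)
  invisible(path)
}
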