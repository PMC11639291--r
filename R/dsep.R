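#' d-separation in a causal DAG
#'
#' Tests whether every path between the node sets `X` and `Y` is blocked by
#' `Z` under the standard rules: a chain or fork is blocked when its middle
#' node is in `Z`; a collider blocks unless the collider or one of its
#' descendants is in `Z`. Implemented by the classical
#' moralized-ancestral-graph reduction: `X` and `Y` are d-separated by `Z`
#' iff they are disconnected after (i) restricting to the ancestral closure
#' of `X` and `Y` and `Z`, (ii) marrying co-parents and dropping edge
#' directions, and (iii) deleting `Z`.
#'
#' @param dag a `causal_dag` (must be acyclic).
#' @param X,Y,Z disjoint character vectors of node ids (`Z` may be empty).
#' @return `TRUE` iff `X` and `Y` are d-separated given `Z`.
#' @export
d_separated <- function(dag, X, Y, Z = character(0)) {
  stopifnot(inherits(dag, "relation_graph"),
            length(X) >= 1, length(Y) >= 1)
  if (!is_acyclic(dag)) abort("d-separation requires an acyclic graph")
  sets <- list(X = X, Y = Y, Z = Z)
  if (length(intersect(X, Y)) || length(intersect(X, Z)) ||
      length(intersect(Y, Z))) {
    abort("X, Y and Z must be disjoint")
  }
  unknown <- setdiff(unlist(sets), dag$nodes)
  if (length(unknown)) abort("unknown node(s): %s",
                             paste(unknown, collapse = ", "))
  g <- as_igraph(dag)
  anc <- unique(unlist(lapply(c(X, Y, Z), function(v) {
    names(igraph::subcomponent(g, v, mode = "in"))
  })))
  sub_edges <- dag$edges[dag$edges$cause %in% anc & dag$edges$effect %in% anc,
                         c("cause", "effect"), drop = FALSE]
  # marry parents that share a child within the ancestral subgraph
  marry <- do.call(rbind, lapply(split(sub_edges$cause, sub_edges$effect),
                                 function(ps) {
    ps <- unique(ps)
    if (length(ps) < 2) return(NULL)
    t(utils::combn(ps, 2))
  }))
  und <- rbind(as.matrix(sub_edges),
               if (!is.null(marry)) marry)
  gu <- igraph::graph_from_edgelist(und, directed = FALSE)
  gu <- gu + igraph::vertices(setdiff(anc, igraph::V(gu)$name))
  gu <- igraph::delete_vertices(gu, intersect(Z, igraph::V(gu)$name))
  xs <- intersect(X, igraph::V(gu)$name)
  ys <- intersect(Y, igraph::V(gu)$name)
  if (!length(xs) || !length(ys)) return(TRUE)
  comp <- igraph::components(gu)$membership
  !any(outer(comp[xs], comp[ys], "=="))
}

#' Check the backdoor criterion for an adjustment set
#'
#' `Z` satisfies the backdoor criterion relative to (`treatment`,
#' `outcome`) iff no member of `Z` is a descendant of the treatment, and
#' `Z` d-separates treatment from outcome in the graph with the
#' treatment's outgoing edges removed (blocking every backdoor path while
#' leaving directed causal paths intact).
#'
#' @param dag a `causal_dag`.
#' @param treatment,outcome node ids.
#' @param Z character vector of candidate adjustment nodes (may be empty).
#' @return `TRUE` iff `Z` is a valid backdoor adjustment set.
#' @export
check_backdoor <- function(dag, treatment, outcome, Z = character(0)) {
  stopifnot(inherits(dag, "relation_graph"),
            is_string(treatment), is_string(outcome),
            treatment != outcome)
  if (treatment %in% Z || outcome %in% Z) {
    abort("Z must exclude treatment and outcome")
  }
  if (length(Z) && any(Z %in% dag_descendants(dag, treatment))) {
    return(FALSE)
  }
  pruned <- dag
  keep <- pruned$edges$cause != treatment
  pruned$edges <- pruned$edges[keep, , drop = FALSE]
  d_separated(pruned, treatment, outcome, Z)
}
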