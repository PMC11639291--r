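# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms (brute force, enumeration,
# closed forms) than the code under test.

# phi via direct evaluation of the closed form, in double precision
oracle_phi <- function(n11, n10, n01, n00) {
  n11 <- as.numeric(n11); n10 <- as.numeric(n10)
  n01 <- as.numeric(n01); n00 <- as.numeric(n00)
  m <- c(n11 + n10, n01 + n00, n11 + n01, n10 + n00)
  if (any(m == 0)) return(0)
  (n11 * n00 - n10 * n01) / sqrt(prod(m))
}

# AUC by exhaustive comparison of every case-control pair
oracle_auc <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  cmp <- outer(cs, ct, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Cohen's d from the textbook pooled-standard-deviation formula
oracle_cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  (mean(a) - mean(b)) / sp
}

# Student t statistic for two independent samples (equal-variance form)
oracle_t_stat <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# --- greedy DAG oracle -------------------------------------------------
# A literal re-enactment of the procedure: insert edges in descending
# score order; after each insertion enumerate every directed cycle through
# the new edge and delete the cycle's lowest-score edge (ties resolved by
# the (-score, cause, effect) ordering), repeating until no cycle remains.

oracle_all_paths <- function(edges, from, to) {
  # all simple directed paths from `from` to `to`; edges as data frame
  out <- list()
  walk <- function(node, path_nodes, path_edges) {
    if (node == to) {
      out[[length(out) + 1L]] <<- path_edges
      return(invisible())
    }
    nxt <- which(edges$cause == node & !(edges$effect %in% path_nodes))
    for (i in nxt) {
      walk(edges$effect[i], c(path_nodes, edges$effect[i]),
           c(path_edges, i))
    }
  }
  walk(from, from, integer(0))
  out
}

oracle_greedy_dag <- function(edges) {
  ord <- order(-edges$score, edges$cause, edges$effect)
  edges <- edges[ord, , drop = FALSE]
  kept <- edges[0, , drop = FALSE]
  removed <- edges[0, , drop = FALSE]
  for (i in seq_len(nrow(edges))) {
    kept <- rbind(kept, edges[i, , drop = FALSE])
    repeat {
      # cycles through the most recent edge still present
      cyc <- NULL
      for (j in seq_len(nrow(kept))) {
        paths <- oracle_all_paths(kept[-j, , drop = FALSE],
                                  kept$effect[j], kept$cause[j])
        if (length(paths)) {
          # re-map path indices (they index kept[-j, ]) back into kept
          cyc <- c(j, setdiff(seq_len(nrow(kept)), j)[paths[[1]]])
          break
        }
      }
      if (is.null(cyc)) break
      sub <- kept[cyc, , drop = FALSE]
      worst <- cyc[order(-sub$score, sub$cause, sub$effect)[nrow(sub)]]
      removed <- rbind(removed, kept[worst, , drop = FALSE])
      kept <- kept[-worst, , drop = FALSE]
    }
  }
  list(kept = kept, removed = removed)
}

# Kahn topological-sort acyclicity check, independent of igraph
oracle_is_acyclic <- function(edges, nodes) {
  indeg <- setNames(integer(length(nodes)), nodes)
  for (v in edges$effect) indeg[v] <- indeg[v] + 1L
  active <- rep(TRUE, nrow(edges))
  queue <- names(indeg)[indeg == 0]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    out <- which(active & edges$cause == v)
    active[out] <- FALSE
    for (w in edges$effect[out]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0) queue <- c(queue, w)
    }
  }
  seen == length(nodes)
}

# random scored digraph for property tests
random_graph <- function(n_nodes, p_edge = 0.35, score_levels = NULL) {
  nodes <- sprintf("A%02d", seq_len(n_nodes))
  grid <- expand.grid(cause = nodes, effect = nodes,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$cause != grid$effect, ]
  pick <- runif(nrow(grid)) < p_edge
  e <- grid[pick, , drop = FALSE]
  e$score <- if (is.null(score_levels)) runif(nrow(e)) else
    sample(score_levels, nrow(e), replace = TRUE)
  rownames(e) <- NULL
  e
}

# --- d-separation oracle ----------------------------------------------
# Enumerates every undirected simple path between x and y and applies the
# chain/fork/collider blocking rules directly.
oracle_descendants <- function(edges, node) {
  out <- character(0)
  frontier <- node
  while (length(frontier)) {
    nxt <- unique(edges$effect[edges$cause %in% frontier])
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

oracle_dsep <- function(edges, x, y, z) {
  # undirected adjacency with orientation memory
  paths <- list()
  walk <- function(node, path) {
    if (node == y) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    nbr <- unique(c(edges$effect[edges$cause == node],
                    edges$cause[edges$effect == node]))
    for (w in setdiff(nbr, path)) walk(w, c(path, w))
  }
  walk(x, x)
  if (!length(paths)) return(TRUE)
  for (p in paths) {
    blocked <- FALSE
    if (length(p) > 2) {
      for (k in 2:(length(p) - 1)) {
        into_prev <- any(edges$cause == p[k - 1] & edges$effect == p[k])
        into_next <- any(edges$cause == p[k + 1] & edges$effect == p[k])
        collider <- into_prev && into_next
        if (collider) {
          open_set <- c(p[k], oracle_descendants(edges, p[k]))
          if (!any(open_set %in% z)) { blocked <- TRUE; break }
        } else if (p[k] %in% z) { blocked <- TRUE; break }
      }
    }
    if (!blocked) return(FALSE)
  }
  TRUE
}

# random DAG edges (acyclic by construction over an index order)
random_dag_edges <- function(n_nodes, p_edge = 0.4) {
  nodes <- sprintf("V%02d", seq_len(n_nodes))
  e <- NULL
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      if (runif(1) < p_edge) e <- rbind(e, c(nodes[i], nodes[j]))
    }
  }
  if (is.null(e)) {
    return(data.frame(cause = character(), effect = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  data.frame(cause = e[, 1], effect = e[, 2], score = runif(nrow(e)),
             stringsAsFactors = FALSE)
}

# quick patient_records builder from a status/year list:
# diseases = named list of data.frames (individual_id, year)
make_records <- function(diseases, n, ages = NULL) {
  ids <- sprintf("i%04d", seq_len(n))
  rows <- do.call(rbind, lapply(names(diseases), function(code) {
    d <- diseases[[code]]
    data.frame(individual_id = ids[d$idx], code = code, year = d$year,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(individual_id = character(), code = character(),
                       year = integer(), stringsAsFactors = FALSE)
  }
  demo <- data.frame(individual_id = ids,
                     age = ages %||% rep(50L, n), sex = "F",
                     stringsAsFactors = FALSE)
  patient_records(rows, demo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
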