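# Seven node-centrality algorithms used for hub screening, each implemented
# from its defining formula on the undirected simple graph. d(v,t) denotes
# the unweighted shortest-path length computed by breadth-first search.

#' Degree centrality
#'
#' `score(v) = |neighbors(v)|`.
#'
#' @param net A network or graph-like object (see [as_graph()]).
#' @return Named numeric vector of scores.
#' @export
degree_centrality <- function(net) {
  g <- as_graph(net)
  stats::setNames(vapply(g$adj, length, integer(1L)) + 0, g$nodes)
}

#' Harmonic closeness centrality
#'
#' `score(v) = sum_{t != v} 1 / d(v,t)`; unreachable targets contribute 0.
#' This is the harmonic form, which is well defined on disconnected graphs.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector of scores.
#' @export
closeness_centrality <- function(net) {
  g <- as_graph(net)
  n <- length(g$nodes)
  score <- numeric(n)
  for (v in seq_len(n)) {
    d <- bfs_dist(g$adj, v)
    d <- d[-v]
    score[v] <- sum(1 / d[is.finite(d) & d > 0])
  }
  stats::setNames(score, g$nodes)
}

#' Eccentricity centrality
#'
#' `score(v) = 1 / max_t d(v,t)` over targets reachable from `v`; isolated
#' nodes score 0.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector of scores.
#' @export
eccentricity_centrality <- function(net) {
  g <- as_graph(net)
  n <- length(g$nodes)
  score <- numeric(n)
  for (v in seq_len(n)) {
    d <- bfs_dist(g$adj, v)
    d <- d[is.finite(d) & d > 0]
    score[v] <- if (length(d)) 1 / max(d) else 0
  }
  stats::setNames(score, g$nodes)
}

#' Radiality centrality
#'
#' Within the connected component of `v` (size `n_c`, diameter `D`):
#' `score(v) = sum_{t != v} (D + 1 - d(v,t)) / (n_c - 1)`. Nodes in
#' singleton components score 0.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector of scores.
#' @export
radiality_centrality <- function(net) {
  g <- as_graph(net)
  n <- length(g$nodes)
  comp <- graph_components(g$adj)
  dists <- lapply(seq_len(n), function(v) bfs_dist(g$adj, v))
  score <- numeric(n)
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    if (length(members) < 2L) next
    diam <- max(vapply(members, function(v) {
      max(dists[[v]][members])
    }, numeric(1L)))
    for (v in members) {
      d <- dists[[v]][setdiff(members, v)]
      score[v] <- sum(diam + 1 - d) / (length(members) - 1L)
    }
  }
  stats::setNames(score, g$nodes)
}

#' Betweenness centrality
#'
#' `score(v) = sum_{s != v != t} sigma_st(v) / sigma_st` over unordered
#' pairs, where `sigma_st` counts shortest s-t paths. Computed with the
#' standard dependency-accumulation algorithm over BFS shortest-path DAGs.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector of scores.
#' @export
betweenness_centrality <- function(net) {
  g <- as_graph(net)
  n <- length(g$nodes)
  score <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    pred <- rep(list(integer()), n)
    queue <- s; head <- 1L
    order_visited <- integer()
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      order_visited <- c(order_visited, v)
      for (w in g$adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          pred[[w]] <- c(pred[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in pred[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) score[w] <- score[w] + delta[w]
    }
  }
  # each unordered pair was accumulated from both endpoints
  stats::setNames(score / 2, g$nodes)
}

# Maximal clique enumeration (Bron-Kerbosch with pivoting); returns a list
# of integer vectors. Includes singleton cliques for isolated nodes.
maximal_cliques <- function(adj) {
  cliques <- list()
  bk <- function(R, P, X) {
    if (length(P) == 0L && length(X) == 0L) {
      cliques[[length(cliques) + 1L]] <<- R
      return(invisible())
    }
    pool <- c(P, X)
    u <- pool[which.max(vapply(pool, function(v) {
      length(intersect(adj[[v]], P))
    }, integer(1L)))]
    for (v in setdiff(P, adj[[u]])) {
      bk(c(R, v), intersect(P, adj[[v]]), intersect(X, adj[[v]]))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(), seq_along(adj), integer())
  cliques
}

#' Maximal clique centrality (MCC)
#'
#' `score(v) = sum over maximal cliques C containing v of (|C|-1)!`. When
#' the neighborhood of `v` contains no edge, every maximal clique through
#' `v` is a single edge and the score reduces to `degree(v)`; isolated
#' nodes score 0.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector of scores.
#' @export
mcc_centrality <- function(net) {
  g <- as_graph(net)
  n <- length(g$nodes)
  score <- numeric(n)
  for (cl in maximal_cliques(g$adj)) {
    if (length(cl) < 2L) next
    score[cl] <- score[cl] + factorial(length(cl) - 1L)
  }
  stats::setNames(score, g$nodes)
}

#' Edge-percolated component (EPC) centrality
#'
#' Monte-Carlo estimate of `score(v) = E[ |{t != v : t connected to v in
#' G'}| ]`, where `G'` retains each edge independently with probability
#' `p_keep`. With `p_keep = 1` the score is exactly the component size
#' minus one; with `p_keep = 0` it is 0.
#'
#' @inheritParams degree_centrality
#' @param n_realizations Number of percolation realizations (default 1000).
#' @param p_keep Edge retention probability (default 0.5).
#' @param seed Integer seed for the percolation draws.
#' @return Named numeric vector of mean connected counts.
#' @export
epc_centrality <- function(net, n_realizations = 1000L, p_keep = 0.5,
                           seed = 1L) {
  stopifnot(n_realizations >= 1L, p_keep >= 0, p_keep <= 1)
  g <- as_graph(net)
  n <- length(g$nodes)
  m <- nrow(g$edge_index)
  total <- numeric(n)
  if (n > 0L && m > 0L && p_keep > 0) {
    a <- g$edge_index[, 1L]; b <- g$edge_index[, 2L]
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    keep_mat <- matrix(stats::runif(n_realizations * m) < p_keep,
                       nrow = n_realizations)
    for (r in seq_len(n_realizations)) {
      keep <- keep_mat[r, ]
      comp <- uf_components(n, a[keep], b[keep])
      sizes <- tabulate(comp, nbins = max(comp))
      total <- total + (sizes[comp] - 1)
    }
  }
  stats::setNames(total / n_realizations, g$nodes)
}

# Union-find connected components for a fixed node count and edge list.
uf_components <- function(n, a, b) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_along(a)) {
    ra <- find(a[i]); rb <- find(b[i])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, integer(1L))
}

# Save/seed/restore helpers so seeded internals do not clobber the caller's
# RNG stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
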