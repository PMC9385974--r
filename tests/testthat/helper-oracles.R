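# Brute-force oracles for the centrality algorithms, kept independent of
# the package implementations: dense-matrix Floyd-Warshall distances,
# explicit shortest-path enumeration, subset-enumeration clique finding,
# and exact edge-subset expectations for percolation.

# random simple graph as a list(nodes, edges); m capped so the exact EPC
# enumeration (2^m subsets) stays cheap
random_graph <- function(n, m = NULL, max_m = 10L) {
  all_pairs <- t(utils::combn(n, 2L))
  cap <- min(max_m, nrow(all_pairs))
  if (is.null(m)) m <- sample.int(cap + 1L, 1L) - 1L
  idx <- if (m > 0L) sample.int(nrow(all_pairs), m) else integer()
  ids <- sprintf("n%02d", seq_len(n))
  list(nodes = ids,
       edges = data.frame(from = ids[all_pairs[idx, 1L]],
                          to = ids[all_pairs[idx, 2L]],
                          stringsAsFactors = FALSE))
}

graph_adjmat <- function(g) {
  n <- length(g$nodes)
  A <- matrix(0L, n, n, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges)) {
    i <- match(g$edges$from, g$nodes)
    j <- match(g$edges$to, g$nodes)
    A[cbind(i, j)] <- 1L
    A[cbind(j, i)] <- 1L
  }
  A
}

fw_dist <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1L] <- 1
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

oracle_degree <- function(A) rowSums(A)

oracle_closeness <- function(A) {
  D <- fw_dist(A)
  vapply(seq_len(nrow(A)), function(v) {
    d <- D[v, -v]
    sum(1 / d[is.finite(d)])
  }, numeric(1L))
}

oracle_eccentricity <- function(A) {
  D <- fw_dist(A)
  vapply(seq_len(nrow(A)), function(v) {
    d <- D[v, -v]
    d <- d[is.finite(d)]
    if (length(d)) 1 / max(d) else 0
  }, numeric(1L))
}

oracle_components <- function(A) {
  n <- nrow(A)
  R <- (A + diag(n)) > 0
  for (i in seq_len(ceiling(log2(max(n, 2))))) {
    R <- (R %*% R) > 0
  }
  match(apply(R, 1L, paste, collapse = ""),
        unique(apply(R, 1L, paste, collapse = "")))
}

oracle_radiality <- function(A) {
  D <- fw_dist(A)
  comp <- oracle_components(A)
  n <- nrow(A)
  score <- numeric(n)
  for (cc in unique(comp)) {
    mem <- which(comp == cc)
    if (length(mem) < 2L) next
    diam <- max(D[mem, mem])
    for (v in mem) {
      d <- D[v, setdiff(mem, v)]
      score[v] <- sum(diam + 1 - d) / (length(mem) - 1L)
    }
  }
  score
}

# all shortest paths enumerated explicitly
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- fw_dist(A)
  score <- numeric(n)
  if (n < 3L) return(score)
  for (s in seq_len(n - 1L)) for (t in seq(s + 1L, n)) {
    if (!is.finite(D[s, t]) || D[s, t] == 0) next
    paths <- list()
    rec <- function(v, acc) {
      if (v == t) {
        paths[[length(paths) + 1L]] <<- acc
        return(invisible())
      }
      for (w in which(A[v, ] == 1L)) {
        if (is.finite(D[w, t]) && D[w, t] == D[v, t] - 1) rec(w, c(acc, w))
      }
    }
    rec(s, s)
    sigma <- length(paths)
    inner <- unlist(lapply(paths, function(p) p[-c(1L, length(p))]))
    if (length(inner)) {
      score <- score + tabulate(inner, n) / sigma
    }
  }
  score
}

# maximal cliques by full subset enumeration
oracle_maximal_cliques <- function(A) {
  n <- nrow(A)
  is_clique <- function(S) {
    if (length(S) < 2L) return(TRUE)
    all(A[S, S][upper.tri(diag(length(S)))] == 1L)
  }
  subsets <- lapply(seq_len(2^n - 1L), function(mask) {
    which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
  })
  cliques <- Filter(is_clique, subsets)
  Filter(function(S) {
    !any(vapply(setdiff(seq_len(n), S), function(v) {
      is_clique(c(S, v))
    }, logical(1L)))
  }, cliques)
}

oracle_mcc <- function(A) {
  n <- nrow(A)
  score <- numeric(n)
  for (cl in oracle_maximal_cliques(A)) {
    if (length(cl) < 2L) next
    score[cl] <- score[cl] + factorial(length(cl) - 1L)
  }
  score
}

# exact EPC mean and variance by enumerating all 2^m edge subsets
oracle_epc_exact <- function(g, p_keep) {
  A0 <- graph_adjmat(g)
  n <- nrow(A0)
  m <- nrow(g$edges)
  ei <- cbind(match(g$edges$from, g$nodes), match(g$edges$to, g$nodes))
  mean_v <- numeric(n)
  second <- numeric(n)
  for (mask in 0:(2^m - 1L)) {
    keep <- if (m > 0L) bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0 else logical()
    prob <- prod(ifelse(keep, p_keep, 1 - p_keep))
    A <- matrix(0L, n, n)
    if (any(keep)) {
      A[ei[keep, , drop = FALSE]] <- 1L
      A[ei[keep, c(2L, 1L), drop = FALSE]] <- 1L
    }
    comp <- oracle_components(A)
    sizes <- tabulate(comp)
    x <- sizes[comp] - 1
    mean_v <- mean_v + prob * x
    second <- second + prob * x^2
  }
  list(mean = mean_v, var = pmax(second - mean_v^2, 0))
}
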