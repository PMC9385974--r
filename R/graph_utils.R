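# Internal undirected simple-graph representation shared by the centrality
# code: list(nodes = character ids, adj = list of integer neighbour vectors).

#' Coerce to the internal graph representation
#'
#' Accepts a `cerna_network`, a two-column edge data frame (`from`, `to`),
#' or a list with elements `nodes` (character) and `edges` (data frame).
#' Self-loops are forbidden; duplicate edges collapse.
#'
#' @param x Graph-like object.
#' @return List with `nodes` (character) and `adj` (list of integer
#'   vectors).
#' @keywords internal
as_graph <- function(x) {
  if (inherits(x, "cerna_graph")) return(x)
  if (inherits(x, "cerna_network")) {
    nodes <- x$nodes$id
    edges <- x$edges
  } else if (is.data.frame(x)) {
    edges <- data.frame(from = as.character(x[[1L]]),
                        to = as.character(x[[2L]]),
                        stringsAsFactors = FALSE)
    nodes <- unique(c(edges$from, edges$to))
  } else if (is.list(x) && !is.null(x$nodes)) {
    nodes <- as.character(if (is.data.frame(x$nodes)) x$nodes$id else x$nodes)
    edges <- x$edges
  } else {
    stop("cannot interpret object as a graph", call. = FALSE)
  }
  n <- length(nodes)
  adj <- rep(list(integer()), n)
  ei <- matrix(integer(), 0L, 2L)
  if (!is.null(edges) && nrow(edges) > 0L) {
    a <- match(as.character(edges[[1L]]), nodes)
    b <- match(as.character(edges[[2L]]), nodes)
    if (anyNA(a) || anyNA(b)) {
      stop("edge endpoint not present in node set", call. = FALSE)
    }
    if (any(a == b)) stop("self-loops are not allowed", call. = FALSE)
    key <- paste(pmin(a, b), pmax(a, b))
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]
    for (i in seq_along(a)) {
      adj[[a[i]]] <- c(adj[[a[i]]], b[i])
      adj[[b[i]]] <- c(adj[[b[i]]], a[i])
    }
    adj <- lapply(adj, sort)
    ei <- cbind(a, b)
  }
  structure(list(nodes = nodes, adj = adj, edge_index = ei),
            class = "cerna_graph")
}

# BFS distances from source s; unreachable nodes get Inf.
bfs_dist <- function(adj, s) {
  n <- length(adj)
  dist <- rep(Inf, n)
  dist[s] <- 0
  queue <- s
  head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# Connected component labels (integer vector).
graph_components <- function(adj) {
  n <- length(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      for (w in adj[[v]]) {
        if (is.na(comp[w])) {
          comp[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}
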