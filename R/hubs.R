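#' Centrality configuration
#'
#' @param k_top Top-list size per algorithm (default 10).
#' @param epc_realizations EPC Monte-Carlo realizations (default 1000).
#' @param epc_p_keep EPC edge retention probability (default 0.5).
#' @param seed Seed for the EPC percolation draws.
#' @param tie_policy `"include_ties"` (default: the top list is extended to
#'   every node tied with the k-th score) or `"truncate"`.
#' @return A list of class `centrality_config`.
#' @export
centrality_config <- function(k_top = 10L, epc_realizations = 1000L,
                              epc_p_keep = 0.5, seed = 1L,
                              tie_policy = c("include_ties", "truncate")) {
  stopifnot(k_top >= 1L, epc_realizations >= 1L,
            epc_p_keep >= 0, epc_p_keep <= 1)
  structure(list(k_top = as.integer(k_top),
                 epc_realizations = as.integer(epc_realizations),
                 epc_p_keep = epc_p_keep, seed = as.integer(seed),
                 tie_policy = match.arg(tie_policy)),
            class = "centrality_config")
}

#' Names of the seven hub-screening algorithms
#' @return Character vector.
#' @export
centrality_algorithms <- function() {
  c("MCC", "Degree", "EPC", "EcCentricity", "Closeness", "Radiality",
    "Betweenness")
}

#' Compute all seven centralities and their top-k lists
#'
#' @param net Network or graph-like object.
#' @param config A [centrality_config()].
#' @return List of class `centrality_report` with elements `scores` (named
#'   list of named numeric vectors, one per algorithm) and `top` (named
#'   list of ordered node-id vectors).
#' @export
centrality_report <- function(net, config = centrality_config()) {
  stopifnot(inherits(config, "centrality_config"))
  g <- as_graph(net)
  scores <- list(
    MCC = mcc_centrality(g),
    Degree = degree_centrality(g),
    EPC = epc_centrality(g, n_realizations = config$epc_realizations,
                         p_keep = config$epc_p_keep, seed = config$seed),
    EcCentricity = eccentricity_centrality(g),
    Closeness = closeness_centrality(g),
    Radiality = radiality_centrality(g),
    Betweenness = betweenness_centrality(g))
  top <- lapply(scores, top_k, k = config$k_top,
                tie_policy = config$tie_policy)
  structure(list(scores = scores, top = top, config = config),
            class = "centrality_report")
}

#' Top-k nodes by score
#'
#' Nodes are ordered by score descending, ties broken by node identifier
#' ascending. Under `"include_ties"` the list extends past rank `k` to all
#' nodes tied with the k-th score; `"truncate"` cuts at exactly `k`.
#'
#' @param scores Named numeric vector.
#' @param k List length (default 10).
#' @param tie_policy `"include_ties"` or `"truncate"`.
#' @return Character vector of node identifiers.
#' @export
top_k <- function(scores, k = 10L, tie_policy = c("include_ties", "truncate")) {
  tie_policy <- match.arg(tie_policy)
  if (length(scores) == 0L) return(character())
  ord <- order(-scores, names(scores))
  sorted <- scores[ord]
  if (length(sorted) <= k) return(names(sorted))
  if (tie_policy == "include_ties") {
    cutoff <- sorted[[k]]
    names(sorted)[sorted >= cutoff]
  } else {
    names(sorted)[seq_len(k)]
  }
}

#' Seven-way consensus hubs
#'
#' Hub nodes are those present in the top list of all seven algorithms —
#' full consensus, not a majority. Also returns the node-by-algorithm
#' membership matrix used for UpSet-style reporting; its row-wise AND
#' reproduces the hub set.
#'
#' @param report A [centrality_report()].
#' @return List of class `hub_set` with `hubs` (sorted character vector)
#'   and `membership` (logical matrix, nodes x algorithms).
#' @export
consensus_hubs <- function(report) {
  stopifnot(inherits(report, "centrality_report"))
  algos <- centrality_algorithms()
  missing <- setdiff(algos, names(report$top))
  if (length(missing)) {
    stop(sprintf("missing algorithm(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  nodes <- sort(unique(unlist(report$top, use.names = FALSE)))
  membership <- vapply(algos, function(a) nodes %in% report$top[[a]],
                       logical(length(nodes)))
  membership <- matrix(membership, nrow = length(nodes),
                       dimnames = list(nodes, algos))
  hubs <- nodes[rowSums(membership) == length(algos)]
  structure(list(hubs = hubs, membership = membership), class = "hub_set")
}

#' Enumerate hub regulatory axes
#'
#' All lncRNA-miRNA-mRNA triples whose three members are hubs and whose two
#' constituent edges (lncRNA-miRNA and miRNA-mRNA) exist in the network,
#' sorted lexicographically. The output is independent of edge insertion
#' order.
#'
#' @param net A [cerna_network()].
#' @param hubs A `hub_set` from [consensus_hubs()], or a character vector
#'   of hub node identifiers.
#' @return Data frame with columns `lncrna`, `mirna`, `mrna`.
#' @export
extract_axes <- function(net, hubs) {
  stopifnot(inherits(net, "cerna_network"))
  if (inherits(hubs, "hub_set")) hubs <- hubs$hubs
  if (!all(hubs %in% net$nodes$id)) {
    stop("hub identifiers must be nodes of the network", call. = FALSE)
  }
  cls <- stats::setNames(net$nodes$class, net$nodes$id)
  hl <- hubs[cls[hubs] == "lncRNA"]
  hm <- hubs[cls[hubs] == "miRNA"]
  hg <- hubs[cls[hubs] == "mRNA"]
  ek <- edge_keys(net$edges)
  out <- expand.grid(lncrna = hl, mirna = hm, mrna = hg,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  if (nrow(out)) {
    keep <- edge_keys(data.frame(from = out$lncrna, to = out$mirna)) %in% ek &
            edge_keys(data.frame(from = out$mirna, to = out$mrna)) %in% ek
    out <- out[keep, , drop = FALSE]
    out <- out[order(out$lncrna, out$mirna, out$mrna), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

edge_keys <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0L) return(character())
  paste(pmin(edges[[1L]], edges[[2L]]), pmax(edges[[1L]], edges[[2L]]),
        sep = "\r")
}

#' Deduplicate regulatory axes across networks
#'
#' The same axis can arise in several category networks; this collapses to
#' unique (lncRNA, miRNA, mRNA) triples and annotates each with the set of
#' networks carrying it.
#'
#' @param axes Data frame with columns `network`, `lncrna`, `mirna`,
#'   `mrna`.
#' @return Data frame with columns `lncrna`, `mirna`, `mrna`, `networks`
#'   (`";"`-joined labels), sorted lexicographically.
#' @export
dedup_axes <- function(axes) {
  cols <- c("lncrna", "mirna", "mrna")
  if (nrow(axes) == 0L) {
    return(data.frame(lncrna = character(), mirna = character(),
                      mrna = character(), networks = character(),
                      stringsAsFactors = FALSE))
  }
  key <- do.call(paste, c(axes[cols], sep = "\r"))
  nets <- vapply(split(axes$network, key), function(x) {
    paste(sort(unique(x)), collapse = ";")
  }, character(1L))
  uniq <- axes[!duplicated(key), cols, drop = FALSE]
  uniq$networks <- unname(nets[key[!duplicated(key)]])
  uniq <- uniq[order(uniq$lncrna, uniq$mirna, uniq$mrna), , drop = FALSE]
  rownames(uniq) <- NULL
  uniq
}
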