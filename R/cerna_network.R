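#' Construct a tripartite ceRNA network
#'
#' Nodes carry a class in \{lncRNA, miRNA, mRNA\}; edges are undirected and
#' may only join lncRNA-miRNA or miRNA-mRNA (the regulatory direction is an
#' attribute of the edge, not of the topology). Node identifier namespaces
#' are kept disjoint by class tag, so a symbol occurring both as gene and
#' as lncRNA host-gene name cannot merge nodes.
#'
#' @param nodes Data frame with columns `id`, `class`.
#' @param edges Data frame with columns `from`, `to` (node ids).
#' @param label Network label (e.g. `"apoptosis"`).
#' @param strict When `TRUE`, additionally require every miRNA node to have
#'   both a lncRNA and an mRNA neighbor (the full sponge invariant).
#' @return An object of class `cerna_network`.
#' @export
cerna_network <- function(nodes, edges, label = "", strict = FALSE) {
  nodes <- data.frame(id = as.character(nodes$id),
                      class = as.character(nodes$class),
                      stringsAsFactors = FALSE)
  edges <- if (is.null(edges) || nrow(edges) == 0L) {
    data.frame(from = character(), to = character(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = as.character(edges$from),
               to = as.character(edges$to), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node identifiers", call. = FALSE)
  }
  if (!all(nodes$class %in% c("lncRNA", "miRNA", "mRNA"))) {
    stop("node class must be lncRNA, miRNA or mRNA", call. = FALSE)
  }
  cls <- stats::setNames(nodes$class, nodes$id)
  if (nrow(edges)) {
    if (!all(c(edges$from, edges$to) %in% nodes$id)) {
      stop("edge endpoint not in node table", call. = FALSE)
    }
    if (any(edges$from == edges$to)) {
      stop("self-loops are not allowed", call. = FALSE)
    }
    rank <- c(lncRNA = 1L, miRNA = 2L, mRNA = 3L)
    ra <- rank[cls[edges$from]]; rb <- rank[cls[edges$to]]
    pair <- paste(pmin(ra, rb), pmax(ra, rb))
    ok <- pair %in% c("1 2", "2 3")
    if (!all(ok)) {
      stop("tripartite constraint violated: edges must join lncRNA-miRNA or miRNA-mRNA",
           call. = FALSE)
    }
    edges <- edges[!duplicated(edge_keys(edges)), , drop = FALSE]
    # canonical orientation: regulator first (lncRNA->miRNA, miRNA->mRNA)
    flip <- cls[edges$from] %in% c("mRNA") |
      (cls[edges$from] == "miRNA" & cls[edges$to] == "lncRNA")
    tmp <- edges$from[flip]
    edges$from[flip] <- edges$to[flip]
    edges$to[flip] <- tmp
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  }
  rownames(edges) <- NULL
  nodes <- nodes[order(match(nodes$class, c("lncRNA", "miRNA", "mRNA")),
                       nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  net <- structure(list(nodes = nodes, edges = edges,
                        label = as.character(label)[1L]),
                   class = "cerna_network")
  if (strict) {
    mirnas <- nodes$id[nodes$class == "miRNA"]
    for (m in mirnas) {
      nb <- c(edges$to[edges$from == m], edges$from[edges$to == m])
      nbc <- cls[nb]
      if (!any(nbc == "lncRNA") || !any(nbc == "mRNA")) {
        stop(sprintf("miRNA '%s' lacks a lncRNA or mRNA neighbor", m),
             call. = FALSE)
      }
    }
  }
  net
}

#' @export
print.cerna_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("cerna_network '%s': %d nodes (%d lncRNA, %d miRNA, %d mRNA), %d edges\n",
              x$label, s$n_nodes, s$n_lncrna, s$n_mirna, s$n_mrna,
              s$n_edges))
  invisible(x)
}

#' Load interaction-prediction evidence tables
#'
#' Reads one or more TSVs with columns `source`, `regulator`,
#' `regulator_class`, `target`, `target_class`. Valid class pairs are
#' (miRNA, mRNA) and (lncRNA, miRNA). mRNA targets are normalized via
#' [normalize_symbol()]; miRNA and lncRNA identifiers are case-preserved.
#' Duplicate rows within a source collapse to one.
#'
#' @param paths Character vector of TSV paths (or a data frame already in
#'   the evidence layout, validated and deduplicated the same way).
#' @return Data frame of class `interaction_evidence`.
#' @export
load_evidence <- function(paths) {
  if (is.data.frame(paths)) {
    tabs <- list(paths)
  } else {
    tabs <- lapply(paths, utils::read.delim, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, tabs)
  need <- c("source", "regulator", "regulator_class", "target",
            "target_class")
  if (!all(need %in% names(ev))) {
    stop(sprintf("evidence table must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  ev <- ev[, need]
  ok <- (ev$regulator_class == "miRNA" & ev$target_class == "mRNA") |
        (ev$regulator_class == "lncRNA" & ev$target_class == "miRNA")
  if (!all(ok)) {
    bad <- ev[!ok, , drop = FALSE][1L, ]
    stop(sprintf("invalid interaction class pair: %s -> %s",
                 bad$regulator_class, bad$target_class), call. = FALSE)
  }
  is_mrna <- ev$target_class == "mRNA"
  ev$target[is_mrna] <- normalize_symbol(ev$target[is_mrna])
  ev <- ev[!duplicated(ev[, c("source", "regulator", "target")]), ,
           drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("interaction_evidence", class(ev))
  ev
}

#' Consensus voting over prediction sources
#'
#' A (regulator, target) pair is retained iff reported by at least
#' `min_support` distinct sources. Defaults elsewhere in the pipeline:
#' miRNA-to-mRNA predictions require 3 of 4 sources, lncRNA-to-miRNA
#' predictions require 2 of 2.
#'
#' @param evidence An [load_evidence()] table.
#' @param regulator_class `"miRNA"` or `"lncRNA"`; evidence is filtered to
#'   this class first.
#' @param min_support Minimum number of distinct supporting sources.
#' @return Data frame with columns `regulator`, `target`, `support`,
#'   `sources` (`";"`-joined labels), sorted by regulator then target.
#' @export
consensus_targets <- function(evidence, regulator_class, min_support) {
  stopifnot(min_support >= 1L)
  ev <- evidence[evidence$regulator_class == regulator_class, , drop = FALSE]
  n_src <- length(unique(ev$source))
  if (min_support > n_src) {
    warning(sprintf(
      "min_support (%d) exceeds the %d distinct source(s) present; result is empty",
      min_support, n_src))
  }
  if (nrow(ev) == 0L) {
    return(data.frame(regulator = character(), target = character(),
                      support = integer(), sources = character(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(ev$regulator, ev$target, sep = "\r")
  src <- lapply(split(ev$source, key), function(x) sort(unique(x)))
  support <- vapply(src, length, integer(1L))
  first <- !duplicated(key)
  out <- data.frame(regulator = ev$regulator[first],
                    target = ev$target[first],
                    support = support[key[first]],
                    sources = vapply(src[key[first]], paste,
                                     character(1L), collapse = ";"),
                    stringsAsFactors = FALSE)
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- out[order(out$regulator, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a tripartite ceRNA network
#'
#' Keeps consensus miRNA-mRNA pairs whose mRNA belongs to `mrna_set` (the
#' differentially expressed PCD genes of one category), then consensus
#' lncRNA-miRNA pairs whose miRNA appears in a kept miRNA-mRNA pair, i.e.
#' the lncRNA and mRNA sides must share the same miRNA. Nodes are the
#' endpoints of the surviving edges; an empty network is allowed.
#'
#' @param mrna_set Character vector of gene symbols (normalized
#'   internally).
#' @param mirna_consensus Consensus miRNA-to-mRNA pairs from
#'   [consensus_targets()].
#' @param lncrna_consensus Consensus lncRNA-to-miRNA pairs.
#' @param label Network label.
#' @param require_lncrna_partner When `TRUE`, miRNAs with no predicted
#'   lncRNA sponge are dropped (and the strict sponge invariant is
#'   enforced); the default `FALSE` retains them as targets of the mRNA
#'   predictions.
#' @return A [cerna_network()].
#' @export
assemble_cerna <- function(mrna_set, mirna_consensus, lncrna_consensus,
                           label = "", require_lncrna_partner = FALSE) {
  if (length(mrna_set) == 0L) {
    stop("mrna_set must be non-empty", call. = FALSE)
  }
  mrna_set <- unique(normalize_symbol(mrna_set))
  mm <- mirna_consensus[mirna_consensus$target %in% mrna_set, , drop = FALSE]
  lm <- lncrna_consensus[lncrna_consensus$target %in% mm$regulator, ,
                         drop = FALSE]
  if (require_lncrna_partner) {
    mm <- mm[mm$regulator %in% lm$target, , drop = FALSE]
    lm <- lm[lm$target %in% mm$regulator, , drop = FALSE]
  }
  nodes <- rbind(
    data.frame(id = unique(lm$regulator), class = "lncRNA",
               stringsAsFactors = FALSE),
    data.frame(id = unique(c(lm$target, mm$regulator)), class = "miRNA",
               stringsAsFactors = FALSE),
    data.frame(id = unique(mm$target), class = "mRNA",
               stringsAsFactors = FALSE))
  edges <- rbind(
    data.frame(from = lm$regulator, to = lm$target,
               stringsAsFactors = FALSE),
    data.frame(from = mm$regulator, to = mm$target,
               stringsAsFactors = FALSE))
  cerna_network(nodes, edges, label = label,
                strict = require_lncrna_partner)
}

#' Summarize a ceRNA network
#'
#' @param net A [cerna_network()].
#' @return List with `n_lncrna`, `n_mirna`, `n_mrna`, `n_nodes`,
#'   `n_edges`; the class counts partition the node count.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  cls <- net$nodes$class
  list(n_lncrna = sum(cls == "lncRNA"),
       n_mirna = sum(cls == "miRNA"),
       n_mrna = sum(cls == "mRNA"),
       n_nodes = nrow(net$nodes),
       n_edges = nrow(net$edges))
}

#' Export a ceRNA network
#'
#' Writes any of: SIF (`from  ceRNA  to`), GraphML (with a `class` node
#' attribute), and node/edge attribute TSVs. Reading a written GraphML or
#' TSV pair back returns an identical network.
#'
#' @param net A [cerna_network()].
#' @param dir Output directory (created if needed).
#' @param basename File stem.
#' @param formats Subset of `c("sif", "graphml", "tsv")`.
#' @return Character vector of written paths, invisibly.
#' @export
export_network <- function(net, dir, basename = net$label,
                           formats = c("sif", "graphml", "tsv")) {
  stopifnot(inherits(net, "cerna_network"))
  bad <- setdiff(formats, c("sif", "graphml", "tsv"))
  if (length(bad)) {
    stop(sprintf("unknown export format(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!nzchar(basename)) basename <- "network"
  written <- character()
  if ("sif" %in% formats) {
    p <- file.path(dir, paste0(basename, ".sif"))
    lines <- if (nrow(net$edges)) {
      paste(net$edges$from, "ceRNA", net$edges$to, sep = "\t")
    } else character()
    writeLines(lines, p)
    written <- c(written, p)
  }
  if ("graphml" %in% formats) {
    p <- file.path(dir, paste0(basename, ".graphml"))
    writeLines(graphml_text(net), p)
    written <- c(written, p)
  }
  if ("tsv" %in% formats) {
    pn <- file.path(dir, paste0(basename, "_nodes.tsv"))
    pe <- file.path(dir, paste0(basename, "_edges.tsv"))
    write_table_tsv(net$nodes, pn)
    write_table_tsv(net$edges, pe)
    written <- c(written, pn, pe)
  }
  invisible(written)
}

graphml_text <- function(net) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  c('<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="class" for="node" attr.name="class" attr.type="string"/>',
    sprintf('  <graph id="%s" edgedefault="undirected">',
            esc(net$label)),
    sprintf('    <node id="%s"><data key="class">%s</data></node>',
            esc(net$nodes$id), net$nodes$class),
    if (nrow(net$edges)) {
      sprintf('    <edge source="%s" target="%s"/>',
              esc(net$edges$from), esc(net$edges$to))
    },
    "  </graph>",
    "</graphml>")
}

#' Read a ceRNA network from GraphML
#'
#' @param path GraphML file written by [export_network()] (or any GraphML
#'   with a `class` node attribute). The network label is taken from the
#'   graph id.
#' @return A [cerna_network()].
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  graph <- xml2::xml_find_first(doc, ".//g:graph", ns)
  label <- xml2::xml_attr(graph, "id")
  node_xml <- xml2::xml_find_all(graph, ".//g:node", ns)
  nodes <- data.frame(
    id = xml2::xml_attr(node_xml, "id"),
    class = xml2::xml_text(xml2::xml_find_first(node_xml, ".//g:data", ns)),
    stringsAsFactors = FALSE)
  edge_xml <- xml2::xml_find_all(graph, ".//g:edge", ns)
  edges <- data.frame(from = xml2::xml_attr(edge_xml, "source"),
                      to = xml2::xml_attr(edge_xml, "target"),
                      stringsAsFactors = FALSE)
  cerna_network(nodes, edges, label = if (is.na(label)) "" else label)
}

#' Read a ceRNA network from node/edge TSVs
#'
#' @param nodes_path Node table TSV (`id`, `class`).
#' @param edges_path Edge table TSV (`from`, `to`).
#' @param label Network label.
#' @return A [cerna_network()].
#' @export
read_network_tsv <- function(nodes_path, edges_path, label = "") {
  nodes <- utils::read.delim(nodes_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  edges <- utils::read.delim(edges_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  cerna_network(nodes, edges, label = label)
}

#' Read a ceRNA network from SIF plus a node-attribute TSV
#'
#' SIF does not carry node classes, so the node table written alongside it
#' is required.
#'
#' @param sif_path SIF path.
#' @param nodes_path Node table TSV (`id`, `class`).
#' @param label Network label.
#' @return A [cerna_network()].
#' @export
read_sif <- function(sif_path, nodes_path, label = "") {
  lines <- readLines(sif_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  edges <- if (length(lines)) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    data.frame(from = vapply(fields, `[[`, character(1L), 1L),
               to = vapply(fields, `[[`, character(1L), 3L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(), to = character(),
               stringsAsFactors = FALSE)
  }
  nodes <- utils::read.delim(nodes_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  cerna_network(nodes, edges, label = label)
}
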