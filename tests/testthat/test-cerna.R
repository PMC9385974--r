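evidence_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(source = r[[1L]], regulator = r[[2L]],
               regulator_class = r[[3L]], target = r[[4L]],
               target_class = r[[5L]], stringsAsFactors = FALSE)
  }))
}

test_that("load_evidence validates classes, normalizes targets and dedups", {
  p <- withr::local_tempfile(fileext = ".tsv")
  ev <- evidence_df(
    list("s1", "miR-1", "miRNA", "BAX", "mRNA"),
    list("s1", "miR-1", "miRNA", "BAX", "mRNA"),
    list("s2", "miR-1", "miRNA", "Bax", "mRNA"),
    list("s1", "lncRNA-A", "lncRNA", "miR-1", "miRNA"))
  write_table_tsv(ev, p)
  out <- load_evidence(p)
  expect_identical(nrow(out), 3L)
  expect_setequal(out$target[out$target_class == "mRNA"], "Bax")
  expect_identical(sort(unique(out$source)), c("s1", "s2"))
  bad <- evidence_df(list("s1", "lncRNA-A", "lncRNA", "Bax", "mRNA"))
  expect_error(load_evidence(bad), "invalid interaction class")
})

test_that("consensus voting retains pairs meeting the source threshold", {
  ev <- evidence_df(
    list("A", "miR-1", "miRNA", "Bax", "mRNA"),
    list("B", "miR-1", "miRNA", "Bax", "mRNA"),
    list("C", "miR-1", "miRNA", "Bax", "mRNA"),
    list("A", "miR-2", "miRNA", "Bax", "mRNA"),
    list("B", "miR-2", "miRNA", "Bax", "mRNA"),
    list("D", "miR-3", "miRNA", "Tnf", "mRNA"))
  ev <- load_evidence(ev)
  cons3 <- consensus_targets(ev, "miRNA", 3)
  expect_identical(cons3$regulator, "miR-1")
  expect_identical(cons3$support, 3L)
  expect_identical(cons3$sources, "A;B;C")
  cons1 <- consensus_targets(ev, "miRNA", 1)
  expect_identical(nrow(cons1), 3L)
  expect_warning(consensus_targets(ev, "miRNA", 5), "exceeds")
})

test_that("voting support recount matches raw evidence for random tables", {
  set.seed(17)
  for (i in 1:10) {
    truth <- simulate_cerna_truth(sprintf("G%d", 1:4), seed = i)
    noise <- source_noise_model(0.7, 0.8, seed = i)
    ev <- simulate_prediction_sources(truth, 4, noise, "miRNA")
    cons <- consensus_targets(ev, "miRNA", 3)
    if (nrow(cons) == 0L) next
    for (j in seq_len(nrow(cons))) {
      n_src <- length(unique(ev$source[
        ev$regulator == cons$regulator[j] & ev$target == cons$target[j]]))
      expect_identical(cons$support[j], n_src)
      expect_gte(n_src, 3L)
    }
  }
})

test_that("assemble_cerna builds minimal triples and drops orphan lncRNA pairs", {
  mm <- data.frame(regulator = "miR-1", target = "Bax",
                   support = 3L, sources = "A;B;C")
  lm <- data.frame(regulator = c("lncRNA-A", "lncRNA-B"),
                   target = c("miR-1", "miR-9"),
                   support = 2L, sources = "X;Y")
  net <- assemble_cerna("Bax", mm, lm, label = "apoptosis")
  s <- network_summary(net)
  expect_identical(s$n_nodes, 3L)
  expect_identical(s$n_edges, 2L)
  expect_false("lncRNA-B" %in% net$nodes$id)
  # miRNA with no lncRNA partner: retained by default, dropped when strict
  mm2 <- rbind(mm, data.frame(regulator = "miR-7", target = "Bax",
                              support = 4L, sources = "A;B;C;D"))
  lax <- assemble_cerna("Bax", mm2, lm)
  expect_true("miR-7" %in% lax$nodes$id)
  strict <- assemble_cerna("Bax", mm2, lm, require_lncrna_partner = TRUE)
  expect_false("miR-7" %in% strict$nodes$id)
  expect_error(assemble_cerna(character(), mm, lm), "non-empty")
})

test_that("assembly is idempotent and always tripartite", {
  set.seed(31)
  for (i in 1:8) {
    truth <- simulate_cerna_truth(sprintf("G%d", 1:5), seed = 40 + i)
    noise <- source_noise_model(0.8, 0.6, seed = i)
    ev <- rbind(simulate_prediction_sources(truth, 4, noise, "miRNA"),
                simulate_prediction_sources(truth, 2, noise, "lncRNA"))
    mm <- consensus_targets(ev, "miRNA", 3)
    lm <- consensus_targets(ev, "lncRNA", 2)
    mrna <- unique(truth$interactions$target[
      truth$interactions$target_class == "mRNA"])
    net <- assemble_cerna(mrna, mm, lm, label = "x")
    # rebuilding from the network's own edges returns the same network
    cls <- setNames(net$nodes$class, net$nodes$id)
    e <- net$edges
    mm2 <- data.frame(regulator = e$from[cls[e$from] == "miRNA"],
                      target = e$to[cls[e$from] == "miRNA"])
    lm2 <- data.frame(regulator = e$from[cls[e$from] == "lncRNA"],
                      target = e$to[cls[e$from] == "lncRNA"])
    if (nrow(mm2) == 0L) next
    net2 <- assemble_cerna(unique(mm2$target), mm2, lm2, label = "x")
    expect_identical(net2$nodes, net$nodes)
    expect_identical(net2$edges, net$edges)
    # tripartite constraint is enforced by the constructor on every build
    rank <- c(lncRNA = 1L, miRNA = 2L, mRNA = 3L)
    pairs <- paste(pmin(rank[cls[e$from]], rank[cls[e$to]]),
                   pmax(rank[cls[e$from]], rank[cls[e$to]]))
    expect_true(all(pairs %in% c("1 2", "2 3")))
  }
})

test_that("noiseless consensus assembly reproduces the ground-truth network", {
  truth <- simulate_cerna_truth(sprintf("Gene%d", 1:5), seed = 77)
  perfect <- source_noise_model(1, 0, seed = 1)
  ev <- rbind(simulate_prediction_sources(truth, 4, perfect, "miRNA"),
              simulate_prediction_sources(truth, 2, perfect, "lncRNA"))
  mm <- consensus_targets(ev, "miRNA", 3)
  lm <- consensus_targets(ev, "lncRNA", 2)
  mrna <- unique(truth$interactions$target[
    truth$interactions$target_class == "mRNA"])
  net <- assemble_cerna(mrna, mm, lm, label = "truth")
  ref <- truth_network(truth)
  expect_identical(net$nodes, ref$nodes)
  expect_identical(net$edges, ref$edges)
})

test_that("network constructor rejects invalid structures", {
  nodes <- data.frame(id = c("L", "m", "G"),
                      class = c("lncRNA", "miRNA", "mRNA"))
  expect_error(cerna_network(nodes, data.frame(from = "L", to = "G")),
               "tripartite")
  expect_error(cerna_network(nodes, data.frame(from = "L", to = "L")),
               "self-loop")
  expect_error(cerna_network(rbind(nodes, nodes[1, ]), NULL), "duplicate")
  dangle <- data.frame(from = "L", to = "zzz")
  expect_error(cerna_network(nodes, dangle), "not in node table")
  # strict mode requires both miRNA sides
  expect_error(cerna_network(nodes, data.frame(from = "m", to = "G"),
                             strict = TRUE), "lacks")
})

test_that("network summary counts partition nodes, including the empty network", {
  empty <- cerna_network(data.frame(id = character(), class = character()),
                         NULL, label = "empty")
  s <- network_summary(empty)
  expect_identical(unlist(s), c(n_lncrna = 0L, n_mirna = 0L, n_mrna = 0L,
                                n_nodes = 0L, n_edges = 0L))
  truth <- simulate_cerna_truth(sprintf("G%d", 1:6), seed = 13)
  net <- truth_network(truth)
  s2 <- network_summary(net)
  expect_identical(s2$n_nodes, s2$n_lncrna + s2$n_mirna + s2$n_mrna)
  expect_identical(s2$n_nodes,
                   length(unique(c(net$edges$from, net$edges$to))))
})

test_that("SIF, GraphML and TSV exports round-trip the network", {
  truth <- simulate_cerna_truth(sprintf("G%d", 1:4), seed = 5)
  net <- truth_network(truth)
  dir <- withr::local_tempdir()
  paths <- export_network(net, dir, basename = "net")
  expect_length(paths, 4L)
  gml <- read_graphml(file.path(dir, "net.graphml"))
  expect_identical(gml$nodes, net$nodes)
  expect_identical(gml$edges, net$edges)
  tsv <- read_network_tsv(file.path(dir, "net_nodes.tsv"),
                          file.path(dir, "net_edges.tsv"),
                          label = net$label)
  expect_identical(tsv$nodes, net$nodes)
  expect_identical(tsv$edges, net$edges)
  sif <- read_sif(file.path(dir, "net.sif"),
                  file.path(dir, "net_nodes.tsv"), label = net$label)
  expect_identical(sif$edges, net$edges)
  # minimal triple: two SIF lines
  mini <- cerna_network(
    data.frame(id = c("L1", "m1", "G1"),
               class = c("lncRNA", "miRNA", "mRNA")),
    data.frame(from = c("L1", "m1"), to = c("m1", "G1")))
  export_network(mini, dir, basename = "mini", formats = "sif")
  expect_length(readLines(file.path(dir, "mini.sif")), 2L)
  # empty network exports valid documents
  empty <- cerna_network(data.frame(id = character(), class = character()),
                         NULL, label = "none")
  export_network(empty, dir, basename = "empty")
  expect_identical(nrow(read_graphml(file.path(dir, "empty.graphml"))$edges),
                   0L)
  expect_error(export_network(mini, dir, formats = "gexf"), "unknown")
})
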