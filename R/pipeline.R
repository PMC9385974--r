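#' Build a pipeline configuration
#'
#' One declarative object drives the full analysis. Thresholds default to
#' the published choices: raw p < 0.05 and |log2FC| > 1 for DEG calling,
#' 3-of-4 source consensus for miRNA-mRNA predictions, 2-of-2 for
#' lncRNA-miRNA, top-10 per centrality algorithm.
#'
#' @param datasets List of dataset entries, each a list with `label`,
#'   `path`, `groups`, `platform`, and optional `transform`.
#' @param pcd_lists List of gene-list entries, each with `path`,
#'   `category`, and optional `provenance`.
#' @param evidence Character vector of evidence TSV paths.
#' @param annotation_gmt Optional GMT path enabling the enrichment stage.
#' @param out_dir Output directory.
#' @param p_cut,lfc_cut DEG cutoffs (strict inequalities).
#' @param mirna_min_support,lncrna_min_support Consensus vote thresholds.
#' @param k_top Top-list size per centrality algorithm.
#' @param epc_realizations,epc_p_keep EPC Monte-Carlo parameters.
#' @param require_lncrna_partner Drop miRNAs lacking a lncRNA sponge.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(datasets, pcd_lists, evidence,
                            annotation_gmt = NULL, out_dir = ".",
                            p_cut = 0.05, lfc_cut = 1.0,
                            mirna_min_support = 3L,
                            lncrna_min_support = 2L, k_top = 10L,
                            epc_realizations = 1000L, epc_p_keep = 0.5,
                            require_lncrna_partner = FALSE, seed = 1L) {
  if (length(datasets) < 2L) {
    stop("at least 2 datasets are required for the intersection stage",
         call. = FALSE)
  }
  stopifnot(p_cut >= 0, p_cut <= 1, lfc_cut >= 0,
            mirna_min_support >= 1L, lncrna_min_support >= 1L, k_top >= 1L)
  structure(list(datasets = datasets, pcd_lists = pcd_lists,
                 evidence = evidence, annotation_gmt = annotation_gmt,
                 out_dir = out_dir, p_cut = p_cut, lfc_cut = lfc_cut,
                 mirna_min_support = as.integer(mirna_min_support),
                 lncrna_min_support = as.integer(lncrna_min_support),
                 k_top = as.integer(k_top),
                 epc_realizations = as.integer(epc_realizations),
                 epc_p_keep = epc_p_keep,
                 require_lncrna_partner = isTRUE(require_lncrna_partner),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with the [pipeline_config()] fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  args <- raw
  args$evidence <- unlist(raw$evidence)
  args$annotation_gmt <- if (is.null(raw$annotation_gmt)) NULL
                         else raw$annotation_gmt[[1]]
  scalars <- c("out_dir", "p_cut", "lfc_cut", "mirna_min_support",
               "lncrna_min_support", "k_top", "epc_realizations",
               "epc_p_keep", "require_lncrna_partner", "seed")
  for (s in scalars) if (!is.null(raw[[s]])) args[[s]] <- raw[[s]][[1]]
  do.call(pipeline_config, args)
}

#' Write a pipeline configuration to JSON
#'
#' @param config A [pipeline_config()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Run the full screening pipeline
#'
#' Stages: per-dataset moderated-t differential expression and DEG
#' calling; cross-dataset intersection; PCD membership table; optional
#' hypergeometric enrichment per category; consensus voting and tripartite
#' network assembly per category; seven-algorithm hub analysis; axis
#' extraction and global deduplication. All stage outputs are written
#' under `config$out_dir`; the machine-readable run report is returned and
#' written as `report.json`. Identical config and seed give byte-identical
#' outputs (no timestamps are emitted).
#'
#' @param config A [pipeline_config()] or path to its JSON file.
#' @param quiet Suppress stage logging.
#' @return The run report, invisibly (a nested list).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  # stage 1: differential expression per dataset
  degs <- list()
  ds_report <- list()
  for (entry in config$datasets) {
    label <- entry$label
    transform <- if (!is.null(entry$transform)) entry$transform else "log2p1"
    ds <- read_expression_tsv(entry$path, entry$groups,
                              platform = entry$platform)
    de <- run_de(ds, transform = transform)
    called <- call_degs(de, p_cut = config$p_cut, lfc_cut = config$lfc_cut)
    write_table_tsv(de, file.path(out, paste0("de_", label, ".tsv")))
    write_table_tsv(called, file.path(out, paste0("degs_", label, ".tsv")))
    degs[[label]] <- called
    ds_report[[label]] <- list(n_genes = nrow(de), n_degs = nrow(called),
                               n_up = sum(called$direction == "up"),
                               n_down = sum(called$direction == "down"))
    say("[de] %s: %d genes, %d DEGs (%d up / %d down)", label, nrow(de),
        nrow(called), sum(called$direction == "up"),
        sum(called$direction == "down"))
  }

  # stage 2: intersection and membership
  common <- intersect_datasets(degs)
  pcd_sets <- lapply(config$pcd_lists, function(e) {
    read_gene_list(e$path, category = e$category,
                   provenance = if (!is.null(e$provenance)) e$provenance
                                else character())
  })
  membership <- build_membership(common, pcd_sets)
  write_table_tsv(as.data.frame(membership),
                  file.path(out, "membership.tsv"))
  venn <- if (nrow(membership)) venn_counts(membership) else integer()
  say("[membership] %d common DEGs, %d PCD-related", nrow(common),
      nrow(membership))

  # stage 3 (optional): enrichment per category
  enr_report <- NULL
  if (!is.null(config$annotation_gmt)) {
    collection <- read_annotation_gmt(config$annotation_gmt)
    enr_report <- list()
    for (s in pcd_sets) {
      lab <- category_label(s$category)
      genes <- membership$gene[grepl(lab, membership$categories,
                                     fixed = TRUE)]
      if (length(genes) == 0L) next
      res <- run_ora(genes, collection)
      write_table_tsv(res, file.path(out, paste0("enrichment_", s$category,
                                                 ".tsv")))
      enr_report[[s$category]] <- list(n_terms = nrow(res))
      say("[enrich] %s: %d terms", s$category, nrow(res))
    }
  }

  # stage 4-5: per-category network assembly and hub analysis
  evidence <- load_evidence(config$evidence)
  mirna_cons <- consensus_targets(evidence, "miRNA",
                                  config$mirna_min_support)
  lncrna_cons <- consensus_targets(evidence, "lncRNA",
                                   config$lncrna_min_support)
  net_report <- list()
  all_axes <- data.frame(network = character(), lncrna = character(),
                         mirna = character(), mrna = character(),
                         stringsAsFactors = FALSE)
  cat_idx <- 0L
  for (s in pcd_sets) {
    cat_idx <- cat_idx + 1L
    lab <- category_label(s$category)
    genes <- membership$gene[grepl(lab, membership$categories,
                                   fixed = TRUE)]
    if (length(genes) == 0L) {
      net_report[[s$category]] <- list(empty = TRUE)
      next
    }
    net <- assemble_cerna(genes, mirna_cons, lncrna_cons,
                          label = s$category,
                          require_lncrna_partner =
                            config$require_lncrna_partner)
    export_network(net, out, basename = paste0("network_", s$category))
    summ <- network_summary(net)
    say("[cerna] %s: %d nodes (%d/%d/%d), %d edges", s$category,
        summ$n_nodes, summ$n_lncrna, summ$n_mirna, summ$n_mrna,
        summ$n_edges)
    hubs <- character()
    axes <- data.frame(lncrna = character(), mirna = character(),
                       mrna = character(), stringsAsFactors = FALSE)
    if (summ$n_nodes > 0L) {
      cc <- centrality_config(k_top = config$k_top,
                              epc_realizations = config$epc_realizations,
                              epc_p_keep = config$epc_p_keep,
                              seed = config$seed + 30L + cat_idx)
      rep_c <- centrality_report(net, cc)
      hub_set <- consensus_hubs(rep_c)
      hubs <- hub_set$hubs
      scores <- data.frame(node = names(rep_c$scores[[1L]]),
                           as.data.frame(rep_c$scores),
                           stringsAsFactors = FALSE, check.names = FALSE)
      write_table_tsv(scores, file.path(out, paste0("centrality_",
                                                    s$category, ".tsv")))
      memb <- data.frame(node = rownames(hub_set$membership),
                         hub_set$membership, check.names = FALSE,
                         stringsAsFactors = FALSE)
      write_table_tsv(memb, file.path(out, paste0("hub_membership_",
                                                  s$category, ".tsv")))
      axes <- extract_axes(net, hub_set)
    }
    if (nrow(axes)) {
      all_axes <- rbind(all_axes,
                        cbind(network = s$category, axes,
                              stringsAsFactors = FALSE))
    }
    ax_out <- cbind(network = rep(s$category, nrow(axes)), axes)
    write_table_tsv(ax_out, file.path(out, paste0("axes_", s$category,
                                                  ".tsv")))
    say("[hubs] %s: %d hubs, %d axes", s$category, length(hubs),
        nrow(axes))
    net_report[[s$category]] <- list(summary = summ, hubs = as.list(hubs),
                                     axes = axes)
  }

  unique_axes <- dedup_axes(all_axes)
  write_table_tsv(unique_axes, file.path(out, "axes_unique.tsv"))
  say("[axes] %d unique regulatory axes", nrow(unique_axes))

  report <- list(
    package = "ceRNAscreen",
    version = as.character(utils::packageVersion("ceRNAscreen")),
    seed = config$seed,
    config = unclass(config),
    datasets = ds_report,
    membership = list(n_common_degs = nrow(common),
                      n_pcd_degs = nrow(membership),
                      venn = as.list(venn),
                      per_category = as.list(attr(venn, "per_category"))),
    enrichment = enr_report,
    networks = net_report,
    n_unique_axes = nrow(unique_axes),
    unique_axes = unique_axes)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", pretty = TRUE)
  invisible(report)
}
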