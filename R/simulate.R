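# Synthetic-data generator: two-group expression with planted effects, a
# ground-truth sponge structure, and noisy multi-source prediction tables.
# Each artifact draws from its own RNG stream (a fixed offset from the
# master seed) so adding sources does not perturb the expression draw.

#' Simulation configuration
#'
#' Defaults state the simulated world: a 3-vs-3 two-group design, 1000
#' genes, 10% of them differentially expressed with a planted
#' |log2 fold change| of 5 against unit-scale noise (gene variances drawn
#' from a scaled inverse chi-square with d0 = 4, s0^2 = 0.05, the same
#' hierarchical family the moderated-t prior assumes). Counts use a
#' negative binomial with dispersion 0.1 and log-normal library sizes
#' (sdlog 0.2).
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per group (>= 2).
#' @param platform `"intensity"` or `"count"`.
#' @param de_fraction Fraction of genes with a planted effect, in \[0, 1\].
#' @param effect_size_log2 Planted |log2 fold change| (> 0).
#' @param variance_shape Prior degrees of freedom d0 of the gene-variance
#'   distribution.
#' @param variance_scale Prior variance s0^2.
#' @param nb_dispersion Negative-binomial dispersion (count platform).
#' @param libsize_sdlog Log-normal sdlog of library-size factors.
#' @param seed Master integer seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 1000L, n_per_group = 3L,
                              platform = c("intensity", "count"),
                              de_fraction = 0.1, effect_size_log2 = 5,
                              variance_shape = 4, variance_scale = 0.05,
                              nb_dispersion = 0.1, libsize_sdlog = 0.2,
                              seed = 1L) {
  platform <- match.arg(platform)
  stopifnot(n_genes >= 1L, de_fraction >= 0, de_fraction <= 1,
            effect_size_log2 > 0, variance_shape > 0, variance_scale > 0)
  if (n_per_group < 2L) {
    stop("n_per_group must be at least 2 (variance not estimable)",
         call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_per_group = as.integer(n_per_group),
                 platform = platform, de_fraction = de_fraction,
                 effect_size_log2 = effect_size_log2,
                 variance_shape = variance_shape,
                 variance_scale = variance_scale,
                 nb_dispersion = nb_dispersion,
                 libsize_sdlog = libsize_sdlog,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a two-group expression dataset with planted effects
#'
#' Intensity platform: Gaussian log2-scale values with gene-wise variances
#' `s_g^2 ~ s0^2 d0 / chisq(d0)` and group means split `+/- effect/2`
#' around a baseline for planted genes (so case minus control equals the
#' signed effect). Count platform: negative-binomial counts whose log2
#' expectation shifts by the planted effect, scaled by per-sample library
#' factors.
#'
#' @param config A [simulation_config()].
#' @return List with `dataset` (an [expression_dataset()]) and `truth`
#'   (class `ground_truth`: `de_genes` data frame of planted genes with
#'   signed log2 fold changes; empty `interactions`/`axes`, see
#'   [simulate_cerna_truth()]).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old <- local_seed(config$seed)
  on.exit(restore_seed(old), add = TRUE)
  n <- config$n_genes
  k <- config$n_per_group
  genes <- sprintf("Gene%05d", seq_len(n))
  n_de <- round(config$de_fraction * n)
  de_idx <- if (n_de > 0L) sort(sample.int(n, n_de)) else integer()
  sign <- ifelse(stats::runif(n_de) < 0.5, 1, -1)
  lfc <- numeric(n)
  lfc[de_idx] <- sign * config$effect_size_log2
  labels <- rep(c("control", "case"), each = k)
  samples <- c(paste0("ctrl_", seq_len(k)), paste0("case_", seq_len(k)))
  if (config$platform == "intensity") {
    base <- stats::rnorm(n, mean = 7, sd = 1)
    s2 <- config$variance_scale * config$variance_shape /
      stats::rchisq(n, df = config$variance_shape)
    mu <- outer(base - lfc / 2, rep(1, k))
    mu <- cbind(mu, outer(base + lfc / 2, rep(1, k)))
    values <- mu + matrix(stats::rnorm(n * 2 * k), n) * sqrt(s2)
  } else {
    base <- stats::rnorm(n, mean = 5, sd = 1.5)
    libf <- stats::rlnorm(2 * k, meanlog = 0, sdlog = config$libsize_sdlog)
    mu <- 2^cbind(outer(base - lfc / 2, rep(1, k)),
                  outer(base + lfc / 2, rep(1, k)))
    mu <- sweep(mu, 2L, libf, "*")
    values <- matrix(stats::rnbinom(n * 2 * k, mu = mu,
                                    size = 1 / config$nb_dispersion), n)
  }
  colnames(values) <- samples
  dataset <- expression_dataset(values, genes, labels,
                                platform = config$platform)
  truth <- structure(
    list(de_genes = data.frame(gene = genes[de_idx],
                               log2fc = lfc[de_idx],
                               stringsAsFactors = FALSE),
         interactions = empty_interactions(),
         axes = data.frame(lncrna = character(), mirna = character(),
                           mrna = character(), stringsAsFactors = FALSE)),
    class = "ground_truth")
  list(dataset = dataset, truth = truth)
}

empty_interactions <- function() {
  data.frame(regulator = character(), regulator_class = character(),
             target = character(), target_class = character(),
             stringsAsFactors = FALSE)
}

#' Plant a ground-truth ceRNA sponge structure
#'
#' Builds true lncRNA-miRNA and miRNA-mRNA interactions over the supplied
#' mRNAs: each mRNA is targeted by `mirna_per_mrna` miRNAs drawn from a
#' pool of `n_mirna`, each used miRNA sponges `lncrna_per_mirna` lncRNAs
#' drawn from a pool of `n_lncrna`; unused pool members are dropped, so
#' every miRNA in the truth has both a lncRNA and an mRNA neighbor. True
#' axes are all (lncRNA, miRNA, mRNA) triples composed of two true
#' interactions.
#'
#' @param mrna Character vector of mRNA symbols.
#' @param n_mirna,n_lncrna Pool sizes.
#' @param mirna_per_mrna,lncrna_per_mirna Out-degrees.
#' @param seed Integer seed.
#' @return A `ground_truth` object (empty `de_genes`).
#' @export
simulate_cerna_truth <- function(mrna, n_mirna = 8L, n_lncrna = 6L,
                                 mirna_per_mrna = 3L, lncrna_per_mirna = 2L,
                                 seed = 1L) {
  stopifnot(length(mrna) >= 1L, n_mirna >= mirna_per_mrna,
            n_lncrna >= lncrna_per_mirna)
  mrna <- unique(normalize_symbol(mrna))
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  mirnas <- sprintf("miR-sim-%d-5p", seq_len(n_mirna))
  lncrnas <- sprintf("lncRNA-sim-%d", seq_len(n_lncrna))
  mm <- do.call(rbind, lapply(mrna, function(g) {
    data.frame(regulator = sample(mirnas, mirna_per_mrna),
               regulator_class = "miRNA", target = g,
               target_class = "mRNA", stringsAsFactors = FALSE)
  }))
  used_mir <- sort(unique(mm$regulator))
  lm <- do.call(rbind, lapply(used_mir, function(m) {
    data.frame(regulator = sample(lncrnas, lncrna_per_mirna),
               regulator_class = "lncRNA", target = m,
               target_class = "miRNA", stringsAsFactors = FALSE)
  }))
  interactions <- rbind(lm, mm)
  axes <- merge(
    stats::setNames(lm[, c("regulator", "target")], c("lncrna", "mirna")),
    stats::setNames(mm[, c("regulator", "target")], c("mirna", "mrna")),
    by = "mirna")[, c("lncrna", "mirna", "mrna")]
  axes <- axes[order(axes$lncrna, axes$mirna, axes$mrna), , drop = FALSE]
  rownames(axes) <- NULL
  structure(list(de_genes = data.frame(gene = character(),
                                       log2fc = numeric(),
                                       stringsAsFactors = FALSE),
                 interactions = interactions, axes = axes),
            class = "ground_truth")
}

#' Convert a ground truth to its exact ceRNA network
#'
#' @param truth A `ground_truth` with non-empty interactions.
#' @param label Network label.
#' @return A [cerna_network()].
#' @export
truth_network <- function(truth, label = "truth") {
  ints <- truth$interactions
  mm <- ints[ints$regulator_class == "miRNA", , drop = FALSE]
  lm <- ints[ints$regulator_class == "lncRNA", , drop = FALSE]
  nodes <- rbind(
    data.frame(id = unique(lm$regulator), class = "lncRNA",
               stringsAsFactors = FALSE),
    data.frame(id = unique(c(lm$target, mm$regulator)), class = "miRNA",
               stringsAsFactors = FALSE),
    data.frame(id = unique(mm$target), class = "mRNA",
               stringsAsFactors = FALSE))
  edges <- data.frame(from = ints$regulator, to = ints$target,
                      stringsAsFactors = FALSE)
  cerna_network(nodes, edges, label = label)
}

#' Noise model for interaction-prediction sources
#'
#' @param sensitivity Per-source probability that a true interaction is
#'   reported, in \[0, 1\].
#' @param fpr_rate Expected spurious interactions per source as a fraction
#'   of the true interaction count (>= 0).
#' @param seed Integer seed.
#' @return List of class `source_noise_model`.
#' @export
source_noise_model <- function(sensitivity = 0.9, fpr_rate = 0.5,
                               seed = 1L) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, fpr_rate >= 0)
  structure(list(sensitivity = sensitivity, fpr_rate = fpr_rate,
                 seed = as.integer(seed)),
            class = "source_noise_model")
}

#' Simulate noisy prediction-source tables
#'
#' Each source reports each true interaction of the requested regulator
#' class independently with probability `sensitivity`, plus
#' `round(fpr_rate * n_true)` spurious pairs sampled without replacement
#' from the non-interacting regulator/target combinations (never
#' duplicating a true pair). Each source draws from its own RNG stream.
#'
#' @param truth A `ground_truth` with non-empty interactions.
#' @param n_sources Number of sources (>= 1).
#' @param noise A [source_noise_model()].
#' @param regulator_class `"miRNA"` or `"lncRNA"`.
#' @param source_labels Optional distinct labels; default
#'   `src_<class>_1..n`.
#' @return An `interaction_evidence` data frame covering all sources.
#' @export
simulate_prediction_sources <- function(truth, n_sources, noise,
                                        regulator_class = "miRNA",
                                        source_labels = NULL) {
  if (n_sources < 1L) stop("n_sources must be >= 1", call. = FALSE)
  ints <- truth$interactions
  ints <- ints[ints$regulator_class == regulator_class, , drop = FALSE]
  if (nrow(ints) == 0L) {
    stop("ground truth has no interactions of the requested class",
         call. = FALSE)
  }
  if (is.null(source_labels)) {
    source_labels <- sprintf("src_%s_%d", tolower(regulator_class),
                             seq_len(n_sources))
  }
  stopifnot(length(source_labels) == n_sources,
            !anyDuplicated(source_labels))
  target_class <- ints$target_class[1L]
  regulators <- unique(ints$regulator)
  targets <- unique(ints$target)
  true_key <- paste(ints$regulator, ints$target, sep = "\r")
  all_pairs <- expand.grid(regulator = regulators, target = targets,
                           stringsAsFactors = FALSE,
                           KEEP.OUT.ATTRS = FALSE)
  all_key <- paste(all_pairs$regulator, all_pairs$target, sep = "\r")
  nonint <- all_pairs[!(all_key %in% true_key), , drop = FALSE]
  n_spur <- round(noise$fpr_rate * nrow(ints))
  out <- vector("list", n_sources)
  for (i in seq_len(n_sources)) {
    old <- local_seed(noise$seed + 200L + i)
    reported <- stats::runif(nrow(ints)) < noise$sensitivity
    rows <- ints[reported, c("regulator", "target"), drop = FALSE]
    if (n_spur > 0L && nrow(nonint) > 0L) {
      take <- sample.int(nrow(nonint), min(n_spur, nrow(nonint)))
      rows <- rbind(rows, nonint[take, , drop = FALSE])
    }
    restore_seed(old)
    if (nrow(rows) == 0L) next
    out[[i]] <- data.frame(source = source_labels[i],
                           regulator = rows$regulator,
                           regulator_class = regulator_class,
                           target = rows$target,
                           target_class = target_class,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  ev <- if (length(out)) do.call(rbind, out) else {
    data.frame(source = character(), regulator = character(),
               regulator_class = character(), target = character(),
               target_class = character(), stringsAsFactors = FALSE)
  }
  rownames(ev) <- NULL
  class(ev) <- c("interaction_evidence", class(ev))
  ev
}

#' Simulate a complete pipeline scenario
#'
#' Generates everything the full pipeline needs: two expression datasets
#' sharing the same planted differentially expressed genes (seed offsets 1
#' and 2 from the master seed), three PCD gene lists built over those
#' genes (each planted gene joins 1-3 of apoptosis/necroptosis/pyroptosis,
#' padded with non-DE members), a ground-truth sponge structure over the
#' planted PCD genes, and noisy prediction-source tables (4 miRNA-target
#' sources, 2 lncRNA-target sources).
#'
#' @param config A [simulation_config()].
#' @param noise A [source_noise_model()]; its seed is ignored in favour of
#'   offsets from `config$seed`.
#' @param n_pcd_mrna Number of planted genes recruited as ceRNA mRNAs.
#' @return List with `datasets` (named list of two
#'   [expression_dataset()]s), `pcd_sets`, `evidence`, and `truth`.
#' @export
simulate_scenario <- function(config = simulation_config(),
                              noise = source_noise_model(),
                              n_pcd_mrna = 5L) {
  cfg_a <- config; cfg_a$seed <- config$seed + 1L
  cfg_b <- config; cfg_b$seed <- config$seed + 2L
  # shared planted genes: draw dataset A first, then force B onto the same
  # planted set by re-using its truth
  sim_a <- simulate_expression(cfg_a)
  sim_b <- replant_expression(cfg_b, sim_a$truth$de_genes)
  de <- sim_a$truth$de_genes
  old <- local_seed(config$seed + 3L)
  cats <- c("apoptosis", "necroptosis", "pyroptosis")
  n_cat <- sample(1:3, nrow(de), replace = TRUE)
  membership <- lapply(seq_len(nrow(de)),
                       function(i) sample(cats, n_cat[i]))
  all_genes <- sim_a$dataset$gene_ids
  non_de <- setdiff(all_genes, de$gene)
  pcd_sets <- lapply(cats, function(cat) {
    members <- de$gene[vapply(membership, function(m) cat %in% m,
                              logical(1L))]
    pad <- sample(non_de, min(20L, length(non_de)))
    gene_set(cat, c(members, pad), category = cat,
             provenance = "simulated")
  })
  names(pcd_sets) <- cats
  restore_seed(old)
  pcd_de <- unique(unlist(lapply(pcd_sets, function(s)
    intersect(s$symbols, normalize_symbol(de$gene)))))
  mrna <- utils::head(pcd_de, n_pcd_mrna)
  truth <- simulate_cerna_truth(mrna, seed = config$seed + 4L)
  truth$de_genes <- de
  nm <- source_noise_model(noise$sensitivity, noise$fpr_rate,
                           seed = config$seed + 10L)
  nl <- source_noise_model(noise$sensitivity, noise$fpr_rate,
                           seed = config$seed + 20L)
  evidence <- rbind(
    simulate_prediction_sources(truth, 4L, nm, "miRNA"),
    simulate_prediction_sources(truth, 2L, nl, "lncRNA"))
  class(evidence) <- c("interaction_evidence", "data.frame")
  list(datasets = list(dsA = sim_a$dataset, dsB = sim_b$dataset),
       pcd_sets = pcd_sets, evidence = evidence, truth = truth,
       membership_truth = membership)
}

# Regenerate an expression draw with a fixed planted-effect pattern.
replant_expression <- function(config, de_genes) {
  old <- local_seed(config$seed)
  on.exit(restore_seed(old), add = TRUE)
  n <- config$n_genes
  k <- config$n_per_group
  genes <- sprintf("Gene%05d", seq_len(n))
  lfc <- numeric(n)
  lfc[match(de_genes$gene, genes)] <- de_genes$log2fc
  labels <- rep(c("control", "case"), each = k)
  samples <- c(paste0("ctrl_", seq_len(k)), paste0("case_", seq_len(k)))
  if (config$platform == "intensity") {
    base <- stats::rnorm(n, mean = 7, sd = 1)
    s2 <- config$variance_scale * config$variance_shape /
      stats::rchisq(n, df = config$variance_shape)
    mu <- cbind(outer(base - lfc / 2, rep(1, k)),
                outer(base + lfc / 2, rep(1, k)))
    values <- mu + matrix(stats::rnorm(n * 2 * k), n) * sqrt(s2)
  } else {
    base <- stats::rnorm(n, mean = 5, sd = 1.5)
    libf <- stats::rlnorm(2 * k, meanlog = 0, sdlog = config$libsize_sdlog)
    mu <- 2^cbind(outer(base - lfc / 2, rep(1, k)),
                  outer(base + lfc / 2, rep(1, k)))
    mu <- sweep(mu, 2L, libf, "*")
    values <- matrix(stats::rnbinom(n * 2 * k, mu = mu,
                                    size = 1 / config$nb_dispersion), n)
  }
  colnames(values) <- samples
  truth <- structure(
    list(de_genes = de_genes, interactions = empty_interactions(),
         axes = data.frame(lncrna = character(), mirna = character(),
                           mrna = character(), stringsAsFactors = FALSE)),
    class = "ground_truth")
  list(dataset = expression_dataset(values, genes, labels,
                                    platform = config$platform),
       truth = truth)
}

#' Write scenario inputs to a directory
#'
#' Emits every pipeline input format: expression TSVs with group files,
#' PCD gene lists (plain text), evidence TSVs (one per source), and a
#' `truth.json` record of the planted parameters.
#'
#' @param scenario Output of [simulate_scenario()].
#' @param dir Output directory.
#' @return List of written paths, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(datasets = list(), groups = list(), pcd = list(),
                evidence = character())
  for (nm in names(scenario$datasets)) {
    ds <- scenario$datasets[[nm]]
    ep <- file.path(dir, paste0(nm, "_expression.tsv"))
    gp <- file.path(dir, paste0(nm, "_groups.tsv"))
    write_expression_tsv(ds, ep, gp)
    paths$datasets[[nm]] <- ep
    paths$groups[[nm]] <- gp
  }
  for (nm in names(scenario$pcd_sets)) {
    p <- file.path(dir, paste0(nm, "_genes.txt"))
    writeLines(scenario$pcd_sets[[nm]]$symbols, p)
    paths$pcd[[nm]] <- p
  }
  for (src in unique(scenario$evidence$source)) {
    p <- file.path(dir, paste0("evidence_", src, ".tsv"))
    write_table_tsv(scenario$evidence[scenario$evidence$source == src, ],
                    p)
    paths$evidence <- c(paths$evidence, p)
  }
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(de_genes = scenario$truth$de_genes,
         interactions = scenario$truth$interactions,
         axes = scenario$truth$axes),
    truth_path, dataframe = "rows", digits = NA)
  paths$truth <- truth_path
  invisible(paths)
}

#' Write an expression dataset and its group file
#'
#' @param dataset An [expression_dataset()].
#' @param path Expression TSV path (first column `gene`, then samples).
#' @param groups_path Group TSV path (`sample`, `group`).
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(dataset, path, groups_path) {
  tab <- data.frame(gene = dataset$gene_ids, dataset$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_table_tsv(tab, path)
  write_table_tsv(data.frame(sample = colnames(dataset$values),
                             group = dataset$group_labels,
                             stringsAsFactors = FALSE), groups_path)
  invisible(path)
}
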