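#' Construct a two-group expression dataset
#'
#' @param values Numeric genes x samples matrix (no missing values).
#' @param gene_ids Character vector of gene symbols, one per row.
#' @param group_labels Per-sample labels, each `"case"` or `"control"`;
#'   both groups need at least 2 samples.
#' @param platform `"intensity"` (already on the log2 scale) or `"count"`.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, gene_ids, group_labels,
                               platform = c("intensity", "count")) {
  platform <- match.arg(platform)
  values <- as.matrix(values)
  if (nrow(values) != length(gene_ids)) {
    stop("row count must equal the number of gene ids", call. = FALSE)
  }
  if (ncol(values) != length(group_labels)) {
    stop("column count must equal the number of group labels", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression matrix contains missing or non-finite values",
         call. = FALSE)
  }
  group_labels <- as.character(group_labels)
  if (!all(group_labels %in% c("case", "control"))) {
    stop("group labels must be 'case' or 'control'", call. = FALSE)
  }
  if (sum(group_labels == "case") < 2L || sum(group_labels == "control") < 2L) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  rownames(values) <- gene_ids
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  }
  structure(
    list(values = values, gene_ids = as.character(gene_ids),
         group_labels = group_labels, platform = platform),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset (%s): %d genes x %d samples (%d case / %d control)\n",
              x$platform, nrow(x$values), ncol(x$values),
              sum(x$group_labels == "case"),
              sum(x$group_labels == "control")))
  invisible(x)
}

#' Prepare an expression matrix for linear modelling
#'
#' Count-platform data are transformed to an approximately log scale;
#' intensity-platform data are assumed to already be log2 and pass through
#' untouched.
#'
#' @param dataset An [expression_dataset()].
#' @param transform Count transform: `"log2p1"` (log2(x+1), default),
#'   `"log2cpm"` (log2 counts-per-million with pseudocount 0.5), or
#'   `"none"` (apply the linear model to the raw counts).
#' @return The dataset with transformed values.
#' @export
prepare_matrix <- function(dataset, transform = c("log2p1", "log2cpm", "none")) {
  transform <- match.arg(transform)
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$platform == "intensity") return(dataset)
  x <- dataset$values
  if (any(x < 0)) {
    stop("negative values are not valid counts", call. = FALSE)
  }
  dataset$values <- switch(transform,
    log2p1 = log2(x + 1),
    log2cpm = {
      lib <- colSums(x)
      log2(sweep(x + 0.5, 2L, lib + 1, "/") * 1e6)
    },
    none = x)
  dataset
}

#' Per-gene two-group fit
#'
#' Ordinary least squares for the two-group design: the log2 fold change is
#' mean(case) - mean(control), the residual variance is the pooled
#' within-group variance on d_g = n_case + n_control - 2 degrees of freedom.
#'
#' @param dataset A prepared [expression_dataset()].
#' @return A data frame with columns `gene`, `log2fc`, `s_g_sq`, and the
#'   scalar attributes `d_g`, `n_case`, `n_control`.
#' @export
fit_two_group <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  case <- dataset$values[, dataset$group_labels == "case", drop = FALSE]
  ctrl <- dataset$values[, dataset$group_labels == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  log2fc <- rowMeans(case) - rowMeans(ctrl)
  ss <- rowSums((case - rowMeans(case))^2) +
        rowSums((ctrl - rowMeans(ctrl))^2)
  d_g <- n1 + n2 - 2L
  out <- data.frame(gene = dataset$gene_ids, log2fc = unname(log2fc),
                    s_g_sq = unname(ss) / d_g, stringsAsFactors = FALSE)
  attr(out, "d_g") <- d_g
  attr(out, "n_case") <- n1
  attr(out, "n_control") <- n2
  out
}

#' Invert the trigamma function
#'
#' Newton iteration for y = trigamma(x), monotone decreasing on (0, Inf).
#' Used by the empirical-Bayes prior estimator.
#'
#' @param y Positive numeric vector.
#' @return x with trigamma(x) = y.
#' @keywords internal
trigamma_inverse <- function(y) {
  stopifnot(all(is.finite(y)), all(y > 0))
  # good starting value: trigamma(x) ~ 1/x + 1/(2x^2)
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  x
}

#' Estimate the empirical-Bayes variance prior
#'
#' Moment matching on the log sample variances. With `z_g = log(s_g^2)` and
#' `e_g = z_g - digamma(d_g/2) + log(d_g/2)`, the prior degrees of freedom
#' `d0` solve `trigamma(d0/2) = var(e_g) - trigamma(d_g/2)` and the prior
#' variance is `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. If the
#' empirical spread of `e_g` does not exceed its sampling component, the
#' prior is degenerate: `d0 = Inf`, `s0^2 = exp(mean(e))`.
#'
#' @param s_sq Numeric vector of at least 10 gene-wise sample variances.
#'   Zeros are floored to the smallest positive variance observed.
#' @param d_g Residual degrees of freedom shared by all genes.
#' @param eps Positive floor for the trigamma argument.
#' @return A list with elements `d0` and `s0_sq` (class
#'   `moderated_test_params`).
#' @export
estimate_prior <- function(s_sq, d_g, eps = 1e-8) {
  s_sq <- as.numeric(s_sq)
  if (length(s_sq) < 10L) {
    stop("at least 10 gene-wise variances are required", call. = FALSE)
  }
  if (anyNA(s_sq) || any(s_sq < 0)) {
    stop("variances must be finite and non-negative", call. = FALSE)
  }
  if (all(s_sq == 0)) {
    stop("all sample variances are zero: degenerate data", call. = FALSE)
  }
  minpos <- min(s_sq[s_sq > 0])
  s_sq[s_sq == 0] <- minpos
  z <- log(s_sq)
  e <- z - digamma(d_g / 2) + log(d_g / 2)
  ebar <- mean(e)
  G <- length(e)
  evar <- mean((e - ebar)^2) * G / (G - 1)
  target <- evar - trigamma(d_g / 2)
  if (target <= eps) {
    params <- list(d0 = Inf, s0_sq = exp(ebar))
  } else {
    d0 <- 2 * trigamma_inverse(target)
    params <- list(d0 = d0, s0_sq = exp(ebar + digamma(d0 / 2) - log(d0 / 2)))
  }
  structure(params, class = "moderated_test_params")
}

#' Moderated t-statistic and p-value
#'
#' Shrinks each gene-wise variance toward the prior:
#' `s_tilde^2 = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)`, then
#' `t = log2fc / sqrt(s_tilde^2 * (1/n_case + 1/n_control))` with a
#' two-sided p-value from a t distribution on `d0 + d_g` degrees of freedom
#' (standard normal when `d0` is infinite).
#'
#' @param log2fc,s_g_sq Numeric vectors from [fit_two_group()].
#' @param d_g Residual degrees of freedom.
#' @param params A `moderated_test_params` object from [estimate_prior()].
#' @param n_case,n_control Group sizes.
#' @return A list with numeric vectors `t` and `p`.
#' @export
moderated_t <- function(log2fc, s_g_sq, d_g, params, n_case, n_control) {
  stopifnot(inherits(params, "moderated_test_params"), d_g >= 1)
  d0 <- params$d0; s0 <- params$s0_sq
  if (is.infinite(d0)) {
    s_post <- rep(s0, length(s_g_sq))
  } else {
    s_post <- (d0 * s0 + d_g * s_g_sq) / (d0 + d_g)
  }
  if (any(s_post <= 0)) {
    stop("posterior variance is zero: statistic undefined", call. = FALSE)
  }
  se <- sqrt(s_post * (1 / n_case + 1 / n_control))
  t <- log2fc / se
  p <- if (is.infinite(d0)) {
    2 * stats::pnorm(-abs(t))
  } else {
    2 * stats::pt(-abs(t), df = d0 + d_g)
  }
  list(t = t, p = p)
}

#' Run moderated-t differential expression on one dataset
#'
#' Convenience wrapper: [prepare_matrix()], [fit_two_group()],
#' [estimate_prior()], [moderated_t()].
#'
#' @param dataset An [expression_dataset()].
#' @param transform Count transform passed to [prepare_matrix()].
#' @return A data frame of class `de_result` with columns `gene`, `log2fc`,
#'   `s_g_sq`, `t`, `p_value`; the prior is attached as attribute `params`.
#' @export
run_de <- function(dataset, transform = "log2p1") {
  prepped <- prepare_matrix(dataset, transform = transform)
  fit <- fit_two_group(prepped)
  d_g <- attr(fit, "d_g")
  params <- estimate_prior(fit$s_g_sq, d_g)
  mt <- moderated_t(fit$log2fc, fit$s_g_sq, d_g, params,
                    attr(fit, "n_case"), attr(fit, "n_control"))
  out <- data.frame(gene = fit$gene, log2fc = fit$log2fc,
                    s_g_sq = fit$s_g_sq, t = mt$t, p_value = mt$p,
                    stringsAsFactors = FALSE)
  attr(out, "params") <- params
  class(out) <- c("de_result", class(out))
  out
}

#' Call differentially expressed genes
#'
#' A gene is called iff `p_value < p_cut` and `|log2fc| > lfc_cut`, both
#' strict. Direction is the sign of the fold change.
#'
#' @param result A `de_result` data frame (needs `gene`, `log2fc`,
#'   `p_value`).
#' @param p_cut P-value cutoff (default 0.05).
#' @param lfc_cut Absolute log2 fold-change cutoff (default 1).
#' @return Data frame with columns `gene`, `direction` (`"up"`/`"down"`),
#'   `log2fc`, `p_value`.
#' @export
call_degs <- function(result, p_cut = 0.05, lfc_cut = 1.0) {
  keep <- result$p_value < p_cut & abs(result$log2fc) > lfc_cut
  out <- result[keep, c("gene", "log2fc", "p_value"), drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out[, c("gene", "direction", "log2fc", "p_value")]
}

#' Intersect DEG sets across datasets
#'
#' Genes called in every dataset (matched on normalized symbol), regardless
#' of direction agreement; the per-dataset directions are retained. Genes
#' commonly flip sign between heterogeneous platforms, so concordance is
#' deliberately not required.
#'
#' @param degs_by_dataset Named list (>= 2 entries) of DEG data frames from
#'   [call_degs()].
#' @return Data frame with column `gene` plus one direction column per
#'   dataset label.
#' @export
intersect_datasets <- function(degs_by_dataset) {
  if (length(degs_by_dataset) < 2L) {
    stop("at least 2 datasets are required for the intersection",
         call. = FALSE)
  }
  labels <- names(degs_by_dataset)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("datasets must be named", call. = FALSE)
  }
  sets <- lapply(degs_by_dataset, function(d) normalize_symbol(d$gene))
  common <- Reduce(intersect, sets)
  out <- data.frame(gene = common, stringsAsFactors = FALSE)
  for (lab in labels) {
    d <- degs_by_dataset[[lab]]
    out[[lab]] <- d$direction[match(common, normalize_symbol(d$gene))]
  }
  out
}

#' Build the PCD membership table
#'
#' One row per common DEG found in at least one PCD gene set; the
#' `categories` column lists every set containing the gene (labels
#' `DEARG`/`DENRG`/`DEPRG` for apoptosis/necroptosis/pyroptosis sets,
#' the set name otherwise), joined with `";"`. Genes in no PCD set are
#' dropped.
#'
#' @param common_degs Data frame from [intersect_datasets()].
#' @param pcd_sets List of [gene_set()] objects with distinct categories.
#' @return Data frame of class `membership_table` with attribute `datasets`.
#' @export
build_membership <- function(common_degs, pcd_sets) {
  cats <- vapply(pcd_sets, function(s) s$category, character(1L))
  if (anyDuplicated(cats)) {
    stop("PCD sets must have distinct categories", call. = FALSE)
  }
  labels <- category_label(cats)
  labels[cats == "other"] <- vapply(pcd_sets, function(s) s$name,
                                    character(1L))[cats == "other"]
  genes <- normalize_symbol(common_degs$gene)
  member <- vapply(pcd_sets, function(s) genes %in% s$symbols,
                   logical(length(genes)))
  member <- matrix(member, nrow = length(genes))
  keep <- rowSums(member) >= 1L
  out <- common_degs[keep, , drop = FALSE]
  out$categories <- apply(member[keep, , drop = FALSE], 1L, function(r) {
    paste(labels[r], collapse = ";")
  })
  rownames(out) <- NULL
  ds <- setdiff(names(common_degs), "gene")
  structure(out, datasets = ds,
            class = c("membership_table", class(out)))
}

category_label <- function(category) {
  map <- c(apoptosis = "DEARG", necroptosis = "DENRG", pyroptosis = "DEPRG")
  out <- unname(map[category])
  out[is.na(out)] <- category[is.na(out)]
  out
}

#' Venn counts over membership categories
#'
#' Counts genes per exact category combination. All non-empty combinations
#' of the observed category universe are reported (7 for the usual three
#' PCD categories); counts sum to the number of rows.
#'
#' @param table A `membership_table` (or any data frame with a
#'   `categories` column of `";"`-joined labels).
#' @return Named integer vector; names are sorted category labels joined
#'   with `"+"`. Attribute `per_category` carries the per-category totals.
#' @export
venn_counts <- function(table) {
  cats <- strsplit(table$categories, ";", fixed = TRUE)
  universe <- sort(unique(unlist(cats)))
  combos <- character()
  for (k in seq_along(universe)) {
    cmb <- utils::combn(universe, k, paste, collapse = "+")
    combos <- c(combos, cmb)
  }
  key <- vapply(cats, function(x) paste(sort(x), collapse = "+"),
                character(1L))
  counts <- stats::setNames(integer(length(combos)), combos)
  tab <- table(key)
  counts[names(tab)] <- as.integer(tab)
  per_cat <- vapply(universe, function(u) {
    sum(vapply(cats, function(x) u %in% x, logical(1L)))
  }, integer(1L))
  attr(counts, "per_category") <- per_cat
  counts
}

#' Read an expression TSV
#'
#' First column gene symbol, header row of sample IDs. Group assignments
#' come from a two-column TSV (sample ID, group in case/control).
#'
#' @param path Expression TSV path.
#' @param groups_path Group assignment TSV path.
#' @param platform `"intensity"` or `"count"`.
#' @return An [expression_dataset()].
#' @export
read_expression_tsv <- function(path, groups_path, platform = "intensity") {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  genes <- tab[[1L]]
  values <- as.matrix(tab[, -1L, drop = FALSE])
  groups <- utils::read.delim(groups_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  labels <- groups[[2L]][match(colnames(values), groups[[1L]])]
  if (anyNA(labels)) {
    stop("group file is missing assignments for some samples", call. = FALSE)
  }
  expression_dataset(values, genes, labels, platform = platform)
}

#' Write a DE result or membership table to TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
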