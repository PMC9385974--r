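make_ds <- function(case, ctrl, genes = NULL, platform = "intensity") {
  values <- cbind(ctrl, case)
  if (is.null(genes)) genes <- sprintf("Gene%03d", seq_len(nrow(values)))
  expression_dataset(values, genes,
                     rep(c("control", "case"),
                         c(ncol(ctrl), ncol(case))),
                     platform = platform)
}

test_that("prepare_matrix transforms counts and passes intensities through", {
  ds <- make_ds(matrix(c(7, 0), 1), matrix(c(3, 1), 1),
                platform = "count")
  out <- prepare_matrix(ds)
  expect_equal(unname(out$values[1, ]), c(2, 1, 3, 0))
  intens <- make_ds(matrix(rnorm(4), 1), matrix(rnorm(4), 1))
  expect_identical(prepare_matrix(intens)$values, intens$values)
  neg <- make_ds(matrix(-1, 1, 2), matrix(1, 1, 2), platform = "count")
  expect_error(prepare_matrix(neg), "negative")
})

test_that("fit_two_group computes fold change and pooled variance", {
  ds <- make_ds(matrix(2, 1, 3), matrix(1, 1, 3))
  fit <- fit_two_group(ds)
  expect_equal(fit$log2fc, 1)
  expect_equal(fit$s_g_sq, 0)
  expect_equal(attr(fit, "d_g"), 4L)
  # hand-computed pooled variance (2 + 0) / 2
  ds2 <- make_ds(matrix(c(3, 5), 1), matrix(c(1, 1), 1))
  fit2 <- fit_two_group(ds2)
  expect_equal(fit2$log2fc, 3)
  expect_equal(fit2$s_g_sq, 1)
  expect_equal(attr(fit2, "d_g"), 2L)
  sym <- make_ds(matrix(1:6, 2, 3), matrix(1:6, 2, 3))
  expect_equal(fit_two_group(sym)$log2fc, c(0, 0))
})

test_that("estimate_prior recovers the simulated hierarchical parameters", {
  d0_true <- 4; s0_true <- 0.05; d_g <- 4
  d0_hat <- s0_hat <- numeric(10)
  for (i in 1:10) {
    set.seed(100 + i)
    s2 <- s0_true * d0_true / rchisq(5000, df = d0_true) *
      rchisq(5000, df = d_g) / d_g
    prior <- estimate_prior(s2, d_g)
    d0_hat[i] <- prior$d0
    s0_hat[i] <- prior$s0_sq
  }
  expect_lt(abs(mean(d0_hat) - d0_true) / d0_true, 0.3)
  expect_lt(abs(mean(s0_hat) - s0_true) / s0_true, 0.2)
})

test_that("estimate_prior edge cases: equal variances, tiny input, zeros", {
  prior <- estimate_prior(rep(0.3, 100), d_g = 4)
  expect_identical(prior$d0, Inf)
  # infinite-d0 branch: s0^2 = exp(mean(e)) with the digamma offset
  expect_equal(prior$s0_sq, exp(log(0.3) - digamma(2) + log(2)),
               tolerance = 1e-12)
  expect_error(estimate_prior(rep(0.5, 9), 4), "at least 10")
  expect_error(estimate_prior(rep(0, 20), 4), "degenerate")
  # zeros floored to min positive, not fatal
  s2 <- c(rep(0, 5), runif(20, 0.1, 1))
  expect_silent(estimate_prior(s2, 4))
})

test_that("moderated_t limit cases match the pooled t and the normal", {
  lfc <- c(1.2, -0.4); s2 <- c(0.5, 0.2); d_g <- 4
  near0 <- structure(list(d0 = 1e-9, s0_sq = 1), class = "moderated_test_params")
  mt <- moderated_t(lfc, s2, d_g, near0, 3, 3)
  t_ref <- lfc / sqrt(s2 * (1 / 3 + 1 / 3))
  expect_equal(mt$t, t_ref, tolerance = 1e-6)
  inf <- structure(list(d0 = Inf, s0_sq = 0.3), class = "moderated_test_params")
  mtinf <- moderated_t(lfc, s2, d_g, inf, 3, 3)
  expect_equal(mtinf$t, lfc / sqrt(0.3 * (2 / 3)))
  expect_equal(mtinf$p, 2 * pnorm(-abs(mtinf$t)))
})

test_that("moderated pipeline agrees with the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(7)
  sim <- simulate_expression(simulation_config(n_genes = 400, seed = 7))
  de <- run_de(sim$dataset)
  design <- cbind(1, sim$dataset$group_labels == "case")
  fit <- limma::eBayes(limma::lmFit(sim$dataset$values, design))
  expect_equal(de$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-8)
  expect_equal(attr(de, "params")$d0, fit$df.prior, tolerance = 1e-4)
  expect_equal(attr(de, "params")$s0_sq, fit$s2.prior, tolerance = 1e-6)
  expect_equal(de$t, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(de$p_value, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("null p-values are calibrated and approximately uniform", {
  frac <- numeric(10)
  ks <- numeric(10)
  for (i in 1:10) {
    sim <- simulate_expression(
      simulation_config(n_genes = 5000, de_fraction = 0, seed = 500 + i))
    de <- run_de(sim$dataset)
    frac[i] <- mean(de$p_value < 0.05)
    ecdf_p <- ecdf(de$p_value)
    grid <- seq(0, 1, length.out = 512)
    ks[i] <- max(abs(ecdf_p(grid) - grid))
  }
  expect_lt(abs(mean(frac) - 0.05), 0.01)
  expect_lt(mean(ks), 0.05)
})

test_that("call_degs uses strict cutoffs and is monotone in both", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(1.5, 1.0, -2.0, 3.0),
                    p_value = c(0.01, 0.001, 0.049, 0.05))
  out <- call_degs(res)
  expect_setequal(out$gene, c("a", "c"))
  expect_identical(out$direction[out$gene == "a"], "up")
  expect_identical(out$direction[out$gene == "c"], "down")
  # boundary values are excluded (strict < and >)
  expect_false("b" %in% out$gene)
  expect_false("d" %in% out$gene)
  set.seed(11)
  res2 <- data.frame(gene = sprintf("g%03d", 1:200),
                     log2fc = rnorm(200, sd = 2),
                     p_value = runif(200))
  strict <- call_degs(res2, 0.05, 1)$gene
  relax_p <- call_degs(res2, 0.2, 1)$gene
  relax_l <- call_degs(res2, 0.05, 0.5)$gene
  expect_true(all(strict %in% relax_p))
  expect_true(all(strict %in% relax_l))
})

test_that("intersect_datasets keeps discordant directions and matches brute force", {
  A <- data.frame(gene = c("Genex", "Geney"), direction = c("up", "down"))
  B <- data.frame(gene = c("Geney", "Genez"), direction = c("up", "up"))
  out <- intersect_datasets(list(A = A, B = B))
  expect_identical(out$gene, "Geney")
  expect_identical(out$A, "down")
  expect_identical(out$B, "up")
  disjoint <- intersect_datasets(list(A = A, B = data.frame(
    gene = "Geneq", direction = "up")))
  expect_identical(nrow(disjoint), 0L)
  same <- intersect_datasets(list(A = A, B = A))
  expect_setequal(same$gene, A$gene)
  # brute-force oracle over k random datasets
  set.seed(3)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    dfs <- lapply(seq_len(k), function(j) {
      g <- sample(sprintf("g%02d", 1:20), sample(5:15, 1))
      data.frame(gene = g,
                 direction = sample(c("up", "down"), length(g), TRUE))
    })
    names(dfs) <- paste0("d", seq_len(k))
    expected <- Reduce(intersect, lapply(dfs, function(d)
      normalize_symbol(d$gene)))
    expect_setequal(intersect_datasets(dfs)$gene, expected)
  }
  expect_error(intersect_datasets(list(A = A)), "at least 2")
})

test_that("build_membership and venn_counts reconstruct the published table", {
  fix <- published_inputs()
  mt <- build_membership(fix$common_degs, fix$pcd_sets)
  expect_identical(nrow(mt), 15L)
  per_cat <- attr(venn_counts(mt), "per_category")
  expect_identical(unname(per_cat[c("DEARG", "DENRG", "DEPRG")]),
                   c(6L, 9L, 10L))
  triple <- mt$gene[mt$categories == "DEARG;DENRG;DEPRG"]
  expect_setequal(triple, c("Bax", "Pycard", "Zbp1"))
  # a common DEG in no PCD list is dropped
  degs <- rbind(fix$common_degs,
                data.frame(gene = "Notapcdgene", GSE58720 = "up",
                           GSE131193 = "down"))
  expect_identical(nrow(build_membership(degs, fix$pcd_sets)), 15L)
})

test_that("venn_counts partitions the table and handles empties", {
  fix <- published_membership()
  v <- venn_counts(fix)
  expect_identical(sum(v), 15L)
  expect_length(v, 7L)
  expect_identical(unname(v["DEARG+DENRG+DEPRG"]), 3L)
  only_nrg <- fix$gene[fix$categories == "DENRG"]
  expect_setequal(only_nrg, c("Cxcl1", "Ripk3", "Mlkl"))
  empty <- fix[0, ]
  expect_identical(sum(venn_counts(empty)), 0L)
})

test_that("expression TSV and group file round-trip through the reader", {
  sim <- simulate_expression(simulation_config(n_genes = 50, seed = 2))
  ep <- withr::local_tempfile(fileext = ".tsv")
  gp <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(sim$dataset, ep, gp)
  back <- read_expression_tsv(ep, gp, platform = "intensity")
  expect_equal(back$values, sim$dataset$values, tolerance = 1e-12)
  expect_identical(back$group_labels, sim$dataset$group_labels)
})
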