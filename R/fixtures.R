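# Worked-example fixtures: the published 15-gene PCD membership table for
# the mouse MCAO/R 24 h reperfusion contrast (two GEO series) and the
# published hub regulatory axes, encoded in source so tests and examples
# need no external files.

#' Published PCD membership table fixture
#'
#' The 15 differentially expressed PCD-related genes with their direction
#' in each of the two expression series (GSE58720 microarray, GSE131193
#' RNA-seq) and their category memberships (DEARG = apoptosis, DENRG =
#' necroptosis, DEPRG = pyroptosis). Every gene is up in GSE58720 and down
#' in GSE131193 except Mapt, which shows the opposite pattern.
#'
#' @return A `membership_table` data frame with columns `gene`,
#'   `GSE58720`, `GSE131193`, `categories`.
#' @export
published_membership <- function() {
  rows <- list(
    list("Bax",       "up",   "down", "DEARG;DENRG;DEPRG"),
    list("Pycard",    "up",   "down", "DEARG;DENRG;DEPRG"),
    list("Zbp1",      "up",   "down", "DEARG;DENRG;DEPRG"),
    list("Tnfrsf10b", "up",   "down", "DEARG;DENRG"),
    list("Il1b",      "up",   "down", "DENRG;DEPRG"),
    list("Tnf",       "up",   "down", "DENRG;DEPRG"),
    list("Cd14",      "up",   "down", "DEARG;DEPRG"),
    list("Mapt",      "down", "up",   "DEARG"),
    list("Cxcl1",     "up",   "down", "DENRG"),
    list("Ripk3",     "up",   "down", "DENRG"),
    list("Mlkl",      "up",   "down", "DENRG"),
    list("Mefv",      "up",   "down", "DEPRG"),
    list("Il1rn",     "up",   "down", "DEPRG"),
    list("Anxa2",     "up",   "down", "DEPRG"),
    list("Ccr5",      "up",   "down", "DEPRG"))
  out <- data.frame(
    gene = vapply(rows, `[[`, character(1L), 1L),
    GSE58720 = vapply(rows, `[[`, character(1L), 2L),
    GSE131193 = vapply(rows, `[[`, character(1L), 3L),
    categories = vapply(rows, `[[`, character(1L), 4L),
    stringsAsFactors = FALSE)
  structure(out, datasets = c("GSE58720", "GSE131193"),
            class = c("membership_table", "data.frame"))
}

#' Published hub regulatory axes fixture
#'
#' The eight lncRNA/miRNA/mRNA axes formed by the consensus hub nodes of
#' the three category networks: four apoptosis axes converging on Mapt,
#' two necroptosis and two pyroptosis axes converging on Tnf. The
#' Malat1/miR-181a-5p/Tnf axis occurs in both the necroptosis and the
#' pyroptosis network, so the deduplicated total is seven.
#'
#' @return Data frame with columns `network`, `lncrna`, `mirna`, `mrna`.
#' @export
published_axes <- function() {
  data.frame(
    network = c(rep("apoptosis", 4L), rep("necroptosis", 2L),
                rep("pyroptosis", 2L)),
    lncrna = c("Malat1", "Malat1", "Neat1", "Neat1",
               "Malat1", "Neat1",
               "Malat1", "Malat1"),
    mirna = c("miR-181a-5p", "miR-181b-5p", "miR-181a-5p", "miR-181b-5p",
              "miR-181a-5p", "miR-181a-5p",
              "miR-181a-5p", "miR-181c-5p"),
    mrna = c("Mapt", "Mapt", "Mapt", "Mapt",
             "Tnf", "Tnf",
             "Tnf", "Tnf"),
    stringsAsFactors = FALSE)
}

#' Reconstruct the common-DEG table behind the membership fixture
#'
#' Splits the fixture back into its ingredients: the cross-dataset common
#' DEG table (gene plus per-dataset direction) and the three PCD gene
#' sets, so [build_membership()] and [venn_counts()] can be exercised on
#' published data.
#'
#' @return List with `common_degs` (data frame) and `pcd_sets` (list of
#'   three [gene_set()]s).
#' @export
published_inputs <- function() {
  fix <- published_membership()
  cats <- strsplit(fix$categories, ";", fixed = TRUE)
  label_to_cat <- c(DEARG = "apoptosis", DENRG = "necroptosis",
                    DEPRG = "pyroptosis")
  pcd_sets <- lapply(names(label_to_cat), function(lab) {
    members <- fix$gene[vapply(cats, function(x) lab %in% x, logical(1L))]
    gene_set(label_to_cat[[lab]], members,
             category = label_to_cat[[lab]], provenance = "published")
  })
  names(pcd_sets) <- unname(label_to_cat)
  list(common_degs = fix[, c("gene", "GSE58720", "GSE131193")],
       pcd_sets = pcd_sets)
}
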