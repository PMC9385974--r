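#' Normalize a gene symbol
#'
#' Trims whitespace and applies the mouse gene-symbol casing convention
#' (first character upper case, remainder lower case). Identifiers that
#' contain a `"miR-"` fragment or start with `"lncRNA"` are non-coding RNA
#' names, not gene symbols, and are returned trimmed but otherwise
#' unchanged. All downstream symbol comparison is performed on the
#' normalized form.
#'
#' @param raw Character vector of raw symbols.
#' @return Character vector of normalized symbols.
#' @examples
#' normalize_symbol(c("BAX", " Pycard ", "miR-181a-5p"))
#' @export
normalize_symbol <- function(raw) {
  if (length(raw) == 0L) return(character())
  if (!is.character(raw)) raw <- as.character(raw)
  x <- trimws(raw)
  if (anyNA(x) || any(!nzchar(x))) {
    stop("invalid gene symbol: empty or NA after trimming whitespace",
         call. = FALSE)
  }
  exempt <- grepl("miR-", x, fixed = TRUE) | grepl("^lncRNA", x)
  fix <- !exempt
  x[fix] <- paste0(toupper(substr(x[fix], 1L, 1L)),
                   tolower(substring(x[fix], 2L)))
  x
}

#' Construct a gene set
#'
#' A `gene_set` is a named, ordered, duplicate-free collection of normalized
#' gene symbols belonging to exactly one programmed-cell-death category.
#' Original spellings are retained for reporting; membership operations use
#' the normalized form.
#'
#' @param name Set name.
#' @param symbols Character vector of raw symbols (normalized and
#'   deduplicated in first-seen order).
#' @param category One of `"apoptosis"`, `"necroptosis"`, `"pyroptosis"`,
#'   `"other"`.
#' @param provenance Character vector of provenance labels
#'   (e.g. `"reactome"`, `"literature"`).
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, symbols, category = "other",
                     provenance = character()) {
  category <- match.arg(category,
                        c("apoptosis", "necroptosis", "pyroptosis", "other"))
  norm <- normalize_symbol(symbols)
  keep <- !duplicated(norm)
  structure(
    list(name = as.character(name)[1L],
         category = category,
         provenance = unique(as.character(provenance)),
         symbols = norm[keep],
         original = as.character(symbols)[keep]),
    class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s' (%s): %d symbols", x$name, x$category,
              length(x$symbols)))
  if (length(x$provenance)) {
    cat(sprintf(" [%s]", paste(x$provenance, collapse = ", ")))
  }
  cat("\n")
  show <- utils::head(x$symbols, 8L)
  cat("  ", paste(show, collapse = ", "),
      if (length(x$symbols) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$symbols)

#' Read a gene list from disk
#'
#' Accepts either plain text (one symbol per line, `#` comments and blank
#' lines ignored) or GMT rows (tab separated: set name, description, then
#' member symbols). A line containing at least two tabs is treated as a GMT
#' row; its member fields are used. Symbols are normalized and deduplicated
#' in first-seen order.
#'
#' @param path File path.
#' @param category Category passed to [gene_set()].
#' @param provenance Provenance label(s).
#' @param name Set name; defaults to the file base name.
#' @return A [gene_set()].
#' @export
read_gene_list <- function(path, category = "other",
                           provenance = character(), name = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read gene list: no such file '%s'", path),
         call. = FALSE)
  }
  if (is.null(name)) {
    name <- tools::file_path_sans_ext(basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  symbols <- character()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(fields) >= 3L) {
      # GMT row: name, description, members...
      symbols <- c(symbols, fields[-(1:2)])
    } else {
      symbols <- c(symbols, fields[1L])
    }
  }
  symbols <- symbols[nzchar(trimws(symbols))]
  if (length(symbols) == 0L) {
    stop(sprintf("no gene symbols parsed from '%s'", path), call. = FALSE)
  }
  gene_set(name, symbols, category = category, provenance = provenance)
}

#' Merge gene sets of one category
#'
#' Set-union merge: symbols are the deduplicated union in first-seen order
#' across the input sets, provenance labels are pooled. All inputs must
#' share a single category. Merging is commutative, associative and
#' idempotent up to symbol order; cardinality follows inclusion-exclusion.
#'
#' @param sets List of [gene_set()] objects.
#' @param name Name for the merged set.
#' @return A [gene_set()].
#' @export
merge_gene_sets <- function(sets, name) {
  stopifnot(length(sets) >= 1L)
  if (inherits(sets, "gene_set")) sets <- list(sets)
  cats <- unique(vapply(sets, function(s) s$category, character(1L)))
  if (length(cats) != 1L) {
    stop(sprintf("category mismatch in merge: {%s}",
                 paste(cats, collapse = ", ")), call. = FALSE)
  }
  symbols <- unlist(lapply(sets, function(s) s$symbols), use.names = FALSE)
  originals <- unlist(lapply(sets, function(s) s$original), use.names = FALSE)
  keep <- !duplicated(symbols)
  prov <- unique(unlist(lapply(sets, function(s) s$provenance),
                        use.names = FALSE))
  out <- gene_set(name, symbols[keep], category = cats, provenance = prov)
  out$original <- originals[keep]
  out
}

#' Read a GMT file
#'
#' @param path GMT file path (tab separated: name, description, members).
#' @param category Category applied to every set.
#' @param provenance Provenance label(s) applied to every set.
#' @return A list of [gene_set()] objects, one per row.
#' @export
read_gmt <- function(path, category = "other", provenance = character()) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read GMT: no such file '%s'", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(ln) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("malformed GMT row: fewer than 3 tab-separated fields",
           call. = FALSE)
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(trimws(members))]
    gs <- gene_set(fields[1L], members, category = category,
                   provenance = provenance)
    gs$description <- fields[2L]
    gs
  })
  names(out) <- vapply(out, function(s) s$name, character(1L))
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets A [gene_set()] or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    desc <- if (!is.null(s$description)) s$description else s$category
    paste(c(s$name, desc, s$symbols), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
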