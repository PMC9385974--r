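#' Upper tail of the hypergeometric distribution
#'
#' Probability of observing `k` or more annotated genes in a query of size
#' `n` drawn without replacement from a universe of `N` genes of which `K`
#' carry the annotation:
#' `p = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`.
#' Terms are evaluated in log space and combined with log-sum-exp.
#'
#' @param k Observed overlap (0 <= k <= min(K, n)).
#' @param K Term size within the universe.
#' @param n Query size.
#' @param N Universe size.
#' @return The tail probability in (0, 1].
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L,
            length(N) == 1L)
  if (K > N || n > N || k < 0 || k > min(K, n)) {
    stop("inconsistent hypergeometric counts", call. = FALSE)
  }
  if (k == 0) return(1)
  i <- k:min(K, n)
  logterms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logterms)
  min(exp(m + log(sum(exp(logterms - m)))), 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, clipped at 1, returned in the
#' original input order. Idempotent and monotone along the sorted order.
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @return Adjusted values in input order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Construct an annotation collection
#'
#' @param terms List of terms, each a list with `id`, `name`, and `genes`
#'   (raw symbols, normalized on construction).
#' @param universe Optional background gene universe; defaults to the union
#'   of all term members. A measured-gene universe can be supplied instead.
#' @return An object of class `annotation_collection`.
#' @export
annotation_collection <- function(terms, universe = NULL) {
  stopifnot(length(terms) >= 1L)
  terms <- lapply(terms, function(tm) {
    tm$genes <- unique(normalize_symbol(tm$genes))
    tm
  })
  if (is.null(universe)) {
    universe <- unique(unlist(lapply(terms, `[[`, "genes"), use.names = FALSE))
  } else {
    universe <- unique(normalize_symbol(universe))
  }
  if (length(universe) == 0L) stop("empty annotation universe", call. = FALSE)
  terms <- lapply(terms, function(tm) {
    tm$genes <- intersect(tm$genes, universe)
    tm
  })
  nonempty <- vapply(terms, function(tm) length(tm$genes) > 0L, logical(1L))
  structure(list(terms = terms[nonempty], universe = universe),
            class = "annotation_collection")
}

#' Read an annotation collection from GMT
#'
#' @param path GMT file path.
#' @param universe Optional background universe (see
#'   [annotation_collection()]).
#' @return An `annotation_collection`.
#' @export
read_annotation_gmt <- function(path, universe = NULL) {
  sets <- read_gmt(path)
  terms <- lapply(sets, function(s) {
    list(id = s$name,
         name = if (!is.null(s$description)) s$description else s$name,
         genes = s$symbols)
  })
  annotation_collection(unname(terms), universe = universe)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each term of the collection for over-representation in the query
#' set. Rows with overlap below `min_overlap` are dropped; the remaining
#' p-values are BH-adjusted and sorted ascending with ties broken by term
#' id.
#'
#' @param query A [gene_set()] or character vector of symbols.
#' @param collection An [annotation_collection()].
#' @param min_overlap Minimum overlap to report a term (default 2).
#' @return Data frame with columns `term_id`, `term_name`, `k`, `K`, `n`,
#'   `p_value`, `fdr`, `genes`. Empty (with a warning) if the query does
#'   not intersect the universe.
#' @export
run_ora <- function(query, collection, min_overlap = 2L) {
  stopifnot(inherits(collection, "annotation_collection"))
  symbols <- if (inherits(query, "gene_set")) query$symbols
             else unique(normalize_symbol(query))
  eff <- intersect(symbols, collection$universe)
  empty <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      p_value = numeric(), fdr = numeric(),
                      genes = character(), stringsAsFactors = FALSE)
  if (length(eff) == 0L) {
    warning("query does not intersect the annotation universe")
    return(empty)
  }
  N <- length(collection$universe)
  n <- length(eff)
  rows <- lapply(collection$terms, function(tm) {
    hit <- intersect(eff, tm$genes)
    k <- length(hit)
    if (k < min_overlap) return(NULL)
    data.frame(term_id = tm$id, term_name = tm$name, k = k,
               K = length(tm$genes), n = n,
               p_value = hypergeometric_tail(k, length(tm$genes), n, N),
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  out[, c("term_id", "term_name", "k", "K", "n", "p_value", "fdr", "genes")]
}
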