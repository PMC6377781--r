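#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing at
#' least k pathway genes in a query of size n from a universe of N genes
#' of which K belong to the pathway. This is the one-sided enrichment
#' p-value. Computed via \code{stats::phyper}, which works in log space
#' internally.
#'
#' @param k observed overlap (0 <= k <= min(K, n)).
#' @param N universe size.
#' @param K pathway size within the universe.
#' @param n query size within the universe.
#' @return Probability in (0, 1\].
#' @examples
#' hypergeom_upper_tail(0, 50, 10, 5)          # 1
#' hypergeom_upper_tail(5, 10, 5, 5)           # 1 / choose(10, 5)
#' @export
hypergeom_upper_tail <- function(k, N, K, n) {
  stopifnot(length(k) == 1L, length(N) == 1L, length(K) == 1L,
            length(n) == 1L)
  if (K < 0 || K > N || n < 0 || n > N || k < 0 || k > min(K, n)) {
    stopf("require 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(K, n)")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Adjust p-values for multiple testing
#'
#' @param ps numeric vector of p-values in (0, 1\].
#' @param method \code{"BH"} (Benjamini-Hochberg step-up, default),
#'   \code{"bonferroni"}, or \code{"none"}.
#' @return Adjusted values, input order preserved, clipped at 1.
#' @export
adjust_pvalues <- function(ps, method = c("BH", "bonferroni", "none")) {
  method <- match.arg(method)
  if (length(ps) && (any(ps <= 0) || any(ps > 1))) {
    stopf("p-values must lie in (0, 1]")
  }
  if (method == "none") return(ps)
  stats::p.adjust(ps, method = method)
}

#' Hypergeometric pathway enrichment of a gene group
#'
#' Tests each pathway for over-representation in the query set with the
#' one-sided hypergeometric test. Identifiers are matched
#' case-insensitively. The universe defaults to the measured genes
#' intersected with the database's gene universe; pathways with no overlap
#' (k = 0) are reported as untested rather than assigned a p-value.
#'
#' @param query_genes character vector of gene identifiers.
#' @param db list of \code{fh_pathway} (or merged pathway) objects.
#' @param universe \code{"measured"}, \code{"db_union"}, or
#'   \code{"custom"}.
#' @param measured_genes gene identifiers measured in the experiment
#'   (required for \code{universe = "measured"}).
#' @param custom_universe explicit universe (for \code{"custom"}).
#' @param correction multiple-testing method passed to
#'   \code{\link{adjust_pvalues}}.
#' @return A data frame of class \code{fh_enrichment}, sorted by adjusted
#'   p, then p, then pathway id, with columns pathway_id, name,
#'   members_hit, k, K, n, N, p, q. Attributes: \code{universe_size},
#'   \code{universe_choice}, \code{untested} (pathway ids with k = 0),
#'   \code{status} (\code{"ok"} or \code{"empty-intersection"}).
#' @export
enrich <- function(query_genes, db,
                   universe = c("measured", "db_union", "custom"),
                   measured_genes = NULL, custom_universe = NULL,
                   correction = "BH") {
  universe <- match.arg(universe)
  if (length(query_genes) == 0L) stopf("query gene set is empty")
  db_union <- unique(tolower(unlist(lapply(db, `[[`, "genes"))))
  uni <- switch(universe,
    db_union = db_union,
    measured = {
      if (is.null(measured_genes)) {
        stopf("universe='measured' requires measured_genes")
      }
      intersect(unique(tolower(measured_genes)), db_union)
    },
    custom = {
      if (is.null(custom_universe)) {
        stopf("universe='custom' requires custom_universe")
      }
      unique(tolower(custom_universe))
    })
  N <- length(uni)
  query <- intersect(unique(tolower(query_genes)), uni)
  n <- length(query)
  empty_cols <- data.frame(pathway_id = character(0), name = character(0),
                           members_hit = character(0), k = integer(0),
                           K = integer(0), n = integer(0), N = integer(0),
                           p = numeric(0), q = numeric(0),
                           stringsAsFactors = FALSE)
  if (n == 0L) {
    warning("query has no genes in the universe; empty enrichment result")
    return(structure(empty_cols, class = c("fh_enrichment", "data.frame"),
                     universe_size = N, universe_choice = universe,
                     untested = vapply(db, `[[`, character(1),
                                       "pathway_id"),
                     status = "empty-intersection"))
  }
  rows <- lapply(db, function(p) {
    genes <- intersect(unique(tolower(p$genes)), uni)
    K <- length(genes)
    hit <- intersect(query, genes)
    k <- length(hit)
    list(pathway_id = p$pathway_id, name = p$name, k = k, K = K,
         hit = sort(hit))
  })
  tested <- vapply(rows, function(r) r$k >= 1L, logical(1))
  untested <- vapply(rows[!tested], `[[`, character(1), "pathway_id")
  rows <- rows[tested]
  res <- data.frame(
    pathway_id = vapply(rows, `[[`, character(1), "pathway_id"),
    name = vapply(rows, `[[`, character(1), "name"),
    members_hit = vapply(rows, function(r) paste(r$hit, collapse = ";"),
                         character(1)),
    k = vapply(rows, `[[`, integer(1), "k"),
    K = vapply(rows, `[[`, integer(1), "K"),
    n = n, N = N, stringsAsFactors = FALSE)
  if (nrow(res)) {
    res$p <- vapply(seq_len(nrow(res)), function(i) {
      hypergeom_upper_tail(res$k[i], N, res$K[i], n)
    }, numeric(1))
    res$q <- adjust_pvalues(res$p, correction)
    res <- res[order(res$q, res$p, res$pathway_id, method = "radix"), ]
    rownames(res) <- NULL
  } else {
    res <- empty_cols
  }
  structure(res, class = c("fh_enrichment", "data.frame"),
            universe_size = N, universe_choice = universe,
            untested = untested, status = "ok")
}

#' @export
print.fh_enrichment <- function(x, ...) {
  cat(sprintf("Enrichment: %d pathway(s) tested (universe %s, N=%d; %d untested with k=0)\n",
              nrow(x), attr(x, "universe_choice"),
              attr(x, "universe_size"), length(attr(x, "untested"))))
  NextMethod()
}
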