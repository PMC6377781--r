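#' Remove super-large and tiny pathways
#'
#' Very large pathways (thousands of genes, e.g. generic cancer pathways)
#' bias enrichment and are removed before merging, as are sets too small
#' to test meaningfully.
#'
#' @param db list of \code{fh_pathway} objects.
#' @param max_size,min_size inclusive bounds on gene-set size; pathways
#'   strictly outside are removed.
#' @return The retained pathways, with a removal report (id, size, reason)
#'   in \code{attr(, "removed")}.
#' @export
trim_pathways <- function(db, max_size = 1000L, min_size = 3L) {
  if (max_size <= min_size || min_size < 1L) {
    stopf("need max_size > min_size >= 1")
  }
  sizes <- vapply(db, function(p) length(p$genes), integer(1))
  too_big <- sizes > max_size
  too_small <- sizes < min_size
  keep <- !(too_big | too_small)
  removed <- data.frame(
    pathway_id = vapply(db[!keep], `[[`, character(1), "pathway_id"),
    size = sizes[!keep],
    reason = ifelse(too_big[!keep], "above max_size", "below min_size"),
    stringsAsFactors = FALSE)
  out <- db[keep]
  class(out) <- class(db)
  attr(out, "removed") <- removed
  out
}

#' Overlap rate between two gene sets
#'
#' Defined as min(|A|, |B|) / |A union B|. It equals 1 if and only if the
#' two sets are identical. Note this is not the Jaccard index: disjoint
#' equal-size sets score 0.5 rather than 0, because the smaller set's size
#' (not the intersection) sits in the numerator.
#'
#' @param a,b character vectors (treated as sets; non-empty).
#' @return A value in (0, 1\].
#' @export
overlap_rate <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) {
    stopf("overlap_rate requires non-empty sets")
  }
  inter <- length(intersect(a, b))
  min(length(a), length(b)) / (length(a) + length(b) - inter)
}

#' Pairwise overlap-rate matrix of a pathway database
#'
#' @param db list of \code{fh_pathway} objects.
#' @return Symmetric matrix with unit diagonal, dimnames = pathway ids.
#' @export
overlap_matrix <- function(db) {
  n <- length(db)
  ids <- vapply(db, `[[`, character(1), "pathway_id")
  m <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        m[i, j] <- m[j, i] <- overlap_rate(db[[i]]$genes, db[[j]]$genes)
      }
    }
  }
  dimnames(m) <- list(ids, ids)
  m
}

#' Merge near-duplicate pathways by overlap-rate clustering
#'
#' Pathways curated from several resources often duplicate each other.
#' Using d(i, j) = 1 - overlap_rate(i, j) as the distance, the database is
#' clustered with average linkage and every cluster fully merged below the
#' cut height becomes one merged pathway (gene union, names joined). The
#' default cut of 0.15 merges pairs with roughly 85% overlap or more.
#' Singletons pass through as single-member merged pathways.
#'
#' @param db list of \code{fh_pathway} objects (trim first).
#' @param cut non-negative distance cutoff.
#' @return List of merged pathways (class \code{fh_pathway_db}), ordered
#'   by smallest member id; each element carries \code{member_ids}, and
#'   the whole list a merge report in \code{attr(, "report")}.
#' @export
cluster_and_merge <- function(db, cut = 0.15) {
  if (cut < 0) stopf("cut must be non-negative")
  n <- length(db)
  if (n == 0L) {
    return(structure(list(), class = "fh_pathway_db",
                     report = data.frame(merged_id = character(0),
                                         member_ids = character(0),
                                         n_members = integer(0),
                                         n_genes = integer(0))))
  }
  ids <- vapply(db, `[[`, character(1), "pathway_id")
  cl <- if (n == 1L) 1L else {
    d <- stats::as.dist(1 - overlap_matrix(db))
    hc <- stats::hclust(d, method = "average")
    stats::cutree(hc, h = cut)
  }
  merged <- lapply(split(seq_len(n), cl), function(i) {
    member_ids <- sort(ids[i])
    p <- pathway(
      id = paste0("MRG_", fnv1a_hash(paste(member_ids, collapse = "|"))),
      name = paste(vapply(db[i], `[[`, character(1), "name")[order(ids[i])],
                   collapse = " | "),
      source = "merged",
      genes = sort(unique(unlist(lapply(db[i], `[[`, "genes")))))
    p$member_ids <- member_ids
    p
  })
  merged <- merged[order(vapply(merged, function(p) p$member_ids[1],
                                character(1)))]
  names(merged) <- NULL
  report <- data.frame(
    merged_id = vapply(merged, `[[`, character(1), "pathway_id"),
    member_ids = vapply(merged, function(p) paste(p$member_ids,
                                                  collapse = ";"),
                        character(1)),
    n_members = vapply(merged, function(p) length(p$member_ids),
                       integer(1)),
    n_genes = vapply(merged, function(p) length(p$genes), integer(1)),
    stringsAsFactors = FALSE)
  structure(merged, class = "fh_pathway_db", report = report)
}
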