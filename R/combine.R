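#' Consolidate time points by averaging
#'
#' Cohorts with different time grids can be compared after consolidation:
#' contiguous time points are collapsed by taking the arithmetic mean of
#' their log2 fold changes. Consolidated p-values default to the maximum of
#' the members (conservative); Fisher's combination is available.
#'
#' @param table an \code{fh_cohort}.
#' @param grouping ordered list of integer vectors; together they must
#'   cover 1..T exactly once, in order.
#' @param p_combine \code{"max"} or \code{"fisher"}.
#' @return A new \code{fh_cohort} with one time point per group.
#' @export
consolidate_timepoints <- function(table, grouping,
                                   p_combine = c("max", "fisher")) {
  p_combine <- match.arg(p_combine)
  stopifnot(inherits(table, "fh_cohort"))
  T <- length(table$timepoints)
  idx <- unlist(grouping)
  if (length(idx) != T || anyDuplicated(idx) || !setequal(idx, seq_len(T))) {
    stopf("grouping must cover time points 1..%d exactly once", T)
  }
  if (is.unsorted(idx)) stopf("grouping must be order-preserving")
  fc <- vapply(grouping, function(g) {
    rowMeans(table$fc[, g, drop = FALSE])
  }, numeric(nrow(table$fc)))
  if (nrow(table$fc) == 1L) fc <- matrix(fc, nrow = 1L)
  pv <- NULL
  if (!is.null(table$pvalue)) {
    pv <- vapply(grouping, function(g) {
      block <- table$pvalue[, g, drop = FALSE]
      if (p_combine == "max") {
        apply(block, 1, max)
      } else {
        apply(block, 1, function(p) {
          stat <- -2 * sum(log(pmax(p, .Machine$double.xmin)))
          stats::pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
        })
      }
    }, numeric(nrow(table$pvalue)))
    if (nrow(table$pvalue) == 1L) pv <- matrix(pv, nrow = 1L)
  }
  tp <- vapply(grouping, function(g) {
    paste(table$timepoints[g], collapse = "+")
  }, character(1))
  cohort_table(table$cohort_id, tp, fc, table$gene_id, pvalue = pv,
               entrez = table$entrez, symbol = table$symbol,
               fc_scale = "log2", flagged = table$flagged)
}

#' Combine cohorts into a pooled set
#'
#' Pools the (cohort, gene) entries of two or more cohorts sharing the same
#' number of time points, each entry carrying its pattern key. A gene
#' measured in several cohorts contributes one entry per cohort, so pooled
#' group counts are per-cohort sub-pattern counts; use
#' \code{\link{synchronized_genes}} for the strict per-gene view.
#'
#' @param tables list of two or more \code{fh_cohort}s with equal T
#'   (consolidate first otherwise).
#' @param rule a \code{\link{disc_rule}}.
#' @return An \code{fh_combined} object.
#' @export
combine_cohorts <- function(tables, rule = disc_rule()) {
  if (inherits(tables, "fh_cohort")) tables <- list(tables)
  if (length(tables) < 2L) {
    stopf("combine needs at least 2 cohorts; use the master-panel view for one")
  }
  Ts <- vapply(tables, function(t) length(t$timepoints), integer(1))
  if (length(unique(Ts)) != 1L) {
    stopf("cohorts have unequal time-point counts (%s); consolidate_timepoints first",
          paste(Ts, collapse = ", "))
  }
  ids <- vapply(tables, `[[`, character(1), "cohort_id")
  if (anyDuplicated(ids)) stopf("duplicate cohort ids: %s",
                                paste(ids[duplicated(ids)], collapse = ", "))
  entries_all <- do.call(rbind, lapply(tables, function(tab) {
    keys <- pattern_keys(tab, rule)
    data.frame(cohort_id = tab$cohort_id, gene_id = names(keys),
               key = unname(keys), stringsAsFactors = FALSE)
  }))
  rownames(entries_all) <- NULL
  nk <- null_key(Ts[1])
  structure(list(cohorts = stats::setNames(tables, ids),
                 entries = entries_all[entries_all$key != nk, , drop = FALSE],
                 entries_all = entries_all,
                 T = Ts[1], rule = rule),
            class = "fh_combined")
}

#' @export
print.fh_combined <- function(x, ...) {
  cat(sprintf("Combined set: %d cohorts (%s), T=%d, %d non-null entries\n",
              length(x$cohorts), paste(names(x$cohorts), collapse = ", "),
              x$T, nrow(x$entries)))
  invisible(x)
}

#' @export
group_by_pattern.fh_combined <- function(table, rule = NULL,
                                         drop_null = TRUE) {
  entries <- if (drop_null) table$entries else table$entries_all
  group_entries(entries, T = table$T, rule = rule %||% table$rule,
                drop_null = drop_null)
}

#' Genes with identical patterns across cohorts
#'
#' A gene is synchronized when it carries the same pattern key in every
#' cohort (\code{all_cohorts} scope) or in at least \code{k} cohorts. The
#' all-'0' key is excluded unless \code{drop_null = FALSE}.
#'
#' @param combined an \code{fh_combined}.
#' @param scope \code{"all_cohorts"} or \code{"at_least_k"}.
#' @param k required number of agreeing cohorts for \code{at_least_k}.
#' @param drop_null exclude genes synchronized on the all-'0' key.
#' @return Named list: pattern key -> sorted vector of gene ids.
#' @export
synchronized_genes <- function(combined,
                               scope = c("all_cohorts", "at_least_k"),
                               k = NULL, drop_null = TRUE) {
  scope <- match.arg(scope)
  stopifnot(inherits(combined, "fh_combined"))
  n_cohorts <- length(combined$cohorts)
  if (scope == "at_least_k") {
    if (is.null(k) || k < 1L || k > n_cohorts) {
      stopf("k must lie in 1..%d", n_cohorts)
    }
  } else {
    k <- n_cohorts
  }
  e <- combined$entries_all
  if (drop_null) e <- e[e$key != null_key(combined$T), , drop = FALSE]
  out <- list()
  for (g in unique(e$gene_id)) {
    rows <- e[e$gene_id == g, , drop = FALSE]
    if (scope == "all_cohorts") {
      present_everywhere <- all(vapply(combined$cohorts, function(tab) {
        g %in% tab$gene_id
      }, logical(1)))
      if (present_everywhere && nrow(rows) == n_cohorts &&
          length(unique(rows$key)) == 1L) {
        out[[rows$key[1]]] <- c(out[[rows$key[1]]], g)
      }
    } else {
      tab <- table(rows$key)
      hit <- names(tab)[tab >= k]
      for (key in hit) out[[key]] <- c(out[[key]], g)
    }
  }
  out <- lapply(out, sort)
  out[order(key_collate(names(out)), method = "radix")]
}

#' Define a Venn-region query over time points
#'
#' Selects entries by the symbols at a subset of time points, e.g. "genes
#' significant (up or down) at time points 1, 2 and 5".
#'
#' @param positions integer vector of required time-point indices.
#' @param symbols per-position constraints: \code{"+"}, \code{"-"},
#'   \code{"0"}, or \code{"s"} for any significant (non-'0') symbol.
#'   Recycled to the length of \code{positions}; default all-\code{"s"}.
#' @return A list of class \code{fh_region_query}.
#' @export
region_query <- function(positions, symbols = "s") {
  positions <- as.integer(positions)
  if (length(positions) == 0L || anyDuplicated(positions) ||
      any(positions < 1L)) {
    stopf("positions must be a non-empty set of positive indices")
  }
  symbols <- rep_len(symbols, length(positions))
  if (!all(symbols %in% c("+", "-", "0", "s"))) {
    stopf("symbols must come from +, -, 0, s")
  }
  structure(list(positions = positions, symbols = symbols),
            class = "fh_region_query")
}

symbol_matches <- function(got, want) {
  if (want == "s") got != "0" else got == want
}

#' Count and stratify entries matching a region query
#'
#' In the default \code{"exact"} mode an entry matches when its required
#' positions satisfy their symbol constraints and every other position is
#' neutral — the semantics of a single Venn region. In \code{"at_least"}
#' mode the other positions are unconstrained. Matches are stratified by
#' their sub-key (the key restricted to the query positions); the strata
#' partition the matched set.
#'
#' @param combined an \code{fh_combined}.
#' @param query an \code{\link{region_query}}.
#' @param match \code{"exact"} or \code{"at_least"}.
#' @return List with \code{count}, \code{members} (cohort_id, gene_id, key,
#'   sub_key) and \code{strata} (named counts per sub-key).
#' @export
region_counts <- function(combined, query, match = c("exact", "at_least")) {
  match <- match.arg(match)
  stopifnot(inherits(combined, "fh_combined"),
            inherits(query, "fh_region_query"))
  if (any(query$positions > combined$T)) {
    stopf("query positions exceed T=%d", combined$T)
  }
  e <- combined$entries_all
  if (nrow(e) == 0L) {
    return(list(count = 0L,
                members = cbind(e, sub_key = character(0)),
                strata = integer(0)))
  }
  km <- do.call(rbind, strsplit(e$key, "", fixed = TRUE))
  req <- query$positions
  ok <- rep(TRUE, nrow(e))
  for (j in seq_along(req)) {
    ok <- ok & symbol_matches(km[, req[j]], query$symbols[j])
  }
  if (match == "exact") {
    others <- setdiff(seq_len(combined$T), req)
    for (j in others) ok <- ok & km[, j] == "0"
  }
  members <- e[ok, , drop = FALSE]
  members$sub_key <- apply(km[ok, req, drop = FALSE], 1, paste,
                           collapse = "")
  rownames(members) <- NULL
  strata <- table(members$sub_key)
  strata <- strata[order(key_collate(names(strata)), method = "radix")]
  list(count = nrow(members), members = members,
       strata = stats::setNames(as.integer(strata), names(strata)))
}
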