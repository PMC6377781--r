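#' Trend key of a single profile
#'
#' Encodes the direction of expression change over time. In
#' \code{diff_only} mode the key has T-1 symbols, one per adjacent pair of
#' time points: \code{'+'} for an increase, \code{'-'} for a decrease,
#' \code{'0'} when the absolute change is within \code{zero_band}. In
#' \code{baseline_inclusive} mode (the default) a leading symbol encodes
#' the change from baseline (log2 fold change 0) to the first time point,
#' giving one symbol per time point.
#'
#' @param fc_log2 numeric vector of log2 fold changes.
#' @param mode \code{"baseline_inclusive"} or \code{"diff_only"}.
#' @param zero_band non-negative log2 magnitude under which a change counts
#'   as flat. Default 0: exact sign.
#' @return A string over \{+, -, 0\}; length T or T-1 by mode.
#' @examples
#' trend_key(linear_to_log2(c(2, 3, 4)), mode = "diff_only")  # "++"
#' trend_key(linear_to_log2(c(5, 4, 3)), mode = "diff_only")  # "--"
#' trend_key(linear_to_log2(c(5, 4, 3)))                      # "+--"
#' @export
trend_key <- function(fc_log2, mode = c("baseline_inclusive", "diff_only"),
                      zero_band = 0) {
  mode <- match.arg(mode)
  if (!all(is.finite(fc_log2))) stopf("non-finite fold change")
  if (length(fc_log2) < 2L) stopf("profiles need at least 2 time points")
  if (zero_band < 0) stopf("zero_band must be non-negative")
  deltas <- diff(fc_log2)
  if (mode == "baseline_inclusive") deltas <- c(fc_log2[1], deltas)
  sym <- ifelse(abs(deltas) <= zero_band, "0",
                ifelse(deltas > 0, "+", "-"))
  paste(sym, collapse = "")
}

profile_lookup <- function(tables) {
  if (inherits(tables, "fh_cohort")) tables <- list(tables)
  names(tables) <- vapply(tables, `[[`, character(1), "cohort_id")
  function(cohort_id, gene_id) {
    tab <- tables[[cohort_id]]
    if (is.null(tab)) stopf("consistency error: unknown cohort '%s'",
                            cohort_id)
    i <- match(gene_id, tab$gene_id)
    if (is.na(i)) stopf("consistency error: gene '%s' not in cohort '%s'",
                        gene_id, cohort_id)
    tab$fc[i, ]
  }
}

#' Decompose a pattern group into trend sub-groups
#'
#' Genes sharing a primary pattern (e.g. \code{"+++"}) may still differ in
#' shape: fold changes (2, 3, 4) rise while (5, 4, 3) fall, though both
#' exceed 2-fold everywhere. Trend sub-groups partition a pattern group by
#' trend key, recovering that distinction.
#'
#' @param group a single group as returned by \code{\link{get_group}} (a
#'   list with \code{key} and a \code{members} data frame).
#' @param tables the \code{fh_cohort} (or list of cohorts) the members
#'   came from; used to look up profiles.
#' @param mode,zero_band passed to \code{\link{trend_key}}.
#' @return An \code{fh_trends} object: parent key, per-trend member tables
#'   and counts, ordered by descending count then key collation.
#' @export
group_by_trend <- function(group, tables,
                           mode = c("baseline_inclusive", "diff_only"),
                           zero_band = 0) {
  mode <- match.arg(mode)
  if (is.null(group$members) || nrow(group$members) == 0L) {
    stopf("group is empty")
  }
  lookup <- profile_lookup(tables)
  m <- group$members
  tkeys <- vapply(seq_len(nrow(m)), function(i) {
    trend_key(lookup(m$cohort_id[i], m$gene_id[i]), mode, zero_band)
  }, character(1))
  members <- lapply(split(seq_len(nrow(m)), tkeys), function(i) {
    x <- m[i, , drop = FALSE]
    rownames(x) <- NULL
    x
  })
  counts <- vapply(members, nrow, integer(1))
  ord <- order(-counts, key_collate(names(members)), method = "radix")
  structure(list(parent = group$key,
                 keys = names(members)[ord],
                 members = members[ord],
                 counts = unname(counts[ord]),
                 mode = mode, zero_band = zero_band),
            class = "fh_trends")
}

#' @export
print.fh_trends <- function(x, ...) {
  cat(sprintf("Trends of pattern '%s' (%s mode): %d sub-group(s), %d genes\n",
              x$parent, x$mode, length(x$keys), sum(x$counts)))
  print(data.frame(trend = x$keys, count = x$counts, row.names = NULL))
  invisible(x)
}

#' @export
as.data.frame.fh_trends <- function(x, ...) {
  data.frame(pattern = x$parent,
             trend = x$keys,
             mode = x$mode,
             count = x$counts,
             gene_ids = vapply(x$members, function(m) {
               paste(paste0(m$cohort_id, ":", m$gene_id), collapse = ";")
             }, character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-cohort membership of one trend sub-group
#'
#' Splits a trend's members by cohort, e.g. to see that a trend is carried
#' predominantly by particular doses or tissues.
#'
#' @param trends an \code{fh_trends}.
#' @param key trend key to inspect; if NULL, the most abundant trend.
#' @return Named list of gene-id vectors, one per cohort; lengths sum to
#'   the trend's count.
#' @export
trend_members_by_cohort <- function(trends, key = NULL) {
  stopifnot(inherits(trends, "fh_trends"))
  key <- key %||% trends$keys[1]
  i <- match(key, trends$keys)
  if (is.na(i)) stopf("no trend with key '%s'", key)
  m <- trends$members[[i]]
  if (nrow(m) == 0L) return(list())
  split(m$gene_id, m$cohort_id)
}
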