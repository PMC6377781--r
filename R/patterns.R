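#' Pattern key of a single profile
#'
#' Discretizes each time point of a profile and concatenates the symbols
#' into a string such as \code{"++-"} (up, up, down).
#'
#' @param fc_log2 numeric vector of log2 fold changes (length T >= 2).
#' @param p optional numeric vector of p-values, same length.
#' @param rule a \code{\link{disc_rule}}.
#' @param na_as_zero treat missing fold changes as neutral.
#' @return A single string over \{+, -, 0\} of length T.
#' @examples
#' r <- disc_rule()
#' pattern_key(linear_to_log2(c(2, 3, 4)), c(0.01, 0.01, 0.01), r)  # "+++"
#' pattern_key(linear_to_log2(c(5, 4, 3)), c(0.01, 0.01, 0.01), r)  # "+++"
#' @export
pattern_key <- function(fc_log2, p = NULL, rule = disc_rule(),
                        na_as_zero = FALSE) {
  if (length(fc_log2) < 2L) stopf("profiles need at least 2 time points")
  paste(discretize(fc_log2, p, rule, na_as_zero = na_as_zero),
        collapse = "")
}

#' Pattern keys for every profile of a cohort
#'
#' @param table an \code{fh_cohort}.
#' @param rule a \code{\link{disc_rule}}.
#' @return Named character vector (names = gene ids) of pattern keys.
#' @export
pattern_keys <- function(table, rule = disc_rule()) {
  stopifnot(inherits(table, "fh_cohort"))
  n <- nrow(table$fc)
  keys <- vapply(seq_len(n), function(i) {
    pattern_key(table$fc[i, ],
                if (!is.null(table$pvalue)) table$pvalue[i, ],
                rule,
                na_as_zero = table$gene_id[i] %in% table$flagged)
  }, character(1))
  names(keys) <- table$gene_id
  keys
}

null_key <- function(T) strrep("0", T)

new_groups <- function(members, null_members, T, rule) {
  counts <- vapply(members, nrow, integer(1))
  structure(list(keys = names(members), members = members,
                 counts = counts,
                 null_count = nrow(null_members),
                 null_members = null_members,
                 T = T, rule = rule),
            class = "fh_groups")
}

#' Partition a cohort's profiles into pattern groups
#'
#' Profiles sharing an identical pattern key form one group. The all-'0'
#' (null) group is by default excluded from the output but its size is
#' always reported, so that group counts plus the null count account for
#' every profile.
#'
#' @param table an \code{fh_cohort} (or an \code{fh_combined} set, whose
#'   pooled entries are grouped).
#' @param rule a \code{\link{disc_rule}}.
#' @param drop_null exclude the all-'0' group from the group list.
#' @return An \code{fh_groups} object: per-key member tables
#'   (cohort_id, gene_id), counts, and \code{null_count}.
#' @export
group_by_pattern <- function(table, rule = disc_rule(), drop_null = TRUE) {
  UseMethod("group_by_pattern")
}

#' @export
group_by_pattern.fh_cohort <- function(table, rule = disc_rule(),
                                       drop_null = TRUE) {
  keys <- pattern_keys(table, rule)
  entries <- data.frame(cohort_id = rep(table$cohort_id, length(keys)),
                        gene_id = names(keys), key = unname(keys),
                        stringsAsFactors = FALSE)
  group_entries(entries, T = length(table$timepoints), rule = rule,
                drop_null = drop_null)
}

group_entries <- function(entries, T, rule, drop_null = TRUE) {
  nk <- null_key(T)
  is_null <- entries$key == nk
  null_members <- entries[is_null, c("cohort_id", "gene_id"), drop = FALSE]
  rownames(null_members) <- NULL
  live <- entries[!is_null, , drop = FALSE]
  members <- lapply(split(seq_len(nrow(live)), live$key), function(i) {
    m <- live[i, c("cohort_id", "gene_id"), drop = FALSE]
    rownames(m) <- NULL
    m
  })
  members <- members[order(key_collate(names(members)), method = "radix")]
  if (!drop_null && nrow(null_members) > 0L) {
    members[[nk]] <- null_members
  }
  new_groups(members, null_members, T, rule)
}

#' @export
print.fh_groups <- function(x, ...) {
  cat(sprintf("%d pattern group(s) over %d time points; null ('%s') count: %d\n",
              length(x$keys), x$T, null_key(x$T), x$null_count))
  if (length(x$keys)) {
    show <- utils::head(data.frame(key = x$keys, count = x$counts,
                                   row.names = NULL), 10)
    print(show)
  }
  invisible(x)
}

#' @export
as.data.frame.fh_groups <- function(x, ...) {
  data.frame(key = x$keys,
             count = unname(x$counts),
             gene_ids = vapply(x$members, function(m) {
               paste(paste0(m$cohort_id, ":", m$gene_id), collapse = ";")
             }, character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sort pattern groups
#'
#' \code{count_desc} sorts by descending member count, the usual
#' "sort by count" view; ties are broken by key under the fixed symbol
#' collation \code{'+' < '-' < '0'}. \code{key_lex} sorts by key alone.
#'
#' @param groups an \code{fh_groups}.
#' @param by \code{"count_desc"} or \code{"key_lex"}.
#' @return The \code{fh_groups} with groups reordered.
#' @export
sort_groups <- function(groups, by = c("count_desc", "key_lex")) {
  by <- match.arg(by)
  stopifnot(inherits(groups, "fh_groups"))
  ord <- if (by == "count_desc") {
    order(-groups$counts, key_collate(groups$keys), method = "radix")
  } else {
    order(key_collate(groups$keys), method = "radix")
  }
  groups$keys <- groups$keys[ord]
  groups$counts <- groups$counts[ord]
  groups$members <- groups$members[ord]
  groups
}

#' Extract one pattern group by key
#'
#' @param groups an \code{fh_groups}.
#' @param key pattern key string.
#' @return A list with \code{key} and \code{members}.
#' @export
get_group <- function(groups, key) {
  stopifnot(inherits(groups, "fh_groups"))
  i <- match(key, groups$keys)
  if (is.na(i)) stopf("no group with key '%s'", key)
  list(key = key, members = groups$members[[i]])
}

#' Filter groups to early- or late-responsive patterns
#'
#' A pattern is early-responsive when its first non-neutral symbol falls
#' within the first ceiling(T/2) time points, late-responsive otherwise.
#' All-'0' keys are excluded from both.
#'
#' @param groups an \code{fh_groups}.
#' @param stage \code{"early"} or \code{"late"}.
#' @return The \code{fh_groups} restricted to the matching keys.
#' @export
stage_filter <- function(groups, stage = c("early", "late")) {
  stage <- match.arg(stage)
  stopifnot(inherits(groups, "fh_groups"))
  first_sig <- vapply(groups$keys, function(k) {
    pos <- regexpr("[+-]", k)
    as.integer(pos)
  }, integer(1))
  half <- ceiling(groups$T / 2)
  keep <- if (stage == "early") first_sig >= 1L & first_sig <= half
          else first_sig > half
  keep[first_sig < 1L] <- FALSE  # all-'0' keys
  groups$keys <- groups$keys[keep]
  groups$counts <- groups$counts[keep]
  groups$members <- groups$members[keep]
  groups
}
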