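#' Discretization rule for symbolic pattern keys
#'
#' A rule maps a per-time-point (log2 fold change, p-value) pair to one of
#' the symbols \code{'+'}, \code{'-'} or \code{'0'}. The default thresholds
#' correspond to a 2-fold change on the linear scale (\code{fc_threshold = 1}
#' in log2 units) gated at \code{p < 0.05} when p-values are available.
#'
#' @param fc_threshold positive log2 fold-change magnitude required for a
#'   non-neutral symbol; 1.0 means linear 2-fold.
#' @param p_threshold significance cutoff in (0, 1], or \code{NULL} to gate
#'   on fold change only.
#' @param p_direction \code{"less"} calls a time point significant when
#'   \code{p < p_threshold} (the conventional reading); \code{"greater"}
#'   inverts the comparison.
#' @return An object of class \code{fh_rule}.
#' @examples
#' r <- disc_rule()
#' discretize(1.0, 0.01, r)   # "+"
#' discretize(-1.0, 0.01, r)  # "-"
#' discretize(0, 0.001, r)    # "0"
#' @export
disc_rule <- function(fc_threshold = 1.0, p_threshold = 0.05,
                      p_direction = c("less", "greater")) {
  p_direction <- match.arg(p_direction)
  if (!is.numeric(fc_threshold) || length(fc_threshold) != 1L ||
      !is.finite(fc_threshold) || fc_threshold <= 0) {
    stopf("fc_threshold must be a single positive number (log2 units)")
  }
  if (!is.null(p_threshold)) {
    if (!is.numeric(p_threshold) || length(p_threshold) != 1L ||
        is.na(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
      stopf("p_threshold must lie in (0, 1] or be NULL")
    }
  }
  structure(list(fc_threshold = fc_threshold,
                 p_threshold = p_threshold,
                 p_direction = p_direction),
            class = "fh_rule")
}

#' @export
print.fh_rule <- function(x, ...) {
  gate <- if (is.null(x$p_threshold)) "FC-only" else {
    sprintf("p %s %g", if (x$p_direction == "less") "<" else ">",
            x$p_threshold)
  }
  cat(sprintf("Discretization rule: |log2 FC| >= %g (linear %g-fold), %s\n",
              x$fc_threshold, 2^x$fc_threshold, gate))
  invisible(x)
}

#' Convert signed linear fold changes to log2
#'
#' Signed linear fold changes use negative values for down-regulation: a
#' linear value of -2 means half the control expression, mapping to log2
#' fold change -1. Values strictly inside (-1, 1), other than exactly 0,
#' are ambiguous under this convention and are rejected; 0 maps to 0.
#'
#' @param v numeric vector of signed linear fold changes.
#' @return numeric vector of log2 fold changes.
#' @export
linear_to_log2 <- function(v) {
  stopifnot(is.numeric(v))
  bad <- !is.na(v) & abs(v) < 1 & v != 0
  if (any(bad)) {
    stopf("signed linear fold changes in (-1, 1) other than 0 are invalid: %s",
          paste(utils::head(v[bad], 5), collapse = ", "))
  }
  out <- numeric(length(v))
  out[is.na(v)] <- NA_real_
  pos <- !is.na(v) & v >= 1
  neg <- !is.na(v) & v <= -1
  out[pos] <- log2(v[pos])
  out[neg] <- -log2(-v[neg])
  out
}

#' Discretize one (fold change, p-value) pair into a symbol
#'
#' Returns \code{'+'} when the log2 fold change meets \code{fc_threshold}
#' and the p-value gate passes, \code{'-'} for the mirrored down case, and
#' \code{'0'} otherwise. Threshold comparisons are inclusive. When the rule
#' carries no p-threshold, or no p-value is supplied, gating is FC-only.
#'
#' @param fc_log2 numeric vector of log2 fold changes (finite; NA allowed
#'   only when \code{na_as_zero = TRUE}).
#' @param p optional numeric vector of p-values in \[0, 1\] (or NULL).
#' @param rule an \code{\link{disc_rule}} object.
#' @param na_as_zero map missing fold changes to \code{'0'} instead of
#'   raising an error (used for profiles flagged by the reader's
#'   \code{allow_missing} option).
#' @return character vector of symbols over \{+, -, 0\}.
#' @export
discretize <- function(fc_log2, p = NULL, rule = disc_rule(),
                       na_as_zero = FALSE) {
  stopifnot(inherits(rule, "fh_rule"), is.numeric(fc_log2))
  nas <- is.na(fc_log2)
  if (any(nas) && !na_as_zero) stopf("non-finite fold change")
  if (any(!nas & !is.finite(fc_log2))) stopf("non-finite fold change")
  if (!is.null(p)) {
    if (length(p) != length(fc_log2)) {
      stopf("p and fc_log2 lengths differ (%d vs %d)", length(p),
            length(fc_log2))
    }
    pok <- is.na(p) | (p >= 0 & p <= 1)
    if (!all(pok)) stopf("p-values must lie in [0, 1]")
  }
  gate <- rep(TRUE, length(fc_log2))
  if (!is.null(p) && !is.null(rule$p_threshold)) {
    gate <- if (rule$p_direction == "less") p < rule$p_threshold
            else p > rule$p_threshold
    gate[is.na(gate)] <- FALSE
  }
  out <- rep("0", length(fc_log2))
  up <- !nas & fc_log2 >= rule$fc_threshold & gate
  dn <- !nas & fc_log2 <= -rule$fc_threshold & gate
  out[up] <- "+"
  out[dn] <- "-"
  out
}
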