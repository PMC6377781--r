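#' Construct a cohort table
#'
#' A cohort is one condition/tissue/file: an ordered grid of time points
#' plus one expression profile per gene. Fold changes are stored internally
#' on the canonical log2 scale; p-values are either present for every time
#' point or absent altogether.
#'
#' @param cohort_id short label for the cohort.
#' @param timepoints character vector of time-point labels (length T >= 2).
#' @param fc numeric matrix, genes x T, of fold changes.
#' @param gene_id character vector of unique gene identifiers (rows of
#'   \code{fc}).
#' @param pvalue optional numeric matrix, same shape as \code{fc}, values
#'   in \[0, 1\].
#' @param entrez,symbol optional per-gene annotation vectors.
#' @param fc_scale scale of the supplied \code{fc}: \code{"log2"} or
#'   \code{"linear_signed"} (converted on construction).
#' @param flagged gene ids whose profiles contain imputed/missing values.
#' @return An object of class \code{fh_cohort}.
#' @export
cohort_table <- function(cohort_id, timepoints, fc, gene_id,
                         pvalue = NULL, entrez = NULL, symbol = NULL,
                         fc_scale = c("log2", "linear_signed"),
                         flagged = character()) {
  fc_scale <- match.arg(fc_scale)
  timepoints <- as.character(timepoints)
  # T = 1 arises transiently when consolidation collapses a whole grid;
  # pattern/trend operations themselves still demand T >= 2
  if (length(timepoints) < 1L) stopf("at least one time point is required")
  fc <- as.matrix(fc)
  if (ncol(fc) != length(timepoints)) {
    stopf("fc has %d columns but %d time points were given", ncol(fc),
          length(timepoints))
  }
  gene_id <- as.character(gene_id)
  if (length(gene_id) != nrow(fc)) stopf("gene_id length != rows of fc")
  if (anyDuplicated(gene_id)) {
    stopf("duplicate gene IDs: %s",
          paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  }
  if (fc_scale == "linear_signed") fc[] <- linear_to_log2(as.vector(fc))
  if (!is.null(pvalue)) {
    pvalue <- as.matrix(pvalue)
    if (!all(dim(pvalue) == dim(fc))) stopf("pvalue and fc shapes differ")
    bad <- !is.na(pvalue) & (pvalue < 0 | pvalue > 1)
    if (any(bad)) stopf("p-values outside [0, 1]")
    dimnames(pvalue) <- list(gene_id, timepoints)
  }
  dimnames(fc) <- list(gene_id, timepoints)
  structure(list(cohort_id = as.character(cohort_id),
                 timepoints = timepoints,
                 gene_id = gene_id,
                 fc = fc, pvalue = pvalue,
                 entrez = if (!is.null(entrez)) as.character(entrez),
                 symbol = if (!is.null(symbol)) as.character(symbol),
                 flagged = flagged),
            class = "fh_cohort")
}

#' @export
print.fh_cohort <- function(x, ...) {
  cat(sprintf("Cohort '%s': %d genes x %d time points (%s); p-values %s\n",
              x$cohort_id, nrow(x$fc), length(x$timepoints),
              paste(x$timepoints, collapse = ", "),
              if (is.null(x$pvalue)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.fh_cohort <- function(x) dim(x$fc)

#' Column-naming dialect for cohort table files
#'
#' Fold-change columns are recognised by prefix (default \code{"FC"}),
#' p-value columns likewise (default \code{"P"}), paired with the FC
#' columns by order of appearance. An explicit column map via the prefix
#' arguments overrides the defaults.
#'
#' @param id_col,entrez_col,symbol_col column names for the identifier and
#'   optional annotation columns.
#' @param fc_prefix,p_prefix prefixes identifying fold-change and p-value
#'   columns (matched case-insensitively).
#' @param fc_scale scale of fold changes in the file.
#' @param allow_missing impute missing fold-change cells as neutral
#'   (symbol \code{'0'}) and flag the profile, instead of rejecting the row.
#' @return A list of class \code{fh_dialect}.
#' @export
table_dialect <- function(id_col = "ID", entrez_col = "Entrez",
                          symbol_col = "Symbol", fc_prefix = "FC",
                          p_prefix = "P",
                          fc_scale = c("linear_signed", "log2"),
                          allow_missing = FALSE) {
  fc_scale <- match.arg(fc_scale)
  structure(list(id_col = id_col, entrez_col = entrez_col,
                 symbol_col = symbol_col, fc_prefix = fc_prefix,
                 p_prefix = p_prefix, fc_scale = fc_scale,
                 allow_missing = allow_missing),
            class = "fh_dialect")
}

match_prefix <- function(nms, prefix) {
  grepl(paste0("^", prefix), nms, ignore.case = TRUE)
}

#' Read a cohort table from tab-delimited text
#'
#' Expects a header row with an ID column, optional Entrez/Symbol columns,
#' and per-time-point fold-change columns, optionally interleaved with
#' p-value columns (one per FC column, paired by order). Rows whose numeric
#' cells cannot be parsed are rejected, never silently dropped: the
#' returned object carries a row-level rejection report in
#' \code{attr(, "rejected")} and the invariant
#' \code{rows_in == rows_parsed + rows_rejected} holds.
#'
#' @param path file path.
#' @param dialect a \code{\link{table_dialect}}.
#' @param cohort_id label for the cohort; defaults to the file name without
#'   extension.
#' @return An \code{fh_cohort} with attributes \code{rejected} (data frame
#'   of row, id, reason) and \code{rows_in}.
#' @export
read_cohort_table <- function(path, dialect = table_dialect(),
                              cohort_id = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  cohort_id <- cohort_id %||% sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "#", quote = "",
                           na.strings = character(0),
                           stringsAsFactors = FALSE)
  nms <- names(raw)
  id_i <- match(tolower(dialect$id_col), tolower(nms))
  if (is.na(id_i)) stopf("format error: missing ID column '%s'",
                         dialect$id_col)
  ent_i <- match(tolower(dialect$entrez_col), tolower(nms))
  sym_i <- match(tolower(dialect$symbol_col), tolower(nms))
  special <- stats::na.omit(c(id_i, ent_i, sym_i))
  fc_i <- setdiff(which(match_prefix(nms, dialect$fc_prefix)), special)
  p_i <- setdiff(which(match_prefix(nms, dialect$p_prefix)), c(special, fc_i))
  if (length(fc_i) == 0L) stopf("format error: no fold-change columns with prefix '%s'",
                                dialect$fc_prefix)
  if (length(p_i) > 0L && length(p_i) != length(fc_i)) {
    stopf("format error: %d p-value columns but %d fold-change columns",
          length(p_i), length(fc_i))
  }
  tp <- sub(paste0("^", dialect$fc_prefix, "[_. ]?"), "", nms[fc_i],
            ignore.case = TRUE)
  if (anyDuplicated(tp) || any(tp == "")) tp <- nms[fc_i]

  ids <- raw[[id_i]]
  dup <- duplicated(ids)
  if (any(dup)) stopf("duplicate gene IDs: %s",
                      paste(unique(ids[dup]), collapse = ", "))

  n <- nrow(raw)
  parse_num <- function(cols) {
    m <- suppressWarnings(
      vapply(cols, function(i) as.numeric(raw[[i]]), numeric(n)))
    if (n == 1L) m <- matrix(m, nrow = 1L)
    m
  }
  fc <- parse_num(fc_i)
  pv <- if (length(p_i)) parse_num(p_i) else NULL
  blank_fc <- vapply(fc_i, function(i) trimws(raw[[i]]) == "" |
                       toupper(trimws(raw[[i]])) == "NA", logical(n))
  if (n == 1L) blank_fc <- matrix(blank_fc, nrow = 1L)

  unparseable <- is.na(fc) & !blank_fc
  missing_fc <- is.na(fc) & blank_fc
  bad_p <- if (is.null(pv)) rep(FALSE, n) else apply(is.na(pv), 1, any)
  reason <- character(n)
  reason[bad_p] <- "unparseable p-value"
  reason[apply(missing_fc, 1, any) & !dialect$allow_missing] <-
    "missing fold-change cell"
  reason[apply(unparseable, 1, any)] <- "unparseable fold change"
  reject <- reason != ""
  rejected <- data.frame(row = which(reject), id = ids[reject],
                         reason = reason[reject],
                         stringsAsFactors = FALSE)
  keep <- !reject
  if (!any(keep)) stopf("no parseable rows in %s", path)

  flagged <- ids[keep & apply(missing_fc, 1, any)]
  fc_k <- fc[keep, , drop = FALSE]
  if (dialect$fc_scale == "linear_signed") {
    fc_k[] <- linear_to_log2(as.vector(fc_k))
  }
  tab <- cohort_table(
    cohort_id = cohort_id, timepoints = tp, fc = fc_k,
    gene_id = ids[keep],
    pvalue = if (!is.null(pv)) pv[keep, , drop = FALSE],
    entrez = if (!is.na(ent_i)) raw[[ent_i]][keep],
    symbol = if (!is.na(sym_i)) raw[[sym_i]][keep],
    fc_scale = "log2", flagged = flagged)
  attr(tab, "rejected") <- rejected
  attr(tab, "rows_in") <- n
  tab
}

#' Write a cohort table as tab-delimited text
#'
#' Writes the canonical log2 fold changes (and p-values when present) under
#' the default dialect headers, so that reading the file back with
#' \code{table_dialect(fc_scale = "log2")} round-trips all fields.
#'
#' @param table an \code{fh_cohort}.
#' @param path output path.
#' @export
write_cohort_table <- function(table, path) {
  stopifnot(inherits(table, "fh_cohort"))
  out <- data.frame(ID = table$gene_id, stringsAsFactors = FALSE)
  if (!is.null(table$entrez)) out$Entrez <- table$entrez
  if (!is.null(table$symbol)) out$Symbol <- table$symbol
  for (j in seq_along(table$timepoints)) {
    tp <- table$timepoints[j]
    if (!is.null(table$pvalue)) {
      out[[paste0("P_", tp)]] <- fmt_num(table$pvalue[, j])
    }
    out[[paste0("FC_", tp)]] <- fmt_num(table$fc[, j])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a pathway database in GMT format
#'
#' One gene set per line: name, description, then tab-separated gene
#' identifiers. Empty gene fields are dropped and duplicate genes within a
#' line are deduplicated (recorded in \code{attr(, "dedup")}).
#'
#' @param path file path.
#' @param source label recorded as each pathway's database of origin;
#'   defaults to the file name.
#' @return A list of \code{fh_pathway} objects (class \code{fh_pathway_db}).
#' @export
read_gmt <- function(path, source = basename(path)) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  dedup <- character()
  db <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stopf("format error in GMT line %d: fewer than 3 tab-separated fields", i)
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(trimws(genes))]
    if (anyDuplicated(genes)) dedup <- c(dedup, fields[1])
    genes <- unique(genes)
    if (length(genes) == 0L) {
      stopf("format error in GMT line %d: pathway '%s' has no genes", i,
            fields[1])
    }
    db[[i]] <- pathway(id = fields[1], name = fields[1],
                       source = if (nzchar(fields[2])) fields[2] else source,
                       genes = genes)
  }
  structure(db, class = "fh_pathway_db", dedup = dedup)
}

#' Write a pathway database in GMT format
#'
#' Merged pathways carry their member provenance in the description field.
#'
#' @param db a list of \code{fh_pathway} objects.
#' @param path output path.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(db, function(p) {
    desc <- if (!is.null(p$member_ids)) {
      paste0("members:", paste(p$member_ids, collapse = ","))
    } else p$source
    paste(c(p$pathway_id, desc, p$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a result table as TSV or JSON
#'
#' All exports are byte-stable for fixed input: columns are emitted in a
#' fixed order, floats at fixed precision, and every file opens with a
#' provenance comment naming the tool version and configuration hash.
#'
#' @param result a data frame (or an object with an
#'   \code{as.data.frame} method, e.g. pattern groups or enrichment
#'   results).
#' @param path output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @param config optional named list echoed into the provenance hash.
#' @export
write_export <- function(result, path, format = c("tsv", "json"),
                         config = NULL) {
  format <- match.arg(format)
  df <- as.data.frame(result, stringsAsFactors = FALSE)
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (format == "tsv") {
    writeLines(provenance_line(config), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    payload <- list(provenance = list(
      tool = "funheatmap",
      version = as.character(utils::packageVersion("funheatmap")),
      config = config_hash(config)),
      results = df)
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE,
                                na = "null"), con)
  }
  invisible(path)
}

#' Constructor for a single pathway
#'
#' @param id,name,source pathway identifier, display name and database of
#'   origin.
#' @param genes character vector of gene identifiers (non-empty; duplicates
#'   removed).
#' @return An object of class \code{fh_pathway}.
#' @export
pathway <- function(id, name = id, source = "", genes) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stopf("pathway '%s': gene set is empty", id)
  structure(list(pathway_id = as.character(id), name = as.character(name),
                 source = as.character(source), genes = genes),
            class = "fh_pathway")
}

#' @export
print.fh_pathway <- function(x, ...) {
  cat(sprintf("Pathway %s (%s): %d genes\n", x$pathway_id, x$source,
              length(x$genes)))
  invisible(x)
}
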