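#' Run configuration
#'
#' Collects every tunable of the pipeline with its default, so that runs
#' are reproducible from a flat key=value config file and each output can
#' be stamped with the effective configuration hash.
#'
#' @param fc_scale input fold-change scale.
#' @param fc_threshold,p_threshold discretization thresholds (log2 units;
#'   p cutoff).
#' @param trend_mode trend alphabet mode.
#' @param zero_band flat-change band for trends (log2 units).
#' @param merge_cut pathway-merge distance cutoff.
#' @param universe enrichment universe choice.
#' @param correction multiple-testing method.
#' @param sort_by group ordering.
#' @param drop_null exclude the all-'0' group.
#' @param out_dir output directory.
#' @param seed RNG seed for the simulate subcommand.
#' @return Named list of class \code{fh_config}.
#' @export
run_config <- function(fc_scale = "linear_signed", fc_threshold = 1.0,
                       p_threshold = 0.05, trend_mode = "baseline_inclusive",
                       zero_band = 0, merge_cut = 0.15,
                       universe = "measured", correction = "BH",
                       sort_by = "count_desc", drop_null = TRUE,
                       out_dir = ".", seed = 1L) {
  structure(list(fc_scale = fc_scale, fc_threshold = fc_threshold,
                 p_threshold = p_threshold, trend_mode = trend_mode,
                 zero_band = zero_band, merge_cut = merge_cut,
                 universe = universe, correction = correction,
                 sort_by = sort_by, drop_null = drop_null,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = c("fh_config", "list"))
}

#' Read / write a flat key=value config file
#'
#' @param path file path.
#' @param config an \code{\link{run_config}} (for writing).
#' @return \code{read_config} returns an \code{fh_config} with file values
#'   overriding the defaults.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) < 2L
  if (any(bad)) stopf("config line without '=': %s", lines[bad][1])
  cfg <- run_config()
  for (pair in kv) {
    key <- trimws(pair[1])
    val <- trimws(paste(pair[-1], collapse = "="))
    if (!key %in% names(cfg)) stopf("unknown config key '%s'", key)
    old <- cfg[[key]]
    cfg[[key]] <- if (is.numeric(old)) as.numeric(val)
                  else if (is.logical(old)) as.logical(val)
                  else val
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  writeLines(vapply(names(config), function(k) {
    paste0(k, "=", format(config[[k]], digits = 12))
  }, character(1)), path)
  invisible(path)
}

rule_from_config <- function(config) {
  disc_rule(fc_threshold = config$fc_threshold,
            p_threshold = if (!is.na(config$p_threshold) &&
                              config$p_threshold > 0) config$p_threshold)
}

#' Heatmap matrix of pattern groups
#'
#' One row per pattern key, one column per time point, cells holding the
#' symbols; the display matrix behind the primary heatmap.
#'
#' @param groups an \code{fh_groups}.
#' @param timepoints column labels.
#' @return Character matrix with a \code{count} attribute.
#' @export
heatmap_matrix <- function(groups, timepoints = NULL) {
  stopifnot(inherits(groups, "fh_groups"))
  m <- if (length(groups$keys) == 0L) {
    matrix(character(0), nrow = 0, ncol = groups$T)
  } else {
    do.call(rbind, strsplit(groups$keys, "", fixed = TRUE))
  }
  dimnames(m) <- list(groups$keys,
                      timepoints %||% paste0("T", seq_len(groups$T)))
  attr(m, "count") <- unname(groups$counts)
  m
}

#' Master Panel analysis: per-cohort patterns, trends and enrichment
#'
#' For each cohort independently: pattern groups (sorted per config),
#' trend decomposition of every group, optional enrichment of every group,
#' and a heatmap matrix export. Side-by-side per-cohort reports are the
#' text equivalent of the Master Panel view.
#'
#' @param tables an \code{fh_cohort} or list of them.
#' @param config an \code{\link{run_config}}.
#' @param db optional pathway database for per-group enrichment.
#' @param write write TSV reports into \code{config$out_dir}.
#' @return Named list per cohort: \code{groups}, \code{trends} (per key),
#'   \code{enrichment} (per key, if \code{db} given), \code{heatmap},
#'   \code{null_count}, and written \code{files}.
#' @export
run_master_panel <- function(tables, config = run_config(), db = NULL,
                             write = FALSE) {
  if (inherits(tables, "fh_cohort")) tables <- list(tables)
  if (length(tables) < 1L) stopf("at least one cohort is required")
  rule <- rule_from_config(config)
  out <- lapply(tables, function(tab) {
    groups <- sort_groups(group_by_pattern(tab, rule,
                                           drop_null = config$drop_null),
                          by = config$sort_by)
    trends <- lapply(groups$keys, function(k) {
      group_by_trend(get_group(groups, k), tab, mode = config$trend_mode,
                     zero_band = config$zero_band)
    })
    names(trends) <- groups$keys
    enr <- NULL
    if (!is.null(db) && length(groups$keys)) {
      measured <- if (!is.null(tab$symbol)) tab$symbol else tab$gene_id
      enr <- lapply(groups$keys, function(k) {
        members <- groups$members[[k]]$gene_id
        q <- if (!is.null(tab$symbol)) {
          tab$symbol[match(members, tab$gene_id)]
        } else members
        # groups disjoint from the database come back as explicit
        # empty results (status attribute), no need to propagate the
        # warning per group
        suppressWarnings(
          enrich(q, db, universe = config$universe,
                 measured_genes = measured,
                 correction = config$correction))
      })
      names(enr) <- groups$keys
    }
    files <- character(0)
    if (write) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      base <- file.path(config$out_dir, tab$cohort_id)
      files <- c(patterns = paste0(base, "_patterns.tsv"),
                 trends = paste0(base, "_trends.tsv"),
                 heatmap = paste0(base, "_heatmap.tsv"))
      write_export(groups, files[["patterns"]], "tsv", config)
      write_export(do.call(rbind, lapply(trends, as.data.frame)),
                   files[["trends"]], "tsv", config)
      hm <- heatmap_matrix(groups, tab$timepoints)
      hm_df <- data.frame(key = rownames(hm), count = attr(hm, "count"),
                          as.data.frame(hm, stringsAsFactors = FALSE),
                          check.names = FALSE)
      write_export(hm_df, files[["heatmap"]], "tsv", config)
      if (!is.null(enr)) {
        files[["enrichment"]] <- paste0(base, "_enrichment.tsv")
        flat <- do.call(rbind, lapply(names(enr), function(k) {
          e <- as.data.frame(enr[[k]])
          if (nrow(e)) cbind(pattern = k, e)
        }))
        write_export(flat %||% data.frame(pattern = character(0)),
                     files[["enrichment"]], "tsv", config)
      }
    }
    list(cohort_id = tab$cohort_id, groups = groups, trends = trends,
         enrichment = enr,
         heatmap = heatmap_matrix(groups, tab$timepoints),
         null_count = groups$null_count, files = files)
  })
  names(out) <- vapply(tables, `[[`, character(1), "cohort_id")
  out
}

#' Combined-page analysis across cohorts
#'
#' Pools the cohorts, reports pooled pattern groups sorted by count, the
#' trend breakdown and per-cohort membership of each pattern, the
#' synchronized-gene table, and a line-chart export of per-gene log2
#' fold-change series keyed by (cohort, gene, pattern, trend).
#'
#' @param tables list of >= 2 \code{fh_cohort}s with equal T.
#' @param config an \code{\link{run_config}}.
#' @param db optional pathway database for per-pattern enrichment.
#' @param write write TSV reports into \code{config$out_dir}.
#' @return List: \code{combined}, \code{groups}, \code{trends},
#'   \code{per_cohort} (trend membership by cohort for the top pattern),
#'   \code{synchronized}, \code{linechart}, \code{enrichment},
#'   \code{files}.
#' @export
run_combined <- function(tables, config = run_config(), db = NULL,
                         write = FALSE) {
  if (inherits(tables, "fh_cohort") || length(tables) < 2L) {
    stopf("the combined view needs >= 2 cohorts; use run_master_panel for one")
  }
  rule <- rule_from_config(config)
  combined <- combine_cohorts(tables, rule)
  groups <- sort_groups(group_by_pattern(combined,
                                         drop_null = config$drop_null),
                        by = config$sort_by)
  trends <- lapply(groups$keys, function(k) {
    group_by_trend(get_group(groups, k), tables, mode = config$trend_mode,
                   zero_band = config$zero_band)
  })
  names(trends) <- groups$keys
  per_cohort <- if (length(groups$keys)) {
    tr <- trends[[groups$keys[1]]]
    lapply(stats::setNames(tr$keys, tr$keys), function(tk) {
      vapply(trend_members_by_cohort(tr, tk), length, integer(1))
    })
  }
  sync <- synchronized_genes(combined, scope = "all_cohorts")
  lookup <- profile_lookup(tables)
  e <- combined$entries
  linechart <- if (nrow(e)) {
    fc <- t(vapply(seq_len(nrow(e)), function(i) {
      lookup(e$cohort_id[i], e$gene_id[i])
    }, numeric(combined$T)))
    colnames(fc) <- paste0("fc_", seq_len(combined$T))
    trend <- vapply(seq_len(nrow(e)), function(i) {
      trend_key(lookup(e$cohort_id[i], e$gene_id[i]),
                mode = config$trend_mode, zero_band = config$zero_band)
    }, character(1))
    data.frame(cohort_id = e$cohort_id, gene_id = e$gene_id,
               pattern = e$key, trend = trend, fc,
               stringsAsFactors = FALSE)
  } else {
    data.frame(cohort_id = character(0), gene_id = character(0),
               pattern = character(0), trend = character(0))
  }
  enr <- NULL
  if (!is.null(db) && length(groups$keys)) {
    measured <- unique(unlist(lapply(tables, function(t) {
      if (!is.null(t$symbol)) t$symbol else t$gene_id
    })))
    enr <- lapply(groups$keys, function(k) {
      suppressWarnings(
        enrich(unique(groups$members[[k]]$gene_id), db,
               universe = config$universe, measured_genes = measured,
               correction = config$correction))
    })
    names(enr) <- groups$keys
  }
  files <- character(0)
  if (write) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(patterns = file.path(config$out_dir, "combined_patterns.tsv"),
               entries = file.path(config$out_dir, "combined_entries.tsv"),
               synchronized = file.path(config$out_dir,
                                        "combined_synchronized.tsv"),
               linechart = file.path(config$out_dir,
                                     "combined_linechart.tsv"))
    write_export(groups, files[["patterns"]], "tsv", config)
    write_export(combined$entries, files[["entries"]], "tsv", config)
    sync_df <- data.frame(
      key = rep(names(sync), lengths(sync)),
      gene_id = unlist(sync, use.names = FALSE),
      stringsAsFactors = FALSE)
    write_export(sync_df, files[["synchronized"]], "tsv", config)
    write_export(linechart, files[["linechart"]], "tsv", config)
  }
  list(combined = combined, groups = groups, trends = trends,
       per_cohort = per_cohort, synchronized = sync,
       linechart = linechart, enrichment = enr, files = files)
}

#' Render static heatmap / line-chart figures
#'
#' Purely presentational: draws the symbol matrix as a colored grid
#' (red = up, black = neutral, blue = down) or the line-chart table as
#' log2 fold-change series. No numbers originate here.
#'
#' @param x a \code{\link{heatmap_matrix}} result or a line-chart data
#'   frame from \code{\link{run_combined}}.
#' @param path output PNG path.
#' @param what \code{"heatmap"} or \code{"linechart"}.
#' @param width,height device size in pixels.
#' @return The path, invisibly; NULL (with a warning) for empty input.
#' @export
render_static <- function(x, path, what = c("heatmap", "linechart"),
                          width = 640, height = 480) {
  what <- match.arg(what)
  if (what == "heatmap") {
    if (is.null(dim(x)) || nrow(x) == 0L) {
      warning("empty heatmap matrix; nothing rendered")
      return(invisible(NULL))
    }
    vals <- matrix(match(x, c("-", "0", "+")) - 2L, nrow = nrow(x))
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(4, 6, 2, 1))
    graphics::image(t(vals[rev(seq_len(nrow(vals))), , drop = FALSE]),
                    col = c("#2166AC", "#000000", "#B2182B"),
                    zlim = c(-1, 1), axes = FALSE)
    graphics::axis(1, at = seq(0, 1, length.out = ncol(x)),
                   labels = colnames(x), las = 2)
    graphics::axis(2, at = seq(0, 1, length.out = nrow(x)),
                   labels = rev(rownames(x)), las = 1)
  } else {
    fc_cols <- grep("^fc_", names(x))
    if (nrow(x) == 0L || length(fc_cols) == 0L) {
      warning("empty line-chart table; nothing rendered")
      return(invisible(NULL))
    }
    series <- t(as.matrix(x[, fc_cols, drop = FALSE]))
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off())
    graphics::matplot(series, type = "l", lty = 1,
                      xlab = "time point", ylab = "log2 fold change")
  }
  invisible(path)
}
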