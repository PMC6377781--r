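# evaluate code under a fixed RNG seed, then restore the caller's RNG state
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env, inherits = FALSE)
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic cohort with planted patterns
#'
#' Describes a cohort whose genes are constructed so that discretization
#' under a given rule reproduces requested pattern keys exactly. Because
#' the pipeline consumes precomputed DEG statistics (not raw counts), the
#' generator only needs to control the discretized outcome: significant
#' positions sit at +/- \code{fc_magnitude} log2 units with a small jitter,
#' neutral positions are drawn uniformly from the middle half of the
#' neutral band, and p-values land on the significant or null side of the
#' gate accordingly.
#'
#' @param seed integer RNG seed.
#' @param patterns named integer vector: pattern key -> number of genes.
#' @param timepoints time-point labels; default \code{T1..Tk} matching the
#'   key length.
#' @param fc_magnitude log2 effect size at significant positions; must
#'   exceed \code{fc_threshold}.
#' @param fc_threshold the discretization threshold the cohort is built
#'   for (log2 units).
#' @param jitter uniform jitter added on top of \code{fc_magnitude}.
#' @param noise_frac neutral positions are drawn uniformly from
#'   (-noise_frac, +noise_frac) x \code{fc_threshold}; must be < 1 so the
#'   neutral band is never crossed.
#' @param with_pvalues also generate p-values.
#' @param p_significant,p_null p-value ranges for significant and neutral
#'   positions.
#' @return A list of class \code{fh_plant_spec}.
#' @export
plant_spec <- function(seed, patterns, timepoints = NULL,
                       fc_magnitude = 1.5, fc_threshold = 1.0,
                       jitter = 0.25, noise_frac = 0.5,
                       with_pvalues = TRUE,
                       p_significant = c(1e-5, 0.01),
                       p_null = c(0.2, 0.9)) {
  if (length(patterns) == 0L || is.null(names(patterns))) {
    stopf("patterns must be a named vector: key -> gene count")
  }
  keys <- names(patterns)
  assert_symbols(keys)
  Ts <- nchar(keys)
  if (length(unique(Ts)) != 1L) stopf("all pattern keys must share one length")
  T <- Ts[1]
  if (T < 2L) stopf("keys need at least 2 time points")
  timepoints <- timepoints %||% paste0("T", seq_len(T))
  if (length(timepoints) != T) stopf("timepoints length must equal key length")
  if (fc_magnitude <= fc_threshold) {
    stopf("infeasible spec: fc_magnitude must exceed fc_threshold")
  }
  if (noise_frac < 0 || noise_frac >= 1) {
    stopf("infeasible spec: noise_frac must lie in [0, 1) so noise stays inside the neutral band")
  }
  structure(list(seed = as.integer(seed), patterns = patterns,
                 timepoints = timepoints, T = T,
                 fc_magnitude = fc_magnitude, fc_threshold = fc_threshold,
                 jitter = jitter, noise_frac = noise_frac,
                 with_pvalues = with_pvalues,
                 p_significant = p_significant, p_null = p_null),
            class = "fh_plant_spec")
}

#' Generate a synthetic cohort with planted pattern structure
#'
#' Deterministic for a fixed spec seed: running twice yields identical
#' tables. Grouping the result with a rule whose thresholds match the
#' spec recovers exactly the planted groups.
#'
#' @param spec a \code{\link{plant_spec}}.
#' @param cohort_id cohort label.
#' @param gene_ids optional explicit gene identifiers (length = total
#'   planted genes); used e.g. to plant a pathway's genes as a group.
#' @return An \code{fh_cohort}; each gene's true key is recorded in
#'   \code{attr(, "planted")}.
#' @export
generate_cohort <- function(spec, cohort_id = "synthetic",
                            gene_ids = NULL) {
  stopifnot(inherits(spec, "fh_plant_spec"))
  total <- sum(spec$patterns)
  ids <- gene_ids %||% sprintf("G%05d", seq_len(total))
  if (length(ids) != total || anyDuplicated(ids)) {
    stopf("gene_ids must supply %d unique identifiers", total)
  }
  true_key <- rep(names(spec$patterns), spec$patterns)
  with_seed(spec$seed, {
    fc <- matrix(0, nrow = total, ncol = spec$T)
    pv <- if (spec$with_pvalues) matrix(0, nrow = total, ncol = spec$T)
    for (i in seq_len(total)) {
      sym <- strsplit(true_key[i], "", fixed = TRUE)[[1]]
      for (t in seq_len(spec$T)) {
        if (sym[t] == "0") {
          fc[i, t] <- stats::runif(1, -spec$noise_frac * spec$fc_threshold,
                                   spec$noise_frac * spec$fc_threshold)
          if (spec$with_pvalues) {
            pv[i, t] <- stats::runif(1, spec$p_null[1], spec$p_null[2])
          }
        } else {
          mag <- spec$fc_magnitude + stats::runif(1, 0, spec$jitter)
          fc[i, t] <- if (sym[t] == "+") mag else -mag
          if (spec$with_pvalues) {
            pv[i, t] <- stats::runif(1, spec$p_significant[1],
                                     spec$p_significant[2])
          }
        }
      }
    }
    tab <- cohort_table(cohort_id, spec$timepoints, fc, ids, pvalue = pv,
                        symbol = ids, fc_scale = "log2")
    attr(tab, "planted") <- stats::setNames(true_key, ids)
    tab
  })
}

#' Generate a synthetic GMT database with controlled overlap
#'
#' Pathways named in the overlap plan share exactly the number of genes
#' that realizes the requested overlap rate (to within 0.02 after integer
#' rounding); all other pathways receive disjoint gene sets, whose mutual
#' overlap rate never exceeds 0.5 and which therefore never merge at any
#' cut below 0.5.
#'
#' @param seed integer RNG seed.
#' @param n_pathways number of pathways.
#' @param size_range inclusive range of gene-set sizes.
#' @param overlap_plan list of \code{list(i, j, rate)} triples requesting
#'   \code{overlap_rate(pathway i, pathway j) == rate}; each pathway may
#'   appear in at most one triple.
#' @param gene_prefix prefix for generated gene identifiers.
#' @return A list of \code{fh_pathway} objects (class
#'   \code{fh_pathway_db}).
#' @export
generate_gmt <- function(seed, n_pathways, size_range = c(10L, 50L),
                         overlap_plan = list(), gene_prefix = "PG") {
  if (n_pathways < 1L) stopf("n_pathways must be >= 1")
  planned <- unlist(lapply(overlap_plan, function(p) c(p[[1]], p[[2]])))
  if (anyDuplicated(planned)) {
    stopf("each pathway may appear in at most one overlap-plan pair")
  }
  if (length(planned) && max(planned) > n_pathways) {
    stopf("overlap plan references pathway beyond n_pathways")
  }
  with_seed(seed, {
    pool <- seq.int(size_range[1], size_range[2])
    sizes <- pool[sample.int(length(pool), n_pathways, replace = TRUE)]
    counter <- 0L
    fresh <- function(n) {
      out <- sprintf("%s%06d", gene_prefix, counter + seq_len(n))
      counter <<- counter + n
      out
    }
    genes <- vector("list", n_pathways)
    for (p in overlap_plan) {
      i <- p[[1]]; j <- p[[2]]; rate <- p[[3]]
      si <- sizes[i]; sj <- sizes[j]
      m <- round(si + sj - min(si, sj) / rate)
      if (m < 0 || m > min(si, sj)) {
        stopf("infeasible overlap target %.2f for sizes %d/%d", rate, si, sj)
      }
      got <- min(si, sj) / (si + sj - m)
      if (abs(got - rate) > 0.02) {
        stopf("overlap target %.3f unreachable for sizes %d/%d (closest %.3f)",
              rate, si, sj, got)
      }
      shared <- fresh(m)
      genes[[i]] <- c(shared, fresh(si - m))
      genes[[j]] <- c(shared, fresh(sj - m))
    }
    for (i in seq_len(n_pathways)) {
      if (is.null(genes[[i]])) genes[[i]] <- fresh(sizes[i])
    }
    db <- lapply(seq_len(n_pathways), function(i) {
      pathway(id = sprintf("SYN_PW%03d", i),
              name = sprintf("synthetic pathway %d", i),
              source = "synthetic", genes = genes[[i]])
    })
    structure(db, class = "fh_pathway_db")
  })
}
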