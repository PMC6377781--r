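test_that("time-point consolidation averages log2 FC and is a no-op for singletons", {
  p <- matrix(c(0.01, 0.03), nrow = 1)
  tab <- linear_cohort(matrix(c(2, 4), nrow = 1), p)
  cons <- consolidate_timepoints(tab, list(1:2))
  # linear 2 and 4 are log2 1 and 2; their mean is 1.5
  expect_equal(unname(cons$fc[1, 1]), 1.5)
  # conservative p: max of the members
  expect_equal(unname(cons$pvalue[1, 1]), 0.03)
  expect_equal(length(cons$timepoints), 1L)

  tab3 <- linear_cohort(matrix(c(2, 4, 8), nrow = 1),
                        matrix(c(0.1, 0.2, 0.3), nrow = 1))
  ident <- consolidate_timepoints(tab3, list(1, 2, 3))
  expect_equal(unname(ident$fc), unname(tab3$fc))
  expect_equal(unname(ident$pvalue), unname(tab3$pvalue))
  expect_error(consolidate_timepoints(tab3, list(1, 2)), "cover")
  expect_error(consolidate_timepoints(tab3, list(c(1, 3), 2)),
               "order-preserving")
})

test_that("combining pools per-cohort entries and rejects unequal grids", {
  r <- disc_rule()
  c1 <- linear_cohort(rbind(c(2, 1.1, -2)), id = "a", gene_id = "G")
  c2 <- linear_cohort(rbind(c(2, 1.1, -2)), id = "b", gene_id = "G")
  comb <- combine_cohorts(list(c1, c2), r)
  expect_equal(nrow(comb$entries), 2L)
  g <- group_by_pattern(comb)
  expect_equal(g$keys, "+0-")
  expect_equal(unname(g$counts), 2L)

  c3 <- linear_cohort(rbind(c(2, 3)), id = "c")
  expect_error(combine_cohorts(list(c1, c3), r), "consolidate")
  expect_error(combine_cohorts(list(c1), r), "at least 2")
})

test_that("pooled counts equal the sum of per-cohort counts per key", {
  r <- disc_rule()
  set.seed(13)
  for (rep in 1:10) {
    tabs <- lapply(1:3, function(i) {
      n <- sample(3:12, 1)
      linear_cohort(matrix(sample(c(-3, -2, 1.1, 2, 3), n * 3,
                                  replace = TRUE), nrow = n),
                    id = paste0("c", i),
                    gene_id = sprintf("c%dG%02d", i, 1:n))
    })
    comb <- combine_cohorts(tabs, r)
    pooled <- group_by_pattern(comb)
    per <- lapply(tabs, function(t) group_by_pattern(t, r))
    for (k in pooled$keys) {
      expect_equal(unname(pooled$counts[pooled$keys == k]),
                   sum(vapply(per, function(g) {
                     if (k %in% g$keys) unname(g$counts[g$keys == k]) else 0L
                   }, integer(1))))
    }
  }
})

test_that("synchronized genes require identical keys, with an at-least-k relaxation", {
  r <- disc_rule()
  mk <- function(id, rows, genes) {
    linear_cohort(rows, id = id, gene_id = genes)
  }
  c1 <- mk("c1", rbind(c(2, 1.1, -2), c(2, 2, 2), c(-2, 1.1, 1.1)),
           c("G1", "G2", "G3"))
  c2 <- mk("c2", rbind(c(3, 1.2, -3), c(2, 1.1, 2), c(-3, 1.2, 1.1)),
           c("G1", "G2", "G3"))
  c3 <- mk("c3", rbind(c(2, 1.1, -2), c(2, 2, 2)), c("G1", "G2"))
  comb <- combine_cohorts(list(c1, c2, c3), r)
  sync <- synchronized_genes(comb, "all_cohorts")
  # G1 is "+0-" everywhere; G2 differs in c2; G3 is absent from c3
  expect_equal(sync, list("+0-" = "G1"))
  al2 <- synchronized_genes(comb, "at_least_k", k = 2)
  expect_true("G1" %in% al2[["+0-"]])
  expect_true("G2" %in% al2[["+++"]])
  expect_true("G3" %in% al2[["-00"]])
  expect_error(synchronized_genes(comb, "at_least_k", k = 4), "1..3")
  # invariance under cohort reordering
  comb_rev <- combine_cohorts(list(c3, c2, c1), r)
  expect_equal(synchronized_genes(comb_rev, "all_cohorts"), sync)
})

test_that("at-least-k synchronization matches enumeration over planted configurations", {
  r <- disc_rule()
  set.seed(29)
  keys <- c("+0-", "++-", "-00")
  fc_for <- list("+" = 2.5, "-" = -2.5, "0" = 1.1)
  for (rep in 1:10) {
    # each gene gets a random key per cohort; brute-force the answer
    assignment <- matrix(sample(keys, 3 * 4, replace = TRUE), nrow = 4)
    tabs <- lapply(1:3, function(ci) {
      fc <- t(vapply(1:4, function(gi) {
        unlist(fc_for[strsplit(assignment[gi, ci], "")[[1]]])
      }, numeric(3)))
      linear_cohort(fc, id = paste0("c", ci),
                    gene_id = sprintf("G%d", 1:4))
    })
    comb <- combine_cohorts(tabs, r)
    got <- synchronized_genes(comb, "at_least_k", k = 2)
    for (gi in 1:4) {
      tally <- table(assignment[gi, ])
      for (k in names(tally)) {
        in_result <- !is.null(got[[k]]) && sprintf("G%d", gi) %in% got[[k]]
        expect_equal(in_result, unname(tally[k]) >= 2)
      }
    }
  }
})

test_that("region queries match, stratify and partition the Venn region", {
  r <- disc_rule()
  c1 <- linear_cohort(rbind(c(2, -2, 1.1, 1.1, -2),
                            c(2, 2, 1.1, 1.1, 2),
                            c(1.1, 1.1, 1.1, 1.1, 1.1),
                            c(2, -2, 2, 1.1, -2)),
                      id = "a", gene_id = paste0("G", 1:4))
  c2 <- linear_cohort(rbind(c(-2, -2, 1.1, 1.1, -2)),
                      id = "b", gene_id = "H1")
  comb <- combine_cohorts(list(c1, c2), r)
  q <- region_query(c(1, 2, 5))
  res <- region_counts(comb, q, match = "exact")
  # G4 is also significant at position 3, so exact mode excludes it
  expect_equal(res$count, 3L)
  expect_setequal(res$members$gene_id, c("G1", "G2", "H1"))
  expect_equal(res$members$sub_key[res$members$gene_id == "G1"], "+--")
  expect_equal(sum(res$strata), res$count)
  res_al <- region_counts(comb, q, match = "at_least")
  expect_equal(res_al$count, 4L)
  # all-'0' keys never match a significance query
  expect_false("G3" %in% res_al$members$gene_id)
  # per-position symbol constraints
  res_up <- region_counts(comb, region_query(c(1, 2, 5), c("+", "s", "s")),
                          match = "exact")
  expect_setequal(res_up$members$gene_id, c("G1", "G2"))
})

test_that("all eight up/down combinations at three positions appear as sub-keys", {
  r <- disc_rule()
  signs <- expand.grid(c("+", "-"), c("+", "-"), c("+", "-"),
                       stringsAsFactors = FALSE)
  fc <- t(apply(signs, 1, function(s) {
    ifelse(s == "+", 2.5, -2.5)
  }))
  c1 <- linear_cohort(fc, id = "a")
  c2 <- linear_cohort(fc[1:2, , drop = FALSE], id = "b",
                      gene_id = c("H1", "H2"))
  comb <- combine_cohorts(list(c1, c2), r)
  res <- region_counts(comb, region_query(1:3), match = "exact")
  expect_length(res$strata, 8L)
  expect_equal(sum(res$strata), nrow(comb$entries))
})

test_that("two-cohort significance sets obey Venn arithmetic", {
  r <- disc_rule()
  set.seed(31)
  for (rep in 1:10) {
    genes <- sprintf("G%02d", 1:12)
    mk <- function(id) {
      n <- sample(5:12, 1)
      ids <- sample(genes, n)
      linear_cohort(matrix(sample(c(-2.5, 1.1, 2.5), n * 2,
                                  replace = TRUE), nrow = n),
                    id = id, gene_id = ids)
    }
    t1 <- mk("a"); t2 <- mk("b")
    comb <- combine_cohorts(list(t1, t2), r)
    sig <- function(cid) unique(comb$entries$gene_id[
      comb$entries$cohort_id == cid])
    a <- sig("a"); b <- sig("b")
    expect_equal(length(setdiff(a, b)) + length(setdiff(b, a)) +
                   length(intersect(a, b)),
                 length(union(a, b)))
  }
})
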