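test_that("discretization follows the three-level rule with inclusive thresholds", {
  r <- disc_rule()
  expect_equal(discretize(1.0, 0.01, r), "+")    # linear 2-fold up
  expect_equal(discretize(-1.0, 0.01, r), "-")   # linear 2-fold down
  expect_equal(discretize(0, 0.001, r), "0")
  expect_equal(discretize(0.999, 0.001, r), "0") # just inside the band
  # p-gate forces neutral even at large fold change
  expect_equal(discretize(2.0, 0.5, r), "0")
  # FC-only gating when the rule has no p-threshold or no p given
  expect_equal(discretize(2.0, 0.5, disc_rule(p_threshold = NULL)), "+")
  expect_equal(discretize(2.0, NULL, r), "+")
  expect_error(discretize(Inf, 0.01, r), "non-finite")
})

test_that("discretize is monotone in fold change for fixed p", {
  r <- disc_rule()
  rank <- c("-" = 1L, "0" = 2L, "+" = 3L)
  set.seed(42)
  for (rep in 1:200) {
    fcs <- sort(stats::runif(2, -3, 3))
    p <- stats::runif(1)
    s <- rank[c(discretize(fcs[1], p, r), discretize(fcs[2], p, r))]
    expect_gte(s[[2]], s[[1]])
  }
})

test_that("pattern keys concatenate symbols; rising and falling 2+-fold profiles share '+++'", {
  r <- disc_rule()
  p_sig <- c(0.01, 0.01, 0.01)
  expect_equal(pattern_key(linear_to_log2(c(2, 3, 4)), p_sig, r), "+++")
  expect_equal(pattern_key(linear_to_log2(c(5, 4, 3)), p_sig, r), "+++")
  expect_equal(pattern_key(c(0, 0, 0), c(0.01, 0.01, 0.01), r), "000")
})

test_that("grouping partitions profiles and matches a nested-loop oracle", {
  r <- disc_rule()
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:25, 1)
    T <- sample(2:5, 1)
    fc <- matrix(stats::runif(n * T, -3, 3), nrow = n)
    tab <- cohort_table("c", paste0("T", 1:T), fc,
                        sprintf("G%02d", 1:n), fc_scale = "log2")
    keys <- pattern_keys(tab, r)
    groups <- group_by_pattern(tab, r, drop_null = TRUE)
    # partition: every profile in exactly one group or the null bucket
    expect_equal(sum(groups$counts) + groups$null_count, n)
    got <- stats::setNames(groups$counts, groups$keys)
    want <- oracle_group_counts(unname(keys))
    want <- want[names(want) != strrep("0", T)]
    expect_mapequal(as.list(got), as.list(want))
    all_members <- do.call(rbind, c(groups$members,
                                    list(groups$null_members)))
    expect_setequal(all_members$gene_id, tab$gene_id)
  }
})

test_that("the null group is dropped but reported, or kept on request", {
  r <- disc_rule()
  tab <- linear_cohort(matrix(c(2, 1.2, 3, 1.1), nrow = 2))
  dropped <- group_by_pattern(tab, r, drop_null = TRUE)
  expect_equal(dropped$keys, "++")
  expect_equal(dropped$null_count, 1L)
  kept <- group_by_pattern(tab, r, drop_null = FALSE)
  expect_setequal(kept$keys, c("++", "00"))
})

test_that("group sorting is stable with the declared '+' < '-' < '0' collation", {
  r <- disc_rule()
  # counts: "+-0" 3, "-+0" 3, "0+0" 1  (tie between the first two)
  fc <- rbind(matrix(rep(c(2, -2, 1.1), 3), nrow = 3, byrow = TRUE),
              matrix(rep(c(-2, 2, 1.1), 3), nrow = 3, byrow = TRUE),
              c(1.1, 2, 1.2))
  tab <- linear_cohort(fc)
  g <- sort_groups(group_by_pattern(tab, r), by = "count_desc")
  expect_equal(g$keys, c("+-0", "-+0", "0+0"))
  g2 <- sort_groups(g, by = "key_lex")
  expect_equal(g2$keys, c("+-0", "-+0", "0+0"))
  # '0'-leading keys collate after '+'-leading ones
  expect_equal(key_order <- sort_groups(group_by_pattern(
    linear_cohort(rbind(c(1.1, 1.1, 1.1), c(2, 2, -2))), r,
    drop_null = FALSE), "key_lex")$keys, c("++-", "000"))
})

test_that("stage filter splits early from late responders and drops null keys", {
  r <- disc_rule()
  fc <- rbind(c(1.1, 2, 1.1, 1.1, 1.1),   # "0+000" early (pos 2 <= 3)
              c(1.1, 1.1, 1.1, 1.1, -2),  # "0000-" late
              c(1.1, 1.1, 1.1, 1.1, 1.1)) # "00000" excluded
  tab <- linear_cohort(fc)
  g <- group_by_pattern(tab, r, drop_null = FALSE)
  expect_equal(stage_filter(g, "early")$keys, "0+000")
  expect_equal(stage_filter(g, "late")$keys, "0000-")
  expect_false("00000" %in% c(stage_filter(g, "early")$keys,
                              stage_filter(g, "late")$keys))
})
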