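test_that("config files round-trip and feed the rule", {
  cfg <- run_config(fc_threshold = 0.8, p_threshold = 0.01,
                    trend_mode = "diff_only", merge_cut = 0.2, seed = 9L)
  f <- withr::local_tempfile(fileext = ".cfg")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(back[names(cfg)], cfg[names(cfg)])
  expect_error(read_config({
    f2 <- withr::local_tempfile(fileext = ".cfg")
    writeLines("nosuchkey=1", f2); f2
  }), "unknown config key")
})

test_that("the master panel reports patterns, trends and a heatmap per cohort", {
  cfg <- run_config(out_dir = withr::local_tempdir())
  t1 <- generate_cohort(plant_spec(21, c("++-" = 3L, "+0-" = 2L,
                                         "-00" = 1L)), "c1")
  t2 <- generate_cohort(plant_spec(22, c("++-" = 2L)), "c2")
  res <- run_master_panel(list(t1, t2), cfg, write = TRUE)
  expect_named(res, c("c1", "c2"))
  expect_equal(nrow(res$c1$heatmap), 3L)
  expect_equal(rownames(res$c1$heatmap)[1], "++-")
  expect_length(res$c1$trends, 3L)
  expect_true(all(file.exists(res$c1$files)))
  # per-group enrichment when a database is supplied
  db <- list(pathway("PW", genes = t1$gene_id[1:3]))
  res_e <- run_master_panel(t1, cfg, db = db)
  expect_s3_class(res_e$c1$enrichment[["++-"]], "fh_enrichment")
})

test_that("the combined run pools cohorts and writes deterministic exports", {
  dir <- withr::local_tempdir()
  cfg <- run_config(out_dir = dir)
  t1 <- generate_cohort(plant_spec(23, c("++-" = 3L, "+0-" = 2L)), "c1")
  t2 <- generate_cohort(plant_spec(24, c("++-" = 2L, "-00" = 2L)), "c2")
  res <- run_combined(list(t1, t2), cfg, write = TRUE)
  expect_equal(res$groups$keys[1], "++-")
  expect_equal(unname(res$groups$counts[1]), 5L)
  expect_equal(sum(vapply(res$per_cohort, sum, integer(1))), 5L)
  expect_equal(nrow(res$linechart), nrow(res$combined$entries))
  expect_true(all(file.exists(res$files)))
  expect_error(run_combined(t1, cfg), ">= 2 cohorts")

  # byte-identical rerun
  first <- lapply(res$files, function(f) readBin(f, "raw", file.size(f)))
  res2 <- run_combined(list(t1, t2), cfg, write = TRUE)
  for (nm in names(res$files)) {
    expect_identical(readBin(res2$files[[nm]], "raw",
                             file.size(res2$files[[nm]])), first[[nm]])
  }
})

test_that("static rendering draws figures and warns on empty input", {
  cfg <- run_config()
  tab <- generate_cohort(plant_spec(25, c("++-" = 3L)))
  res <- run_master_panel(tab, cfg)
  png <- withr::local_tempfile(fileext = ".png")
  out <- render_static(res[[1]]$heatmap, png, "heatmap")
  expect_true(file.exists(png) && file.size(png) > 0)
  empty <- matrix(character(0), nrow = 0, ncol = 3)
  expect_warning(render_static(empty, png, "heatmap"), "empty")
  lc <- data.frame(cohort_id = "c", gene_id = c("a", "b"),
                   pattern = "+++", trend = c("++", "--"),
                   fc_1 = c(1, 2.3), fc_2 = c(1.6, 2), fc_3 = c(2, 1.6))
  png2 <- withr::local_tempfile(fileext = ".png")
  render_static(lc, png2, "linechart")
  expect_true(file.exists(png2) && file.size(png2) > 0)
})

test_that("the command-line tool runs end to end and is deterministic", {
  cli <- system.file("cli", "funheatmap", package = "funheatmap")
  expect_true(nzchar(cli))
  dir <- withr::local_tempdir()
  sim_dir <- file.path(dir, "sim")
  # the child Rscript must see the same library paths as this session
  libs <- paste0("R_LIBS=", paste(.libPaths(),
                                  collapse = .Platform$path.sep))
  run_cli <- function(...) {
    system2("Rscript", c(cli, ...), stdout = TRUE, stderr = TRUE,
            env = libs)
  }
  run_cli("simulate", "--out", sim_dir, "--seed", "5", "--cohorts", "2",
          "--pathways", "6")
  expect_true(file.exists(file.path(sim_dir, "sim01.tsv")))
  expect_true(file.exists(file.path(sim_dir, "sim.gmt")))

  out1 <- file.path(dir, "run1")
  out2 <- file.path(dir, "run2")
  for (out in c(out1, out2)) {
    run_cli("combine", "--fc-scale", "log2", "--out", out,
            file.path(sim_dir, "sim01.tsv"), file.path(sim_dir, "sim02.tsv"))
  }
  f1 <- file.path(out1, "combined_patterns.tsv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1),
                   readLines(file.path(out2, "combined_patterns.tsv")))

  # expected failures: system2 warns about the non-zero status by design
  status <- attr(suppressWarnings(
    run_cli("combine", file.path(sim_dir, "sim01.tsv"))), "status")
  expect_equal(status, 2L)
  status3 <- attr(suppressWarnings(run_cli("nosuchcmd")), "status")
  expect_equal(status3, 3L)
})
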