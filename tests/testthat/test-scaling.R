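test_that("size regressions recover exact lines and calibrate under the null", {
  sizes <- 10^seq(-0.4, 3, length.out = 12)
  metrics <- data.frame(group = paste0("g", 1:12), size_um = sizes,
                        metric = 2 * log10(sizes) + 1)
  r <- regress_on_size(metrics, "metric")
  expect_equal(r$slope, 2, tolerance = 1e-10)
  expect_equal(r$intercept, 1, tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
  expect_equal(r$n, 12)

  # within-kingdom scope
  metrics$kingdom <- rep(c("bacteria", "fungi"), each = 6)
  rk <- regress_on_size(metrics, "metric", scope = "within-kingdom")
  expect_equal(nrow(rk), 2)
  expect_equal(rk$slope, c(2, 2), tolerance = 1e-9)

  expect_error(regress_on_size(metrics[1:2, ], "metric"), "fewer than 3")
  expect_error(regress_on_size(metrics, "nope"), "no metric column")

  # permutation calibration: response independent of size gives uniform p
  set.seed(77)
  y <- rnorm(12)
  hits <- 0
  n_perm <- 1000
  for (i in seq_len(n_perm)) {
    metrics$metric <- sample(y)
    if (regress_on_size(metrics, "metric")$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_perm, 0.02)
  expect_lte(hits / n_perm, 0.08)
})

test_that("group comparison runs ANOVA + Tukey with letters", {
  # clearly separated categories get distinct letters
  set.seed(3)
  v <- c(rnorm(8, 0), rnorm(8, 30), rnorm(8, 60))
  g <- rep(c("a", "b", "c"), each = 8)
  res <- compare_groups(v, g)
  expect_lt(res$p_value, 1e-6)
  expect_true(all(res$tukey[, "p adj"] < 0.01))
  expect_equal(length(unique(res$letters)), 3)

  # two categories reduce to the equal-variance t test
  v2 <- c(rnorm(10, 0), rnorm(10, 1))
  g2 <- rep(c("x", "y"), each = 10)
  res2 <- compare_groups(v2, g2)
  tt <- t.test(v2 ~ g2, var.equal = TRUE)
  expect_equal(unname(res2$tukey[, "p adj"]), tt$p.value, tolerance = 1e-6)

  # single shared distribution: F p-value roughly uniform
  set.seed(9)
  ps <- replicate(400, {
    compare_groups(rnorm(18), rep(c("a", "b", "c"), each = 6))$p_value
  })
  expect_gte(mean(ps < 0.05), 0.01)
  expect_lte(mean(ps < 0.05), 0.10)

  expect_error(compare_groups(1:3, c("a", "a", "b")), "fewer than 2")
  expect_error(compare_groups(1:4, rep("a", 4)), "2 categories")
})

small_cfg <- function(seed = 5, coupling = TRUE) {
  simulation_config(n_sites = 12, n_otus_per_group = 20, depth = 400,
                    n_individuals = 800, generations = 10,
                    size_coupling = coupling, seed = seed)
}

test_that("run_pipeline emits one metrics row per retained group,
           deterministically", {
  st <- generate_study(small_cfg())
  gm <- suppressWarnings(
    run_pipeline(st, n_reps = 49, n_perm = 99, seed = 2,
                 stages = c("alpha", "ddr", "ndv", "neutral", "omi")))
  expect_s3_class(gm, "group_metrics")
  expect_true(all(gm$group %in% st$truth$groups$label))
  expect_true(all(is.finite(gm$mean_ndv)))
  expect_true(all(is.finite(gm$chao1_mean)))
  expect_true(all(gm$chao1_mean >= gm$richness_mean))
  expect_true(all(is.finite(gm$size_um)))

  gm2 <- suppressWarnings(
    run_pipeline(st, n_reps = 49, n_perm = 99, seed = 2,
                 stages = c("alpha", "ddr", "ndv", "neutral", "omi")))
  strip <- function(d) data.frame(unclass(d)[names(d)])
  expect_identical(strip(gm), strip(gm2))

  # manifest captures the run parameters
  expect_equal(attr(gm, "manifest")$n_reps, 49)
  expect_setequal(attr(gm, "manifest")$groups, gm$group)
})

test_that("a study without body sizes degrades cleanly at the scaling stage", {
  st <- generate_study(small_cfg())
  dir <- withr::local_tempdir()
  write_study(st, dir)
  unlink(file.path(dir, "sizes.csv"))
  gm <- run_pipeline(dir, n_reps = 19, seed = 3, stages = c("alpha", "ndv"))
  expect_false("size_um" %in% names(gm))
  expect_true(all(is.finite(gm$mean_ndv)))
  expect_error(regress_on_size(gm, "mean_ndv"), "size_um")
})

test_that("meta-analysis harness pools per-study NDVs by ecosystem", {
  st <- generate_study(small_cfg(seed = 8))
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_study(st, dir1)
  write_study(st, dir2)
  pooled <- suppressMessages(
    meta_batch(list(dir1, dir2), ecosystems = c("paddy", "forest"),
               n_reps = 19, seed = 1))
  expect_setequal(unique(pooled$ecosystem), c("paddy", "forest"))
  # identical studies give identical per-group NDVs
  a <- pooled[pooled$ecosystem == "paddy", ]
  b <- pooled[pooled$ecosystem == "forest", ]
  expect_equal(a$mean_ndv[order(a$group)], b$mean_ndv[order(b$group)],
               tolerance = 1e-12)

  # malformed study directory skipped with a message
  bad <- withr::local_tempdir()
  expect_message(pooled2 <- meta_batch(list(dir1, bad), n_reps = 19, seed = 1),
                 "skipped")
  expect_setequal(unique(pooled2$study), 1)
  expect_error(meta_batch(list(dir1)), "at least 2")
})
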