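test_that("environment standardization uses population moments", {
  si <- sample_info(data.frame(sample_id = paste0("s", 1:4),
                               latitude = 1:4, longitude = 0,
                               env = c(1, 2, 3, 4)))
  z <- standardize_environment(si, pca = FALSE)
  expect_equal(as.vector(z), c(-1.3416, -0.4472, 0.4472, 1.3416),
               tolerance = 1e-4)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(mean(z^2), 1, tolerance = 1e-12)

  # PCA rotation preserves total variance (= number of variables)
  set.seed(6)
  si2 <- sample_info(data.frame(sample_id = paste0("s", 1:20),
                                latitude = 0, longitude = 0,
                                a = rnorm(20), b = rnorm(20), c = rnorm(20)))
  zp <- standardize_environment(si2, pca = TRUE)
  expect_equal(sum(colMeans(zp^2)), 3, tolerance = 1e-10)

  expect_error(standardize_environment(
    sample_info(data.frame(sample_id = c("x", "y"), latitude = 0,
                           longitude = 0, flat = c(2, 2)))), "flat")
})

test_that("OMI equals the squared distance of the weighted niche centroid", {
  si <- sample_info(data.frame(sample_id = paste0("s", 1:4),
                               latitude = 1:4, longitude = 0,
                               env = c(1, 2, 3, 4)))
  z <- standardize_environment(si, pca = FALSE)
  m <- rbind(c(2, 0), c(2, 0), c(2, 0), c(2, 5))
  dimnames(m) <- list(paste0("s", 1:4), c("uniform", "site4"))
  rec <- omi_per_otu(count_table(m), z)

  # uniform OTU sits at the origin
  expect_equal(rec$omi[rec$otu_id == "uniform"], 0, tolerance = 1e-12)
  # single-site OTU at standardized coordinate 1.3416: omi = 1.8 exactly
  expect_equal(rec$omi[rec$otu_id == "site4"], 1.8, tolerance = 1e-9)

  # permutation invariance of site order
  perm <- c(3, 1, 4, 2)
  rec2 <- omi_per_otu(count_table(m[perm, ]), z[perm, , drop = FALSE])
  expect_equal(rec2$omi[order(rec2$otu_id)], rec$omi[order(rec$otu_id)],
               tolerance = 1e-12)

  # OMI is invariant under the PCA rotation
  si3 <- sample_info(data.frame(sample_id = paste0("s", 1:10),
                                latitude = 0, longitude = 0,
                                a = rnorm(10), b = rnorm(10)))
  set.seed(2)
  mm <- matrix(rpois(10 * 6, 3), 10, 6,
               dimnames = list(paste0("s", 1:10), paste0("o", 1:6)))
  raw <- omi_per_otu(count_table(mm), standardize_environment(si3, pca = FALSE))
  rot <- omi_per_otu(count_table(mm), standardize_environment(si3, pca = TRUE))
  expect_equal(raw$omi, rot$omi, tolerance = 1e-10)

  expect_error(omi_per_otu(count_table(mm), z), "sample ids")
})

test_that("duplicating a site shifts OMI per direct recomputation", {
  set.seed(9)
  env <- matrix(rnorm(12), 6, 2,
                dimnames = list(paste0("s", 1:6), c("e1", "e2")))
  m <- matrix(rpois(6 * 4, 4), 6, 4,
              dimnames = list(paste0("s", 1:6), paste0("o", 1:4)))
  dup_m <- rbind(m, s7 = m[3, ])
  dup_env <- rbind(env, s7 = env[3, ])
  got <- omi_per_otu(count_table(dup_m), dup_env)
  # naive oracle: recompute with elementary arithmetic
  for (k in seq_len(4)) {
    w <- dup_m[, k] / sum(dup_m[, k])
    np <- colSums(dup_env * w)
    omi <- sum((np - colMeans(dup_env))^2)
    expect_equal(got$omi[got$otu_id == paste0("o", k)], omi,
                 tolerance = 1e-12)
  }
})

test_that("group OMI summarizes and tracks selection strength", {
  taxa <- data.frame(otu_id = c("u1", "n1", "n2"),
                     group = c("neutral", "niche", "niche"))
  rec <- data.frame(otu_id = c("u1", "n1", "n2"), omi = c(0.1, 2, 4),
                    weight = c(10, 10, 30))
  gs <- group_omi(rec, taxa)
  expect_equal(gs$mean_omi[gs$group == "niche"], 3)
  expect_equal(gs$weighted_mean_omi[gs$group == "niche"], (2 * 10 + 4 * 30) / 40)
  expect_equal(gs$mean_omi[gs$group == "neutral"], 0.1)
  expect_warning(group_omi(rec, rbind(taxa,
    data.frame(otu_id = "ghost", group = "empty"))), "empty")

  # simulation contrast: smaller niche breadth -> larger mean OMI
  meta <- simulate_metacommunity(25, seed = 11)
  mu <- seq(0, 10, length.out = 25)
  env_vals <- seq(1, 9, length.out = 10)
  si <- sample_info(data.frame(sample_id = paste0("S", 1:10),
                               latitude = 1:10, longitude = 0,
                               env = env_vals))
  z <- standardize_environment(si, pca = FALSE)
  wins <- 0
  for (s in 1:10) {
    sim <- function(sigma, off) {
      t(vapply(1:10, function(k)
        simulate_niche_local(meta, env_vals[k], mu, sigma, N = 400,
                             seed = s * 37 + k + off), integer(25)))
    }
    narrow <- sim(0.7, 0); wide <- sim(5, 1000)
    colnames(narrow) <- colnames(wide) <- paste0("o", 1:25)
    rownames(narrow) <- rownames(wide) <- paste0("S", 1:10)
    o_n <- omi_per_otu(count_table(narrow), z)
    o_w <- omi_per_otu(count_table(wide), z)
    if (mean(o_n$omi) > mean(o_w$omi)) wins <- wins + 1
  }
  expect_gte(wins, 9)
})
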