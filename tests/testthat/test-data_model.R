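test_that("count table readers parse, validate and round-trip", {
  dir <- withr::local_tempdir()
  # 2x2 TSV parse
  p <- file.path(dir, "t.tsv")
  writeLines(c("sample_id\tA\tB", "s1\t1\t2", "s2\t3\t4"), p)
  tab <- read_count_table(p)
  expect_equal(unname(rowSums(tab)), c(3, 7))
  expect_equal(colnames(tab), c("A", "B"))

  # negative and non-numeric cells are format errors naming the cell
  writeLines(c("sample_id\tA\tB", "s1\t1\t-2", "s2\t3\t4"), p)
  expect_error(read_count_table(p), "negative count.*s1.*B")
  writeLines(c("sample_id\tA\tB", "s1\t1\tx", "s2\t3\t4"), p)
  expect_error(read_count_table(p), "non-numeric")

  # duplicate ids rejected
  writeLines(c("sample_id\tA\tA", "s1\t1\t2"), p)
  expect_error(read_count_table(p), "duplicate OTU")
  writeLines(c("sample_id\tA\tB", "s1\t1\t2", "s1\t3\t4"), p)
  expect_error(read_count_table(p), "duplicate sample")

  # write -> read round-trip on a random 3x5 table, zero column preserved
  set.seed(1)
  m <- matrix(rpois(15, 4), 3, 5)
  m[, 2] <- 0L
  tab <- toy_table(m)
  p2 <- file.path(dir, "rt.tsv")
  write_count_table(tab, p2)
  back <- read_count_table(p2)
  expect_identical(unclass(back), unclass(tab))
  expect_true(all(back[, "OTU2"] == 0))
  expect_error(write_count_table(tab, file.path(dir, "no/such/dir/x.tsv")),
               "no such directory")

  # biom classic dense text (OTUs as rows) is transposed on read
  p3 <- file.path(dir, "b.tsv")
  writeLines(c("# Constructed from biom file",
               "#OTU ID\ts1\ts2", "A\t1\t3", "B\t2\t4"), p3)
  btab <- read_count_table(p3, dialect = "biom-text")
  expect_equal(unname(rowSums(btab)), c(3, 7))
  expect_equal(rownames(btab), c("s1", "s2"))
})

test_that("metadata reader validates coordinates and keeps numeric env", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "m.csv")
  writeLines(c("sample_id,latitude,longitude,pH",
               "s1,10,100,6.5", "s2,11,101,7.0", "s3,12,102,5.5"), p)
  si <- read_metadata(p)
  expect_s3_class(si, "sample_info")
  expect_equal(nrow(si), 3)
  expect_equal(names(si), c("sample_id", "latitude", "longitude", "pH"))

  writeLines(c("sample_id,latitude,longitude,pH", "s1,95,100,6.5"), p)
  expect_error(read_metadata(p), "latitude")
  writeLines(c("sample_id,longitude,pH", "s1,100,6.5"), p)
  expect_error(read_metadata(p), "missing column")
  # extra text column ignored with a warning
  writeLines(c("sample_id,latitude,longitude,pH,note",
               "s1,10,100,6.5,dry", "s2,11,101,7.0,wet"), p)
  expect_warning(si <- read_metadata(p), "non-numeric")
  expect_false("note" %in% names(si))
})

test_that("rarefaction conserves depth, support and expected proportions", {
  # single-OTU sample is forced
  tab <- toy_table(matrix(c(10, 0, 0), 1))
  r <- rarefy(tab, 5, seed = 1)
  expect_equal(as.vector(unclass(r)), c(5, 0, 0))

  # all row sums equal depth; zero cells stay zero
  set.seed(3)
  m <- matrix(rpois(24, 20), 4, 6)
  m[2, 3] <- 0L
  tab <- toy_table(m)
  r <- rarefy(tab, 30, seed = 9)
  expect_true(all(rowSums(r) == 30))
  expect_equal(r[2, 3], 0L)
  expect_identical(unclass(rarefy(tab, 30, seed = 9)),
                   unclass(rarefy(tab, 30, seed = 9)))

  # undersampled samples are named
  m2 <- m; m2[1, ] <- 0L; m2[1, 1] <- 3L
  expect_error(rarefy(toy_table(m2), 30), "S1")

  # hypergeometric mean: mean rarefied proportion over seeds matches the
  # original proportions within 3 standard errors
  x <- c(50, 30, 15, 5)
  tab1 <- toy_table(matrix(x, 1))
  depth <- 40
  reps <- t(vapply(1:1000, function(s) unclass(rarefy(tab1, depth, seed = s))[1, ],
                   numeric(4)))
  expected <- depth * x / sum(x)
  se <- apply(reps, 2, sd) / sqrt(nrow(reps))
  expect_true(all(abs(colMeans(reps) - expected) <= 3 * pmax(se, 1e-9)))
})

test_that("dominant-group filter applies pooled abundance and presence rules", {
  # group A in 8/10 samples at ~2%; group B in 7/10 at ~5%; C dominates.
  m <- matrix(0L, 10, 3, dimnames = list(paste0("s", 1:10), c("a1", "b1", "c1")))
  m[, "c1"] <- 100L
  m[1:8, "a1"] <- 3L   # pooled 24/1059 = 2.3%
  m[1:7, "b1"] <- 5L   # pooled 35/1059 = 3.3% but presence 70%
  taxa <- data.frame(otu_id = c("a1", "b1", "c1"), group = c("A", "B", "C"))
  got <- filter_dominant_groups(count_table(m), taxa)
  expect_setequal(names(got), c("A", "C"))
  expect_equal(colnames(got$A), "a1")
  expect_equal(nrow(got$A), 10)  # all samples retained

  # 0.5% pooled abundance excluded at defaults even with full presence
  m2 <- cbind(rare = rep(1L, 10), common = rep(199L, 10))
  rownames(m2) <- paste0("s", 1:10)
  taxa2 <- data.frame(otu_id = c("rare", "common"), group = c("R", "K"))
  got2 <- filter_dominant_groups(count_table(m2), taxa2)
  expect_setequal(names(got2), c("K"))

  # subsets partition a subset of the OTUs (no OTU in two groups)
  all_otus <- unlist(lapply(got, colnames))
  expect_false(anyDuplicated(all_otus) > 0)

  expect_error(filter_dominant_groups(count_table(m2),
                                      data.frame(otu_id = "rare", group = "R")),
               "missing from the taxon map")
})
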