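test_that("omics matrices round-trip through disk in both orientations", {
  x <- matrix(c(1.5, 2, 0, 3.25, 4, 5e-3), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"), c("fA", "fB")))
  m <- omics_matrix(x, view_name = "toy")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_omics_matrix(m, path)
  back <- read_omics_matrix(path, orientation = "samples")
  expect_identical(back$sample_ids, m$sample_ids)
  expect_identical(back$feature_ids, m$feature_ids)
  expect_equal(back$values, m$values)

  # transposed file with features in rows gives the identical object
  tpath <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(feature = colnames(x), t(x), check.names = FALSE)
  utils::write.table(df, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  tback <- read_omics_matrix(tpath, orientation = "features")
  expect_equal(tback$values, unname(m$values), ignore_attr = TRUE)
  expect_identical(rownames(tback$values), rownames(x))
})

test_that("malformed tables are rejected with informative errors", {
  expect_error(omics_matrix(matrix(1:4, 2, 2,
                                   dimnames = list(c("a", "a"), c("f", "g")))),
               "duplicate sample")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tf1\tf2", "s1\t1\tx", "s2\t2\t3"), path)
  expect_error(read_omics_matrix(path), "non-numeric")
})

test_that("align_samples intersects, orders, and is idempotent", {
  mk <- function(ids, name) {
    omics_matrix(matrix(seq_along(ids) * 1.0, length(ids), 1,
                        dimnames = list(ids, "f")), view_name = name)
  }
  ds <- multi_omics_dataset(list(mk(c("c", "a", "b"), "v1"),
                                 mk(c("b", "c", "d"), "v2")))
  al <- align_samples(ds)
  expect_identical(al$views[[1]]$sample_ids, c("b", "c"))
  expect_identical(al$views[[2]]$sample_ids, c("b", "c"))
  al2 <- align_samples(al)
  expect_equal(al2$views, al$views)

  same <- multi_omics_dataset(list(mk(c("a", "b", "c"), "v1"),
                                   mk(c("c", "b", "a"), "v2")))
  expect_setequal(align_samples(same)$views[[1]]$sample_ids, c("a", "b", "c"))

  disjoint <- multi_omics_dataset(list(mk(c("a", "b"), "v1"),
                                       mk(c("c", "d"), "v2")))
  expect_error(align_samples(disjoint), "no samples shared")
})

test_that("samples with missing survival are dropped during alignment", {
  ids <- c("a", "b", "c", "d")
  m <- omics_matrix(matrix(rnorm(8), 4, 2, dimnames = list(ids, c("f", "g"))))
  sv <- survival_table(ids, c(1, NA, 3, 4), c(1, 1, NA, 0))
  al <- align_samples(multi_omics_dataset(list(m), survival = sv))
  expect_identical(al$views[[1]]$sample_ids, c("a", "d"))
  expect_identical(al$survival$sample_ids, c("a", "d"))
})

test_that("zero-fraction filter keeps the 30% boundary and drops above it", {
  x <- cbind(
    four_zeros = c(rep(0, 4), 1:6),            # 40% zeros -> dropped
    three_zeros = c(rep(0, 3), 1:7),           # 30% zeros -> kept
    has_na = c(NA, 1:9),                       # missing -> dropped
    constant = rep(2, 10),                     # zero variance -> dropped
    dense = rnorm(10)
  )
  rownames(x) <- paste0("s", 1:10)
  f <- filter_expression_features(omics_matrix(x))
  expect_identical(f$feature_ids, c("three_zeros", "dense"))

  dense_only <- omics_matrix(x[, c("three_zeros", "dense")])
  expect_identical(filter_expression_features(dense_only)$values,
                   dense_only$values)
  expect_error(filter_expression_features(omics_matrix(x[, "constant",
                                                         drop = FALSE])),
               "all features removed")
})

test_that("log2 transform matches hand values and rejects negatives", {
  m <- omics_matrix(matrix(c(0, 3, 1, 7), 2, 2,
                           dimnames = list(c("a", "b"), c("f", "g"))))
  lt <- log2_transform(m)
  expect_equal(lt$values[1, 1], 0)          # log2(0 + 1)
  expect_equal(lt$values[2, 1], 2)          # log2(3 + 1)
  expect_equal(lt$values[2, 2], 3)          # log2(7 + 1)
  neg <- omics_matrix(matrix(c(-1, 1, 2, 3), 2, 2))
  expect_error(log2_transform(neg), "nonnegative")
})

test_that("duplicate probes are averaged and constant features dropped", {
  x <- cbind(p1 = c(0.2, 0.6), p2 = c(0.4, 0.8), p3 = c(0.9, 0.1),
             flat = c(0.5, 0.5))
  rownames(x) <- c("s1", "s2")
  m <- omics_matrix(x)
  f <- filter_variance(m, feature_groups = c("gA", "gA", "gB", "gC"))
  expect_identical(f$feature_ids, c("gA", "gB"))
  expect_equal(unname(f$values[, "gA"]), c(0.3, 0.7))  # mean of p1, p2
  # no duplicates, all variable: unchanged
  nodup <- omics_matrix(x[, c("p1", "p3")])
  expect_equal(filter_variance(nodup)$values, nodup$values)
})

test_that("clinical tables validate types and record missingness", {
  ct <- clinical_table(c("a", "b", "c"),
                       list(age = c(60, NA, 70), stage = c("I", "II", "II")),
                       types = c(age = "numeric", stage = "categorical"))
  expect_equal(unname(ct$missingness["age"]), 1 / 3)
  expect_error(
    clinical_table(c("a", "b"), list(age = c("x", "y")),
                   types = c(age = "numeric")),
    "tagged numeric")
})
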