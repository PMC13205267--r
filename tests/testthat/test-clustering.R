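test_that("spectral clustering recovers ideal block structure exactly", {
  s <- matrix(0, 6, 6)
  s[1:3, 1:3] <- 0.8
  s[4:6, 4:6] <- 0.6
  diag(s) <- 1
  cl <- spectral_cluster(s, 2, seed = 1)
  expect_equal(adjusted_rand_index(cl$labels, rep(1:2, each = 3)), 1)
  # invariance to uniform scaling of S
  cl2 <- spectral_cluster(s * 10, 2, seed = 1)
  expect_identical(cl$labels, cl2$labels)
  expect_error(spectral_cluster(s, 6, seed = 1), "smaller")
  expect_error(spectral_cluster(s, 1, seed = 1), ">= 2")
})

test_that("duplicating samples preserves the partition of the originals", {
  set.seed(44)
  base <- matrix(0, 8, 8)
  base[1:4, 1:4] <- 0.7 + matrix(runif(16, 0, 0.1), 4)
  base[5:8, 5:8] <- 0.7 + matrix(runif(16, 0, 0.1), 4)
  base <- (base + t(base)) / 2
  diag(base) <- 1
  big <- base[rep(1:8, 2), rep(1:8, 2)]
  cl_small <- spectral_cluster(base, 2, seed = 2)
  cl_big <- spectral_cluster(big, 2, seed = 2)
  expect_equal(adjusted_rand_index(cl_small$labels, cl_big$labels[1:8]), 1)
  expect_equal(adjusted_rand_index(cl_big$labels[1:8], cl_big$labels[9:16]), 1)
})

test_that("eigengap selection finds planted block counts", {
  s <- matrix(0, 8, 8)
  s[1:4, 1:4] <- 0.9
  s[5:8, 5:8] <- 0.9
  diag(s) <- 1
  expect_identical(select_k(s), 2L)
  # planted k = 4 stochastic-block similarity
  hits <- 0
  for (seed in 1:5) {
    bg <- generate_block_graph(15, 4, 0.8, 0.1, seed = seed)
    if (select_k(bg$adjacency) == 4L) hits <- hits + 1
  }
  expect_gte(hits, 4)
  # single block: k_min with a warning
  one <- matrix(1, 5, 5)
  expect_warning(k1 <- select_k(one), "flat|k_min")
  expect_identical(k1, 2L)
})

test_that("log-rank matches the risk-set oracle and its degenerate case", {
  # identical survival in both groups: statistic 0, p = 1
  sv <- survival_table(letters[1:6], rep(c(1, 2, 3), 2), rep(1, 6))
  lr <- logrank_test(sv, rep(1:2, each = 3))
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  expect_error(logrank_test(sv, rep(1, 6)), "two nonempty")

  set.seed(77)
  done <- 0
  while (done < 20) {
    n <- sample(8:30, 1)
    g <- sample(2:3, 1)
    time <- round(runif(n, 0.1, 10), 2)
    event <- rbinom(n, 1, 0.7)
    group <- sample(seq_len(g), n, replace = TRUE)
    if (length(unique(group)) < g || sum(event) < 3) next
    orc <- tryCatch(logrank_oracle(time, event, group),
                    error = function(e) NULL)
    if (is.null(orc) || !is.finite(orc$chi2)) next
    sv <- survival_table(paste0("s", seq_len(n)), time, event)
    got <- logrank_test(sv, group)
    expect_equal(got$chi2, orc$chi2, tolerance = 1e-6)
    expect_equal(got$p, orc$p, tolerance = 1e-6)
    done <- done + 1
  }
})

test_that("clinical enrichment applies the right test per column type", {
  labels <- rep(1:2, each = 10)
  perfect <- c(rep("x", 10), rep("y", 10))       # 2x2 table [[10,0],[0,10]]
  age <- c(rnorm(10, 50, 2), rnorm(10, 70, 2))   # strongly separated
  ct <- clinical_table(sprintf("s%02d", 1:20),
                       list(marker = perfect, age = age),
                       types = c(marker = "categorical", age = "numeric"))
  rep_ <- suppressWarnings(clinical_enrichment(ct, labels))
  tab <- rep_$table
  expect_equal(tab$statistic[tab$column == "marker"], 20)
  expect_identical(tab$test[tab$column == "age"], "kruskal-wallis")
  expect_true(all(tab$p_adjusted >= tab$p))
  expect_equal(rep_$n_significant, sum(tab$p_adjusted < 0.05))
  # single-level column is skipped and excluded from the family
  ct2 <- clinical_table(sprintf("s%02d", 1:20),
                        list(flat = rep("z", 20), marker = perfect),
                        types = c(flat = "categorical",
                                  marker = "categorical"))
  expect_warning(rep2 <- clinical_enrichment(ct2, labels), "single level")
  expect_equal(nrow(rep2$table), 1)
})

test_that("ARI behaves at its reference points and matches mclust", {
  a <- rep(1:3, each = 10)
  expect_equal(adjusted_rand_index(a, a), 1)
  relab <- c(3, 1, 2)[a]
  expect_equal(adjusted_rand_index(a, relab), 1)
  set.seed(99)
  b <- sample(1:3, 3000, replace = TRUE)
  cc <- sample(1:3, 3000, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(b, cc)), 0.05)
  skip_if_not_installed("mclust")
  for (rep in 1:10) {
    x <- sample(1:4, 50, replace = TRUE)
    y <- sample(1:3, 50, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
})
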