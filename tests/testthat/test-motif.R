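test_that("gaussian similarity matches its closed form", {
  X <- rbind(c(0, 0), c(1, 1))
  s <- gaussian_similarity(X, sigma = 1)
  expect_equal(s$values[1, 2], exp(-1), tolerance = 1e-12)
  expect_equal(diag(s$values), c(1, 1), ignore_attr = TRUE)

  set.seed(3)
  Xr <- matrix(rnorm(40), 8, 5)
  sr <- gaussian_similarity(Xr, sigma = "auto")$values
  expect_identical(sr, t(sr))
  expect_true(all(sr > 0 & sr <= 1))
  expect_error(gaussian_similarity(Xr, sigma = -1), "positive")
})

test_that("median thresholding keeps ties and zeroes the diagonal", {
  s <- diag(3)
  s[1, 2] <- s[2, 1] <- 0.9
  s[1, 3] <- s[3, 1] <- 0.5
  s[2, 3] <- s[3, 2] <- 0.1
  tg <- threshold_graph(s)
  expect_equal(tg$threshold, 0.5)
  expect_equal(sum(tg$binary) / 2, 2)               # 0.9 and 0.5 kept
  expect_equal(tg$weighted[1, 2], 0.9)
  expect_equal(tg$weighted[1, 3], 0.5)
  expect_equal(tg$weighted[2, 3], 0)
  expect_true(all(diag(tg$binary) == 0))

  # all equal off-diagonal: complete graph
  u <- matrix(0.4, 4, 4); diag(u) <- 1
  expect_equal(sum(threshold_graph(u)$binary), 4 * 3)
})

test_that("triangle counts reproduce worked K3, K4 and path cases", {
  k3 <- matrix(1, 3, 3) - diag(3)
  m3 <- count_triangle_motifs(k3)
  expect_true(all(m3$values[upper.tri(m3$values)] == 1))
  expect_equal(m3$triangle_count, 1L)

  k4 <- matrix(1, 4, 4) - diag(4)
  m4 <- count_triangle_motifs(k4)
  expect_true(all(m4$values[upper.tri(m4$values)] == 2))
  expect_equal(m4$triangle_count, 4L)

  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  expect_true(all(count_triangle_motifs(path)$values == 0))

  expect_error(count_triangle_motifs(matrix(c(0, 1, 0, 0), 2, 2)),
               "symmetric")
})

test_that("triangle counts equal brute-force enumeration on random graphs", {
  set.seed(17)
  for (rep in 1:30) {
    n <- sample(5:30, 1)
    p <- runif(1, 0.1, 0.5)
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, p)
    a <- a + t(a)
    got <- count_triangle_motifs(a)
    want <- triangle_oracle(a)
    expect_identical(unname(got$values), want$values)
    expect_identical(got$triangle_count, as.integer(want$triangle_count))
    expect_equal(sum(got$values[upper.tri(got$values)]),
                 3 * got$triangle_count)
  }
})

test_that("motif weighting multiplies counts by retained edge weights", {
  k3 <- matrix(1, 3, 3) - diag(3)
  w3 <- k3 * 0.5
  m <- motif_weighted_similarity(count_triangle_motifs(k3), w3)
  expect_true(all(m[upper.tri(m)] == 0.5))
  k4 <- matrix(1, 4, 4) - diag(4)
  m4 <- motif_weighted_similarity(count_triangle_motifs(k4), k4 * 0.5)
  expect_true(all(m4[upper.tri(m4)] == 1.0))
  expect_error(motif_weighted_similarity(matrix(0, 2, 2), matrix(0, 3, 3)),
               "shape")
})

test_that("hybrid blend is a convex combination with rescaled motif term", {
  set.seed(4)
  S <- random_affinity(6) + diag(6)
  M <- random_affinity(6) * 3
  h1 <- hybrid_similarity(S, M, eta = 1)
  expect_equal(h1$hybrid, S)
  h0 <- hybrid_similarity(S, M, eta = 0)
  expect_equal(h0$hybrid, h0$motif_sim)
  expect_equal(range(h0$motif_sim), c(0, 1))
  # midpoint blend on engineered entries
  Sm <- matrix(c(0, 0.8, 0.8, 0), 2, 2)
  Mm <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  hm <- hybrid_similarity(Sm, Mm, eta = 0.5)
  # rescaled M has max 0.4 -> 1; blend = 0.5*0.8 + 0.5*1
  expect_equal(hm$hybrid[1, 2], 0.9)
  expect_error(hybrid_similarity(S, M, eta = 1.5), "eta")
})

test_that("stage-2 outputs keep their typed symmetries", {
  set.seed(8)
  X <- matrix(rnorm(20 * 6), 20, 6)
  g <- build_view_graph(X, eta = 0.5)
  expect_identical(g$S, t(g$S))
  expect_identical(unname(g$WM$values), unname(t(g$WM$values)))
  expect_equal(g$A, t(g$A))
  expect_true(all(g$A >= 0 & g$A <= 1))
  expect_true(all(diag(g$threshold_graph$binary) == 0))
  expect_true(all(g$WM$values[g$threshold_graph$binary == 0] == 0))
})
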