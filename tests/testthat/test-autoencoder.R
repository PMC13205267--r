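test_that("l21 norm matches hand values and norm axioms", {
  expect_equal(l21_norm(matrix(0, 3, 3)), 0)
  expect_equal(l21_norm(diag(2)), 2)
  expect_equal(l21_norm(rbind(c(3, 4), c(0, 0))), 5)
  set.seed(13)
  for (rep in 1:20) {
    A <- matrix(rnorm(12), 3, 4)
    B <- matrix(rnorm(12), 3, 4)
    c1 <- rnorm(1)
    expect_equal(l21_norm(c1 * A), abs(c1) * l21_norm(A), tolerance = 1e-12)
    expect_lte(l21_norm(A + B), l21_norm(A) + l21_norm(B) + 1e-12)
  }
})

test_that("loss terms match their closed forms", {
  X <- matrix(0, 2, 3)
  Xr <- matrix(1, 2, 3)
  expect_equal(reconstruction_loss(X, X), 0)
  expect_equal(reconstruction_loss(X, Xr, n = 2), 6 / 4)
  expect_equal(reconstruction_loss(X, 3 * Xr, n = 2),
               9 * reconstruction_loss(X, Xr, n = 2))

  set.seed(2)
  Z <- matrix(rnorm(12), 4, 3)
  C <- matrix(rnorm(16), 4, 4); diag(C) <- 0
  expect_equal(self_expression_loss(Z, matrix(0, 4, 4), 2, 3),
               2 * sum(Z^2))
  expect_equal(self_expression_loss(matrix(0, 4, 3), C, 2, 3), 3 * sum(C^2))

  A <- random_affinity(4)
  expect_equal(high_order_alignment_loss(A, A, 5), 0)
  expect_equal(high_order_alignment_loss(matrix(1, 2, 2), matrix(0, 2, 2), 2),
               8)
  expect_equal(high_order_alignment_loss(A, C, 7),
               high_order_alignment_loss(C, A, 7))
})

test_that("encode_decode is deterministic and shape-checked", {
  set.seed(6)
  st <- init_encoder_state(5, 4, 3)
  X <- matrix(rnorm(40), 8, 5)
  f1 <- encode_decode(X, st)
  f2 <- encode_decode(X, st)
  expect_identical(f1$Xrec, f2$Xrec)
  expect_equal(dim(f1$Z), c(8, 3))
  expect_error(encode_decode(matrix(0, 4, 7), st), "dimension")
  # with C supplied the decoder consumes the self-expressed codes
  C <- matrix(rnorm(64, sd = 0.2), 8, 8); diag(C) <- 0
  fc <- encode_decode(X, st, C = C)
  expect_equal(fc$Zc, C %*% fc$Z)
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(42)
  n <- 6; d <- 4; V <- 2
  Xs <- lapply(1:V, function(v) matrix(rnorm(n * d), n, d))
  states <- lapply(1:V, function(v) init_encoder_state(d, 4, 3))
  A_list <- lapply(1:V, function(v) random_affinity(n))
  Cs <- lapply(1:V, function(v) {
    C <- matrix(rnorm(n * n, sd = 0.3), n, n); diag(C) <- 0; C
  })
  att_W <- matrix(runif(n * V * V, 0.5, 1.5), n * V, V)
  L_surr <- lapply(1:V, function(v) matrix(rnorm(n * n, sd = 0.1), n, n))
  cfg <- train_config(alpha = 0.05, lambda1 = 0.7, lambda2 = 0.3,
                      lambda3 = 0.4, beta = 0.6, tnn_weight = 0.2,
                      p1 = 4, p2 = 3)
  Csym <- lapply(Cs, symmetrize_affinity)
  att <- attention_weights(Csym, att_W, slope = cfg$leaky_slope)
  cons <- normalize_f1(fuse_graphs(Csym, att))
  P <- target_distribution_f2(cons)

  smooth_loss <- function(Cs, att_W, states) {
    tot <- 0
    Csym <- lapply(Cs, symmetrize_affinity)
    for (v in 1:V) {
      fwd <- encode_decode(Xs[[v]], states[[v]], C = Cs[[v]])
      tot <- tot + reconstruction_loss(Xs[[v]], fwd$Xrec, n) +
        cfg$alpha * l21_norm(states[[v]]$W1) +
        self_expression_loss(fwd$Z, Cs[[v]], cfg$lambda1, cfg$lambda2) +
        high_order_alignment_loss(A_list[[v]], Cs[[v]], cfg$lambda3) +
        cfg$tnn_weight * sum((Cs[[v]] - L_surr[[v]])^2)
    }
    att <- attention_weights(Csym, att_W, slope = cfg$leaky_slope)
    cons <- normalize_f1(fuse_graphs(Csym, att))
    tot + cfg$beta * kl_refinement(P, cons)
  }

  DCF <- mhsgtr:::kl_grad_wrt_cf(P, cons, cfg$beta)
  fb <- mhsgtr:::fusion_backprop(DCF, Csym, att)
  v <- 1
  fwd <- encode_decode(Xs[[v]], states[[v]], C = Cs[[v]])
  E <- fwd$Z - Cs[[v]] %*% fwd$Z
  g <- mhsgtr:::backprop_view(
    Xs[[v]], states[[v]], fwd, cfg$alpha, n, C = Cs[[v]],
    dZ_extra = 2 * cfg$lambda1 * (E - t(Cs[[v]]) %*% E))
  dC <- g$dC - 2 * cfg$lambda1 * E %*% t(fwd$Z) + 2 * cfg$lambda2 * Cs[[v]] -
    2 * cfg$lambda3 * (A_list[[v]] - Cs[[v]]) +
    2 * cfg$tnn_weight * (Cs[[v]] - L_surr[[v]])
  Dv <- fb$dGraphs[[v]]
  dC <- dC + sign(Cs[[v]]) * (Dv + t(Dv)) / 2

  relerr <- function(a, b)
    max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
  numgrad <- function(p0, wrap, eps = 1e-6) {
    gn <- p0 * 0
    for (i in seq_along(p0)) {
      pp <- p0; pp[i] <- p0[i] + eps; lp <- wrap(pp)
      pp[i] <- p0[i] - eps; lm <- wrap(pp)
      gn[i] <- (lp - lm) / (2 * eps)
    }
    gn
  }

  gn_C <- numgrad(Cs[[1]], function(p) {
    Cs2 <- Cs; Cs2[[1]] <- p; smooth_loss(Cs2, att_W, states)
  })
  expect_lt(relerr(dC, gn_C), 1e-4)

  gn_W <- numgrad(att_W, function(p) smooth_loss(Cs, p, states))
  expect_lt(relerr(fb$dW, gn_W), 1e-4)

  for (nm in c("W1", "W2", "W3", "W4", "b2", "b4")) {
    gn <- numgrad(states[[1]][[nm]], function(p) {
      st2 <- states; st2[[1]][[nm]] <- p; smooth_loss(Cs, att_W, st2)
    })
    expect_lt(relerr(g[[nm]], gn), 1e-4)
  }
})
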