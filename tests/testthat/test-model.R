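test_that("positional encoding follows the sinusoidal closed form", {
  pe <- positional_encoding(10, 8)
  expect_equal(pe[1, seq(1, 8, 2)], rep(0, 4))  # sin at position 0
  expect_equal(pe[1, seq(2, 8, 2)], rep(1, 4))  # cos at position 0
  expect_true(all(pe >= -1 & pe <= 1))
  expect_equal(pe[2, 1], sin(1))
  expect_equal(positional_encoding(5, 12)[2, 1], sin(1))
  expect_error(positional_encoding(4, 7), "even")
})

test_that("attention reproduces hand-computed softmax weighting", {
  # singleton: weight 1, output = V row
  out <- attention(matrix(1, 1, 2), matrix(2, 1, 2), matrix(5, 1, 1))
  expect_equal(out$weights[1, 1], 1)
  expect_equal(out$context[1, 1], 5)
  # zero queries: uniform weights, output = column means of V
  V <- matrix(rnorm(6), 3, 2)
  out <- attention(matrix(0, 2, 4), matrix(rnorm(12), 3, 4), V)
  expect_equal(out$weights, matrix(1 / 3, 2, 3))
  expect_equal(out$context, rbind(colMeans(V), colMeans(V)))
  # 2-token closed form with d_k = 1
  out <- attention(matrix(c(1, 0), 2, 1), matrix(c(1, 0), 2, 1),
                   matrix(c(1, 0), 2, 1))
  w <- exp(1) / (exp(1) + 1)
  expect_equal(out$weights[1, ], c(w, 1 - w))
  expect_equal(out$context[1, 1], w)
  expect_equal(rowSums(out$weights), c(1, 1))
})

test_that("SE gating obeys its zero-weight and zero-input closed forms", {
  L <- 6; C <- 8; r <- 4
  U <- matrix(rnorm(L * C), L, C)
  W0 <- matrix(0, C, C / r); W0b <- matrix(0, C / r, C)
  out <- se_block(U, W0, W0b)
  expect_equal(attr(out, "gates"), rep(0.5, C))  # sigmoid(0) gates
  expect_equal(unclass(out)[, ], U / 2)
  W1 <- matrix(rnorm(C * C / r), C, C / r)
  W2 <- matrix(rnorm(C / r * C), C / r, C)
  expect_equal(unclass(se_block(U * 0, W1, W2))[, ], U * 0)
  g <- attr(se_block(U, W1, W2), "gates")
  expect_true(all(g > 0 & g < 1))
})

test_that("multi-head attention with one head equals plain attention", {
  d <- 6; L <- 5
  X <- matrix(rnorm(L * d), L, d)
  id <- diag(d)
  W <- list(Wq = matrix(rnorm(d * d), d), Wk = matrix(rnorm(d * d), d),
            Wv = matrix(rnorm(d * d), d), Wo = id, n_heads = 1)
  ref <- attention(X %*% W$Wq, X %*% W$Wk, X %*% W$Wv)$context
  expect_equal(multi_head(X, W), ref)
  # output shape preserved for several heads
  W$n_heads <- 3
  W$Wo <- matrix(rnorm(d * d), d)
  expect_equal(dim(multi_head(X, W)), c(L, d))
})

test_that("encoder layer normalises tokens and is deterministic in eval mode", {
  d <- 8; L <- 5
  p <- list(Wq = matrix(rnorm(d * d), d), Wk = matrix(rnorm(d * d), d),
            Wv = matrix(rnorm(d * d), d), Wo = matrix(rnorm(d * d), d),
            n_heads = 2, ln1_g = rep(1, d), ln1_b = rep(0, d),
            ffn_W1 = matrix(rnorm(d * 12), d, 12), ffn_b1 = rep(0, 12),
            ffn_W2 = matrix(rnorm(12 * d), 12, d), ffn_b2 = rep(0, d),
            ln2_g = rep(1, d), ln2_b = rep(0, d))
  X <- matrix(rnorm(L * d), L, d)
  out1 <- encoder_layer(X, p)
  out2 <- encoder_layer(X, p)
  expect_identical(out1, out2)
  expect_equal(dim(out1), dim(X))
  # with unit gain / zero bias the LayerNorm contract holds exactly
  expect_equal(rowMeans(out1), rep(0, L), tolerance = 1e-10)
  expect_equal(apply(out1, 1, function(r) mean(r^2)), rep(1, L),
               tolerance = 1e-4)
  # stacking preserves shape
  for (i in 1:4) X <- encoder_layer(X, p)
  expect_equal(dim(X), c(L, d))
})

test_that("compiled batch forward matches the composed reference primitives", {
  mc <- tiny_model_config()
  set.seed(5)
  X <- matrix(rnorm(4 * 7), 4, 7)
  for (v in c("mt_ctse", "mt_cnn_transformer", "mt_transformer_se",
              "mt_transformer", "mt_cnn", "st_transformer_task2")) {
    net <- build_network(mc, v, seed = 11)
    a <- net_forward(net, X)
    b <- spectramt:::r_forward(net, X)
    if (!is.null(a$p1)) {
      expect_equal(a$p1, b$p1, tolerance = 1e-12)
      expect_equal(rowSums(a$p1), rep(1, 4), tolerance = 1e-6)
    }
    if (!is.null(a$p2)) expect_equal(a$p2, b$p2, tolerance = 1e-12)
  }
})

test_that("ablation variants differ only by the stated components", {
  mc <- tiny_model_config()
  blocks <- function(v) build_network(mc, v, seed = 1)$layout$name
  full <- blocks("mt_ctse")
  no_se <- blocks("mt_cnn_transformer")
  no_cnn <- blocks("mt_transformer_se")
  bare <- blocks("mt_transformer")
  expect_setequal(setdiff(full, no_se), c("se_W1", "se_W2"))
  expect_setequal(setdiff(full, no_cnn), c("conv1_W", "conv1_b", "conv2_W", "conv2_b"))
  expect_setequal(setdiff(full, bare),
                  c("se_W1", "se_W2", "conv1_W", "conv1_b", "conv2_W", "conv2_b"))
  expect_false(any(grepl("enc", blocks("mt_cnn"))))
  # MT and ST backbones have identical sizes; MT adds exactly one head
  lay_mt <- build_network(mc, "mt_ctse", seed = 1)$layout
  lay_st <- build_network(mc, "st_ctse_task1", seed = 1)$layout
  extra <- setdiff(lay_mt$name, lay_st$name)
  expect_setequal(extra, c("head2_W", "head2_b"))
  shared <- lay_mt[lay_mt$name %in% lay_st$name, c("name", "size")]
  expect_equal(shared, lay_st[, c("name", "size")])
})

test_that("single-task variants expose exactly one head", {
  mc <- tiny_model_config()
  st1 <- net_forward(build_network(mc, "st_ctse_task1", seed = 2),
                     matrix(rnorm(14), 2, 7))
  expect_null(st1$p2)
  expect_false(is.null(st1$p1))
  st2 <- net_forward(build_network(mc, "st_cnn_task2", seed = 2),
                     matrix(rnorm(14), 2, 7))
  expect_null(st2$p1)
  expect_false(is.null(st2$p2))
})

test_that("analytic gradients match finite differences", {
  mc <- tiny_model_config()
  net <- build_network(mc, "mt_ctse", seed = 7)
  set.seed(8)
  X <- matrix(rnorm(4 * 7), 4, 7)
  y1 <- sample(1:3, 4, TRUE); y2 <- sample(1:3, 4, TRUE)
  # through the SE block, one encoder layer, and the full network
  expect_lt(fd_check(net, X, y1, y2, blocks = "^se_"), 1e-3)
  expect_lt(fd_check(net, X, y1, y2, blocks = "^enc1_"), 1e-3)
  expect_lt(fd_check(net, X, y1, y2, per_block = 3), 1e-3)
})

test_that("unbalanced task weights annihilate the idle head's gradient", {
  mc <- tiny_model_config()
  net <- build_network(mc, "mt_ctse", seed = 3)
  cfg <- spectramt:::cpp_cfg(net$config, net$variant)
  set.seed(4)
  X <- matrix(rnorm(4 * 7), 4, 7)
  y1 <- sample(1:3, 4, TRUE); y2 <- sample(1:3, 4, TRUE)
  g <- spectramt:::cpp_loss_grad(cfg, net$params, X, y1, y2, 0.5, 0)
  lay <- net$layout
  h2 <- lay[lay$name %in% c("head2_W", "head2_b"), ]
  idx2 <- unlist(mapply(function(o, s) o:(o + s - 1), h2$offset, h2$size))
  expect_equal(g$grad[idx2], rep(0, length(idx2)))
  h1 <- lay[lay$name == "head1_W", ]
  expect_gt(max(abs(g$grad[h1$offset:(h1$offset + h1$size - 1)])), 0)
})
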