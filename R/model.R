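#' Network architecture configuration
#'
#' Hyperparameters of the multi-task spectral classifier: a 1-D convolutional
#' stack over the selected bands, a channel-wise squeeze-and-excitation (SE)
#' gate, a sinusoidal-position Transformer encoder, and one softmax head per
#' task sharing every backbone parameter.
#'
#' @param n_bands_in input sequence length (number of selected bands).
#' @param conv_channels per-layer channel counts of the CNN stack.
#' @param conv_kernel odd convolution width.
#' @param se_reduction SE bottleneck ratio (gates act on `d_model` channels).
#' @param d_model token width of the encoder.
#' @param n_heads attention heads; must divide `d_model`.
#' @param n_layers encoder depth.
#' @param ffn_dim hidden width of the position-wise feed-forward network.
#' @param dropout dropout probability in \[0, 1), applied inside encoder
#'   layers during training.
#' @param n_classes_task1,n_classes_task2 class counts of the variety and
#'   storage-period heads.
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_bands_in = 21L, conv_channels = c(32L, 64L),
                         conv_kernel = 5L, se_reduction = 4L, d_model = 64L,
                         n_heads = 4L, n_layers = 4L, ffn_dim = 128L,
                         dropout = 0.2, n_classes_task1 = 3L,
                         n_classes_task2 = 3L) {
  if (d_model %% n_heads != 0) stop("d_model must be divisible by n_heads")
  if (d_model %% 2 != 0) stop("d_model must be even")
  if (conv_kernel %% 2 == 0) stop("conv_kernel must be odd")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  structure(list(n_bands_in = as.integer(n_bands_in),
                 conv_channels = as.integer(conv_channels),
                 conv_kernel = as.integer(conv_kernel),
                 se_reduction = as.integer(se_reduction),
                 d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers), ffn_dim = as.integer(ffn_dim),
                 dropout = dropout,
                 n_classes_task1 = as.integer(n_classes_task1),
                 n_classes_task2 = as.integer(n_classes_task2)),
            class = "model_config")
}

#' Model variants
#'
#' Multi-task (`mt_`) variants expose both heads; single-task (`st_`)
#' variants exactly one. The ablations drop the CNN stack and/or the SE gate
#' while leaving everything else identical, and the `cnn`-only variants drop
#' the encoder.
#'
#' @return Character vector of valid variant codes.
#' @export
model_variants <- function() {
  c("mt_ctse", "mt_cnn_transformer", "mt_transformer_se", "mt_transformer",
    "mt_cnn", "st_ctse_task1", "st_ctse_task2", "st_transformer_task1",
    "st_transformer_task2", "st_cnn_task1", "st_cnn_task2")
}

#' Structural flags of a variant
#'
#' @param variant one of [model_variants()].
#' @return List with logical fields `cnn`, `se`, `encoder`, `task1`, `task2`.
#' @export
variant_flags <- function(variant) {
  variant <- match.arg(variant, model_variants())
  list(
    cnn = variant %in% c("mt_ctse", "mt_cnn_transformer", "mt_cnn",
                         "st_ctse_task1", "st_ctse_task2", "st_cnn_task1",
                         "st_cnn_task2"),
    se = variant %in% c("mt_ctse", "mt_transformer_se", "st_ctse_task1",
                        "st_ctse_task2"),
    encoder = !(variant %in% c("mt_cnn", "st_cnn_task1", "st_cnn_task2")),
    task1 = !(variant %in% c("st_ctse_task2", "st_transformer_task2",
                             "st_cnn_task2")),
    task2 = !(variant %in% c("st_ctse_task1", "st_transformer_task1",
                             "st_cnn_task1"))
  )
}

# config + variant -> the list consumed by the compiled core
cpp_cfg <- function(config, variant) {
  fl <- variant_flags(variant)
  list(L = config$n_bands_in,
       conv_channels = if (fl$cnn) config$conv_channels else integer(0),
       kernel = config$conv_kernel, d_model = config$d_model,
       n_heads = config$n_heads, n_layers = config$n_layers,
       ffn_dim = config$ffn_dim, se_red = config$se_reduction,
       dropout = config$dropout, K1 = config$n_classes_task1,
       K2 = config$n_classes_task2, has_cnn = fl$cnn, has_se = fl$se,
       has_encoder = fl$encoder, has_task1 = fl$task1, has_task2 = fl$task2)
}

#' Build a network with freshly initialised weights
#'
#' Weight matrices get Glorot-normal initialisation from a seeded draw;
#' biases start at zero and LayerNorm gains at one.
#'
#' @param config a [model_config()].
#' @param variant one of [model_variants()].
#' @param seed RNG seed for the initial weights.
#' @return Object of class `ctse_net` with fields `config`, `variant`,
#'   `params` (flat parameter vector) and `layout` (per-block offsets).
#' @export
build_network <- function(config, variant = "mt_ctse", seed = 42L) {
  cfg <- cpp_cfg(config, variant)
  np <- cpp_param_count(cfg)
  z <- with_seed(seed, stats::rnorm(np))
  params <- cpp_init_params(cfg, z)
  structure(list(config = config, variant = variant, params = params,
                 layout = cpp_param_layout(cfg), init_seed = as.integer(seed)),
            class = "ctse_net")
}

#' @export
print.ctse_net <- function(x, ...) {
  cat(sprintf("<ctse_net> variant '%s', %d parameters, input length %d\n",
              x$variant, length(x$params), x$config$n_bands_in))
  invisible(x)
}

#' Forward pass: per-task class probabilities
#'
#' Evaluation-mode (deterministic, dropout off) forward pass of the network
#' on a batch of spectra restricted to its input bands.
#'
#' @param network a [build_network()] (possibly trained) object.
#' @param X numeric matrix, one spectrum per row, `n_bands_in` columns.
#' @return List with `p1` and `p2` (each `NULL` for absent heads): row-wise
#'   softmax probability matrices.
#' @export
net_forward <- function(network, X) {
  stopifnot(inherits(network, "ctse_net"))
  X <- as.matrix(X)
  if (ncol(X) != network$config$n_bands_in) {
    stop("input length must equal n_bands_in")
  }
  cpp_forward(cpp_cfg(network$config, network$variant), network$params, X)
}

#' @rdname net_forward
#' @param ... unused.
#' @return `predict()` returns the probability matrices plus `pred1`/`pred2`
#'   class-index vectors (argmax).
#' @export
predict.ctse_net <- function(object, X, ...) {
  out <- net_forward(object, X)
  out$pred1 <- if (!is.null(out$p1)) max.col(out$p1, ties.method = "first") else NULL
  out$pred2 <- if (!is.null(out$p2)) max.col(out$p2, ties.method = "first") else NULL
  out
}

# ------------------------------------------------------------------------
# Reference implementations of the network primitives. These are the
# readable, single-sample definitions of each block; the compiled batch path
# is verified against their composition in the test suite.
# ------------------------------------------------------------------------

#' Sinusoidal positional encoding
#'
#' `PE(pos, 2i) = sin(pos / 10000^(2i/d))`, `PE(pos, 2i+1) = cos(...)`, with
#' `pos` and `i` counted from zero.
#'
#' @param L sequence length.
#' @param d_model even embedding width.
#' @return `L x d_model` matrix with entries in \[-1, 1\].
#' @export
positional_encoding <- function(L, d_model) {
  if (d_model %% 2 != 0) stop("d_model must be even")
  pos <- 0:(L - 1)
  pe <- matrix(0, L, d_model)
  for (i in 0:(d_model / 2 - 1)) {
    ang <- pos / 10000^((2 * i) / d_model)
    pe[, 2 * i + 1] <- sin(ang)
    pe[, 2 * i + 2] <- cos(ang)
  }
  pe
}

row_softmax <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`; each attention row sums to one.
#'
#' @param Q,K,V numeric matrices; `Q` is `n_q x d_k`, `K` and `V` share
#'   `n_k` rows.
#' @return List with `context` (`n_q x ncol(V)`) and the attention `weights`.
#' @export
attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop("Q and K widths differ")
  if (nrow(K) != nrow(V)) stop("K and V row counts differ")
  W <- row_softmax(Q %*% t(K) / sqrt(ncol(K)))
  list(context = W %*% V, weights = W)
}

#' Squeeze-and-excitation gating
#'
#' Squeeze: global average pool over the sequence axis. Excitation:
#' `s = sigmoid(W2 relu(W1 z))` (no biases). Reweight: every channel of the
#' input is scaled by its gate, which lies in (0, 1).
#'
#' @param U feature matrix `L x C` (one sample) or 3-D array `B x L x C`.
#' @param W1 `C x C/r` bottleneck weights.
#' @param W2 `C/r x C` expansion weights.
#' @return Same shape as `U`, with attribute `gates`.
#' @export
se_block <- function(U, W1, W2) {
  gate <- function(z) 1 / (1 + exp(-(pmax(z %*% W1, 0) %*% W2)))
  if (is.matrix(U)) {
    s <- gate(matrix(colMeans(U), 1))
    out <- sweep(U, 2, drop(s), "*")
    attr(out, "gates") <- drop(s)
    return(out)
  }
  stopifnot(length(dim(U)) == 3)
  out <- U
  gates <- matrix(NA_real_, dim(U)[1], dim(U)[3])
  for (b in seq_len(dim(U)[1])) {
    Ub <- matrix(U[b, , ], dim(U)[2], dim(U)[3])
    s <- gate(matrix(colMeans(Ub), 1))
    out[b, , ] <- sweep(Ub, 2, drop(s), "*")
    gates[b, ] <- drop(s)
  }
  attr(out, "gates") <- gates
  out
}

#' Multi-head self-attention (single sample)
#'
#' Splits `d_model` into `n_heads` equal slices after the Q/K/V projections,
#' runs scaled dot-product attention per head, concatenates the heads and
#' applies the output projection.
#'
#' @param X token matrix `L x d_model`.
#' @param params list with `Wq`, `Wk`, `Wv`, `Wo` (`d_model x d_model`),
#'   optional biases `bq`, `bk`, `bv`, `bo`, and `n_heads`.
#' @return `L x d_model` matrix.
#' @export
multi_head <- function(X, params) {
  d <- ncol(X)
  h <- params$n_heads
  if (d %% h != 0) stop("d_model must be divisible by n_heads")
  dk <- d / h
  addb <- function(M, b) if (is.null(b)) M else sweep(M, 2, b, "+")
  Q <- addb(X %*% params$Wq, params$bq)
  K <- addb(X %*% params$Wk, params$bk)
  V <- addb(X %*% params$Wv, params$bv)
  ctx <- matrix(0, nrow(X), d)
  for (i in seq_len(h)) {
    cols <- ((i - 1) * dk + 1):(i * dk)
    ctx[, cols] <- attention(Q[, cols, drop = FALSE], K[, cols, drop = FALSE],
                             V[, cols, drop = FALSE])$context
  }
  addb(ctx %*% params$Wo, params$bo)
}

layer_norm <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  v <- rowMeans((X - mu)^2)
  nhat <- (X - mu) / sqrt(v + eps)
  sweep(sweep(nhat, 2, gamma, "*"), 2, beta, "+")
}

#' Transformer encoder layer (single sample, evaluation mode)
#'
#' Post-norm arrangement: `X1 = LayerNorm(X + MHA(X))`, then
#' `X' = LayerNorm(X1 + FFN(X1))` with a two-layer ReLU feed-forward network.
#' Dropout is inactive in this reference (evaluation) path.
#'
#' @param X token matrix `L x d_model`.
#' @param params list with the [multi_head()] parameters plus `ln1_g`,
#'   `ln1_b`, `ffn_W1`, `ffn_b1`, `ffn_W2`, `ffn_b2`, `ln2_g`, `ln2_b`.
#' @return `L x d_model` matrix.
#' @export
encoder_layer <- function(X, params) {
  X1 <- layer_norm(X + multi_head(X, params), params$ln1_g, params$ln1_b)
  F1 <- pmax(sweep(X1 %*% params$ffn_W1, 2, params$ffn_b1, "+"), 0)
  F2 <- sweep(F1 %*% params$ffn_W2, 2, params$ffn_b2, "+")
  layer_norm(X1 + F2, params$ln2_g, params$ln2_b)
}

# unpack the flat parameter vector into named blocks via the layout table
unpack_params <- function(network) {
  lay <- network$layout
  out <- list()
  for (i in seq_len(nrow(lay))) {
    idx <- lay$offset[i]:(lay$offset[i] + lay$size[i] - 1)
    v <- network$params[idx]
    out[[lay$name[i]]] <- if (lay$cols[i] > 0) {
      matrix(v, lay$rows[i], lay$cols[i])
    } else {
      v
    }
  }
  out
}

# reference forward pass composed from the single-sample primitives;
# used by the test suite to validate the compiled batch implementation
r_forward <- function(network, X) {
  cfg <- network$config
  fl <- variant_flags(network$variant)
  pp <- unpack_params(network)
  L <- cfg$n_bands_in
  out1 <- NULL; out2 <- NULL
  G <- matrix(0, nrow(X), cfg$d_model)
  for (b in seq_len(nrow(X))) {
    A <- matrix(X[b, ], ncol = 1)
    if (fl$cnn) {
      for (i in seq_along(cfg$conv_channels)) {
        W <- pp[[sprintf("conv%d_W", i)]]
        bb <- pp[[sprintf("conv%d_b", i)]]
        k <- cfg$conv_kernel; pad <- (k - 1) / 2
        Cin <- ncol(A)
        M <- matrix(0, L, Cin * k)
        for (cc in seq_len(Cin)) {
          for (j in seq_len(k)) {
            sh <- (j - 1) - pad
            src <- (1:L) + sh
            okk <- src >= 1 & src <= L
            M[okk, (cc - 1) * k + j] <- A[src[okk], cc]
          }
        }
        A <- pmax(sweep(M %*% W, 2, bb, "+"), 0)
      }
    }
    H <- sweep(A %*% pp$lift_W, 2, pp$lift_b, "+")
    if (fl$se) H <- se_block(H, pp$se_W1, pp$se_W2)
    if (fl$encoder) {
      H <- H + positional_encoding(L, cfg$d_model)
      for (l in seq_len(cfg$n_layers)) {
        p <- sprintf("enc%d_", l)
        H <- encoder_layer(H, list(
          Wq = pp[[paste0(p, "Wq")]], bq = pp[[paste0(p, "bq")]],
          Wk = pp[[paste0(p, "Wk")]], bk = pp[[paste0(p, "bk")]],
          Wv = pp[[paste0(p, "Wv")]], bv = pp[[paste0(p, "bv")]],
          Wo = pp[[paste0(p, "Wo")]], bo = pp[[paste0(p, "bo")]],
          n_heads = cfg$n_heads,
          ln1_g = pp[[paste0(p, "ln1_g")]], ln1_b = pp[[paste0(p, "ln1_b")]],
          ffn_W1 = pp[[paste0(p, "ffn_W1")]], ffn_b1 = pp[[paste0(p, "ffn_b1")]],
          ffn_W2 = pp[[paste0(p, "ffn_W2")]], ffn_b2 = pp[[paste0(p, "ffn_b2")]],
          ln2_g = pp[[paste0(p, "ln2_g")]], ln2_b = pp[[paste0(p, "ln2_b")]]))
      }
    }
    G[b, ] <- colMeans(H)
  }
  if (fl$task1) {
    out1 <- row_softmax(sweep(G %*% pp$head1_W, 2, pp$head1_b, "+"))
  }
  if (fl$task2) {
    out2 <- row_softmax(sweep(G %*% pp$head2_W, 2, pp$head2_b, "+"))
  }
  list(p1 = out1, p2 = out2)
}
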