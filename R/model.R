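#' Transformer model configuration
#'
#' A small pre-norm transformer encoder classifying the center event of a
#' feature window. `d_model` must be an even integer and a multiple of the
#' number of attention heads. With concatenated position embeddings the
#' 7 event features plus an `n_pe = d_model - 7` embedding make up each
#' input row (e.g. 9-wide embedding + 7 features = 16).
#'
#' @param d_model Width of each encoder vector (even; 16 is the small
#'   reference setting, the tuning scope for larger models is 32-64).
#' @param n_heads Number of attention heads (default 2).
#' @param n_layers Number of encoder layers (default 2).
#' @param d_ff Width of the position-wise feed-forward layer (default
#'   `4 * d_model`).
#' @param window Odd context window size (default 21).
#' @param pe_mode `"concat"` (default) or `"sum"`, see [pe_config()].
#' @param n_pe Embedding width in concat mode (default `d_model - 7`).
#' @param w0 Embedding base frequency (default 1/10000).
#' @param dropout Dropout rate for attention/feed-forward sub-layer outputs
#'   during training (default 0.1).
#' @param seed Integer seed for parameter initialization.
#' @return A list of class `methformer_config`.
#' @export
model_config <- function(d_model = 16L, n_heads = 2L, n_layers = 2L,
                         d_ff = 4L * d_model, window = 21L,
                         pe_mode = c("concat", "sum"), n_pe = d_model - 7L,
                         w0 = 1e-4, dropout = 0.1, seed = 1L) {
  pe_mode <- match.arg(pe_mode)
  d_model <- as.integer(d_model)
  n_heads <- as.integer(n_heads)
  if (d_model %% 2L != 0L) {
    stop(sprintf("d_model must be an even integer (got %d)", d_model))
  }
  if (d_model %% n_heads != 0L) {
    stop(sprintf(
      "d_model must be a multiple of the number of attention heads (got d_model=%d, n_heads=%d)",
      d_model, n_heads))
  }
  window <- as.integer(window)
  if (window %% 2L == 0L) stop(sprintf("window must be odd (got %d)", window))
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  structure(list(
    d_model = d_model, n_heads = n_heads, n_layers = as.integer(n_layers),
    d_ff = as.integer(d_ff), window = window,
    pe = pe_config(pe_mode, d_model = d_model, n_pe = n_pe, w0 = w0),
    dropout = dropout, seed = as.integer(seed)
  ), class = "methformer_config")
}

.glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Build an initialized transformer model
#'
#' Each of the `n_layers` encoder layers has a multi-head self-attention
#' sub-layer and a position-wise feed-forward sub-layer, each wrapped in a
#' residual connection with (pre-)layer normalization; a final layer norm
#' feeds the center-row classification head FC(d_model) -> ReLU ->
#' FC(2) -> softmax. Initialization is Glorot-uniform and deterministic
#' under `cfg$seed`.
#'
#' @param cfg A [model_config()].
#' @return An object of class `methformer_model` (list with `config` and the
#'   named parameter list `params`).
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "methformer_config"))
  d <- cfg$d_model
  dff <- cfg$d_ff
  set.seed(cfg$seed)
  p <- list()
  if (cfg$pe$mode == "sum") {
    p$embed.W <- .glorot(7L, d)
    p$embed.b <- numeric(d)
  }
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("L%d.", l)
    p[[paste0(pre, "ln1.g")]] <- rep(1, d)
    p[[paste0(pre, "ln1.b")]] <- numeric(d)
    p[[paste0(pre, "Wq")]] <- .glorot(d, d)
    p[[paste0(pre, "bq")]] <- numeric(d)
    p[[paste0(pre, "Wk")]] <- .glorot(d, d)
    p[[paste0(pre, "bk")]] <- numeric(d)
    p[[paste0(pre, "Wv")]] <- .glorot(d, d)
    p[[paste0(pre, "bv")]] <- numeric(d)
    p[[paste0(pre, "Wo")]] <- .glorot(d, d)
    p[[paste0(pre, "bo")]] <- numeric(d)
    p[[paste0(pre, "ln2.g")]] <- rep(1, d)
    p[[paste0(pre, "ln2.b")]] <- numeric(d)
    p[[paste0(pre, "W1")]] <- .glorot(d, dff)
    p[[paste0(pre, "b1")]] <- numeric(dff)
    p[[paste0(pre, "W2")]] <- .glorot(dff, d)
    p[[paste0(pre, "b2")]] <- numeric(d)
  }
  p$lnf.g <- rep(1, d)
  p$lnf.b <- numeric(d)
  p$head.W1 <- .glorot(d, d)
  p$head.b1 <- numeric(d)
  p$head.W2 <- .glorot(d, 2L)
  p$head.b2 <- numeric(2)
  structure(list(config = cfg, params = p,
                 feat_stats = list(mu = c(0, 0, 0), sd = c(1, 1, 1)),
                 meta = list()),
            class = "methformer_model")
}

#' @export
print.methformer_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "methformer_model: d_model=%d, heads=%d, layers=%d, d_ff=%d, window=%d, PE=%s, %d parameters\n",
    cfg$d_model, cfg$n_heads, cfg$n_layers, cfg$d_ff, cfg$window,
    cfg$pe$mode, count_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model A `methformer_model` (or its config).
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "methformer_config")) model <- build_model(model)
  sum(vapply(model$params, length, integer(1)))
}

# --- internal numerics -------------------------------------------------------
# The batch lives in one (B*w) x d matrix M; window b occupies rows
# (b-1)*w + 1 .. b*w. All forward caches are kept for the analytic backward
# pass (verified against finite differences in the test suite).

.add_bias <- function(X, b) X + matrix(b, nrow(X), length(b), byrow = TRUE)

.ln_forward <- function(X, g, b, eps = 1e-6) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(y = .add_bias(sweep(xhat, 2L, g, `*`), b), xhat = xhat, inv = inv)
}

.ln_backward <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2L, g, `*`)
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dX = dX, dg = dg, db = db)
}

.row_softmax <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)
  E / rowSums(E)
}

# Embed raw 7-feature rows F7 ((B*w) x 7) to (B*w) x d_model. `stats`
# column-standardizes the numeric features (f_m, f_sd, f_l): the dwell count
# is an order of magnitude larger than the signal features and would
# otherwise dominate the first layer normalization's row statistics.
.mf_embed <- function(params, cfg, F7, B, stats = NULL) {
  F7 <- .apply_feat_stats(F7, stats)
  w <- cfg$window
  pe <- pe_matrix(w, cfg$pe$n_pe, cfg$pe$w0)
  pe_rep <- pe[rep(seq_len(w), B), , drop = FALSE]
  if (cfg$pe$mode == "concat") {
    cbind(F7, pe_rep, deparse.level = 0)
  } else {
    .add_bias(F7 %*% params$embed.W, params$embed.b) + pe_rep
  }
}

# Forward pass from embedded input M; returns probabilities and caches.
.mf_forward_core <- function(params, cfg, M, B, train = FALSE) {
  w <- cfg$window
  d <- cfg$d_model
  H <- cfg$n_heads
  dh <- d %/% H
  scale <- 1 / sqrt(dh)
  drop_p <- if (train) cfg$dropout else 0
  cols <- lapply(seq_len(H), function(h) ((h - 1L) * dh + 1L):(h * dh))
  rows_of <- function(b) ((b - 1L) * w + 1L):(b * w)

  x <- M
  layers <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("L%d.", l)
    ln1 <- .ln_forward(x, params[[paste0(pre, "ln1.g")]], params[[paste0(pre, "ln1.b")]])
    h1 <- ln1$y
    Q <- .add_bias(h1 %*% params[[paste0(pre, "Wq")]], params[[paste0(pre, "bq")]])
    K <- .add_bias(h1 %*% params[[paste0(pre, "Wk")]], params[[paste0(pre, "bk")]])
    V <- .add_bias(h1 %*% params[[paste0(pre, "Wv")]], params[[paste0(pre, "bv")]])
    Cmat <- matrix(0, nrow(x), d)
    A <- vector("list", B)
    for (b in seq_len(B)) {
      rb <- rows_of(b)
      Ab <- vector("list", H)
      for (h in seq_len(H)) {
        ch <- cols[[h]]
        S <- (Q[rb, ch, drop = FALSE] %*% t(K[rb, ch, drop = FALSE])) * scale
        Ah <- .row_softmax(S)
        Cmat[rb, ch] <- Ah %*% V[rb, ch, drop = FALSE]
        Ab[[h]] <- Ah
      }
      A[[b]] <- Ab
    }
    attn <- .add_bias(Cmat %*% params[[paste0(pre, "Wo")]], params[[paste0(pre, "bo")]])
    mask1 <- NULL
    if (drop_p > 0) {
      mask1 <- matrix((runif(length(attn)) >= drop_p) / (1 - drop_p),
                      nrow(attn), ncol(attn))
      attn <- attn * mask1
    }
    x_mid <- x + attn

    ln2 <- .ln_forward(x_mid, params[[paste0(pre, "ln2.g")]], params[[paste0(pre, "ln2.b")]])
    h2 <- ln2$y
    ff_pre <- .add_bias(h2 %*% params[[paste0(pre, "W1")]], params[[paste0(pre, "b1")]])
    ff_act <- ff_pre * (ff_pre > 0)
    ff_out <- .add_bias(ff_act %*% params[[paste0(pre, "W2")]], params[[paste0(pre, "b2")]])
    mask2 <- NULL
    if (drop_p > 0) {
      mask2 <- matrix((runif(length(ff_out)) >= drop_p) / (1 - drop_p),
                      nrow(ff_out), ncol(ff_out))
      ff_out <- ff_out * mask2
    }
    x_out <- x_mid + ff_out

    layers[[l]] <- list(x_in = x, ln1 = ln1, h1 = h1, Q = Q, K = K, V = V,
                        A = A, Cmat = Cmat, mask1 = mask1, x_mid = x_mid,
                        ln2 = ln2, h2 = h2, ff_pre = ff_pre, ff_act = ff_act,
                        mask2 = mask2)
    x <- x_out
  }

  lnf <- .ln_forward(x, params$lnf.g, params$lnf.b)
  ctr_rows <- (seq_len(B) - 1L) * w + (w + 1L) %/% 2L
  Z <- lnf$y[ctr_rows, , drop = FALSE]
  U_pre <- .add_bias(Z %*% params$head.W1, params$head.b1)
  U <- U_pre * (U_pre > 0)
  logits <- .add_bias(U %*% params$head.W2, params$head.b2)
  probs <- .row_softmax(logits)
  colnames(probs) <- c("p_unmeth", "p_meth")

  list(probs = probs,
       cache = list(layers = layers, lnf = lnf, x_top = x, ctr_rows = ctr_rows,
                    Z = Z, U_pre = U_pre, U = U, B = B, w = w, d = d, H = H,
                    dh = dh, scale = scale, cols = cols))
}

.apply_feat_stats <- function(F7, stats) {
  if (is.null(stats)) return(F7)
  for (j in 1:3) F7[, j] <- (F7[, j] - stats$mu[j]) / stats$sd[j]
  F7
}

# Cross-entropy loss and analytic gradients for a batch of raw feature
# windows. y in {0,1}. Returns list(loss, probs, grads).
.mf_loss_grads <- function(params, cfg, F7, y, train = TRUE, stats = NULL) {
  F7 <- .apply_feat_stats(F7, stats)
  B <- length(y)
  M <- .mf_embed(params, cfg, F7, B)
  fwd <- .mf_forward_core(params, cfg, M, B, train = train)
  probs <- fwd$probs
  cc <- fwd$cache
  loss <- -mean(log(pmax(probs[cbind(seq_len(B), y + 1L)], 1e-300)))

  g <- list()
  onehot <- matrix(0, B, 2L)
  onehot[cbind(seq_len(B), y + 1L)] <- 1
  dlogits <- (probs - onehot) / B
  dimnames(dlogits) <- NULL
  g$head.W2 <- t(cc$U) %*% dlogits
  g$head.b2 <- colSums(dlogits)
  dU <- dlogits %*% t(params$head.W2)
  dU_pre <- dU * (cc$U_pre > 0)
  g$head.W1 <- t(cc$Z) %*% dU_pre
  g$head.b1 <- colSums(dU_pre)
  dZ <- dU_pre %*% t(params$head.W1)
  dY <- matrix(0, nrow(cc$x_top), cc$d)
  dY[cc$ctr_rows, ] <- dZ
  lb <- .ln_backward(dY, cc$lnf, params$lnf.g)
  g$lnf.g <- lb$dg
  g$lnf.b <- lb$db
  dx <- lb$dX

  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- sprintf("L%d.", l)
    cl <- cc$layers[[l]]
    # feed-forward sub-layer
    dff_out <- if (is.null(cl$mask2)) dx else dx * cl$mask2
    g[[paste0(pre, "W2")]] <- t(cl$ff_act) %*% dff_out
    g[[paste0(pre, "b2")]] <- colSums(dff_out)
    dff_act <- dff_out %*% t(params[[paste0(pre, "W2")]])
    dff_pre <- dff_act * (cl$ff_pre > 0)
    g[[paste0(pre, "W1")]] <- t(cl$h2) %*% dff_pre
    g[[paste0(pre, "b1")]] <- colSums(dff_pre)
    dh2 <- dff_pre %*% t(params[[paste0(pre, "W1")]])
    lb2 <- .ln_backward(dh2, cl$ln2, params[[paste0(pre, "ln2.g")]])
    g[[paste0(pre, "ln2.g")]] <- lb2$dg
    g[[paste0(pre, "ln2.b")]] <- lb2$db
    dx_mid <- dx + lb2$dX
    # attention sub-layer
    dattn <- if (is.null(cl$mask1)) dx_mid else dx_mid * cl$mask1
    g[[paste0(pre, "Wo")]] <- t(cl$Cmat) %*% dattn
    g[[paste0(pre, "bo")]] <- colSums(dattn)
    dC <- dattn %*% t(params[[paste0(pre, "Wo")]])
    dQ <- matrix(0, nrow(dx), cc$d)
    dK <- matrix(0, nrow(dx), cc$d)
    dV <- matrix(0, nrow(dx), cc$d)
    for (b in seq_len(cc$B)) {
      rb <- ((b - 1L) * cc$w + 1L):(b * cc$w)
      for (h in seq_len(cc$H)) {
        ch <- cc$cols[[h]]
        Ah <- cl$A[[b]][[h]]
        dOb <- dC[rb, ch, drop = FALSE]
        Vb <- cl$V[rb, ch, drop = FALSE]
        dA <- dOb %*% t(Vb)
        dV[rb, ch] <- t(Ah) %*% dOb
        dS <- Ah * (dA - rowSums(dA * Ah))
        dQ[rb, ch] <- (dS %*% cl$K[rb, ch, drop = FALSE]) * cc$scale
        dK[rb, ch] <- (t(dS) %*% cl$Q[rb, ch, drop = FALSE]) * cc$scale
      }
    }
    g[[paste0(pre, "Wq")]] <- t(cl$h1) %*% dQ
    g[[paste0(pre, "bq")]] <- colSums(dQ)
    g[[paste0(pre, "Wk")]] <- t(cl$h1) %*% dK
    g[[paste0(pre, "bk")]] <- colSums(dK)
    g[[paste0(pre, "Wv")]] <- t(cl$h1) %*% dV
    g[[paste0(pre, "bv")]] <- colSums(dV)
    dh1 <- dQ %*% t(params[[paste0(pre, "Wq")]]) +
      dK %*% t(params[[paste0(pre, "Wk")]]) +
      dV %*% t(params[[paste0(pre, "Wv")]])
    lb1 <- .ln_backward(dh1, cl$ln1, params[[paste0(pre, "ln1.g")]])
    g[[paste0(pre, "ln1.g")]] <- lb1$dg
    g[[paste0(pre, "ln1.b")]] <- lb1$db
    dx <- dx_mid + lb1$dX
  }

  if (cfg$pe$mode == "sum") {
    g$embed.W <- t(F7) %*% dx
    g$embed.b <- colSums(dx)
  }
  list(loss = loss, probs = probs, grads = g)
}

# Flatten a meth_windows feature array to the (n*w) x 7 batch layout.
.flatten_windows <- function(windows) {
  n <- dim(windows$x)[3L]
  w <- windows$window
  matrix(aperm(windows$x, c(1L, 3L, 2L)), nrow = n * w, ncol = 7L)
}

.batch_rows <- function(idx, w) {
  rep((idx - 1L) * w, each = w) + rep(seq_len(w), length(idx))
}

#' Forward pass: per-window methylation probabilities
#'
#' Runs the encoder-classifier in evaluation mode (no dropout;
#' deterministic for fixed parameters).
#'
#' @param model A `methformer_model`.
#' @param x Either a `meth_windows` object / `w x 7 x B` array of raw event
#'   features (position embeddings are attached internally according to the
#'   model's configuration), or -- with `embedded = TRUE` -- a
#'   `w x d_model x B` array of already-embedded windows.
#' @param embedded Set to `TRUE` when `x` is already embedded.
#' @return `B x 2` matrix with columns `p_unmeth`, `p_meth`; rows sum to 1.
#' @export
transformer_forward <- function(model, x, embedded = FALSE) {
  cfg <- model$config
  if (inherits(x, "meth_windows")) {
    stopifnot(x$window == cfg$window)
    F7 <- .flatten_windows(x)
    B <- dim(x$x)[3L]
    M <- .mf_embed(model$params, cfg, F7, B, model$feat_stats)
  } else {
    if (is.matrix(x)) x <- array(x, dim = c(nrow(x), ncol(x), 1L))
    stopifnot(length(dim(x)) == 3L, dim(x)[1L] == cfg$window)
    B <- dim(x)[3L]
    if (embedded) {
      if (dim(x)[2L] != cfg$d_model) {
        stop(sprintf("embedded input width %d does not match d_model %d",
                     dim(x)[2L], cfg$d_model))
      }
      M <- matrix(aperm(x, c(1L, 3L, 2L)), nrow = B * cfg$window)
    } else {
      if (dim(x)[2L] != 7L) stop("raw feature windows must have 7 columns")
      F7 <- matrix(aperm(x, c(1L, 3L, 2L)), nrow = B * cfg$window, ncol = 7L)
      M <- .mf_embed(model$params, cfg, F7, B, model$feat_stats)
    }
  }
  .mf_forward_core(model$params, cfg, M, B, train = FALSE)$probs
}

#' Threshold a methylation probability into a binary call
#'
#' Returns 1 (methylated) iff the probability is strictly greater than 0.5;
#' probabilities equal to or lower than 0.5 are called unmethylated.
#'
#' @param p Numeric vector of probabilities in \[0, 1\].
#' @return Integer vector of 0/1 calls.
#' @export
call_methylation <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  as.integer(p > 0.5)
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the configuration, all named parameter arrays and
#' training metadata, and reloads bit-exactly: forward passes after a
#' save/load round trip reproduce probabilities bitwise.
#'
#' @param model A `methformer_model`.
#' @param path Checkpoint file path.
#' @return For the loader, the restored `methformer_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "methformer_model"))
  saveRDS(model, path, version = 3L)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "methformer_model"))
  model
}
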