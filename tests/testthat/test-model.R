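test_that("configuration enforces the width/head divisibility constraint", {
  expect_error(model_config(d_model = 16L, n_heads = 3L),
               "multiple of the number of attention heads")
  expect_s3_class(model_config(d_model = 16L, n_heads = 2L), "methformer_config")
  expect_error(model_config(d_model = 15L, n_heads = 3L), "even")
  expect_error(model_config(window = 20L), "odd")
  expect_error(model_config(dropout = 1), "dropout")
})

test_that("initialization is deterministic under the seed", {
  m1 <- build_model(model_config(seed = 5L))
  m2 <- build_model(model_config(seed = 5L))
  expect_identical(m1$params, m2$params)
  m3 <- build_model(model_config(seed = 6L))
  expect_false(identical(m3$params, m1$params))
})

test_that("forward yields normalized probability pairs, deterministically", {
  m <- build_model(tiny_model_config())
  x <- array(rnorm(5L * 7L * 8L), dim = c(5L, 7L, 8L))
  p <- transformer_forward(m, x)
  expect_equal(dim(p), c(8L, 2L))
  expect_equal(rowSums(p), rep(1, 8L), tolerance = 1e-6)
  expect_true(all(p > 0 & p < 1))
  expect_identical(p, transformer_forward(m, x))   # eval mode is bitwise stable
  expect_error(transformer_forward(m, array(0, dim = c(5L, 9L, 1L)),
                                   embedded = TRUE), "d_model")
})

test_that("parameter count matches the closed-form formula", {
  for (cfg in list(model_config(d_model = 16L, n_heads = 2L, n_layers = 2L),
                   model_config(d_model = 32L, n_heads = 4L, n_layers = 3L,
                                d_ff = 64L),
                   model_config(d_model = 16L, pe_mode = "sum"))) {
    d <- cfg$d_model; dff <- cfg$d_ff; L <- cfg$n_layers
    per_layer <- 4L * (d * d + d) +      # Q,K,V,O projections + biases
      2L * 2L * d +                      # two layer norms (gain + bias)
      (d * dff + dff) + (dff * d + d)    # feed-forward
    expected <- L * per_layer +
      2L * d +                           # final layer norm
      (d * d + d) + (d * 2L + 2L) +      # head FC -> ReLU -> FC(2)
      if (cfg$pe$mode == "sum") 7L * d + d else 0L
    expect_equal(count_parameters(cfg), expected)
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  for (mode in c("concat", "sum")) {
    cfg <- model_config(d_model = 10L, n_heads = 2L, n_layers = 2L, d_ff = 12L,
                        window = 5L, pe_mode = mode, n_pe = 3L, dropout = 0,
                        seed = 3L)
    m <- build_model(cfg)
    F7 <- matrix(rnorm(5L * 3L * 7L), ncol = 7L)
    y <- c(0L, 1L, 1L)
    lg <- methformer:::.mf_loss_grads(m$params, cfg, F7, y, train = TRUE)
    lossf <- function(params) {
      methformer:::.mf_loss_grads(params, cfg, F7, y, train = TRUE)$loss
    }
    h <- 1e-5
    for (nm in names(m$params)) {
      idx <- sample(length(m$params[[nm]]), min(3L, length(m$params[[nm]])))
      for (i in idx) {
        pp <- m$params
        pp[[nm]][i] <- pp[[nm]][i] + h
        lp <- lossf(pp)
        pp[[nm]][i] <- pp[[nm]][i] - 2 * h
        lm <- lossf(pp)
        num <- (lp - lm) / (2 * h)
        expect_equal(lg$grads[[nm]][i], num, tolerance = 1e-4,
                     label = sprintf("grad %s[%d]", nm, i))
      }
    }
  }
})

test_that("without position information the output ignores context order", {
  # zeroed PE block: attention plus row-wise sublayers cannot distinguish a
  # permutation of the non-center rows
  cfg <- model_config(d_model = 16L, n_heads = 2L, window = 9L, n_pe = 9L,
                      seed = 11L)
  m <- build_model(cfg)
  set.seed(8)
  F7 <- matrix(rnorm(9L * 7L), 9L, 7L)
  embed_zero <- cbind(F7, matrix(0, 9L, 9L))
  perm <- c(3L, 7L, 2L, 9L, 5L, 1L, 8L, 4L, 6L)   # fixes center row 5
  x1 <- array(embed_zero, dim = c(9L, 16L, 1L))
  x2 <- array(embed_zero[perm, ], dim = c(9L, 16L, 1L))
  p1 <- transformer_forward(m, x1, embedded = TRUE)
  p2 <- transformer_forward(m, x2, embedded = TRUE)
  expect_equal(p1, p2, tolerance = 1e-5)

  # with the sinusoidal block attached the same permutation changes the output
  pe <- pe_matrix(9L, 9L)
  x1p <- array(cbind(F7, pe), dim = c(9L, 16L, 1L))
  x2p <- array(cbind(F7[perm, ], pe), dim = c(9L, 16L, 1L))
  p1p <- transformer_forward(m, x1p, embedded = TRUE)
  p2p <- transformer_forward(m, x2p, embedded = TRUE)
  expect_gt(max(abs(p1p - p2p)), 1e-5)
})

test_that("one training step sends gradient to every parameter array", {
  cfg <- tiny_model_config(seed = 21L)
  m <- build_model(cfg)
  set.seed(9)
  F7 <- matrix(rnorm(5L * 32L * 7L), ncol = 7L)
  y <- rep(0:1, 16L)
  lg <- methformer:::.mf_loss_grads(m$params, cfg, F7, y, train = TRUE)
  # key bias excepted: softmax scores are exactly invariant to it
  for (nm in setdiff(names(lg$grads), c("L1.bk", "L2.bk"))) {
    expect_gt(max(abs(lg$grads[[nm]])), 0)
  }
})

test_that("checkpoints reload bit-exactly", {
  m <- build_model(tiny_model_config(seed = 2L))
  x <- array(rnorm(5L * 7L * 4L), dim = c(5L, 7L, 4L))
  p1 <- transformer_forward(m, x)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(transformer_forward(m2, x), p1)
})

test_that("probability thresholding calls methylated strictly above 0.5", {
  expect_equal(call_methylation(c(0.51, 0.5, 0, 1)), c(1L, 0L, 0L, 1L))
  expect_error(call_methylation(1.2), "0, 1")
  expect_error(call_methylation(-0.1), "0, 1")
})
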