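test_that("confusion counts partition the examples", {
  cc <- confusion(c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L))
  expect_equal(unclass(cc)[c("TP", "FN", "FP", "TN")],
               list(TP = 1L, FN = 1L, FP = 1L, TN = 1L))
  expect_equal(cc$P + cc$N, 4L)

  perfect <- confusion(c(1L, 0L, 1L), c(1L, 0L, 1L))
  expect_equal(perfect$FP, 0L)
  expect_equal(perfect$FN, 0L)

  empty <- confusion(integer(), integer())
  expect_equal(empty$P + empty$N, 0L)
  expect_error(confusion(c(1L, 0L), 1L), "length")
})

test_that("metric formulas reproduce hand-computed values", {
  m <- metrics_report(structure(
    list(TP = 8L, FP = 2L, FN = 1L, TN = 9L, P = 9L, N = 11L),
    class = "meth_confusion"))
  expect_equal(m$precision, 0.8, tolerance = 1e-4)
  expect_equal(m$recall, 0.8889, tolerance = 1e-4)
  expect_equal(m$f1, 0.8421, tolerance = 1e-4)
  expect_equal(m$accuracy, 0.85, tolerance = 1e-4)

  perfect <- metrics_report(confusion(c(1L, 0L), c(1L, 0L)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)

  degen <- metrics_report(confusion(c(1L, 1L), c(0L, 0L)))
  expect_equal(degen$precision, 0)
  expect_equal(degen$recall, 0)
  expect_true(all(c("precision", "f1") %in% degen$undefined))
})

test_that("metrics agree with an independent recomputation on random tables", {
  set.seed(2024)
  for (i in 1:500) {
    n <- sample(2:60, 1L)
    y <- rbinom(n, 1L, runif(1, 0.2, 0.8))
    yhat <- rbinom(n, 1L, runif(1, 0.2, 0.8))
    cc <- confusion(y, yhat)
    m <- metrics_report(cc)
    tp <- sum(y & yhat); fp <- sum(!y & yhat)
    fn <- sum(y & !yhat); tn <- sum(!y & !yhat)
    expect_equal(cc$TP, tp); expect_equal(cc$FP, fp)
    expect_equal(cc$FN, fn); expect_equal(cc$TN, tn)
    expect_equal(m$accuracy, (tp + tn) / n, tolerance = 1e-9)
    if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp), tolerance = 1e-9)
    if (tp + fn > 0) expect_equal(m$recall, tp / (tp + fn), tolerance = 1e-9)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec + rec > 0) {
      expect_equal(m$f1, 2 * prec * rec / (prec + rec), tolerance = 1e-9)
    }
  }
})

test_that("AUC equals brute-force pairwise concordance, ties at 0.5", {
  expect_equal(roc_auc(c(1L, 1L, 0L, 0L), c(0.9, 0.8, 0.3, 0.1)), 1)
  expect_equal(roc_auc(c(1L, 0L, 1L, 0L), rep(0.4, 4L)), 0.5)
  expect_equal(roc_auc(c(1L, 0L, 1L, 0L), c(0.9, 0.8, 0.4, 0.1)), 0.75)
  expect_error(roc_auc(c(1L, 1L), c(0.2, 0.3)), "both classes")

  brute <- function(y, p) {
    pos <- p[y == 1L]; neg <- p[y == 0L]
    s <- 0
    for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
    s / (length(pos) * length(neg))
  }
  set.seed(77)
  for (i in 1:20) {
    n <- sample(4:200, 1L)
    y <- c(0L, 1L, rbinom(n - 2L, 1L, 0.5))
    p <- round(runif(n), 2)                       # coarse grid forces ties
    expect_equal(roc_auc(y, p), brute(y, p))
    expect_equal(roc_auc(y, p) + roc_auc(y, 1 - p), 1)
  }
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  y <- rbinom(150L, 1L, 0.4)
  p <- runif(150L)
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(y, p), ref, tolerance = 1e-12)
})

test_that("training learns a separable problem and is seed-deterministic", {
  win <- separable_windows(n = 240L, w = 9L, shift = 3, seed = 10L)
  cfg <- model_config(d_model = 16L, n_heads = 2L, n_layers = 1L, d_ff = 16L,
                      window = 9L, seed = 4L)
  tcfg <- train_config(batch_size = 64L, learning_rate = 0.01, epochs = 6L,
                       seed = 4L, validation_fraction = 0.25)
  fit <- train_transformer(win, cfg, tcfg, quiet = TRUE)
  expect_gte(fit$validation$metrics$f1, 0.95)
  expect_equal(nrow(fit$trace), 6L)

  fit2 <- train_transformer(win, cfg, tcfg, quiet = TRUE)
  expect_identical(fit$trace$train_loss[1L], fit2$trace$train_loss[1L])
  expect_identical(fit$model$params, fit2$model$params)
})

test_that("degenerate training inputs are rejected", {
  win <- separable_windows(n = 40L, w = 9L, seed = 2L)
  win$label <- rep(0L, 40L)
  expect_error(train_transformer(win, model_config(window = 9L)), "single class")
  win2 <- separable_windows(n = 40L, w = 9L, seed = 2L)
  win2$label <- NULL
  expect_error(train_transformer(win2, model_config(window = 9L)), "labeled")
  win3 <- separable_windows(n = 40L, w = 9L, seed = 2L)
  expect_error(train_transformer(win3, model_config(window = 21L)), "mismatch")
})

test_that("evaluate_predictions joins on read and site identity", {
  labels <- data.frame(read_id = c("a", "b", "c"), chrom = "chr1", strand = "+",
                       ref_pos = c(1L, 2L, 3L), label = c(1L, 0L, 1L),
                       stringsAsFactors = FALSE)
  preds <- data.frame(read_id = c("b", "a", "c"), chrom = "chr1", strand = "+",
                      ref_pos = c(2L, 1L, 3L), prob = c(0.2, 0.9, 0.4),
                      call = c(0L, 1L, 0L), stringsAsFactors = FALSE)
  ev <- evaluate_predictions(preds, labels)
  expect_equal(ev$n, 3L)
  expect_equal(ev$confusion$TP, 1L)
  expect_equal(ev$confusion$FN, 1L)
  expect_equal(ev$metrics$accuracy, 2 / 3)
})
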