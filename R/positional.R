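#' Position-embedding configuration
#'
#' Two ways of attaching sinusoidal position information to the 7-feature
#' event vectors are supported: `"concat"` appends an `n_pe`-wide embedding
#' (so `d_model = n_pe + 7`), `"sum"` maps the 7 features through a learned
#' affine projection to `d_model` and adds a `d_model`-wide embedding
#' elementwise.
#'
#' @param mode `"concat"` or `"sum"`.
#' @param d_model Total model width (even, and in concat mode `n_pe + 7`).
#' @param n_pe Embedding width in concat mode (may be odd, e.g. 9 for
#'   `d_model = 16`); ignored in sum mode where the embedding width is
#'   `d_model`.
#' @param w0 Base (minimum) frequency of the embedding, default 1/10000.
#' @return A list of class `pe_config`.
#' @export
pe_config <- function(mode = c("concat", "sum"), d_model = 16L,
                      n_pe = d_model - 7L, w0 = 1e-4) {
  mode <- match.arg(mode)
  d_model <- as.integer(d_model)
  n_pe <- as.integer(n_pe)
  if (mode == "concat" && n_pe + 7L != d_model) {
    stop(sprintf("concat position embedding requires n_pe + 7 == d_model (got %d + 7 != %d)",
                 n_pe, d_model))
  }
  if (mode == "sum") n_pe <- d_model
  if (n_pe < 1L) stop("position embedding width must be >= 1")
  if (w0 <= 0) stop("w0 must be positive")
  structure(list(mode = mode, d_model = d_model, n_pe = n_pe, w0 = w0),
            class = "pe_config")
}

#' Sinusoidal position embedding vector
#'
#' Component `2j` (0-based) equals `sin(i * w0^(2j/n))` and component `2j+1`
#' equals `cos(i * w0^(2j/n))`, `j = 0, 1, ...`; for odd `n` the final
#' unpaired component is the sine term only. `w0` is the minimum frequency of
#' the embedding.
#'
#' @param position Integer position `i >= 0`.
#' @param width Embedding width `n >= 1`.
#' @param w0 Base frequency (default 1/10000).
#' @return Numeric vector of length `width`.
#' @export
sinusoidal_pe <- function(position, width, w0 = 1e-4) {
  if (position < 0) stop("position must be >= 0")
  drop(pe_matrix(1L, width, w0, first = position))
}

#' Sinusoidal embedding block for window rows 0..n_positions-1
#'
#' @param n_positions Number of rows.
#' @param width Embedding width.
#' @param w0 Base frequency.
#' @param first Position of the first row (default 0).
#' @return `n_positions x width` matrix; row `r` is the embedding of position
#'   `first + r - 1`.
#' @export
pe_matrix <- function(n_positions, width, w0 = 1e-4, first = 0L) {
  if (width < 1L) stop("width must be >= 1")
  pos <- first + seq_len(n_positions) - 1L
  npair <- ceiling(width / 2)
  j <- seq_len(npair) - 1L
  freq <- w0^(2 * j / width)
  ang <- outer(pos, freq)                      # n x npair
  out <- matrix(0, n_positions, width)
  out[, 2L * j + 1L] <- sin(ang)
  cos_cols <- 2L * j + 2L
  keep <- cos_cols <= width
  out[, cos_cols[keep]] <- cos(ang[, keep, drop = FALSE])
  out
}

#' Attach position embeddings to a feature window
#'
#' Positions are window-relative (row 0 is the most upstream event). In
#' concat mode row `r` becomes `[7 event features, pe(r, n_pe)]`; in sum mode
#' the 7-feature row is first mapped through the learned affine `projection`
#' (a list with `W` 7 x d_model and `b` length d_model) and the d_model-wide
#' embedding is added elementwise.
#'
#' @param window `w x 7` feature matrix (one [new_meth_windows()] slice).
#' @param cfg A [pe_config()].
#' @param projection Sum mode only: list with elements `W` and `b` (taken
#'   from the trained model's parameters).
#' @return `w x d_model` matrix.
#' @export
attach_pe <- function(window, cfg, projection = NULL) {
  stopifnot(inherits(cfg, "pe_config"), ncol(window) == 7L)
  w <- nrow(window)
  if (cfg$mode == "concat") {
    unname(cbind(window, pe_matrix(w, cfg$n_pe, cfg$w0)))
  } else {
    if (is.null(projection)) {
      stop("sum mode requires the learned input projection (list(W, b))")
    }
    proj <- window %*% projection$W +
      matrix(projection$b, w, cfg$d_model, byrow = TRUE)
    proj + pe_matrix(w, cfg$d_model, cfg$w0)
  }
}
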