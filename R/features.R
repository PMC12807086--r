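#' Robust per-read signal normalization
#'
#' Pools every raw signal sample of one read, centers by the median and
#' scales by 1.4826 x MAD (a robust standard-deviation estimate), then clips
#' to `[-clip, clip]`. This realizes the rescaling of raw currents to the
#' [-5, 5] range while staying insensitive to current spikes. If the read's
#' MAD is zero (constant signal) the scale falls back to 1 with a warning.
#'
#' @param samples Either a numeric vector or a list of numeric vectors (one
#'   per event) belonging to a single read.
#' @param clip Clipping bound (default 5).
#' @return The same structure with normalized values.
#' @export
normalize_read <- function(samples, clip = 5) {
  is_list <- is.list(samples)
  pooled <- if (is_list) unlist(samples, use.names = FALSE) else samples
  if (length(pooled) == 0L) stop("normalize_read: read has no samples")
  med <- stats::median(pooled)
  s <- stats::mad(pooled, center = med)
  if (s == 0) {
    warning("normalize_read: MAD is zero (constant signal); using scale 1")
    s <- 1
  }
  f <- function(x) pmin(pmax((x - med) / s, -clip), clip)
  if (is_list) lapply(samples, f) else f(samples)
}

#' Normalize all reads of an event table
#'
#' Applies [normalize_read()] independently to each read's pooled samples.
#'
#' @param events Event data frame (see [read_event_table()]).
#' @return The event data frame with normalized `samples`.
#' @export
normalize_events <- function(events) {
  if (nrow(events) == 0L) return(events)
  for (g in split(seq_len(nrow(events)), events$read_id)) {
    events$samples[g] <- normalize_read(events$samples[g])
  }
  events
}

#' One-hot encode a reference base
#'
#' Fixed order A, C, G, T; e.g. `one_hot("C")` is `c(0, 1, 0, 0)`.
#'
#' @param base A single character among A, C, G, T.
#' @return Numeric indicator vector of length 4.
#' @export
one_hot <- function(base) {
  i <- match(base, .valid_bases)
  if (length(base) != 1L || is.na(i)) {
    stop(sprintf("one_hot: invalid base '%s' (must be one of A,C,G,T)",
                 paste(base, collapse = ",")))
  }
  v <- numeric(4)
  v[i] <- 1
  v
}

#' Compute the 7-feature vector of one event
#'
#' Features, in order: signal mean `f_m`, population standard deviation
#' `f_sd`, number of samples `f_l`, and the one-hot base indicators
#' `f_A, f_C, f_G, f_T`. Samples are expected to be already normalized (see
#' [normalize_read()]).
#'
#' @param samples Numeric vector of (normalized) signal values, non-empty.
#' @param ref_base Reference base, one of A, C, G, T.
#' @return Numeric vector of length 7.
#' @export
featurize_event <- function(samples, ref_base) {
  if (length(samples) == 0L) stop("featurize_event: empty sample set")
  m <- mean(samples)
  c(m, sqrt(mean((samples - m)^2)), length(samples), one_hot(ref_base))
}

# Vectorized 7-feature matrix for all events of a table (rows follow `events`).
.featurize_all <- function(events) {
  n <- nrow(events)
  f_m <- vapply(events$samples, mean, numeric(1))
  f_sd <- sqrt(vapply(events$samples, function(x) mean((x - mean(x))^2), numeric(1)))
  f_l <- vapply(events$samples, length, integer(1))
  oh <- matrix(0, n, 4L)
  oh[cbind(seq_len(n), match(events$ref_base, .valid_bases))] <- 1
  cbind(f_m, f_sd, as.numeric(f_l), oh, deparse.level = 0)
}

#' Construct a feature-window container
#'
#' @param x Numeric array `w x 7 x n` of event features.
#' @param meta Data frame with one row per window: `read_id`, `chrom`,
#'   `strand`, `ref_pos` of the center event.
#' @param label Optional integer vector of 0/1 labels for the center events.
#' @param window Window size `w` (odd).
#' @return An object of class `meth_windows`.
#' @export
new_meth_windows <- function(x, meta, label = NULL, window = dim(x)[1L]) {
  stopifnot(length(dim(x)) == 3L, dim(x)[2L] == 7L, nrow(meta) == dim(x)[3L])
  rownames(meta) <- NULL
  structure(list(x = x, meta = meta, label = label, window = as.integer(window)),
            class = "meth_windows")
}

#' @export
print.meth_windows <- function(x, ...) {
  cat(sprintf("meth_windows: %d windows of size %d (%s)\n",
              dim(x$x)[3L], x$window,
              if (is.null(x$label)) "unlabeled" else "labeled"))
  invisible(x)
}

#' Extract labeled context windows from one read
#'
#' For each candidate reference position, takes the candidate event together
#' with its floor(w/2) upstream and floor(w/2) downstream events (by event
#' order within the read). Candidates whose event lies closer than floor(w/2)
#' to either read end are skipped -- windows are never padded -- and counted
#' in the `n_skipped` attribute.
#'
#' @param events Events of a single read, sorted by `ref_pos`.
#' @param candidates Integer vector of candidate 0-based reference positions.
#' @param w Odd window size (default 21).
#' @param labels Optional data frame of per-read labels (`read_id`, `chrom`,
#'   `strand`, `ref_pos`, `label`) used to label the windows.
#' @return A `meth_windows` object.
#' @export
extract_windows <- function(events, candidates, w = 21L, labels = NULL) {
  if (w %% 2L == 0L) stop("window size w must be odd")
  if (length(unique(events$read_id)) > 1L) {
    stop("extract_windows operates on a single read")
  }
  half <- w %/% 2L
  n <- nrow(events)
  idx <- match(candidates, events$ref_pos)
  ok <- !is.na(idx) & idx > half & idx <= n - half
  n_skipped <- sum(!ok)
  idx <- idx[ok]
  fmat <- .featurize_all(events)
  nw <- length(idx)
  x <- array(0, dim = c(w, 7L, nw))
  for (j in seq_len(nw)) {
    x[, , j] <- fmat[(idx[j] - half):(idx[j] + half), , drop = FALSE]
  }
  meta <- data.frame(
    read_id = rep(events$read_id[1L], nw),
    chrom = events$chrom[idx], strand = events$strand[idx],
    ref_pos = events$ref_pos[idx], stringsAsFactors = FALSE
  )
  label <- .lookup_labels(meta, labels)
  out <- new_meth_windows(x, meta, label, w)
  attr(out, "n_skipped") <- n_skipped
  out
}

.lookup_labels <- function(meta, labels) {
  if (is.null(labels) || nrow(meta) == 0L) return(NULL)
  key <- paste(meta$read_id, meta$chrom, meta$strand, meta$ref_pos)
  lkey <- paste(labels$read_id, labels$chrom, labels$strand, labels$ref_pos)
  lab <- labels$label[match(key, lkey)]
  if (anyNA(lab)) stop("missing label for ", sum(is.na(lab)), " window(s)")
  as.integer(lab)
}

#' Build feature windows for all reads of an event table
#'
#' Convenience wrapper over [extract_windows()]: candidate sites (e.g. from
#' [find_cpg_candidates()]) are intersected with each read's events, and all
#' resulting windows are stacked into one container.
#'
#' @param events Event data frame covering one or more reads (signals should
#'   already be normalized, see [normalize_events()]).
#' @param candidates Data frame with columns `chrom`, `pos` (0-based) and
#'   `strand`, e.g. from [cpg_sites()].
#' @param w Odd window size (default 21).
#' @param labels Optional label data frame (see [read_labels()]).
#' @return A `meth_windows` object with an `n_skipped` attribute.
#' @export
build_windows <- function(events, candidates, w = 21L, labels = NULL) {
  if (w %% 2L == 0L) stop("window size w must be odd")
  groups <- split(seq_len(nrow(events)), events$read_id)
  # keep first-appearance read order
  groups <- groups[unique(events$read_id)]
  pieces <- vector("list", length(groups))
  skipped <- 0L
  for (i in seq_along(groups)) {
    ev <- events[groups[[i]], , drop = FALSE]
    cand <- candidates$pos[candidates$chrom == ev$chrom[1L] &
                             candidates$strand == ev$strand[1L]]
    cand <- cand[cand >= min(ev$ref_pos) & cand <= max(ev$ref_pos)]
    pw <- extract_windows(ev, cand, w = w, labels = labels)
    skipped <- skipped + attr(pw, "n_skipped")
    pieces[[i]] <- pw
  }
  ns <- vapply(pieces, function(p) dim(p$x)[3L], integer(1))
  x <- array(0, dim = c(w, 7L, sum(ns)))
  at <- 0L
  for (p in pieces[ns > 0L]) {
    x[, , at + seq_len(dim(p$x)[3L])] <- p$x
    at <- at + dim(p$x)[3L]
  }
  meta <- do.call(rbind, lapply(pieces, `[[`, "meta"))
  label <- if (is.null(labels)) NULL else unlist(lapply(pieces, `[[`, "label"))
  out <- new_meth_windows(x, meta, label, w)
  attr(out, "n_skipped") <- skipped
  out
}

#' Crop feature windows to a smaller window size
#'
#' Keeps the central `w_new` rows of each window. Used by the window-size
#' ablation so every window size sees exactly the same candidate set.
#'
#' @param windows A `meth_windows` object.
#' @param w_new New odd window size, at most `windows$window`.
#' @return A `meth_windows` object of window size `w_new`.
#' @export
crop_windows <- function(windows, w_new) {
  w <- windows$window
  if (w_new %% 2L == 0L) stop("window size must be odd")
  if (w_new > w) stop("cannot crop to a larger window")
  half <- (w - w_new) %/% 2L
  x <- windows$x[(half + 1L):(half + w_new), , , drop = FALSE]
  new_meth_windows(x, windows$meta, windows$label, w_new)
}

#' Find CpG candidate positions in a sequence
#'
#' Forward mode returns 0-based positions `p` with `seq[p] == "C"` and
#' `seq[p+1] == "G"`. Both-strands mode additionally returns `p + 1` flagged
#' minus-strand: the G of the forward CpG is the C of the palindromic CpG on
#' the reverse complement.
#'
#' @param seq A single sequence: character string, [Biostrings::DNAString],
#'   or a length-1 [Biostrings::DNAStringSet].
#' @param strand_mode `"forward"` or `"both"`.
#' @return Data frame with columns `pos` (0-based) and `strand`.
#' @export
find_cpg_candidates <- function(seq, strand_mode = c("forward", "both")) {
  strand_mode <- match.arg(strand_mode)
  if (methods::is(seq, "DNAStringSet")) {
    stopifnot(length(seq) == 1L)
    seq <- seq[[1L]]
  }
  if (is.character(seq)) seq <- Biostrings::DNAString(toupper(seq))
  hits <- Biostrings::matchPattern("CG", seq)
  p0 <- Biostrings::start(hits) - 1L
  out <- data.frame(pos = p0, strand = rep("+", length(p0)),
                    stringsAsFactors = FALSE)
  if (strand_mode == "both" && length(p0)) {
    out <- rbind(out, data.frame(pos = p0 + 1L, strand = "-",
                                 stringsAsFactors = FALSE))
    out <- out[order(out$pos, out$strand), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' CpG candidate sites for a multi-record reference
#'
#' @param genome A [Biostrings::DNAStringSet] (named records).
#' @param strand_mode `"forward"` or `"both"`; see [find_cpg_candidates()].
#' @return Data frame with columns `chrom`, `pos` (0-based), `strand`.
#' @export
cpg_sites <- function(genome, strand_mode = c("forward", "both")) {
  strand_mode <- match.arg(strand_mode)
  out <- lapply(seq_along(genome), function(i) {
    d <- find_cpg_candidates(genome[[i]], strand_mode)
    if (nrow(d)) cbind(chrom = names(genome)[i], d, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  }
  out
}
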