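#' Read a reference genome FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] so the rest of the
#' package can stay agnostic about the sequence container.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record.
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write a reference genome FASTA
#'
#' @param seqs A [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    nm <- names(seqs)
    seqs <- Biostrings::DNAStringSet(seqs)
    names(seqs) <- nm
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

.valid_bases <- c("A", "C", "G", "T")

#' Read a reference-anchored event table
#'
#' The event table is a headerless TSV with one row per translocation event:
#' `read_id`, `chrom`, `strand` (+/-), `ref_pos` (0-based), `ref_base`
#' (A/C/G/T), and `samples` -- the event's raw signal values as a
#' comma-separated list of decimals. It stands in for the event data stored in
#' basecalled FAST5 files, after signals have been anchored to reference
#' positions by alignment.
#'
#' Events are returned grouped by read (reads keep their order of first
#' appearance) and sorted by `ref_pos` within each read.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `read_id`, `chrom`, `strand`,
#'   `ref_pos`, `ref_base` and the list-column `samples` (numeric vectors).
#' @export
read_event_table <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(.empty_events())

  parts <- strsplit(lines, "\t", fixed = TRUE)
  lens <- lengths(parts)
  if (any(lens != 6L)) {
    i <- which(lens != 6L)[1L]
    stop(sprintf(
      "malformed event row at line %d: expected 6 tab-separated fields, found %d",
      line_no[i], lens[i]
    ))
  }
  m <- matrix(unlist(parts, use.names = FALSE), ncol = 6L, byrow = TRUE)

  strand <- m[, 3L]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) {
    stop(sprintf("invalid strand '%s' at line %d", strand[bad[1L]], line_no[bad[1L]]))
  }
  ref_pos <- suppressWarnings(as.integer(m[, 4L]))
  bad <- which(is.na(ref_pos) | ref_pos < 0L)
  if (length(bad)) {
    stop(sprintf("invalid ref_pos '%s' at line %d (need integer >= 0)",
                 m[bad[1L], 4L], line_no[bad[1L]]))
  }
  ref_base <- m[, 5L]
  bad <- which(!ref_base %in% .valid_bases)
  if (length(bad)) {
    stop(sprintf("invalid ref_base '%s' at line %d (must be one of A,C,G,T)",
                 ref_base[bad[1L]], line_no[bad[1L]]))
  }
  samples <- lapply(strsplit(m[, 6L], ",", fixed = TRUE),
                    function(x) suppressWarnings(as.numeric(x)))
  bad <- which(vapply(samples, function(x) length(x) == 0L || anyNA(x), logical(1)))
  if (length(bad)) {
    stop(sprintf("unparseable samples field at line %d", line_no[bad[1L]]))
  }

  ev <- data.frame(
    read_id = m[, 1L], chrom = m[, 2L], strand = strand,
    ref_pos = ref_pos, ref_base = ref_base,
    stringsAsFactors = FALSE
  )
  ev$samples <- samples
  ord <- order(match(ev$read_id, unique(ev$read_id)), ev$ref_pos)
  ev <- ev[ord, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

.empty_events <- function() {
  ev <- data.frame(
    read_id = character(), chrom = character(), strand = character(),
    ref_pos = integer(), ref_base = character(), stringsAsFactors = FALSE
  )
  ev$samples <- list()
  ev
}

#' Write an event table
#'
#' Inverse of [read_event_table()]; signal values are written with 17
#' significant digits so that write/read round-trips are exact.
#'
#' @param events Event data frame as returned by [read_event_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  if (nrow(events) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  sam <- vapply(events$samples, function(x) {
    paste(formatC(x, format = "g", digits = 17), collapse = ",")
  }, character(1))
  writeLines(paste(events$read_id, events$chrom, events$strand,
                   events$ref_pos, events$ref_base, sam, sep = "\t"),
             path)
  invisible(path)
}

#' Read / write per-read methylation labels
#'
#' Labels are a headerless TSV: `read_id`, `chrom`, `strand`, `ref_pos`
#' (0-based), `label` (1 = methylated, 0 = unmethylated).
#'
#' @param path File path.
#' @return For the reader, a data.frame of labeled sites.
#' @export
read_labels <- function(path) {
  empty <- data.frame(read_id = character(), chrom = character(),
                      strand = character(), ref_pos = integer(),
                      label = integer(), stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1:3, integer = 4:5))
  if (nrow(dt) == 0L) return(empty)
  data.table::setnames(dt, c("read_id", "chrom", "strand", "ref_pos", "label"))
  if (!all(dt$label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  as.data.frame(dt)
}

#' @rdname read_labels
#' @param labels Data frame with columns `read_id`, `chrom`, `strand`,
#'   `ref_pos`, `label`.
#' @export
write_labels <- function(labels, path) {
  data.table::fwrite(labels[, c("read_id", "chrom", "strand", "ref_pos", "label")],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read / write per-read methylation predictions
#'
#' Predictions are a headerless TSV: `read_id`, `chrom`, `strand`, `ref_pos`,
#' `prob` (methylation probability, 6 decimals), `call` (1 iff prob > 0.5).
#'
#' @param path File path.
#' @return For the reader, a data.frame of per-read predictions.
#' @export
read_predictions <- function(path) {
  empty <- data.frame(read_id = character(), chrom = character(),
                      strand = character(), ref_pos = integer(),
                      prob = numeric(), call = integer(),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (nrow(dt) == 0L) return(empty)
  data.table::setnames(dt, c("read_id", "chrom", "strand", "ref_pos", "prob", "call"))
  as.data.frame(dt)
}

#' @rdname read_predictions
#' @param predictions Data frame with columns `read_id`, `chrom`, `strand`,
#'   `ref_pos`, `prob` (`call` is re-derived from `prob` by the 0.5 rule).
#' @export
write_predictions <- function(predictions, path) {
  if (nrow(predictions) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  writeLines(paste(predictions$read_id, predictions$chrom, predictions$strand,
                   predictions$ref_pos, sprintf("%.6f", predictions$prob),
                   call_methylation(predictions$prob), sep = "\t"),
             path)
  invisible(path)
}

#' Write a bedMethyl-style per-site summary
#'
#' One line per site, sorted by (chrom, pos): `chrom`, `start` (0-based),
#' `end` (= start + 1), `name` ("5mC"), `coverage`, `strand`,
#' `methylated_count`, `frequency_percent` (one decimal).
#'
#' @param summaries Site summary data frame from [summarize_sites()] (columns
#'   `chrom`, `pos`, `strand`, `coverage`, `methylated`, `frequency`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedmethyl <- function(summaries, path) {
  if (nrow(summaries) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  if (any(summaries$coverage < 1L)) stop("site summaries must have coverage >= 1")
  s <- summaries[order(summaries$chrom, summaries$pos, summaries$strand), , drop = FALSE]
  writeLines(paste(s$chrom, s$pos, s$pos + 1L, "5mC", s$coverage, s$strand,
                   s$methylated, sprintf("%.1f", 100 * s$frequency), sep = "\t"),
             path)
  invisible(path)
}

#' Read a bedMethyl-style summary written by [write_bedmethyl()]
#'
#' @param path File path.
#' @return Data frame with columns `chrom`, `pos`, `strand`, `coverage`,
#'   `methylated`, `frequency`.
#' @export
read_bedmethyl <- function(path) {
  empty <- data.frame(chrom = character(), pos = integer(), strand = character(),
                      coverage = integer(), methylated = integer(),
                      frequency = numeric(), stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (nrow(dt) == 0L) return(empty)
  data.table::setnames(dt, c("chrom", "pos", "end", "name", "coverage",
                             "strand", "methylated", "freq_pct"))
  data.frame(chrom = dt$chrom, pos = dt$pos, strand = dt$strand,
             coverage = dt$coverage, methylated = dt$methylated,
             frequency = dt$freq_pct / 100, stringsAsFactors = FALSE)
}

#' Save / load a feature-window container
#'
#' Windows are stored as two plain-text files: `<prefix>.index.tsv` (window
#' metadata and labels, one row per window) and `<prefix>.features.tsv` (the
#' stacked w-row feature matrices, `n * w` rows by 7 columns).
#'
#' @param windows A `meth_windows` object from [build_windows()].
#' @param prefix Path prefix for the two files.
#' @return For the loader, the reconstructed `meth_windows` object.
#' @export
save_windows <- function(windows, prefix) {
  w <- windows$window
  idx <- windows$meta
  idx$label <- if (is.null(windows$label)) NA_integer_ else windows$label
  idx$window <- w
  data.table::fwrite(idx, paste0(prefix, ".index.tsv"), sep = "\t")
  n <- dim(windows$x)[3L]
  flat <- matrix(aperm(windows$x, c(1L, 3L, 2L)), nrow = w * max(n, 1L), ncol = 7L)
  if (n == 0L) flat <- flat[0L, , drop = FALSE]
  data.table::fwrite(as.data.frame(flat), paste0(prefix, ".features.tsv"),
                     sep = "\t", col.names = FALSE)
  invisible(prefix)
}

#' @rdname save_windows
#' @export
load_windows <- function(prefix) {
  idx <- as.data.frame(data.table::fread(paste0(prefix, ".index.tsv"), sep = "\t"))
  w <- if (nrow(idx)) idx$window[1L] else 21L
  fm <- as.matrix(data.table::fread(paste0(prefix, ".features.tsv"),
                                    sep = "\t", header = FALSE))
  n <- nrow(idx)
  x <- array(0, dim = c(w, 7L, n))
  if (n > 0L) x <- aperm(array(fm, dim = c(w, n, 7L)), c(1L, 3L, 2L))
  label <- if (nrow(idx) && !anyNA(idx$label)) as.integer(idx$label) else NULL
  new_meth_windows(x, idx[, c("read_id", "chrom", "strand", "ref_pos")], label, w)
}
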