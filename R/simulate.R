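#' Simulation configuration
#'
#' The simulator emulates the statistical structure the caller relies on:
#' each event's clean current level depends on the k bases inside the pore
#' (k = 7 by default, matching the approximate pore footprint), and
#' 5mC at a CpG shifts the levels of the surrounding events with a
#' triangular taper, so neighboring positions carry methylation signal too.
#'
#' The per-k-mer level map is a deterministic, seeded map with N(0,
#' level_scale^2) marginals, composed of two parts: position-additive base
#' effects (fraction `sqrt(1 - kmer_frac^2)` of the sd) plus an
#' idiosyncratic per-k-mer deviation (fraction `kmer_frac`). Real pore
#' models are largely position-additive with k-mer-specific deviations;
#' the additive share is what lets a model trained on one set of sites
#' generalize to unseen sites, the deviation share is irreducible context
#' noise.
#'
#' @param genome_length Reference length (bases).
#' @param n_reads Number of reads.
#' @param read_length Events (= bases) per read.
#' @param k Pore k-mer width (odd, default 7).
#' @param level_scale Sd of per-k-mer clean levels (default 1).
#' @param kmer_frac Fraction of `level_scale` carried by the idiosyncratic
#'   per-k-mer deviation (default 0.5; 0 = purely additive map).
#' @param noise_sd Per-sample Gaussian noise sd in level units (default 0.3).
#' @param delta Methylation shift at the CpG center event, in level units
#'   (default 0.6).
#' @param shift_span Number of events around the methylated C affected by
#'   the shift (odd, default `k`; triangular taper with weight 1 at the
#'   center).
#' @param site_meth_prob Probability a CpG site is methylated (default 0.5).
#' @param read_meth_fidelity Probability a read agrees with its site's
#'   methylation status (default 1).
#' @param dwell_mean Mean samples per event (default 8; samples per event
#'   are 1 + Poisson(dwell_mean - 1), hence always >= 1).
#' @param signal_offset,signal_scale Affine map from level units to the
#'   emitted raw signal (defaults 100 and 10, a picoampere-like scale), so
#'   event tables arrive pre-normalization as they would from a sequencer.
#' @param strand_mode `"forward"` (default) or `"both"` (reads are assigned
#'   a random strand; minus-strand reads carry reverse-complement bases and
#'   levels).
#' @param chrom_name Reference record name.
#' @param seed Integer seed; all outputs are byte-reproducible under it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 10000L, n_reads = 100L,
                       read_length = 500L, k = 7L, level_scale = 1,
                       kmer_frac = 0.5, noise_sd = 0.3, delta = 0.6,
                       shift_span = k, site_meth_prob = 0.5,
                       read_meth_fidelity = 1, dwell_mean = 8,
                       signal_offset = 100, signal_scale = 10,
                       strand_mode = c("forward", "both"),
                       chrom_name = "chrSim", seed = 1L) {
  strand_mode <- match.arg(strand_mode)
  if (k %% 2L == 0L) stop("k must be odd")
  if (shift_span %% 2L == 0L) stop("shift_span must be odd")
  if (delta < 0) stop("delta must be >= 0")
  if (site_meth_prob < 0 || site_meth_prob > 1) stop("site_meth_prob in [0,1]")
  if (read_meth_fidelity < 0 || read_meth_fidelity > 1) {
    stop("read_meth_fidelity in [0,1]")
  }
  if (kmer_frac < 0 || kmer_frac > 1) stop("kmer_frac in [0,1]")
  if (dwell_mean < 1) stop("dwell_mean must be >= 1")
  structure(list(
    genome_length = as.integer(genome_length), n_reads = as.integer(n_reads),
    read_length = as.integer(read_length), k = as.integer(k),
    level_scale = level_scale, kmer_frac = kmer_frac, noise_sd = noise_sd,
    delta = delta, shift_span = as.integer(shift_span),
    site_meth_prob = site_meth_prob, read_meth_fidelity = read_meth_fidelity,
    dwell_mean = dwell_mean, signal_offset = signal_offset,
    signal_scale = signal_scale, strand_mode = strand_mode,
    chrom_name = chrom_name, seed = as.integer(seed)
  ), class = "sim_config")
}

# k-mer integer code (0-based) for every window start of an integer genome
# g0 (A=0, C=1, G=2, T=3).
.kmer_codes <- function(g0, k) {
  L <- length(g0)
  code <- integer(L - k + 1L)
  for (j in seq_len(k)) code <- code * 4L + g0[j:(L - k + j)]
  code
}

# Position-additive part of the level map for every window start.
.kmer_additive <- function(g0, k, amat) {
  L <- length(g0)
  addv <- numeric(L - k + 1L)
  for (j in seq_len(k)) addv <- addv + amat[j, g0[j:(L - k + j)] + 1L]
  addv
}

#' Simulate a nanopore methylation dataset
#'
#' Generates a uniform-random ACGT reference, draws the seeded k-mer level
#' map, assigns each CpG site a methylation status, and emits reads of
#' consecutive events: clean level of the centered k-mer, plus the
#' methylation shift (triangular taper over `shift_span` events around each
#' methylated C the read carries), plus per-sample Gaussian noise, mapped to
#' the raw signal scale. Dwell (samples per event) is 1 + Poisson.
#'
#' @param cfg A [sim_config()].
#' @param out_prefix Optional path prefix; when given, writes
#'   `<prefix>.fa` (reference), `<prefix>.events.tsv`, `<prefix>.labels.tsv`
#'   and `<prefix>.truth.bed` (per-site truth in bedMethyl layout).
#' @return List of class `meth_sim`: `genome` (DNAStringSet), `events`,
#'   `labels`, `truth` (per-site `status`, `coverage`, `rho` = realized
#'   per-read methylation rate), `sites`, `position_level` (clean level per
#'   0-based genome position, NA at edges), `level_map` (additive matrix +
#'   deviation table), `config`.
#' @export
simulate_nanopore <- function(cfg, out_prefix = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  L <- cfg$genome_length
  rl <- cfg$read_length
  k <- cfg$k
  h <- k %/% 2L
  if (L < rl + 2L * h + 2L) stop("genome too short for read_length")
  set.seed(cfg$seed)

  g0 <- sample.int(4L, L, replace = TRUE) - 1L
  genome_chars <- .valid_bases[g0 + 1L]
  genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
  names(genome) <- cfg$chrom_name

  sd_add <- cfg$level_scale * sqrt(1 - cfg$kmer_frac^2)
  amat <- matrix(rnorm(4L * k, 0, sd_add / sqrt(k)), k, 4L, byrow = FALSE)
  dev <- rnorm(4L^k, 0, cfg$level_scale * cfg$kmer_frac)
  codes <- .kmer_codes(g0, k)
  addv <- .kmer_additive(g0, k, amat)
  position_level <- rep(NA_real_, L)
  position_level[(h + 1L):(L - h)] <- addv + dev[codes + 1L]
  level_minus <- NULL
  if (cfg$strand_mode == "both") {
    g0c <- 3L - g0
    # reverse-complement k-mer centered at the same position
    codes_rc <- integer(L - k + 1L)
    addv_rc <- numeric(L - k + 1L)
    for (j in seq_len(k)) {
      b <- g0c[(k - j + 1L):(L - j + 1L)]
      codes_rc <- codes_rc * 4L + b
      addv_rc <- addv_rc + amat[j, b + 1L]
    }
    level_minus <- rep(NA_real_, L)
    level_minus[(h + 1L):(L - h)] <- addv_rc + dev[codes_rc + 1L]
  }

  # CpG sites on the forward strand (1-based C positions)
  cpg1 <- which(g0[seq_len(L - 1L)] == 1L & g0[2:L] == 2L)
  cpg1 <- cpg1[cpg1 > h & cpg1 < L - h]
  status <- rbinom(length(cpg1), 1L, cfg$site_meth_prob)

  start_min <- h + 1L
  start_max <- L - rl + 1L - h
  starts <- sample(start_min:start_max, cfg$n_reads, replace = TRUE)
  strands <- if (cfg$strand_mode == "both") {
    c("+", "-")[1L + rbinom(cfg$n_reads, 1L, 0.5)]
  } else rep("+", cfg$n_reads)

  span_h <- cfg$shift_span %/% 2L
  taper <- 1 - abs(seq.int(-span_h, span_h)) / (span_h + 1)

  ev_read <- ev_pos <- ev_base <- ev_strand <- vector("list", cfg$n_reads)
  ev_samples <- vector("list", cfg$n_reads)
  lab_read <- lab_pos <- lab_lab <- lab_strand <- vector("list", cfg$n_reads)
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  for (r in seq_len(cfg$n_reads)) {
    s <- starts[r]
    posn <- s:(s + rl - 1L)
    strand <- strands[r]
    minus <- strand == "-"
    site_pos1 <- if (minus) cpg1 + 1L else cpg1
    sidx <- which(site_pos1 >= s & site_pos1 <= s + rl - 1L)
    lab <- status[sidx]
    if (cfg$read_meth_fidelity < 1 && length(lab)) {
      flip <- runif(length(lab)) < 1 - cfg$read_meth_fidelity
      lab <- ifelse(flip, 1L - lab, lab)
    }
    shift <- numeric(rl)
    for (i in which(lab == 1L)) {
      o <- site_pos1[sidx[i]] - s + 1L
      lo <- max(1L, o - span_h)
      hi <- min(rl, o + span_h)
      shift[lo:hi] <- shift[lo:hi] + cfg$delta * taper[(lo - o + span_h + 1L):(hi - o + span_h + 1L)]
    }
    base_level <- if (minus) level_minus[posn] else position_level[posn]
    clean <- base_level + shift
    ns <- 1L + rpois(rl, cfg$dwell_mean - 1)
    raw <- cfg$signal_offset + cfg$signal_scale *
      (rep(clean, ns) + rnorm(sum(ns), 0, cfg$noise_sd))
    rid <- sprintf("read_%05d", r)
    ev_read[[r]] <- rep(rid, rl)
    ev_pos[[r]] <- posn - 1L
    ev_base[[r]] <- if (minus) unname(comp[genome_chars[posn]]) else genome_chars[posn]
    ev_strand[[r]] <- rep(strand, rl)
    ev_samples[[r]] <- unname(split(raw, rep(seq_len(rl), ns)))
    lab_read[[r]] <- rep(rid, length(sidx))
    lab_pos[[r]] <- site_pos1[sidx] - 1L
    lab_lab[[r]] <- as.integer(lab)
    lab_strand[[r]] <- rep(strand, length(sidx))
  }

  events <- data.frame(
    read_id = unlist(ev_read), chrom = cfg$chrom_name,
    strand = unlist(ev_strand),
    ref_pos = unlist(ev_pos), ref_base = unlist(ev_base),
    stringsAsFactors = FALSE
  )
  events$samples <- unlist(ev_samples, recursive = FALSE)

  labels <- data.frame(
    read_id = unlist(lab_read), chrom = cfg$chrom_name,
    strand = unlist(lab_strand),
    ref_pos = if (is.null(unlist(lab_pos))) integer() else unlist(lab_pos),
    label = if (is.null(unlist(lab_lab))) integer() else unlist(lab_lab),
    stringsAsFactors = FALSE
  )

  sites <- data.frame(chrom = cfg$chrom_name, pos = cpg1 - 1L, strand = "+",
                      status = status, stringsAsFactors = FALSE)
  truth <- .site_truth(labels, sites, cfg)

  out <- structure(list(
    genome = genome, events = events, labels = labels, truth = truth,
    sites = sites, position_level = position_level,
    level_map = list(additive = amat, deviation = dev), config = cfg
  ), class = "meth_sim")

  if (!is.null(out_prefix)) {
    write_fasta(genome, paste0(out_prefix, ".fa"))
    write_event_table(events, paste0(out_prefix, ".events.tsv"))
    write_labels(labels, paste0(out_prefix, ".labels.tsv"))
    tb <- truth
    tb$methylated <- tb$meth_reads
    tb$frequency <- tb$rho
    write_bedmethyl(tb[tb$coverage >= 1L, ], paste0(out_prefix, ".truth.bed"))
  }
  out
}

.site_truth <- function(labels, sites, cfg) {
  key_site <- paste(sites$chrom, sites$pos, "+")
  # minus-strand labels refer to the G of the forward CpG; map back to the C
  lpos <- ifelse(labels$strand == "-", labels$ref_pos - 1L, labels$ref_pos)
  key_lab <- paste(labels$chrom, lpos, "+")
  cov <- as.integer(table(factor(key_lab, levels = key_site)))
  meth <- as.integer(tapply(labels$label, factor(key_lab, levels = key_site), sum,
                            default = 0L))
  data.frame(chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
             status = sites$status, coverage = cov, meth_reads = meth,
             rho = ifelse(cov > 0L, meth / cov, NA_real_),
             stringsAsFactors = FALSE)
}

#' @export
print.meth_sim <- function(x, ...) {
  cat(sprintf(
    "meth_sim: %d bp genome, %d reads x %d events, %d CpG sites (%.0f%% methylated), delta=%.2f\n",
    x$config$genome_length, x$config$n_reads, x$config$read_length,
    nrow(x$sites), 100 * mean(x$sites$status), x$config$delta))
  invisible(x)
}

#' Clean level of arbitrary k-mers under a simulation's level map
#'
#' Exposes the seeded level map so runs are auditable: the same k-mer always
#' maps to the same clean level within a run.
#'
#' @param sim A `meth_sim` object.
#' @param kmers Character vector of k-mers (A/C/G/T, length `config$k`).
#' @return Numeric vector of clean levels (level units).
#' @export
sim_kmer_level <- function(sim, kmers) {
  k <- sim$config$k
  vapply(kmers, function(km) {
    b <- match(strsplit(km, "")[[1L]], .valid_bases) - 1L
    if (length(b) != k || anyNA(b)) stop("k-mer must be ", k, " ACGT bases")
    code <- 0L
    for (j in seq_len(k)) code <- code * 4L + b[j]
    sum(sim$level_map$additive[cbind(seq_len(k), b + 1L)]) +
      sim$level_map$deviation[code + 1L]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Per-site coverage with full window context
#'
#' Tabulates, for each CpG site, the reads that overlap it with at least
#' floor(w/2) events on both sides -- i.e. the reads that can contribute a
#' full feature window for the site.
#'
#' @param truth Per-site truth table (needs `chrom`, `pos`, `strand`).
#' @param events Event table.
#' @param w Window size used downstream (default 21).
#' @return `truth` with an added `context_coverage` column.
#' @export
truth_coverage_report <- function(truth, events, w = 21L) {
  half <- w %/% 2L
  out <- truth
  out$context_coverage <- 0L
  if (nrow(events) == 0L || nrow(truth) == 0L) return(out)
  rng <- do.call(rbind, lapply(split(events$ref_pos, events$read_id), range))
  for (i in seq_len(nrow(rng))) {
    hit <- out$pos >= rng[i, 1L] + half & out$pos <= rng[i, 2L] - half
    out$context_coverage[hit] <- out$context_coverage[hit] + 1L
  }
  out
}
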