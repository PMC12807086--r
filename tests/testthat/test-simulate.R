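test_that("simulation is byte-reproducible under its seed", {
  cfg <- sim_config(genome_length = 800L, n_reads = 6L, read_length = 120L,
                    seed = 99L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_nanopore(cfg, out_prefix = file.path(d1, "run"))
  simulate_nanopore(cfg, out_prefix = file.path(d2, "run"))
  for (f in c("run.fa", "run.events.tsv", "run.labels.tsv", "run.truth.bed")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  s3 <- simulate_nanopore(sim_config(genome_length = 800L, n_reads = 6L,
                                     read_length = 120L, seed = 100L))
  expect_false(identical(as.character(s3$genome),
                         as.character(simulate_nanopore(cfg)$genome)))
})

test_that("outputs are mutually consistent", {
  cfg <- sim_config(genome_length = 1500L, n_reads = 12L, read_length = 200L,
                    seed = 5L, site_meth_prob = 0.4)
  sim <- simulate_nanopore(cfg)
  expect_equal(nrow(sim$events), 12L * 200L)
  # every event base matches the reference (forward strand)
  chars <- strsplit(as.character(sim$genome[[1L]]), "")[[1L]]
  expect_identical(sim$events$ref_base, chars[sim$events$ref_pos + 1L])
  # every labeled site is a CpG C and truth rho aggregates the labels
  expect_true(all(sim$labels$ref_pos %in% sim$sites$pos))
  agg <- tapply(sim$labels$label, sim$labels$ref_pos, mean)
  covered <- sim$truth[sim$truth$coverage > 0L, ]
  expect_equal(as.vector(agg[as.character(covered$pos)]), covered$rho)
  # with perfect fidelity, rho equals the planted status
  expect_equal(covered$rho, as.numeric(covered$status))
})

test_that("dwell times are shifted-Poisson with the configured mean", {
  cfg <- sim_config(genome_length = 3000L, n_reads = 10L, read_length = 1200L,
                    dwell_mean = 8, seed = 12L)
  sim <- simulate_nanopore(cfg)
  ns <- lengths(sim$events$samples)
  expect_true(all(ns >= 1L))
  expect_lt(abs(mean(ns) - 8) / 8, 0.05)
})

test_that("the level map is a pure function of the k-mer", {
  cfg <- sim_config(genome_length = 2000L, n_reads = 2L, read_length = 100L,
                    seed = 3L)
  sim <- simulate_nanopore(cfg)
  chars <- strsplit(as.character(sim$genome[[1L]]), "")[[1L]]
  k <- cfg$k
  h <- k %/% 2L
  kmer_at <- function(p1) paste(chars[(p1 - h):(p1 + h)], collapse = "")
  interior <- (h + 1L):(cfg$genome_length - h)
  kmers <- vapply(interior, kmer_at, character(1))
  # positions sharing a k-mer share a clean level
  dups <- split(interior, kmers)
  dups <- dups[lengths(dups) > 1L][1:5]
  for (d in dups) {
    expect_equal(length(unique(sim$position_level[d])), 1L)
  }
  # and the exported map reproduces the per-position levels
  some <- sample(interior, 20L)
  expect_equal(sim_kmer_level(sim, vapply(some, kmer_at, character(1))),
               sim$position_level[some], tolerance = 1e-12)
})

test_that("methylated fraction of sites tracks site_meth_prob", {
  cfg <- sim_config(genome_length = 30000L, n_reads = 1L, read_length = 100L,
                    site_meth_prob = 0.5, seed = 8L)
  sim <- simulate_nanopore(cfg)
  n <- nrow(sim$sites)
  expect_gt(n, 1000L)
  phat <- mean(sim$sites$status)
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / n))
})

test_that("delta shifts the methylated center-event mean by delta", {
  cfg <- sim_config(genome_length = 12000L, n_reads = 60L, read_length = 400L,
                    delta = 2, noise_sd = 0.3, seed = 21L)
  sim <- simulate_nanopore(cfg)
  ev_mean <- vapply(sim$events$samples, mean, numeric(1))
  key <- paste(sim$events$read_id, sim$events$ref_pos)
  lkey <- paste(sim$labels$read_id, sim$labels$ref_pos)
  lab <- sim$labels$label[match(key, lkey)]
  # compare against the site's clean unmethylated level, in level units
  base <- cfg$signal_offset + cfg$signal_scale * sim$position_level[sim$events$ref_pos + 1L]
  excess <- (ev_mean - base) / cfg$signal_scale
  d_m <- mean(excess[which(lab == 1L)])
  d_u <- mean(excess[which(lab == 0L)])
  expect_gt(sum(lab == 1L, na.rm = TRUE), 500L)
  expect_lt(abs((d_m - d_u) - 2), 0.1)
})

test_that("delta = 0 leaves methylated and unmethylated signals indistinguishable", {
  cfg <- sim_config(genome_length = 12000L, n_reads = 60L, read_length = 400L,
                    delta = 0, seed = 22L)
  sim <- simulate_nanopore(cfg)
  ev_mean <- vapply(sim$events$samples, mean, numeric(1))
  key <- paste(sim$events$read_id, sim$events$ref_pos)
  lkey <- paste(sim$labels$read_id, sim$labels$ref_pos)
  lab <- sim$labels$label[match(key, lkey)]
  base <- cfg$signal_offset + cfg$signal_scale * sim$position_level[sim$events$ref_pos + 1L]
  excess <- (ev_mean - base) / cfg$signal_scale
  m <- excess[which(lab == 1L)]
  u <- excess[which(lab == 0L)]
  ks <- suppressWarnings(stats::ks.test(sample(m, 500L), sample(u, 500L)))
  expect_gt(ks$p.value, 0.01)
})

test_that("minus-strand reads carry complemented bases", {
  cfg <- sim_config(genome_length = 1500L, n_reads = 20L, read_length = 150L,
                    strand_mode = "both", seed = 31L)
  sim <- simulate_nanopore(cfg)
  expect_setequal(unique(sim$events$strand), c("+", "-"))
  chars <- strsplit(as.character(sim$genome[[1L]]), "")[[1L]]
  minus <- sim$events[sim$events$strand == "-", ]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_identical(minus$ref_base, unname(comp[chars[minus$ref_pos + 1L]]))
})

test_that("coverage with window context follows the Lander-Waterman expectation", {
  cfg <- sim_config(genome_length = 20000L, n_reads = 200L, read_length = 500L,
                    seed = 13L)
  sim <- simulate_nanopore(cfg)
  rep0 <- truth_coverage_report(sim$truth, sim$events, w = 21L)
  expected <- cfg$n_reads * cfg$read_length / cfg$genome_length
  expect_lt(abs(mean(rep0$context_coverage) - expected) / expected, 0.1)

  empty <- truth_coverage_report(sim$truth, sim$events[0L, ], w = 21L)
  expect_true(all(empty$context_coverage == 0L))

  one <- sim$events[sim$events$read_id == sim$events$read_id[1L], ]
  site1 <- sim$truth[sim$truth$pos > min(one$ref_pos) + 10L &
                       sim$truth$pos < max(one$ref_pos) - 10L, ][1L, ]
  r1 <- truth_coverage_report(site1, one, w = 21L)
  expect_equal(r1$context_coverage, 1L)
})

test_that("simulation rejects a genome too short for the reads", {
  expect_error(simulate_nanopore(sim_config(genome_length = 100L,
                                            read_length = 99L)),
               "too short")
})
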