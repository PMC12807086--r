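#' Run the full pipeline on a simulated dataset
#'
#' Simulate -> normalize -> featurize -> train -> predict -> summarize, the
#' end-to-end parameter-recovery experiment: a dataset with known per-site
#' methylation status is generated, the caller is trained on a site-grouped
#' training split, and both read-level (held-out sites) and site-level
#' (genome-scale summary vs planted truth) recovery are measured.
#'
#' @param scfg A [sim_config()].
#' @param mcfg A [model_config()].
#' @param tcfg A [train_config()].
#' @param min_site_coverage Coverage threshold for the site-level evaluation
#'   (default 20).
#' @param quiet Suppress per-epoch logging.
#' @return List of class `meth_study`: `sim`, `windows`, `fit`,
#'   `predictions`, `site_summary`, `site_eval` (per-site call vs truth at
#'   the coverage threshold), `holdout` (read-level metrics on held-out
#'   sites), `site_metrics` (site-status accuracy and mean |frequency - rho|).
#' @export
run_simulation_study <- function(scfg, mcfg = model_config(),
                                 tcfg = train_config(), min_site_coverage = 20L,
                                 quiet = FALSE) {
  sim <- simulate_nanopore(scfg)
  events <- normalize_events(sim$events)
  cand <- cpg_sites(sim$genome,
                    if (scfg$strand_mode == "both") "both" else "forward")
  windows <- build_windows(events, cand, w = mcfg$window, labels = sim$labels)
  fit <- train_transformer(windows, mcfg, tcfg, quiet = quiet)
  predictions <- predict_windows(fit$model, windows)
  site_summary <- summarize_sites(predictions)

  truth <- sim$truth
  key_s <- paste(site_summary$chrom, site_summary$pos, site_summary$strand)
  key_t <- paste(truth$chrom, truth$pos, truth$strand)
  m <- match(key_s, key_t)
  se <- cbind(site_summary, truth[m, c("status", "rho"), drop = FALSE])
  se <- se[!is.na(se$status) & se$coverage >= min_site_coverage, , drop = FALSE]
  rownames(se) <- NULL
  se$status_call <- as.integer(se$frequency > 0.5)

  site_metrics <- list(
    n_sites = nrow(se),
    status_accuracy = if (nrow(se)) mean(se$status_call == se$status) else NA_real_,
    freq_mae = if (nrow(se)) mean(abs(se$frequency - se$rho)) else NA_real_,
    min_coverage = min_site_coverage
  )

  structure(list(sim = sim, windows = windows, fit = fit,
                 predictions = predictions, site_summary = site_summary,
                 site_eval = se, holdout = fit$validation,
                 site_metrics = site_metrics),
            class = "meth_study")
}

#' @export
print.meth_study <- function(x, ...) {
  h <- x$holdout
  s <- x$site_metrics
  cat(sprintf("meth_study on %d windows (%d CpG sites)\n",
              dim(x$windows$x)[3L], nrow(x$sim$sites)))
  cat(sprintf("  held-out reads: F1 %.4f, AUC %.4f, accuracy %.4f (n = %d)\n",
              h$metrics$f1, h$auc, h$metrics$accuracy, h$n))
  cat(sprintf("  sites (coverage >= %d): status accuracy %.4f, mean |freq - rho| %.4f (n = %d)\n",
              s$min_coverage, s$status_accuracy, s$freq_mae, s$n_sites))
  invisible(x)
}
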