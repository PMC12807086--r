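#' Aggregate per-read predictions into per-site methylation frequencies
#'
#' Groups predictions by (chrom, pos, strand): coverage is the group size,
#' `methylated` the number of hard calls equal to 1, and `frequency` their
#' ratio. The mean methylation probability is carried along as auxiliary
#' output. Sites below `min_coverage` are dropped (their total coverage is
#' recorded in the `dropped_coverage` attribute) and the result is sorted by
#' chrom, pos, strand.
#'
#' @param predictions Data frame with columns `chrom`, `ref_pos` (or `pos`),
#'   `strand`, `call`, `prob`.
#' @param min_coverage Minimum reads per site (default 1).
#' @return Data frame: `chrom`, `pos`, `strand`, `coverage`, `methylated`,
#'   `frequency`, `mean_prob`.
#' @export
summarize_sites <- function(predictions, min_coverage = 1L) {
  pos <- if ("ref_pos" %in% names(predictions)) predictions$ref_pos else predictions$pos
  dt <- data.table::data.table(
    chrom = predictions$chrom, pos = pos, strand = predictions$strand,
    call = as.integer(predictions$call), prob = predictions$prob
  )
  agg <- dt[, list(coverage = .N, methylated = sum(call),
                   mean_prob = mean(prob)),
            by = c("chrom", "pos", "strand")]
  dropped <- sum(agg$coverage[agg$coverage < min_coverage])
  agg <- agg[agg$coverage >= min_coverage, ]
  data.table::setorder(agg, chrom, pos, strand)
  out <- data.frame(chrom = agg$chrom, pos = agg$pos, strand = agg$strand,
                    coverage = agg$coverage, methylated = agg$methylated,
                    frequency = agg$methylated / agg$coverage,
                    mean_prob = agg$mean_prob, stringsAsFactors = FALSE)
  attr(out, "dropped_coverage") <- dropped
  out
}
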