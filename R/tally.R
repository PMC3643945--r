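#' Tally type 1 error across replicates
#'
#' For association scans, the rate at threshold `t` is the mean over
#' replicates of (number of testable SNPs with p below `t`) / (number of
#' testable SNPs); monomorphic/not-testable loci are excluded from both
#' numerator and denominator.  For linkage scans pass `denominator` to
#' divide by a fixed panel size (the literal "divide by 124" convention)
#' and `stat_high = TRUE` so scores above the threshold count.
#'
#' @param stat replicates x loci matrix of p-values (or HLOD scores);
#'   `NA` = not testable.
#' @param thresholds numeric thresholds.
#' @param denominator optional fixed per-replicate denominator (e.g. 124);
#'   default: testable loci per replicate.
#' @param stat_high if `TRUE`, count `stat > threshold` (LOD-type scores)
#'   instead of `stat < threshold` (p-values).
#' @return data.frame with `threshold`, `rate_pct` (mean percentage) and
#'   `se_pct` (Monte-Carlo standard error of the mean, in percentage
#'   points), plus `n_replicates`.
#' @export
tally_type1 <- function(stat, thresholds, denominator = NULL,
                        stat_high = FALSE) {
  if (!is.matrix(stat) || nrow(stat) == 0)
    ped_stop("empty_results", "no replicate results to tally")
  rows <- lapply(thresholds, function(t) {
    hit <- if (stat_high) stat > t else stat < t
    cnt <- rowSums(hit, na.rm = TRUE)
    den <- if (is.null(denominator)) rowSums(!is.na(stat)) else denominator
    r <- 100 * cnt / den
    data.frame(threshold = t, rate_pct = mean(r),
               se_pct = sd(r) / sqrt(length(r)),
               n_replicates = nrow(stat))
  })
  do.call(rbind, rows)
}

#' Tally power at the disease SNP across replicates
#'
#' Percentage of replicates whose disease-SNP p-value (or HLOD) beats each
#' threshold.  A replicate where the disease SNP is not testable counts as
#' a miss.
#'
#' @param stat vector (one entry per replicate) of disease-SNP p-values or
#'   HLOD scores; `NA` = not testable (counted as a miss).
#' @param thresholds numeric thresholds.
#' @param stat_high if `TRUE`, count `stat >= threshold` (HLOD-type);
#'   otherwise `stat <= threshold` (p-values).
#' @return data.frame with `threshold`, `power_pct`, `se_pct`,
#'   `n_replicates`.
#' @export
tally_power <- function(stat, thresholds, stat_high = FALSE) {
  if (!length(stat))
    ped_stop("empty_results", "no replicate results to tally")
  if (anyNA(stat))
    message(sum(is.na(stat)), " replicate(s) with untestable disease SNP counted as misses")
  rows <- lapply(thresholds, function(t) {
    hit <- if (stat_high) stat >= t else stat <= t
    hit[is.na(hit)] <- FALSE
    data.frame(threshold = t, power_pct = 100 * mean(hit),
               se_pct = 100 * sd(hit) / sqrt(length(hit)),
               n_replicates = length(stat))
  })
  do.call(rbind, rows)
}

# default threshold sets
p_thresholds_power <- function() c(0.05, 5e-3, 5e-4, 5e-5, 5e-6, 5e-7, 5e-8)
p_thresholds_null <- function() c(0.05, 0.01, 0.005, 0.001)
hlod_thresholds <- function() c(1, 2, 3)
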