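#' GenTrain/GenCall quality filtering
#'
#' Removes loci whose per-locus GenTrain clustering score is below
#' `gentrain_min` (strict `<`, so a score exactly at the threshold is kept),
#' blanks individual calls whose GenCall confidence is below `gencall_min`
#' (strict `<`), and finally drops loci left with no call in any sample.
#' GenTrain is a per-locus score and GenCall a per-call score, so the two
#' thresholds act at different granularities. Absent scores are treated as
#' passing and counted in the report. The operation is idempotent.
#'
#' @param m a [genotype_matrix()].
#' @param gentrain_min,gencall_min thresholds in \[0, 1\]; defaults 0.4 / 0.2.
#' @return a list with `matrix` (the filtered [genotype_matrix()]) and
#'   `report`, a tibble with one row per filtering stage
#'   (`stage`, `removed`, `detail`).
#' @export
apply_quality_filters <- function(m, gentrain_min = 0.4, gencall_min = 0.2) {
  stopifnot(gentrain_min >= 0, gentrain_min <= 1,
            gencall_min >= 0, gencall_min <= 1)
  gt <- m$loci$gentrain
  gt_absent <- sum(is.na(gt))
  drop_gt <- !is.na(gt) & gt < gentrain_min
  m1 <- gm_subset(m, loci = !drop_gt)

  blanked <- 0L
  gc_absent <- if (is.null(m1$gencall)) length(m1$calls) else sum(is.na(m1$gencall))
  if (!is.null(m1$gencall)) {
    low <- !is.na(m1$gencall) & m1$gencall < gencall_min & !is.na(m1$calls)
    blanked <- sum(low)
    m1$calls[low] <- NA_integer_
  }

  all_missing <- colSums(!is.na(m1$calls)) == 0L
  m2 <- gm_subset(m1, loci = !all_missing)

  report <- tibble::tibble(
    stage = c("gentrain_locus", "gencall_call", "all_missing_locus"),
    removed = c(sum(drop_gt), blanked, sum(all_missing)),
    detail = c(
      sprintf("loci with GenTrain < %g removed (%d loci had no score)",
              gentrain_min, gt_absent),
      sprintf("calls with GenCall < %g set to missing (%d calls had no score)",
              gencall_min, gc_absent),
      "loci missing in every sample removed"
    )
  )
  list(matrix = m2, report = report)
}

#' Missing-data accounting
#'
#' `obtained` is the number of non-missing calls in the matrix; `possible`
#' defaults to the full grid but can be set to the submitted loci x submitted
#' samples product so the percentage reflects attrition from what was sent
#' for genotyping, as array bookkeeping conventionally does.
#'
#' @param m a [genotype_matrix()].
#' @param possible total possible data points; default `nrow * ncol` of `m`.
#' @return tibble with `obtained`, `possible`, `percent_missing`
#'   (100 * (1 - obtained/possible)) and its nearest-integer rounding.
#' @export
missing_data_summary <- function(m, possible = NULL) {
  obtained <- sum(!is.na(m$calls))
  if (is.null(possible)) possible <- length(m$calls)
  if (possible == 0) stop("possible = 0: percent missing undefined")
  pct <- 100 * (1 - obtained / possible)
  tibble::tibble(
    obtained = obtained, possible = possible,
    percent_missing = pct, percent_missing_int = round_half_up(pct, 0)
  )
}

#' Find (near-)duplicate samples
#'
#' All unordered sample pairs whose mismatch fraction over co-typed loci
#' (loci missing in either member are ignored) is at most
#' `max_mismatch_frac`. Pairs with zero co-typed loci cannot be compared and
#' are returned flagged instead of judged.
#'
#' @param m a [genotype_matrix()].
#' @param max_mismatch_frac tolerated mismatch fraction in \[0, 1).
#' @return tibble with `sample_a`, `sample_b`, `n_compared`, `n_mismatch`,
#'   `mismatch_frac`, `comparable` (FALSE for zero co-typed loci).
#' @export
find_duplicate_samples <- function(m, max_mismatch_frac = 0) {
  stopifnot(max_mismatch_frac >= 0, max_mismatch_frac < 1)
  x <- m$calls
  n <- nrow(x)
  if (n < 2L) {
    return(tibble::tibble(sample_a = character(), sample_b = character(),
                          n_compared = integer(), n_mismatch = integer(),
                          mismatch_frac = double(), comparable = logical()))
  }
  # matches between samples a,b = sum over genotype states g of
  # (x_a == g)(x_b == g); co-typed = (obs_a)(obs_b). Three BLAS products keep
  # this O(n^2 m) but vectorized.
  obs <- !is.na(x)
  typed <- obs %*% t(obs)
  match_ct <- matrix(0, n, n)
  for (g in 0:2) {
    ind <- (x == g) & obs
    storage.mode(ind) <- "double"
    match_ct <- match_ct + ind %*% t(ind)
  }
  mism <- typed - match_ct
  idx <- which(upper.tri(typed), arr.ind = TRUE)
  n_comp <- typed[idx]
  n_mis <- mism[idx]
  frac <- ifelse(n_comp > 0, n_mis / n_comp, NA_real_)
  keep <- (n_comp > 0 & frac <= max_mismatch_frac) | n_comp == 0
  tibble::tibble(
    sample_a = rownames(x)[idx[keep, 1]],
    sample_b = rownames(x)[idx[keep, 2]],
    n_compared = as.integer(n_comp[keep]),
    n_mismatch = as.integer(n_mis[keep]),
    mismatch_frac = frac[keep],
    comparable = n_comp[keep] > 0
  )
}

#' Percent heterozygosity of a sample
#'
#' @param m a [genotype_matrix()].
#' @param sample a sample id present in `m`.
#' @return percent of non-missing calls that are heterozygous.
#' @export
heterozygosity <- function(m, sample) {
  if (!sample %in% rownames(m$calls)) stop("unknown sample: ", sample)
  g <- m$calls[sample, ]
  g <- g[!is.na(g)]
  if (!length(g)) stop("sample ", sample, " has no non-missing calls")
  100 * mean(g == 1L)
}

# round-half-up (the presentation rounding used for reported percents; R's
# round() is half-to-even)
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}
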