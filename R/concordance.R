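# Cross-platform genotype comparison: a 3x3 contingency grid of array calls
# (rows) against sequencing calls (columns) over the jointly called loci.

CONC_CLASSES <- c("HOM_REF", "HET", "HOM_ALT")

new_concordance_table <- function(counts, label = NA_character_) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3, 3)))
  dimnames(counts) <- list(array = CONC_CLASSES, sequencing = CONC_CLASSES)
  n <- sum(counts)
  conc <- sum(diag(counts))
  structure(
    list(
      counts = counts, label = label,
      n_compared = n, n_concordant = conc, n_discordant = n - conc,
      percent_concordant_raw = if (n > 0) 100 * conc / n else NA_real_,
      percent_concordant = if (n > 0) round_half_up(100 * conc / n, 0) else NA_real_
    ),
    class = "concordance_table"
  )
}

#' Build a cross-platform concordance table
#'
#' Counts jointly called loci into a 3x3 grid of array genotype (rows)
#' against sequencing genotype (columns); loci missing on either platform
#' are excluded. The reported integer percent uses half-up rounding; the raw
#' ratio is retained alongside.
#'
#' @param array_calls,seq_calls call codes (0/1/2/NA) over aligned loci, or a
#'   3x3 count grid passed directly via [concordance_table()].
#' @param label optional sample label carried in the result.
#' @return a `concordance_table` object.
#' @export
build_concordance <- function(array_calls, seq_calls, label = NA_character_) {
  stopifnot(length(array_calls) == length(seq_calls))
  ok <- !is.na(array_calls) & !is.na(seq_calls)
  if (!any(ok)) stop("no jointly called loci: percent concordance undefined")
  counts <- table(
    factor(array_calls[ok], levels = 0:2),
    factor(seq_calls[ok], levels = 0:2)
  )
  new_concordance_table(unclass(counts), label = label)
}

#' @rdname build_concordance
#' @param counts a 3x3 numeric grid (array in rows, sequencing in columns,
#'   both in HOM_REF/HET/HOM_ALT order), e.g. a published contingency table.
#' @export
concordance_table <- function(counts, label = NA_character_) {
  new_concordance_table(counts, label = label)
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf("<concordance_table>%s n = %d, concordant = %d (%g%%)\n",
              if (is.na(x$label)) "" else paste0(" ", x$label),
              x$n_compared, x$n_concordant, x$percent_concordant))
  print(x$counts)
  invisible(x)
}

#' One-row summary of a concordance table
#' @param x a `concordance_table`.
#' @param ... unused.
#' @return tibble with label, counts and percents.
#' @export
#' @method glance concordance_table
glance.concordance_table <- function(x, ...) {
  tibble::tibble(
    label = x$label, n_compared = x$n_compared,
    n_concordant = x$n_concordant, n_discordant = x$n_discordant,
    percent_concordant_raw = x$percent_concordant_raw,
    percent_concordant = x$percent_concordant
  )
}

#' Pool concordance tables by summing their grids
#'
#' The pooled percent is recomputed from the pooled counts (never a mean of
#' per-table percents).
#'
#' @param tables a list of `concordance_table` objects.
#' @param label optional label for the pooled table.
#' @return a `concordance_table`.
#' @export
pool_concordance <- function(tables, label = "pooled") {
  stopifnot(length(tables) >= 1)
  counts <- Reduce(`+`, lapply(tables, function(t) t$counts))
  new_concordance_table(counts, label = label)
}

#' Classify discordant calls
#'
#' Splits the off-diagonal mass of a concordance table into the three
#' biologically distinct classes: array heterozygous vs sequencing
#' homozygous, array homozygous vs sequencing heterozygous, and opposite
#' homozygotes. The class counts sum to `n_discordant`.
#'
#' @param t a `concordance_table`.
#' @return tibble with `class` and `count`.
#' @export
discordance_profile <- function(t) {
  cts <- t$counts
  tibble::tibble(
    class = c("array_het_seq_hom", "array_hom_seq_het", "hom_hom_opposite"),
    count = c(
      cts["HET", "HOM_REF"] + cts["HET", "HOM_ALT"],
      cts["HOM_REF", "HET"] + cts["HOM_ALT", "HET"],
      cts["HOM_REF", "HOM_ALT"] + cts["HOM_ALT", "HOM_REF"]
    )
  )
}

#' Published control-clone concordance grids for the cacao 15K array
#'
#' The six 3x3 contingency grids (array genotype in rows, sequencing
#' genotype in columns, HOM_REF/HET/HOM_ALT order) comparing the array calls
#' of the six diversity-panel control clones with their sequencing-based
#' calls, as published with the array. Used to reproduce the per-clone and
#' pooled concordance statistics.
#'
#' @return named list of six 3x3 integer matrices.
#' @export
cacao15k_concordance_grids <- function() {
  g <- function(...) matrix(c(...), nrow = 3, byrow = TRUE)
  list(
    `Matina 1-6` = g(10604, 9, 0,
                     11, 0, 0,
                     19, 0, 0),
    `Criollo 13` = g(2114, 10, 14,
                     10, 5, 11,
                     22, 6, 8383),
    `TSH 1188` = g(4425, 25, 1,
                   805, 3305, 258,
                   35, 13, 1598),
    `CCN 51` = g(4015, 22, 1,
                 693, 4417, 198,
                 17, 12, 1207),
    `Pound 7` = g(6648, 11, 1,
                  139, 2079, 19,
                  22, 5, 1711),
    `UF273 Type I` = g(4069, 20, 4,
                       479, 3069, 102,
                       26, 14, 2860)
  )
}
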