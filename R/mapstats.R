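# Summary statistics of a finished linkage map against the physical
# assembly, plus collinearity and scaffold-placement diagnostics.

#' Per-linkage-group summary of a linkage map
#'
#' For each LG: marker count, genetic length (max - min cM), largest
#' adjacent cM gap, the physical length of its chromosome, genome coverage
#' (anchored physical span over chromosome length), SNPs/cM, bp/cM
#' (chromosome length over map length) and bp/SNP (chromosome length over
#' marker count). A `Total` row sums counts and lengths and recomputes the
#' ratio columns from the sums.
#'
#' @param map tibble with `marker`, `lg`, `cm`.
#' @param anchors tibble with `marker`, `chrom`, `pos` giving physical
#'   placements; markers without anchors are ignored for physical columns.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp,
#'   named by the chromosome each LG corresponds to (`as.character(lg)`).
#' @return tibble, one row per LG plus a `Total` row.
#' @export
map_summary <- function(map, anchors, chrom_lengths) {
  lgs <- sort(unique(map$lg))
  rows <- lapply(lgs, function(g) {
    sub <- map[map$lg == g, , drop = FALSE]
    sub <- sub[order(sub$cm), , drop = FALSE]
    if (nrow(sub) < 2) {
      return(tibble::tibble(
        lg = as.character(g), n_snps = nrow(sub), length_cm = NA_real_,
        largest_gap_cm = NA_real_, chrom_length_bp = NA_real_,
        coverage_pct = NA_real_, snps_per_cm = NA_real_, bp_per_cm = NA_real_,
        bp_per_snp = NA_real_, flagged = "fewer than 2 markers"
      ))
    }
    len <- max(sub$cm) - min(sub$cm)
    gap <- max(diff(sub$cm))
    anc <- anchors[anchors$marker %in% sub$marker, , drop = FALSE]
    chrom <- as.character(g)
    anc <- anc[anc$chrom == chrom, , drop = FALSE]
    clen <- chrom_lengths[[chrom]]
    span <- if (nrow(anc) >= 2) max(anc$pos) - min(anc$pos) else NA_real_
    tibble::tibble(
      lg = as.character(g), n_snps = nrow(sub), length_cm = len,
      largest_gap_cm = gap, chrom_length_bp = clen,
      coverage_pct = 100 * span / clen,
      snps_per_cm = nrow(sub) / len,
      bp_per_cm = clen / len,
      bp_per_snp = clen / nrow(sub),
      flagged = NA_character_
    )
  })
  per <- dplyr::bind_rows(rows)
  tot_len <- sum(per$length_cm, na.rm = TRUE)
  tot_n <- sum(per$n_snps)
  tot_clen <- sum(per$chrom_length_bp, na.rm = TRUE)
  tot_span <- sum(per$coverage_pct * per$chrom_length_bp / 100, na.rm = TRUE)
  total <- tibble::tibble(
    lg = "Total", n_snps = tot_n, length_cm = tot_len,
    largest_gap_cm = mean(per$largest_gap_cm, na.rm = TRUE),
    chrom_length_bp = tot_clen,
    coverage_pct = 100 * tot_span / tot_clen,
    snps_per_cm = tot_n / tot_len,
    bp_per_cm = tot_clen / tot_len,
    bp_per_snp = tot_clen / tot_n,
    flagged = NA_character_
  )
  dplyr::bind_rows(per, total)
}

#' Collinearity of genetic and physical marker order
#'
#' For each LG, the Spearman rank correlation between cM position and
#' physical bp position of co-anchored markers, and the Kendall distance
#' (minimum adjacent transpositions separating the two orders). Ties take
#' average ranks.
#'
#' @inheritParams map_summary
#' @return tibble with `lg`, `n`, `spearman_rho`, `n_inversions`.
#' @export
collinearity <- function(map, anchors) {
  lgs <- sort(unique(map$lg))
  rows <- lapply(lgs, function(g) {
    sub <- map[map$lg == g, , drop = FALSE]
    anc <- anchors[anchors$marker %in% sub$marker &
                     anchors$chrom == as.character(g), , drop = FALSE]
    sub <- sub[match(anc$marker, sub$marker), , drop = FALSE]
    if (nrow(sub) < 3) {
      return(tibble::tibble(lg = g, n = nrow(sub),
                            spearman_rho = NA_real_, n_inversions = NA_integer_))
    }
    rho <- stats::cor(sub$cm, anc$pos, method = "spearman")
    tibble::tibble(lg = g, n = nrow(sub), spearman_rho = rho,
                   n_inversions = kendall_distance(sub$cm, anc$pos))
  })
  dplyr::bind_rows(rows)
}

# discordant pair count between two orderings (strict; ties not counted)
kendall_distance <- function(a, b) {
  n <- length(a)
  d <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if ((a[i] - a[j]) * (b[i] - b[j]) < 0) d <- d + 1L
    }
  }
  d
}

#' Place unanchored scaffolds on linkage groups
#'
#' Each scaffold is assigned the majority linkage group of its mapped
#' markers with the supporting fraction; ties and scaffolds with no mapped
#' markers stay unplaced.
#'
#' @param map tibble with `marker`, `lg`, `cm`.
#' @param scaffold_anchors tibble with `marker`, `scaffold`.
#' @return tibble with `scaffold`, `lg` (NA when unplaced), `n_markers`,
#'   `support`.
#' @export
place_scaffolds <- function(map, scaffold_anchors) {
  rows <- lapply(unique(scaffold_anchors$scaffold), function(sc) {
    mk <- scaffold_anchors$marker[scaffold_anchors$scaffold == sc]
    lgs <- map$lg[match(mk, map$marker)]
    lgs <- lgs[!is.na(lgs)]
    if (!length(lgs)) {
      return(tibble::tibble(scaffold = sc, lg = NA_integer_,
                            n_markers = 0L, support = NA_real_))
    }
    tab <- sort(table(lgs), decreasing = TRUE)
    tied <- length(tab) > 1 && tab[1] == tab[2]
    tibble::tibble(
      scaffold = sc,
      lg = if (tied) NA_integer_ else as.integer(names(tab)[1]),
      n_markers = length(lgs),
      support = if (tied) NA_real_ else as.numeric(tab[1]) / length(lgs)
    )
  })
  dplyr::bind_rows(rows)
}
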