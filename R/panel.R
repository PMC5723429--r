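# Candidate-variant filtering and panel selection for an Infinium II array.
# Candidate variants are tibbles with columns: variant_id, chrom, pos,
# allele_ref, allele_alt, phred_quality, alt_freq, alt_read_count, is_indel,
# flank_unique, gene_id, effect, adt_score, source.

SINGLE_BEAD_PAIRS <- c("AC", "AG", "CT", "GT")
DOUBLE_BEAD_PAIRS <- c("AT", "CG")

allele_pair <- function(ref, alt) {
  paste0(pmin(ref, alt), pmax(ref, alt))
}

#' Initial candidate-variant filters
#'
#' Retains biallelic SNVs with Phred quality >= `quality_min`, alternate
#' allele frequency >= `freq_min` and >= `reads_min` reads supporting the
#' variant (all gates inclusive); indels are removed.
#'
#' @param vs candidate-variant tibble.
#' @param quality_min,freq_min,reads_min inclusive thresholds
#'   (defaults 20 / 0.20 / 2).
#' @return the filtered tibble.
#' @export
filter_variants <- function(vs, quality_min = 20, freq_min = 0.20,
                            reads_min = 2) {
  dplyr::filter(
    vs,
    !.data$is_indel,
    nchar(.data$allele_ref) == 1, nchar(.data$allele_alt) == 1,
    .data$phred_quality >= quality_min,
    .data$alt_freq >= freq_min,
    .data$alt_read_count >= reads_min
  )
}

#' Remove variants with close neighbours
#'
#' Drops every candidate that has another variant within `window_bp`
#' (inclusive) on the same chromosome — both members of a close pair go,
#' since either would contaminate the other's probe flank. An optional
#' `context` set of additional variants (not themselves candidates) also
#' triggers removal.
#'
#' @param vs candidate-variant tibble.
#' @param window_bp exclusion distance in bp (default 60).
#' @param context optional tibble of additional variants with `chrom`/`pos`.
#' @return the filtered tibble.
#' @export
proximity_filter <- function(vs, window_bp = 60, context = NULL) {
  all_pos <- vs[, c("chrom", "pos")]
  if (!is.null(context)) all_pos <- rbind(all_pos, context[, c("chrom", "pos")])
  keep <- rep(TRUE, nrow(vs))
  for (ch in unique(vs$chrom)) {
    cand_idx <- which(vs$chrom == ch)
    p_cand <- vs$pos[cand_idx]
    p_all <- sort(all_pos$pos[all_pos$chrom == ch])
    # a candidate fails if any *other* variant lies within the window
    lo <- findInterval(p_cand - window_bp - 1L, p_all)
    hi <- findInterval(p_cand + window_bp, p_all)
    n_within <- hi - lo # neighbours within window, including self once
    self <- p_all[findInterval(p_cand, p_all)] == p_cand
    keep[cand_idx] <- (n_within - as.integer(self)) == 0L
  }
  vs[keep, , drop = FALSE]
}

#' Intersect two discovery datasets
#'
#' Keeps only sites present in both datasets (matched on chromosome and
#' position), marking them `source = "both"`. Metadata come from the second
#' (genome) dataset, which wins on conflict; sites whose alleles disagree
#' between datasets are excluded and reported.
#'
#' @param ds1,ds2 candidate-variant tibbles (transcript and genome datasets).
#' @return list with `merged` (tibble) and `conflicts` (tibble of excluded
#'   shared sites with disagreeing alleles).
#' @export
merge_datasets <- function(ds1, ds2) {
  key1 <- paste(ds1$chrom, ds1$pos)
  key2 <- paste(ds2$chrom, ds2$pos)
  shared <- intersect(key1, key2)
  i1 <- match(shared, key1)
  i2 <- match(shared, key2)
  agree <- ds1$allele_ref[i1] == ds2$allele_ref[i2] &
    ds1$allele_alt[i1] == ds2$allele_alt[i2]
  merged <- ds2[i2[agree], , drop = FALSE]
  merged$source <- "both"
  conflicts <- dplyr::bind_cols(
    ds1[i1[!agree], c("chrom", "pos", "allele_ref", "allele_alt")],
    stats::setNames(
      ds2[i2[!agree], c("allele_ref", "allele_alt")],
      c("allele_ref_genome", "allele_alt_genome")
    )
  )
  list(merged = tibble::as_tibble(merged),
       conflicts = tibble::as_tibble(conflicts))
}

#' Genes overlapping published QTL regions
#'
#' A gene is included when its 1-based inclusive interval overlaps any
#' region by at least one bp.
#'
#' @param genes tibble with `gene_id`, `chrom`, `start`, `end`.
#' @param regions tibble with `trait`, `chrom`, `start`, `end`.
#' @return character vector of unique gene ids.
#' @export
genes_in_qtl_regions <- function(genes, regions) {
  hit <- rep(FALSE, nrow(genes))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (genes$chrom == regions$chrom[i] &
                    genes$start <= regions$end[i] &
                    genes$end >= regions$start[i])
  }
  unique(genes$gene_id[hit])
}

#' Functional-term enrichment of QTL genes against the genome background
#'
#' One-sided hypergeometric test per functional term (GO/INTERPRO/EC/KEGG
#' ids, any namespace): drawing `|qtl_genes|` genes from the genome, what is
#' the probability of at least the observed number carrying the term?
#' Benjamini-Hochberg q-values are attached and rows sorted by ascending p.
#'
#' @param qtl_genes character vector of gene ids (must all be in
#'   `all_genes`).
#' @param all_genes tibble with `gene_id` and a list-column `terms` of
#'   character term ids.
#' @return tibble with `term`, `in_count`, `bg_count`, `p`, `q`.
#' @export
term_enrichment <- function(qtl_genes, all_genes) {
  if (!length(qtl_genes)) stop("empty QTL gene set")
  stopifnot(all(qtl_genes %in% all_genes$gene_id))
  n_bg <- nrow(all_genes)
  k <- length(unique(qtl_genes))
  in_set <- all_genes$gene_id %in% qtl_genes
  bg_tab <- table(unlist(all_genes$terms[!duplicated(all_genes$gene_id)]))
  in_tab <- table(unlist(all_genes$terms[in_set]))
  terms <- names(bg_tab)
  in_count <- as.integer(in_tab[terms])
  in_count[is.na(in_count)] <- 0L
  bg_count <- as.integer(bg_tab)
  p <- stats::phyper(in_count - 1L, bg_count, n_bg - bg_count, k,
                     lower.tail = FALSE)
  out <- tibble::tibble(
    term = terms, in_count = in_count, bg_count = bg_count,
    p = p, q = stats::p.adjust(p, method = "BH")
  )
  dplyr::arrange(out, .data$p)
}

#' Keep one SNP per priority gene
#'
#' Applies the ADT gate (strictly greater than `adt_min`), then within each
#' priority gene keeps the single SNP ranked best by, in decreasing order of
#' importance: unique flanking region, predicted missense effect,
#' single-bead-type allele pair (A/C, A/G, T/C, T/G), and descending ADT
#' score; residual ties break deterministically by (chrom, pos).
#'
#' @param vs candidate-variant tibble.
#' @param priority_genes character vector of gene ids to represent.
#' @param adt_min ADT gate (strict `>`; default 0.9).
#' @return tibble with at most one variant per priority gene.
#' @export
select_one_per_gene <- function(vs, priority_genes, adt_min = 0.9) {
  eligible <- dplyr::filter(
    vs,
    !is.na(.data$adt_score), .data$adt_score > adt_min,
    !is.na(.data$gene_id), .data$gene_id %in% priority_genes
  )
  if (!nrow(eligible)) return(eligible)
  eligible |>
    dplyr::mutate(
      .single_bead = allele_pair(.data$allele_ref, .data$allele_alt) %in%
        SINGLE_BEAD_PAIRS
    ) |>
    dplyr::arrange(
      .data$gene_id, dplyr::desc(.data$flank_unique),
      dplyr::desc(.data$effect == "missense"), dplyr::desc(.data$.single_bead),
      dplyr::desc(.data$adt_score), .data$chrom, .data$pos
    ) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE) |>
    dplyr::select(-".single_bead")
}

# largest-remainder apportionment of `target` seats over `weights`
largest_remainder <- function(weights, target) {
  quota <- target * weights / sum(weights)
  base <- floor(quota)
  left <- target - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Allocate anchor markers proportionally to gene content
#'
#' Gives each chromosome a quota of `target` anchors apportioned (largest
#' remainder) by its share of predicted gene models, then down-samples
#' overrepresented chromosomes uniformly at random and fills
#' underrepresented ones from `fill_pool`. All randomness is seeded.
#'
#' @param anchor_pool candidate-variant tibble of available anchors.
#' @param gene_counts_per_chrom named numeric vector: gene models per chrom.
#' @param target total anchors wanted (default 1000).
#' @param seed integer seed.
#' @param fill_pool optional tibble of additional variants usable as fills.
#' @return list with `selected` (tibble) and `shortfall`, a tibble of chroms
#'   whose quota could not be met.
#' @export
allocate_anchors <- function(anchor_pool, gene_counts_per_chrom, target = 1000,
                             seed, fill_pool = NULL) {
  stopifnot(sum(gene_counts_per_chrom) > 0)
  chroms <- names(gene_counts_per_chrom)
  quota <- stats::setNames(
    largest_remainder(as.numeric(gene_counts_per_chrom), target), chroms
  )
  rng <- substream_rng(seed, "allocate_anchors")
  picked <- list()
  short_chrom <- character()
  short_n <- integer()
  for (ch in chroms) {
    have <- anchor_pool[anchor_pool$chrom == ch, , drop = FALSE]
    q <- quota[[ch]]
    if (nrow(have) > q) {
      have <- have[sample_int(rng, nrow(have), q), , drop = FALSE]
    } else if (nrow(have) < q && !is.null(fill_pool)) {
      fills <- fill_pool[fill_pool$chrom == ch &
                           !fill_pool$variant_id %in% have$variant_id, ,
                         drop = FALSE]
      n_add <- min(q - nrow(have), nrow(fills))
      if (n_add > 0) {
        have <- dplyr::bind_rows(
          have, fills[sample_int(rng, nrow(fills), n_add), , drop = FALSE]
        )
      }
    }
    if (nrow(have) < q) {
      short_chrom <- c(short_chrom, ch)
      short_n <- c(short_n, q - nrow(have))
    }
    picked[[ch]] <- have
  }
  list(
    selected = dplyr::bind_rows(picked),
    quota = tibble::tibble(chrom = chroms, quota = unname(quota)),
    shortfall = tibble::tibble(chrom = short_chrom, missing = short_n)
  )
}

#' Infinium II bead-type usage
#'
#' A/T and C/G SNPs cannot be distinguished by a single probe and cost two
#' bead-types; the four other allele pairs (A/C, A/G, T/C, T/G) cost one.
#'
#' @param vs candidate-variant tibble (biallelic SNVs).
#' @return total bead-types (integer).
#' @export
bead_usage <- function(vs) {
  if (!nrow(vs)) return(0L)
  if (any(vs$is_indel) ||
      any(nchar(vs$allele_ref) != 1) || any(nchar(vs$allele_alt) != 1)) {
    stop("bead accounting is defined for biallelic SNVs only")
  }
  pairs <- allele_pair(vs$allele_ref, vs$allele_alt)
  sum(ifelse(pairs %in% DOUBLE_BEAD_PAIRS, 2L, 1L))
}

#' Fill the largest inter-marker gaps up to the bead budget
#'
#' Repeatedly finds the largest bp gap between adjacent selected markers
#' genome-wide (chromosome termini count as virtual markers, so telomeric
#' deserts are fillable) and adds the pool variant inside that gap nearest
#' its midpoint, until the bead budget would be exceeded or no gap contains
#' a pool variant.
#'
#' @param selected candidate-variant tibble already on the panel.
#' @param pool candidate-variant tibble of eligible additions.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param bead_budget total bead-types allowed (default 15000).
#' @return list with `selected` (augmented tibble) and `audit`, a tibble of
#'   insertions (`iteration`, `chrom`, `gap_start`, `gap_end`, `variant_id`).
#' @export
fill_gaps <- function(selected, pool, chrom_lengths, bead_budget = 15000) {
  used <- bead_usage(selected)
  stopifnot(used <= bead_budget)
  pool <- pool[!pool$variant_id %in% selected$variant_id, , drop = FALSE]
  audit <- list()
  it <- 0L
  repeat {
    if (!nrow(pool)) break
    gaps <- gap_table(selected, chrom_lengths)
    gaps <- gaps[order(-gaps$width), , drop = FALSE]
    chosen <- NULL
    for (g in seq_len(nrow(gaps))) {
      inside <- which(pool$chrom == gaps$chrom[g] &
                        pool$pos > gaps$start[g] & pool$pos < gaps$end[g])
      if (length(inside)) {
        mid <- (gaps$start[g] + gaps$end[g]) / 2
        chosen <- inside[which.min(abs(pool$pos[inside] - mid))]
        gap_row <- gaps[g, ]
        break
      }
    }
    if (is.null(chosen)) break
    cost <- bead_usage(pool[chosen, , drop = FALSE])
    if (used + cost > bead_budget) break
    it <- it + 1L
    audit[[it]] <- tibble::tibble(
      iteration = it, chrom = gap_row$chrom,
      gap_start = gap_row$start, gap_end = gap_row$end,
      variant_id = pool$variant_id[chosen]
    )
    selected <- dplyr::bind_rows(selected, pool[chosen, , drop = FALSE])
    used <- used + cost
    pool <- pool[-chosen, , drop = FALSE]
  }
  list(selected = selected, audit = dplyr::bind_rows(audit))
}

gap_table <- function(selected, chrom_lengths) {
  out <- list()
  for (ch in names(chrom_lengths)) {
    p <- sort(selected$pos[selected$chrom == ch])
    bounds <- c(1, p, chrom_lengths[[ch]])
    out[[ch]] <- tibble::tibble(
      chrom = ch,
      start = bounds[-length(bounds)],
      end = bounds[-1]
    )
  }
  gaps <- dplyr::bind_rows(out)
  gaps$width <- gaps$end - gaps$start
  gaps
}

#' Per-scaffold summary of a selected panel
#'
#' For each scaffold: number of SNPs, number inside gene models, and
#' mean/max/min adjacent inter-SNP distance, with `all` and `LG 1-10`
#' roll-ups (roll-up gap statistics pool the within-scaffold adjacent gaps).
#'
#' @param selected candidate-variant tibble.
#' @param lg_chroms chromosomes counted in the `LG 1-10` roll-up
#'   (default `as.character(1:10)`).
#' @return tibble with one row per scaffold plus the two roll-ups.
#' @export
panel_summary <- function(selected, lg_chroms = as.character(1:10)) {
  per <- selected |>
    dplyr::group_by(chrom = .data$chrom) |>
    dplyr::arrange(.data$pos, .by_group = TRUE) |>
    dplyr::summarise(
      n_snps = dplyr::n(),
      n_in_genes = sum(!is.na(.data$gene_id)),
      mean_gap = mean_or_na(diff(.data$pos)),
      max_gap = max_or_na(diff(.data$pos)),
      min_gap = min_or_na(diff(.data$pos)),
      .groups = "drop"
    )
  gaps_by_chrom <- selected |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$pos, .by_group = TRUE) |>
    dplyr::reframe(gap = diff(.data$pos))
  rollup <- function(chroms, label) {
    sub <- selected[selected$chrom %in% chroms, , drop = FALSE]
    g <- gaps_by_chrom$gap[gaps_by_chrom$chrom %in% chroms]
    tibble::tibble(
      chrom = label, n_snps = nrow(sub),
      n_in_genes = sum(!is.na(sub$gene_id)),
      mean_gap = mean_or_na(g), max_gap = max_or_na(g), min_gap = min_or_na(g)
    )
  }
  dplyr::bind_rows(
    per,
    rollup(unique(selected$chrom), "all"),
    rollup(lg_chroms, "LG 1-10")
  )
}

mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
max_or_na <- function(x) if (length(x)) max(x) else NA_real_
min_or_na <- function(x) if (length(x)) min(x) else NA_real_
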