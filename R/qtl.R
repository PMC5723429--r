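# Single-marker interval-style QTL scan for a CP family, with centered
# additive/dominance predictor codings per segregation type, joint Wald
# tests, an effective-number-of-tests (Li-Ji) corrected threshold, and a
# composite scan that conditions on cofactor markers outside a cM window.

#' Additive/dominance predictor coding for one marker
#'
#' Coding by segregation type: `lmxll` — maternal-allele indicator, -1/2 for
#' the homozygous class and +1/2 for the heterozygote, no dominance;
#' `nnxnp` — the same for the paternal allele; `hkxhk` — additive = alt
#' count - 1 (-1/0/+1) and dominance = heterozygote indicator - 1/2.
#' Missing or Mendelian-impossible genotypes yield missing predictors
#' (excluded casewise downstream).
#'
#' @param calls progeny call codes at the marker.
#' @param mother,father parental call codes at the marker (non-missing).
#' @return numeric matrix with column `add` and, for `hkxhk`, `dom`.
#' @export
encode_predictors <- function(calls, mother, father) {
  st <- classify_segregation(mother, father)
  if (st == "uninformative") {
    stop("uninformative marker (neither parent heterozygous)")
  }
  if (st == "hkxhk") {
    add <- as.numeric(calls) - 1
    dom <- ifelse(is.na(calls), NA_real_, (calls == 1L) - 0.5)
    return(cbind(add = add, dom = dom))
  }
  hom_parent <- if (st == "lmxll") father else mother
  add <- rep(NA_real_, length(calls))
  add[!is.na(calls) & calls == hom_parent] <- -0.5
  add[!is.na(calls) & calls == 1L] <- 0.5
  cbind(add = add)
}

# predictor matrices for every informative marker of a mapping dataset
predictor_list <- function(dataset) {
  inf <- dataset$loci$segtype %in% c("lmxll", "nnxnp", "hkxhk")
  idx <- which(inf)
  out <- vector("list", length(idx))
  names(out) <- dataset$loci$locus_id[idx]
  for (k in seq_along(idx)) {
    j <- idx[k]
    out[[k]] <- encode_predictors(dataset$calls[, j], dataset$mother[j],
                                  dataset$father[j])
  }
  out
}

#' Single-marker QTL scan
#'
#' For every informative marker, fits the trait by least squares on the
#' marker's centered predictors plus the predictors of all supplied cofactor
#' markers except those within `cofactor_window_cM` of the tested marker on
#' its own linkage group, and tests the marker's predictors jointly with a
#' Wald chi-square statistic. Percent variance explained is the incremental
#' R-squared of the marker over the cofactor-only model.
#'
#' @param trait numeric response per progeny (aligned with the dataset's
#'   sample order).
#' @param dataset a [mapping_dataset()].
#' @param map optional tibble `marker`, `lg`, `cm` giving map positions
#'   (required when `cofactors` are used; carried into the result).
#' @param cofactors character vector of cofactor marker ids.
#' @param cofactor_window_cM cofactors this close to the tested marker (same
#'   linkage group) are left out of its model; default 10.
#' @param min_n minimum complete observations to test a marker.
#' @return a `qtl_scan` tibble: `marker`, `lg`, `cm`, `segtype`, `n`, `df`,
#'   `wald`, `p`, `neg_log10_p`, `pct_var`, `eff_add`, `eff_dom`, `note`.
#' @export
qtl_scan <- function(trait, dataset, map = NULL, cofactors = character(),
                     cofactor_window_cM = 10, min_n = 30) {
  stopifnot(length(trait) == nrow(dataset$calls))
  preds <- predictor_list(dataset)
  markers <- names(preds)
  if (length(cofactors)) {
    if (is.null(map)) stop("cofactors require a map (marker, lg, cm)")
    missing_cof <- setdiff(cofactors, markers)
    if (length(missing_cof)) stop("unknown cofactor: ", missing_cof[1])
  }
  mp <- if (is.null(map)) NULL else map[match(markers, map$marker), ]
  seg <- dataset$loci$segtype[match(markers, dataset$loci$locus_id)]
  n_mark <- length(markers)
  out_n <- integer(n_mark)
  out_df <- integer(n_mark)
  out_w <- out_p <- out_nlp <- out_pv <- out_a <- out_d <- rep(NA_real_, n_mark)
  out_note <- rep(NA_character_, n_mark)
  for (k in seq_len(n_mark)) {
    mk <- markers[k]
    cof <- setdiff(cofactors, mk)
    if (length(cof) && !is.null(mp)) {
      same_lg <- map$lg[match(cof, map$marker)] == mp$lg[k]
      near <- abs(map$cm[match(cof, map$marker)] - mp$cm[k]) <= cofactor_window_cM
      cof <- cof[!(same_lg & near)]
    }
    pj <- preds[[mk]]
    xc <- if (length(cof)) do.call(cbind, preds[cof]) else NULL
    full <- cbind(1, xc, pj)
    ok <- stats::complete.cases(full) & !is.na(trait)
    out_n[k] <- sum(ok)
    if (sum(ok) < min_n) {
      out_note[k] <- "skipped: too few complete observations"
      next
    }
    y <- trait[ok]
    x1 <- full[ok, , drop = FALSE]
    x0 <- x1[, seq_len(ncol(x1) - ncol(pj)), drop = FALSE]
    f1 <- stats::lm.fit(x1, y)
    f0 <- stats::lm.fit(x0, y)
    rss1 <- sum(f1$residuals^2)
    rss0 <- sum(f0$residuals^2)
    q <- f1$rank - f0$rank
    out_df[k] <- q
    if (rss0 <= .Machine$double.eps * sum(y^2) || q == 0) {
      out_note[k] <- if (q == 0) "marker collinear with cofactors" else
        "zero residual variance under null model"
      next
    }
    df_res <- sum(ok) - f1$rank
    if (df_res <= 0 || rss1 <= 0) {
      out_note[k] <- "saturated fit"
      next
    }
    s2 <- rss1 / df_res
    out_w[k] <- (rss0 - rss1) / s2
    lp <- stats::pchisq(out_w[k], df = q, lower.tail = FALSE, log.p = TRUE)
    out_p[k] <- exp(lp)
    out_nlp[k] <- -lp / log(10) # survives p-values that underflow to 0
    out_pv[k] <- 100 * (rss0 - rss1) / rss0
    cf <- f1$coefficients
    mcols <- seq.int(ncol(x1) - ncol(pj) + 1L, ncol(x1))
    out_a[k] <- cf[mcols[1]]
    if (ncol(pj) == 2L) out_d[k] <- cf[mcols[2]]
  }
  res <- tibble::tibble(
    marker = markers,
    lg = if (is.null(mp)) NA_integer_ else mp$lg,
    cm = if (is.null(mp)) NA_real_ else mp$cm,
    segtype = seg, n = out_n, df = out_df, wald = out_w, p = out_p,
    neg_log10_p = out_nlp, pct_var = out_pv,
    eff_add = out_a, eff_dom = out_d, note = out_note
  )
  class(res) <- c("qtl_scan", class(res))
  attr(res, "cofactors") <- cofactors
  res
}

#' @export
#' @method tidy qtl_scan
tidy.qtl_scan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "qtl_scan")
  out
}

#' @export
#' @method glance qtl_scan
glance.qtl_scan <- function(x, ...) {
  tibble::tibble(
    n_markers = nrow(x),
    n_tested = sum(!is.na(x$p)),
    n_cofactors = length(attr(x, "cofactors")),
    min_p = suppressWarnings(min(x$p, na.rm = TRUE)),
    max_neg_log10_p = suppressWarnings(max(x$neg_log10_p, na.rm = TRUE))
  )
}

#' Profile plot of a QTL scan
#'
#' @param object a `qtl_scan` result with map positions.
#' @param rule optional [significance_rule()] tibble; draws the threshold.
#' @param ... unused.
#' @return a ggplot: -log10(p) against cM, faceted by linkage group.
#' @export
#' @method autoplot qtl_scan
autoplot.qtl_scan <- function(object, rule = NULL, ...) {
  p <- ggplot2::ggplot(tidy.qtl_scan(object),
                       ggplot2::aes(x = .data$cm, y = .data$neg_log10_p)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~lg, nrow = 2) +
    ggplot2::labs(x = "position (cM)", y = expression(-log[10](p)))
  if (!is.null(rule)) {
    p <- p + ggplot2::geom_hline(yintercept = rule$threshold_neg_log10,
                                 linetype = "dashed")
  }
  p
}

#' Effective number of independent tests (Li-Ji)
#'
#' From the eigenvalues of the marker correlation matrix (additive codes,
#' pairwise-complete correlations), Meff = sum over eigenvalues of
#' I(lambda >= 1) + (lambda - floor(lambda)). Computed per linkage group and
#' summed genome-wide when `lg` is supplied. Zero-variance markers are
#' excluded.
#'
#' @param geno numeric matrix (progeny x markers) of additive codes, or a
#'   [mapping_dataset()] (additive codings are derived).
#' @param lg optional linkage-group id per marker.
#' @return Meff (numeric scalar), with attribute `per_lg` when grouped.
#' @export
li_ji_meff <- function(geno, lg = NULL) {
  if (inherits(geno, "mapping_dataset")) {
    preds <- predictor_list(geno)
    geno <- do.call(cbind, lapply(preds, function(p) p[, "add"]))
    colnames(geno) <- names(preds)
  }
  if (ncol(geno) < 2) stop("need at least 2 markers")
  v <- apply(geno, 2, stats::var, na.rm = TRUE)
  keep <- !is.na(v) & v > 0
  geno <- geno[, keep, drop = FALSE]
  if (!is.null(lg)) lg <- lg[keep]
  groups <- if (is.null(lg)) rep(1L, ncol(geno)) else lg
  per <- vapply(unique(groups), function(g) {
    sub <- geno[, groups == g, drop = FALSE]
    if (ncol(sub) == 1) return(1)
    cc <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
    cc[is.na(cc)] <- 0
    diag(cc) <- 1
    lam <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
    lam <- pmax(lam, 0) # pairwise-complete grids can leak tiny negatives
    sum((lam >= 1) + (lam - floor(lam)))
  }, numeric(1))
  out <- sum(per)
  if (!is.null(lg)) attr(out, "per_lg") <- stats::setNames(per, unique(groups))
  out
}

#' Genome-wide significance rule from an effective test count
#'
#' @param meff effective number of tests (>= 1).
#' @param alpha genome-wide significance level (default 0.05).
#' @return tibble with `alpha`, `meff`, `threshold_p` (= alpha / meff) and
#'   `threshold_neg_log10`.
#' @export
significance_rule <- function(meff, alpha = 0.05) {
  stopifnot(meff >= 1)
  tibble::tibble(
    alpha = alpha, meff = as.numeric(meff),
    threshold_p = alpha / as.numeric(meff),
    threshold_neg_log10 = -log10(alpha / as.numeric(meff))
  )
}

# peak markers of the significant part of a scan: greedy selection of the
# strongest marker, masking its +/- merge_cM neighbourhood, repeated until
# no significant marker remains — so every distinct signal contributes one
# cofactor even when significance is contiguous across a whole stretch
peak_cofactors <- function(res, rule, merge_cM = 10) {
  sig <- res[!is.na(res$p) & res$p < rule$threshold_p, , drop = FALSE]
  peaks <- character()
  while (nrow(sig)) {
    top <- which.max(sig$neg_log10_p)
    peaks <- c(peaks, sig$marker[top])
    masked <- sig$lg == sig$lg[top] & abs(sig$cm - sig$cm[top]) <= merge_cM
    sig <- sig[!masked, , drop = FALSE]
  }
  peaks
}

#' Composite scan by iterated cofactor selection
#'
#' Iteration 0 is the plain single-marker (interval-style) scan; each later
#' iteration takes the peak marker of every significant region as cofactors
#' and rescans, stopping when the cofactor set stabilizes or after
#' `max_iter` composite iterations (two suffice in practice).
#'
#' @inheritParams qtl_scan
#' @param rule a [significance_rule()] tibble.
#' @param max_iter maximum composite iterations (default 2).
#' @param merge_cM significant markers this close on one linkage group
#'   belong to one region when picking peaks.
#' @return list with `scan` (final `qtl_scan`), `history` (tibble of
#'   cofactors per iteration) and `iterations`.
#' @export
cim_iterate <- function(trait, dataset, map, rule, max_iter = 2,
                        cofactor_window_cM = 10, merge_cM = 10, min_n = 30) {
  res <- qtl_scan(trait, dataset, map, character(), cofactor_window_cM, min_n)
  cof <- peak_cofactors(res, rule, merge_cM)
  history <- list(tibble::tibble(iteration = 0L,
                                 cofactors = paste(cof, collapse = ",")))
  it <- 0L
  prev <- character()
  while (it < max_iter && !setequal(cof, prev) && length(cof)) {
    it <- it + 1L
    res <- qtl_scan(trait, dataset, map, cof, cofactor_window_cM, min_n)
    prev <- cof
    cof <- peak_cofactors(res, rule, merge_cM)
    history[[it + 1L]] <- tibble::tibble(
      iteration = it, cofactors = paste(cof, collapse = ",")
    )
  }
  list(scan = res, history = dplyr::bind_rows(history), iterations = it)
}

#' Summarize significant QTL regions
#'
#' Markers significant under the rule with percent variance explained
#' strictly greater than `pct_var_min` are grouped into regions by map
#' contiguity (within `merge_cM` on one linkage group). Each region reports
#' its peak marker, the outermost significant positions as lower/upper
#' limits (bp when the dataset carries physical positions, and cM), the
#' peak's statistics and the favorable parental allele implied by the signs
#' of the effect estimates.
#'
#' @param res a `qtl_scan` result with map positions.
#' @param rule a [significance_rule()] tibble.
#' @param dataset the [mapping_dataset()] that was scanned (for physical
#'   positions and alleles); optional.
#' @param pct_var_min percent-variance gate, strict `>` (default 4).
#' @param merge_cM region contiguity window (default 10).
#' @return tibble, one row per QTL region.
#' @export
summarize_qtl <- function(res, rule, dataset = NULL, pct_var_min = 4,
                          merge_cM = 10) {
  sig <- res[!is.na(res$p) & res$p < rule$threshold_p &
               !is.na(res$pct_var) & res$pct_var > pct_var_min, , drop = FALSE]
  empty <- tibble::tibble(
    lg = integer(), peak_marker = character(), peak_cm = double(),
    peak_pos = double(), lower_limit = double(), upper_limit = double(),
    lower_cm = double(), upper_cm = double(), neg_log10_p = double(),
    pct_var = double(), eff_add = double(), eff_dom = double(),
    favorable_parent = character(), favorable_allele = character()
  )
  if (!nrow(sig)) return(empty)
  pos_of <- function(mk) {
    if (is.null(dataset)) return(NA_real_)
    as.numeric(dataset$loci$pos[match(mk, dataset$loci$locus_id)])
  }
  rows <- list()
  for (g in unique(sig$lg)) {
    sub <- sig[sig$lg == g, , drop = FALSE]
    sub <- sub[order(sub$cm), , drop = FALSE]
    brk <- c(0, cumsum(diff(sub$cm) > merge_cM))
    for (b in unique(brk)) {
      reg <- sub[brk == b, , drop = FALSE]
      pk <- reg[which.max(reg$neg_log10_p), ]
      fav <- favorable_allele(pk, dataset)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        lg = g, peak_marker = pk$marker, peak_cm = pk$cm,
        peak_pos = pos_of(pk$marker),
        lower_limit = min_or_na(pos_of(reg$marker)),
        upper_limit = max_or_na(pos_of(reg$marker)),
        lower_cm = min(reg$cm), upper_cm = max(reg$cm),
        neg_log10_p = pk$neg_log10_p, pct_var = pk$pct_var,
        eff_add = pk$eff_add, eff_dom = pk$eff_dom,
        favorable_parent = fav$parent, favorable_allele = fav$allele
      )
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$lg, .data$peak_cm)
}

# which parental allele raises the trait, from the sign of the additive
# effect and the segregation structure of the peak marker
favorable_allele <- function(pk, dataset) {
  if (is.null(dataset) || is.na(pk$eff_add)) {
    return(list(parent = NA_character_, allele = NA_character_))
  }
  j <- match(pk$marker, dataset$loci$locus_id)
  ref <- dataset$loci$allele_ref[j]
  alt <- dataset$loci$allele_alt[j]
  st <- pk$segtype
  up <- pk$eff_add > 0
  if (st == "hkxhk") {
    return(list(parent = "both", allele = if (up) alt else ref))
  }
  seg_parent <- if (st == "lmxll") "mother" else "father"
  hom_geno <- if (st == "lmxll") dataset$father[j] else dataset$mother[j]
  shared <- if (hom_geno == 0L) ref else alt # the "l"/"n" allele
  other <- if (hom_geno == 0L) alt else ref # the "m"/"p" allele
  list(parent = seg_parent, allele = if (up) other else shared)
}
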