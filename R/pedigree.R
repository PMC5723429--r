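# Segregation machinery for an outbred full-sib (CP) family. Genotypes are
# alt-allele counts (0/1/2/NA); a parent with count g transmits the alternate
# allele with probability g/2, so the expected progeny distribution is the
# convolution of the two transmission Bernoullis.

SEG_LEVELS <- c("lmxll", "nnxnp", "hkxhk", "uninformative")

#' Classify the CP segregation type of a locus
#'
#' `lmxll`: only the mother is heterozygous; `nnxnp`: only the father;
#' `hkxhk`: both; `uninformative`: neither. Vectorized over loci.
#'
#' @param mother,father parental call codes (0/1/2). Missing parent calls are
#'   an error: infer them first with [infer_unknown_parent()].
#' @return character vector among `lmxll`, `nnxnp`, `hkxhk`, `uninformative`.
#' @export
classify_segregation <- function(mother, father) {
  if (anyNA(mother) || anyNA(father)) {
    stop("missing parental call; use infer_unknown_parent() first")
  }
  mh <- mother == 1L
  fh <- father == 1L
  out <- rep("uninformative", length(mother))
  out[mh & !fh] <- "lmxll"
  out[!mh & fh] <- "nnxnp"
  out[mh & fh] <- "hkxhk"
  out
}

#' Expected Mendelian progeny distribution
#'
#' @param mother,father single parental call codes (0/1/2, non-missing).
#' @return named numeric vector of probabilities over
#'   `HOM_REF`/`HET`/`HOM_ALT` (alt-allele counts 0/1/2), summing to 1.
#' @export
expected_progeny_distribution <- function(mother, father) {
  if (is.na(mother) || is.na(father)) stop("parental calls must be non-missing")
  pm <- mother / 2 # P(mother transmits alt)
  pf <- father / 2
  p <- c(
    (1 - pm) * (1 - pf),
    pm * (1 - pf) + (1 - pm) * pf,
    pm * pf
  )
  names(p) <- c("HOM_REF", "HET", "HOM_ALT")
  p
}

# 3x3x3 lookup: is progeny genotype c possible under parents (m, f)?
possible_lookup <- local({
  arr <- array(FALSE, dim = c(3, 3, 3))
  for (m in 0:2) for (f in 0:2) {
    pm <- m / 2
    pf <- f / 2
    arr[m + 1, f + 1, ] <- c((1 - pm) * (1 - pf),
                             pm * (1 - pf) + (1 - pm) * pf,
                             pm * pf) > 0
  }
  function() arr
})

#' Infer an unknown parent genotype at one locus
#'
#' Given the maternal genotype and observed progeny genotype counts, computes
#' the Pearson chi-square goodness of fit of the counts against the Mendelian
#' expectation under each candidate father genotype, over the categories with
#' positive expectation. Candidates whose zero-expectation categories hold
#' more than `impossible_tolerance * N` observed progeny (genotyping error
#' allowance) are assigned `+Inf`. The candidate with the smallest statistic
#' wins; ties within `1e-9` flag the locus ambiguous, with the deterministic
#' preference order HOM_REF < HET < HOM_ALT recorded as the best.
#'
#' @param mother maternal call code (0/1/2, non-missing).
#' @param progeny_counts numeric length-3 vector of progeny counts in
#'   HOM_REF/HET/HOM_ALT order (missing progeny excluded upstream).
#' @param impossible_tolerance fraction of N tolerated in impossible classes.
#' @param min_n minimum progeny count; below it the locus is skipped.
#' @return a list with `best_father` (code or NA), `chi2_by_candidate`
#'   (length 3), `df_by_candidate`, `ambiguous`, `skipped`, `reason`.
#' @export
infer_unknown_parent <- function(mother, progeny_counts,
                                 impossible_tolerance = 0.02, min_n = 20) {
  if (is.na(mother)) stop("maternal call must be non-missing")
  stopifnot(length(progeny_counts) == 3)
  n <- sum(progeny_counts)
  chi2 <- rep(NA_real_, 3)
  df <- rep(NA_integer_, 3)
  names(chi2) <- names(df) <- c("HOM_REF", "HET", "HOM_ALT")
  if (n < min_n) {
    return(list(best_father = NA_integer_, chi2_by_candidate = chi2,
                df_by_candidate = df, ambiguous = FALSE, skipped = TRUE,
                reason = sprintf("n = %d below minimum %d", n, min_n)))
  }
  for (f in 0:2) {
    p <- expected_progeny_distribution(mother, f)
    pos <- p > 0
    if (sum(progeny_counts[!pos]) > impossible_tolerance * n) {
      chi2[f + 1] <- Inf
    } else {
      e <- n * p[pos]
      chi2[f + 1] <- sum((progeny_counts[pos] - e)^2 / e)
    }
    df[f + 1] <- sum(pos) - 1L
  }
  if (all(is.infinite(chi2))) {
    return(list(best_father = NA_integer_, chi2_by_candidate = chi2,
                df_by_candidate = df, ambiguous = TRUE, skipped = TRUE,
                reason = "no candidate father fits the observed classes"))
  }
  best <- unname(which.min(chi2)) - 1L # first minimum = preference order
  ambiguous <- sum(abs(chi2 - min(chi2)) < 1e-9) > 1L
  list(best_father = best, chi2_by_candidate = chi2, df_by_candidate = df,
       ambiguous = ambiguous, skipped = FALSE, reason = NA_character_)
}

#' Infer a whole unknown-parent genome from progeny segregation
#'
#' Applies [infer_unknown_parent()] locus by locus. Loci where the mother is
#' missing, the progeny count is below `min_n`, or the fit is ambiguous get a
#' missing inferred call.
#'
#' @param mother_row maternal call codes over loci (aligned with `progeny`).
#' @param progeny a [genotype_matrix()] of the F1 progeny.
#' @inheritParams infer_unknown_parent
#' @return list with `father` (integer call vector over loci) and `report`,
#'   a tibble per locus (`locus_id`, `best_father`, `min_chi2`, `ambiguous`,
#'   `skipped`, `reason`).
#' @export
infer_parent_genome <- function(mother_row, progeny,
                                impossible_tolerance = 0.02, min_n = 20) {
  x <- progeny$calls
  stopifnot(length(mother_row) == ncol(x))
  counts <- rbind(
    colSums(x == 0L, na.rm = TRUE),
    colSums(x == 1L, na.rm = TRUE),
    colSums(x == 2L, na.rm = TRUE)
  )
  n <- colSums(counts)
  n_loc <- ncol(x)
  chi2 <- matrix(NA_real_, nrow = 3, ncol = n_loc)
  for (m in 0:2) {
    sel <- which(!is.na(mother_row) & mother_row == m)
    if (!length(sel)) next
    for (f in 0:2) {
      p <- expected_progeny_distribution(m, f)
      pos <- p > 0
      e <- outer(p[pos], n[sel])
      stat <- colSums((counts[pos, sel, drop = FALSE] - e)^2 / e)
      imp <- colSums(counts[!pos, sel, drop = FALSE])
      stat[imp > impossible_tolerance * n[sel]] <- Inf
      chi2[f + 1, sel] <- stat
    }
  }
  best <- rep(NA_integer_, n_loc)
  min_chi2 <- rep(NA_real_, n_loc)
  ambiguous <- rep(FALSE, n_loc)
  skipped <- rep(FALSE, n_loc)
  reason <- rep(NA_character_, n_loc)
  for (j in seq_len(n_loc)) {
    if (is.na(mother_row[j])) {
      skipped[j] <- TRUE
      reason[j] <- "mother missing"
      next
    }
    if (n[j] < min_n) {
      skipped[j] <- TRUE
      reason[j] <- sprintf("n = %d below minimum %d", n[j], min_n)
      next
    }
    cj <- chi2[, j]
    if (all(is.infinite(cj))) {
      skipped[j] <- TRUE
      reason[j] <- "no candidate father fits the observed classes"
      next
    }
    min_chi2[j] <- min(cj)
    amb <- sum(abs(cj - min(cj)) < 1e-9) > 1L
    ambiguous[j] <- amb
    if (!amb) best[j] <- unname(which.min(cj)) - 1L
  }
  report <- tibble::tibble(
    locus_id = locus_ids(progeny),
    best_father = best, min_chi2 = min_chi2,
    ambiguous = ambiguous, skipped = skipped, reason = reason
  )
  list(father = stats::setNames(best, locus_ids(progeny)), report = report)
}

#' Mendelian error rate of one progeny against its parents
#'
#' A locus is typed when mother, father and progeny calls are all present;
#' it is an error when the progeny genotype has probability zero under
#' Mendelian transmission from the parents.
#'
#' @param mother,father parental call codes over loci.
#' @param progeny_row progeny call codes over the same loci.
#' @return tibble with `errors`, `typed`, `rate` (NA when `typed` is 0).
#' @export
mendelian_error_rate <- function(mother, father, progeny_row) {
  stopifnot(length(mother) == length(father),
            length(mother) == length(progeny_row))
  typed <- !is.na(mother) & !is.na(father) & !is.na(progeny_row)
  lk <- possible_lookup()
  idx <- cbind(mother[typed] + 1L, father[typed] + 1L, progeny_row[typed] + 1L)
  err <- !lk[idx]
  tibble::tibble(
    errors = sum(err), typed = sum(typed),
    rate = if (sum(typed) == 0) NA_real_ else sum(err) / sum(typed)
  )
}

#' Screen progeny for off-types by Mendelian error rate
#'
#' Progeny whose Mendelian error rate is `threshold` or more (inclusive) are
#' flagged as off-types, sorted by rate descending.
#'
#' @param mother,father parental call codes over the loci of `progeny`.
#' @param progeny a [genotype_matrix()] of putative F1 progeny.
#' @param threshold error-rate cutoff; default 0.03.
#' @return list with `off_types` (tibble of flagged samples) and `rates`,
#'   a tibble of every progeny's `sample_id`, `errors`, `typed`, `rate`.
#' @export
detect_off_types <- function(mother, father, progeny, threshold = 0.03) {
  x <- progeny$calls
  stopifnot(length(mother) == ncol(x), length(father) == ncol(x))
  lk <- possible_lookup()
  p27 <- as.vector(lk) # index (m, f, c) flattened as m + 3 f + 9 c (0-based)
  parent_ok <- !is.na(mother) & !is.na(father)
  base <- (mother + 3L * father)[parent_ok]
  xs <- x[, parent_ok, drop = FALSE]
  code <- sweep(9L * xs, 2L, base, "+") + 1L
  ok <- !is.na(code)
  err <- matrix(FALSE, nrow = nrow(xs), ncol = ncol(xs))
  err[ok] <- !p27[code[ok]]
  typed <- rowSums(ok)
  errors <- rowSums(err)
  rates <- tibble::tibble(
    sample_id = rownames(x),
    errors = as.integer(errors), typed = as.integer(typed),
    rate = ifelse(typed > 0, errors / typed, NA_real_)
  )
  off <- rates[!is.na(rates$rate) & rates$rate >= threshold, ]
  off <- off[order(-off$rate), ]
  list(off_types = off, rates = rates)
}

#' Segregation-distortion chi-square for one marker
#'
#' Pearson chi-square of observed progeny genotype counts against the
#' segregation type's Mendelian ratio: 1:1 over the two expected classes for
#' `lmxll`/`nnxnp`, 1:2:1 for `hkxhk`. When the parents are supplied the two
#' 1:1 classes are identified exactly; otherwise the two observed genotype
#' classes are used. Progeny in impossible classes are excluded from the
#' statistic (they are Mendelian errors, screened elsewhere).
#'
#' @param progeny_calls call codes of the progeny at the marker.
#' @param segtype one of `lmxll`, `nnxnp`, `hkxhk`.
#' @param mother,father optional parental call codes at the marker.
#' @return the chi-square statistic (numeric scalar).
#' @export
segregation_distortion_chi2 <- function(progeny_calls, segtype,
                                        mother = NULL, father = NULL) {
  if (!segtype %in% c("lmxll", "nnxnp", "hkxhk")) {
    stop("segtype must be informative (lmxll, nnxnp or hkxhk)")
  }
  g <- progeny_calls[!is.na(progeny_calls)]
  if (!length(g)) stop("no non-missing progeny calls")
  counts <- tabulate(g + 1L, nbins = 3L)
  if (segtype == "hkxhk") {
    p <- c(0.25, 0.5, 0.25)
    classes <- 1:3
  } else if (!is.null(mother) && !is.null(father)) {
    p_full <- expected_progeny_distribution(mother, father)
    classes <- which(p_full > 0)
    p <- rep(1 / length(classes), length(classes))
  } else {
    # 1:1 over the two classes consistent with a het x hom cross: the het
    # class plus the more frequent homozygous class
    hom <- if (counts[1] >= counts[3]) 1L else 3L
    classes <- sort(c(2L, hom))
    p <- c(0.5, 0.5)
  }
  obs <- counts[classes]
  n <- sum(obs)
  e <- n * p
  sum((obs - e)^2 / e)
}
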