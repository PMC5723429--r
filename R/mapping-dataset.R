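#' Bundle parents and progeny into a mapping dataset
#'
#' A `mapping_dataset` holds the progeny call grid, the two parental call
#' vectors and per-locus segregation types; it is the input to
#' [export_joinmap_loc()] and [qtl_scan()].
#'
#' @param progeny a [genotype_matrix()] of the F1 progeny.
#' @param mother,father parental call codes over the loci of `progeny`.
#' @return an object of class `mapping_dataset`: list with `calls`, `mother`,
#'   `father` and `loci` (locus tibble augmented with `segtype`).
#' @export
mapping_dataset <- function(progeny, mother, father) {
  stopifnot(length(mother) == ncol(progeny$calls),
            length(father) == ncol(progeny$calls))
  known <- !is.na(mother) & !is.na(father)
  segtype <- rep(NA_character_, length(mother))
  segtype[known] <- classify_segregation(mother[known], father[known])
  loci <- progeny$loci
  loci$segtype <- segtype
  structure(
    list(calls = progeny$calls, mother = as.integer(mother),
         father = as.integer(father), loci = loci),
    class = "mapping_dataset"
  )
}

#' @export
print.mapping_dataset <- function(x, ...) {
  tab <- table(factor(x$loci$segtype, levels = SEG_LEVELS))
  cat(sprintf("<mapping_dataset> %d progeny x %d loci (%s)\n",
              nrow(x$calls), ncol(x$calls),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Prepare genotype data for linkage mapping
#'
#' Applies, in order, the input hygiene rules used before CP map
#' construction: drop loci with a missing parent call or an uninformative
#' (both-parents-homozygous) segregation type; drop loci missing in more than
#' `locus_missing_max` of the progeny (strict `>`); drop loci whose
#' segregation-distortion chi-square exceeds `chi_max` (strict `>`); drop
#' progeny missing more than `indiv_missing_max` of the remaining loci
#' (strict `>`); drop loci whose genotype vector is identical to an earlier
#' locus (first listed kept); drop progeny whose genotype vector duplicates
#' an earlier individual.
#'
#' @inheritParams mapping_dataset
#' @param locus_missing_max,indiv_missing_max missingness fractions.
#' @param chi_max segregation-distortion chi-square cutoff.
#' @return list with `dataset` (a [mapping_dataset()]) and `report`, a tibble
#'   of removals (`rule`, `id`, `value`).
#' @export
prepare_mapping_dataset <- function(progeny, mother, father,
                                    locus_missing_max = 0.05, chi_max = 15,
                                    indiv_missing_max = 0.15) {
  ds <- mapping_dataset(progeny, mother, father)
  rep_rule <- character()
  rep_id <- character()
  rep_val <- numeric()
  note <- function(rule, id, value) {
    rep_rule <<- c(rep_rule, rep(rule, length(id)))
    rep_id <<- c(rep_id, id)
    rep_val <<- c(rep_val, rep_len(value, length(id)))
  }
  keep <- rep(TRUE, ncol(ds$calls))

  uninf <- is.na(ds$loci$segtype) | ds$loci$segtype == "uninformative"
  note("uninformative_locus", ds$loci$locus_id[uninf], NA_real_)
  keep[uninf] <- FALSE

  miss_frac <- colMeans(is.na(ds$calls))
  too_missing <- keep & miss_frac > locus_missing_max
  note("locus_missing", ds$loci$locus_id[too_missing], miss_frac[too_missing])
  keep[too_missing] <- FALSE

  chi <- rep(NA_real_, ncol(ds$calls))
  for (j in which(keep)) {
    g <- ds$calls[, j]
    if (all(is.na(g))) {
      chi[j] <- Inf
    } else {
      chi[j] <- segregation_distortion_chi2(
        g, ds$loci$segtype[j], ds$mother[j], ds$father[j]
      )
    }
  }
  distorted <- keep & !is.na(chi) & chi > chi_max
  note("distortion_chi2", ds$loci$locus_id[distorted], chi[distorted])
  keep[distorted] <- FALSE

  calls <- ds$calls[, keep, drop = FALSE]
  ind_miss <- rowMeans(is.na(calls))
  drop_ind <- ind_miss > indiv_missing_max
  note("individual_missing", rownames(calls)[drop_ind], ind_miss[drop_ind])
  calls <- calls[!drop_ind, , drop = FALSE]

  loc_key <- apply(calls, 2, paste, collapse = ",")
  dup_loc <- duplicated(loc_key)
  note("duplicate_locus", colnames(calls)[dup_loc], NA_real_)
  calls <- calls[, !dup_loc, drop = FALSE]

  ind_key <- apply(calls, 1, paste, collapse = ",")
  dup_ind <- duplicated(ind_key)
  note("duplicate_individual", rownames(calls)[dup_ind], NA_real_)
  calls <- calls[!dup_ind, , drop = FALSE]

  keep_final <- match(colnames(calls), ds$loci$locus_id)
  prog2 <- genotype_matrix(calls, loci = progeny$loci[keep_final, , drop = FALSE])
  out <- mapping_dataset(prog2, ds$mother[keep_final], ds$father[keep_final])
  list(
    dataset = out,
    report = tibble::tibble(rule = rep_rule, id = rep_id, value = rep_val)
  )
}

# JoinMap CP-code token tables. For lmxll the shared allele l is the father's
# homozygous allele; for nnxnp, n is the mother's; for hkxhk the phase
# default is h = reference allele (true phase determination is out of scope).
joinmap_tokens <- function(segtype, mother, father, calls) {
  tok <- rep("--", length(calls))
  ok <- !is.na(calls)
  if (segtype == "lmxll") {
    ll_geno <- father # 0 or 2
    tok[ok & calls == ll_geno] <- "ll"
    tok[ok & calls == 1L] <- "lm"
  } else if (segtype == "nnxnp") {
    nn_geno <- mother
    tok[ok & calls == nn_geno] <- "nn"
    tok[ok & calls == 1L] <- "np"
  } else if (segtype == "hkxhk") {
    tok[ok & calls == 0L] <- "hh"
    tok[ok & calls == 1L] <- "hk"
    tok[ok & calls == 2L] <- "kk"
  }
  tok
}

#' Export a mapping dataset as a JoinMap CP .loc file
#'
#' Writes the outbreeding full-sib ("CP") population format: a header with
#' the population name, `popt = CP`, `nloc` and `nind`, then one record per
#' informative locus with its segregation code and per-progeny tokens
#' (`ll`/`lm`, `nn`/`np`, `hh`/`hk`/`kk`, `--` for missing). The
#' letter-to-allele mapping of every locus is recorded in a
#' `<path>.alleles.tsv` sidecar; `hkxhk` phase letters default to
#' h = reference allele.
#'
#' @param dataset a [mapping_dataset()] (uninformative loci are skipped).
#' @param population_name name written in the header.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_joinmap_loc <- function(dataset, population_name, path) {
  inf <- which(dataset$loci$segtype %in% c("lmxll", "nnxnp", "hkxhk"))
  header <- c(
    sprintf("name = %s", population_name),
    "popt = CP",
    sprintf("nloc = %d", length(inf)),
    sprintf("nind = %d", nrow(dataset$calls))
  )
  records <- character(0)
  side <- vector("list", length(inf))
  for (k in seq_along(inf)) {
    j <- inf[k]
    st <- dataset$loci$segtype[j]
    tok <- joinmap_tokens(st, dataset$mother[j], dataset$father[j],
                          dataset$calls[, j])
    records <- c(records,
                 sprintf("%s <%s>", dataset$loci$locus_id[j], st),
                 paste(tok, collapse = " "))
    ref <- dataset$loci$allele_ref[j]
    alt <- dataset$loci$allele_alt[j]
    letters <- switch(st,
      lmxll = c(l = if (dataset$father[j] == 0L) ref else alt,
                m = if (dataset$father[j] == 0L) alt else ref),
      nnxnp = c(n = if (dataset$mother[j] == 0L) ref else alt,
                p = if (dataset$mother[j] == 0L) alt else ref),
      hkxhk = c(h = ref, k = alt)
    )
    side[[k]] <- tibble::tibble(
      locus_id = dataset$loci$locus_id[j], segtype = st,
      letter = names(letters), allele = unname(letters)
    )
  }
  writeLines(c(header, records), path)
  utils::write.table(dplyr::bind_rows(side), paste0(path, ".alleles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a JoinMap CP .loc file written by [export_joinmap_loc()]
#'
#' @param path the `.loc` file path.
#' @return list with `name`, `nloc`, `nind`, and `loci`: a tibble of
#'   `locus_id`, `segtype` and a list-column `tokens` of per-progeny codes.
#' @export
read_joinmap_loc <- function(path) {
  lines <- readLines(path)
  get_field <- function(key) {
    ln <- grep(sprintf("^%s = ", key), lines, value = TRUE)[1]
    sub(sprintf("^%s = ", key), "", ln)
  }
  name <- get_field("name")
  nloc <- as.integer(get_field("nloc"))
  nind <- as.integer(get_field("nind"))
  body <- lines[-(1:4)]
  ids <- character(nloc)
  segtype <- character(nloc)
  tokens <- vector("list", nloc)
  for (k in seq_len(nloc)) {
    head_ln <- body[[2 * k - 1]]
    parts <- strsplit(head_ln, " ", fixed = TRUE)[[1]]
    ids[k] <- parts[[1]]
    segtype[k] <- gsub("[<>]", "", parts[[2]])
    tokens[[k]] <- strsplit(body[[2 * k]], " ", fixed = TRUE)[[1]]
  }
  list(name = name, nloc = nloc, nind = nind,
       loci = tibble::tibble(locus_id = ids, segtype = segtype,
                             tokens = tokens))
}
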