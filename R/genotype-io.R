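# Two on-disk dialects are supported:
#  * matrix_tsv  — a samples x loci TSV of AA/AB/BB tokens ("--" = missing),
#    with optional sidecars <path>.loci.tsv (locus metadata incl. GenTrain)
#    and <path>.gencall.tsv (per-call GenCall grid). Lossless.
#  * plink_ped_map — PED/MAP pair for interoperability with Mendelian-error
#    tooling ("0 0" = missing). An .alleles.tsv sidecar records the ref/alt
#    orientation so calls survive a round trip; the GenCall grid and GenTrain
#    scores are dropped by this dialect.

TOKENS_TSV <- c("AA", "AB", "BB")
MISSING_TSV <- "--"

#' Read a genotype matrix from disk
#'
#' @param path file path. For `plink_ped_map` this is the common stem of the
#'   `.ped`/`.map` pair (with or without the `.ped` extension).
#' @param dialect `"matrix_tsv"` or `"plink_ped_map"`.
#' @return a [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, dialect = c("matrix_tsv", "plink_ped_map")) {
  dialect <- match.arg(dialect)
  switch(dialect,
    matrix_tsv = read_matrix_tsv(path),
    plink_ped_map = read_plink(path)
  )
}

#' Write a genotype matrix to disk
#'
#' `read_genotype_matrix(write_genotype_matrix(m, path, d), d)` is the
#' identity for every field the dialect supports.
#'
#' @param m a [genotype_matrix()].
#' @inheritParams read_genotype_matrix
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(m, path, dialect = c("matrix_tsv", "plink_ped_map")) {
  dialect <- match.arg(dialect)
  switch(dialect,
    matrix_tsv = write_matrix_tsv(m, path),
    plink_ped_map = write_plink(m, path)
  )
  invisible(path)
}

read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("parse error at line 1: empty file")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 1L || header[[1]] != "sample_id") {
    stop("parse error at line 1: header must start with 'sample_id'")
  }
  ids <- header[-1]
  if (anyDuplicated(ids)) stop("parse error at line 1: duplicated locus id")
  body <- lines[-1]
  calls <- matrix(NA_integer_, nrow = length(body), ncol = length(ids))
  samples <- character(length(body))
  for (i in seq_along(body)) {
    fields <- strsplit(body[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(ids) + 1L) {
      stop(sprintf("parse error at line %d: expected %d fields, got %d",
                   i + 1L, length(ids) + 1L, length(fields)))
    }
    samples[[i]] <- fields[[1]]
    tok <- fields[-1]
    known <- tok %in% c(TOKENS_TSV, MISSING_TSV)
    if (!all(known)) {
      stop(sprintf("parse error at line %d: unknown call token '%s'",
                   i + 1L, tok[!known][[1]]))
    }
    calls[i, ] <- match(tok, TOKENS_TSV) - 1L
  }
  if (anyDuplicated(samples)) {
    stop(sprintf("parse error at line %d: duplicated sample id '%s'",
                 which(duplicated(samples))[[1]] + 1L,
                 samples[duplicated(samples)][[1]]))
  }
  rownames(calls) <- samples
  colnames(calls) <- ids
  loci <- NULL
  loci_path <- paste0(path, ".loci.tsv")
  if (file.exists(loci_path)) {
    loci <- utils::read.delim(loci_path, colClasses = "character")
    loci$pos <- as.integer(loci$pos)
    loci$gentrain <- if ("gentrain" %in% names(loci)) as.numeric(loci$gentrain) else NA_real_
    bad <- !loci$allele_ref %in% c("A", "C", "G", "T") |
      !loci$allele_alt %in% c("A", "C", "G", "T")
    if (any(bad)) {
      stop(sprintf("parse error at line %d of %s: allele outside {A,C,G,T}",
                   which(bad)[[1]] + 1L, basename(loci_path)))
    }
    loci <- tibble::as_tibble(loci)
  }
  gencall <- NULL
  gc_path <- paste0(path, ".gencall.tsv")
  if (file.exists(gc_path)) {
    gc_df <- utils::read.delim(gc_path, check.names = FALSE)
    gencall <- as.matrix(gc_df[, -1, drop = FALSE])
    rownames(gencall) <- gc_df[[1]]
    gencall <- gencall[samples, ids, drop = FALSE]
  }
  genotype_matrix(calls, loci = loci, gencall = gencall)
}

write_matrix_tsv <- function(m, path) {
  tok <- matrix(MISSING_TSV, nrow = nrow(m$calls), ncol = ncol(m$calls))
  ok <- !is.na(m$calls)
  tok[ok] <- TOKENS_TSV[m$calls[ok] + 1L]
  lines <- c(
    paste(c("sample_id", colnames(m$calls)), collapse = "\t"),
    vapply(seq_len(nrow(tok)), function(i) {
      paste(c(rownames(m$calls)[i], tok[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  utils::write.table(m$loci, paste0(path, ".loci.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(m$gencall)) {
    gc_df <- data.frame(sample_id = rownames(m$calls), m$gencall,
                        check.names = FALSE)
    utils::write.table(gc_df, paste0(path, ".gencall.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

plink_stem <- function(path) sub("\\.ped$", "", path)

write_plink <- function(m, path) {
  stem <- plink_stem(path)
  ref <- m$loci$allele_ref
  alt <- m$loci$allele_alt
  n <- nrow(m$calls)
  ped <- vapply(seq_len(n), function(i) {
    g <- m$calls[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, alt, ref))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, alt, ref))
    paste(c(rownames(m$calls)[i], rownames(m$calls)[i], "0", "0", "0", "-9",
            as.vector(rbind(a1, a2))), collapse = " ")
  }, character(1))
  writeLines(ped, paste0(stem, ".ped"))
  map <- data.frame(chrom = m$loci$chrom, id = m$loci$locus_id,
                    cm = 0, pos = m$loci$pos)
  utils::write.table(map, paste0(stem, ".map"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(
    data.frame(locus_id = m$loci$locus_id, allele_ref = ref, allele_alt = alt),
    paste0(stem, ".alleles.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

read_plink <- function(path) {
  stem <- plink_stem(path)
  ped_path <- paste0(stem, ".ped")
  map_path <- paste0(stem, ".map")
  if (!file.exists(ped_path)) stop("no such file: ", ped_path)
  if (!file.exists(map_path)) stop("no such file: ", map_path)
  map <- utils::read.table(map_path, sep = "\t", colClasses = "character")
  names(map) <- c("chrom", "locus_id", "cm", "pos")
  if (anyDuplicated(map$locus_id)) {
    stop(sprintf("parse error at line %d of %s: duplicated locus id",
                 which(duplicated(map$locus_id))[[1]], basename(map_path)))
  }
  n_loc <- nrow(map)
  lines <- readLines(ped_path)
  samples <- character(length(lines))
  calls <- matrix(NA_integer_, nrow = length(lines), ncol = n_loc)
  alleles_path <- paste0(stem, ".alleles.tsv")
  ra <- NULL
  if (file.exists(alleles_path)) {
    ra <- utils::read.delim(alleles_path, colClasses = "character")
    ra <- ra[match(map$locus_id, ra$locus_id), ]
  }
  allele_pool <- vector("list", n_loc)
  geno_rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    if (length(fields) != 6L + 2L * n_loc) {
      stop(sprintf("parse error at line %d: expected %d fields, got %d",
                   i, 6L + 2L * n_loc, length(fields)))
    }
    samples[[i]] <- fields[[2]]
    g <- matrix(fields[-(1:6)], nrow = 2L)
    bad <- !(g %in% c("A", "C", "G", "T", "0"))
    if (any(bad)) {
      stop(sprintf("parse error at line %d: allele token '%s' outside {A,C,G,T}",
                   i, g[bad][[1]]))
    }
    geno_rows[[i]] <- g
  }
  if (anyDuplicated(samples)) {
    stop(sprintf("parse error at line %d: duplicated sample id '%s'",
                 which(duplicated(samples))[[1]],
                 samples[duplicated(samples)][[1]]))
  }
  if (is.null(ra)) {
    # no orientation sidecar: ref allele = first allele observed per locus
    ref <- rep(NA_character_, n_loc)
    alt <- rep(NA_character_, n_loc)
    for (i in seq_along(geno_rows)) {
      g <- geno_rows[[i]]
      for (j in seq_len(n_loc)) {
        for (a in g[, j]) {
          if (a == "0") next
          if (is.na(ref[j])) ref[j] <- a
          else if (a != ref[j] && is.na(alt[j])) alt[j] <- a
        }
      }
    }
    alt[is.na(alt)] <- setdiff(c("A", "C", "G", "T"), ref)[1]
  } else {
    ref <- ra$allele_ref
    alt <- ra$allele_alt
  }
  for (i in seq_along(geno_rows)) {
    g <- geno_rows[[i]]
    miss <- g[1, ] == "0" | g[2, ] == "0"
    cnt <- (g[1, ] == alt) + (g[2, ] == alt)
    cnt[miss] <- NA_integer_
    calls[i, ] <- as.integer(cnt)
  }
  rownames(calls) <- samples
  loci <- tibble::tibble(
    locus_id = map$locus_id, chrom = map$chrom, pos = as.integer(map$pos),
    allele_ref = ref, allele_alt = alt, gentrain = NA_real_
  )
  genotype_matrix(calls, loci = loci)
}
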