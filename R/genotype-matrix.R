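# Biallelic calls are stored as integers: 0 = HOM_REF, 1 = HET, 2 = HOM_ALT,
# NA = MISSING. The integer is the count of the alternate allele, which makes
# Mendelian transmission and predictor coding arithmetic rather than lookup.

#' Genotype call codes
#'
#' Calls are represented throughout the package as the count of the alternate
#' allele: `0` homozygous reference, `1` heterozygous, `2` homozygous
#' alternate, `NA` missing. These helpers convert between the integer codes
#' and their labels.
#'
#' @param x integer vector of call codes (0/1/2/NA).
#' @return `call_labels()` returns a character vector among
#'   `"HOM_REF"`, `"HET"`, `"HOM_ALT"`, `NA`.
#' @export
call_labels <- function(x) {
  c("HOM_REF", "HET", "HOM_ALT")[x + 1L]
}

#' @rdname call_labels
#' @param labels character vector of call labels.
#' @return `call_codes()` returns the integer codes.
#' @export
call_codes <- function(labels) {
  out <- match(labels, c("HOM_REF", "HET", "HOM_ALT")) - 1L
  out
}

#' Construct a genotype matrix
#'
#' A `genotype_matrix` couples a samples x loci grid of biallelic calls with
#' per-locus metadata (chromosome, 1-based position, ref/alt alleles and an
#' optional per-locus GenTrain clustering score) and an optional per-call
#' GenCall confidence grid. Positions are 1-based and inclusive everywhere in
#' the package.
#'
#' @param calls integer matrix (samples in rows, loci in columns) of call
#'   codes 0/1/2/NA; dimnames are taken as sample and locus ids when `samples`
#'   / `loci` are not supplied.
#' @param loci tibble of locus metadata with columns `locus_id`, `chrom`,
#'   `pos`, `allele_ref`, `allele_alt` and optionally `gentrain`. May be
#'   `NULL`, in which case placeholder metadata are created from column names.
#' @param gencall optional numeric matrix of per-call GenCall scores in
#'   \[0, 1\], same shape as `calls`.
#' @param samples optional character vector of sample ids.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, loci = NULL, gencall = NULL, samples = NULL) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (!is.null(samples)) rownames(calls) <- samples
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("S%03d", seq_len(nrow(calls)))
  }
  if (is.null(loci)) {
    ids <- colnames(calls)
    if (is.null(ids)) ids <- sprintf("M%05d", seq_len(ncol(calls)))
    loci <- tibble::tibble(
      locus_id = ids, chrom = "1", pos = seq_len(ncol(calls)),
      allele_ref = "A", allele_alt = "C", gentrain = NA_real_
    )
  }
  loci <- tibble::as_tibble(loci)
  if (!"gentrain" %in% names(loci)) loci$gentrain <- NA_real_
  colnames(calls) <- loci$locus_id
  bad <- calls[!is.na(calls) & (calls < 0L | calls > 2L)]
  if (length(bad)) stop("call codes must be 0, 1, 2 or NA")
  if (anyDuplicated(rownames(calls))) stop("duplicated sample id")
  if (anyDuplicated(loci$locus_id)) stop("duplicated locus id")
  if (nrow(loci) != ncol(calls)) stop("loci metadata does not match call grid")
  if (any(loci$pos < 1, na.rm = TRUE)) stop("positions must be >= 1")
  same <- !is.na(loci$allele_ref) & loci$allele_ref == loci$allele_alt
  if (any(same)) stop("allele_ref must differ from allele_alt")
  if (!is.null(gencall)) {
    gencall <- as.matrix(gencall)
    if (!all(dim(gencall) == dim(calls))) stop("gencall grid shape mismatch")
    dimnames(gencall) <- dimnames(calls)
  }
  structure(
    list(calls = calls, loci = loci, gencall = gencall),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d loci (%.1f%% missing%s)\n",
    nrow(x$calls), ncol(x$calls),
    if (length(x$calls)) 100 * mean(is.na(x$calls)) else 0,
    if (is.null(x$gencall)) "" else ", with GenCall grid"
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Sample and locus accessors
#' @param m a `genotype_matrix`.
#' @return character vector of ids.
#' @export
sample_ids <- function(m) rownames(m$calls)

#' @rdname sample_ids
#' @export
locus_ids <- function(m) m$loci$locus_id

#' Subset a genotype matrix
#'
#' @param m a `genotype_matrix`.
#' @param samples,loci character ids or logical/integer indices; `NULL` keeps
#'   everything.
#' @return a `genotype_matrix`.
#' @export
gm_subset <- function(m, samples = NULL, loci = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(m$calls)) else samples
  li <- if (is.null(loci)) seq_len(ncol(m$calls)) else loci
  if (is.character(si)) si <- match(si, rownames(m$calls))
  if (is.character(li)) li <- match(li, m$loci$locus_id)
  if (is.logical(li)) li <- which(li)
  if (is.logical(si)) si <- which(si)
  genotype_matrix(
    m$calls[si, li, drop = FALSE],
    loci = m$loci[li, , drop = FALSE],
    gencall = if (is.null(m$gencall)) NULL else m$gencall[si, li, drop = FALSE]
  )
}

#' Genotype calls as a long tibble
#'
#' @param x a `genotype_matrix`.
#' @param ... unused.
#' @return tibble with columns `sample_id`, `locus_id`, `call` (integer code)
#'   and `gencall` when present.
#' @export
#' @method tidy genotype_matrix
tidy.genotype_matrix <- function(x, ...) {
  out <- tibble::tibble(
    sample_id = rep(rownames(x$calls), times = ncol(x$calls)),
    locus_id = rep(colnames(x$calls), each = nrow(x$calls)),
    call = as.integer(x$calls)
  )
  if (!is.null(x$gencall)) out$gencall <- as.numeric(x$gencall)
  out
}
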