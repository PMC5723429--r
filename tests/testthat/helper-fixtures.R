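# In-code fixtures shared across the suite.

# small genotype matrix with full metadata and a GenCall grid
toy_matrix <- function(calls, gentrain = NULL, gencall = NULL,
                       chrom = "1") {
  calls <- as.matrix(calls)
  n_loc <- ncol(calls)
  loci <- tibble::tibble(
    locus_id = sprintf("mk%02d", seq_len(n_loc)),
    chrom = rep_len(chrom, n_loc),
    pos = seq_len(n_loc) * 100L,
    allele_ref = rep_len(c("A", "C", "G", "T"), n_loc),
    allele_alt = rep_len(c("C", "G", "T", "A"), n_loc),
    gentrain = if (is.null(gentrain)) NA_real_ else gentrain
  )
  genotype_matrix(calls, loci = loci, gencall = gencall)
}

# independent oracle: expected progeny distribution by exhaustive
# enumeration of the four equally likely gamete combinations
enumerate_progeny <- function(mother, father) {
  gametes <- function(g) switch(as.character(g),
    "0" = c(0L, 0L), "1" = c(0L, 1L), "2" = c(1L, 1L))
  gm <- gametes(mother)
  gf <- gametes(father)
  out <- c(HOM_REF = 0, HET = 0, HOM_ALT = 0)
  for (a in gm) for (b in gf) out[a + b + 1L] <- out[a + b + 1L] + 0.25
  out
}

# simulated cross bundle used by several files
small_cross <- function(seed = 1, n_progeny = 120, markers_per_lg = 30,
                        mother_het = 0.901, father_het = 0.205, ...) {
  cfg <- sim_config(n_lg = 10, markers_per_lg = markers_per_lg,
                    lg_lengths_cM = 100, mother_het = mother_het,
                    father_het = father_het, n_progeny = n_progeny,
                    seed = seed, ...)
  parents <- simulate_parents(cfg)
  sim <- simulate_f1(parents, cfg)
  list(cfg = cfg, parents = parents, sim = sim)
}

# a minimal candidate-variant tibble with sensible defaults
make_variants <- function(n, chrom = "1", pos = seq_len(n) * 1000L,
                          ref = "A", alt = "C", quality = 30,
                          freq = 0.5, reads = 10, indel = FALSE,
                          flank_unique = TRUE, gene = NA_character_,
                          effect = "unknown", adt = 0.95,
                          source = "genome") {
  tibble::tibble(
    variant_id = sprintf("%s_v%04d", chrom, seq_len(n)),
    chrom = rep_len(chrom, n), pos = pos,
    allele_ref = rep_len(ref, n), allele_alt = rep_len(alt, n),
    phred_quality = rep_len(quality, n), alt_freq = rep_len(freq, n),
    alt_read_count = rep_len(reads, n), is_indel = rep_len(indel, n),
    flank_unique = rep_len(flank_unique, n), gene_id = rep_len(gene, n),
    effect = rep_len(effect, n), adt_score = rep_len(adt, n),
    source = rep_len(source, n)
  )
}
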