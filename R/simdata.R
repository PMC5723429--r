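# Synthetic F1-cross generator: phased parents with target heterozygosity
# over a multi-linkage-group genetic map, progeny gametes by a Markov walk
# with Haldane recombination, symmetric genotyping error, missingness,
# injected off-type individuals, and QTL-driven phenotypes. Every stochastic
# stage draws from its own named substream of one master seed.

#' Simulation configuration
#'
#' Defaults emulate a Stalin-A-like cacao cross: 10 linkage groups, a highly
#' heterozygous mother (90.1%) by a mostly homozygous father (20.5%
#' heterozygous); a Stalin-B-like cross uses 0.50 / 0.588. Physical
#' positions are laid down at a constant 350,000 bp/cM, in the range
#' estimated for the cacao genome.
#'
#' @param n_lg number of linkage groups.
#' @param markers_per_lg markers per linkage group (evenly spaced).
#' @param lg_lengths_cM numeric vector (recycled) of LG genetic lengths.
#' @param mother_het,father_het target parental heterozygosity in \[0, 1\].
#' @param n_progeny F1 family size.
#' @param genotyping_error per-call probability of a symmetric state flip.
#' @param het_hom_bias if `TRUE`, errors on true heterozygotes always go to
#'   a homozygote (array-style bias) instead of a uniform other state.
#' @param missing_rate per-call missingness probability.
#' @param off_type_fraction fraction of progeny replaced by unrelated
#'   individuals drawn from population allele frequencies.
#' @param qtl_spec tibble with `lg`, `cm`, `add`, `dom`, `trait` rows
#'   planting QTL at the nearest marker (traits: `pods`, `fp`, `cherelle`,
#'   `weight`).
#' @param trait_noise_sd residual SD of the Gaussian weight component.
#' @param n_months months of phenotype observation records.
#' @param bp_per_cm physical bp per cM used to lay marker positions.
#' @param seed master integer seed (mandatory).
#' @return a `sim_config` list, including the generated `map` tibble
#'   (`marker`, `lg`, `cm`, `chrom`, `pos`).
#' @export
sim_config <- function(n_lg = 10, markers_per_lg = 50,
                       lg_lengths_cM = 100, mother_het = 0.901,
                       father_het = 0.205, n_progeny = 200,
                       genotyping_error = 0, het_hom_bias = FALSE,
                       missing_rate = 0, off_type_fraction = 0,
                       qtl_spec = NULL, trait_noise_sd = 1, n_months = 12,
                       bp_per_cm = 350000, seed) {
  if (missing(seed)) stop("seed is mandatory")
  rates <- c(mother_het, father_het, genotyping_error, missing_rate,
             off_type_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  lens <- rep_len(lg_lengths_cM, n_lg)
  map <- dplyr::bind_rows(lapply(seq_len(n_lg), function(g) {
    cm <- if (markers_per_lg == 1) 0 else
      seq(0, lens[g], length.out = markers_per_lg)
    tibble::tibble(
      marker = sprintf("LG%02d_M%04d", g, seq_len(markers_per_lg)),
      lg = g, cm = cm, chrom = as.character(g),
      pos = as.integer(round(cm * bp_per_cm)) + 1L
    )
  }))
  structure(
    list(n_lg = n_lg, markers_per_lg = markers_per_lg,
         lg_lengths_cM = lens, mother_het = mother_het,
         father_het = father_het, n_progeny = n_progeny,
         genotyping_error = genotyping_error, het_hom_bias = het_hom_bias,
         missing_rate = missing_rate, off_type_fraction = off_type_fraction,
         qtl_spec = qtl_spec, trait_noise_sd = trait_noise_sd,
         n_months = n_months, bp_per_cm = bp_per_cm, seed = seed, map = map),
    class = "sim_config"
  )
}

#' Simulate phased parental diplotypes
#'
#' Each marker is heterozygous with the parent's target probability (phase
#' random); homozygous markers are alt/alt with the marker's population
#' allele frequency. Population frequencies are drawn once per marker from
#' Uniform(0.1, 0.9) so off-type draws and homozygote assignment share one
#' frequency model.
#'
#' @param cfg a [sim_config()].
#' @return list with `mother`/`father` (each `h1`, `h2` alt-indicator
#'   vectors and `geno` call codes), `freq` (per-marker alt frequency) and
#'   `loci` (locus tibble with ref/alt alleles).
#' @export
simulate_parents <- function(cfg) {
  n <- nrow(cfg$map)
  rng <- substream_rng(cfg$seed, "parents")
  freq <- rng_eval(rng, stats::runif(n, 0.1, 0.9))
  draw_parent <- function(target_het) {
    het <- rng_eval(rng, stats::runif(n)) < target_het
    first_alt <- rng_eval(rng, stats::runif(n)) < 0.5
    hom_alt <- rng_eval(rng, stats::runif(n)) < freq
    h1 <- ifelse(het, as.integer(first_alt), as.integer(hom_alt))
    h2 <- ifelse(het, 1L - as.integer(first_alt), as.integer(hom_alt))
    list(h1 = h1, h2 = h2, geno = h1 + h2)
  }
  pair_pool <- c("AC", "AG", "CT", "GT", "AT", "CG")
  pairs <- rng_eval(rng, sample(pair_pool, n, replace = TRUE,
                                prob = c(rep(0.225, 4), 0.05, 0.05)))
  loci <- tibble::tibble(
    locus_id = cfg$map$marker, chrom = cfg$map$chrom, pos = cfg$map$pos,
    allele_ref = substr(pairs, 1, 1), allele_alt = substr(pairs, 2, 2),
    gentrain = NA_real_
  )
  list(mother = draw_parent(cfg$mother_het),
       father = draw_parent(cfg$father_het),
       freq = freq, loci = loci)
}

# one gamete per row: Markov walk along each LG with Haldane switch
# probabilities r = (1 - exp(-2d)) / 2, d in Morgans
simulate_gametes <- function(parent, map, n_gametes, rng) {
  n_mark <- nrow(map)
  out <- matrix(0L, nrow = n_gametes, ncol = n_mark)
  for (g in unique(map$lg)) {
    idx <- which(map$lg == g)
    d_cm <- diff(map$cm[idx])
    r <- (1 - exp(-2 * d_cm / 100)) / 2
    m <- length(idx)
    state <- matrix(0L, nrow = n_gametes, ncol = m)
    state[, 1] <- rng_eval(rng, stats::rbinom(n_gametes, 1L, 0.5))
    if (m > 1) {
      flips <- rng_eval(rng, matrix(
        stats::rbinom(n_gametes * (m - 1), 1L, rep(r, each = n_gametes)),
        nrow = n_gametes
      ))
      for (k in 2:m) state[, k] <- bitwXor(state[, k - 1], flips[, k - 1])
    }
    h1 <- parent$h1[idx]
    h2 <- parent$h2[idx]
    out[, idx] <- t(ifelse(t(state) == 0L, h1, h2))
  }
  out
}

#' Simulate an F1 family with noise and off-types
#'
#' True progeny are unions of two recombinant gametes; then
#' `off_type_fraction` of individuals are replaced by Hardy-Weinberg draws
#' from the population allele frequencies, genotyping errors flip calls, and
#' missingness blanks them.
#'
#' @param parents output of [simulate_parents()].
#' @param cfg the same [sim_config()].
#' @return list with `progeny` (an observed [genotype_matrix()]) and
#'   `truth`: phased parents, the pre-noise genotype matrix `true_geno`,
#'   `off_type_ids`, the population `freq` and the `map`.
#' @export
simulate_f1 <- function(parents, cfg) {
  n <- cfg$n_progeny
  n_mark <- nrow(cfg$map)
  rng <- substream_rng(cfg$seed, "meiosis")
  gm <- simulate_gametes(parents$mother, cfg$map, n, rng)
  gf <- simulate_gametes(parents$father, cfg$map, n, rng)
  true_geno <- gm + gf
  ids <- sprintf("F1_%04d", seq_len(n))
  rownames(true_geno) <- ids

  rng_off <- substream_rng(cfg$seed, "off_types")
  n_off <- round(cfg$off_type_fraction * n)
  off_ids <- character()
  if (n_off > 0) {
    off_rows <- sample_int(rng_off, n, n_off)
    off_ids <- ids[off_rows]
    hw <- rng_eval(rng_off, matrix(
      stats::rbinom(n_off * n_mark, 2L, rep(parents$freq, each = n_off)),
      nrow = n_off
    ))
    true_geno[off_rows, ] <- hw
  }

  obs <- true_geno
  rng_err <- substream_rng(cfg$seed, "errors")
  if (cfg$genotyping_error > 0) {
    hit <- rng_eval(rng_err, matrix(
      stats::runif(n * n_mark) < cfg$genotyping_error, nrow = n
    ))
    wrong <- which(hit)
    if (length(wrong)) {
      cur <- obs[wrong]
      if (cfg$het_hom_bias) {
        # heterozygotes err to a random homozygote; homozygotes stay uniform
        pick <- rng_eval(rng_err, stats::runif(length(wrong)))
        new <- ifelse(cur == 1L, ifelse(pick < 0.5, 0L, 2L),
                      ifelse(pick < 0.5, 1L,
                             ifelse(cur == 0L, 2L, 0L)))
      } else {
        shift <- rng_eval(rng_err,
                          sample(c(1L, 2L), length(wrong), replace = TRUE))
        new <- (cur + shift) %% 3L
      }
      obs[wrong] <- new
    }
  }
  if (cfg$missing_rate > 0) {
    gone <- rng_eval(rng_err, matrix(
      stats::runif(n * n_mark) < cfg$missing_rate, nrow = n
    ))
    obs[gone] <- NA_integer_
  }
  progeny <- genotype_matrix(obs, loci = parents$loci)
  truth <- list(
    mother = parents$mother, father = parents$father,
    true_geno = true_geno, off_type_ids = off_ids,
    freq = parents$freq, map = cfg$map
  )
  list(progeny = progeny, truth = truth)
}

# nearest marker to each planted QTL
resolve_qtl_markers <- function(qtl_spec, map) {
  idx <- integer(nrow(qtl_spec))
  for (i in seq_len(nrow(qtl_spec))) {
    on_lg <- which(map$lg == qtl_spec$lg[i])
    if (!length(on_lg)) stop("QTL planted on unknown linkage group ",
                             qtl_spec$lg[i])
    idx[i] <- on_lg[which.min(abs(map$cm[on_lg] - qtl_spec$cm[i]))]
  }
  idx
}

#' Latent genetic values of planted QTL
#'
#' Sum of additive (`add * (genotype - 1)`) and dominance
#' (`dom * (het - 1/2)`) contributions at each planted QTL's nearest marker,
#' per trait, computed from the true pre-error genotypes.
#'
#' @param truth the `truth` element of [simulate_f1()].
#' @param qtl_spec tibble with `lg`, `cm`, `add`, `dom`, `trait`.
#' @return numeric matrix (individuals x traits), zero columns for traits
#'   with no planted QTL.
#' @export
genetic_values <- function(truth, qtl_spec) {
  traits <- c("pods", "fp", "cherelle", "weight")
  g <- matrix(0, nrow = nrow(truth$true_geno), ncol = length(traits),
              dimnames = list(rownames(truth$true_geno), traits))
  if (is.null(qtl_spec) || !nrow(qtl_spec)) return(g)
  idx <- resolve_qtl_markers(qtl_spec, truth$map)
  for (i in seq_len(nrow(qtl_spec))) {
    geno <- truth$true_geno[, idx[i]]
    contrib <- qtl_spec$add[i] * (geno - 1) +
      qtl_spec$dom[i] * ((geno == 1L) - 0.5)
    g[, qtl_spec$trait[i]] <- g[, qtl_spec$trait[i]] + contrib
  }
  g
}

#' Simulate monthly phenotype observation records
#'
#' Per tree and month: healthy pods and wilted cherelles are Poisson with a
#' log-mean shifted by their traits' genetic values; frosty-pod counts are
#' Poisson given a logistic monthly infection indicator driven by the `fp`
#' genetic value; sick (non-FP) pods are background Poisson; wet weight is
#' Gaussian around a per-pod mean shifted by the `weight` genetic value.
#'
#' @param truth the `truth` element of [simulate_f1()].
#' @param cfg the [sim_config()] (uses `qtl_spec`, `n_months`,
#'   `trait_noise_sd`, `seed`).
#' @param base_means named list overriding the baseline monthly means
#'   (`pods` 3, `cherelle` 2, `sick` 0.5, `fp_prob` 0.3, `fp_count` 2,
#'   `weight_per_pod` 120 g).
#' @return observation tibble as accepted by [aggregate_observations()].
#' @export
simulate_traits <- function(truth, cfg, base_means = list()) {
  mu <- utils::modifyList(
    list(pods = 3, cherelle = 2, sick = 0.5, fp_prob = 0.3, fp_count = 2,
         weight_per_pod = 120),
    base_means
  )
  g <- genetic_values(truth, cfg$qtl_spec)
  ids <- rownames(truth$true_geno)
  n <- length(ids)
  rng <- substream_rng(cfg$seed, "traits")
  months <- format(seq(as.Date("2003-01-01"), by = "month",
                       length.out = cfg$n_months), "%Y-%m")
  rows <- vector("list", cfg$n_months)
  for (m in seq_len(cfg$n_months)) {
    healthy <- rng_eval(rng, stats::rpois(n, exp(log(mu$pods) + g[, "pods"])))
    cher <- rng_eval(rng, stats::rpois(n, exp(log(mu$cherelle) +
                                                g[, "cherelle"])))
    sick <- rng_eval(rng, stats::rpois(n, mu$sick))
    infected <- rng_eval(rng, stats::rbinom(
      n, 1L, stats::plogis(stats::qlogis(mu$fp_prob) + g[, "fp"])
    ))
    fp <- infected * rng_eval(rng, 1L + stats::rpois(n, mu$fp_count - 1))
    w_mean <- healthy * mu$weight_per_pod * exp(g[, "weight"])
    weight <- pmax(0, rng_eval(rng, stats::rnorm(
      n, w_mean, cfg$trait_noise_sd * mu$weight_per_pod / 4
    )))
    rows[[m]] <- tibble::tibble(
      tree_id = ids, month = months[m], healthy_pods = healthy,
      fp_pods = fp, sick_pods = sick, cherelles_wilted = cher,
      wet_weight = weight
    )
  }
  dplyr::bind_rows(rows)
}
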