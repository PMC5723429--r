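# Monthly field observations per tree: healthy pods, frosty-pod (FP) rot
# pods, other sick pods (FP excluded by definition), wilted cherelles
# (aborted immature fruits) and wet bean weight, with optional annual
# witches'-broom / canker counts carried through unchanged.

#' Aggregate monthly observations per tree
#'
#' Sums each monthly count and the wet weight over the collection window and
#' keeps the observation tallies needed by the probability-type derived
#' traits: the number of observations, the number where pods were present,
#' and the number where at least one FP-infected pod was seen.
#'
#' @param observations tibble with columns `tree_id`, `month` (`"YYYY-MM"`),
#'   `healthy_pods`, `fp_pods`, `sick_pods`, `cherelles_wilted`,
#'   `wet_weight`; optional annual columns (`cankers`, `wb_vegetative`,
#'   `wb_cushion`, `wb_pod`) are summed too when present.
#' @return trait tibble, one row per tree.
#' @export
aggregate_observations <- function(observations) {
  stopifnot(all(c("tree_id", "month", "healthy_pods", "fp_pods", "sick_pods",
                  "cherelles_wilted", "wet_weight") %in% names(observations)))
  dup <- duplicated(observations[, c("tree_id", "month")])
  if (any(dup)) {
    off <- observations[dup, c("tree_id", "month")]
    stop("duplicate (tree, month) records: ",
         paste(sprintf("%s/%s", off$tree_id, off$month), collapse = ", "))
  }
  neg <- c("healthy_pods", "fp_pods", "sick_pods", "cherelles_wilted",
           "wet_weight")
  if (any(as.matrix(observations[neg]) < 0, na.rm = TRUE)) {
    stop("counts and weights must be non-negative")
  }
  annual <- intersect(c("cankers", "wb_vegetative", "wb_cushion", "wb_pod"),
                      names(observations))
  observations |>
    dplyr::group_by(tree_id = .data$tree_id) |>
    dplyr::summarise(
      total_pods = sum(.data$healthy_pods + .data$fp_pods + .data$sick_pods),
      fp_count = sum(.data$fp_pods),
      sick_count = sum(.data$sick_pods),
      cherelle_count = sum(.data$cherelles_wilted),
      fresh_weight = sum(.data$wet_weight),
      n_observations = dplyr::n(),
      n_obs_with_pods = sum(.data$healthy_pods + .data$fp_pods +
                              .data$sick_pods >= 1),
      n_obs_with_fp = sum(.data$fp_pods >= 1),
      dplyr::across(dplyr::all_of(annual), \(x) sum(x, na.rm = TRUE)),
      .groups = "drop"
    )
}

#' Derived yield and disease traits
#'
#' Augments an aggregated trait table with the QTL response ratios:
#' cherelle wilt ratio = cherelles / (cherelles + total pods) — the share of
#' potential yield lost to wilt; percent sick and percent FP pods relative
#' to total pods; probability of monilia = observations with >= 1 FP pod
#' over observations with pods present; and fresh weight per pod. Zero
#' denominators propagate as missing, never as zero — a tree with no pods
#' carries no information about its infection ratios.
#'
#' @param t trait tibble from [aggregate_observations()].
#' @return `t` with columns `cherelle_wilt_ratio`, `pct_sick`, `pct_fp`,
#'   `prob_monilia`, `fresh_weight_per_pod` appended.
#' @export
derived_traits <- function(t) {
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  dplyr::mutate(
    t,
    cherelle_wilt_ratio = safe_div(.data$cherelle_count,
                                   .data$cherelle_count + .data$total_pods),
    pct_sick = safe_div(.data$sick_count, .data$total_pods),
    pct_fp = safe_div(.data$fp_count, .data$total_pods),
    prob_monilia = safe_div(.data$n_obs_with_fp, .data$n_obs_with_pods),
    fresh_weight_per_pod = safe_div(.data$fresh_weight, .data$total_pods)
  )
}
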