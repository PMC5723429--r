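# End-to-end orchestration: simulate -> QC -> pedigree screen / parent
# inference -> traits -> QTL scan, driven by one YAML config, with a JSON
# run manifest recording the config snapshot, seed, stage timings, output
# paths and file digests.

pipeline_schema <- list(
  top = c("seed", "out_dir", "stages", "simulate", "qc", "pedigree",
          "traits", "qtl"),
  simulate = c("n_lg", "markers_per_lg", "lg_lengths_cM", "mother_het",
               "father_het", "n_progeny", "genotyping_error", "missing_rate",
               "off_type_fraction", "qtl", "trait_noise_sd", "n_months"),
  qc = c("gentrain_min", "gencall_min"),
  pedigree = c("off_type_threshold", "infer_father"),
  traits = character(),
  qtl = c("alpha", "cim_iters", "cofactor_window_cM", "trait")
)

validate_config <- function(cfg) {
  check <- function(keys, allowed, where) {
    bad <- setdiff(keys, allowed)
    if (length(bad)) {
      stop(sprintf("config error: unknown key '%s' in %s", bad[[1]], where))
    }
  }
  check(names(cfg), pipeline_schema$top, "top level")
  for (s in c("simulate", "qc", "pedigree", "traits", "qtl")) {
    if (!is.null(cfg[[s]])) check(names(cfg[[s]]), pipeline_schema[[s]], s)
  }
  if (is.null(cfg$seed)) stop("config error: missing required key 'seed'")
  if (is.null(cfg$out_dir)) stop("config error: missing required key 'out_dir'")
  stages <- cfg$stages %||% c("simulate", "qc", "pedigree", "traits", "qtl")
  known <- c("simulate", "qc", "pedigree", "traits", "qtl")
  check(stages, known, "stages")
  if (!"simulate" %in% stages) {
    stop("config error: the pipeline is simulation-driven; ",
         "'stages' must include 'simulate'")
  }
  stages
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the demonstration pipeline from a config file
#'
#' Executes the requested stages in dependency order
#' (simulate -> qc -> pedigree -> traits -> qtl). A stage failure stops
#' downstream stages but preserves the outputs already written. Reruns with
#' the same config and seed reproduce every output byte for byte.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#'   Required keys: `seed`, `out_dir`; optional per-stage blocks `simulate`,
#'   `qc`, `pedigree`, `traits`, `qtl` and a `stages` vector.
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    yaml::read_yaml(config)
  } else {
    config
  }
  stages <- validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  timings <- list()
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    fun()
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }
  emit <- function(df, file) {
    path <- file.path(cfg$out_dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    sc <- cfg$simulate %||% list()
    qtl_spec <- if (!is.null(sc$qtl)) dplyr::bind_rows(sc$qtl) else NULL
    simcfg <- sim_config(
      n_lg = sc$n_lg %||% 10, markers_per_lg = sc$markers_per_lg %||% 50,
      lg_lengths_cM = unlist(sc$lg_lengths_cM %||% 100),
      mother_het = sc$mother_het %||% 0.901,
      father_het = sc$father_het %||% 0.205,
      n_progeny = sc$n_progeny %||% 200,
      genotyping_error = sc$genotyping_error %||% 0,
      missing_rate = sc$missing_rate %||% 0,
      off_type_fraction = sc$off_type_fraction %||% 0,
      qtl_spec = qtl_spec, trait_noise_sd = sc$trait_noise_sd %||% 1,
      n_months = sc$n_months %||% 12, seed = cfg$seed
    )
    parents <- simulate_parents(simcfg)
    sim <- simulate_f1(parents, simcfg)
    state$simcfg <- simcfg
    state$parents <- parents
    state$sim <- sim
    write_genotype_matrix(sim$progeny, file.path(cfg$out_dir, "progeny.tsv"))
    outputs <<- c(outputs, file.path(cfg$out_dir, "progeny.tsv"))
    emit(simcfg$map, "map.tsv")
  })

  if ("qc" %in% stages) run_stage("qc", function() {
    qc <- cfg$qc %||% list()
    filt <- apply_quality_filters(
      state$sim$progeny,
      gentrain_min = qc$gentrain_min %||% 0.4,
      gencall_min = qc$gencall_min %||% 0.2
    )
    state$sim$progeny <- filt$matrix
    emit(filt$report, "qc_report.tsv")
    emit(missing_data_summary(filt$matrix), "missing_summary.tsv")
  })

  if ("pedigree" %in% stages) run_stage("pedigree", function() {
    pd <- cfg$pedigree %||% list()
    mother <- state$parents$mother$geno
    father <- state$parents$father$geno
    keep <- match(locus_ids(state$sim$progeny), state$parents$loci$locus_id)
    mother <- mother[keep]
    father <- father[keep]
    off <- detect_off_types(mother, father, state$sim$progeny,
                            threshold = pd$off_type_threshold %||% 0.03)
    emit(off$rates, "mendelian_rates.tsv")
    emit(off$off_types, "off_types.tsv")
    clean <- gm_subset(state$sim$progeny,
                       samples = !sample_ids(state$sim$progeny) %in%
                         off$off_types$sample_id)
    if (isTRUE(pd$infer_father)) {
      inf <- infer_parent_genome(mother, clean)
      emit(inf$report, "inferred_father.tsv")
      father <- inf$father
    }
    prep <- prepare_mapping_dataset(clean, mother, father)
    emit(prep$report, "mapping_prep_report.tsv")
    state$dataset <- prep$dataset
    state$clean <- clean
    loc_path <- file.path(cfg$out_dir, "population.loc")
    export_joinmap_loc(prep$dataset, "simulated_cp", loc_path)
    outputs <<- c(outputs, loc_path)
  })

  if ("traits" %in% stages) run_stage("traits", function() {
    obs <- simulate_traits(state$sim$truth, state$simcfg)
    traits <- derived_traits(aggregate_observations(obs))
    state$traits <- traits
    emit(obs, "observations.tsv")
    emit(traits, "traits.tsv")
  })

  if ("qtl" %in% stages) run_stage("qtl", function() {
    qt <- cfg$qtl %||% list()
    trait_name <- qt$trait %||% "fresh_weight"
    ds <- state$dataset
    progeny_ids <- rownames(ds$calls)
    y <- state$traits[[trait_name]][match(progeny_ids,
                                          state$traits$tree_id)]
    map <- state$simcfg$map[match(ds$loci$locus_id, state$simcfg$map$marker), ]
    names(map)[names(map) == "marker"] <- "marker"
    meff <- li_ji_meff(ds, lg = map$lg)
    rule <- significance_rule(meff, alpha = qt$alpha %||% 0.05)
    cim <- cim_iterate(y, ds, map, rule,
                       max_iter = qt$cim_iters %||% 2,
                       cofactor_window_cM = qt$cofactor_window_cM %||% 10)
    emit(tidy.qtl_scan(cim$scan), "scan.tsv")
    emit(summarize_qtl(cim$scan, rule, ds), "qtl_summary.tsv")
    emit(rule, "significance_rule.tsv")
    emit(cim$history, "cim_history.tsv")
  })

  manifest <- list(
    config = cfg,
    seed = cfg$seed,
    stages_run = stages,
    timings_sec = timings,
    outputs = outputs,
    digests = as.list(tools::md5sum(outputs))
  )
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
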