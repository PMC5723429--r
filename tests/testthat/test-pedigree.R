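test_that("expected progeny distributions match exhaustive gamete enumeration", {
  for (m in 0:2) for (f in 0:2) {
    p <- expected_progeny_distribution(m, f)
    expect_equal(sum(p), 1)
    expect_equal(p, enumerate_progeny(m, f),
                 info = sprintf("mother %d x father %d", m, f))
  }
  expect_error(expected_progeny_distribution(NA, 1), "non-missing")
})

test_that("segregation typing follows the CP convention", {
  expect_equal(classify_segregation(1L, 0L), "lmxll")
  expect_equal(classify_segregation(1L, 2L), "lmxll")
  expect_equal(classify_segregation(2L, 1L), "nnxnp")
  expect_equal(classify_segregation(1L, 1L), "hkxhk")
  expect_equal(classify_segregation(0L, 0L), "uninformative")
  expect_equal(classify_segregation(0L, 2L), "uninformative")
  expect_error(classify_segregation(NA, 1L), "infer_unknown_parent")
})

test_that("unknown-parent inference reproduces worked chi-square examples", {
  # mother HET, counts 52/101/47 vs 1:2:1 expectation (50, 100, 50)
  res <- infer_unknown_parent(1L, c(52, 101, 47))
  expect_equal(res$best_father, 1L)
  expect_equal(res$chi2_by_candidate[["HET"]],
               (52 - 50)^2 / 50 + (101 - 100)^2 / 100 + (47 - 50)^2 / 50)
  expect_equal(res$chi2_by_candidate[["HET"]], 0.27)
  # mother HOM_REF, all-HET progeny: only HOM_ALT expects pure HET
  res2 <- infer_unknown_parent(0L, c(0, 200, 0))
  expect_equal(res2$best_father, 2L)
  expect_equal(res2$chi2_by_candidate[["HOM_ALT"]], 0)
  # mother HET, 98/102/0: HOM_REF father (1:1, no HOM_ALT class) wins
  res3 <- infer_unknown_parent(1L, c(98, 102, 0))
  expect_equal(res3$best_father, 0L)
  expect_lt(res3$chi2_by_candidate[["HOM_REF"]],
            res3$chi2_by_candidate[["HET"]])
})

test_that("inference is consistent: expected counts return their model exactly", {
  for (m in 0:2) for (f in 0:2) {
    p <- expected_progeny_distribution(m, f)
    res <- infer_unknown_parent(m, 200 * p)
    expect_equal(res$chi2_by_candidate[[f + 1]], 0)
    # the generating father attains the minimum (possibly tied when another
    # model fits the same distribution)
    expect_true(res$chi2_by_candidate[[f + 1]] ==
                  min(res$chi2_by_candidate))
  }
})

test_that("small families are skipped and impossible classes give +Inf", {
  res <- infer_unknown_parent(1L, c(5, 5, 5))
  expect_true(res$skipped)
  # mother HOM_REF x father HOM_REF expects pure HOM_REF; 10% HOM_ALT mass
  # exceeds the 2% tolerance
  res2 <- infer_unknown_parent(0L, c(180, 0, 20))
  expect_identical(res2$chi2_by_candidate[["HOM_REF"]], Inf)
})

test_that("whole-genome father inference recovers truth on clean simulation", {
  cross <- small_cross(seed = 31, n_progeny = 240, markers_per_lg = 40,
                       mother_het = 0.5, father_het = 0.588)
  inf <- infer_parent_genome(cross$parents$mother$geno, cross$sim$progeny)
  usable <- !inf$report$ambiguous & !inf$report$skipped
  expect_equal(mean(inf$father[usable] ==
                      cross$parents$father$geno[usable]), 1)
})

test_that("father recovery stays high under genotyping error", {
  # at 0.5% error the impossible-class tolerance (2% of N) comfortably
  # absorbs miscalls and recovery clears 99%
  cross <- small_cross(seed = 32, n_progeny = 240, markers_per_lg = 40,
                       mother_het = 0.5, father_het = 0.588,
                       genotyping_error = 0.005)
  inf <- infer_parent_genome(cross$parents$mother$geno, cross$sim$progeny)
  usable <- !inf$report$ambiguous & !inf$report$skipped
  expect_gte(mean(inf$father[usable] == cross$parents$father$geno[usable]),
             0.99)
  # at 1% error occasional hom x hom loci overflow the tolerance and lose
  # their true model to +Inf; recovery degrades gracefully, not sharply
  cross2 <- small_cross(seed = 32, n_progeny = 240, markers_per_lg = 40,
                        mother_het = 0.5, father_het = 0.588,
                        genotyping_error = 0.01)
  inf2 <- infer_parent_genome(cross2$parents$mother$geno, cross2$sim$progeny)
  usable2 <- !inf2$report$ambiguous & !inf2$report$skipped
  expect_gte(mean(inf2$father[usable2] ==
                    cross2$parents$father$geno[usable2]), 0.97)
})

test_that("recovery accuracy does not improve as genotyping error grows", {
  acc <- vapply(c(0, 0.02, 0.1, 0.3), function(e) {
    cross <- small_cross(seed = 33, n_progeny = 200, markers_per_lg = 30,
                         mother_het = 0.5, father_het = 0.588,
                         genotyping_error = e)
    inf <- infer_parent_genome(cross$parents$mother$geno, cross$sim$progeny)
    usable <- !inf$report$ambiguous & !inf$report$skipped
    mean(inf$father[usable] == cross$parents$father$geno[usable])
  }, numeric(1))
  expect_true(all(diff(acc) <= 1e-9))
})

test_that("a missing mother call yields a missing inferred father call", {
  cross <- small_cross(seed = 34, n_progeny = 100, markers_per_lg = 10)
  mother <- cross$parents$mother$geno
  mother[5] <- NA
  inf <- infer_parent_genome(mother, cross$sim$progeny)
  expect_true(is.na(inf$father[5]))
  expect_equal(inf$report$reason[5], "mother missing")
})

test_that("Mendelian errors are exactly the zero-probability trio genotypes", {
  expect_equal(mendelian_error_rate(0L, 0L, 1L)$errors, 1) # hom x hom -> het
  expect_equal(mendelian_error_rate(0L, 2L, 0L)$errors, 1) # opposite homs
  for (g in 0:2) expect_equal(mendelian_error_rate(1L, 1L, g)$errors, 0)
  # missing members leave the locus untyped
  r <- mendelian_error_rate(c(0L, NA), c(0L, 0L), c(1L, 1L))
  expect_equal(r$typed, 1)
  r0 <- mendelian_error_rate(NA, 0L, 1L)
  expect_true(is.na(r0$rate))
})

test_that("error-free true trios have zero Mendelian error and no off-types", {
  cross <- small_cross(seed = 35, n_progeny = 150, markers_per_lg = 30)
  ot <- detect_off_types(cross$parents$mother$geno,
                         cross$parents$father$geno, cross$sim$progeny)
  expect_equal(nrow(ot$off_types), 0)
  expect_true(all(ot$rates$rate == 0))
})

test_that("the 3% off-type rule is inclusive and ranks by rate", {
  # construct one progeny at exactly 3% violations over 100 typed loci
  mother <- rep(0L, 100)
  father <- rep(0L, 100)
  good <- rep(0L, 100)
  borderline <- c(rep(1L, 3), rep(0L, 97))
  worse <- c(rep(1L, 10), rep(0L, 90))
  prog <- toy_matrix(rbind(ok = good, edge = borderline, bad = worse))
  ot <- detect_off_types(mother, father, prog)
  expect_identical(ot$off_types$sample_id, c("bad", "edge"))
  expect_equal(ot$off_types$rate, c(0.10, 0.03))
})

test_that("injected unrelated individuals are flagged, true progeny are not", {
  cross <- small_cross(seed = 36, n_progeny = 200, markers_per_lg = 50,
                       genotyping_error = 0.005, off_type_fraction = 0.05)
  ot <- detect_off_types(cross$parents$mother$geno,
                         cross$parents$father$geno, cross$sim$progeny)
  expect_setequal(ot$off_types$sample_id, cross$sim$truth$off_type_ids)
})

test_that("segregation-distortion chi-square matches direct arithmetic", {
  g <- c(rep(0L, 150), rep(1L, 50))
  expect_equal(segregation_distortion_chi2(g, "lmxll"), 50)
  expect_equal(segregation_distortion_chi2(c(rep(0L, 100), rep(1L, 100)),
                                           "lmxll"), 0)
  hk <- c(rep(0L, 50), rep(1L, 100), rep(2L, 50))
  expect_equal(segregation_distortion_chi2(hk, "hkxhk"), 0)
  expect_error(segregation_distortion_chi2(0L, "uninformative"), "informative")
})

test_that("mapping preparation applies every hygiene rule in order", {
  set.seed(44)
  n <- 100
  # ten clean filler loci keep per-individual missingness low so the
  # individual rule does not fire here
  fillers <- replicate(10, sample(0:1, n, TRUE))
  mother <- rep(1L, 17)
  father <- c(rep(0L, 4), c(0L, 0L, 0L, 0L, 1L, 0L, 0L), rep(0L, 6))
  mother[8] <- 0L # mk08 uninformative (both parents homozygous)
  seg_ok <- sample(0:1, n, TRUE)
  calls <- cbind(
    fillers[, 1:4],
    mk05 = seg_ok, # clean lmxll
    mk06 = replace(seg_ok, 1:6, NA), # 6% missing -> dropped (> 5%)
    mk07 = c(rep(0L, 90), rep(1L, 10)), # distorted: chi2 = 64 > 15
    mk08 = rep(0L, n), # uninformative
    mk09 = sample(0:2, n, TRUE), # hkxhk, kept
    mk10 = seg_ok, # duplicate of mk05 -> dropped
    mk11 = replace(seg_ok, 2:6, NA), # 5% missing exactly -> kept
    fillers[, 5:10]
  )
  rownames(calls) <- sprintf("p%03d", seq_len(n))
  prog <- toy_matrix(calls)
  prep <- prepare_mapping_dataset(prog, mother, father)
  kept <- prep$dataset$loci$locus_id
  expect_true(all(c("mk05", "mk09", "mk11") %in% kept))
  rules <- split(prep$report$id, prep$report$rule)
  expect_equal(rules$locus_missing, "mk06")
  expect_equal(rules$distortion_chi2, "mk07")
  expect_equal(rules$uninformative_locus, "mk08")
  expect_true("mk10" %in% rules$duplicate_locus)
})

test_that("chi-square boundary 15 is exclusive for locus removal", {
  expect_equal(segregation_distortion_chi2(c(rep(0L, 75), rep(1L, 45)),
                                           "lmxll"), 7.5)
  # 150/90 over n = 240 gives chi2 = 2 * 30^2 / 120 = 15 exactly
  g <- c(rep(0L, 150), rep(1L, 90))
  expect_equal(segregation_distortion_chi2(g, "lmxll"), 15)
  prog <- toy_matrix(cbind(mk1 = g))
  prep <- prepare_mapping_dataset(prog, 1L, 0L)
  expect_equal(prep$dataset$loci$locus_id, "mk01") # 15.0 retained
})

test_that("individuals with too much missing data or duplicates are removed", {
  set.seed(45)
  calls <- matrix(sample(0:1, 20 * 10, TRUE), 20, 10)
  calls[1, 1:2] <- NA # 20% missing -> dropped
  calls[3, ] <- calls[2, ] # duplicate individual -> dropped
  rownames(calls) <- sprintf("p%02d", 1:20)
  prog <- toy_matrix(calls)
  prep <- prepare_mapping_dataset(prog, rep(1L, 10), rep(0L, 10),
                                  locus_missing_max = 1, chi_max = Inf)
  expect_false("p01" %in% rownames(prep$dataset$calls))
  expect_false("p03" %in% rownames(prep$dataset$calls))
  expect_true("p02" %in% rownames(prep$dataset$calls))
})

test_that("JoinMap export round-trips through its own reader", {
  mother <- c(1L, 0L, 1L, 2L)
  father <- c(0L, 1L, 1L, 1L)
  calls <- rbind(
    p1 = c(0L, 0L, 0L, 1L),
    p2 = c(1L, 1L, 1L, 2L),
    p3 = c(NA, 0L, 2L, 1L)
  )
  ds <- mapping_dataset(toy_matrix(calls), mother, father)
  path <- withr::local_tempfile(fileext = ".loc")
  export_joinmap_loc(ds, "toy_pop", path)
  back <- read_joinmap_loc(path)
  expect_equal(back$name, "toy_pop")
  expect_equal(back$nloc, 4L)
  expect_equal(back$nind, 3L)
  expect_equal(back$loci$segtype, c("lmxll", "nnxnp", "hkxhk", "nnxnp"))
  # token grammar per segregation type, "--" for missing
  expect_equal(back$loci$tokens[[1]], c("ll", "lm", "--"))
  expect_equal(back$loci$tokens[[3]], c("hh", "hk", "kk"))
  expect_equal(back$loci$tokens[[4]], c("np", "nn", "np"))
  side <- read.delim(paste0(path, ".alleles.tsv"))
  expect_equal(nrow(side), 8) # two letters per informative locus
})

test_that("all-missing progeny at a locus export as all '--'", {
  ds <- mapping_dataset(toy_matrix(cbind(mk1 = c(NA_integer_, NA_integer_))),
                        1L, 0L)
  path <- withr::local_tempfile(fileext = ".loc")
  export_joinmap_loc(ds, "toy", path)
  back <- read_joinmap_loc(path)
  expect_equal(back$loci$tokens[[1]], c("--", "--"))
})
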