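fixture_tables <- function() {
  list(t2 = load_fixture("table2_16s"),
       t4 = load_fixture("table4_coi_adults"),
       t5 = load_fixture("table5_coi_families_tissues"))
}

test_that("NUMT hypotheses are rejected by the published family and tissue data", {
  tb <- fixture_tables()
  v2 <- evaluate_numt(tb$t2)
  expect_identical(v2$homozygous$status, "rejected")
  # the M26 brood drives it: eggs homoplasmic and only one clone combination
  expect_true(any(v2$homozygous$evidence$rule == "homoplasmic_offspring"))
  expect_true(any(v2$homozygous$evidence$rule == "clone_combinations"))
  expect_true(any(grepl("MbraAG-M26", v2$homozygous$evidence$individuals)))

  # tissue discordance (MbraAG-4D2V and others) rejects both NUMT forms
  v5 <- evaluate_numt(tb$t5)
  expect_identical(v5$homozygous$status, "rejected")
  expect_identical(v5$heterozygous$status, "rejected")
  disc <- v5$heterozygous$evidence
  expect_true(any(grepl("MbraAG-4D2V", disc$individuals)))

  # no pedigree/tissue structure at all -> insufficient data
  lone <- percent_table(list(prow("a", "adult", 1, "T", "C", 80, 20,
                                  sex = "female")))
  vl <- evaluate_numt(lone)
  expect_identical(vl$homozygous$status, "insufficient_data")
})

test_that("simulated NUMT families do not reject the generating NUMT form", {
  fam <- simulate_family(mat_mix(0), tiny_config("numt_homozygous",
                                                 n_eggs = 20L, seed = 31L))
  calls <- call_family(fam, positions = tiny_sites())
  v <- evaluate_numt(calls)
  expect_identical(v$homozygous$status, "not_rejected")
  expect_identical(v$heterozygous$status, "not_rejected")
})

test_that("duplication is rejected by homoplasmic eggs of double-peak mothers", {
  tb <- fixture_tables()
  v <- evaluate_duplication(tb$t2)
  expect_identical(v$status, "rejected")
  expect_true(any(grepl("MbraAG-M26", v$evidence$individuals)))

  fam <- simulate_family(mat_mix(0), tiny_config("mito_duplication", seed = 13L))
  calls <- call_family(fam, positions = tiny_sites())
  expect_identical(evaluate_duplication(calls)$status, "not_rejected")

  # homoplasmic mother everywhere: nothing to test against
  fam0 <- simulate_family(mat_mix(0), tiny_config("maternal_strict", seed = 14L))
  calls0 <- call_family(fam0, positions = tiny_sites())
  expect_identical(evaluate_duplication(calls0)$status, "insufficient_data")

  # cross-locus note: individuals double-peaked at one locus only
  all_t <- combine_call_tables(tb$t2, tb$t4, tb$t5)
  vall <- evaluate_duplication(all_t)
  expect_match(vall$note, "one locus only")
})

test_that("DUI is rejected when both sexes are heteroplasmic", {
  t4 <- load_fixture("table4_coi_adults")
  v <- evaluate_dui(t4)
  expect_identical(v$status, "rejected")
  expect_match(v$evidence$observed, "4 heteroplasmic males, 12 heteroplasmic females")
  expect_match(v$note, "Fisher")

  males_only <- percent_table(list(
    prow("m1", "adult", 1, "T", "C", 80, 20, sex = "male"),
    prow("f1", "adult", 1, "T", "C", 100, 0, sex = "female")))
  expect_identical(evaluate_dui(males_only)$status, "not_rejected")

  no_het <- percent_table(list(
    prow("m1", "adult", 1, "T", "C", 100, 0, sex = "male"),
    prow("f1", "adult", 1, "T", "C", 100, 0, sex = "female")))
  expect_identical(evaluate_dui(no_het)$status, "insufficient_data")

  single_sex <- percent_table(list(
    prow("f1", "adult", 1, "T", "C", 80, 20, sex = "female")))
  expect_identical(evaluate_dui(single_sex)$status, "insufficient_data")
})

test_that("de novo mutation cannot explain the observed incidence", {
  # binomial oracle computed here, independently of the evaluator internals
  mu <- 1.63e-7; n_sites <- 4; n <- 83; obs <- 22
  p_oracle <- 1 - (1 - mu)^n_sites
  expect_equal(p_oracle, 6.52e-7, tolerance = 1e-3)
  expect_gt(obs, qbinom(0.999, n, p_oracle))

  v <- evaluate_de_novo(obs, n, n_sites, mu)
  expect_identical(v$status, "rejected")
  expect_identical(evaluate_de_novo(0, n, n_sites, mu)$status, "not_rejected")
  expect_identical(evaluate_de_novo(obs, n, n_sites, 0.1)$status, "not_rejected")
  expect_error(evaluate_de_novo(1, 10, 4, 0), "positive")
})

test_that("the combined published tables classify as paternal leakage", {
  tb <- fixture_tables()
  cls <- classify_dataset(combine_call_tables(tb$t2, tb$t4, tb$t5))
  st <- vapply(cls$verdicts, `[[`, "", "status")
  expect_identical(unname(st[c("numt_homozygous", "numt_heterozygous",
                               "mito_duplication", "dui", "de_novo")]),
                   rep("rejected", 5))
  expect_identical(cls$final_call, "paternal_leakage")
  expect_true(isTRUE(cls$verdicts$recombination$non_primary))
  # the egg heteroplasmic under a double-peak-free mother is recorded, not resolved
  expect_true(any(grepl("MbraAG-2DN-1", cls$maternal_undetected)))
})

test_that("verdicts are monotone: more evidence can only add rejections", {
  tb <- fixture_tables()
  partial <- classify_dataset(tb$t2)
  full <- classify_dataset(combine_call_tables(tb$t2, tb$t4, tb$t5))
  rejected <- function(cls)
    names(cls$verdicts)[vapply(cls$verdicts, function(v)
      v$status == "rejected", logical(1))]
  expect_true(all(rejected(partial) %in% rejected(full)))

  partial4 <- classify_dataset(tb$t4)
  expect_true(all(rejected(partial4) %in% rejected(full)))
})

test_that("raising the detection floor never adds homoplasmic-offspring rejections", {
  tb <- fixture_tables()
  tab <- combine_call_tables(tb$t2, tb$t5)
  n_dropout_rejections <- function(floor) {
    det <- detection_model(detection_floor = floor)
    v <- evaluate_numt(tab, det)
    d <- evaluate_duplication(tab, det)
    sum(v$homozygous$evidence$rule == "homoplasmic_offspring") +
      sum(d$evidence$rule == "homoplasmic_offspring")
  }
  counts <- vapply(c(0.05, 0.1, 0.2, 0.4), n_dropout_rejections, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # with the floor above the predicted NUMT fraction the guard disarms
  det_hi <- detection_model(0.4, 0.02)
  v_hi <- evaluate_numt(tb$t2, det_hi)
  expect_false(any(v_hi$homozygous$evidence$rule == "homoplasmic_offspring"))
})

test_that("a quiet strict-maternal dataset yields no-heteroplasmy", {
  fam <- simulate_family(mat_mix(0), tiny_config("maternal_strict", seed = 77L))
  calls <- call_family(fam, positions = tiny_sites())
  cls <- classify_dataset(calls)
  expect_identical(cls$final_call, "no_heteroplasmy_detected")
})
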