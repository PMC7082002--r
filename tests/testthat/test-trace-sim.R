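test_that("noiseless traces put all signal in the generating channels", {
  ts <- noiseless_trace(mat_mix(0))
  for (rd in c("forward", "reverse")) {
    h <- ts$reads[[rd]]$heights
    amp <- ts$reads[[rd]]$amplitude
    expect_equal(rowSums(h), rep(amp, nrow(h)))           # conservation
    expect_true(all(rowSums(h > 0) == 1))                 # one channel/pos
  }

  ts <- noiseless_trace(mixture_state(c(MAT = 0.7, ALT = 0.3)))
  for (rd in c("forward", "reverse")) {
    h <- ts$reads[[rd]]$heights
    expect_equal(unname(h[5, "C"] / h[5, "T"]), 7 / 3)    # exact 7:3
    expect_equal(unname(h[8, "T"] / h[8, "A"]), 7 / 3)
    expect_equal(rowSums(h), rep(ts$reads[[rd]]$amplitude, nrow(h)))
  }
})

test_that("noisy trace heights stay nonnegative and conserve signal in expectation", {
  ts <- simulate_trace_set(tiny_haps(), mat_mix(0.3), seed = 7L)
  for (rd in ts$reads) expect_true(all(rd$heights >= 0))
  # lognormal mean exp(sd^2/2) inflates totals slightly; just sanity-band it
  tot <- mean(rowSums(ts$reads$forward$heights))
  expect_gt(tot, 800); expect_lt(tot, 1400)
})

test_that("trace simulation is bit-identical under a fixed seed", {
  a <- simulate_trace_set(tiny_haps(), mat_mix(0.3), seed = 42L)
  b <- simulate_trace_set(tiny_haps(), mat_mix(0.3), seed = 42L)
  expect_identical(a, b)
  fam1 <- simulate_family(mat_mix(0), tiny_config("paternal_leakage", seed = 9L))
  fam2 <- simulate_family(mat_mix(0), tiny_config("paternal_leakage", seed = 9L))
  expect_identical(fam1, fam2)
})

test_that("trace simulation rejects invalid input", {
  expect_error(haplotype_set(H1 = "ACGT", H2 = "ACG"), "equal length")
  expect_error(haplotype_set(H1 = "ACGU"), "alphabet")
  expect_error(mixture_state(c(A = 0.5, B = 0.4)), "sum to 1")
  expect_error(mixture_state(numeric(0)), "empty")
  expect_error(simulate_trace_set(tiny_haps(), mat_mix(0), amplitude_f = 0),
               "positive")
})

test_that("family simulation follows the binomial bottleneck model", {
  # homoplasmic mother, strict maternal: every egg homoplasmic maternal
  fam <- simulate_family(mat_mix(0), tiny_config("maternal_strict", seed = 3L))
  expect_true(all(fam$truth$egg_fractions == 0))
  calls <- call_family(fam, positions = tiny_sites())
  eggs <- calls[calls$role == "egg", ]
  expect_false(any(eggs$heteroplasmic))
  expect_true(all(eggs$major_base[eggs$position == 5] == "C"))

  # bottleneck of one unit: eggs fix one haplotype or the other
  fam1 <- simulate_family(mat_mix(0.4),
                          tiny_config("maternal_strict", bottleneck_N = 1L,
                                      seed = 11L, n_eggs = 50L))
  expect_true(all(fam1$truth$egg_fractions %in% c(0, 1)))

  # leakage Monte-Carlo: mean egg fraction ~ lambda for a homoplasmic mother
  cfg <- tiny_config("paternal_leakage", leakage_rate = 0.2,
                     bottleneck_N = 200L, n_eggs = 1000L, seed = 5L)
  fam2 <- simulate_family(mat_mix(0), cfg)
  expect_equal(fam2$truth$zygote_fraction, 0.2)
  se <- sqrt(0.2 * 0.8 / 200) / sqrt(1000)
  expect_lt(abs(mean(fam2$truth$egg_fractions) - 0.2), 3 * se)
})

test_that("leakage without a paternal haplotype is a configuration error", {
  haps <- haplotype_set(MAT = "ACGACTGTACGA")
  expect_error(scenario_config("paternal_leakage", haplotypes = haps,
                               maternal_id = "MAT", paternal_id = NULL,
                               leakage_rate = 0.2),
               "paternal")
  expect_error(tiny_config("maternal_strict", leakage_rate = 0.1),
               "paternal_leakage")
})

test_that("tissue panels drift except for the Mendelian NUMT signal", {
  # huge drift N: all tissues glued to the zygote fraction
  pan <- simulate_tissue_panel(mat_mix(0.3), paste0("t", 1:6),
                               tiny_config("maternal_strict",
                                           tissue_drift_N = 1000000L, seed = 2L))
  expect_true(all(abs(pan$truth$tissue_fractions - 0.3) < 0.01))

  # homozygous NUMT: identical secondary fraction in every tissue
  cfgn <- tiny_config("numt_homozygous", noise_sd = 0, baseline_sd = 0, seed = 4L)
  pann <- simulate_tissue_panel(mat_mix(0), c("gonad", "gill", "muscle"), cfgn)
  fracs <- vapply(pann$tissues, function(ts) {
    calls <- call_trace_set(ts, positions = tiny_sites())
    calls$prop_minor[1]
  }, numeric(1))
  expect_equal(unname(fracs), rep(1 / 3, 3), tolerance = 1e-12)

  # binomial drift variance at N = 50
  cfgd <- tiny_config("maternal_strict", tissue_drift_N = 50L, seed = 8L)
  pand <- simulate_tissue_panel(mat_mix(0.3), paste0("t", 1:10), cfgd)
  v <- var(pand$truth$tissue_fractions)
  expected <- 0.3 * 0.7 / 50
  se_v <- expected * sqrt(2 / 9)
  expect_lt(abs(v - expected), 3 * se_v)
  expect_error(simulate_tissue_panel(mat_mix(0.3), character(0),
                                     tiny_config("maternal_strict")),
               "nonempty")
})

test_that("clone sampling is categorical over the molecule pool", {
  expect_identical(unique(simulate_clones(c(AAA = 1), 5, seed = 1L)), "AAA")
  cl <- simulate_clones(c(`T-A` = 1, `C-T` = 0), 20, seed = 2L)
  expect_false(any(cl == "C-T"))
  expect_error(simulate_clones(numeric(0), 3), "empty")

  pool <- c(`T-A` = 0.7, `C-T` = 0.2, `T-T` = 0.1)
  draws <- unlist(lapply(1:200, function(s) simulate_clones(pool, 9, seed = s)))
  expect_true(all(draws %in% names(pool)))
  freq <- table(draws) / length(draws)
  expect_equal(as.numeric(freq[names(pool)]), unname(pool), tolerance = 0.05)
})

test_that("trace CSV round-trips", {
  ts <- simulate_trace_set(tiny_haps(), mat_mix(0.3), seed = 6L, specimen = "sp1")
  f <- tempfile(fileext = ".csv")
  write_trace_csv(ts, f)
  back <- read_trace_csv(f)[["sp1"]]
  expect_equal(back$reads$forward$heights, ts$reads$forward$heights,
               tolerance = 1e-6)
  calls_a <- call_trace_set(ts, positions = tiny_sites())
  calls_b <- call_trace_set(back, positions = tiny_sites())
  expect_equal(calls_a$prop_minor, calls_b$prop_minor, tolerance = 1e-6)
})
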