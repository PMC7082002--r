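## Labelled synthetic data: trace sets, families, tissue panels, clone pools.

#' Construct a set of aligned haplotype sequences
#'
#' @param ... named nucleotide strings (A/C/G/T), all of equal length;
#'   positions are 1-based.
#' @return a named character vector of class `haplotype_set`.
#' @examples
#' haplotype_set(H1 = "ACGT", H2 = "ACTT")
#' @export
haplotype_set <- function(...) {
  seqs <- toupper(unlist(list(...)))
  if (length(seqs) == 0L || is.null(names(seqs)) || any(names(seqs) == ""))
    stop("haplotypes must be named, nonempty sequences")
  if (any(nchar(seqs) == 0L)) stop("empty haplotype sequence")
  if (length(unique(nchar(seqs))) != 1L)
    stop("all haplotypes in a set must have equal length")
  if (any(grepl("[^ACGT]", seqs)))
    stop("haplotype alphabet restricted to A/C/G/T")
  structure(seqs, class = "haplotype_set")
}

#' Construct a mixture state over haplotypes
#'
#' @param fractions named numeric vector, haplotype id -> fraction; must be
#'   nonnegative and sum to 1 within 1e-9.
#' @return named numeric of class `mixture_state`.
#' @export
mixture_state <- function(fractions) {
  if (length(fractions) == 0L) stop("empty mixture")
  if (is.null(names(fractions)) || any(names(fractions) == ""))
    stop("mixture fractions must be named by haplotype id")
  if (any(fractions < 0)) stop("mixture fractions must be nonnegative")
  if (abs(sum(fractions) - 1) > 1e-9) stop("mixture fractions must sum to 1")
  structure(as.numeric(setNames(fractions, names(fractions))),
            names = names(fractions), class = "mixture_state")
}

SCENARIOS <- c("maternal_strict", "paternal_leakage", "numt_homozygous",
               "numt_heterozygous", "mito_duplication", "dui")

#' Scenario configuration for family / tissue-panel simulation
#'
#' Bundles the inheritance scenario with the haplotype set and the trace
#' parameters.  Defaults are chosen so that simulated minor fractions fall
#' in the 6--45% range observed in real broods.
#'
#' @param scenario one of `maternal_strict`, `paternal_leakage`,
#'   `numt_homozygous`, `numt_heterozygous`, `mito_duplication`, `dui`.
#' @param haplotypes a [haplotype_set()]; needs at least the maternal
#'   haplotype plus one alternative (paternal / NUMT / duplicated copy).
#' @param maternal_id,paternal_id haplotype ids.  `paternal_id` is required
#'   whenever `leakage_rate > 0` and for the `dui`, NUMT and duplication
#'   scenarios (it doubles as the alternative sequence carried by the
#'   nuclear insert or duplicated copy).
#' @param leakage_rate paternal leakage fraction lambda in \[0,1\]; must be 0
#'   except under `paternal_leakage`.
#' @param bottleneck_N germline bottleneck size (segregating units per egg).
#' @param tissue_drift_N drift units for somatic tissue divergence.
#' @param numt_signal_ratio fraction of total trace signal contributed by
#'   the nuclear copy in NUMT scenarios, in (0,1).  The default 1/3 means
#'   the nuclear signal is half as strong as the mitochondrial one.
#' @param duplication_ratio apparent minor fraction produced by a
#'   mitochondrial duplication (0.5 = one diverged extra copy per genome).
#' @param dui_gonad_m_fraction fraction of male (M-type) genome in the male
#'   gonad under doubly uniparental inheritance.
#' @param n_eggs number of eggs per simulated brood.
#' @param amplitude_f,amplitude_r forward/reverse read amplitudes
#'   (arbitrary fluorescence units; unequal by default, as PCR yield
#'   differs between primers).
#' @param noise_sd sd of the multiplicative lognormal peak-height noise.
#' @param baseline_sd sd of the half-normal baseline noise, as a fraction
#'   of the read amplitude (default 0.025, i.e. mean baseline ~2% of
#'   amplitude).
#' @param seed master integer seed; all draws descend from it via
#'   [substream_seed()].
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(scenario,
                            haplotypes = default_haplotypes(),
                            maternal_id = names(haplotypes)[1],
                            paternal_id = if (length(haplotypes) > 1) names(haplotypes)[2] else NULL,
                            leakage_rate = if (identical(scenario, "paternal_leakage")) 0.2 else 0,
                            bottleneck_N = 200L,
                            tissue_drift_N = 200L,
                            numt_signal_ratio = 1 / 3,
                            duplication_ratio = 0.5,
                            dui_gonad_m_fraction = 0.8,
                            n_eggs = 10L,
                            amplitude_f = 1000,
                            amplitude_r = 700,
                            noise_sd = 0.15,
                            baseline_sd = 0.025,
                            seed = 1L) {
  scenario <- match.arg(scenario, SCENARIOS)
  stopifnot(inherits(haplotypes, "haplotype_set"))
  if (!maternal_id %in% names(haplotypes)) stop("unknown maternal_id")
  if (!is.null(paternal_id) && !paternal_id %in% names(haplotypes))
    stop("unknown paternal_id")
  if (leakage_rate < 0 || leakage_rate > 1) stop("leakage_rate must be in [0,1]")
  if (leakage_rate > 0 && scenario != "paternal_leakage")
    stop("leakage_rate > 0 is only meaningful under the paternal_leakage scenario")
  if (leakage_rate > 0 && is.null(paternal_id))
    stop("paternal_leakage with leakage_rate > 0 requires a paternal haplotype")
  if (scenario %in% c("numt_homozygous", "numt_heterozygous", "mito_duplication", "dui") &&
      is.null(paternal_id))
    stop("scenario ", scenario, " requires an alternative haplotype (paternal_id)")
  if (numt_signal_ratio <= 0 || numt_signal_ratio >= 1)
    stop("numt_signal_ratio must be in (0,1)")
  if (bottleneck_N < 1 || tissue_drift_N < 1) stop("drift sizes must be positive")
  if (n_eggs < 1) stop("n_eggs must be >= 1")
  structure(list(scenario = scenario, haplotypes = haplotypes,
                 maternal_id = maternal_id, paternal_id = paternal_id,
                 leakage_rate = leakage_rate,
                 bottleneck_N = as.integer(bottleneck_N),
                 tissue_drift_N = as.integer(tissue_drift_N),
                 numt_signal_ratio = numt_signal_ratio,
                 duplication_ratio = duplication_ratio,
                 dui_gonad_m_fraction = dui_gonad_m_fraction,
                 n_eggs = as.integer(n_eggs),
                 amplitude_f = amplitude_f, amplitude_r = amplitude_r,
                 noise_sd = noise_sd, baseline_sd = baseline_sd,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Default synthetic haplotype pair
#'
#' Two synthetic 600 bp amplicon haplotypes differing at positions 365 and
#' 580 (a T/C and a T/A polymorphism), mimicking the site structure of a
#' ribosomal mtDNA fragment.  The background sequence is a fixed
#' pseudo-random draw, identical on every call.
#'
#' @param length amplicon length.
#' @return a [haplotype_set()] with haplotypes `MAT` (C365, T580) and
#'   `ALT` (T365, A580).
#' @export
default_haplotypes <- function(length = 600L) {
  base <- with_stream(20200319L, sample(BASES, length, replace = TRUE))
  mat <- base; mat[365] <- "C"; mat[580] <- "T"
  alt <- base; alt[365] <- "T"; alt[580] <- "A"
  haplotype_set(MAT = paste(mat, collapse = ""),
                ALT = paste(alt, collapse = ""))
}

#' Positions at which a haplotype set varies
#' @param haplotypes a [haplotype_set()].
#' @return integer vector of 1-based positions.
#' @export
variable_positions <- function(haplotypes) {
  m <- do.call(rbind, strsplit(unclass(haplotypes), ""))
  which(apply(m, 2, function(col) length(unique(col)) > 1))
}

#' Simulate one specimen's paired-read trace set
#'
#' For each position i and channel b, each read's height is
#' `amplitude_read * (sum_k fraction_k * [seq_k(i) == b]) * exp(N(0, noise_sd))`
#' plus half-normal baseline noise `|N(0, baseline_sd * amplitude)|`.
#'
#' @param haplotypes a [haplotype_set()].
#' @param mix a [mixture_state()] over (a subset of) the haplotype ids.
#' @param amplitude_f,amplitude_r positive read amplitudes.
#' @param noise_sd,baseline_sd nonnegative noise parameters; `baseline_sd`
#'   is relative to the read amplitude.
#' @param seed integer seed (local to this call).
#' @param specimen specimen label stored in the result.
#' @return list of class `trace_set` with elements `specimen`, `positions`
#'   and `reads` (forward/reverse, each with a positions x 4 `heights`
#'   matrix, `amplitude`, and `baseline_level`, the expected baseline
#'   height used by the caller's baseline criterion).
#' @export
simulate_trace_set <- function(haplotypes, mix, amplitude_f = 1000,
                               amplitude_r = 700, noise_sd = 0.15,
                               baseline_sd = 0.025, seed = 1L,
                               specimen = "sim") {
  stopifnot(inherits(haplotypes, "haplotype_set"))
  if (!inherits(mix, "mixture_state")) mix <- mixture_state(mix)
  if (!all(names(mix) %in% names(haplotypes)))
    stop("mixture refers to haplotypes absent from the set")
  if (amplitude_f <= 0 || amplitude_r <= 0) stop("amplitudes must be positive")
  if (noise_sd < 0 || baseline_sd < 0) stop("noise parameters must be nonnegative")

  seqs <- strsplit(unclass(haplotypes)[names(mix)], "")
  L <- length(seqs[[1]])
  # expected per-channel signal fraction at each position
  frac <- matrix(0, nrow = L, ncol = 4, dimnames = list(NULL, BASES))
  for (k in seq_along(seqs)) {
    idx <- cbind(seq_len(L), match(seqs[[k]], BASES))
    frac[idx] <- frac[idx] + mix[[k]]
  }
  make_read <- function(amplitude, sub) {
    with_stream(sub, {
      noise <- if (noise_sd > 0)
        matrix(exp(rnorm(L * 4, 0, noise_sd)), L, 4) else 1
      base <- if (baseline_sd > 0)
        matrix(abs(rnorm(L * 4, 0, baseline_sd * amplitude)), L, 4) else 0
      h <- amplitude * frac * noise + base
      dimnames(h) <- list(NULL, BASES)
      list(heights = h, amplitude = amplitude,
           baseline_level = baseline_sd * amplitude * sqrt(2 / pi))
    })
  }
  structure(list(specimen = specimen, positions = seq_len(L),
                 reads = list(forward = make_read(amplitude_f, substream_seed(seed, 1L)),
                              reverse = make_read(amplitude_r, substream_seed(seed, 2L)))),
            class = "trace_set")
}

# Apparent haplotype mixture shown by a specimen's trace, given its latent
# mitochondrial minor fraction f, a NUMT/duplication carrier flag, and the
# scenario.  Returns a mixture over c(maternal, alternative).
apparent_mix <- function(config, f, carrier = TRUE) {
  r <- switch(config$scenario,
    numt_homozygous = ,
    numt_heterozygous = if (carrier) config$numt_signal_ratio else 0,
    mito_duplication = config$duplication_ratio,
    0)
  # nuclear/duplicated signal overlays the mitochondrial mixture
  alt <- (1 - r) * f + r
  fr <- c(1 - alt, alt)
  names(fr) <- c(config$maternal_id,
                 if (!is.null(config$paternal_id)) config$paternal_id else config$maternal_id)
  if (names(fr)[1] == names(fr)[2]) return(mixture_state(setNames(1, names(fr)[1])))
  mixture_state(fr[fr > 0 | names(fr) == config$maternal_id])
}

sim_specimen <- function(config, mix, seed, specimen) {
  simulate_trace_set(config$haplotypes, mix,
                     amplitude_f = config$amplitude_f,
                     amplitude_r = config$amplitude_r,
                     noise_sd = config$noise_sd,
                     baseline_sd = config$baseline_sd,
                     seed = seed, specimen = specimen)
}

#' Simulate a mother and her brood under an inheritance scenario
#'
#' Egg minor fractions are drawn as `Binomial(bottleneck_N, p0) /
#' bottleneck_N` where the zygote fraction `p0 = (1 - lambda) * maternal +
#' lambda` under paternal leakage and `p0 = maternal` otherwise.  NUMT
#' scenarios add a constant nuclear signal (Mendelian: all eggs under
#' `numt_homozygous`, each egg with probability 1/2 under
#' `numt_heterozygous`); a mitochondrial duplication adds a constant
#' duplicated-copy signal to every specimen.  Under `dui` the brood is
#' homoplasmic maternal and a male (father) record with a heteroplasmic
#' gonad trace is included.
#'
#' @param mother_mix [mixture_state()] of the mother's mitochondrial pool
#'   (over `maternal_id` and optionally `paternal_id`).
#' @param config a [scenario_config()].
#' @return list of class `sim_family`: `mother`, `eggs` (list of
#'   `trace_set`), optional `father`, and `truth` (scenario label plus all
#'   latent fractions and carrier flags).
#' @export
simulate_family <- function(mother_mix, config) {
  stopifnot(inherits(config, "scenario_config"))
  if (!inherits(mother_mix, "mixture_state")) mother_mix <- mixture_state(mother_mix)
  sc <- config$scenario
  alt_id <- config$paternal_id
  mat_minor <- if (!is.null(alt_id) && alt_id %in% names(mother_mix))
    mother_mix[[alt_id]] else 0

  p0 <- switch(sc,
    paternal_leakage = (1 - config$leakage_rate) * mat_minor + config$leakage_rate,
    dui = 0,           # sperm M genome not retained in the brood soma
    mat_minor)

  n <- config$n_eggs
  egg_f <- with_stream(substream_seed(config$seed, 100L),
                       rbinom(n, config$bottleneck_N, p0) / config$bottleneck_N)
  carrier <- rep(TRUE, n)
  if (sc == "numt_heterozygous")
    carrier <- with_stream(substream_seed(config$seed, 101L),
                           runif(n) < 0.5)

  mother_carrier <- TRUE
  mother <- sim_specimen(config, apparent_mix(config, mat_minor, mother_carrier),
                         substream_seed(config$seed, 200L), "mother")
  eggs <- lapply(seq_len(n), function(i) {
    sim_specimen(config, apparent_mix(config, egg_f[i], carrier[i]),
                 substream_seed(config$seed, 200L + i), paste0("egg-", i))
  })
  father <- NULL
  if (sc == "dui") {
    g <- config$dui_gonad_m_fraction
    fmix <- mixture_state(setNames(c(1 - g, g), c(config$maternal_id, alt_id)))
    father <- sim_specimen(config, fmix,
                           substream_seed(config$seed, 300L), "father")
  }
  structure(list(mother = mother, eggs = eggs, father = father,
                 truth = list(scenario = sc, zygote_fraction = p0,
                              maternal_minor = mat_minor,
                              egg_fractions = egg_f,
                              numt_carrier = if (sc %in% c("numt_homozygous", "numt_heterozygous")) carrier else NULL,
                              config = config[c("leakage_rate", "bottleneck_N",
                                                "numt_signal_ratio", "n_eggs", "seed")])),
            class = "sim_family")
}

#' Simulate trace sets for several tissues of one individual
#'
#' Each tissue's mitochondrial minor fraction is an independent binomial
#' drift `Binomial(tissue_drift_N, p) / tissue_drift_N` of the zygote
#' fraction.  Under NUMT scenarios every tissue carries the identical
#' nuclear signal (Mendelian, no drift); a duplication likewise shows the
#' same ratio everywhere.
#'
#' @param individual_mix [mixture_state()] giving the zygote mitochondrial
#'   mixture of the individual.
#' @param tissues nonempty character vector of tissue labels.
#' @param config a [scenario_config()].
#' @return list of class `sim_panel`: `tissues` (named list of
#'   `trace_set`) and `truth`.
#' @export
simulate_tissue_panel <- function(individual_mix, tissues, config) {
  stopifnot(inherits(config, "scenario_config"))
  if (length(tissues) == 0L) stop("tissue list must be nonempty")
  if (!inherits(individual_mix, "mixture_state"))
    individual_mix <- mixture_state(individual_mix)
  alt_id <- config$paternal_id
  p <- if (!is.null(alt_id) && alt_id %in% names(individual_mix))
    individual_mix[[alt_id]] else 0
  nt <- length(tissues)
  f <- with_stream(substream_seed(config$seed, 400L),
                   rbinom(nt, config$tissue_drift_N, p) / config$tissue_drift_N)
  # apparent_mix overlays the cell-universal nuclear / duplicated signal
  # (no drift of that component); only the mitochondrial fraction f drifts
  traces <- lapply(seq_len(nt), function(i)
    sim_specimen(config, apparent_mix(config, f[i], TRUE),
                 substream_seed(config$seed, 400L + i), tissues[i]))
  names(traces) <- tissues
  structure(list(tissues = traces,
                 truth = list(scenario = config$scenario, zygote_fraction = p,
                              tissue_fractions = setNames(f, tissues))),
            class = "sim_panel")
}

#' Draw single-molecule clone sequences from a molecule pool
#'
#' Each clone is one molecule drawn with probability proportional to its
#' pool fraction; clones are full unambiguous sequences (no double peaks).
#'
#' @param pool named numeric vector: molecule sequence (or type label) ->
#'   pool fraction; fractions need not sum to 1 (they are normalized).
#' @param n_clones number of clones to draw.
#' @param seed integer seed.
#' @return character vector of length `n_clones`.
#' @export
simulate_clones <- function(pool, n_clones, seed = 1L) {
  if (length(pool) == 0L || sum(pool) <= 0) stop("empty molecule pool")
  if (n_clones < 1) stop("n_clones must be >= 1")
  with_stream(seed,
              sample(names(pool), n_clones, replace = TRUE, prob = pool))
}

#' Serialize a trace set to the long CSV dialect
#'
#' Columns: specimen, read, position, A, C, G, T, baseline.
#'
#' @param ts a `trace_set` (or list of them).
#' @param path output CSV path.
#' @return the written data frame, invisibly.
#' @export
write_trace_csv <- function(ts, path) {
  if (inherits(ts, "trace_set")) ts <- list(ts)
  rows <- lapply(ts, function(t) {
    do.call(rbind, lapply(names(t$reads), function(rd) {
      h <- t$reads[[rd]]$heights
      data.frame(specimen = t$specimen, read = rd,
                 position = t$positions,
                 A = h[, "A"], C = h[, "C"], G = h[, "G"], T = h[, "T"],
                 baseline = t$reads[[rd]]$baseline_level)
    }))
  })
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Read a trace CSV back into trace sets
#' @param path CSV written by [write_trace_csv()].
#' @return named list of `trace_set`.
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "read", "position", "A", "C", "G", "T", "baseline")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$specimen), function(d) {
    reads <- lapply(split(d, d$read), function(r) {
      r <- r[order(r$position), ]
      h <- as.matrix(r[, BASES])
      dimnames(h) <- list(NULL, BASES)
      list(heights = h, amplitude = max(rowSums(h)),
           baseline_level = r$baseline[1])
    })
    structure(list(specimen = d$specimen[1],
                   positions = sort(unique(d$position)),
                   reads = reads[intersect(c("forward", "reverse"), names(reads))]),
              class = "trace_set")
  })
  out
}
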