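# Small synthetic building blocks shared across test files.

# 12 bp haplotype pair differing at positions 5 (T/C) and 8 (T/A); short on
# purpose so family/panel simulations stay cheap.
tiny_haps <- function() {
  haplotype_set(MAT = "ACGACTGTACGA",
                ALT = "ACGATTGAACGA")
}
tiny_sites <- function() variable_positions(tiny_haps())  # c(5, 8)

tiny_config <- function(scenario, seed = 1L, ...) {
  scenario_config(scenario, haplotypes = tiny_haps(),
                  maternal_id = "MAT", paternal_id = "ALT",
                  seed = seed, ...)
}

# mother mixture with a given minor (ALT) fraction
mat_mix <- function(minor = 0) {
  if (minor > 0) mixture_state(c(MAT = 1 - minor, ALT = minor))
  else mixture_state(c(MAT = 1))
}

# noiseless trace for one mixture
noiseless_trace <- function(mix, specimen = "s", amp_f = 1000, amp_r = 700) {
  simulate_trace_set(tiny_haps(), mix, amplitude_f = amp_f,
                     amplitude_r = amp_r, noise_sd = 0, baseline_sd = 0,
                     seed = 1L, specimen = specimen)
}

# minimal percent-dialect data frame -> call_table via a temp file
percent_table <- function(rows) {
  df <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE, quote = FALSE)
  read_percent_table(f)
}

prow <- function(specimen, role, position, base1, base2, pct1, pct2,
                 mother_id = "", sex = "", tissue = "", individual = specimen,
                 population = "sim", locus = "L") {
  list(specimen = specimen, individual = individual, role = role, sex = sex,
       tissue = tissue, mother_id = mother_id, population = population,
       locus = locus, position = position, base1 = base1, base2 = base2,
       pct1 = pct1, pct2 = pct2)
}
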