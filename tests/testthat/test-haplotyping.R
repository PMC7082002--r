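# brute-force column/string oracles kept deliberately naive
oracle_variable <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  out <- integer(0)
  for (j in seq_len(ncol(m))) if (length(unique(m[, j])) > 1) out <- c(out, j)
  out
}
oracle_class <- function(seqs, site) {
  col <- substring(seqs, site, site)
  tab <- table(col)
  if (sum(tab >= 2) >= 2) "parsimony_informative" else "singleton"
}
random_alignment <- function(n, L, n_states = 2) {
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T")[seq_len(n_states)], L, replace = TRUE),
          collapse = ""), "")
  names(seqs) <- paste0("s", seq_len(n))
  alignment(seqs)
}

test_that("variable sites and their classes follow the column definitions", {
  aln <- alignment(c(a = "AAAA", b = "AAAA", c = "AAAA"))
  expect_length(find_variable_sites(aln), 0)

  aln2 <- alignment(c(a = "AAAT", b = "AAAT", c = "AAAT", d = "AGAT"))
  expect_equal(find_variable_sites(aln2), 2)
  expect_equal(unname(classify_sites(aln2, 2)), "singleton")

  aln3 <- alignment(c(a = "ATT", b = "ATT", c = "GTT", d = "GTT"))
  expect_equal(unname(classify_sites(aln3, 1)), "parsimony_informative")
  expect_error(classify_sites(aln3, 2), "not variable")

  expect_error(find_variable_sites(alignment(c(a = "ACGT"))), "insufficient")
})

test_that("site classification matches a brute-force tally on random columns", {
  set.seed(7)
  for (rep in 1:25) {
    aln <- random_alignment(sample(4:12, 1), 40, n_states = sample(2:4, 1))
    vs <- find_variable_sites(aln)
    expect_equal(vs, oracle_variable(aln$seqs))
    if (length(vs)) {
      cls <- classify_sites(aln, vs)
      expect_equal(unname(cls),
                   vapply(vs, function(p) oracle_class(aln$seqs, p), ""))
      # every variable site classified exactly once, classes partition
      expect_equal(length(vs),
                   sum(cls == "singleton") + sum(cls == "parsimony_informative"))
    }
  }
})

test_that("haplotype enumeration equals distinct-string counting and ignores order", {
  expect_equal(nrow(enumerate_haplotypes(
    alignment(c(a = "ACG", b = "ACG")))$haplotypes), 1)

  set.seed(11)
  for (rep in 1:10) {
    aln <- random_alignment(10, 20)
    hs <- enumerate_haplotypes(aln)
    expect_equal(nrow(hs$haplotypes), length(unique(aln$seqs)))
    expect_equal(sum(hs$haplotypes$count), sum(!aln$ambiguous))
    # permutation invariance
    perm <- sample(length(aln$seqs))
    aln_p <- alignment(setNames(aln$seqs[perm], aln$ids[perm]))
    hs_p <- enumerate_haplotypes(aln_p)
    expect_equal(sort(hs_p$haplotypes$count), sort(hs$haplotypes$count))
    expect_setequal(hs_p$haplotypes$sequence, hs$haplotypes$sequence)
  }
})

test_that("ambiguous (double-peak) sequences are excluded whole", {
  aln <- alignment(c(a = "AAA", b = "AAA", c = "AAC", d = "AAC"),
                   ambiguous = c(FALSE, FALSE, FALSE, TRUE))
  hs <- enumerate_haplotypes(aln)
  expect_equal(sum(hs$haplotypes$count), 3)
  expect_identical(hs$excluded, "d")
  expect_false("d" %in% unlist(hs$members))
})

test_that("the synthetic 16S-like alignment reproduces the published site structure", {
  aln <- synthetic_16s_alignment()
  vs <- find_variable_sites(aln)
  expect_equal(vs, c(365, 442, 580))
  cls <- classify_sites(aln, vs)
  expect_identical(unname(cls["365"]), "parsimony_informative")
  expect_identical(unname(cls["442"]), "singleton")
  expect_identical(unname(cls["580"]), "parsimony_informative")
  hs <- enumerate_haplotypes(aln)
  expect_equal(hs$haplotypes$count, c(8L, 2L, 1L))
})

test_that("clone combination enumeration matches exhaustive counting", {
  clones <- c("AATAT", "AACAT", "AATAT")
  cc <- enumerate_combinations(clones, c(3, 5))
  expect_equal(cc$n_distinct, 2)
  expect_equal(cc$combinations$count, c(2L, 1L))

  expect_equal(enumerate_combinations("ACGT", sites = c(1, 2))$n_distinct, 1)

  set.seed(5)
  for (rep in 1:20) {
    cl <- vapply(1:12, function(i)
      paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = ""), "")
    sites <- sort(sample(6, 2))
    cc <- enumerate_combinations(cl, sites)
    oracle <- length(unique(paste(substring(cl, sites[1], sites[1]),
                                  substring(cl, sites[2], sites[2]))))
    expect_equal(cc$n_distinct, oracle)
    expect_equal(sum(cc$combinations$count), 12)
  }
})

test_that("reading-frame inference minimizes stop codons (table 5 code)", {
  core <- "ATGTTTGCAATTCGA"   # no stops in frame 0 under the invertebrate code
  for (pad in 0:2) {
    padded <- paste0(strrep("T", pad), core)
    rf <- infer_reading_frame(padded)
    # TGA is Trp here, so padding with T cannot create stops upstream
    expect_equal(rf$stop_counts[[as.character(pad)]], 0)
    expect_true(rf$clean)
  }
  withTAA <- "TAAGGGGGG"      # stop in frame 0 only
  rf <- suppressWarnings(infer_reading_frame(withTAA))
  expect_true(rf$frame != 0)
  # stops in every frame: TAA(f0), TAG(f1), TAA(f2)
  expect_warning(infer_reading_frame("TAAATAGATAA"), "stop codons")
})

test_that("syn/non-syn counting uses the invertebrate mitochondrial code", {
  expect_equal(unname(count_syn_nonsyn("TTA", "TTG")), c(1, 0))   # Leu/Leu
  expect_equal(unname(count_syn_nonsyn("ATT", "CTT")), c(0, 1))   # Ile/Leu
  expect_equal(unname(count_syn_nonsyn("TGA", "TGG")), c(1, 0))   # Trp/Trp (table 5)
  expect_equal(unname(count_syn_nonsyn("AGA", "AGT")), c(1, 0))   # Ser/Ser (table 5)
  # multi-hit codon: direct pair comparison classifies all differing sites
  expect_equal(unname(count_syn_nonsyn("TTA", "CTG")), c(2, 0))   # Leu/Leu, 2 sites
  # symmetry
  set.seed(3)
  for (rep in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = "")
    expect_equal(count_syn_nonsyn(a, b), count_syn_nonsyn(b, a))
  }
  expect_error(count_syn_nonsyn("ACG", "AC"), "equal length")
  expect_error(count_syn_nonsyn("ACN", "ACG"), "unambiguous")
})

test_that("max pairwise differences and consensus behave on a toy set", {
  seqs <- c(h1 = "ATTAAATTTGGA", h2 = "ATTAAATTTGGG", h3 = "CTTAAATTTGGA")
  aln <- alignment(seqs, locus = "COI")
  hs <- enumerate_haplotypes(aln)
  mx <- max_pairwise_syn_nonsyn(hs, frame = 0)
  # h1/h2: GGA->GGG syn; h1/h3: ATT->CTT nonsyn; h2/h3 one of each
  expect_equal(unname(mx), c(1, 1))
  expect_equal(nchar(consensus_sequence(aln)), 12)
  expect_identical(substring(consensus_sequence(aln), 1, 1), "A")
})

test_that("FASTA IO preserves ambiguity flags", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGT", ">s2 [ambiguous]", "ACGA", ">s3", "ACGT"), f)
  aln <- read_alignment_fasta(f, locus = "16S")
  expect_equal(aln$ambiguous, c(FALSE, TRUE, FALSE))
  hs <- enumerate_haplotypes(aln)
  expect_equal(sum(hs$haplotypes$count), 2)
})
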