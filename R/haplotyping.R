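## Alignment-column analysis: variable sites, singleton vs
## parsimony-informative classification, haplotype and clone-combination
## enumeration, reading-frame inference and synonymous / non-synonymous
## difference counts under the invertebrate mitochondrial code.

#' Construct an aligned sequence set
#'
#' @param seqs named character vector of equal-length nucleotide sequences
#'   (A/C/G/T, plus N/- permitted as explicit marks).
#' @param locus locus label (e.g. "16S", "COI").
#' @param ambiguous logical vector (recycled) marking sequences carrying
#'   any heteroplasmic / double-peak site; flagged sequences are excluded
#'   whole from haplotype and variable-site analysis.
#' @return list of class `alignment`.
#' @export
alignment <- function(seqs, locus = "unknown", ambiguous = FALSE) {
  seqs <- toupper(seqs)
  if (length(seqs) == 0L) stop("alignment is empty")
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  if (length(unique(nchar(seqs))) != 1L)
    stop("all sequences must have equal length")
  if (any(grepl("[^ACGTN-]", seqs)))
    stop("alignment alphabet restricted to A/C/G/T/N/-")
  ambiguous <- rep_len(ambiguous, length(seqs))
  structure(list(ids = names(seqs), seqs = unname(seqs), locus = locus,
                 ambiguous = ambiguous, length = nchar(seqs[[1]])),
            class = "alignment")
}

#' Read an aligned FASTA into an `alignment`
#'
#' Sequence names containing the tag `[ambiguous]` (or listed in
#' `ambiguous_ids`) are flagged as double-peak carriers.
#'
#' @param path FASTA path.
#' @param locus locus label.
#' @param ambiguous_ids ids to flag as ambiguous.
#' @return an [alignment()].
#' @export
read_alignment_fasta <- function(path, locus = "unknown",
                                 ambiguous_ids = character(0)) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  ids <- sub("\\s.*$", "", names(seqs))
  amb <- grepl("\\[ambiguous\\]", names(seqs)) | ids %in% ambiguous_ids
  names(seqs) <- ids
  alignment(seqs, locus = locus, ambiguous = amb)
}

aln_matrix <- function(aln, unambiguous_only = TRUE) {
  keep <- if (unambiguous_only) !aln$ambiguous else rep(TRUE, length(aln$seqs))
  m <- do.call(rbind, strsplit(aln$seqs[keep], ""))
  rownames(m) <- aln$ids[keep]
  m
}

#' Find variable alignment columns
#'
#' Positions (1-based) with at least two distinct bases among the
#' unambiguous sequences.
#'
#' @param aln an [alignment()].
#' @return integer vector of positions.
#' @export
find_variable_sites <- function(aln) {
  stopifnot(inherits(aln, "alignment"))
  if (sum(!aln$ambiguous) < 2L)
    stop("insufficient data: need >= 2 unambiguous sequences")
  m <- aln_matrix(aln)
  which(apply(m, 2, function(col) length(unique(col)) > 1))
}

#' Classify variable sites as singleton or parsimony-informative
#'
#' A column is parsimony-informative iff at least two distinct bases each
#' occur in at least two sequences; otherwise its minor variant occurs in
#' exactly one sequence and the site is a singleton.
#'
#' @param aln an [alignment()].
#' @param sites variable positions (see [find_variable_sites()]).
#' @return named character vector position -> class.
#' @export
classify_sites <- function(aln, sites = find_variable_sites(aln)) {
  stopifnot(inherits(aln, "alignment"))
  m <- aln_matrix(aln)
  vapply(as.character(sites), function(p) {
    col <- m[, as.integer(p)]
    tab <- table(col)
    if (length(tab) < 2L) stop("site ", p, " is not variable")
    if (sum(tab >= 2L) >= 2L) "parsimony_informative" else "singleton"
  }, character(1))
}

#' Enumerate haplotypes among unambiguous sequences
#'
#' Distinct full sequences with their members and counts; sequences
#' flagged ambiguous (any double-peak site) are excluded whole and listed
#' separately.  Haplotypes are numbered by decreasing count, ties by first
#' occurrence.
#'
#' @param aln an [alignment()].
#' @return list of class `haplotype_summary`: `haplotypes` (data.frame id,
#'   count, sequence), `members` (named list), `excluded` (ambiguous ids),
#'   `variable_sites`, `site_class` (when >= 2 usable sequences).
#' @export
enumerate_haplotypes <- function(aln) {
  stopifnot(inherits(aln, "alignment"))
  keep <- !aln$ambiguous
  seqs <- aln$seqs[keep]; ids <- aln$ids[keep]
  uniq <- unique(seqs)
  members <- lapply(uniq, function(s) ids[seqs == s])
  counts <- lengths(members)
  ord <- order(-counts, match(uniq, seqs))
  uniq <- uniq[ord]; members <- members[ord]; counts <- counts[ord]
  hap_ids <- paste0("Hap-", aln$locus, "-", seq_along(uniq))
  names(members) <- hap_ids
  vs <- NULL; cls <- NULL
  if (sum(keep) >= 2L) {
    vs <- find_variable_sites(aln)
    cls <- if (length(vs)) classify_sites(aln, vs) else setNames(character(0), character(0))
  }
  structure(list(
    haplotypes = data.frame(id = hap_ids, count = as.integer(counts),
                            sequence = uniq, stringsAsFactors = FALSE),
    members = members,
    excluded = aln$ids[aln$ambiguous],
    variable_sites = vs, site_class = cls,
    locus = aln$locus), class = "haplotype_summary")
}

#' Enumerate distinct site-state combinations across clones
#'
#' @param clones character vector of clone sequences, or a character
#'   matrix (clones x sites) of bases.
#' @param sites 1-based positions (ignored when `clones` is already a
#'   base matrix).
#' @return list with `combinations` (data.frame combination, count,
#'   decreasing) and `n_distinct`.
#' @export
enumerate_combinations <- function(clones, sites = NULL) {
  if (is.matrix(clones)) {
    m <- clones
  } else {
    if (length(clones) == 0L) stop("need >= 1 clone")
    if (is.null(sites)) stop("sites must be given for sequence input")
    m <- do.call(rbind, lapply(strsplit(toupper(clones), ""),
                               function(s) s[sites]))
  }
  keys <- apply(m, 1, paste, collapse = "-")
  tab <- sort(table(keys), decreasing = TRUE)
  list(combinations = data.frame(combination = names(tab),
                                 count = as.integer(tab),
                                 stringsAsFactors = FALSE),
       n_distinct = length(tab))
}

# invertebrate mitochondrial genetic code (TGA=Trp, AGA/AGG=Ser, ATA=Met)
mito_code <- function() Biostrings::getGeneticCode("5")

codons <- function(seq, frame) {
  s <- substring(seq, frame + 1L)
  n <- nchar(s) %/% 3L
  if (n == 0L) return(character(0))
  substring(s, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
}

#' Infer the reading frame of a protein-coding consensus
#'
#' Returns the frame (0, 1 or 2 skipped leading bases) minimizing stop
#' codons under the invertebrate mitochondrial code; ties broken by the
#' smallest frame index.  If every frame contains stops, a warning is
#' issued and the minimizing frame is still returned.
#'
#' @param consensus nucleotide string.
#' @return list with `frame`, `stop_counts` (named "0","1","2") and
#'   `clean` (TRUE iff the chosen frame has zero stops).
#' @export
infer_reading_frame <- function(consensus) {
  gc <- mito_code()
  stops <- vapply(0:2, function(f) {
    cds <- codons(consensus, f)
    cds <- cds[!grepl("[^ACGT]", cds)]
    sum(gc[cds] == "*")
  }, numeric(1))
  names(stops) <- as.character(0:2)
  frame <- as.integer(names(stops)[which.min(stops)])  # ties -> smallest
  if (min(stops) > 0)
    warning("all reading frames contain stop codons; returning frame ", frame)
  list(frame = frame, stop_counts = stops, clean = min(stops) == 0)
}

#' Count synonymous and non-synonymous differences between two sequences
#'
#' Sequences are split into codons in the given frame (incomplete edge
#' codons dropped).  Within each differing codon, every differing site is
#' counted and all sites of that codon classified by direct codon-pair
#' translation under the invertebrate mitochondrial code: synonymous iff
#' the two codons encode the same amino acid.  Symmetric in its arguments.
#'
#' @param a,b equal-length unambiguous nucleotide strings.
#' @param frame reading frame (0, 1 or 2).
#' @return c(synonymous = ..., non_synonymous = ...).
#' @export
count_syn_nonsyn <- function(a, b, frame = 0L) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b))
    stop("sequences must be unambiguous A/C/G/T")
  ca <- codons(a, frame); cb <- codons(b, frame)
  gc <- mito_code()
  syn <- 0L; nonsyn <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    ndiff <- sum(strsplit(ca[i], "")[[1]] != strsplit(cb[i], "")[[1]])
    if (gc[[ca[i]]] == gc[[cb[i]]]) syn <- syn + ndiff else nonsyn <- nonsyn + ndiff
  }
  c(synonymous = syn, non_synonymous = nonsyn)
}

#' Majority-rule consensus of the unambiguous sequences
#' @param aln an [alignment()].
#' @return nucleotide string.
#' @export
consensus_sequence <- function(aln) {
  m <- aln_matrix(aln)
  paste(apply(m, 2, function(col) names(which.max(table(col)))), collapse = "")
}

#' Maximum pairwise synonymous / non-synonymous differences
#'
#' Evaluates [count_syn_nonsyn()] over every haplotype pair and returns
#' the two maxima (each over all pairs, independently).
#'
#' @param hs a `haplotype_summary` (protein-coding locus).
#' @param frame reading frame; default inferred from the most frequent
#'   haplotype via [infer_reading_frame()].
#' @return c(max_synonymous = ..., max_non_synonymous = ...).
#' @export
max_pairwise_syn_nonsyn <- function(hs, frame = NULL) {
  stopifnot(inherits(hs, "haplotype_summary"))
  seqs <- hs$haplotypes$sequence
  if (is.null(frame)) frame <- infer_reading_frame(seqs[1])$frame
  best <- c(max_synonymous = 0L, max_non_synonymous = 0L)
  if (length(seqs) < 2L) return(best)
  for (i in seq_len(length(seqs) - 1L))
    for (j in (i + 1L):length(seqs)) {
      d <- count_syn_nonsyn(seqs[i], seqs[j], frame)
      best["max_synonymous"] <- max(best["max_synonymous"], d["synonymous"])
      best["max_non_synonymous"] <- max(best["max_non_synonymous"], d["non_synonymous"])
    }
  best
}

#' Synthetic 16S-like alignment with the observed site structure
#'
#' A fully synthetic stand-in for the deposited 16S haplotypes (which
#' require a download): eleven 600 bp sequences carrying three haplotypes
#' with counts 8/1/2, variable at positions 365 (T/C), 442 (singleton) and
#' 580 (T/A), so that 365 and 580 are parsimony-informative and 442 is a
#' singleton.  The background is a fixed pseudo-random sequence.
#'
#' @return an [alignment()] with locus "16S".
#' @export
synthetic_16s_alignment <- function() {
  hp <- default_haplotypes()   # MAT = C365/T580, ALT = T365/A580
  h1 <- hp[["MAT"]]
  h3 <- hp[["ALT"]]
  h2 <- h1
  substr(h2, 442, 442) <- if (substr(h1, 442, 442) == "A") "G" else "A"
  seqs <- c(rep(h1, 8), h2, rep(h3, 2))
  names(seqs) <- c(paste0("syn16S-h1-", 1:8), "syn16S-h2-1",
                   paste0("syn16S-h3-", 1:2))
  alignment(seqs, locus = "16S")
}

#' Write a haplotype summary as CSV + JSON
#' @param hs a `haplotype_summary`.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return `hs`, invisibly.
#' @export
write_haplotype_summary <- function(hs, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    df <- hs$haplotypes
    df$members <- vapply(hs$members, paste, "", collapse = ";")
    write.csv(df[c("id", "count", "members")], csv_path,
              row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      locus = hs$locus,
      n_haplotypes = nrow(hs$haplotypes),
      haplotypes = hs$haplotypes[c("id", "count")],
      members = hs$members, excluded = hs$excluded,
      variable_sites = hs$variable_sites,
      site_class = as.list(hs$site_class)),
      json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(hs)
}
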