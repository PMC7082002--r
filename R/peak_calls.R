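## Per-site nucleotide proportions and heteroplasmy calls from paired-read
## peak heights or transcribed percentage tables.

CALL_COLS <- c("specimen", "individual", "role", "sex", "tissue", "mother_id",
               "population", "locus", "position", "major_base", "minor_base",
               "prop_major", "prop_minor", "prop_f", "prop_r", "single_read",
               "heteroplasmic", "confirmed")

#' Averaged nucleotide proportions from paired-read peak heights
#'
#' Identifies the two candidate bases (largest combined height over the
#' available reads), converts each read's heights to proportions by
#' dividing each candidate peak by the sum of the two candidate peaks, and
#' averages over the available reads.  With a single read, that read's
#' proportions are returned and flagged.
#'
#' @param forward_heights,reverse_heights named numeric vectors of channel
#'   heights (names among A,C,G,T); either read may be `NULL` (failed).
#' @return list with `bases` (candidate pair, major first), `prop` (named
#'   averaged proportions over the pair, summing to 1), `per_read` (named
#'   list of per-read proportions) and `single_read` flag.
#' @examples
#' proportion_from_heights(c(T = 60, C = 40), c(T = 80, C = 20))  # T 0.7
#' @export
proportion_from_heights <- function(forward_heights, reverse_heights = NULL) {
  reads <- Filter(Negate(is.null),
                  list(forward = forward_heights, reverse = reverse_heights))
  if (length(reads) == 0L) stop("at least one read must be present")
  reads <- lapply(reads, function(h) {
    if (any(h < 0)) stop("peak heights must be nonnegative")
    full <- setNames(numeric(4), BASES)
    full[names(h)] <- h
    full
  })
  total <- Reduce(`+`, reads)
  if (sum(total) <= 0) stop("no signal: all peak heights are zero")
  cand <- names(sort(total, decreasing = TRUE))[1:2]
  per_read <- lapply(reads, function(h) {
    s <- sum(h[cand])
    if (s <= 0) return(NULL)  # read with no signal at the candidate bases
    h[cand] / s
  })
  per_read <- Filter(Negate(is.null), per_read)
  if (length(per_read) == 0L) stop("no signal at candidate bases")
  prop <- Reduce(`+`, per_read) / length(per_read)
  list(bases = cand, prop = prop, per_read = per_read,
       single_read = length(per_read) < 2L)
}

#' Call one site from averaged proportions
#'
#' Heteroplasmic iff the minor proportion reaches `min_minor_fraction` and
#' the baseline criterion holds.  Exact 50/50 ties are heteroplasmic, with
#' the major base chosen by the fixed order A < C < G < T.
#'
#' @param prop named numeric of length 1 or 2 (proportions over the
#'   candidate bases, summing to 1).
#' @param min_minor_fraction detection threshold in (0, 0.5); default 0.05
#'   sits just below the smallest minor proportion reported as real in
#'   curated trace data (6.5%).
#' @param baseline_ok logical: did the minor peak clear the baseline?
#' @param specimen,position,prop_f,prop_r,single_read metadata carried into
#'   the call record.
#' @return one-row data.frame site call.
#' @export
call_site <- function(prop, min_minor_fraction = 0.05, baseline_ok = TRUE,
                      specimen = NA_character_, position = NA_integer_,
                      prop_f = NA_real_, prop_r = NA_real_,
                      single_read = FALSE) {
  if (min_minor_fraction <= 0 || min_minor_fraction >= 0.5)
    stop("min_minor_fraction must be in (0, 0.5)")
  if (any(prop < -1e-9) || abs(sum(prop) - 1) > 1e-9)
    stop("proportions must be nonnegative and sum to 1")
  if (length(prop) == 1L) {
    major <- names(prop); minor <- NA_character_
    pmaj <- 1; pmin <- 0
  } else {
    ord <- order(-prop, match(names(prop), BASES))  # tie -> base order
    major <- names(prop)[ord[1]]; minor <- names(prop)[ord[2]]
    pmaj <- unname(prop[ord[1]]); pmin <- unname(prop[ord[2]])
    if (pmin == 0) minor <- NA_character_
  }
  het <- !is.na(minor) && pmin >= min_minor_fraction && isTRUE(baseline_ok)
  data.frame(specimen = specimen, position = as.integer(position),
             major_base = major, minor_base = minor,
             prop_major = pmaj, prop_minor = pmin,
             prop_f = prop_f, prop_r = prop_r,
             single_read = single_read, heteroplasmic = het,
             confirmed = "not_tested", stringsAsFactors = FALSE)
}

#' Call all (or selected) positions of a simulated/parsed trace set
#'
#' The baseline criterion requires the minor candidate peak to exceed
#' `baseline_factor` times the read's baseline level in every available
#' read.
#'
#' @param ts a `trace_set`.
#' @param positions positions to call (default: all).
#' @param min_minor_fraction passed to [call_site()].
#' @param baseline_factor multiple of the baseline level a minor peak must
#'   clear (default 3).
#' @return data.frame of site calls.
#' @export
call_trace_set <- function(ts, positions = NULL, min_minor_fraction = 0.05,
                           baseline_factor = 3) {
  stopifnot(inherits(ts, "trace_set"))
  if (is.null(positions)) positions <- ts$positions
  rows <- lapply(positions, function(p) {
    i <- match(p, ts$positions)
    if (is.na(i)) stop("position ", p, " not covered by trace set")
    fh <- if ("forward" %in% names(ts$reads)) ts$reads$forward$heights[i, ] else NULL
    rh <- if ("reverse" %in% names(ts$reads)) ts$reads$reverse$heights[i, ] else NULL
    pr <- proportion_from_heights(fh, rh)
    minor_b <- pr$bases[which.min(pr$prop[pr$bases])]
    base_ok <- all(vapply(names(ts$reads), function(rd) {
      h <- ts$reads[[rd]]$heights[i, minor_b]
      h > baseline_factor * ts$reads[[rd]]$baseline_level
    }, logical(1)))
    pf <- if (!is.null(pr$per_read$forward)) unname(pr$per_read$forward[pr$bases[1]]) else NA_real_
    prv <- if (!is.null(pr$per_read$reverse)) unname(pr$per_read$reverse[pr$bases[1]]) else NA_real_
    call_site(pr$prop, min_minor_fraction, baseline_ok = base_ok,
              specimen = ts$specimen, position = p,
              prop_f = pf, prop_r = prv, single_read = pr$single_read)
  })
  do.call(rbind, rows)
}

#' Assemble a call table
#'
#' A call table is a tidy data.frame (one row per specimen x position)
#' carrying specimen metadata (individual, role, sex, tissue, mother link,
#' population, locus) alongside the site call.
#'
#' @param calls data.frame of site calls ([call_site()] rows).
#' @param meta data.frame with columns specimen, individual, role, sex,
#'   tissue, mother_id, population, locus (one row per specimen).
#' @return data.frame of class `call_table`.
#' @export
call_table <- function(calls, meta) {
  need <- c("specimen", "individual", "role", "sex", "tissue", "mother_id",
            "population", "locus")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$specimen))
    stop("every specimen must have exactly one metadata record")
  unknown <- setdiff(calls$specimen, meta$specimen)
  if (length(unknown))
    stop("calls reference specimens without metadata: ",
         paste(unknown, collapse = ", "))
  bad_link <- meta$role %in% c("egg", "clone") &
    (is.na(meta$mother_id) | meta$mother_id == "")
  if (any(bad_link))
    stop("egg/clone records must carry a mother_id: ",
         paste(meta$specimen[bad_link], collapse = ", "))
  out <- merge(meta[need], calls, by = "specimen", sort = FALSE)
  out <- out[order(match(out$specimen, meta$specimen), out$position), ]
  rownames(out) <- NULL
  class(out) <- c("call_table", "data.frame")
  out
}

#' Read a percent-dialect table and call every site
#'
#' Input CSV columns: specimen, role, sex, tissue, mother_id, population,
#' position, base1, base2, pct1, pct2, plus optional individual and locus.
#' Percentage pairs are renormalized to sum to 1 (printed tables
#' occasionally sum to 99.6--100.3 due to rounding).  Percentages are used
#' as given: there are no raw heights to average, and baseline screening
#' is assumed done upstream.
#'
#' @param path CSV path.
#' @param min_minor_fraction heteroplasmy threshold.
#' @return a [call_table()].
#' @export
read_percent_table <- function(path, min_minor_fraction = 0.05) {
  # base columns may be all-"T" and must not be parsed as logicals
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(pct1 = "numeric", pct2 = "numeric",
                                base1 = "character", base2 = "character"))
  need <- c("specimen", "role", "sex", "tissue", "mother_id", "population",
            "position", "base1", "base2", "pct1", "pct2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("percent table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!"individual" %in% names(df)) df$individual <- df$specimen
  if (!"locus" %in% names(df)) df$locus <- "unknown"
  bad <- which(df$pct1 < 0 | df$pct2 < 0 | df$pct1 + df$pct2 <= 0 |
                 is.na(df$pct1) | is.na(df$pct2))
  if (length(bad))
    stop("invalid percentage pair at row ", bad[1], " of ", path)
  calls <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    prop <- setNames(c(r$pct1, r$pct2), c(r$base1, r$base2))
    prop <- prop / sum(prop)
    call_site(prop, min_minor_fraction, baseline_ok = TRUE,
              specimen = r$specimen, position = r$position)
  }))
  meta <- unique(df[c("specimen", "individual", "role", "sex", "tissue",
                      "mother_id", "population", "locus")])
  call_table(calls, meta)
}

#' Confirm heteroplasmy calls across replicate extractions
#'
#' A site is confirmed heteroplasmic iff heteroplasmic in both replicates
#' at the same position with the same base pair; sites heteroplasmic in
#' exactly one replicate are flagged `unconfirmed` (never dropped
#' silently); concordant homoplasmic sites are `confirmed` homoplasmic.
#' Specimens covered by only one table produce a coverage warning and stay
#' `not_tested`.
#'
#' @param calls_rep1,calls_rep2 [call_table()]s covering the same
#'   specimens/positions.
#' @return `calls_rep1` with its `confirmed` column filled
#'   (`confirmed` / `unconfirmed` / `not_tested`); coverage gaps are
#'   recorded in `attr(, "coverage_warnings")`.
#' @export
confirm_replicates <- function(calls_rep1, calls_rep2) {
  key <- function(x) paste(x$specimen, x$position, sep = "@")
  k1 <- key(calls_rep1); k2 <- key(calls_rep2)
  missing2 <- setdiff(unique(calls_rep1$specimen), unique(calls_rep2$specimen))
  missing1 <- setdiff(unique(calls_rep2$specimen), unique(calls_rep1$specimen))
  warnings <- character(0)
  if (length(missing2))
    warnings <- c(warnings, paste("specimen absent from replicate 2:", missing2))
  if (length(missing1))
    warnings <- c(warnings, paste("specimen absent from replicate 1:", missing1))
  if (length(warnings)) warning(paste(warnings, collapse = "; "))
  m <- match(k1, k2)
  out <- calls_rep1
  for (i in seq_along(m)) {
    j <- m[i]
    if (is.na(j)) { out$confirmed[i] <- "not_tested"; next }
    r1 <- calls_rep1[i, ]; r2 <- calls_rep2[j, ]
    same_pair <- identical(sort(c(r1$major_base, r1$minor_base)),
                           sort(c(r2$major_base, r2$minor_base)))
    out$confirmed[i] <-
      if (r1$heteroplasmic && r2$heteroplasmic && same_pair) "confirmed"
      else if (xor(r1$heteroplasmic, r2$heteroplasmic)) "unconfirmed"
      else if (!r1$heteroplasmic && !r2$heteroplasmic) "confirmed"
      else "unconfirmed"  # both het but different base pairs
  }
  attr(out, "coverage_warnings") <- warnings
  out
}

#' Count heteroplasmic eggs of one mother
#'
#' An egg counts as heteroplasmic iff at least one of the listed positions
#' is heteroplasmic.
#'
#' @param table a [call_table()].
#' @param mother_id individual id of the mother.
#' @param positions positions considered (default: all present).
#' @return c(n_het = ..., n_total = ...).
#' @export
count_het_offspring <- function(table, mother_id, positions = NULL) {
  eggs <- table[table$role == "egg" & table$mother_id == mother_id, ]
  if (nrow(eggs) == 0L) {
    if (!mother_id %in% c(table$individual, table$mother_id))
      stop("unknown mother id: ", mother_id)
    stop("mother ", mother_id, " has no eggs in the table")
  }
  if (!is.null(positions)) eggs <- eggs[eggs$position %in% positions, ]
  het <- tapply(eggs$heteroplasmic, eggs$specimen, any)
  c(n_het = sum(het), n_total = length(het))
}

#' Count heteroplasmic tissue records of one individual
#'
#' @param table a [call_table()].
#' @param individual_id individual owning the tissue panel.
#' @param positions positions considered (default: all present).
#' @return c(n_het_tissues = ..., n_tissues = ...).
#' @export
count_het_tissues <- function(table, individual_id, positions = NULL) {
  tis <- table[table$individual == individual_id &
                 table$role %in% c("adult", "tissue"), ]
  if (nrow(tis) == 0L) stop("no tissue records for individual ", individual_id)
  if (!is.null(positions)) tis <- tis[tis$position %in% positions, ]
  het <- tapply(tis$heteroplasmic, tis$specimen, any)
  c(n_het_tissues = sum(het), n_tissues = length(het))
}

#' Build a call table from a simulated family
#'
#' Runs the caller on the mother, each egg and (if present) the father at
#' the given positions and assembles the pedigree metadata.
#'
#' @param fam a `sim_family` from [simulate_family()].
#' @param positions positions to call (default: the variable positions of
#'   the generating haplotype set).
#' @param min_minor_fraction,baseline_factor passed to [call_trace_set()].
#' @param locus locus label.
#' @return a [call_table()].
#' @export
call_family <- function(fam, positions = NULL, min_minor_fraction = 0.05,
                        baseline_factor = 3, locus = "sim") {
  stopifnot(inherits(fam, "sim_family"))
  specs <- c(list(fam$mother), fam$eggs,
             if (!is.null(fam$father)) list(fam$father))
  calls <- do.call(rbind, lapply(specs, call_trace_set, positions = positions,
                                 min_minor_fraction = min_minor_fraction,
                                 baseline_factor = baseline_factor))
  meta <- data.frame(
    specimen = vapply(specs, `[[`, "", "specimen"),
    stringsAsFactors = FALSE)
  meta$individual <- meta$specimen
  meta$role <- ifelse(meta$specimen %in% c("mother", "father"), "adult", "egg")
  meta$sex <- ifelse(meta$specimen == "mother", "female",
                     ifelse(meta$specimen == "father", "male", ""))
  meta$tissue <- ifelse(meta$role == "adult",
                        ifelse(meta$specimen == "father", "gonad", "pleopod_setae"), "")
  meta$mother_id <- ifelse(meta$role == "egg", "mother", "")
  meta$population <- "sim"
  meta$locus <- locus
  call_table(calls, meta)
}

#' Build a call table from a simulated tissue panel
#'
#' @param panel a `sim_panel` from [simulate_tissue_panel()].
#' @param individual_id label for the owning individual.
#' @inheritParams call_family
#' @return a [call_table()].
#' @export
call_panel <- function(panel, individual_id = "ind", positions = NULL,
                       min_minor_fraction = 0.05, baseline_factor = 3,
                       locus = "sim") {
  stopifnot(inherits(panel, "sim_panel"))
  calls <- do.call(rbind, lapply(panel$tissues, call_trace_set,
                                 positions = positions,
                                 min_minor_fraction = min_minor_fraction,
                                 baseline_factor = baseline_factor))
  meta <- data.frame(specimen = names(panel$tissues),
                     individual = individual_id, role = "tissue",
                     sex = "female", tissue = names(panel$tissues),
                     mother_id = "", population = "sim", locus = locus,
                     stringsAsFactors = FALSE)
  call_table(calls, meta)
}

#' Write a call table (CSV) plus a JSON summary
#' @param table a [call_table()].
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return the table, invisibly.
#' @export
write_call_table <- function(table, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    write.csv(as.data.frame(table), csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    het <- table[table$heteroplasmic, ]
    summary <- list(
      n_specimens = length(unique(table$specimen)),
      n_sites = nrow(table),
      n_heteroplasmic_sites = nrow(het),
      heteroplasmic_specimens = sort(unique(het$specimen)))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(table)
}
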