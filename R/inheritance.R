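## Elimination logic over a call table with pedigree, clone, tissue and
## sex structure: which explanations of double peaks survive the data?

HYPOTHESES <- c("de_novo", "recombination", "numt_homozygous",
                "numt_heterozygous", "mito_duplication", "dui",
                "paternal_leakage")

#' Detection model for dropout-aware rejection rules
#'
#' Conventional PCR + Sanger misses minor variants below a floor; every
#' rejection driven by a "this specimen is homoplasmic" observation is
#' guarded by requiring the predicted minor fraction to exceed
#' `detection_floor + dropout_margin`, so low-proportion variants are
#' never counted as evidence of absence.
#'
#' @param detection_floor minimum minor fraction reliably called, in
#'   (0, 0.5); default 0.05 matches the caller's threshold.
#' @param dropout_margin extra safety margin (default 0.02).
#' @return list of class `detection_model`.
#' @export
detection_model <- function(detection_floor = 0.05, dropout_margin = 0.02) {
  if (detection_floor <= 0 || detection_floor >= 0.5)
    stop("detection_floor must be in (0, 0.5)")
  if (dropout_margin < 0) stop("dropout_margin must be nonnegative")
  structure(list(detection_floor = detection_floor,
                 dropout_margin = dropout_margin),
            class = "detection_model")
}

verdict <- function(hypothesis, status, evidence = NULL, note = NULL) {
  if (is.null(evidence))
    evidence <- data.frame(rule = character(0), individuals = character(0),
                           positions = character(0), observed = character(0),
                           predicted = character(0), stringsAsFactors = FALSE)
  if (status == "rejected" && nrow(evidence) == 0L)
    stop("a rejected verdict must carry evidence")
  structure(list(hypothesis = hypothesis, status = status,
                 evidence = evidence, note = note),
            class = "hypothesis_verdict")
}

ev_row <- function(rule, individuals, positions, observed, predicted) {
  data.frame(rule = rule,
             individuals = paste(individuals, collapse = ";"),
             positions = paste(positions, collapse = ";"),
             observed = observed, predicted = predicted,
             stringsAsFactors = FALSE)
}

#' @export
print.hypothesis_verdict <- function(x, ...) {
  cat(sprintf("%-18s %s\n", x$hypothesis, x$status))
  if (nrow(x$evidence))
    for (i in seq_len(nrow(x$evidence)))
      cat(sprintf("  [%s] %s @ %s: observed %s, predicted %s\n",
                  x$evidence$rule[i], x$evidence$individuals[i],
                  x$evidence$positions[i], x$evidence$observed[i],
                  x$evidence$predicted[i]))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

# per-locus heteroplasmic positions of an individual's reference adult
# record (role == "adult")
mother_het_sites <- function(table, individual) {
  rows <- table[table$individual == individual & table$role == "adult" &
                  table$heteroplasmic, ]
  split(rows$position, rows$locus)
}

mothers_with_eggs <- function(table) {
  eggs <- table[table$role == "egg", ]
  unique(eggs$mother_id)
}

#' Evaluate the NUMT hypotheses
#'
#' Three deterministic rules, all dropout-guarded:
#' * homozygous-NUMT: a nuclear insert present on both chromosomes is
#'   transmitted to every egg, so any egg of a double-peak mother that is
#'   homoplasmic at all of her heteroplasmic sites rejects it -- provided
#'   the predicted nuclear signal (`numt_signal_ratio`) exceeds
#'   `detection_floor + dropout_margin`.
#' * tissue discordance: a nuclear insert is in every cell, so an
#'   individual heteroplasmic in one tissue and homoplasmic in another at
#'   the same site rejects both NUMT forms.
#' * clone counting: >= 3 distinct site combinations among single-molecule
#'   clones of one tissue imply (under homozygous NUMT) at least two
#'   combinations in every egg; broods showing < 2 reject it.
#'
#' @param table a [call_table()] (may combine loci).
#' @param det a [detection_model()].
#' @param numt_signal_ratio predicted trace fraction of the nuclear copy.
#' @return list with elements `homozygous` and `heterozygous`, each a
#'   `hypothesis_verdict`.
#' @export
evaluate_numt <- function(table, det = detection_model(),
                          numt_signal_ratio = 1 / 3) {
  guard <- numt_signal_ratio > det$detection_floor + det$dropout_margin
  ev_hom <- list(); ev_both <- list()

  moms <- mothers_with_eggs(table)
  tissues_ind <- unique(table$individual[table$role %in% c("adult", "tissue")])
  multi_tissue <- tissues_ind[vapply(tissues_ind, function(i)
    length(unique(table$specimen[table$individual == i &
                                   table$role %in% c("adult", "tissue")])) > 1,
    logical(1))]
  if (length(moms) == 0L && length(multi_tissue) == 0L) {
    v <- verdict("numt_homozygous", "insufficient_data",
                 note = "no pedigree or multi-tissue structure")
    return(list(homozygous = v,
                heterozygous = verdict("numt_heterozygous", "insufficient_data",
                                       note = v$note)))
  }

  # homozygous rule: homoplasmic offspring of a double-peak mother
  for (mom in moms) {
    hs <- mother_het_sites(table, mom)
    for (locus in names(hs)) {
      sites <- hs[[locus]]
      if (length(sites) == 0L) next
      eggs <- table[table$role == "egg" & table$mother_id == mom &
                      table$locus == locus & table$position %in% sites, ]
      if (nrow(eggs) == 0L) next
      homo_eggs <- names(which(!tapply(eggs$heteroplasmic, eggs$specimen, any)))
      if (length(homo_eggs) && guard)
        ev_hom[[length(ev_hom) + 1L]] <- ev_row(
          "homoplasmic_offspring", c(mom, homo_eggs), paste0(locus, ":", sites),
          sprintf("%d/%d eggs homoplasmic at all double-peak sites",
                  length(homo_eggs), length(unique(eggs$specimen))),
          sprintf("all eggs show the maternal nuclear signal (~%.0f%%)",
                  100 * numt_signal_ratio))
    }
  }

  # tissue discordance rule (rejects both forms)
  for (ind in multi_tissue) {
    rows <- table[table$individual == ind & table$role %in% c("adult", "tissue"), ]
    for (key in unique(paste(rows$locus, rows$position))) {
      sub <- rows[paste(rows$locus, rows$position) == key, ]
      if (any(sub$heteroplasmic) && any(!sub$heteroplasmic)) {
        het_t <- unique(sub$specimen[sub$heteroplasmic])
        hom_t <- unique(sub$specimen[!sub$heteroplasmic])
        ev_both[[length(ev_both) + 1L]] <- ev_row(
          "tissue_discordance", ind, key,
          sprintf("het in %s; homoplasmic in %s",
                  paste(het_t, collapse = ","), paste(hom_t, collapse = ",")),
          "a Mendelian nuclear copy is present in every cell")
      }
    }
  }

  # clone rule
  clones <- table[table$role == "clone", ]
  for (mom in unique(clones$mother_id)) {
    hs <- mother_het_sites(table, mom)
    for (locus in names(hs)) {
      sites <- hs[[locus]]
      cl <- clones[clones$mother_id == mom & clones$locus == locus &
                     clones$position %in% sites, ]
      if (nrow(cl) == 0L || length(sites) == 0L) next
      m <- tapply(cl$major_base, list(cl$specimen, cl$position),
                  function(x) x[1])
      cc <- enumerate_combinations(as.matrix(m))
      eggs <- table[table$role == "egg" & table$mother_id == mom &
                      table$locus == locus & table$position %in% sites, ]
      if (nrow(eggs) == 0L) next
      egg_keys <- tapply(eggs$major_base, list(eggs$specimen, eggs$position),
                         function(x) x[1])
      egg_cc <- enumerate_combinations(as.matrix(egg_keys))
      if (cc$n_distinct >= 3L && egg_cc$n_distinct < 2L && guard)
        ev_hom[[length(ev_hom) + 1L]] <- ev_row(
          "clone_combinations", mom, paste0(locus, ":", sites),
          sprintf("%d clone combinations but %d combination(s) across eggs",
                  cc$n_distinct, egg_cc$n_distinct),
          "a maternal NUMT implies >= 2 combinations in every egg")
    }
  }

  ev_both_df <- if (length(ev_both)) do.call(rbind, ev_both) else NULL
  ev_hom_df <- if (length(ev_hom) || length(ev_both))
    do.call(rbind, c(ev_hom, ev_both)) else NULL
  hom <- if (!is.null(ev_hom_df)) verdict("numt_homozygous", "rejected", ev_hom_df)
         else verdict("numt_homozygous", "not_rejected")
  het <- if (!is.null(ev_both_df)) verdict("numt_heterozygous", "rejected", ev_both_df)
         else verdict("numt_heterozygous", "not_rejected")
  list(homozygous = hom, heterozygous = het)
}

#' Evaluate the mitochondrial-duplication hypothesis
#'
#' A duplication rides on every mtDNA molecule, so every descendant of a
#' double-peak mother must show the double peak.  Rejected if any egg of a
#' double-peak mother is homoplasmic at a maternal heteroplasmic site
#' whose maternal minor fraction exceeds the dropout guard.  Cross-locus
#' consistency (duplication seen at one locus but not the other in the
#' same individuals) is recorded as supporting evidence.
#'
#' @inheritParams evaluate_numt
#' @return a `hypothesis_verdict`.
#' @export
evaluate_duplication <- function(table, det = detection_model()) {
  ev <- list()
  moms <- mothers_with_eggs(table)
  dp_moms <- character(0)
  for (mom in moms) {
    hs <- mother_het_sites(table, mom)
    if (length(hs) == 0L) next
    dp_moms <- c(dp_moms, mom)
    for (locus in names(hs)) {
      for (site in hs[[locus]]) {
        mrow <- table[table$individual == mom & table$role == "adult" &
                        table$locus == locus & table$position == site, ]
        pred <- mrow$prop_minor[1]
        if (pred <= det$detection_floor + det$dropout_margin) next
        eggs <- table[table$role == "egg" & table$mother_id == mom &
                        table$locus == locus & table$position == site, ]
        homo <- eggs$specimen[!eggs$heteroplasmic]
        if (length(homo))
          ev[[length(ev) + 1L]] <- ev_row(
            "homoplasmic_offspring", c(mom, homo), paste0(locus, ":", site),
            sprintf("%d/%d eggs homoplasmic", length(homo), nrow(eggs)),
            sprintf("every egg inherits the duplication (maternal minor %.1f%%)",
                    100 * pred))
      }
    }
  }
  if (length(dp_moms) == 0L)
    return(verdict("mito_duplication", "insufficient_data",
                   note = "no double-peak mother with eggs in the table"))
  note <- NULL
  if (length(unique(table$locus)) > 1L) {
    per_locus <- lapply(split(table, table$locus), function(d)
      unique(d$individual[d$heteroplasmic & d$role == "adult"]))
    one_only <- setdiff(unique(unlist(per_locus)),
                        Reduce(intersect, per_locus))
    if (length(one_only))
      note <- paste0("duplication would require independent events per locus; ",
                     "individuals double-peaked at one locus only: ",
                     paste(one_only, collapse = ", "))
  }
  if (length(ev)) verdict("mito_duplication", "rejected", do.call(rbind, ev),
                          note = note)
  else verdict("mito_duplication", "not_rejected", note = note)
}

#' Evaluate doubly uniparental inheritance
#'
#' DUI predicts the divergent (male-transmitted) genome in males only;
#' heteroplasmic somatic calls in both sexes reject it.  A two-sided
#' Fisher exact test of heteroplasmy incidence by sex is attached as
#' evidence (descriptive only -- rejection rests on the qualitative rule).
#'
#' @param table a [call_table()].
#' @return a `hypothesis_verdict`.
#' @export
evaluate_dui <- function(table) {
  adults <- table[table$role %in% c("adult", "tissue") &
                    table$sex %in% c("male", "female"), ]
  if (nrow(adults) == 0L || length(unique(adults$sex)) < 2L)
    return(verdict("dui", "insufficient_data",
                   note = "need sexed adults of both sexes"))
  het_by_ind <- tapply(adults$heteroplasmic, adults$individual, any)
  sex_by_ind <- tapply(adults$sex, adults$individual, function(s) s[1])
  tab <- table(sex = sex_by_ind, het = factor(het_by_ind, c(FALSE, TRUE)))
  ft <- tryCatch(fisher.test(tab), error = function(e) NULL)
  het_sexes <- unique(sex_by_ind[het_by_ind])
  n_m <- sum(het_by_ind & sex_by_ind == "male")
  n_f <- sum(het_by_ind & sex_by_ind == "female")
  if (length(het_sexes) == 2L) {
    verdict("dui", "rejected",
            ev_row("both_sexes_heteroplasmic", "", "",
                   sprintf("%d heteroplasmic males, %d heteroplasmic females",
                           n_m, n_f),
                   "under DUI only males carry the divergent genome"),
            note = if (!is.null(ft))
              sprintf("Fisher exact p = %.3g (descriptive)", ft$p.value))
  } else if (length(het_sexes) == 0L) {
    verdict("dui", "insufficient_data", note = "no heteroplasmic adults")
  } else {
    verdict("dui", "not_rejected",
            note = sprintf("heteroplasmy confined to %ss", het_sexes))
  }
}

#' Evaluate de novo mutation as the primary cause
#'
#' With a per-site per-generation mutation rate `mu`, the probability that
#' an individual carries a heteroplasmic site among `n_sites` scored
#' positions is ~ `1 - (1 - mu)^n_sites`.  Rejected as the primary cause
#' if the observed incidence exceeds the Binomial(n, p) 99.9% quantile;
#' the exact binomial tail is attached.
#'
#' @param observed_het number of heteroplasmic individuals.
#' @param n_individuals number screened.
#' @param n_sites scored positions per individual.
#' @param mu mutation rate per site per generation (default 1.63e-7, the
#'   Daphnia pulex estimate).
#' @return a `hypothesis_verdict`.
#' @export
evaluate_de_novo <- function(observed_het, n_individuals, n_sites,
                             mu = 1.63e-7) {
  if (mu <= 0) stop("mu must be positive")
  p <- 1 - (1 - mu)^n_sites
  crit <- qbinom(0.999, n_individuals, p)
  tail <- pbinom(observed_het - 1, n_individuals, p, lower.tail = FALSE)
  ev <- ev_row("binomial_incidence", "", "",
               sprintf("%d/%d individuals heteroplasmic", observed_het,
                       n_individuals),
               sprintf("expected per-individual probability %.3g; P(X >= obs) = %.3g",
                       p, tail))
  if (observed_het > crit) verdict("de_novo", "rejected", ev)
  else verdict("de_novo", "not_rejected", ev)
}

#' Run all hypothesis evaluators and summarize the surviving set
#'
#' Recombination is reported only as a non-primary flag: it cannot create
#' novel site states and presupposes existing heteroplasmy, so it is never
#' the sole explanation.  Eggs heteroplasmic under a mother with no double
#' peaks are recorded as `maternal_undetected` (detection dropout), not
#' used against any hypothesis.  The final call is `paternal_leakage` when
#' heteroplasmy is present and every alternative is rejected; with no
#' heteroplasmic calls it is `no_heteroplasmy_detected`; otherwise the
#' surviving hypotheses are listed.
#'
#' @param table a [call_table()] (loci may be combined by row-binding).
#' @param det a [detection_model()].
#' @param numt_signal_ratio predicted NUMT trace fraction.
#' @param mu de novo mutation rate per site per generation.
#' @param require_confirmed if TRUE, only `confirmed` heteroplasmic sites
#'   count towards the final paternal-leakage call.
#' @return list of class `classification`: `verdicts` (named list),
#'   `surviving`, `final_call`, `maternal_undetected`, `het_adults`.
#' @export
classify_dataset <- function(table, det = detection_model(),
                             numt_signal_ratio = 1 / 3, mu = 1.63e-7,
                             require_confirmed = FALSE) {
  nu <- evaluate_numt(table, det, numt_signal_ratio)
  dup <- evaluate_duplication(table, det)
  dui <- evaluate_dui(table)
  adults <- table[table$role %in% c("adult", "tissue"), ]
  het_ind <- tapply(adults$heteroplasmic, adults$individual, any)
  n_sites <- length(unique(table$position))
  dn <- evaluate_de_novo(sum(het_ind), length(het_ind), n_sites, mu)
  rec <- verdict("recombination", "not_rejected",
                 note = paste("non-primary: cannot create novel site states",
                              "and requires pre-existing heteroplasmy"))
  rec$non_primary <- TRUE
  pl <- verdict("paternal_leakage", "not_rejected")

  verdicts <- list(de_novo = dn, recombination = rec,
                   numt_homozygous = nu$homozygous,
                   numt_heterozygous = nu$heterozygous,
                   mito_duplication = dup, dui = dui,
                   paternal_leakage = pl)

  any_het <- if (require_confirmed)
    any(table$heteroplasmic & table$confirmed == "confirmed")
  else any(table$heteroplasmic)

  surviving <- names(verdicts)[vapply(verdicts, function(v)
    v$status != "rejected", logical(1))]
  primaries <- setdiff(surviving, "recombination")

  final <- if (!any_het) "no_heteroplasmy_detected"
  else if (identical(primaries, "paternal_leakage")) "paternal_leakage"
  else paste0("unresolved: surviving hypotheses ",
              paste(primaries, collapse = ", "))

  # eggs heteroplasmic though the mother shows no double peak at that site
  mu_rec <- character(0)
  eggs <- table[table$role == "egg" & table$heteroplasmic, ]
  for (i in seq_len(nrow(eggs))) {
    mrow <- table[table$individual == eggs$mother_id[i] &
                    table$role == "adult" &
                    table$locus == eggs$locus[i] &
                    table$position == eggs$position[i], ]
    if (nrow(mrow) && !any(mrow$heteroplasmic))
      mu_rec <- c(mu_rec, paste0(eggs$specimen[i], "@", eggs$locus[i], ":",
                                 eggs$position[i]))
  }
  structure(list(verdicts = verdicts, surviving = surviving,
                 final_call = final,
                 maternal_undetected = unique(mu_rec),
                 het_adults = names(het_ind)[het_ind],
                 thresholds = list(detection_floor = det$detection_floor,
                                   dropout_margin = det$dropout_margin,
                                   numt_signal_ratio = numt_signal_ratio,
                                   mu = mu)),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat("Hypothesis verdicts\n-------------------\n")
  for (v in x$verdicts) print(v)
  cat("final call:", x$final_call, "\n")
  if (length(x$maternal_undetected))
    cat("maternal-undetected heteroplasmic eggs:",
        paste(x$maternal_undetected, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a classification as JSON
#' @param cls a `classification`.
#' @param path output path.
#' @return `cls`, invisibly.
#' @export
write_classification <- function(cls, path) {
  out <- list(
    final_call = cls$final_call,
    surviving = cls$surviving,
    maternal_undetected = cls$maternal_undetected,
    thresholds = cls$thresholds,
    verdicts = lapply(cls$verdicts, function(v)
      list(hypothesis = v$hypothesis, status = v$status,
           note = v$note, evidence = v$evidence)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(cls)
}
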