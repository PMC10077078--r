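#' Default report keywords for tube-study retention
#' @return character vector of keywords.
#' @export
ngt_keywords <- function() {
  c("nasogastric", "tube", "placement", "insertion", "bronchus")
}

# 16 years expressed in whole days via calendar arithmetic is not constant
# (leap years), so the age rule compares true calendar dates, not a fixed
# day count.
age_at_least_years <- function(birth_date, study_date, years) {
  b <- as.Date(birth_date)
  s <- as.Date(study_date)
  # birthday of the `years`-th year; Feb 29 births roll to Mar 1
  bday <- suppressWarnings(as.Date(paste(
    as.integer(format(b, "%Y")) + years, format(b, "%m-%d"), sep = "-")))
  roll <- is.na(bday)
  if (any(roll)) {
    bday[roll] <- as.Date(paste(
      as.integer(format(b[roll], "%Y")) + years, "03-01", sep = "-"))
  }
  s >= bday
}

#' Quality-control filter for a cohort manifest
#'
#' Retains records satisfying every rule: width >= 1024 AND height >= 1024
#' pixels; body part matching "chest" case-insensitively; view AP or PA;
#' patient aged at least 16 years on the study date. Records failing a rule
#' (or missing a required field) are excluded, and an exclusion log records
#' each excluded record with its *first* failing rule in the order
#' (missing_field, resolution, body_part, view, age).
#'
#' @param cohort manifest `data.frame` (columns width, height, body_part,
#'   view, study_date, birth_date at minimum).
#' @return list with `cohort` (retained rows) and `log` (`data.frame` of
#'   record_id, rule for each exclusion).
#' @export
qc_filter <- function(cohort) {
  req <- c("width", "height", "body_part", "view", "study_date", "birth_date")
  n <- nrow(cohort)
  rule <- rep(NA_character_, n)
  present <- rep(TRUE, n)
  for (f in req) {
    col <- cohort[[f]]
    if (is.null(col)) { present[] <- FALSE; break }
    present <- present & !is.na(col) & !(is.character(col) & col == "")
  }
  rule[!present] <- "missing_field"
  ok <- present

  res_ok <- ok & cohort$width >= 1024 & cohort$height >= 1024
  rule[ok & !res_ok] <- "resolution"
  ok <- res_ok

  bp_ok <- ok & grepl("chest", cohort$body_part, ignore.case = TRUE)
  rule[ok & !bp_ok] <- "body_part"
  ok <- bp_ok

  view_ok <- ok & cohort$view %in% c("AP", "PA")
  rule[ok & !view_ok] <- "view"
  ok <- view_ok

  age_ok <- ok
  age_ok[ok] <- age_at_least_years(cohort$birth_date[ok],
                                   cohort$study_date[ok], 16L)
  rule[ok & !age_ok] <- "age"
  ok <- age_ok

  log <- data.frame(record_id = cohort$record_id[!ok],
                    rule = rule[!ok], stringsAsFactors = FALSE)
  list(cohort = cohort[ok, , drop = FALSE], log = log)
}

#' Write a QC exclusion log as JSON-lines
#'
#' @param log exclusion log `data.frame` from [qc_filter()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_exclusion_log <- function(log, path) {
  lines <- vapply(seq_len(nrow(log)), function(i) {
    as.character(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Keyword retention filter on report text
#'
#' Retains records whose report text matches any keyword, case-insensitive,
#' by whole-substring regular-expression matching (no stemming). Absent or
#' empty report text never matches.
#'
#' @param cohort manifest `data.frame` with a `report_text` column.
#' @param keywords non-empty character vector; defaults to [ngt_keywords()].
#' @return the retained rows.
#' @export
keyword_filter <- function(cohort, keywords = ngt_keywords()) {
  if (length(keywords) == 0) stop2("keyword list must be non-empty")
  txt <- cohort$report_text
  if (is.null(txt)) txt <- rep(NA_character_, nrow(cohort))
  pattern <- paste(vapply(keywords, function(k) {
    paste0("(", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", k), ")")
  }, ""), collapse = "|")
  hit <- !is.na(txt) & grepl(pattern, txt, ignore.case = TRUE)
  cohort[hit, , drop = FALSE]
}

#' Majority-vote consensus of three rater labels
#'
#' Returns the label held by at least two of the three raters. A three-way
#' tie has no majority and returns `"no_consensus"`; tied records are meant
#' to be excluded from downstream agreement metrics rather than resolved
#' arbitrarily.
#'
#' @param rater_labels character vector of exactly 3 labels.
#' @return a single label, or `"no_consensus"`.
#' @export
consensus_label <- function(rater_labels) {
  rater_labels <- as.character(rater_labels)
  if (length(rater_labels) != 3L || anyNA(rater_labels)) {
    stop2("consensus requires exactly 3 non-missing rater labels")
  }
  tab <- sort(table(rater_labels), decreasing = TRUE)
  if (tab[1] >= 2) names(tab)[1] else "no_consensus"
}

#' Consensus labels for a whole manifest
#'
#' @param cohort manifest with rater1, rater2, rater3 columns.
#' @return character vector of consensus labels (with `"no_consensus"` for
#'   three-way ties).
#' @export
consensus_labels <- function(cohort) {
  vapply(seq_len(nrow(cohort)), function(i) {
    consensus_label(c(cohort$rater1[i], cohort$rater2[i], cohort$rater3[i]))
  }, "")
}

#' Patient-grouped stratified split
#'
#' Assigns every record to train / validation / test such that all records
#' of one patient share one split, and both the overall fractions and the
#' per-stratum label frequencies approximate the targets. Patients are
#' shuffled by `seed` and greedily assigned to the split with the largest
#' remaining deficit for the patient's (modal) stratum; exact grouped
#' stratification is NP-hard, so the contract is tolerance-based.
#'
#' @param cohort manifest `data.frame`.
#' @param fractions numeric length 3 summing to 1 (train, validation, test).
#' @param strata character vector of stratification columns (default label,
#'   sex, view).
#' @param group grouping column (default `patient_id`).
#' @param seed integer seed.
#' @param tolerance allowed deviation of realized fractions, as a
#'   proportion (default 0.02 = 2 percentage points).
#' @return object of class `split_assignment`: list with `assignment`
#'   (`data.frame` record_id, split), `fractions` (realized), `strata_table`
#'   (per-stratum frequency by split), `flagged` (TRUE when the tolerance
#'   was not achieved), and `multi_stratum_patients` (ids whose records
#'   spanned several strata, assigned by modal stratum).
#' @export
grouped_stratified_split <- function(cohort,
                                     fractions = c(train = 0.90,
                                                   validation = 0.05,
                                                   test = 0.05),
                                     strata = c("label", "sex", "view"),
                                     group = "patient_id",
                                     seed = 1,
                                     tolerance = 0.02) {
  if (abs(sum(fractions) - 1) > 1e-9) stop2("fractions must sum to 1")
  if (is.null(names(fractions))) {
    names(fractions) <- c("train", "validation", "test")
  }
  strata <- intersect(strata, names(cohort))
  if (length(strata) == 0) stop2("no stratum columns present in cohort")
  n <- nrow(cohort)
  stratum <- do.call(paste, c(cohort[strata], sep = "|"))
  gid <- cohort[[group]]
  if (is.null(gid)) stop2("grouping column '", group, "' absent")

  # patient-level stratum: modal stratum of the patient's records
  pat <- split(seq_len(n), gid)
  pat_sizes <- vapply(pat, length, 1L)
  pat_stratum <- vapply(pat, function(ix) {
    tb <- sort(table(stratum[ix]), decreasing = TRUE)
    names(tb)[1]
  }, "")
  multi <- names(pat)[vapply(pat, function(ix) {
    length(unique(stratum[ix])) > 1L
  }, TRUE)]

  splits <- names(fractions)
  # deficit = target count minus assigned count, per (stratum, split)
  strat_levels <- unique(pat_stratum)
  target <- outer(vapply(strat_levels, function(s) {
    sum(pat_sizes[pat_stratum == s])
  }, 1), fractions)
  dimnames(target) <- list(strat_levels, splits)
  assigned <- target * 0

  ord <- with_seed(seed, "split", sample(seq_along(pat)))
  pat_split <- character(length(pat))
  names(pat_split) <- names(pat)
  for (i in ord) {
    s <- pat_stratum[i]
    deficit <- target[s, ] - assigned[s, ]
    k <- splits[which.max(deficit)]
    pat_split[i] <- k
    assigned[s, k] <- assigned[s, k] + pat_sizes[i]
  }
  split_of <- pat_split[as.character(gid)]
  assignment <- data.frame(record_id = cohort$record_id,
                           split = unname(split_of),
                           stringsAsFactors = FALSE)
  realized <- table(factor(assignment$split, levels = splits)) / n
  flagged <- any(abs(as.numeric(realized) - fractions) > tolerance + 1e-12)
  if (flagged) {
    warning("realized split fractions deviate from targets by more than ",
            "the tolerance; best-effort assignment returned")
  }
  strata_table <- table(stratum = stratum,
                        split = factor(split_of, levels = splits))
  structure(list(assignment = assignment,
                 fractions = as.numeric(realized),
                 strata_table = strata_table,
                 flagged = flagged,
                 multi_stratum_patients = multi),
            class = "split_assignment")
}

#' Write a split assignment as CSV (record_id, split)
#'
#' @param sa a `split_assignment`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_split <- function(sa, path) {
  utils::write.csv(sa$assignment, path, row.names = FALSE)
  invisible(path)
}
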