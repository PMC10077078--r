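test_that("qc_filter applies each rule and logs first failures", {
  fx <- qc_fixture()
  res <- qc_filter(fx)
  expect_equal(nrow(res$cohort), 2L)
  expect_setequal(res$cohort$record_id, c("r5", "r6"))
  expect_equal(nrow(res$log), 4L)
  expect_equal(res$log$rule[res$log$record_id == "r1"], "resolution")
  expect_equal(res$log$rule[res$log$record_id == "r2"], "body_part")
  expect_equal(res$log$rule[res$log$record_id == "r3"], "view")
  expect_equal(res$log$rule[res$log$record_id == "r4"], "age")

  # boundary: width 1023 excluded, exactly 16 years old retained
  b <- fx[5, ]; b$width <- 1023L
  expect_equal(qc_filter(b)$log$rule, "resolution")
  sixteen <- fx[5, ]
  sixteen$birth_date <- "2002-06-01"  # 16th birthday on the study date
  expect_equal(nrow(qc_filter(sixteen)$cohort), 1L)
  under <- sixteen; under$study_date <- "2018-05-31"
  expect_equal(qc_filter(under)$log$rule, "age")

  # missing fields exclude with a dedicated reason, never crash
  miss <- fx[5, ]; miss$view <- NA_character_
  expect_equal(qc_filter(miss)$log$rule, "missing_field")

  # idempotence
  once <- qc_filter(fx)$cohort
  expect_identical(qc_filter(once)$cohort, once)

  lg <- tempfile(fileext = ".jsonl")
  write_exclusion_log(res$log, lg)
  expect_length(readLines(lg), 4L)
})

test_that("keyword retention matches any keyword case-insensitively", {
  co <- data.frame(record_id = 1:10,
                   report_text = c("NGT tip projected over bronchus",
                                   "Nasogastric TUBE well sited",
                                   "No acute abnormality",
                                   "Placement satisfactory",
                                   "Clear lungs", "Normal study",
                                   "Heart size normal", "Effusion noted",
                                   NA, ""),
                   stringsAsFactors = FALSE)
  kept <- keyword_filter(co)
  expect_setequal(kept$record_id, c(1, 2, 4))
  expect_error(keyword_filter(co, character(0)), "non-empty")
})

test_that("majority vote returns the 2-of-3 label and flags three-way ties", {
  expect_equal(consensus_label(c("feed", "feed", "feed")), "feed")
  expect_equal(consensus_label(c("feed", "feed", "do_not_feed")), "feed")
  expect_equal(
    consensus_label(c("satisfactory", "malpositioned", "bronchial")),
    "no_consensus")
  expect_error(consensus_label(c("feed", "feed")), "3")

  # permutation invariance over every ordering of a 2-1 vote
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  votes <- c("bronchial", "bronchial", "satisfactory")
  for (p in perms) expect_equal(consensus_label(votes[p]), "bronchial")
})

test_that("grouped split is patient-disjoint, stratified and reproducible", {
  # a single patient's records all land in one split
  one <- data.frame(record_id = paste0("r", 1:10), patient_id = "p1",
                    label = "satisfactory", sex = "F", view = "AP",
                    stringsAsFactors = FALSE)
  sa1 <- suppressWarnings(grouped_stratified_split(one, seed = 2))
  expect_equal(length(unique(sa1$assignment$split)), 1L)

  # 1000 singleton patients: sizes within the multinomial tolerance
  set.seed(42)
  co <- data.frame(record_id = sprintf("r%04d", 1:1000),
                   patient_id = sprintf("p%04d", 1:1000),
                   label = sample(ngt_classes(), 1000, TRUE),
                   sex = sample(c("M", "F"), 1000, TRUE),
                   view = sample(c("AP", "PA"), 1000, TRUE),
                   stringsAsFactors = FALSE)
  sa <- grouped_stratified_split(co, seed = 7)
  sizes <- table(factor(sa$assignment$split,
                        c("train", "validation", "test")))
  expect_lte(abs(sizes[["train"]] - 900), 20)
  expect_lte(abs(sizes[["validation"]] - 50), 10)
  expect_lte(abs(sizes[["test"]] - 50), 10)
  expect_false(sa$flagged)

  # same seed -> identical assignment; partition + patient disjointness
  sa2 <- grouped_stratified_split(co, seed = 7)
  expect_identical(sa$assignment, sa2$assignment)
  expect_setequal(sa$assignment$record_id, co$record_id)
  pat_splits <- tapply(sa$assignment$split, co$patient_id,
                       function(s) length(unique(s)))
  expect_true(all(pat_splits == 1L))

  # multi-record patients stay together under stratification pressure
  co$patient_id <- sprintf("p%04d", rep(1:250, each = 4))
  sa3 <- grouped_stratified_split(co, seed = 9)
  pat_splits3 <- tapply(sa3$assignment$split, co$patient_id,
                        function(s) length(unique(s)))
  expect_true(all(pat_splits3 == 1L))
  expect_gt(length(sa3$multi_stratum_patients), 0L)
})
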