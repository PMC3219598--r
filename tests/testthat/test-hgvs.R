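test_that("insertion names match the published dialect strings", {
  nm <- the_reproduction$names
  get <- function(id) nm$c_description[nm$case_id == id]
  expect_equal(get("UAB-R340101"),
               "c.4319_4320insAluYb8, 4305_4319dupAAAAGAAGAACATAT")
  expect_equal(get("UAB-R81017"),
               "c.4319_4320insAluYa5, 4305_4319dupAAAAGAAGAACATAT")
  expect_equal(get("UAB-R119201"), "c.1186-86_1186-16delinsAluY")
  expect_match(get("UAB-R316001"), "insTGTGAATTinsL1", fixed = TRUE)
  expect_equal(get("UAB-R10408"),
               "c.1642-1_1642insAluY, 1642-11_1642-1dupAAAAAATTCAG")
  expect_match(get("UAB-R01429"), "^c\\.5606_5607insL1\\(Ta\\)")
})

test_that("strict names parse and re-apply to reproduce the mutant", {
  nm <- the_reproduction$names
  truth <- the_fixtures$cases
  for (i in seq_len(nrow(truth))) {
    strict <- nm$c_strict[nm$case_id == truth$case_id[[i]]]
    rebuilt <- apply_mutation_name(strict, the_fixtures$reference, the_model)
    expect_identical(rebuilt, truth$mutant[[i]])
  }
})

test_that("transcript-effect names match the published r. strings", {
  nm <- the_reproduction$names
  get <- function(id) nm$r_description[nm$case_id == id]
  expect_equal(get("UAB-R30609"), "r.2851_2990del")
  expect_equal(get("MUI-2"), "r.[6859_6999del;6938_6999del]")
  expect_equal(get("UAB-R869001"), "r.1355_1392delins61")
  expect_equal(get("UAB-R91409"), "r.889_1062delins130")
  expect_error(name_transcript_effect(list()), "empty")
})

test_that("frame classification follows the divisible-by-3 rule", {
  fr <- function(lost_start, lost_end, gain = 0L) {
    classify_frame(list(list(lost_start = lost_start, lost_end = lost_end,
                             gain = gain)))
  }
  expect_equal(fr(2851, 2990)$frame_status, "OOF")   # 140-nt exon skip
  expect_equal(fr(1186, 1260)$frame_status, "IF")    # 75-nt exon skip
  r <- fr(889, 1062, 130L)                           # delins130, net -44
  expect_equal(r$net_exonic_change, -44L)
  expect_equal(r$frame_status, "OOF")
  # the two printed frame labels inconsistent with the arithmetic are flagged
  flagged <- the_fixtures$cases$case_id[the_fixtures$cases$frame_flagged]
  expect_setequal(flagged, c("UAB-R10408", "MUI-1"))
})

test_that("render_summary joins results per case with deterministic order", {
  rep <- the_reproduction
  s <- rep$summary
  expect_equal(nrow(s), 18L)
  expect_equal(s$left_break, sort(s$left_break))
  expect_true(all(c("family", "region", "splice_types", "en_score",
                    "recurrence_group") %in% names(s)))
  expect_equal(dplyr::n_distinct(s$recurrence_group), 15L)
  # empty input produces a zero-row table, not an error
  empty <- render_summary(rep$calls[0, ])
  expect_equal(nrow(empty), 0L)
})
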