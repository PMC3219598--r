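test_that("find_variant_interval returns the minimal replacement", {
  iv <- find_variant_interval("AAATTTCCC", "AAAGGTTTCCC")
  expect_equal(iv$ref_left, 3L)
  expect_equal(iv$ref_right, 3L)
  expect_equal(substr("AAAGGTTTCCC", iv$mut_left + 1L, iv$mut_right), "GG")
  expect_error(find_variant_interval("ACGT", "ACGT"),
               class = "retrochar_no_variant")
})

test_that("poly tails are measured at the correct end with a minimum run", {
  expect_equal(measure_poly_tail(paste0("GCGC", strrep("A", 120))),
               list(kind = "A-at-3'", length = 120L))
  expect_equal(measure_poly_tail(paste0(strrep("T", 60), "GCGC")),
               list(kind = "T-at-5'", length = 60L))
  expect_equal(measure_poly_tail("ACGT")$kind, "none")
  # a leading poly(T) dominates when both ends carry runs
  both <- paste0(strrep("T", 30), "GCGC", strrep("A", 30))
  expect_equal(measure_poly_tail(both)$kind, "T-at-5'")
})

test_that("fixture TSDs, deletions and orientations are recovered", {
  calls <- the_reproduction$calls
  truth <- the_fixtures$cases
  m <- match(truth$case_id, calls$case_id)
  expect_equal(calls$tsd_length[m], truth$tsd_expected)
  expect_equal(calls$target_deletion_length[m], truth$target_deletion_length)
  expect_equal(calls$orientation[m], truth$orientation)
  expect_equal(calls$poly_tail_length[m], truth$tail_expected)
  # the deletion-associated case: no TSD, 71 deleted bases, leading poly(T)
  del <- calls[calls$case_id == "UAB-R119201", ]
  expect_equal(del$tsd_length, 0L)
  expect_equal(del$target_deletion_length, 71L)
  expect_equal(del$poly_tail_kind, "T-at-5'")
})

test_that("every call replays to the mutant bit-exactly", {
  calls <- the_reproduction$calls
  for (i in seq_len(nrow(calls))) {
    mut <- the_fixtures$cases$mutant[[
      match(calls$case_id[[i]], the_fixtures$cases$case_id)]]
    expect_identical(apply_call(the_fixtures$reference, calls[i, ]), mut)
  }
})

test_that("reported TSDs are maximal at the reported breakpoint", {
  calls <- the_reproduction$calls
  ref <- the_fixtures$reference
  for (i in which(calls$tsd_length > 0L)) {
    cl <- calls[i, ]
    ins <- cl$inserted_seq
    # the reported TSD is a common suffix ...
    expect_identical(substr(ref, cl$left_break - cl$tsd_length + 1L,
                            cl$left_break), cl$tsd_seq)
    expect_identical(substr(ins, nchar(ins) - cl$tsd_length + 1L, nchar(ins)),
                     cl$tsd_seq)
    # ... and extending it by one base breaks the duplication
    ref_prev <- substr(ref, cl$left_break - cl$tsd_length,
                       cl$left_break - cl$tsd_length)
    ins_prev <- substr(ins, nchar(ins) - cl$tsd_length,
                       nchar(ins) - cl$tsd_length)
    expect_false(ref_prev == ins_prev)
  }
})

test_that("orientation inference uses tail then template strand", {
  lib <- the_library
  body <- lib$sequences[["AluYa5"]]
  expect_equal(infer_orientation(paste0(body, strrep("A", 60))), "sense")
  expect_equal(infer_orientation(paste0(strrep("T", 60), revcomp(body))),
               "antisense")
  # tail-less insert matching no template
  expect_equal(infer_orientation("ACGTACGTACGTACGTACGTACGTT", library = lib),
               "undetermined")
  # tail-less element fragment: strand comes from the template anchor
  expect_equal(infer_orientation(substr(body, 1, 150), library = lib), "sense")
})

test_that("blind recovery on simulated pairs matches truth after TSD normalization", {
  sim <- simulate_dataset(25, library = the_library, seed = 99,
                          ref_length = 1200L)
  calls <- characterize_insertions(
    sim$events[, c("case_id", "reference", "mutant")], library = the_library)
  expect_equal(calls$tsd_length, sim$events$tsd_length)
  expect_equal(calls$target_deletion_length,
               sim$events$target_deletion_length)
  expect_equal(calls$orientation, sim$events$orientation)
})
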