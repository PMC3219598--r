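test_that("pick_insertion_site honors the score threshold", {
  # a single perfect bottom-strand site in an otherwise G-only reference
  s <- paste0(strrep("G", 30), "TTAAAA", strrep("G", 30))
  set.seed(1)
  site <- pick_insertion_site(s, strand = "bottom", min_en_score = 6L,
                              margin = 10L)
  expect_equal(site$nick_position, 32L)
  expect_error(pick_insertion_site(strrep("G", 200), min_en_score = 4L),
               class = "retrochar_no_site")
  # every returned site rescored by an independent scan
  set.seed(2)
  ref <- random_dna(5000)
  for (rep in 1:20) {
    site <- pick_insertion_site(ref, min_en_score = 5L)
    expect_gte(score_en_site(ref, site$nick_position,
                             site$strand)$matches, 5L)
  }
})

test_that("construction arithmetic: forced full-length sense event", {
  cfg <- simulation_config(tsd_length_range = c(12L, 12L),
                           polyA_length_range = c(100L, 100L),
                           l1_category_probs = c(1, 0, 0),
                           alu_truncation_prob = 0,
                           target_deletion_prob = 0,
                           nontemplated_addition_prob = 0,
                           sense_prob = 1)
  set.seed(10)
  ref <- random_dna(2000)
  ev <- simulate_insertion(ref, "AluYa5", cfg, the_library)
  tpl_len <- nchar(the_library$sequences[["AluYa5"]])
  expect_equal(nchar(ev$mutant), 2000L + 12L + tpl_len + 100L)
  # the 12 nt preceding the element equal the 12 nt that re-appear after the
  # tail (the TSD copy)
  j <- ev$truth$g_junction
  expect_identical(substr(ev$mutant, j - 11L, j),
                   substr(ev$mutant, j + tpl_len + 101L, j + tpl_len + 112L))
})

test_that("antisense draws lay down a leading poly(T) and an rc body", {
  cfg <- simulation_config(sense_prob = 0, target_deletion_prob = 0,
                           alu_truncation_prob = 0,
                           nontemplated_addition_prob = 0,
                           polyA_length_range = c(80L, 80L))
  set.seed(12)
  ref <- random_dna(2000)
  ev <- simulate_insertion(ref, "AluY", cfg, the_library)
  j <- ev$truth$g_junction
  expect_identical(substr(ev$mutant, j + 1L, j + 80L), strrep("T", 80))
  expect_identical(substr(ev$mutant, j + 81L, j + 80L + 281L),
                   revcomp(the_library$sequences[["AluY"]]))
})

test_that("conservation: removing the insert and one TSD copy restores the reference", {
  sim <- simulate_dataset(50, library = the_library, seed = 31,
                          ref_length = 1500L)
  for (i in seq_len(nrow(sim$events))) {
    ev <- sim$events[i, ]
    diff <- nchar(ev$mutant) - nchar(ev$reference)
    j <- ev$g_junction
    if (ev$target_deletion_length == 0L) {
      spliced <- paste0(substr(ev$mutant, 1L, j),
                        substr(ev$mutant, j + diff + 1L, nchar(ev$mutant)))
      expect_identical(spliced, ev$reference)
      expect_identical(substr(ev$reference, j - ev$tsd_length + 1L, j),
                       ev$tsd_seq)
    } else {
      # flanks around the replaced interval must match exactly
      expect_identical(substr(ev$mutant, 1L, j), substr(ev$reference, 1L, j))
      expect_identical(
        substr(ev$mutant, j + diff + ev$target_deletion_length + 1L,
               nchar(ev$mutant)),
        substr(ev$reference, j + ev$target_deletion_length + 1L,
               nchar(ev$reference)))
    }
    # drawn lengths respect the configured ranges
    if (ev$target_deletion_length == 0L) {
      expect_true(ev$tsd_length >= 7L && ev$tsd_length <= 20L)
    }
    expect_true(ev$polyA_length >= 60L && ev$polyA_length <= 178L)
  }
})

test_that("identical seed and config give byte-identical datasets", {
  tmp <- withr::local_tempdir()
  s1 <- simulate_dataset(8, library = the_library, seed = 77, ref_length = 800L)
  s2 <- simulate_dataset(8, library = the_library, seed = 77, ref_length = 800L)
  expect_identical(s1$events, s2$events)
  p1 <- emit_dataset(s1, file.path(tmp, "a"))
  p2 <- emit_dataset(s2, file.path(tmp, "b"))
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
  expect_equal(nrow(simulate_dataset(1, library = the_library, seed = 1,
                                     ref_length = 800L)$events), 1L)
})

test_that("L1 category frequencies follow the configured probabilities", {
  # scaled-down L1-like template so that many draws stay cheap; only the
  # category draw is under test
  lib2 <- the_library
  lib2$sequences[["L1"]] <- paste0(substr(lib2$sequences[["L1"]], 1, 299), "G")
  lib2$rc_sequences <- vapply(lib2$sequences, revcomp, character(1))
  cfg <- simulation_config(target_deletion_prob = 0,
                           nontemplated_addition_prob = 0)
  set.seed(123)
  ref <- random_dna(1500)
  n <- 3000L
  cats <- character(n)
  for (i in seq_len(n)) {
    cats[[i]] <- simulate_insertion(ref, "L1", cfg, lib2)$truth$category
  }
  p0 <- cfg$l1_category_probs
  for (k in seq_along(p0)) {
    phat <- mean(cats == names(p0)[[k]])
    se <- sqrt(p0[[k]] * (1 - p0[[k]]) / n)
    expect_lt(abs(phat - p0[[k]]), 3 * se)
  }
})

test_that("truth records replay through blind characterization (n = 50)", {
  sim <- simulate_dataset(50, library = the_library, seed = 55,
                          ref_length = 1500L)
  calls <- characterize_insertions(
    sim$events[, c("case_id", "reference", "mutant")], library = the_library)
  expect_equal(calls$tsd_length, sim$events$tsd_length)
  expect_equal(calls$poly_tail_length, sim$events$polyA_length)
  expect_equal(calls$nontemplated_5prime, sim$events$nontemplated_5prime)
})
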