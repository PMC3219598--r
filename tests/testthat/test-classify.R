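test_that("exact consensus bodies classify to their family with distance 0", {
  for (fam in c("AluY", "AluYa5", "AluYb8", "L1")) {
    cl <- classify_family(the_library$sequences[[fam]], the_library)
    expect_equal(cl$family, fam)
    expect_equal(cl$distance, 0)
    expect_equal(cl$truncation_offset, 0L)
  }
})

test_that("fixture bodies tally 2 AluY, 6 AluYa5, 6 AluYb8 and one polyN", {
  fams <- table(the_reproduction$calls$family)
  expect_equal(unname(fams[["AluY"]]), 2L)
  expect_equal(unname(fams[["AluYa5"]]), 6L)
  expect_equal(unname(fams[["AluYb8"]]), 6L)
  expect_equal(unname(fams[["L1"]]), 3L)
  expect_equal(unname(fams[["polyN"]]), 1L)
})

test_that("homopolymer bodies are classed polyN", {
  expect_equal(classify_family(strrep("T", 120), the_library)$family, "polyN")
  expect_equal(classify_family("", the_library)$family, "polyN")
})

test_that("strand symmetry: the reverse complement classifies to the same family", {
  for (fam in c("AluY", "AluYa5", "AluYb8")) {
    body <- substr(the_library$sequences[[fam]], 25, 260)
    f <- classify_family(body, the_library)
    r <- classify_family(revcomp(body), the_library)
    expect_equal(f$family, fam)
    expect_equal(r$family, fam)
    expect_equal(f$strand, "+")
    expect_equal(r$strand, "-")
  }
})

test_that("k substitutions raise the distance by at most k", {
  set.seed(11)
  for (rep in 1:8) {
    fam <- sample(c("AluY", "AluYa5", "AluYb8"), 1)
    body <- the_library$sequences[[fam]]
    k <- sample(1:4, 1)
    pos <- sample(30:250, k)   # away from the anchor head
    bv <- strsplit(body, "")[[1L]]
    for (p in pos) bv[p] <- setdiff(c("A", "C", "G", "T"), bv[p])[1]
    cl <- classify_family(paste(bv, collapse = ""), the_library)
    expect_lte(cl$distance, k)
    expect_equal(cl$family, fam)
  }
})

test_that("family ties are reported as unknown", {
  lib2 <- the_library
  lib2$sequences <- c(lib2$sequences["AluY"], twin = lib2$sequences[["AluY"]])
  lib2$rc_sequences <- vapply(lib2$sequences, revcomp, character(1))
  cl <- classify_family(substr(lib2$sequences[[1]], 10, 250), lib2)
  expect_equal(cl$family, "unknown")
})

test_that("an empty library is a configuration error", {
  lib0 <- the_library
  lib0$sequences <- character()
  expect_error(classify_family("ACGTACGTACGTACGTACGTACG", lib0),
               class = "retrochar_config_error")
})

test_that("truncation offsets are measured exactly", {
  yb8 <- the_library$sequences[["AluYb8"]]
  expect_equal(measure_truncation(substr(yb8, 40, nchar(yb8)), yb8), 39L)
  expect_equal(measure_truncation(yb8, yb8), 0L)
  # the exon 12 (10a) fixture lacks the first 39 bp of its element
  calls <- the_reproduction$calls
  expect_equal(calls$truncation_offset[calls$case_id == "UAB-R869001"], 39L)
  # simulated truncations recover exactly
  set.seed(5)
  for (rep in 1:20) {
    fam <- sample(c("AluY", "AluYa5", "AluYb8", "L1"), 1)
    tpl <- the_library$sequences[[fam]]
    t <- sample(1:(nchar(tpl) - 60), 1)
    expect_equal(measure_truncation(substr(tpl, t + 1, nchar(tpl)), tpl), t)
  }
})

test_that("5' inversions are detected with their junction microhomology", {
  l1 <- the_library$sequences[["L1"]]
  # non-inverted body
  expect_false(detect_inversion(substr(l1, 100, 2000), l1)$inversion)
  # forced 2-bp microhomology
  set.seed(21)
  inv <- simulate_inverted_l1(l1, microhomology = 2L)
  d <- detect_inversion(inv$body, l1)
  expect_true(d$inversion)
  expect_equal(d$microhomology_length, 2L)
  # clean junction: the segments partition the covered template interval
  inv0 <- simulate_inverted_l1(l1, microhomology = 0L)
  d0 <- detect_inversion(inv0$body, l1)
  expect_true(d0$inversion)
  expect_equal(d0$microhomology_length, 0L)
  expect_equal(d0$seg3_start, d0$seg5_end + 1L)
  # random draws: segments always reconstruct the template intervals
  for (rep in 1:10) {
    inv <- simulate_inverted_l1(l1)
    expect_identical(revcomp(substr(inv$body, 1,
                                    inv$seg5[2] - inv$seg5[1] + 1)),
                     substr(l1, inv$seg5[1], inv$seg5[2]))
    d <- detect_inversion(inv$body, l1)
    expect_true(d$inversion)
    expect_equal(d$microhomology_length, inv$microhomology)
    expect_equal(c(d$seg5_start, d$seg5_end), inv$seg5)
    expect_equal(c(d$seg3_start, d$seg3_end), inv$seg3)
  }
})

test_that("the L1 subset is typed from the diagnostic trinucleotide", {
  l1 <- the_library$sequences[["L1"]]
  ds <- the_library$meta$L1$ta_diagnostic_start
  expect_equal(l1_subset(l1, the_library, 0L), "Ta")
  body <- substr(l1, 3001, nchar(l1))
  body_g <- body
  substr(body_g, ds - 3000 + 2, ds - 3000 + 2) <- "G"
  expect_equal(l1_subset(body_g, the_library, 3000L), "preTa")
  # body not covering the site
  expect_equal(l1_subset(substr(l1, 1, 3000), the_library, 0L), "n/a")
  # the two L1 fixtures type as the running text assigns them
  calls <- the_reproduction$calls
  expect_equal(calls$l1_subset[calls$case_id == "UAB-R316001"], "preTa")
  expect_equal(calls$l1_subset[calls$case_id == "UAB-R01429"], "Ta")
  # the inverted element does not cover the site
  expect_equal(calls$l1_subset[calls$case_id == "UAB-R91409"], "n/a")
})

test_that("the inverted fixture is recognized with 2-bp microhomology", {
  calls <- the_reproduction$calls
  r <- calls[calls$case_id == "UAB-R91409", ]
  expect_true(r$inversion)
  expect_equal(r$microhomology_length, 2L)
  expect_equal(r$family, "L1")
  expect_equal(sum(calls$inversion), 1L)
})
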