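# independent brute-force EN scoring oracle (string comparison, separate code
# path from the vectorized scan)
brute_en <- function(seq, j, strand) {
  x <- strsplit(seq, "")[[1L]]
  if (strand == "bottom") {
    win <- x[(j - 1L):(j + 4L)]
    sum(win == c("T", "T", "A", "A", "A", "A"))
  } else {
    win <- x[(j - 3L):(j + 2L)]
    sum(win == c("T", "T", "T", "T", "A", "A"))
  }
}

test_that("a perfect consensus site scores 6", {
  s <- paste0("GGGG", "TTAAAA", "GGGG")   # bottom-strand consensus at j = 6
  sc <- score_en_site(s, 6L, "bottom")
  expect_equal(sc$matches, 6L)
  expect_equal(sc$motif_window, "AATTTT")
  st <- paste0("GGGG", "TTTTAA", "GGGG")  # top-strand consensus at j = 8
  expect_equal(score_en_site(st, 8L, "top")$matches, 6L)
  expect_error(score_en_site("ACGT", 1L, "bottom"),
               class = "retrochar_coordinate_error")
})

test_that("the exon 33 (25) printed window scores 4 of 6 under strict counting", {
  # the published window reads ...AAGTG TTTTC... on the nicked strand 3'->5':
  # downstream TTTT matches, the upstream dinucleotide TG does not
  calls <- the_reproduction$calls
  nick <- calls$nick_position[calls$case_id == "UAB-R81017"]
  sc <- score_en_site(the_fixtures$reference, nick, "bottom")
  expect_equal(sc$matches, 4L)
})

test_that("the vectorized scan equals the brute-force recount", {
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  sc <- en_site_scan(s)
  for (k in sample(nrow(sc), 200)) {
    expect_equal(sc$matches[[k]],
                 brute_en(s, sc$nick_position[[k]], sc$strand[[k]]))
  }
})

test_that("EN scoring is invariant under reverse complement with strand swap", {
  set.seed(4)
  s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  rs <- revcomp(s)
  L <- nchar(s)
  for (j in sample(10:(L - 10), 50)) {
    expect_equal(score_en_site(s, j, "bottom")$matches,
                 score_en_site(rs, L - j, "top")$matches)
  }
})

test_that("nick inference puts the priming T-run 3' of the nick", {
  calls <- the_reproduction$calls
  truth <- the_fixtures$cases
  m <- match(truth$case_id, calls$case_id)
  expect_equal(calls$nick_strand[m],
               ifelse(truth$orientation == "sense", "bottom", "top"))
  expect_equal(calls$nick_position[m], truth$nick_g)
  # the two intron 14 (10c) events used the same cleavage locus on opposite
  # strands
  pair <- calls[calls$case_id %in% c("UAB-R10408", "UAB-R164201"), ]
  expect_equal(pair$nick_position[[1]], pair$nick_position[[2]])
  expect_setequal(pair$nick_strand, c("bottom", "top"))
  # deletion-associated nick is tentative
  expect_true(calls$nick_tentative[calls$case_id == "UAB-R119201"])
})

test_that("sites annotate as exonic / splice-region / deep-intronic correctly", {
  calls <- the_reproduction$calls
  ann <- function(id, col) calls[[col]][calls$case_id == id]
  expect_equal(ann("UAB-R10408", "splice_region_class"), "canonical-AG")
  expect_equal(ann("UAB-R164201", "splice_region_class"), "polypyrimidine-tract")
  expect_equal(ann("UAB-R07118", "splice_region_class"), "polypyrimidine-tract")
  expect_equal(ann("UAB-R119201", "splice_region_class"), "polypyrimidine-tract")
  expect_equal(ann("UAB-R37305", "region"), "exonic")
  expect_equal(ann("UAB-R37305", "feature_index"), 21L)
  expect_equal(ann("UAB-R91409", "region"), "intronic")
  expect_equal(ann("UAB-R91409", "splice_region_class"), "none")
  expect_equal(sum(calls$region == "exonic"), 13L)
})

test_that("recurrence grouping finds 15 sites with three used twice", {
  rec <- the_reproduction$recurrence
  expect_equal(rec$n_distinct_sites, 15L)
  expect_equal(rec$n_multiply_used, 3L)
  expect_equal(sort(rec$groups$n, decreasing = TRUE)[1:3], c(2L, 2L, 2L))
  # groups partition the calls
  expect_equal(nrow(rec$groups) + sum(rec$groups$n - 1L), 18L)
  twice <- rec$groups$case_ids[rec$groups$n == 2L]
  expect_setequal(lapply(twice, sort),
                  list(c("UAB-R10408", "UAB-R164201"),
                       c("UAB-R37305", "UAB-R37616"),
                       c("UAB-R340101", "UAB-R81017")))
  # a single call is its own group
  one <- find_recurrent_sites(tibble::tibble(case_id = "x",
                                             nick_position = 100L))
  expect_equal(one$n_distinct_sites, 1L)
})

test_that("cluster detection finds the single 6-insertion window", {
  cl <- the_reproduction$clusters
  expect_equal(nrow(cl$windows), 1L)
  expect_equal(cl$windows$n, 6L)
  expect_lte(cl$windows$end - cl$windows$start, 1500L)
  expect_setequal(cl$windows$case_ids[[1]],
                  c("UAB-R37305", "UAB-R37616", "UAB-R30609", "UAB-R39428",
                    "UAB-R50109", "UAB-R316001"))
  # calls farther apart than the window produce no cluster
  far <- tibble::tibble(case_id = letters[1:3],
                        nick_position = c(0L, 2000L, 4000L))
  expect_equal(nrow(find_clusters(far)$windows), 0L)
})

test_that("greedy clustering agrees with an exhaustive scan on random input", {
  set.seed(8)
  for (rep in 1:10) {
    pos <- sort(sample(1:20000, 40))
    calls <- tibble::tibble(case_id = as.character(seq_along(pos)),
                            nick_position = pos)
    got <- find_clusters(calls, window_bp = 1500L, min_count = 3L)$windows
    # exhaustive left-to-right recomputation
    exp_wins <- list()
    i <- 1L
    while (i <= length(pos)) {
      members <- which(pos >= pos[i] & pos <= pos[i] + 1500L)
      if (length(members) >= 3L) {
        exp_wins[[length(exp_wins) + 1L]] <-
          c(min(pos[members]), max(pos[members]), length(members))
        i <- max(members) + 1L
      } else i <- i + 1L
    }
    if (length(exp_wins)) {
      expect_equal(nrow(got), length(exp_wins))
      for (k in seq_along(exp_wins)) {
        expect_equal(c(got$start[[k]], got$end[[k]], got$n[[k]]),
                     exp_wins[[k]])
      }
    } else {
      expect_equal(nrow(got), 0L)
    }
  }
})
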