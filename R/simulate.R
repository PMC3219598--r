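#' Simulation configuration for TPRT products
#'
#' Defaults encode the study conditions reported for L1 EN-mediated de novo
#' insertions: TSDs of 7-20 bp, poly(A)/poly(T) tails of 60-178 bp, L1
#' category probabilities 25.5% full-length / 43.8% 5'-truncated / 30.7%
#' 5'-inverted, ~8% truncated Alu inserts, and small probabilities for
#' target-site-deletion events (no TSD) and non-templated 5' additions.
#' Lengths are drawn uniformly over the configured integer ranges.
#'
#' @param tsd_length_range,polyA_length_range,target_deletion_range,nt5_length_range
#'   Integer ranges (inclusive) for the corresponding lengths.
#' @param l1_category_probs Probabilities of a full-length / 5'-truncated /
#'   5'-inverted L1 (must sum to 1).
#' @param alu_truncation_prob Probability that an Alu insert is 5'-truncated.
#' @param target_deletion_prob Probability of the target-site-deletion branch
#'   (second nick upstream of the first; no TSD).
#' @param nontemplated_addition_prob Probability of a random non-templated
#'   5' addition.
#' @param sense_prob Probability of sense orientation.
#' @param family_probs Named sampling weights over the template families
#'   (`polyN` simulates a bare poly(A)/poly(T) stretch); defaults follow the
#'   observed family mixture.
#' @param polyA_impurity Fraction of non-A bases tolerated in tails (0 =
#'   pure tails).
#' @param microhomology_range Junction microhomology range for 5'-inverted
#'   L1 bodies.
#' @param min_en_score Minimum EN consensus score of a usable nick site.
#' @param min_tail Minimum run length the characterizer calls a tail (used
#'   by the event-canonicality guards).
#' @return A list of class `tprt_config`.
#' @export
simulation_config <- function(tsd_length_range = c(7L, 20L),
                              polyA_length_range = c(60L, 178L),
                              l1_category_probs = c(full = 0.255,
                                                    truncated = 0.438,
                                                    inverted = 0.307),
                              alu_truncation_prob = 0.08,
                              target_deletion_prob = 0.05,
                              nontemplated_addition_prob = 0.05,
                              sense_prob = 0.5,
                              family_probs = c(AluY = 2, AluYa5 = 6,
                                               AluYb8 = 6, L1 = 3, polyN = 1),
                              polyA_impurity = 0,
                              target_deletion_range = c(10L, 100L),
                              nt5_length_range = c(1L, 10L),
                              microhomology_range = c(0L, 4L),
                              min_en_score = 4L,
                              min_tail = 10L) {
  stopifnot(length(l1_category_probs) == 3L,
            abs(sum(l1_category_probs) - 1) < 1e-8,
            all(c(alu_truncation_prob, target_deletion_prob,
                  nontemplated_addition_prob, sense_prob) >= 0),
            all(c(alu_truncation_prob, target_deletion_prob,
                  nontemplated_addition_prob, sense_prob) <= 1),
            diff(tsd_length_range) >= 0, diff(polyA_length_range) >= 0)
  structure(as.list(environment()), class = "tprt_config")
}

runif_int <- function(range) {
  v <- seq(range[[1L]], range[[2L]])
  if (length(v) == 1L) return(as.integer(v))   # sample(n, 1) would draw 1:n
  as.integer(sample(v, 1L))
}

#' Pick an EN-consistent insertion site
#'
#' Scans the reference for nick positions whose EN consensus score reaches
#' `min_en_score` on the requested strand and samples one uniformly.
#'
#' @param reference Top-strand reference sequence.
#' @param strand `"both"`, `"top"` or `"bottom"`.
#' @param min_en_score Minimum match count (0-6).
#' @param margin Bases excluded at each end of the reference.
#' @return A list with `nick_position` (0-based junction) and `strand`.
#'   Signals a `retrochar_no_site` error when no position qualifies.
#' @export
pick_insertion_site <- function(reference, strand = "both", min_en_score = 4L,
                                margin = 150L) {
  if (nchar(reference) < 40L) abort("reference too short",
                                    class = "retrochar_no_site")
  sc <- en_site_scan(reference, strand = strand)
  sc <- sc[sc$matches >= min_en_score &
             sc$nick_position >= margin &
             sc$nick_position <= nchar(reference) - margin, ]
  if (nrow(sc) == 0L) {
    abort("no qualifying EN site in the reference",
          class = "retrochar_no_site")
  }
  k <- sample.int(nrow(sc), 1L)
  list(nick_position = sc$nick_position[[k]], strand = sc$strand[[k]])
}

#' Build a 5'-inverted (twin-primed) L1 body
#'
#' Joins the reverse complement of a 5' template segment to a forward 3'
#' segment ending at the template's 3' end, with a junction microhomology of
#' 0-4 bp (segments overlap on the template by the microhomology length).
#'
#' @param template Element template sequence (length >= 200).
#' @param microhomology Junction microhomology (drawn from
#'   `microhomology_range` when `NULL`).
#' @param min_seg Minimum segment length.
#' @param microhomology_range Range to draw from when `microhomology` is NULL.
#' @return A list with `body`, `seg5` (template interval of the
#'   reverse-complemented segment), `seg3`, and `microhomology`.
#' @export
simulate_inverted_l1 <- function(template, microhomology = NULL,
                                 min_seg = 100L,
                                 microhomology_range = c(0L, 4L)) {
  n <- nchar(template)
  stopifnot(n >= 200L)
  mh <- microhomology %||% runif_int(microhomology_range)
  for (try in 1:100) {
    b1 <- runif_int(c(max(min_seg + 5L, floor(n * 0.3)), floor(n * 0.7)))
    a2 <- b1 - 1L + mh
    a1 <- runif_int(c(max(1L, a2 - 3L * min_seg), a2 - min_seg))
    # the base flanking the junction must not extend either segment's match,
    # or the measured microhomology would exceed the drawn one
    ok <- complement_chr(substr(template, a1, a1)) !=
      substr(template, b1 - 1L, b1 - 1L) &&
      (a2 >= n || complement_chr(substr(template, a2 + 1L, a2 + 1L)) !=
         substr(template, b1, b1))
    if (ok) break
  }
  body <- paste0(revcomp(substr(template, a1, a2)), substr(template, b1, n))
  list(body = body, seg5 = c(a1, a2), seg3 = c(b1, n), microhomology = mh)
}

# canonicality guards: the drawn event must be exactly recoverable from the
# sequences alone (flank coincidences that would lengthen the measured TSD or
# tail are rejected and the site redrawn)
event_is_canonical <- function(reference, nick, orientation, tsd_len, del_len,
                               cassette, config, polyA, body_prev_char = "") {
  first_c <- substr(cassette, 1L, 1L)
  last_c <- substr(cassette, nchar(cassette), nchar(cassette))
  leadT <- run_length(cassette, "T", "start")
  trailA <- run_length(cassette, "A", "end")
  min_tail <- config$min_tail
  if (del_len > 0L) {
    d1 <- nick + 1L; d2 <- nick + del_len
    if (substr(reference, d1, d1) == first_c) return(FALSE)
    if (substr(reference, d2, d2) == last_c) return(FALSE)
  } else if (orientation == "sense") {
    # nick at left TSD edge; TSD = [nick+1, nick+tsd]; junction after the TSD
    if (substr(reference, nick, nick) == last_c) return(FALSE)
    rpos <- nick + tsd_len + 1L
    if (substr(reference, rpos, rpos) == first_c) return(FALSE)
    # a truncated element whose missing 5' base equals the TSD's last base
    # makes the element/TSD attribution ambiguous
    if (nzchar(body_prev_char) &&
        substr(reference, nick + tsd_len, nick + tsd_len) == body_prev_char) {
      return(FALSE)
    }
  } else {
    # nick at the junction; TSD = [nick-tsd+1, nick]
    lpos <- nick - tsd_len
    if (substr(reference, lpos, lpos) == last_c) return(FALSE)
    if (substr(reference, nick + 1L, nick + 1L) == first_c) return(FALSE)
  }
  TRUE
}

#' Simulate one TPRT insertion
#'
#' Draws orientation, element category (truncation/inversion), tail and TSD
#' (or target deletion) lengths per the configuration, picks an
#' EN-consistent site on the strand matching the orientation, and builds the
#' mutant: `[TSD] [non-templated addition] [element body,
#' reverse-complemented for antisense] [tail] [TSD copy]` on the top strand
#' (a leading poly(T) for antisense events), or a replacement with no TSD on
#' the target-deletion branch.
#'
#' @param reference Top-strand reference sequence.
#' @param template_name Family name in `library`, or `"polyN"` for a bare
#'   poly(A)/poly(T) stretch.
#' @param config A [simulation_config()].
#' @param library An [element_library()].
#' @param max_tries Site redraws allowed before giving up.
#' @return A list with `mutant` and `truth` (one-row tibble of every drawn
#'   quantity).
#' @export
simulate_insertion <- function(reference, template_name, config = simulation_config(),
                               library = element_library(), max_tries = 100L) {
  orientation <- if (stats::runif(1) < config$sense_prob) "sense" else "antisense"
  polyA <- runif_int(config$polyA_length_range)
  is_del <- stats::runif(1) < config$target_deletion_prob
  tsd_len <- if (is_del) 0L else runif_int(config$tsd_length_range)
  del_len <- if (is_del) runif_int(config$target_deletion_range) else 0L

  trunc <- 0L
  inv <- NULL
  category <- "full"
  if (template_name == "polyN") {
    body <- ""
    category <- "polyN"
  } else {
    tpl <- library_template(library, template_name)
    if (template_name == "L1") {
      category <- sample(c("full", "truncated", "inverted"), 1L,
                         prob = config$l1_category_probs)
    } else if (stats::runif(1) < config$alu_truncation_prob) {
      category <- "truncated"
    }
    if (category == "truncated") {
      trunc <- runif_int(c(1L, nchar(tpl) - 50L))
      body <- substr(tpl, trunc + 1L, nchar(tpl))
    } else if (category == "inverted") {
      inv <- simulate_inverted_l1(tpl, microhomology_range = config$microhomology_range)
      body <- inv$body
      trunc <- NA_integer_
    } else {
      body <- tpl
    }
  }
  nt5 <- ""
  if (category %in% c("full", "truncated") && template_name != "polyN" &&
      stats::runif(1) < config$nontemplated_addition_prob) {
    nt5 <- random_dna(runif_int(config$nt5_length_range), gc = 0.5)
    if (trunc > 0L) {
      # an addition ending in the template base at the truncation point would
      # be indistinguishable from one more element base
      while (substr(nt5, nchar(nt5), nchar(nt5)) ==
             substr(tpl, trunc, trunc)) {
        nt5 <- random_dna(runif_int(config$nt5_length_range), gc = 0.5)
      }
    }
  }
  tail_seq <- strrep("A", polyA)
  if (config$polyA_impurity > 0) {
    flip <- which(stats::runif(polyA) < config$polyA_impurity)
    if (length(flip)) {
      tv <- strsplit(tail_seq, "")[[1L]]
      tv[flip] <- sample(c("C", "G", "T"), length(flip), replace = TRUE)
      tail_seq <- paste(tv, collapse = "")
    }
  }
  cassette <- if (orientation == "sense") {
    paste0(nt5, body, tail_seq)
  } else {
    paste0(str_rev(chartr("ACGTN", "TGCAN", tail_seq)),
           if (nchar(paste0(nt5, body))) revcomp(paste0(nt5, body)) else "")
  }
  # the drawn tail must be exactly the run the characterizer will measure;
  # a body whose edge happens to extend the tail (or fake one) forces a
  # complete redraw of the event
  tail_ok <- if (config$polyA_impurity > 0) TRUE else if (orientation == "sense") {
    run_length(cassette, "T", "start") < config$min_tail &&
      run_length(cassette, "A", "end") == polyA
  } else {
    run_length(cassette, "T", "start") == polyA
  }
  if (!tail_ok) {
    if (max_tries <= 0L) {
      abort("cannot draw a canonical event for this template/config")
    }
    return(simulate_insertion(reference, template_name, config, library,
                              max_tries = max_tries - 1L))
  }

  want_strand <- if (orientation == "sense") "bottom" else "top"
  for (try in seq_len(max_tries)) {
    site <- pick_insertion_site(reference, strand = want_strand,
                                min_en_score = config$min_en_score)
    nick <- site$nick_position
    body_prev <- if (!is.na(trunc) && trunc > 0L && template_name != "polyN") {
      substr(library_template(library, template_name), trunc, trunc)
    } else ""
    if (event_is_canonical(reference, nick, orientation, tsd_len, del_len,
                           cassette, config, polyA, body_prev)) break
    if (try == max_tries) abort("no canonical site found; reference too adverse")
  }
  L <- nchar(reference)
  if (is_del) {
    mutant <- paste0(substr(reference, 1L, nick), cassette,
                     substr(reference, nick + del_len + 1L, L))
    junction <- nick
    tsd_seq <- ""
  } else if (orientation == "sense") {
    tsd_seq <- substr(reference, nick + 1L, nick + tsd_len)
    junction <- nick + tsd_len
    mutant <- paste0(substr(reference, 1L, junction), cassette, tsd_seq,
                     substr(reference, junction + 1L, L))
  } else {
    tsd_seq <- substr(reference, nick - tsd_len + 1L, nick)
    junction <- nick
    mutant <- paste0(substr(reference, 1L, junction), cassette, tsd_seq,
                     substr(reference, junction + 1L, L))
  }
  truth <- tibble::tibble(
    site_offset = nick, nick_strand = want_strand,
    orientation = orientation, element = template_name, category = category,
    tsd_length = tsd_len, tsd_seq = tsd_seq,
    target_deletion_length = del_len,
    truncation_offset = trunc,
    inversion = !is.null(inv),
    microhomology_length = if (!is.null(inv)) inv$microhomology else NA_integer_,
    seg5_start = if (!is.null(inv)) inv$seg5[[1L]] else NA_integer_,
    seg5_end = if (!is.null(inv)) inv$seg5[[2L]] else NA_integer_,
    seg3_start = if (!is.null(inv)) inv$seg3[[1L]] else NA_integer_,
    seg3_end = if (!is.null(inv)) inv$seg3[[2L]] else NA_integer_,
    polyA_length = polyA, nontemplated_5prime = nt5,
    g_junction = junction
  )
  list(mutant = mutant, truth = truth)
}

#' Simulate a dataset of TPRT insertions with ground truth
#'
#' @param n Number of events (each on its own random reference).
#' @param config A [simulation_config()].
#' @param library An [element_library()].
#' @param seed Seed for reproducibility (`NULL` to use the current RNG
#'   state). Identical `n`/`config`/`seed` give identical datasets.
#' @param ref_length,ref_gc Length and GC content of the per-event random
#'   references.
#' @return An object of class `tprt_simulation`: list with `events` (tibble:
#'   `case_id`, `reference`, `mutant`, and all truth columns) and `config`.
#' @export
simulate_dataset <- function(n, config = simulation_config(),
                             library = element_library(), seed = NULL,
                             ref_length = 3000L, ref_gc = 0.5) {
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  fams <- names(config$family_probs)
  events <- purrr::map_dfr(seq_len(n), function(i) {
    fam <- sample(fams, 1L, prob = config$family_probs)
    repeat {
      reference <- random_dna(ref_length, gc = ref_gc)
      ev <- tryCatch(simulate_insertion(reference, fam, config, library),
                     retrochar_no_site = function(e) NULL)
      if (!is.null(ev)) {
        return(dplyr::bind_cols(
          tibble::tibble(case_id = sprintf("sim%04d", i),
                         reference = reference, mutant = ev$mutant),
          ev$truth))
      }
    }
  })
  structure(list(events = events, config = config),
            class = "tprt_simulation")
}

#' Write a simulated dataset to disk
#'
#' Emits `<prefix>_ref.fa` and `<prefix>_mut.fa` (references and mutants)
#' plus `<prefix>_truth.tsv`. Outputs are byte-identical for identical
#' configuration and seed.
#'
#' @param sim A `tprt_simulation` from [simulate_dataset()].
#' @param out_prefix Path prefix for the three output files.
#' @return Named character vector of the written paths, invisibly.
#' @export
emit_dataset <- function(sim, out_prefix) {
  ev <- sim$events
  paths <- c(ref = paste0(out_prefix, "_ref.fa"),
             mut = paste0(out_prefix, "_mut.fa"),
             truth = paste0(out_prefix, "_truth.tsv"))
  write_fasta(tibble::tibble(id = ev$case_id, seq = ev$reference), paths[["ref"]])
  write_fasta(tibble::tibble(id = ev$case_id, seq = ev$mutant), paths[["mut"]])
  readr::write_tsv(dplyr::select(ev, -"reference", -"mutant"), paths[["truth"]])
  invisible(paths)
}
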