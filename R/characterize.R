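#' Locate the minimal variant interval between two alleles
#'
#' Trims the maximal common prefix and suffix and returns the minimal
#' contiguous replacement, placed as far 3' (rightmost) as the prefix allows.
#' When the alleles share sequence across the junction the placement is
#' ambiguous; [characterize_insertion()] resolves that ambiguity
#' biologically.
#'
#' @param reference,mutant Uppercase DNA strings.
#' @return A list with 0-based half-open interval fields `ref_left`,
#'   `ref_right`, `mut_left`, `mut_right`, plus `prefix`, `suffix` (the
#'   untrimmed maximal common prefix/suffix lengths) and `shift_room` (how
#'   far the replacement can slide left while describing the same mutant).
#' @export
find_variant_interval <- function(reference, mutant) {
  if (identical(reference, mutant)) {
    abort("sequences are identical: no variant", class = "retrochar_no_variant")
  }
  a <- lcp_len(reference, mutant)
  b <- lcs_len(reference, mutant)
  R <- nchar(reference); M <- nchar(mutant)
  b_c <- min(b, R - a, M - a)
  list(ref_left = a, ref_right = R - b_c,
       mut_left = a, mut_right = M - b_c,
       prefix = a, suffix = b,
       shift_room = max(0L, a + b - min(R, M)))
}

# anchor an element body (5'->3') in the library by exact k-mer search:
# smallest non-templated 5' addition d such that the 20-mer at offset d hits a
# template; returns the best-supported family, truncation offset, nt5 length,
# strand, and the number of verified matching bases
template_anchor <- function(body, library, strand = c("both", "fwd"),
                            k = 20L, max_nt5 = 12L) {
  strand <- match.arg(strand)
  n <- nchar(body)
  if (is.null(library) || n < k) return(NULL)
  for (d in 0:min(max_nt5, n - k)) {
    kmer <- substr(body, d + 1L, d + k)
    best <- NULL
    for (fam in names(library$sequences)) {
      tpl_f <- library$sequences[[fam]]
      cand <- list(c(regexpr(kmer, tpl_f, fixed = TRUE), "+"))
      if (strand == "both") {
        cand <- c(cand,
                  list(c(regexpr(kmer, library$rc_sequences[[fam]],
                                 fixed = TRUE), "-")))
      }
      for (cc in cand) {
        q <- as.integer(cc[[1L]])
        if (q > 0L) {
          tpl <- if (cc[[2L]] == "+") tpl_f else library$rc_sequences[[fam]]
          # verified extension beyond the anchor
          ext <- lcp_len(substr(body, d + 1L, n), substr(tpl, q, nchar(tpl)))
          hit <- list(family = fam, truncation = q - 1L, nt5_length = d,
                      strand = cc[[2L]], verified = ext)
          if (is.null(best) || ext > best$verified) best <- hit
        }
      }
    }
    if (!is.null(best)) return(best)
  }
  NULL
}

# evaluate one candidate placement of a pure insertion
eval_placement <- function(reference, p, inserted, library, min_tail,
                           impurity, shift = 0L, allow_tsd = TRUE) {
  tsd_len <- if (allow_tsd) {
    min(lcs_len(substr(reference, 1L, p), inserted), nchar(inserted))
  } else 0L
  tsd <- if (tsd_len > 0L) substr(inserted, nchar(inserted) - tsd_len + 1L,
                                  nchar(inserted)) else ""
  cassette <- substr(inserted, 1L, nchar(inserted) - tsd_len)
  tl <- measure_poly_tail(cassette, min_run = min_tail, impurity = impurity)
  if (tl$kind == "T-at-5'") {
    core <- substr(cassette, tl$length + 1L, nchar(cassette))
    body_fwd <- if (nchar(core)) revcomp(core) else ""
    orientation <- "antisense"
  } else if (tl$kind == "A-at-3'") {
    body_fwd <- substr(cassette, 1L, nchar(cassette) - tl$length)
    orientation <- "sense"
  } else {
    body_fwd <- cassette
    orientation <- "undetermined"
  }
  anchor <- template_anchor(body_fwd, library,
                            strand = if (orientation == "undetermined") "both" else "fwd")
  list(p = p, shift = shift, tsd_length = tsd_len, tsd_seq = tsd,
       cassette = cassette, inserted = inserted,
       tail_kind = tl$kind, tail_length = tl$length,
       orientation = orientation, body_fwd = body_fwd, anchor = anchor)
}

#' Characterize a mutant allele against its reference
#'
#' The core TPRT-product reading: finds the variant interval, resolves the
#' target-site duplication (TSD) or target-site deletion, measures the
#' poly(A)/poly(T) tail, extracts the element body and any non-templated 5'
#' addition, and infers the insert orientation.
#'
#' Breakpoint placement is ambiguous whenever the insert shares sequence with
#' the flanks (e.g. the element head equals the reference bases after the
#' junction). Candidate placements are ranked by (1) minimal 5' truncation of
#' the body against the element library, (2) maximal duplicated flank (TSD),
#' (3) maximal tail length, (4) leftmost position; the winner is reported with the insertion
#' point after the first duplicated copy, the convention used for all HGVS
#' output.
#'
#' @param reference,mutant Uppercase DNA strings (alleles of one locus).
#' @param library An [element_library()] used to anchor element bodies, or
#'   `NULL` to rank placements by tail/TSD only.
#' @param min_tail Minimum homopolymer run length accepted as a tail.
#' @param tail_impurity Tolerated non-A (non-T) fraction within a tail run.
#' @return A one-row tibble (an "insertion call"): 0-based half-open deleted
#'   reference interval `left_break`/`right_break` (equal for pure
#'   insertions), `inserted_seq`, `tsd_seq`, `tsd_length`,
#'   `target_deletion_length`, `poly_tail_kind` (`A-at-3'`, `T-at-5'`,
#'   `none`), `poly_tail_length`, `orientation`, `nontemplated_5prime`,
#'   `body_seq` (element body 5'->3' where orientation is known),
#'   `family_hint` and `truncation_hint` from the library anchor.
#' @export
characterize_insertion <- function(reference, mutant, library = NULL,
                                   min_tail = 10L, tail_impurity = 0) {
  iv <- find_variant_interval(reference, mutant)
  R <- nchar(reference); M <- nchar(mutant)
  del_len <- iv$ref_right - iv$ref_left
  if (del_len > 0L) {
    # replacement: no TSD by definition; single placement
    inserted <- substr(mutant, iv$mut_left + 1L, iv$mut_right)
    chosen <- eval_placement(reference, iv$ref_left, inserted, library,
                             min_tail, tail_impurity, allow_tsd = FALSE)
    left <- iv$ref_left; right <- iv$ref_right
  } else {
    ins_len <- M - R
    room <- iv$shift_room
    cands <- lapply(0:room, function(s) {
      p <- iv$ref_left - s
      eval_placement(reference, p,
                     substr(mutant, p + 1L, p + ins_len), library,
                     min_tail, tail_impurity, shift = s)
    })
    trunc_rank <- vapply(cands, function(e) {
      if (is.null(e$anchor)) Inf else as.numeric(e$anchor$truncation + e$anchor$nt5_length)
    }, numeric(1))
    tails <- vapply(cands, function(e) e$tail_length, numeric(1))
    tsds <- vapply(cands, function(e) e$tsd_length, numeric(1))
    shifts <- vapply(cands, function(e) e$shift, numeric(1))
    # most-complete element first, then maximal left-flank duplication
    chosen <- cands[[order(trunc_rank, -tsds, -tails, -shifts)[[1L]]]]
    left <- right <- chosen$p
  }
  # orientation: tail evidence first, template strand as tie-breaker/backstop
  orientation <- chosen$orientation
  if (orientation == "undetermined" && !is.null(chosen$anchor)) {
    orientation <- switch(chosen$anchor$strand, "+" = "sense", "-" = "antisense",
                          orientation)
  }
  anchor <- chosen$anchor
  nt5 <- ""
  trunc_hint <- NA_integer_
  fam_hint <- NA_character_
  if (!is.null(anchor)) {
    fam_hint <- anchor$family
    trunc_hint <- anchor$truncation
    if (anchor$nt5_length > 0L) {
      nt5 <- substr(chosen$body_fwd, 1L, anchor$nt5_length)
    }
  }
  body <- chosen$body_fwd
  if (nchar(nt5) > 0L) body <- substr(body, nchar(nt5) + 1L, nchar(body))
  tibble::tibble(
    left_break = left, right_break = right,
    inserted_seq = chosen$inserted %||% chosen$cassette,
    tsd_seq = chosen$tsd_seq, tsd_length = chosen$tsd_length,
    target_deletion_length = del_len,
    poly_tail_kind = chosen$tail_kind, poly_tail_length = chosen$tail_length,
    orientation = orientation,
    nontemplated_5prime = nt5,
    body_seq = body,
    family_hint = fam_hint, truncation_hint = trunc_hint
  )
}

#' Characterize many reference/mutant pairs
#'
#' @param pairs A data frame with columns `case_id`, `reference`, `mutant`,
#'   or a fixture set from [build_fixture_set()].
#' @inheritParams characterize_insertion
#' @return A tibble of insertion calls, one row per pair, keyed by `case_id`.
#' @export
characterize_insertions <- function(pairs, library = NULL, min_tail = 10L,
                                    tail_impurity = 0) {
  if (inherits(pairs, "tprt_fixtures")) {
    library <- library %||% pairs$library
    pairs <- tibble::tibble(case_id = pairs$cases$case_id,
                            reference = pairs$reference,
                            mutant = pairs$cases$mutant)
  }
  stopifnot(all(c("case_id", "reference", "mutant") %in% names(pairs)))
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    dplyr::bind_cols(
      tibble::tibble(case_id = pairs$case_id[[i]]),
      characterize_insertion(pairs$reference[[i]], pairs$mutant[[i]],
                             library = library, min_tail = min_tail,
                             tail_impurity = tail_impurity)
    )
  })
}

#' Resolve the target-site duplication of a variant interval
#'
#' Convenience wrapper around [characterize_insertion()] exposing TSD
#' resolution as its own step: the TSD is the longest reference suffix ending
#' at the insertion point that also terminates the inserted sequence, with
#' breakpoints normalized so the insertion is reported after the first
#' duplicated copy. Replacement intervals yield `tsd_length = 0` and a
#' positive `target_deletion_length`.
#'
#' @inheritParams characterize_insertion
#' @param interval Optional precomputed [find_variant_interval()] result
#'   (recomputed if `NULL`).
#' @return A one-row insertion-call tibble.
#' @export
resolve_tsd <- function(reference, mutant, interval = NULL, library = NULL) {
  characterize_insertion(reference, mutant, library = library)
}

#' Measure the homopolymer tail of an inserted sequence
#'
#' @param inserted_seq The inserted sequence after TSD removal (the
#'   "cassette": optional non-templated addition, element body, tail).
#' @param min_run Minimum run length to call a tail.
#' @param impurity Tolerated fraction of non-matching bases within the run.
#' @return A list with `kind` (`"A-at-3'"`, `"T-at-5'"` or `"none"`) and
#'   `length`. A leading poly(T) dominates a trailing poly(A) (5'-inverted
#'   antisense products can carry both).
#' @export
measure_poly_tail <- function(inserted_seq, min_run = 10L, impurity = 0) {
  rT <- run_length(inserted_seq, "T", "start", impurity)
  rA <- run_length(inserted_seq, "A", "end", impurity)
  if (rT >= min_run) list(kind = "T-at-5'", length = rT)
  else if (rA >= min_run) list(kind = "A-at-3'", length = rA)
  else list(kind = "none", length = 0L)
}

#' Infer insert orientation from tail and template evidence
#'
#' A 5' poly(T) tail on the sense strand means the element went in antisense;
#' a 3' poly(A) means sense. When an element library is supplied the strand
#' of the best template anchor must agree; disagreement (or no evidence at
#' all) yields `"undetermined"` with a warning.
#'
#' @param inserted_seq Inserted cassette (TSD removed).
#' @param tail Optional result of [measure_poly_tail()] (recomputed if NULL).
#' @param library Optional [element_library()].
#' @return `"sense"`, `"antisense"` or `"undetermined"`.
#' @export
infer_orientation <- function(inserted_seq, tail = NULL, library = NULL) {
  tail <- tail %||% measure_poly_tail(inserted_seq)
  tail_call <- switch(tail$kind, "T-at-5'" = "antisense", "A-at-3'" = "sense",
                      "none" = "undetermined")
  if (is.null(library)) return(tail_call)
  anc_f <- template_anchor(inserted_seq, library, strand = "both")
  anc_r <- template_anchor(revcomp(inserted_seq), library, strand = "both")
  strand_call <- "undetermined"
  if (!is.null(anc_f) && anc_f$strand == "+") strand_call <- "sense"
  if (!is.null(anc_r) && anc_r$strand == "+") strand_call <- "antisense"
  if (tail_call == "undetermined") return(strand_call)
  if (strand_call != "undetermined" && strand_call != tail_call) {
    warn(paste0("tail (", tail_call, ") and template strand (", strand_call,
                ") disagree; orientation undetermined"))
    return("undetermined")
  }
  tail_call
}

#' Re-apply an insertion call to its reference
#'
#' Reconstruction check: applying the reported edit must reproduce the mutant
#' bit-exactly.
#'
#' @param reference Reference allele.
#' @param call A one-row insertion-call tibble.
#' @return The reconstructed mutant sequence.
#' @export
apply_call <- function(reference, call) {
  paste0(substr(reference, 1L, call$left_break),
         call$inserted_seq,
         substr(reference, call$right_break + 1L, nchar(reference)))
}
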