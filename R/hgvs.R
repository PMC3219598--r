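#' Name an insertion in the published HGVS dialect
#'
#' Emits the mutation description in the source dialect: an `ins` clause with
#' the element name as the inserted-sequence token, placed after the first
#' duplicated copy, followed by a comma-separated `dup` clause giving the TSD
#' span and sequence (e.g. `"c.4319_4320insAluYb8, 4305_4319dupAAAAGAAGAACATAT"`).
#' Deletion-associated events are `"c.A_BdelinsFAMILY"`; a non-templated 5'
#' addition becomes an extra `ins` segment before the element name. With
#' `strict = TRUE` a single strict-HGVS description carrying the full
#' inserted sequence is produced instead (machine round-trippable).
#'
#' @param call One-row insertion-call tibble (genomic breakpoints in the
#'   model frame).
#' @param classification Optional classification row for the same call
#'   (family, subset, truncation); used for the element token.
#' @param model A [gene_model()].
#' @param library An [element_library()] (for ORF metadata in L1 tokens).
#' @param strict Emit strict single-description HGVS instead of the dialect.
#' @return A character scalar.
#' @export
name_insertion <- function(call, classification = NULL, model,
                           library = element_library(), strict = FALSE) {
  cfmt <- function(g0) format_c_position(offset_to_c(model, g0))
  if (call$target_deletion_length > 0L) {
    a <- cfmt(call$left_break)            # first deleted base
    b <- cfmt(call$right_break - 1L)      # last deleted base
    if (strict) {
      return(paste0("c.", a, "_", b, "delins", call$inserted_seq))
    }
    return(paste0("c.", a, "_", b, "delins",
                  element_token(call, classification, library)))
  }
  x <- cfmt(call$left_break - 1L)         # base left of the junction
  y <- cfmt(call$left_break)              # base right of the junction
  if (strict) {
    return(paste0("c.", x, "_", y, "ins", call$inserted_seq))
  }
  tok <- element_token(call, classification, library)
  nt5 <- call$nontemplated_5prime
  ins <- paste0("c.", x, "_", y, "ins",
                if (nzchar(nt5)) paste0(nt5, "ins") else "", tok)
  if (call$tsd_length > 0L) {
    a <- cfmt(call$left_break - call$tsd_length)
    b <- x
    ins <- paste0(ins, ", ", a, "_", b, "dup", call$tsd_seq)
  }
  ins
}

# element name token in the published style
element_token <- function(call, classification, library) {
  fam <- if (!is.null(classification)) classification$family else call$family_hint
  if (is.null(fam) || is.na(fam)) return("N")
  if (fam == "polyN") {
    base <- if (call$poly_tail_kind == "T-at-5'") "T" else "A"
    return(paste0(base, "(n", call$poly_tail_length, ")"))
  }
  if (fam == "L1") {
    subset <- if (!is.null(classification$l1_subset)) classification$l1_subset else "n/a"
    tok <- switch(subset, Ta = "L1(Ta)", preTa = "L1(preTa)", "L1")
    orf2 <- library$meta$L1$orf2_start
    tr <- classification$truncation_offset
    if (!is.null(orf2) && !is.null(tr) && !is.na(tr) && tr >= orf2) {
      tok <- paste0(tok, "_orf2")
    }
    return(tok)
  }
  fam
}

#' Apply a strict-HGVS description to a reference sequence
#'
#' Parses `c.X_Yins<SEQ>` / `c.A_Bdelins<SEQ>` descriptions (as produced by
#' [name_insertion()] with `strict = TRUE`) and applies them, for
#' name/apply round-trip checking.
#'
#' @param description Strict HGVS string.
#' @param reference Reference sequence (model frame).
#' @param model A [gene_model()].
#' @return The mutant sequence.
#' @export
apply_mutation_name <- function(description, reference, model) {
  m <- regmatches(description,
                  regexec("^c\\.([0-9+-]+)_([0-9+-]+)(delins|ins)([ACGTN]+)$",
                          description))[[1L]]
  if (length(m) == 0L) abort(paste0("cannot parse description: ", description))
  g_a <- c_to_offset(model, m[[2L]])
  g_b <- c_to_offset(model, m[[3L]])
  seq <- m[[5L]]
  if (m[[4L]] == "ins") {
    paste0(substr(reference, 1L, g_a + 1L), seq,
           substr(reference, g_b + 1L, nchar(reference)))
  } else {
    paste0(substr(reference, 1L, g_a), seq,
           substr(reference, g_b + 2L, nchar(reference)))
  }
}

#' Name the transcript-level effect
#'
#' @param products List of products (each with `lost_start`, `lost_end`,
#'   `gain`), as parsed from an effect observation.
#' @return `"r.A_Bdel"`, `"r.A_BdelinsN"`, or the bracketed multi-product
#'   form `"r.[x;y]"`.
#' @export
name_transcript_effect <- function(products) {
  if (length(products) == 0L) abort("empty transcript observation")
  one <- function(p) {
    paste0(p$lost_start, "_", p$lost_end,
           if (p$gain > 0L) paste0("delins", p$gain) else "del")
  }
  if (length(products) == 1L) paste0("r.", one(products[[1L]]))
  else paste0("r.[", paste(vapply(products, one, character(1)), collapse = ";"), "]")
}

#' Classify the reading-frame consequence
#'
#' The net exonic change is the number of element-derived nucleotides
#' retained in the transcript minus the number of exonic nucleotides lost;
#' the product is in frame (IF) iff that net change is divisible by 3.
#'
#' @param products List of products (`lost_start`, `lost_end`, `gain`).
#' @return Tibble with one row per product: `net_exonic_change`,
#'   `frame_status` (`IF`/`OOF`).
#' @export
classify_frame <- function(products) {
  purrr::map_dfr(products, function(p) {
    net <- p$gain - (p$lost_end - p$lost_start + 1L)
    tibble::tibble(net_exonic_change = net,
                   frame_status = if (net %% 3L == 0L) "IF" else "OOF")
  })
}

#' Render the per-case summary table
#'
#' Joins characterization, classification, site and splice-effect results
#' into one row per case, in the published table's spirit, plus the EN score
#' at the inferred nick and the recurrence group.
#'
#' @param calls Characterized calls (with nick columns).
#' @param classifications Output of [classify_elements()] (may be the same
#'   table as `calls`).
#' @param annotations Output of [annotate_sites()].
#' @param effects Output of [classify_splice_effects()].
#' @param recurrence A `recurrence_report` (optional).
#' @param reference Reference sequence for EN scoring (optional).
#' @return A tibble with one row per `case_id`, ordered by genomic position;
#'   empty input gives a zero-row tibble with the same columns.
#' @export
render_summary <- function(calls, classifications = NULL, annotations = NULL,
                           effects = NULL, recurrence = NULL,
                           reference = NULL) {
  cols <- c("case_id", "left_break", "tsd_length", "tsd_seq",
            "target_deletion_length", "orientation", "poly_tail_kind",
            "poly_tail_length", "nick_position", "nick_strand")
  base <- calls[, intersect(cols, names(calls))]
  join_in <- function(tab, cols) {
    if (is.null(tab)) return(NULL)
    miss <- setdiff(tab$case_id, base$case_id)
    if (length(miss)) {
      warn(paste0("rows without a matching call: ", paste(miss, collapse = ", ")))
    }
    tab[, intersect(c("case_id", cols), names(tab))]
  }
  out <- base
  for (piece in list(
    join_in(classifications, c("family", "truncation_offset", "inversion",
                               "microhomology_length", "l1_subset")),
    join_in(annotations, c("region", "feature_index", "feature_label",
                           "splice_region_class")),
    join_in(effects, c("splice_types", "frame_status", "net_exonic_change")))) {
    if (!is.null(piece)) out <- dplyr::left_join(out, piece, by = "case_id")
  }
  if (!is.null(reference) && "nick_position" %in% names(out)) {
    out$en_score <- vapply(seq_len(nrow(out)), function(i) {
      if (is.na(out$nick_position[[i]]) || is.na(out$nick_strand[[i]])) {
        return(NA_integer_)
      }
      score_en_site(reference, out$nick_position[[i]],
                    out$nick_strand[[i]])$matches
    }, integer(1))
  }
  if (!is.null(recurrence)) {
    map <- tidyr::unnest(recurrence$groups[, c("group", "case_ids")],
                         "case_ids")
    names(map) <- c("recurrence_group", "case_id")
    out <- dplyr::left_join(out, map, by = "case_id")
  }
  if ("left_break" %in% names(out)) out <- dplyr::arrange(out, .data$left_break)
  out
}
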