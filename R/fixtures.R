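#' Build the reconstructed 18-case insertion fixture set
#'
#' Reconstructs each published NF1 insertion case as a reference/mutant
#' allele pair inside one shared synthetic gene frame. The reference embeds
#' every printed integration-site window (converted from the nicked-strand
#' 3'->5' orientation of the source table to the top strand) and every
#' printed TSD; mutants are assembled as TPRT products: `[TSD] [optional
#' non-templated 5' addition] [element body, reverse-complemented for
#' antisense inserts] [poly(A)/poly(T) tail] [TSD copy]`, or a 71-bp
#' replacement with no TSD for the deletion-associated case. All per-case
#' expected values (the "truth") are carried alongside.
#'
#' @param table1,table2 Paths to the transcription TSVs of the published
#'   per-case list and integration-site windows (`NULL` for the bundled
#'   files).
#' @param library An [element_library()] (`NULL` for the bundled synthetic
#'   one).
#' @param model A [gene_model()] (`NULL` for [nf1_gene_model()]).
#' @param background_seed Seed for the deterministic background sequence of
#'   the shared frame (a fixture constant, isolated from the caller's RNG).
#' @return An object of class `tprt_fixtures`: a list with `reference` (the
#'   shared frame), `cases` (tibble: one row per case with `mutant` plus all
#'   truth fields), `model` and `library`.
#' @export
build_fixture_set <- function(table1 = NULL, table2 = NULL, library = NULL,
                              model = NULL, background_seed = 20111117L) {
  table1 <- table1 %||% system.file("extdata", "table1_insertions.tsv",
                                    package = "retrochar")
  table2 <- table2 %||% system.file("extdata", "table2_sites.tsv",
                                    package = "retrochar")
  library <- library %||% element_library()
  model <- model %||% nf1_gene_model()
  t1 <- readr::read_tsv(table1, comment = "#", show_col_types = FALSE,
                        na = "NA")
  t2 <- readr::read_tsv(table2, comment = "#", show_col_types = FALSE,
                        na = "NA")
  spec <- dplyr::left_join(
    t1, t2[, c("case_id", "printed_window", "conversion", "window_trim5")],
    by = "case_id")
  if (nrow(spec) != nrow(t1)) abort("table1/table2 case_id join is not 1:1")

  L <- model_genomic_length(model)
  ref <- with_fixed_seed(background_seed, random_dna(L, gc = 0.45))
  stamped <- rep(FALSE, L)
  stamp <- function(start1, s, what) {
    idx <- seq(start1, start1 + nchar(s) - 1L)
    old <- substr(ref, start1, start1 + nchar(s) - 1L)
    prev <- stamped[idx]
    if (any(prev)) {
      oldc <- strsplit(old, "")[[1L]]
      newc <- strsplit(s, "")[[1L]]
      if (any(oldc[prev] != newc[prev])) {
        abort(paste0("fixture stamp conflict at genomic ", start1, " (", what, ")"))
      }
    }
    ref <<- `substr_set<-`(ref, start1, s)
    stamped[idx] <<- TRUE
    invisible(NULL)
  }
  g1 <- function(cpos) c_to_offset(model, cpos) + 1L  # 1-based genomic

  # ---- pass 1: stamp printed windows and dup strings --------------------
  for (i in seq_len(nrow(spec))) {
    r <- spec[i, ]
    win <- switch(r$conversion,
      complement = complement_chr(r$printed_window),
      reverse    = str_rev(r$printed_window),
      as_is      = r$printed_window,
      abort(paste0("unknown window conversion '", r$conversion, "'")))
    if (!is.na(r$dup_seq)) {
      dup_len <- nchar(r$dup_seq)
      dstart <- g1(r$dup_start); dend <- g1(r$dup_end)
      if (dend - dstart + 1L != dup_len) {
        abort(paste0(r$case_id, ": dup span does not match dup string length"))
      }
      win_start <- switch(r$conversion,
        complement = dstart - 12L,            # nick at left TSD edge
        reverse    = (dend + 1L) - 24L,       # nick at right TSD edge
        as_is      = dstart - 12L)
      trim <- r$window_trim5 %||% 0L
      if (is.na(trim)) trim <- 0L
      if (trim > 0L) {
        win <- substr(win, trim + 1L, nchar(win))
        win_start <- win_start + trim
      }
      stamp(win_start, win, paste0(r$case_id, " window"))
      stamp(dstart, r$dup_seq, paste0(r$case_id, " dup"))
    } else {
      # deletion-associated case: window ends at the (tentative) nick, the
      # left edge of the deleted interval, followed by its first 12 bases
      del_start <- g1(r$del_start)
      stamp(del_start - 24L, win, paste0(r$case_id, " window"))
    }
  }

  # canonical splice dinucleotides at every modelled intron boundary, where
  # a printed window has not already fixed the sequence
  for (i in seq_len(nrow(model) - 1L)) {
    if (model$intron_after[[i]] < 4L) next
    g_end <- model$g_start[[i]] + (model$c_end[[i]] - model$c_start[[i]])
    for (k in 0:1) {
      if (!stamped[[g_end + 1L + k]]) {
        ref <- `substr_set<-`(ref, g_end + 1L + k, substr("GT", k + 1L, k + 1L))
        stamped[[g_end + 1L + k]] <- TRUE
      }
      pos <- model$g_start[[i + 1L]] - 2L + k
      if (!stamped[[pos]]) {
        ref <- `substr_set<-`(ref, pos, substr("AG", k + 1L, k + 1L))
        stamped[[pos]] <- TRUE
      }
    }
  }

  # ---- pass 2: assemble cassettes ---------------------------------------
  meta <- library$meta
  build_body <- function(r) {
    if (r$family == "polyN") return("")
    tpl <- library_template(library, r$family)
    if (isTRUE(r$inverted == "yes")) {
      # 5'-inverted (twin-primed) L1: reverse-complemented 5' segment joined
      # to a sense 3' segment ending at ORF2 nt 3167, 2-bp junction
      # microhomology, per the published description of this case
      orf2 <- meta$L1$orf2_start
      b2 <- orf2 - 1L + 3167L
      b1 <- b2 - 1088L + 1L
      a2 <- b1 + 1L                       # 2-bp microhomology
      # the inverted segment is ~1 kb; nudge its 5' end so the base beyond it
      # cannot extend the forward-segment match across the junction
      a1 <- a2 - 1000L + 1L
      for (nudge in c(0L, -1L, 1L, -2L, 2L, -3L, 3L)) {
        cand <- a1 + nudge
        if (complement_chr(substr(tpl, b1, b1)) !=
            substr(tpl, cand - 1L, cand - 1L)) {
          a1 <- cand
          break
        }
      }
      return(paste0(revcomp(substr(tpl, a1, a2)), substr(tpl, b1, b2)))
    }
    trunc <- if (is.na(r$truncation)) 0L else r$truncation
    body <- substr(tpl, trunc + 1L, nchar(tpl))
    if (!is.na(r$l1_subset) && r$l1_subset == "preTa") {
      ds <- meta$L1$ta_diagnostic_start - trunc
      body <- `substr_set<-`(body, ds, meta$L1$preta_base)
    }
    body
  }
  spec$body <- vapply(seq_len(nrow(spec)), function(i) build_body(spec[i, ]),
                      character(1))
  spec$cassette <- vapply(seq_len(nrow(spec)), function(i) {
    r <- spec[i, ]
    nt5 <- if (is.na(r$nt5)) "" else r$nt5
    if (r$orientation == "S") {
      paste0(nt5, r$body, strrep("A", r$polyA_len))
    } else if (isTRUE(r$inverted == "yes")) {
      paste0(strrep("T", r$polyA_len), r$body)
    } else if (r$family == "polyN") {
      strrep("T", r$polyA_len)
    } else {
      paste0(strrep("T", r$polyA_len), revcomp(paste0(nt5, r$body)))
    }
  }, character(1))

  # ---- pass 3: breakpoint guards ----------------------------------------
  # a background base adjacent to a breakpoint must not extend the printed
  # duplication (or shift the deletion); printed bases are never altered, and
  # printed coincidences are already recorded in tsd_expected
  safe_base <- function(bad) setdiff(c("G", "C", "A", "T"), bad)[[1L]]
  guard <- function(pos1, bad, what) {
    if (pos1 < 1L || pos1 > L) return(invisible(NULL))
    cur <- substr(ref, pos1, pos1)
    if (stamped[[pos1]]) return(invisible(NULL))
    if (cur %in% bad) {
      ref <<- `substr_set<-`(ref, pos1, safe_base(bad))
    }
    stamped[[pos1]] <<- TRUE
    invisible(NULL)
  }
  for (i in seq_len(nrow(spec))) {
    r <- spec[i, ]
    first_c <- substr(r$cassette, 1L, 1L)
    last_c <- substr(r$cassette, nchar(r$cassette), nchar(r$cassette))
    if (!is.na(r$dup_seq)) {
      guard(g1(r$dup_start) - 1L, last_c, r$case_id)   # TSD left extension
      guard(g1(r$dup_end) + 1L, first_c, r$case_id)    # junction shift
    } else {
      guard(g1(r$del_start), first_c, r$case_id)
      guard(g1(r$del_end), last_c, r$case_id)
    }
  }

  # ---- pass 4: mutants and truth ----------------------------------------
  cases <- purrr::map_dfr(seq_len(nrow(spec)), function(i) {
    r <- spec[i, ]
    if (!is.na(r$dup_seq)) {
      j1 <- g1(r$dup_end) + 1L
      dup_now <- substr(ref, g1(r$dup_start), g1(r$dup_end))
      mutant <- paste0(substr(ref, 1L, j1 - 1L), r$cassette, dup_now,
                       substr(ref, j1, L))
      # expected measured junction (junction_shift covers the one case where
      # the maximal-duplication convention sits 3' of the printed point)
      g_junction <- j1 - 1L + r$junction_shift
      nick_g <- if (r$orientation == "S") g1(r$dup_start) - 1L else g_junction
      del_len <- 0L
      tentative <- FALSE
    } else {
      ds <- g1(r$del_start); de <- g1(r$del_end)
      mutant <- paste0(substr(ref, 1L, ds - 1L), r$cassette,
                       substr(ref, de + 1L, L))
      g_junction <- ds - 1L
      nick_g <- g_junction
      del_len <- de - ds + 1L
      tentative <- TRUE
    }
    net <- local({
      prods <- parse_products(r$products)
      vapply(prods, function(p) p$gain - (p$lost_end - p$lost_start + 1L),
             numeric(1))
    })
    tibble::tibble(
      case_id = r$case_id, row = r$row, location = r$location,
      region = r$region, family = r$family, l1_subset = r$l1_subset,
      orientation = ifelse(r$orientation == "S", "sense", "antisense"),
      nick_strand = ifelse(r$orientation == "S", "bottom", "top"),
      truncation = r$truncation_expected, truncation_built = r$truncation,
      inverted = identical(r$inverted, "yes"),
      polyA_len = r$polyA_len, tail_expected = r$tail_expected,
      polyA_estimated = !grepl("no estimate", r$polyA_printed),
      nt5 = ifelse(is.na(r$nt5), "", r$nt5),
      tsd_printed = r$tsd_printed, tsd_expected = r$tsd_expected,
      tsd_flagged = !is.na(r$tsd_printed) & r$tsd_printed != r$tsd_expected,
      dup_start = r$dup_start, dup_end = r$dup_end, dup_seq = r$dup_seq,
      del_start = r$del_start, del_end = r$del_end,
      target_deletion_length = del_len,
      g_junction = g_junction, nick_g = nick_g, nick_tentative = tentative,
      c_name_printed = r$c_name_printed, r_printed = r$r_printed,
      frame_printed = r$frame_printed,
      frame_computed = paste(ifelse(net %% 3 == 0, "IF", "OOF"), collapse = ";"),
      frame_flagged = !is.na(r$frame_printed) &&
        strsplit(r$frame_printed, ";")[[1L]][[1L]] !=
          ifelse(net[[1L]] %% 3 == 0, "IF", "OOF"),
      splice_type_printed = as.character(r$splice_type_printed),
      products = r$products,
      notes = r$notes,
      cassette = r$cassette,
      mutant = mutant
    )
  })
  out <- list(reference = ref, cases = cases, model = model, library = library)
  class(out) <- "tprt_fixtures"
  # construction invariant: every mutant differs from the reference by one
  # contiguous replacement that replays to the mutant bit-exactly
  for (i in seq_len(nrow(cases))) {
    iv <- find_variant_interval(ref, cases$mutant[[i]])
    stopifnot(iv$ref_right >= iv$ref_left)
  }
  out
}

# parse the products column: "lostStart:lostEnd[:gainLen]" entries, ';'-joined
parse_products <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE)[[1L]], function(p) {
    f <- as.integer(strsplit(p, ":", fixed = TRUE)[[1L]])
    list(lost_start = f[[1L]], lost_end = f[[2L]],
         gain = if (length(f) >= 3L) f[[3L]] else 0L)
  })
}

#' @export
print.tprt_fixtures <- function(x, ...) {
  cat("<tprt_fixtures> ", nrow(x$cases), " reconstructed insertion cases on a ",
      nchar(x$reference), "-bp synthetic gene frame\n", sep = "")
  print(dplyr::select(x$cases, "case_id", "location", "family",
                      "orientation", "tsd_expected",
                      "target_deletion_length", "splice_type_printed"))
  invisible(x)
}
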