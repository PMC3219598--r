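EN_TOP_MOTIF <- "TTTTAA"     # top-strand nick: top reads ...TTTT/AA... in 5'->3'
EN_BOTTOM_MOTIF <- "TTAAAA"  # bottom-strand nick: top strand shows TT/AAAA

#' Score a position against the L1 EN cleavage consensus
#'
#' The L1 endonuclease cleavage consensus, written on the nicked strand read
#' 3'->5', is `AA/TTTT` (with derivates thereof). The score counts the
#' agreement (0-6) of the two bases upstream and four bases downstream of the
#' nick, read on the nicked strand, with that consensus.
#'
#' @param sequence Top-strand sequence, 5'->3'.
#' @param nick_position 0-based junction offset: the nick sits between
#'   positions `nick_position - 1` and `nick_position` of the top strand.
#' @param strand `"top"` or `"bottom"`: the nicked strand.
#' @return One-row tibble: `nick_position`, `strand`, `matches` (0-6) and
#'   `motif_window` (the six scored bases, written on the nicked strand
#'   3'->5' so a perfect site reads `AATTTT`).
#' @export
score_en_site <- function(sequence, nick_position, strand = c("bottom", "top")) {
  strand <- match.arg(strand)
  j <- as.integer(nick_position)
  L <- nchar(sequence)
  if (strand == "bottom") {
    if (j - 2L < 0L || j + 3L > L - 1L) {
      abort("EN score window out of range", class = "retrochar_coordinate_error")
    }
    win <- substr(sequence, j - 1L, j + 4L)            # 1-based [j-2..j+3]
    matches <- sum(strsplit(win, "")[[1L]] == strsplit(EN_BOTTOM_MOTIF, "")[[1L]])
    motif <- complement_chr(win)
  } else {
    if (j - 4L < 0L || j + 1L > L - 1L) {
      abort("EN score window out of range", class = "retrochar_coordinate_error")
    }
    win <- substr(sequence, j - 3L, j + 2L)            # 1-based [j-4..j+1]
    matches <- sum(strsplit(win, "")[[1L]] == strsplit(EN_TOP_MOTIF, "")[[1L]])
    motif <- str_rev(win)
  }
  tibble::tibble(nick_position = j, strand = strand,
                 matches = as.integer(matches), motif_window = motif)
}

#' Score every position of a sequence against the EN consensus
#'
#' Vectorized scan over all valid nick positions on one or both strands.
#'
#' @inheritParams score_en_site
#' @param strand `"both"`, `"top"` or `"bottom"`.
#' @return Tibble with columns `nick_position` (0-based junction), `strand`,
#'   `matches`.
#' @export
en_site_scan <- function(sequence, strand = c("both", "top", "bottom")) {
  strand <- match.arg(strand)
  x <- strsplit(sequence, "")[[1L]]
  L <- length(x)
  out <- list()
  if (strand %in% c("both", "bottom") && L >= 6L) {
    js <- 2:(L - 4L)                       # 0-based junctions
    sc <- (x[js - 1L] == "T") + (x[js] == "T") + (x[js + 1L] == "A") +
      (x[js + 2L] == "A") + (x[js + 3L] == "A") + (x[js + 4L] == "A")
    out$bottom <- tibble::tibble(nick_position = js, strand = "bottom",
                                 matches = as.integer(sc))
  }
  if (strand %in% c("both", "top") && L >= 6L) {
    js <- 4:(L - 2L)
    sc <- (x[js - 3L] == "T") + (x[js - 2L] == "T") + (x[js - 1L] == "T") +
      (x[js] == "T") + (x[js + 1L] == "A") + (x[js + 2L] == "A")
    out$top <- tibble::tibble(nick_position = js, strand = "top",
                              matches = as.integer(sc))
  }
  dplyr::bind_rows(out)
}

#' Infer the first-nick position and strand from insertion calls
#'
#' The freed 3' end at the nick must terminate in the T-run that primes
#' reverse transcription from the transcript's poly(A): for a sense-oriented
#' insert the nick is on the bottom strand at the top-coordinate left edge of
#' the TSD; for an antisense insert it is on the top strand at the right TSD
#' edge (the post-duplication insertion junction). Deletion-associated calls
#' have no TSD; their nick is placed at the left edge of the deleted interval
#' and flagged tentative.
#'
#' @param calls Tibble of insertion calls (needs `left_break`, `tsd_length`,
#'   `target_deletion_length`, `orientation`).
#' @return `calls` with `nick_position`, `nick_strand` and `nick_tentative`
#'   columns appended.
#' @export
infer_nick <- function(calls) {
  dplyr::mutate(calls,
    nick_strand = dplyr::case_when(
      .data$orientation == "sense" ~ "bottom",
      .data$orientation == "antisense" ~ "top",
      TRUE ~ NA_character_),
    nick_position = dplyr::if_else(
      .data$orientation == "sense" & .data$target_deletion_length == 0L,
      .data$left_break - .data$tsd_length,
      .data$left_break),
    nick_tentative = .data$target_deletion_length > 0L
  )
}

#' Annotate insertion sites against a gene model
#'
#' Classifies each call's insertion junction as exonic or intronic and, for
#' intronic sites, whether it falls in the 3' splice region: interrupting the
#' intron-terminal AG dinucleotide (`canonical-AG`, junction within 2 bp of
#' the acceptor) or inside the polypyrimidine tract (acceptor window, intron
#' positions -3 to -20 by default). A deletion-associated call is classified
#' by the overlap of its deleted interval with those windows.
#'
#' @param calls Tibble of insertion calls (genomic breakpoints in the model
#'   frame).
#' @param model A [gene_model()].
#' @param ppt_window Acceptor-window extent (intron positions
#'   `-ppt_window[1]` to `-ppt_window[2]`).
#' @return `calls` with `region` (`exonic`/`intronic`), `feature_index`
#'   (exon index, or the index of the intron's upstream exon),
#'   `feature_label`, `splice_region_class` (`canonical-AG`,
#'   `polypyrimidine-tract`, `none`), `distance_to_acceptor` and
#'   `distance_to_donor` appended.
#' @export
annotate_sites <- function(calls, model, ppt_window = c(3L, 20L)) {
  ann <- purrr::map_dfr(seq_len(nrow(calls)), function(i) {
    j <- calls$left_break[[i]]
    del <- calls$target_deletion_length[[i]]
    cl <- offset_to_c(model, j - 1L)   # base left of the junction
    cr <- offset_to_c(model, j)        # base right of the junction
    if (cl$intron_offset == 0L && cr$intron_offset == 0L && del == 0L) {
      e <- exon_of_base(model, cl$base)
      return(tibble::tibble(
        region = "exonic", feature_index = model$index[[e]],
        feature_label = model$legacy_label[[e]],
        splice_region_class = "none",
        distance_to_acceptor = cl$base - model$c_start[[e]] + 1L,
        distance_to_donor = model$c_end[[e]] - cr$base + 1L))
    }
    # intronic junction (or deletion): use the minus-side offset of the
    # nearest acceptor; for deletions, the deleted interval's overlap
    off_l <- cl$intron_offset
    e_up <- if (off_l > 0L) exon_of_base(model, cl$base)
            else if (off_l < 0L) exon_of_base(model, cl$base) - 1L
            else exon_of_base(model, cl$base)
    acceptor_g1 <- model$g_start[[min(e_up + 1L, nrow(model))]]  # next exon start
    if (del > 0L) {
      d1 <- j + 1L; d2 <- j + del                  # deleted interval, 1-based
      cls <- if (d1 <= acceptor_g1 - 1L && d2 >= acceptor_g1 - 2L) "canonical-AG"
        else if (d1 <= acceptor_g1 - ppt_window[[1L]] &&
                 d2 >= acceptor_g1 - ppt_window[[2L]]) "polypyrimidine-tract"
        else "none"
      k <- acceptor_g1 - d2 - 1L                   # gap to acceptor
    } else {
      k <- if (off_l < 0L) -off_l else NA_integer_ # junction at intron -k/-(k-1)
      cls <- if (!is.na(k) && k <= 2L) "canonical-AG"
        else if (!is.na(k) && k <= ppt_window[[2L]] && k >= ppt_window[[1L]])
          "polypyrimidine-tract"
        else "none"
    }
    tibble::tibble(
      region = "intronic", feature_index = model$index[[e_up]],
      feature_label = model$legacy_label[[e_up]],
      splice_region_class = cls,
      distance_to_acceptor = if (!is.na(k)) as.integer(k) else NA_integer_,
      distance_to_donor = if (off_l > 0L) off_l else NA_integer_)
  })
  dplyr::bind_cols(calls, ann)
}

#' Group calls that used the same integration site
#'
#' Calls whose nick positions lie within `grouping_window` bp of each other
#' (single-linkage on the shared genomic frame, strand-agnostic) are counted
#' as one integration site.
#'
#' @param calls Tibble with `case_id` and `nick_position` columns.
#' @param grouping_window Maximum distance (bp) merging two nicks into one
#'   EN motif locus.
#' @return An object of class `recurrence_report`: list with `groups`
#'   (tibble: `group`, `representative`, `span`, `n`, `case_ids`),
#'   `n_distinct_sites` and `n_multiply_used`.
#' @export
find_recurrent_sites <- function(calls, grouping_window = 12L) {
  stopifnot(nrow(calls) >= 1L)
  ord <- order(calls$nick_position)
  pos <- calls$nick_position[ord]
  ids <- calls$case_id[ord]
  grp <- cumsum(c(1L, diff(pos) > grouping_window))
  groups <- tibble::tibble(pos = pos, case_id = ids, group = grp) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(representative = min(.data$pos),
                     span = max(.data$pos) - min(.data$pos),
                     n = dplyr::n(),
                     case_ids = list(.data$case_id), .groups = "drop")
  structure(list(groups = groups,
                 n_distinct_sites = nrow(groups),
                 n_multiply_used = sum(groups$n > 1L)),
            class = "recurrence_report")
}

#' @export
print.recurrence_report <- function(x, ...) {
  cat("<recurrence_report> ", sum(x$groups$n), " calls at ",
      x$n_distinct_sites, " distinct sites (", x$n_multiply_used,
      " used more than once)\n", sep = "")
  invisible(x)
}

#' Find insertion clusters
#'
#' Greedy left-to-right scan for windows of at most `window_bp` containing at
#' least `min_count` calls on the shared genomic frame.
#'
#' @param calls Tibble with `case_id` and `nick_position`.
#' @param window_bp Maximum window length (bp).
#' @param min_count Minimum number of calls in a reported window.
#' @return An object of class `cluster_report`: list with `windows` (tibble:
#'   `start`, `end`, `n`, `case_ids`) and the parameters used.
#' @export
find_clusters <- function(calls, window_bp = 1500L, min_count = 3L) {
  ord <- order(calls$nick_position)
  pos <- calls$nick_position[ord]
  ids <- calls$case_id[ord]
  wins <- list()
  i <- 1L
  while (i <= length(pos)) {
    jmax <- max(which(pos - pos[[i]] <= window_bp))
    if (jmax - i + 1L >= min_count) {
      wins[[length(wins) + 1L]] <- tibble::tibble(
        start = pos[[i]], end = pos[[jmax]], n = jmax - i + 1L,
        case_ids = list(ids[i:jmax]))
      i <- jmax + 1L
    } else {
      i <- i + 1L
    }
  }
  structure(list(windows = dplyr::bind_rows(wins),
                 window_bp = window_bp, min_count = min_count),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("<cluster_report> ", nrow(x$windows), " window(s) of <= ", x$window_bp,
      " bp with >= ", x$min_count, " insertions\n", sep = "")
  if (nrow(x$windows)) print(x$windows)
  invisible(x)
}
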