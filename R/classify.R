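#' Classify an element body against the template library
#'
#' Global alignment of the body against every template, both strands; the
#' family is the argmin of the per-family edit distance (ties give
#' `"unknown"`). Noise-free bodies that are exact template substrings take an
#' exact-match fast path (distance 0) and skip the alignment. Bodies that are
#' essentially homopolymeric are classed `"polyN"` without alignment.
#'
#' @param body Element body, 5'->3' as laid down (tail and TSD removed).
#' @param library An [element_library()].
#' @param min_len Minimum body length for family assignment.
#' @param polyN_frac Fraction of a single nucleotide above which the body is
#'   called `polyN`.
#' @param align Permit the pairwise-alignment fallback when the exact and
#'   anchored fast paths are inconclusive (`FALSE` returns `"unknown"` with
#'   `NA` distance instead; used internally to defer expensive alignments).
#' @return One-row tibble: `family`, `strand`, `distance` (edits to the
#'   chosen template), `truncation_offset` (missing 5' template bases; NA if
#'   not determined), `distances` (named list-column of per-family
#'   distances), `diag_support` (fraction of the chosen family's diagnostic
#'   sites matched; NA when not assessable).
#' @export
classify_family <- function(body, library, min_len = 20L, polyN_frac = 0.95,
                            align = TRUE) {
  if (length(library$sequences) == 0L) {
    abort("empty element library", class = "retrochar_config_error")
  }
  n <- nchar(body)
  base_tab <- if (n > 0L) table(strsplit(body, "")[[1L]]) else integer()
  if (n < min_len || (n > 0L && max(base_tab) / n >= polyN_frac)) {
    return(tibble::tibble(family = "polyN", strand = NA_character_,
                          distance = NA_real_, truncation_offset = NA_integer_,
                          distances = list(NULL), diag_support = NA_real_))
  }
  fams <- names(library$sequences)
  # tier 1: exact substring; tier 2: anchored ungapped comparison (handles
  # substitution-only divergence without a full alignment)
  fast_one <- function(b, tpl, strand) {
    q <- regexpr(b, tpl, fixed = TRUE)
    if (q > 0L) return(list(dist = 0, strand = strand, trunc = as.integer(q) - 1L))
    nb <- nchar(b)
    if (nb < 20L) return(NULL)
    q <- as.integer(regexpr(substr(b, 1L, 20L), tpl, fixed = TRUE))
    if (q > 0L && q + nb - 1L <= nchar(tpl)) {
      d <- sum(charToRaw(b) != charToRaw(substr(tpl, q, q + nb - 1L)))
      if (d <= max(5, 0.05 * nb)) {
        return(list(dist = as.numeric(d), strand = strand, trunc = q - 1L))
      }
    }
    NULL
  }
  res <- lapply(fams, function(fam) {
    tpl <- library$sequences[[fam]]
    fast_one(body, tpl, "+") %||% fast_one(revcomp(body), tpl, "-")
  })
  names(res) <- fams
  d_fast <- suppressWarnings(
    min(vapply(res, function(r) if (is.null(r)) Inf else r$dist, numeric(1))))
  for (fam in fams) {
    if (!is.null(res[[fam]])) next
    tpl <- library$sequences[[fam]]
    lb <- abs(n - nchar(tpl))   # alignment distance cannot beat the length gap
    if (lb > d_fast) {
      res[[fam]] <- list(dist = as.numeric(lb), strand = NA_character_,
                         trunc = NA_integer_, lower_bound = TRUE)
      next
    }
    if (!align) {
      res[fam] <- list(NULL)
      next
    }
    al_f <- Biostrings::pairwiseAlignment(body, tpl, type = "global-local",
                                          gapOpening = 4, gapExtension = 1)
    al_r <- Biostrings::pairwiseAlignment(revcomp(body), tpl,
                                          type = "global-local",
                                          gapOpening = 4, gapExtension = 1)
    res[[fam]] <- if (Biostrings::score(al_f) >= Biostrings::score(al_r)) {
      list(dist = Biostrings::nedit(al_f), strand = "+",
           trunc = Biostrings::start(Biostrings::subject(al_f)) - 1L)
    } else {
      list(dist = Biostrings::nedit(al_r), strand = "-",
           trunc = Biostrings::start(Biostrings::subject(al_r)) - 1L)
    }
  }
  if (any(vapply(res, is.null, logical(1)))) {
    # fast paths inconclusive and alignment disabled
    return(tibble::tibble(family = "unknown", strand = NA_character_,
                          distance = NA_real_, truncation_offset = NA_integer_,
                          distances = list(NULL), diag_support = NA_real_))
  }
  dists <- vapply(res, function(r) as.numeric(r$dist), numeric(1))
  best <- which(dists == min(dists))
  if (length(best) > 1L) {
    return(tibble::tibble(family = "unknown", strand = NA_character_,
                          distance = min(dists), truncation_offset = NA_integer_,
                          distances = list(dists), diag_support = NA_real_))
  }
  fam <- fams[[best]]
  r <- res[[best]]
  tibble::tibble(family = fam, strand = r$strand, distance = dists[[best]],
                 truncation_offset = as.integer(r$trunc),
                 distances = list(dists),
                 diag_support = diag_site_support(body, library, fam, r))
}

# fraction of the chosen family's diagnostic sites covered by the body whose
# base matches the template (ungapped assumption; NA when none covered)
diag_site_support <- function(body, library, fam, hit) {
  sites <- library$meta[[fam]]$diagnostic_sites
  if (is.null(sites) || length(sites) == 0L || is.na(hit$trunc)) return(NA_real_)
  tpl <- library$sequences[[fam]]
  b <- if (hit$strand == "-") revcomp(body) else body
  off <- hit$trunc
  idx <- unlist(sites) - off
  keep <- idx >= 1L & idx <= nchar(b)
  if (!any(keep)) return(NA_real_)
  mean(substring(b, idx[keep], idx[keep]) ==
         substring(tpl, unlist(sites)[keep], unlist(sites)[keep]))
}

#' Measure the 5' truncation of an element body
#'
#' @param body Element body 5'->3' (forward orientation).
#' @param template Template consensus sequence.
#' @return Integer truncation offset: the first template position covered by
#'   the body, minus one (0 for full-length).
#' @export
measure_truncation <- function(body, template) {
  q <- regexpr(body, template, fixed = TRUE)
  if (q > 0L) return(as.integer(q) - 1L)
  al <- Biostrings::pairwiseAlignment(body, template, type = "global-local",
                                      gapOpening = 4, gapExtension = 1)
  Biostrings::start(Biostrings::subject(al)) - 1L
}

#' Detect a 5' inversion (twin-priming signature) in an element body
#'
#' A twin-primed body is the reverse complement of one template segment
#' joined to a second segment in forward orientation; the two segments may
#' overlap by a short microhomology at the junction. Detection anchors the
#' forward-matching part of the body on the template with an exact k-mer and
#' maximal extension, then maps the reverse-complemented remainder the same
#' way.
#'
#' @param body Element body, 5'->3' as laid down.
#' @param template Template consensus sequence.
#' @param min_seg Minimum length (bp) of each segment to call an inversion.
#' @param k Anchor k-mer length.
#' @return One-row tibble: `inversion` (logical), the template intervals of
#'   the reverse-complemented (`seg5_*`) and forward (`seg3_*`) segments, and
#'   `microhomology_length` (overlap of the two intervals, 0 for a clean
#'   junction; NA when no inversion).
#' @export
detect_inversion <- function(body, template, min_seg = 30L, k = 20L) {
  none <- tibble::tibble(inversion = FALSE, seg5_start = NA_integer_,
                         seg5_end = NA_integer_, seg3_start = NA_integer_,
                         seg3_end = NA_integer_,
                         microhomology_length = NA_integer_)
  n <- nchar(body)
  if (n < 2L * min_seg) return(none)
  anchor_end <- function(x) {
    # map x's maximal suffix onto the template; returns (start, end, len)
    km <- substr(x, nchar(x) - k + 1L, nchar(x))
    hits <- gregexpr(km, template, fixed = TRUE)[[1L]]
    if (hits[[1L]] == -1L) return(NULL)
    best <- NULL
    for (q in as.integer(hits)) {
      m <- lcs_len(x, substr(template, 1L, q + k - 1L))
      if (is.null(best) || m > best$len) {
        best <- list(start = q + k - m, end = q + k - 1L, len = m)
      }
    }
    best
  }
  fw <- anchor_end(body)
  if (is.null(fw) || fw$len >= n || fw$len < min_seg) return(none)
  pre <- substr(body, 1L, n - fw$len)
  if (nchar(pre) < min_seg) return(none)
  rcp <- anchor_end(revcomp(pre))
  if (is.null(rcp) || rcp$len < min_seg) return(none)
  seg5 <- c(rcp$end - rcp$len + 1L, rcp$end)
  seg3 <- c(fw$end - fw$len + 1L, fw$end)
  mh <- max(0L, min(seg5[[2L]], seg3[[2L]]) - max(seg5[[1L]], seg3[[1L]]) + 1L)
  tibble::tibble(inversion = TRUE, seg5_start = seg5[[1L]], seg5_end = seg5[[2L]],
                 seg3_start = seg3[[1L]], seg3_end = seg3[[2L]],
                 microhomology_length = mh)
}

#' Type the L1 subset from the diagnostic trinucleotide
#'
#' The young L1 subsets are discriminated by a 3-bp site in the element: ACA
#' marks the Ta subset, ACG the older pre-Ta subset.
#'
#' @param body Element body 5'->3' (forward orientation).
#' @param library An [element_library()] whose L1 metadata carries the
#'   diagnostic site position.
#' @param truncation 5' truncation offset of the body.
#' @return `"Ta"`, `"preTa"`, or `"n/a"` when the site is not covered or
#'   carries another base.
#' @export
l1_subset <- function(body, library, truncation = 0L) {
  m <- library$meta$L1
  if (is.null(m) || is.null(m$ta_diagnostic_start)) return("n/a")
  idx <- m$ta_diagnostic_start - as.integer(truncation)
  if (is.na(idx) || idx < 1L || idx + 2L > nchar(body)) return("n/a")
  tri <- substr(body, idx, idx + 2L)
  if (tri == m$preta_base) "preTa" else if (tri == m$ta_base) "Ta" else "n/a"
}

#' Classify a table of insertion calls
#'
#' Runs [classify_family()], [measure_truncation()], [detect_inversion()]
#' and [l1_subset()] over the `body_seq` column of a call table.
#'
#' @param calls Tibble of insertion calls from [characterize_insertions()].
#' @param library An [element_library()].
#' @return `calls` with classification columns appended: `family`, `strand`,
#'   `distance`, `truncation_offset`, `inversion`, `microhomology_length`,
#'   `l1_subset`, `diag_support`.
#' @export
classify_elements <- function(calls, library = element_library()) {
  cls <- purrr::map_dfr(seq_len(nrow(calls)), function(i) {
    body <- calls$body_seq[[i]]
    # fast paths first; a composite (inverted) body is cheaper to recognize
    # by split anchoring than by forcing a global alignment
    fam <- classify_family(body, library, align = FALSE)
    deferred <- fam$family == "unknown" && is.na(fam$distance)
    inv <- tibble::tibble(inversion = FALSE, microhomology_length = NA_integer_)
    subset <- "n/a"
    if (deferred) {
      for (cand in names(library$sequences)) {
        d <- detect_inversion(body, library$sequences[[cand]])
        if (d$inversion) {
          fam$family <- cand
          fam$truncation_offset <- NA_integer_
          inv <- d[, c("inversion", "microhomology_length")]
          break
        }
      }
      if (!inv$inversion) fam <- classify_family(body, library)
    }
    if (!inv$inversion && !fam$family %in% c("unknown", "polyN") &&
        !is.na(fam$truncation_offset)) {
      tpl <- library$sequences[[fam$family]]
      d <- detect_inversion(body, tpl)
      if (d$inversion) {
        inv <- d[, c("inversion", "microhomology_length")]
        fam$truncation_offset <- NA_integer_
      } else if (fam$family == "L1") {
        subset <- l1_subset(body, library, fam$truncation_offset)
      }
    }
    dplyr::bind_cols(fam[, c("family", "strand", "distance",
                             "truncation_offset", "diag_support")],
                     inv, tibble::tibble(l1_subset = subset))
  })
  dplyr::bind_cols(calls, cls)
}
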