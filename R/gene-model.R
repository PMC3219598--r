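#' Gene models and the transcript/genomic coordinate map
#'
#' A gene model is an ordered, contiguous set of exons in transcript (c.)
#' coordinates (the A of the ATG start codon is c.1), together with the
#' lengths of the introns separating them in a synthetic genomic frame. The
#' model maps any exonic position `c.N`, or intronic position `c.N+k` /
#' `c.N-k`, to a unique genomic offset and back.
#'
#' @param exons A data frame with columns `index`, `legacy_label`, `c_start`,
#'   `c_end`, `intron_after` (intron length in bp following the exon; 0 for
#'   the last exon). Exons must be strictly ordered and contiguous in c.
#'   coordinates.
#' @param transcript_id Identifier recorded on the model.
#' @param upstream_pad,downstream_pad Genomic padding (bp) before the first
#'   and after the last exon.
#' @return A `gene_model` tibble (one row per exon) carrying the genomic
#'   start of each exon in column `g_start` (1-based).
#' @export
gene_model <- function(exons, transcript_id = "synthetic", upstream_pad = 0L,
                       downstream_pad = 0L) {
  exons <- tibble::as_tibble(exons)
  need <- c("index", "c_start", "c_end", "intron_after")
  if (!all(need %in% names(exons))) {
    abort(paste0("gene model needs columns: ", paste(need, collapse = ", ")))
  }
  if (!"legacy_label" %in% names(exons)) exons$legacy_label <- as.character(exons$index)
  exons <- dplyr::arrange(exons, .data$c_start)
  stopifnot(all(exons$c_start <= exons$c_end))
  if (nrow(exons) > 1L) {
    gaps <- exons$c_start[-1L] - exons$c_end[-nrow(exons)]
    if (any(gaps != 1L)) {
      abort("exons must be contiguous and non-overlapping in c. coordinates")
    }
  }
  if (exons$c_start[[1L]] != 1L) abort("first exon must start at c.1")
  widths <- exons$c_end - exons$c_start + 1L
  g_start <- upstream_pad + 1L +
    cumsum(c(0L, widths[-length(widths)] + exons$intron_after[-length(widths)]))
  exons$g_start <- as.integer(g_start)
  structure(exons,
    class = c("gene_model", class(tibble::tibble())),
    transcript_id = transcript_id,
    upstream_pad = as.integer(upstream_pad),
    downstream_pad = as.integer(downstream_pad)
  )
}

#' Read a gene model from a TSV file
#'
#' @param path TSV with columns `index`, `legacy_label`, `c_start`, `c_end`,
#'   `intron_after` (lines starting with `#` are comments).
#' @inheritParams gene_model
#' @return A [gene_model()] object.
#' @export
read_gene_model <- function(path, transcript_id = "synthetic",
                            upstream_pad = 500L, downstream_pad = 500L) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(legacy_label = "c", .default = "?"))
  gene_model(tab, transcript_id = transcript_id,
             upstream_pad = upstream_pad, downstream_pad = downstream_pad)
}

#' Bundled synthetic NF1-surrogate gene model
#'
#' Exon boundaries anchored by published transcript-level (r.) intervals,
#' synthetic fill elsewhere; introns default to 2 kb except the two short
#' introns between exons 21-23.
#'
#' @return A [gene_model()].
#' @export
nf1_gene_model <- function() {
  read_gene_model(system.file("extdata", "nf1_gene_model.tsv",
                              package = "retrochar"),
                  transcript_id = "NF1-surrogate")
}

#' Parse a c.-style position
#'
#' @param x Position string such as `"1642"`, `"1642-12"` or `"1062+195"`
#'   (with or without a leading `"c."`), or a number.
#' @return A list with integer fields `base` and `intron_offset`.
#' @export
parse_c_position <- function(x) {
  if (is.list(x) && all(c("base", "intron_offset") %in% names(x))) return(x)
  if (is.numeric(x)) return(list(base = as.integer(x), intron_offset = 0L))
  x <- sub("^c\\.", "", trimws(x))
  m <- regmatches(x, regexec("^(\\d+)([+-]\\d+)?$", x))[[1L]]
  if (length(m) == 0L) abort(paste0("cannot parse c. position: '", x, "'"),
                             class = "retrochar_coordinate_error")
  list(base = as.integer(m[[2L]]),
       intron_offset = if (nzchar(m[[3L]])) as.integer(m[[3L]]) else 0L)
}

#' Format a parsed c. position back to its string form
#' @param pos A list as returned by [parse_c_position()].
#' @return A character scalar such as `"1642-12"`.
#' @export
format_c_position <- function(pos) {
  pos <- parse_c_position(pos)
  if (pos$intron_offset == 0L) as.character(pos$base)
  else paste0(pos$base, ifelse(pos$intron_offset > 0L, "+", ""), pos$intron_offset)
}

exon_of_base <- function(model, base) {
  hit <- which(model$c_start <= base & base <= model$c_end)
  if (length(hit) != 1L) {
    abort(paste0("c.", base, " is outside the model's transcript span"),
          class = "retrochar_coordinate_error")
  }
  hit
}

#' Map a c. position to a genomic offset
#'
#' Intronic offsets are resolved relative to the flanking exon boundary:
#' `c.N+k` counts into the intron after the exon ending at `c.N`, `c.N-k`
#' into the intron before the exon starting at `c.N`.
#'
#' @param model A [gene_model()].
#' @param pos A position accepted by [parse_c_position()].
#' @return A 0-based genomic offset into the model's frame.
#' @export
c_to_offset <- function(model, pos) {
  pos <- parse_c_position(pos)
  i <- exon_of_base(model, pos$base)
  g1 <- model$g_start[[i]] + (pos$base - model$c_start[[i]])
  k <- pos$intron_offset
  if (k > 0L) {
    if (pos$base != model$c_end[[i]] || i == nrow(model) || k > model$intron_after[[i]]) {
      abort(paste0("unresolvable intronic position c.", format_c_position(pos)),
            class = "retrochar_coordinate_error")
    }
    g1 <- g1 + k
  } else if (k < 0L) {
    if (pos$base != model$c_start[[i]] || i == 1L || -k > model$intron_after[[i - 1L]]) {
      abort(paste0("unresolvable intronic position c.", format_c_position(pos)),
            class = "retrochar_coordinate_error")
    }
    g1 <- g1 + k
  }
  g1 - 1L
}

#' Map a genomic offset back to a c. position
#'
#' Inverse of [c_to_offset()] for every offset covered by the model (exons
#' and introns; not the terminal pads). Intronic offsets take the nearer
#' exon boundary, the upstream one on ties.
#'
#' @inheritParams c_to_offset
#' @param offset 0-based genomic offset.
#' @return A list with fields `base` and `intron_offset`.
#' @export
offset_to_c <- function(model, offset) {
  g1 <- as.integer(offset) + 1L
  g_end <- model$g_start + (model$c_end - model$c_start)
  i <- which(model$g_start <= g1 & g1 <= g_end)
  if (length(i) == 1L) {
    return(list(base = model$c_start[[i]] + (g1 - model$g_start[[i]]),
                intron_offset = 0L))
  }
  j <- which(g_end < g1 & g1 < c(model$g_start[-1L], Inf))
  if (length(j) == 1L && j == nrow(model)) j <- integer()  # beyond the gene
  if (length(j) != 1L) {
    abort(paste0("genomic offset ", offset, " is outside the modelled gene"),
          class = "retrochar_coordinate_error")
  }
  up <- g1 - g_end[[j]]
  down <- model$g_start[[j + 1L]] - g1
  if (up <= down) list(base = model$c_end[[j]], intron_offset = up)
  else list(base = model$c_start[[j + 1L]], intron_offset = -down)
}

# total genomic length of the modelled frame including pads
model_genomic_length <- function(model) {
  n <- nrow(model)
  model$g_start[[n]] + (model$c_end[[n]] - model$c_start[[n]]) +
    attr(model, "downstream_pad")
}
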