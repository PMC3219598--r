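#' Classify transcript-level splicing effects
#'
#' Types the observed transcript consequence of each insertion into the six
#' patterns seen for L1 EN-mediated insertions:
#'
#' 1. intronic insertion in a splice region, complete skip of the adjacent
#'    exon;
#' 2. exonic insertion, complete skip of the affected exon;
#' 3. exonic insertion, loss of the exon's 3' portion via a cryptic 5' splice
#'    site upstream of the integration site;
#' 4. exonic insertion, loss of the exon's 5' portion via a cryptic 3' splice
#'    site downstream;
#' 5. exonic insertion, loss of the exon's 3' portion from the insertion
#'    point onward plus inclusion of a 5' fragment of the element (cryptic 5'
#'    site inside the element);
#' 6. intronic insertion, skip of an adjacent natural exon plus inclusion of
#'    an element-derived cryptic exon.
#'
#' Full inclusion of the element with no splicing change would be type 0
#' (none observed in the source data). Unmatched patterns are labelled
#' `"unclassified"` with a rationale. Classification is a pure function of
#' the site annotation, the observation and the model.
#'
#' @param annotated Calls annotated by [annotate_sites()] (needs
#'   `left_break`, `region`, `feature_index`).
#' @param observations Tibble with `case_id` and `products` (the observation
#'   string: `"lostStart:lostEnd[:gainLen]"` entries joined by `";"`), or a
#'   list-column of parsed products.
#' @param model A [gene_model()].
#' @return Tibble with one row per case: `splice_types` (per-product labels
#'   joined by `&`, e.g. `"2&3"`), `product_types` (list-column of integer
#'   vectors, NA for unclassified), `frame_status`, `net_exonic_change`
#'   (first product), `rationale`.
#' @export
classify_splice_effects <- function(annotated, observations, model) {
  obs <- observations[, c("case_id", "products")]
  tab <- dplyr::left_join(annotated, obs, by = "case_id")
  purrr::map_dfr(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    if (is.na(r$products)) {
      abort(paste0("no transcript observation for ", r$case_id),
            class = "retrochar_coordinate_error")
    }
    prods <- parse_products(r$products)
    res <- lapply(prods, function(p) classify_one_product(r, p, model))
    types <- vapply(res, function(x) x$type, character(1))
    frames <- classify_frame(prods)
    tibble::tibble(
      case_id = r$case_id,
      splice_types = paste(types, collapse = "&"),
      product_types = list(suppressWarnings(as.integer(types))),
      frame_status = paste(frames$frame_status, collapse = ";"),
      net_exonic_change = frames$net_exonic_change[[1L]],
      rationale = paste(vapply(res, function(x) x$why, character(1)),
                        collapse = " | "))
  })
}

classify_one_product <- function(r, p, model) {
  if (p$lost_start > p$lost_end ||
      p$lost_end > max(model$c_end) || p$lost_start < 1L) {
    abort(paste0("observation interval outside the model for ", r$case_id),
          class = "retrochar_coordinate_error")
  }
  lost_exon <- exon_of_base(model, p$lost_start)
  full <- p$lost_start == model$c_start[[lost_exon]] &&
    p$lost_end == model$c_end[[lost_exon]]
  if (r$region == "intronic") {
    adjacent <- abs(lost_exon - r$feature_index) <= 1L
    if (full && adjacent && p$gain == 0L) {
      side <- if (lost_exon > r$feature_index) "downstream" else "upstream"
      ext <- if (side == "upstream" && r$splice_region_class != "none") ""
        else if (side == "upstream") " (donor-side extension of the pattern)"
        else ""
      return(list(type = "1", why = paste0("intronic insertion; complete skip of the ",
                                           side, " exon", ext)))
    }
    if (full && adjacent && p$gain > 0L) {
      return(list(type = "6", why = paste0(
        "intronic insertion; skip of the adjacent exon plus inclusion of a ",
        p$gain, "-nt element-derived cryptic exon")))
    }
    return(list(type = "unclassified",
                why = "intronic insertion with an unmatched transcript pattern"))
  }
  # exonic insertion
  e <- r$feature_index
  idx <- which(model$index == e)
  ex_start <- model$c_start[[idx]]; ex_end <- model$c_end[[idx]]
  junction_right_c <- offset_to_c(model, r$left_break)$base
  if (lost_exon != idx) {
    return(list(type = "unclassified",
                why = "lost interval is not in the inserted exon"))
  }
  if (full && p$gain == 0L) {
    return(list(type = "2", why = "exonic insertion; complete exon skip"))
  }
  if (p$gain > 0L && p$lost_end == ex_end && p$lost_start == junction_right_c) {
    return(list(type = "5", why = paste0(
      "exonic insertion; 3' exon portion lost from the insertion point, ",
      p$gain, " nt of the element's 5' end retained (cryptic 5' site in the element)")))
  }
  if (p$gain == 0L && p$lost_end == ex_end && p$lost_start > ex_start) {
    return(list(type = "3",
                why = "exonic insertion; 3' exon portion lost (cryptic 5' site upstream)"))
  }
  if (p$gain == 0L && p$lost_start == ex_start && p$lost_end < ex_end) {
    return(list(type = "4",
                why = "exonic insertion; 5' exon portion lost (cryptic 3' site downstream)"))
  }
  list(type = "unclassified", why = "exonic insertion with an unmatched transcript pattern")
}

#' Tally splicing-effect categories
#'
#' @param effects Output of [classify_splice_effects()].
#' @param annotations Output of [annotate_sites()] for the same cases.
#' @return A list with `by_type` (tibble of product counts per type),
#'   `n_exonic`, `n_exonic_pure_skip` (exonic cases whose only effect is a
#'   complete exon skip, type 2), `n_exonic_pure_cryptic5` (exonic cases
#'   whose only effect is type 3), `n_exonic_cryptic3` (type 4),
#'   `n_acceptor_region_intronic` (intronic cases in the 3' splice region).
#' @export
tally_splice_effects <- function(effects, annotations) {
  if (nrow(effects) == 0L) abort("no splice-effect calls to tally")
  tab <- dplyr::left_join(effects,
                          annotations[, c("case_id", "region",
                                          "splice_region_class")],
                          by = "case_id")
  by_type <- tab |>
    tidyr::separate_rows("splice_types", sep = "&") |>
    dplyr::count(.data$splice_types, name = "n_products")
  exonic <- tab[tab$region == "exonic", ]
  list(
    by_type = by_type,
    n_exonic = nrow(exonic),
    n_exonic_pure_skip = sum(exonic$splice_types == "2"),
    n_exonic_pure_cryptic5 = sum(exonic$splice_types == "3"),
    n_exonic_cryptic3 = sum(exonic$splice_types == "4"),
    n_acceptor_region_intronic = sum(tab$region == "intronic" &
                                       tab$splice_region_class != "none")
  )
}
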