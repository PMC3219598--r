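#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Reproduce the published per-case and site summaries end-to-end
#'
#' Builds the 18 reconstructed fixtures, characterizes every allele pair
#' blind, classifies the inserted elements, infers and annotates the
#' integration sites, detects recurrent sites and clusters, emits the HGVS
#' names and splice-effect types, and checks every recovered value against
#' the per-case truth carried by the fixture set.
#'
#' @param fixtures A `tprt_fixtures` set ([build_fixture_set()] by default).
#' @param grouping_window Recurrence grouping window (bp).
#' @param cluster_window,cluster_min Cluster window length (bp) and minimum
#'   insertion count.
#' @return An object of class `tprt_reproduction`: list with `summary` (the
#'   per-case table), `calls`, `recurrence`, `clusters`, `effects`, `tally`,
#'   `names` (HGVS descriptions) and `checks` (tibble of per-field
#'   truth-vs-observed assertions).
#' @export
reproduce_insertion_tables <- function(fixtures = build_fixture_set(),
                                       grouping_window = 12L,
                                       cluster_window = 1500L,
                                       cluster_min = 3L) {
  model <- fixtures$model
  lib <- fixtures$library
  truth <- fixtures$cases
  calls <- characterize_insertions(fixtures, library = lib)
  calls <- classify_elements(calls, lib)
  calls <- infer_nick(calls)
  calls <- annotate_sites(calls, model)
  recurrence <- find_recurrent_sites(calls, grouping_window = grouping_window)
  clusters <- find_clusters(calls, window_bp = cluster_window,
                            min_count = cluster_min)
  effects <- classify_splice_effects(calls, truth[, c("case_id", "products")],
                                     model)
  tally <- tally_splice_effects(effects, calls)
  names_tbl <- tibble::tibble(
    case_id = calls$case_id,
    c_description = vapply(seq_len(nrow(calls)), function(i) {
      name_insertion(calls[i, ], calls[i, ], model, lib)
    }, character(1)),
    c_strict = vapply(seq_len(nrow(calls)), function(i) {
      name_insertion(calls[i, ], calls[i, ], model, lib, strict = TRUE)
    }, character(1)),
    r_description = vapply(truth$products, function(p) {
      name_transcript_effect(parse_products(p))
    }, character(1), USE.NAMES = FALSE)
  )
  summary <- render_summary(calls, calls, calls, effects,
                            recurrence = recurrence,
                            reference = fixtures$reference)
  summary <- dplyr::left_join(summary, names_tbl, by = "case_id")

  chk <- function(field, expected, observed) {
    tibble::tibble(case_id = truth$case_id, field = field,
                   expected = as.character(expected),
                   observed = as.character(observed),
                   pass = !is.na(expected) &
                     as.character(expected) == as.character(observed))
  }
  m <- match(truth$case_id, calls$case_id)
  e <- match(truth$case_id, effects$case_id)
  checks <- dplyr::bind_rows(
    chk("tsd_length", truth$tsd_expected, calls$tsd_length[m]),
    chk("target_deletion_length", truth$target_deletion_length,
        calls$target_deletion_length[m]),
    chk("orientation", truth$orientation, calls$orientation[m]),
    chk("family", truth$family, calls$family[m]),
    chk("poly_tail_length", truth$tail_expected, calls$poly_tail_length[m]),
    chk("truncation", truth$truncation, calls$truncation_offset[m]),
    chk("nick_position", truth$nick_g, calls$nick_position[m]),
    chk("l1_subset", truth$l1_subset, ifelse(calls$l1_subset[m] == "n/a",
                                             NA, calls$l1_subset[m])),
    chk("splice_types", truth$splice_type_printed, effects$splice_types[e]),
    chk("reconstruction",
        rep("ok", nrow(truth)),
        vapply(seq_len(nrow(truth)), function(i) {
          if (identical(apply_call(fixtures$reference, calls[m[i], ]),
                        truth$mutant[[i]])) "ok" else "mismatch"
        }, character(1)))
  )
  checks <- checks[!is.na(checks$expected), ]
  structure(list(summary = summary, calls = calls, recurrence = recurrence,
                 clusters = clusters, effects = effects, tally = tally,
                 names = names_tbl, checks = checks, fixtures = fixtures),
            class = "tprt_reproduction")
}

#' @export
print.tprt_reproduction <- function(x, ...) {
  cat("<tprt_reproduction> ", nrow(x$summary), " cases; ",
      x$recurrence$n_distinct_sites, " distinct sites (",
      x$recurrence$n_multiply_used, " used twice); ",
      nrow(x$clusters$windows), " cluster window(s); checks: ",
      sum(x$checks$pass), "/", nrow(x$checks), " pass\n", sep = "")
  invisible(x)
}

#' @rdname reproduce_insertion_tables
#' @param x A `tprt_reproduction`.
#' @param ... Unused.
#' @method tidy tprt_reproduction
#' @export
tidy.tprt_reproduction <- function(x, ...) x$checks

#' @rdname reproduce_insertion_tables
#' @method glance tprt_reproduction
#' @export
glance.tprt_reproduction <- function(x, ...) {
  fams <- table(x$calls$family)
  tibble::tibble(
    n_cases = nrow(x$summary),
    n_checks_pass = sum(x$checks$pass),
    n_checks = nrow(x$checks),
    n_distinct_sites = x$recurrence$n_distinct_sites,
    n_multiply_used = x$recurrence$n_multiply_used,
    n_cluster_windows = nrow(x$clusters$windows),
    n_AluY = as.integer(fams["AluY"] %||% 0L),
    n_AluYa5 = as.integer(fams["AluYa5"] %||% 0L),
    n_AluYb8 = as.integer(fams["AluYb8"] %||% 0L),
    n_L1 = as.integer(fams["L1"] %||% 0L),
    n_truncated_alu = sum(grepl("^Alu", x$calls$family) &
                            !is.na(x$calls$truncation_offset) &
                            x$calls$truncation_offset >= 5L),
    n_exonic = x$tally$n_exonic,
    n_exonic_pure_skip = x$tally$n_exonic_pure_skip
  )
}

#' @rdname reproduce_insertion_tables
#' @param object A `tprt_reproduction`.
#' @method autoplot tprt_reproduction
#' @export
autoplot.tprt_reproduction <- function(object, ...) {
  calls <- object$calls
  wins <- object$clusters$windows
  p <- ggplot2::ggplot(calls,
                       ggplot2::aes(x = .data$nick_position, y = 0)) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$family,
                                      shape = .data$orientation),
                         height = 0.15, width = 0, size = 2.5) +
    ggplot2::labs(x = "genomic position (synthetic frame, bp)", y = NULL,
                  title = "De novo insertion sites along the gene",
                  subtitle = paste0(object$recurrence$n_distinct_sites,
                                    " distinct integration sites")) +
    ggplot2::scale_y_continuous(breaks = NULL, limits = c(-1, 1)) +
    ggplot2::theme_minimal()
  if (nrow(wins)) {
    p <- p + ggplot2::annotate("rect", xmin = wins$start, xmax = wins$end,
                               ymin = -0.5, ymax = 0.5, alpha = 0.15,
                               fill = "red")
  }
  p
}

#' Benchmark blind recovery on simulated data
#'
#' Simulates `n` TPRT events with full ground truth, characterizes and
#' classifies them blind, and reports per-field exact-recovery rates.
#'
#' @param n Number of simulated events (>= 1).
#' @param config A [simulation_config()].
#' @param library An [element_library()].
#' @param seed RNG seed (fixed seeds give reproducible metrics).
#' @return An object of class `tprt_benchmark`: list with `truth` and
#'   `calls` (per-event tibbles), `recovery` (per-field logical matrix) and
#'   `rates` (per-field recovery rates).
#' @export
benchmark_simulation <- function(n, config = simulation_config(),
                                 library = element_library(), seed = NULL) {
  if (n < 1L) abort("n must be >= 1")
  sim <- simulate_dataset(n, config = config, library = library, seed = seed)
  ev <- sim$events
  calls <- characterize_insertions(
    ev[, c("case_id", "reference", "mutant")], library = library)
  calls <- classify_elements(calls, library)
  calls <- infer_nick(calls)
  ok <- tibble::tibble(
    case_id = ev$case_id,
    tsd_length = ev$tsd_length == calls$tsd_length,
    target_deletion_length = ev$target_deletion_length ==
      calls$target_deletion_length,
    poly_tail_length = ev$polyA_length == calls$poly_tail_length,
    orientation = ev$orientation == calls$orientation,
    family = ifelse(ev$element == "polyN", calls$family == "polyN",
                    ev$element == calls$family),
    truncation = ifelse(ev$element == "polyN" | ev$inversion, NA,
                        ev$truncation_offset == calls$truncation_offset),
    inversion = ev$inversion == calls$inversion,
    microhomology = ifelse(ev$inversion,
                           ev$microhomology_length == calls$microhomology_length,
                           NA),
    nontemplated_5prime = ifelse(ev$element == "polyN", NA,
                                 ev$nontemplated_5prime ==
                                   calls$nontemplated_5prime),
    nick_position = ev$site_offset == calls$nick_position
  )
  rates <- tidyr::pivot_longer(ok, -"case_id", names_to = "field",
                               values_to = "exact") |>
    dplyr::group_by(.data$field) |>
    dplyr::summarise(n = sum(!is.na(.data$exact)),
                     recovered = sum(.data$exact, na.rm = TRUE),
                     rate = mean(.data$exact, na.rm = TRUE),
                     .groups = "drop")
  structure(list(truth = ev, calls = calls,
                 recovery = ok, rates = rates, config = config),
            class = "tprt_benchmark")
}

#' @export
print.tprt_benchmark <- function(x, ...) {
  cat("<tprt_benchmark> ", nrow(x$recovery), " simulated events\n", sep = "")
  print(x$rates)
  invisible(x)
}

#' @rdname benchmark_simulation
#' @param x,object A `tprt_benchmark`.
#' @param ... Unused.
#' @method tidy tprt_benchmark
#' @export
tidy.tprt_benchmark <- function(x, ...) x$rates

#' @rdname benchmark_simulation
#' @method glance tprt_benchmark
#' @export
glance.tprt_benchmark <- function(x, ...) {
  tibble::tibble(n_events = nrow(x$recovery),
                 fields = nrow(x$rates),
                 min_rate = min(x$rates$rate),
                 mean_rate = mean(x$rates$rate))
}

#' @rdname benchmark_simulation
#' @method autoplot tprt_benchmark
#' @export
autoplot.tprt_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$rates,
                  ggplot2::aes(x = stats::reorder(.data$field, .data$rate),
                               y = .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "exact recovery rate",
                  title = "Blind recovery of simulated TPRT events") +
    ggplot2::theme_minimal()
}
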