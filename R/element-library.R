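#' Load an element template library
#'
#' A library pairs a FASTA of element consensus sequences (5'->3', without
#' poly(A) tail) with sidecar YAML metadata describing each family: its class
#' (Alu or L1), diagnostic substitution positions for the young Alu
#' subfamilies, and for L1 the ORF geometry plus the trinucleotide site that
#' discriminates the Ta (ACA) and pre-Ta (ACG) subsets. The default library
#' bundles synthetic consensus stand-ins for AluY, AluYa5, AluYb8 and a
#' 6021-bp L1 (see `system.file("extdata", "synthetic_elements.fa")`).
#'
#' @param fasta,meta Paths to the FASTA and YAML files; `NULL` for the
#'   bundled synthetic library.
#' @return An object of class `element_library`: a list with `sequences`
#'   (named character vector) and `meta` (named list of per-family metadata).
#' @export
element_library <- function(fasta = NULL, meta = NULL) {
  fasta <- fasta %||% system.file("extdata", "synthetic_elements.fa",
                                  package = "retrochar")
  meta <- meta %||% system.file("extdata", "synthetic_elements.yaml",
                                package = "retrochar")
  recs <- read_fasta(fasta)
  if (nrow(recs) == 0L) abort("element library FASTA contains no records",
                              class = "retrochar_config_error")
  seqs <- stats::setNames(recs$seq, recs$id)
  info <- yaml::read_yaml(meta)$families
  for (nm in names(seqs)) {
    if (!is.null(info[[nm]]$length) && info[[nm]]$length != nchar(seqs[[nm]])) {
      abort(paste0("library metadata length mismatch for ", nm),
            class = "retrochar_config_error")
    }
  }
  # reverse complements cached once; anchoring scans both strands repeatedly
  structure(list(sequences = seqs,
                 rc_sequences = vapply(seqs, revcomp, character(1)),
                 meta = info),
            class = "element_library")
}

#' @export
print.element_library <- function(x, ...) {
  cat("<element_library> ", length(x$sequences), " templates: ",
      paste0(names(x$sequences), " (", nchar(x$sequences), " bp)",
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

# fetch one template sequence, with a configuration error when absent
library_template <- function(library, family) {
  if (!family %in% names(library$sequences)) {
    abort(paste0("element family '", family, "' absent from library"),
          class = "retrochar_config_error")
  }
  library$sequences[[family]]
}
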