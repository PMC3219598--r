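#' Read a FASTA file into a tibble
#'
#' Minimal strict FASTA reader for allele and element sequences. Sequences are
#' uppercased and restricted to the alphabet `ACGTN`; anything else is a
#' format error that names the offending line, which is part of this
#' function's contract (malformed inputs must be diagnosable by line).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header) and `seq`.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  ids <- character()
  seqs <- character()
  cur <- NULL
  buf <- character()
  flush <- function() {
    if (!is.null(cur)) {
      ids <<- c(ids, cur)
      seqs <<- c(seqs, paste(buf, collapse = ""))
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^>", ln)) {
      flush()
      cur <- sub("\\s.*$", "", sub("^>", "", ln))
      if (!nzchar(cur)) abort(paste0("FASTA format error at line ", i, ": empty header"))
      buf <- character()
    } else if (nzchar(trimws(ln))) {
      if (is.null(cur)) {
        abort(paste0("FASTA format error at line ", i, ": sequence before any header"))
      }
      sq <- toupper(gsub("\\s", "", ln))
      if (grepl("[^ACGTN]", sq)) {
        abort(paste0("FASTA format error at line ", i, ": non-ACGTN character"))
      }
      buf <- c(buf, sq)
    }
  }
  flush()
  tibble::tibble(id = ids, seq = seqs)
}

#' Write sequences to a FASTA file
#'
#' @param records A data frame with columns `id` and `seq`, or a named
#'   character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly. `read_fasta(write_fasta(x))` round-trips `x`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.character(records)) {
    records <- tibble::tibble(id = names(records), seq = unname(records))
  }
  stopifnot(all(c("id", "seq") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[[k]]), con)
    s <- toupper(records$seq[[k]])
    if (nchar(s) == 0L) next
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
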