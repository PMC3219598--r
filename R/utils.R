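# Internal string helpers. Sequences are plain uppercase character scalars
# (ACGTN); Biostrings is used where real sequence machinery is needed
# (reverse complement, alignment), raw-vector tricks where a tight loop over
# a 100-kb string would otherwise dominate.

#' @importFrom rlang abort warn .data %||%
NULL

#' Reverse complement of a DNA string
#'
#' @param x A character scalar over the alphabet ACGTN.
#' @return The reverse complement, same alphabet.
#' @examples
#' revcomp("ACGTT")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", x))))
}

complement_chr <- function(x) chartr("ACGTN", "TGCAN", x)

str_rev <- function(x) {
  if (nchar(x) == 0L) return(x)
  intToUtf8(rev(utf8ToInt(x)))
}

# longest common prefix length of two strings
lcp_len <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  neq <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

# longest common suffix length of two strings
lcs_len <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  neq <- which(rev(ra)[seq_len(n)] != rev(rb)[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

# length of the homopolymer run of `base` at the start/end of x, allowing a
# mismatch fraction <= impurity (greedy; the run must start and end on `base`)
run_length <- function(x, base, from = c("start", "end"), impurity = 0) {
  from <- match.arg(from)
  n <- nchar(x)
  if (n == 0L) return(0L)
  chars <- charToRaw(x)
  if (from == "end") chars <- rev(chars)
  hit <- chars == charToRaw(base)
  if (!hit[1L]) return(0L)
  if (impurity <= 0) {
    miss <- which(!hit)
    return(if (length(miss) == 0L) n else miss[1L] - 1L)
  }
  best <- 0L
  mism <- 0L
  for (i in seq_len(n)) {
    if (!hit[i]) mism <- mism + 1L
    if (mism / i <= impurity && hit[i]) best <- i
  }
  best
}

# evaluates expr under a fixed seed without
# touching the caller's RNG stream (used for the bundled fixture background)
with_fixed_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

`substr_set<-` <- function(x, start, value) {
  substr(x, start, start + nchar(value) - 1L) <- value
  x
}
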