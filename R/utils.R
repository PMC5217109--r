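# Low-level sequence helpers shared across the package. Sequences are plain
# uppercase character scalars over {A,C,G,T}; coordinates are 0-based,
# half-open; cut positions are between-base junction coordinates in 0..len.

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param seq Uppercase DNA string over `{A,C,G,T}`.
#' @return The reverse complement as a character scalar.
#' @examples
#' revcomp("CCCGC")
#' @export
revcomp <- function(seq) {
  check_dna(seq)
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]),
                               collapse = ""))
}

check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    abort(sprintf("%s must be a non-empty character scalar", what))
  }
  bad <- stringr::str_detect(seq, "[^ACGT]")
  if (bad) {
    offending <- stringr::str_extract(seq, "[^ACGT]")
    abort(sprintf("non-ACGT character '%s' in %s", offending, what))
  }
  invisible(seq)
}

# substring with 0-based half-open coords; subseq0(s, 2, 5) == chars 3..5
subseq0 <- function(s, start, end) {
  if (end <= start) return("")
  substr(s, start + 1L, end)
}

# longest common prefix length of two strings
lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- charToRaw(a)[seq_len(n)]
  bv <- charToRaw(b)[seq_len(n)]
  neq <- which(av != bv)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

# longest common suffix length
lcs_len <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  n <- min(na, nb)
  if (n == 0L) return(0L)
  av <- rev(charToRaw(a))[seq_len(n)]
  bv <- rev(charToRaw(b))[seq_len(n)]
  neq <- which(av != bv)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

# all 0-based start positions of exact occurrences of `pattern` in `subject`
find_all <- function(subject, pattern) {
  if (nchar(pattern) == 0L || nchar(pattern) > nchar(subject)) return(integer())
  hits <- integer()
  from <- 1L
  repeat {
    i <- regexpr(pattern, substr(subject, from, nchar(subject)), fixed = TRUE)
    if (i == -1L) break
    hits <- c(hits, from + i - 2L)   # to 0-based
    from <- from + i
  }
  hits
}

# run `expr` under a fixed RNG state without touching the caller's stream
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

random_dna <- function(n) {
  paste(sample(DNA_ALPHABET, n, replace = TRUE), collapse = "")
}
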