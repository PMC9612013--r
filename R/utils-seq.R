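# Low-level sequence helpers. Sequences are plain upper-case character
# scalars internally; Biostrings handles I/O and reverse complement.

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- character(length(x))
  nz <- nchar(x) > 0
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

# i.i.d. random DNA with a given GC fraction
random_dna <- function(n, gc_content) {
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

gc_fraction <- function(x) {
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(x), c("G", "C"))
  sum(counts) / nchar(x)
}

# Substring on a circular sequence, 1-based inclusive; wraps when start > end.
circular_substr <- function(seq, start, end) {
  n <- nchar(seq)
  stopifnot(start >= 1, start <= n, end >= 1, end <= n)
  if (start <= end) {
    substr(seq, start, end)
  } else {
    paste0(substr(seq, start, n), substr(seq, 1, end))
  }
}

# Rotate a circular sequence so that position `start` becomes position 1.
rotate_seq <- function(seq, start) {
  n <- nchar(seq)
  start <- ((start - 1) %% n) + 1
  if (start == 1) return(seq)
  paste0(substr(seq, start, n), substr(seq, 1, start - 1))
}

# All k-mers of a sequence as a character vector (empty if too short).
seq_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, seq_len(n - k + 1), seq(k, n))
}

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer.", class = "plastidkit_param_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
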