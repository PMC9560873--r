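# Small sequence helpers shared across modules.  Sequences are plain upper
# case character scalars over A,C,G,T,N; coordinates are 0-based half-open
# unless a function says otherwise.

#' Reverse complement of a DNA string
#'
#' @param x character scalar over A,C,G,T,N (case kept upper).
#' @return reverse-complemented character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(x), "", fixed = TRUE)[[1L]]),
                                 collapse = ""))
}

# fast byte view of a sequence (A=65 C=67 G=71 T=84 N=78)
seq_bytes <- function(x) utf8ToInt(toupper(x))

check_dna <- function(x, allow_n = TRUE) {
  b <- seq_bytes(x)
  ok <- b %in% if (allow_n) c(65L, 67L, 71L, 84L, 78L) else c(65L, 67L, 71L, 84L)
  if (!all(ok))
    stop("sequence contains characters outside ",
         if (allow_n) "A/C/G/T/N" else "A/C/G/T",
         " at position ", which(!ok)[1L])
  invisible(toupper(x))
}

substr0 <- function(x, start, end) {
  # 0-based half-open extraction
  if (end <= start) return("")
  substr(x, start + 1L, end)
}

# deterministic scoped RNG: run expr under a seed without clobbering the
# caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

random_dna <- function(len, gc = 0.38) {
  if (len <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# package-level cache (oracle tables, codon machinery)
.plastcomp_cache <- new.env(parent = emptyenv())
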