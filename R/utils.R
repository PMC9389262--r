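# Internal sequence helpers. Sequences are plain uppercase character strings
# over {A,C,G,T,N}; hot paths work on integer (UTF-8 code point) vectors.

.BASE_INT <- c(A = 65L, C = 67L, G = 71L, T = 84L, N = 78L)

.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.seq_to_int <- function(x) utf8ToInt(x)

.int_to_seq <- function(x) intToUtf8(x)

#' Reverse-complement a DNA string
#'
#' Works on plain character vectors over the alphabet `{A,C,G,T,N}` (an `N`
#' complements to `N`).
#'
#' @param x character vector of uppercase DNA strings.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  vapply(x, function(s) {
    v <- rev(utf8ToInt(s))
    # A<->T (65/84), C<->G (67/71); N (78) maps to itself
    out <- v
    out[v == 65L] <- 84L
    out[v == 84L] <- 65L
    out[v == 67L] <- 71L
    out[v == 71L] <- 67L
    intToUtf8(out)
  }, character(1), USE.NAMES = FALSE)
}

# Clean a raw sequence read from disk: uppercase, non-ACGT IUPAC -> N.
.clean_seq <- function(x) {
  x <- toupper(x)
  gsub("[^ACGT]", "N", x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. With seed = NULL the current stream is used.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Base probabilities (A,C,G,T) from a GC content, A/T and C/G split equally
# unless an explicit length-4 vector is given.
.base_probs <- function(gc = 0.332, base_probs = NULL) {
  if (!is.null(base_probs)) {
    stopifnot(length(base_probs) == 4, all(base_probs >= 0))
    p <- as.numeric(base_probs)
    if (abs(sum(p) - 1) > 1e-12) stop("base_probs must sum to 1")
    names(p) <- c("A", "C", "G", "T")
    return(p)
  }
  stopifnot(gc > 0, gc < 1)
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}
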