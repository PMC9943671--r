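# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL leaves the global RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed; keeps results < 2^31.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 101L + as.integer(offset)) %% 2147483629L
}

str_rev <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Reverse complement of DNA strings
#'
#' Plain character-vector reverse complement (uppercase DNA alphabet).
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @keywords internal
rc_dna <- function(x) str_rev(chartr("ACGT", "TGCA", toupper(x)))

rna_to_dna <- function(x) chartr("U", "T", toupper(x))
dna_to_rna <- function(x) chartr("T", "U", toupper(x))

# DNA arm that hybridizes a given RNA window (reverse complement across
# the RNA/DNA duplex: A-T, U-A, G-C, C-G).
arm_for_rna <- function(rna_window) rc_dna(rna_to_dna(rna_window))

gc_fraction <- function(x) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)
  vapply(ch, function(s) mean(s %in% c("G", "C")), numeric(1))
}

# All k-mers of a sequence as a character vector (empty if too short).
kmers <- function(x, k) {
  x <- toupper(x)
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

max_homopolymer <- function(x) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  max(rle(ch)$lengths)
}

random_seq <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

is_purine <- function(base) base %in% c("A", "G")
is_pyrimidine <- function(base) base %in% c("U", "C", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a
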