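# Low-level sequence helpers shared across the pipeline.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC code for a sorted set of bases, and the reverse mapping.
.IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
            AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
            ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")
.IUPAC_MEMBERS <- setNames(strsplit(names(.IUPAC), ""), unname(.IUPAC))

#' IUPAC ambiguity code for a set of bases
#'
#' @param bases character vector of bases drawn from A, C, G, T.
#' @return single IUPAC letter covering exactly the given set.
#' @export
iupac_code <- function(bases) {
  key <- paste(sort(unique(toupper(bases))), collapse = "")
  code <- .IUPAC[key]
  if (is.na(code)) stop("not a set of DNA bases: ", key)
  unname(code)
}

#' Bases represented by an IUPAC letter
#'
#' @param code single IUPAC nucleotide letter (case-insensitive).
#' @return character vector of the member bases (A/C/G/T).
#' @export
iupac_members <- function(code) {
  m <- .IUPAC_MEMBERS[[toupper(code)]]
  if (is.null(m)) character(0) else m
}

#' Reverse complement
#'
#' Complements IUPAC letters and preserves case; gaps and `?` pass through.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse-complemented strings.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYKMBDHVacgtrykmbdhv", "TGCAYRMKVHDBtgcayrmkvhdb", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

# Split a DNA string into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Random i.i.d. uniform-base DNA string(s).
random_dna <- function(n_len) {
  paste(sample(DNA_BASES, n_len, replace = TRUE), collapse = "")
}

# All consecutive k-mers of a string (character vector; empty if too short).
consecutive_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

# Spaced k-mers sampling `k` positions every `step` bases (span (k-1)*step+1).
spaced_kmers <- function(x, k = 20L, step = 3L) {
  span <- (k - 1L) * step + 1L
  n <- nchar(x)
  if (n < span) return(character(0))
  ch <- seq_chars(x)
  starts <- seq_len(n - span + 1L)
  idx <- outer(starts, (0:(k - 1L)) * step, "+")
  apply(matrix(ch[idx], nrow = length(starts)), 1L, paste, collapse = "")
}

# Substitute each base with probability p by one of the other three bases.
# Returns list(seq, errors = integer positions changed).
mutate_bases <- function(x, p) {
  ch <- seq_chars(x)
  hit <- which(runif(length(ch)) < p)
  for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  list(seq = paste(ch, collapse = ""), errors = hit)
}
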