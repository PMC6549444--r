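#' @keywords internal
"_PACKAGE"

## IUPAC nucleotide ambiguity codes and the set of bases each admits.
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Expand an IUPAC nucleotide code to the bases it admits
#'
#' @param code Single IUPAC letter (e.g. `"Y"`).
#' @return Character vector of unambiguous bases, e.g. `c("C","T")`.
#' @export
#' @examples
#' iupac_expand("Y")
iupac_expand <- function(code) {
  out <- IUPAC_CODES[[toupper(code)]]
  if (is.null(out)) stop("not an IUPAC nucleotide code: ", code)
  out
}

#' Merge nucleotides into the IUPAC code for their union
#'
#' Used to emit the consensus signal of a heterozygous male: the code whose
#' admitted base set is the union of the two alleles' bases.
#'
#' @param ... IUPAC letters to merge.
#' @return A single IUPAC letter.
#' @export
#' @examples
#' iupac_merge("C", "T")  # "Y"
iupac_merge <- function(...) {
  bases <- sort(unique(unlist(lapply(c(...), iupac_expand))))
  hit <- vapply(IUPAC_CODES, function(b) identical(sort(b), bases), logical(1))
  names(IUPAC_CODES)[hit][1]
}

#' Do two IUPAC codes admit a common base?
#'
#' @param a,b IUPAC letters (vectorised).
#' @return Logical vector.
#' @export
iupac_compatible <- function(a, b) {
  mapply(function(x, y) length(intersect(iupac_expand(x), iupac_expand(y))) > 0L,
         a, b, USE.NAMES = FALSE)
}

is_unambiguous_base <- function(x) x %in% c("A", "C", "G", "T")

## Substitution matrix over the IUPAC alphabet for anchoring alignments:
## +1 when the two codes admit a common base, -1 otherwise.
iupac_submat <- function(match = 1, mismatch = -1) {
  letters <- names(IUPAC_CODES)
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  for (a in letters) for (b in letters) {
    if (length(intersect(IUPAC_CODES[[a]], IUPAC_CODES[[b]])) > 0L) m[a, b] <- match
  }
  m
}

seq_chars <- function(x) strsplit(toupper(as.character(x)), "")[[1]]
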