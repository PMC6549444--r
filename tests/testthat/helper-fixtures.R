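panel <- default_panel()

## site-wise IUPAC consensus of two equal-length allele sequences, as a
## heterozygous male's single Sanger trace would read
het_consensus <- function(s1, s2) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  stopifnot(length(a) == length(b))
  paste(mapply(function(x, y) if (x == y) x else iupac_merge(x, y), a, b),
        collapse = "")
}

mutate_at <- function(seq, idx, base) {
  s <- strsplit(seq, "")[[1]]
  s[idx] <- base
  paste(s, collapse = "")
}

delete_at <- function(seq, idx) {
  paste0(substr(seq, 1, idx - 1), substr(seq, idx + 1, nchar(seq)))
}

other_base <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]

## independent brute-force global alignment score (affine gaps), used as the
## oracle for the anchoring alignment on small windows
brute_force_align_score <- function(a, b, match = 1, mismatch = -1,
                                    gap_open = 12, gap_ext = 0.25) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - gap_ext * (j - 1)
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - gap_ext * (i - 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (a[i - 1] == b[j - 1]) match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, X[i - 1, j] - gap_ext)
    Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Y[i, j - 1] - gap_ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}
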