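#' Tamura-Nei (TN93) distance between two aligned sequences
#'
#' Maximum-likelihood TN93 distance with base frequencies estimated from the
#' pooled pair. Sites with a gap (`-`) or any IUPAC ambiguity in either
#' sequence are excluded (pairwise deletion). Saturation (a non-positive
#' logarithm argument) yields `Inf`.
#'
#' @param a,b Character sequences of equal length (pairwise-aligned; gaps as
#'   `-`).
#' @param min_sites Minimum number of comparable sites (default 20); fewer
#'   is an error (distance undefined).
#' @return Distance in substitutions per site.
#' @export
tn93_distance <- function(a, b, min_sites = 20L) {
  x <- seq_chars(a); y <- seq_chars(b)
  if (length(x) != length(y)) stop("sequences must be aligned to equal length")
  ok <- is_unambiguous_base(x) & is_unambiguous_base(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < min_sites) stop("fewer than ", min_sites, " comparable sites")

  pool <- c(x, y)
  g <- c(A = mean(pool == "A"), C = mean(pool == "C"),
         G = mean(pool == "G"), T = mean(pool == "T"))
  gR <- g["A"] + g["G"]; gY <- g["C"] + g["T"]

  P1 <- mean((x == "A" & y == "G") | (x == "G" & y == "A"))  # purine transitions
  P2 <- mean((x == "C" & y == "T") | (x == "T" & y == "C"))  # pyrimidine transitions
  diff <- x != y
  Q <- mean(diff) - P1 - P2                                   # transversions

  if (P1 + P2 + Q == 0) return(0)

  k1 <- 2 * g["A"] * g["G"] / gR
  k2 <- 2 * g["C"] * g["T"] / gY
  k3 <- 2 * (gR * gY - g["A"] * g["G"] * gY / gR - g["C"] * g["T"] * gR / gY)
  w1 <- if (k1 > 0) 1 - P1 / k1 - Q / (2 * gR) else 1
  w2 <- if (k2 > 0) 1 - P2 / k2 - Q / (2 * gY) else 1
  w3 <- 1 - Q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(Inf)
  d <- -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
  unname(max(d, 0))
}

#' Pairwise TN93 distance matrix
#'
#' Unaligned inputs are aligned per pair with a global gap-affine alignment
#' (IUPAC-aware scoring) before the distance is computed, so length-variable
#' intron haplotypes (e.g. carrying the 200-bp insertion) are handled;
#' pairwise deletion then drops the indel columns for that pair only.
#'
#' @param seqs Named character vector (or `DNAStringSet`) of sequences.
#' @param align Align each pair first (default `TRUE`; set `FALSE` when the
#'   input is already one aligned block).
#' @param min_sites Passed to [tn93_distance()].
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
tn93_matrix <- function(seqs, align = TRUE, min_sites = 20L) {
  seqs <- stats::setNames(toupper(as.character(seqs)), names(seqs))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) stop("sequences must be named")
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (align && nchar(seqs[i]) != nchar(seqs[j])) {
      pa <- Biostrings::pairwiseAlignment(
        pattern = seqs[[i]], subject = seqs[[j]], type = "global",
        substitutionMatrix = iupac_submat(), gapOpening = 12, gapExtension = 0.25)
      a <- as.character(Biostrings::pattern(pa))
      b <- as.character(Biostrings::subject(pa))
    } else {
      a <- seqs[[i]]; b <- seqs[[j]]
    }
    d[i, j] <- d[j, i] <- tn93_distance(a, b, min_sites = min_sites)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Ties in Q are
#' broken deterministically by the lexicographic order of the joined pair's
#' smallest member tip labels. Negative branch-length estimates are clamped
#' to zero with the deficit transferred to the sibling edge (their sum, the
#' distance between the joined nodes, is preserved), so the returned tree is
#' valid newick with nonnegative lengths. Exact on additive matrices up to
#' the tie-breaking rule.
#'
#' @param d Symmetric numeric matrix (or `dist`) with labels; at least 3
#'   tips, finite entries.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix must have labels")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distance matrix must be nonnegative")
  if (any(!is.finite(d))) stop("distance matrix must be finite")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 tips")

  newick <- rownames(d)            # growing subtree strings
  key <- rownames(d)               # smallest member tip label, for tie-breaks
  clamp_pair <- function(bi, bj) {
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    c(max(bi, 0), max(bj, 0))
  }
  fmt <- function(s, b) sprintf("%s:%.10g", s, b)

  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_key <- apply(cand, 1L, function(ij) {
      k <- sort(c(key[ij[1]], key[ij[2]])); paste(k, collapse = "\r")
    })
    pick <- cand[order(pair_key)[1L], ]
    i <- pick[[1]]; j <- pick[[2]]

    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- d[i, j] - bi
    b <- clamp_pair(bi, bj)
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    dk <- dk[-c(i, j)]

    ## canonical order inside the pair (smaller key first) so the serialized
    ## tree does not depend on input row order
    if (key[i] <= key[j]) {
      new_str <- sprintf("(%s,%s)", fmt(newick[i], b[1]), fmt(newick[j], b[2]))
    } else {
      new_str <- sprintf("(%s,%s)", fmt(newick[j], b[2]), fmt(newick[i], b[1]))
    }
    new_key <- min(key[i], key[j])
    keep <- setdiff(seq_len(m), c(i, j))
    d <- d[keep, keep, drop = FALSE]
    d <- rbind(cbind(d, dk), c(dk, 0))
    newick <- c(newick[keep], new_str)
    key <- c(key[keep], new_key)
  }

  ## final three nodes: closed-form star resolution
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  bs <- pmax(c(b1, b2, b3), 0)
  ord <- order(key)
  parts <- vapply(ord, function(k) fmt(newick[k], bs[k]), "")
  ape::read.tree(text = paste0("(", paste(parts, collapse = ","), ");"))
}

#' Clade composition around a focal tip
#'
#' For each nested clade containing the focal tip, from the smallest
#' outward (ancestors of the tip in the tree's rooted representation; an
#' unrooted NJ tree is traversed from its basal node), reports the fraction
#' of member tips -- excluding the focal tip itself -- in each host-plant
#' class and each COI strain class. The headline row is the smallest
#' non-trivial containing clade (the first with at least one member besides
#' the focal tip).
#'
#' @param tree An `ape::phylo`.
#' @param annotations Data frame with columns `tip`, `host_class`
#'   (`CS-host`/`RS-host`/`unknown`), `coi_strain` (`CS`/`RS`/`unknown`).
#'   Tips absent from the table are `unknown`.
#' @param focal Focal tip label (must be in the tree).
#' @return A `clade_composition`: data frame `report` (one row per nested
#'   clade: `clade`, `n_members`, host fractions, strain fractions) and
#'   `headline` (the first non-trivial row).
#' @export
clade_composition <- function(tree, annotations, focal) {
  if (!focal %in% tree$tip.label) stop("focal tip not in tree: ", focal)
  host_levels <- c("CS-host", "RS-host", "unknown")
  strain_levels <- c("CS", "RS", "unknown")
  ann_of <- function(tips, col, levels) {
    v <- annotations[[col]][match(tips, annotations$tip)]
    v[is.na(v) | !v %in% levels] <- "unknown"
    factor(v, levels = levels)
  }

  ntip <- length(tree$tip.label)
  tip_id <- match(focal, tree$tip.label)
  parent_of <- function(node) {
    e <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(e)) e[1] else NA_integer_
  }
  ## ancestors of the focal tip, nearest first
  anc <- integer()
  node <- tip_id
  repeat {
    node <- parent_of(node)
    if (is.na(node)) break
    anc <- c(anc, node)
  }

  clade_tips <- function(node) {
    tips <- integer(); stack <- node
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (v <= ntip) tips <- c(tips, v)
      else stack <- c(stack, tree$edge[tree$edge[, 1] == v, 2])
    }
    tree$tip.label[tips]
  }

  rows <- lapply(seq_along(anc), function(k) {
    members <- setdiff(clade_tips(anc[k]), focal)
    host <- table(ann_of(members, "host_class", host_levels))
    strain <- table(ann_of(members, "coi_strain", strain_levels))
    nm <- length(members)
    frac <- function(tab) if (nm > 0) as.numeric(tab) / nm else rep(NA_real_, length(tab))
    data.frame(clade = k, n_members = nm,
               t(stats::setNames(frac(host), paste0("host_", host_levels))),
               t(stats::setNames(frac(strain), paste0("coi_", strain_levels))),
               check.names = FALSE)
  })
  report <- do.call(rbind, rows)
  headline <- report[report$n_members >= 1L, , drop = FALSE]
  headline <- if (nrow(headline)) headline[1L, , drop = FALSE] else NULL
  structure(list(focal = focal, report = report, headline = headline),
            class = "clade_composition")
}

#' @export
print.clade_composition <- function(x, ...) {
  cat("Clade composition around", x$focal, "\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Collapse duplicate sequences to unique haplotypes
#'
#' Mirrors the duplicate filtering applied before tree building: identical
#' sequences are collapsed to their first representative.
#'
#' @param seqs Named character vector.
#' @return Named character vector of unique sequences; attribute `members`
#'   maps each kept name to the names it represents.
#' @export
collapse_duplicates <- function(seqs) {
  seqs <- stats::setNames(toupper(as.character(seqs)), names(seqs))
  first <- !duplicated(unname(seqs))
  rep_of <- names(seqs)[first][match(unname(seqs), unname(seqs)[first])]
  out <- seqs[first]
  attr(out, "members") <- split(names(seqs), rep_of)
  out
}
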