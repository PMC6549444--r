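#' Anchor a query sequence to a segment reference
#'
#' Gap-aware pairwise alignment of an amplicon consensus sequence (possibly
#' containing IUPAC ambiguity codes) to a panel segment reference, producing a
#' per-reference-position map into the query. Diagnostic sites are always read
#' through this map, never by absolute offset, because amplicons may start at
#' primer positions and introns carry indels.
#'
#' Alignment is ends-free ("overlap") with affine gap costs (open 12,
#' extend 0.25), match +1, mismatch -1; an ambiguity code scores as a match
#' against any base it admits. The gap extension cost sits below the
#' mismatch cost so that a long biological insertion (such as the ~200-bp
#' intron insertion some haplotypes carry) is kept as one contiguous gap
#' instead of being shredded into spurious matches against the flanks.
#'
#' @param query Character scalar (or `DNAString`) query sequence, length > 50.
#' @param panel A `marker_panel`.
#' @param segment Segment name (`"COIB"`, `"TpiE4"`, `"TpiI4"`).
#' @param identity_floor Minimum fraction of matching columns among aligned
#'   (both-ungapped) columns; below it an `fawstrain_unalignable` error is
#'   thrown. Default 0.8.
#' @param gap_opening,gap_extension Affine gap penalties (defaults 12 and
#'   0.25).
#' @return An `anchor` object: per-reference-position query bases and
#'   coordinates, recorded insertions (reference position, length, query
#'   start), alignment identity.
#' @export
anchor_to_reference <- function(query, panel, segment, identity_floor = 0.8,
                                gap_opening = 12, gap_extension = 0.25) {
  seg <- panel_segment(panel, segment)
  query <- toupper(as.character(query))
  if (nchar(query) <= 50L) stop("query too short to anchor (<= 50 bp)")
  if (!all(seq_chars(query) %in% names(IUPAC_CODES)))
    stop("query contains non-IUPAC characters")

  pa <- Biostrings::pairwiseAlignment(
    pattern = query, subject = seg$reference, type = "overlap",
    substitutionMatrix = iupac_submat(), gapOpening = gap_opening,
    gapExtension = gap_extension)
  p <- seq_chars(Biostrings::pattern(pa))
  s <- seq_chars(Biostrings::subject(pa))

  ref_len <- nchar(seg$reference)
  query_base <- rep(NA_character_, ref_len)
  query_pos <- rep(NA_integer_, ref_len)
  deleted <- rep(FALSE, ref_len)
  ins <- list()

  rp <- Biostrings::start(Biostrings::subject(pa)) - 1L
  qp <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  ins_open <- NULL
  matches <- 0L; aligned_cols <- 0L
  for (k in seq_along(p)) {
    if (s[k] == "-") {            # insertion in query relative to reference
      qp <- qp + 1L
      if (is.null(ins_open)) ins_open <- c(ref_pos = rp, query_start = qp, len = 1L)
      else ins_open["len"] <- ins_open["len"] + 1L
      next
    }
    if (!is.null(ins_open)) { ins[[length(ins) + 1L]] <- ins_open; ins_open <- NULL }
    rp <- rp + 1L
    if (p[k] == "-") {            # deletion in query: site falls in a gap
      deleted[rp] <- TRUE
    } else {
      qp <- qp + 1L
      query_base[rp] <- p[k]
      query_pos[rp] <- qp
      aligned_cols <- aligned_cols + 1L
      if (iupac_compatible(p[k], s[k])) matches <- matches + 1L
    }
  }
  if (!is.null(ins_open)) ins[[length(ins) + 1L]] <- ins_open

  identity <- if (aligned_cols > 0L) matches / aligned_cols else 0
  if (identity < identity_floor) {
    stop(structure(class = c("fawstrain_unalignable", "error", "condition"),
                   list(message = sprintf(
                     "alignment identity %.2f below floor %.2f for segment %s",
                     identity, identity_floor, segment), call = NULL)))
  }
  insertions <- if (length(ins)) {
    data.frame(ref_pos = vapply(ins, `[[`, 0L, "ref_pos") + seg$origin_offset - 1L,
               length = vapply(ins, `[[`, 0L, "len"),
               query_start = vapply(ins, `[[`, 0L, "query_start"))
  } else data.frame(ref_pos = integer(), length = integer(), query_start = integer())

  structure(list(segment = segment, origin_offset = seg$origin_offset,
                 ref_len = ref_len, query_base = query_base,
                 query_pos = query_pos, deleted = deleted,
                 insertions = insertions, identity = identity),
            class = "anchor")
}

#' @export
print.anchor <- function(x, ...) {
  cat(sprintf("Anchor to %s: %d/%d reference positions mapped, identity %.3f, %d insertion(s)\n",
              x$segment, sum(!is.na(x$query_base)), x$ref_len, x$identity,
              nrow(x$insertions)))
  invisible(x)
}

#' Query base at a diagnostic-site position
#'
#' @param anchor An `anchor`.
#' @param position Site position in origin coordinates (as in the panel's
#'   `sites.tsv`).
#' @return Single IUPAC letter, or `NA` if the site is unmapped or falls in a
#'   query gap.
#' @export
site_base <- function(anchor, position) {
  i <- position - anchor$origin_offset + 1L
  if (i < 1L || i > anchor$ref_len) return(NA_character_)
  anchor$query_base[i]
}

## Accept either a raw sequence or a prebuilt anchor.
as_anchor <- function(x, panel, segment, ...) {
  if (inherits(x, "anchor")) {
    if (x$segment != segment) stop("anchor is for segment ", x$segment, ", not ", segment)
    return(x)
  }
  anchor_to_reference(x, panel, segment, ...)
}
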