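#' Read a marker panel from a panel directory
#'
#' A panel directory holds the segment references and the diagnostic-site /
#' reference-haplotype definitions that drive all sequence classification:
#'
#' * `segments_synthetic.fasta` (or `segments.fasta`): one record per segment
#'   (`COIB`, `TpiE4`, `TpiI4`), plain A/C/G/T.
#' * `segments.tsv`: `name`, `coordinate_origin`, `origin_offset`,
#'   `expected_length`. `origin_offset` is the 1-based coordinate (counted
#'   from the segment's origin: translational start for COI, 5' exon start
#'   for TpiE4, 5' intron start for TpiI4) of the first reference base.
#' * `sites.tsv`: `segment`, `label`, `position` (origin coordinates),
#'   `alleles` (admissible bases), `meanings` (`base=tag;...`).
#' * `haplotypes.tsv`: `segment`, `label`, `strain`, `edits`
#'   (`pos=base,...` relative to the segment reference), `indels`
#'   (`ins:pos:seqid,...`).
#' * `insertions_synthetic.fasta` (or `insertions.fasta`): sequences named by
#'   the `seqid`s used in `indels`.
#'
#' The packaged default panel ships synthetic segment references carrying the
#' documented diagnostic allele states (the deposited field sequences are not
#' redistributed); the classification engine itself is panel-agnostic.
#'
#' @param dir Panel directory. Defaults to the packaged panel.
#' @return A `marker_panel` object.
#' @export
read_marker_panel <- function(dir = system.file("extdata", "panel", package = "fawstrain")) {
  fa_path <- function(stem) {
    for (f in file.path(dir, paste0(stem, c("_synthetic.fasta", ".fasta"))))
      if (file.exists(f)) return(f)
    NA_character_
  }
  segs_fa <- read_sequences(fa_path("segments"))
  segments <- utils::read.delim(file.path(dir, "segments.tsv"))
  sites <- utils::read.delim(file.path(dir, "sites.tsv"))
  haplotypes <- utils::read.delim(file.path(dir, "haplotypes.tsv"))
  haplotypes$edits[is.na(haplotypes$edits)] <- ""
  haplotypes$indels[is.na(haplotypes$indels)] <- ""
  ins_file <- fa_path("insertions")
  insertions <- if (!is.na(ins_file)) read_sequences(ins_file) else character()

  stopifnot(all(segments$name %in% names(segs_fa)))
  panel <- structure(
    list(dir = dir, segments = segments, references = segs_fa[segments$name],
         sites = sites, haplotypes = haplotypes, insertions = insertions),
    class = "marker_panel")
  validate_panel(panel)
  panel
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("Marker panel:", nrow(x$segments), "segments,", nrow(x$sites),
      "diagnostic sites,", nrow(x$haplotypes), "reference haplotypes\n")
  for (s in x$segments$name) {
    cat(sprintf("  %-6s %4d bp, %d sites, haplotypes: %s\n", s,
                nchar(x$references[[s]]), sum(x$sites$segment == s),
                paste(x$haplotypes$label[x$haplotypes$segment == s], collapse = ", ")))
  }
  invisible(x)
}

validate_panel <- function(panel) {
  for (i in seq_len(nrow(panel$segments))) {
    seg <- panel$segments[i, ]
    ref <- panel$references[[seg$name]]
    if (!all(seq_chars(ref) %in% c("A", "C", "G", "T")))
      stop("segment reference ", seg$name, " contains non-ACGT characters")
    st <- panel$sites[panel$sites$segment == seg$name, ]
    idx <- st$position - seg$origin_offset + 1L
    if (any(idx < 1L | idx > nchar(ref)))
      stop("diagnostic site outside reference for segment ", seg$name)
  }
  ## within a segment: unique labels and pairwise-distinct allele vectors
  for (s in unique(panel$haplotypes$segment)) {
    h <- panel$haplotypes[panel$haplotypes$segment == s, ]
    if (anyDuplicated(h$label)) stop("duplicate haplotype labels in segment ", s)
    key <- paste(h$edits, h$indels)
    if (anyDuplicated(key)) stop("indistinct haplotype definitions in segment ", s)
  }
  invisible(TRUE)
}

#' The packaged default marker panel
#'
#' @return A `marker_panel` (cached after the first call).
#' @export
default_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_marker_panel()
    cache
  }
})

panel_segment <- function(panel, name) {
  i <- match(name, panel$segments$name)
  if (is.na(i)) stop("unknown segment: ", name)
  list(name = name,
       reference = panel$references[[name]],
       origin_offset = panel$segments$origin_offset[i],
       expected_length = panel$segments$expected_length[i])
}

panel_sites <- function(panel, segment) {
  panel$sites[panel$sites$segment == segment, , drop = FALSE]
}

site_position <- function(panel, label) {
  i <- match(label, panel$sites$label)
  if (is.na(i)) stop("unknown diagnostic site: ", label)
  panel$sites$position[i]
}

parse_edits <- function(edits) {
  if (is.na(edits) || !nzchar(edits)) return(data.frame(position = integer(), base = character()))
  parts <- strsplit(strsplit(edits, ",")[[1]], "=")
  data.frame(position = as.integer(vapply(parts, `[`, "", 1L)),
             base = vapply(parts, `[`, "", 2L))
}

parse_indels <- function(indels) {
  if (is.na(indels) || !nzchar(indels)) {
    return(data.frame(op = character(), position = integer(), seqid = character()))
  }
  parts <- strsplit(strsplit(indels, ",")[[1]], ":")
  data.frame(op = vapply(parts, `[`, "", 1L),
             position = as.integer(vapply(parts, `[`, "", 2L)),
             seqid = vapply(parts, `[`, "", 3L))
}

haplotype_row <- function(panel, label) {
  i <- match(label, panel$haplotypes$label)
  if (is.na(i)) stop("unknown haplotype: ", label)
  panel$haplotypes[i, ]
}

#' Full nucleotide sequence of a panel reference haplotype
#'
#' Applies the haplotype's substitution edits (and insertion features, if
#' `with_indels`) to its segment reference.
#'
#' @param panel A `marker_panel`.
#' @param label Haplotype label, e.g. `"COI-RSa1"`.
#' @param with_indels Apply insertion features (default `TRUE`).
#' @return Character scalar sequence.
#' @export
haplotype_sequence <- function(panel, label, with_indels = TRUE) {
  h <- haplotype_row(panel, label)
  seg <- panel_segment(panel, h$segment)
  s <- seq_chars(seg$reference)
  ed <- parse_edits(h$edits)
  if (nrow(ed)) s[ed$position - seg$origin_offset + 1L] <- ed$base
  out <- paste(s, collapse = "")
  if (with_indels) {
    ind <- parse_indels(h$indels)
    ## apply right-to-left so earlier positions stay valid
    for (j in rev(seq_len(nrow(ind)))) {
      if (ind$op[j] != "ins") stop("unsupported indel op: ", ind$op[j])
      at <- ind$position[j] - seg$origin_offset + 1L
      ins <- panel$insertions[[ind$seqid[j]]]
      if (is.null(ins)) stop("insertion sequence not in panel: ", ind$seqid[j])
      out <- paste0(substr(out, 1L, at), ins, substr(out, at + 1L, nchar(out)))
    }
  }
  out
}

#' Diagnostic-site allele vector of a panel haplotype
#'
#' @param panel A `marker_panel`.
#' @param label Haplotype label.
#' @return Named character vector, site label -> base.
#' @export
haplotype_vector <- function(panel, label) {
  h <- haplotype_row(panel, label)
  seg <- panel_segment(panel, h$segment)
  st <- panel_sites(panel, h$segment)
  s <- seq_chars(haplotype_sequence(panel, label, with_indels = FALSE))
  stats::setNames(s[st$position - seg$origin_offset + 1L], st$label)
}

haplotype_indels <- function(panel, label) parse_indels(haplotype_row(panel, label)$indels)

#' Strain of a panel haplotype
#' @param panel A `marker_panel`.
#' @param label Haplotype label.
#' @return `"corn"`, `"rice"` or `"na"`.
#' @export
haplotype_strain <- function(panel, label) haplotype_row(panel, label)$strain

#' Next free auto-label for a novel haplotype
#'
#' Novel allele vectors can be added to a panel under a deterministic label:
#' strain prefix (`CSa`/`RSa` for COIB, `TpiCa`/`TpiRa` for TpiE4) plus the
#' next free index, plus an optional run suffix.
#'
#' @param panel A `marker_panel`.
#' @param segment Segment name.
#' @param strain `"corn"` or `"rice"`.
#' @param suffix Optional run suffix appended verbatim.
#' @return Character label.
#' @export
auto_label <- function(panel, segment, strain, suffix = "") {
  prefix <- switch(segment,
    COIB = if (strain == "corn") "COI-CSa" else "COI-RSa",
    TpiE4 = if (strain == "corn") "TpiCa" else "TpiRa",
    TpiI4 = "TpiI4x",
    stop("unknown segment: ", segment))
  existing <- panel$haplotypes$label[panel$haplotypes$segment == segment]
  idx <- suppressWarnings(as.integer(sub(paste0("^", gsub("\\-", "\\\\-", prefix)), "",
                                         existing[startsWith(existing, prefix)])))
  nxt <- if (all(is.na(idx))) 1L else max(idx, na.rm = TRUE) + 1L
  paste0(prefix, nxt, suffix)
}
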