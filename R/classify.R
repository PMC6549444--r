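#' Call mitochondrial COI strain from a COIB sequence
#'
#' The strain-diagnostic site is mCOI1164D: T identifies the rice-strain
#' (`RS`) haplotype group, A or G the corn-strain (`CS`); C has not been
#' observed in the species, so any other resolved base yields `unknown` with
#' a QC flag attribute.
#'
#' @param x COIB sequence (character) or a prebuilt [anchor_to_reference()]
#'   anchor.
#' @param panel A `marker_panel` (default packaged panel).
#' @return `"RS"`, `"CS"`, `"unknown"` or `"failed"` (site unmapped, in a
#'   gap, or ambiguous). A `qc` attribute carries flags when not clean.
#' @export
call_coi_strain <- function(x, panel = default_panel()) {
  a <- tryCatch(as_anchor(x, panel, "COIB"),
                fawstrain_unalignable = function(e) NULL)
  if (is.null(a)) return(flagged("failed", "unalignable"))
  b <- site_base(a, site_position(panel, "mCOI1164D"))
  if (is.na(b) || !is_unambiguous_base(b)) return(flagged("failed", "site-1164-unresolved"))
  if (b == "T") return("RS")
  if (b %in% c("A", "G")) return("CS")
  flagged("unknown", "unobserved-base-at-1164")
}

flagged <- function(value, ...) structure(value, qc = c(...))

#' Corn-strain h-configuration of a COIB sequence
#'
#' The two-site lookup over mCOI1164D x mCOI1287R: `h1` = A/A, `h2` = A/G,
#' `h3` = G/A, `h4` = G/G. Rice-strain sequences (T at 1164) are
#' `not-applicable`.
#'
#' @inheritParams call_coi_strain
#' @return One of `"h1".."h4"`, `"not-applicable"`, or `"failed"`.
#' @export
coib_h_config <- function(x, panel = default_panel()) {
  a <- tryCatch(as_anchor(x, panel, "COIB"),
                fawstrain_unalignable = function(e) NULL)
  if (is.null(a)) return(flagged("failed", "unalignable"))
  b1164 <- site_base(a, site_position(panel, "mCOI1164D"))
  b1287 <- site_base(a, site_position(panel, "mCOI1287R"))
  if (is.na(b1164) || is.na(b1287) ||
      !is_unambiguous_base(b1164) || !is_unambiguous_base(b1287))
    return(flagged("failed", "h-config-sites-unresolved"))
  if (b1164 == "T") return("not-applicable")
  key <- paste0(b1164, b1287)
  switch(key, AA = "h1", AG = "h2", GA = "h3", GG = "h4",
         flagged("failed", paste0("unexpected-configuration-", key)))
}

#' Assign a COIB haplotype label by exact allele-vector match
#'
#' The query's bases at every COIB diagnostic site are compared with the
#' panel's reference haplotypes. COIB is mitochondrial, so heterozygosity is
#' not expected: any IUPAC ambiguity at a panel site fails the call.
#'
#' @inheritParams call_coi_strain
#' @return The haplotype label; `"novel"` (with attributes `vector`, the
#'   observed allele vector, and `mismatches`, per-haplotype mismatch
#'   counts); or `"failed"`.
#' @export
assign_coib_haplotype <- function(x, panel = default_panel()) {
  a <- tryCatch(as_anchor(x, panel, "COIB"),
                fawstrain_unalignable = function(e) NULL)
  if (is.null(a)) return(flagged("failed", "unalignable"))
  st <- panel_sites(panel, "COIB")
  v <- stats::setNames(vapply(st$position, function(p) {
    b <- site_base(a, p); if (is.na(b)) "" else b
  }, ""), st$label)
  if (any(v == "")) return(flagged("failed", "panel-site-in-gap"))
  if (!all(is_unambiguous_base(v))) return(flagged("failed", "ambiguity-at-panel-site"))
  labs <- panel$haplotypes$label[panel$haplotypes$segment == "COIB"]
  mism <- vapply(labs, function(l) sum(haplotype_vector(panel, l) != v), 0L)
  hit <- labs[mism == 0L]
  if (length(hit) == 1L) return(hit)
  structure("novel", vector = v, mismatches = mism)
}

#' Species quality check on a COIB sequence
#'
#' A specimen passes the species check when its COIB sequence differs by at
#' most one site (minimum Hamming distance over aligned, ungapped columns)
#' from some panel reference haplotype.
#'
#' @inheritParams call_coi_strain
#' @param max_distance Maximum allowed distance (default 1).
#' @return List with `pass` (logical) and `distance` (integer; `NA` when
#'   unalignable).
#' @export
species_qc <- function(x, panel = default_panel(), max_distance = 1L) {
  a <- tryCatch(as_anchor(x, panel, "COIB"),
                fawstrain_unalignable = function(e) NULL)
  if (is.null(a)) return(list(pass = FALSE, distance = NA_integer_))
  ok <- !is.na(a$query_base)
  qb <- a$query_base[ok]
  labs <- panel$haplotypes$label[panel$haplotypes$segment == "COIB"]
  d <- vapply(labs, function(l) {
    hb <- seq_chars(haplotype_sequence(panel, l))[ok]
    sum(!iupac_compatible(qb, hb))
  }, 0L)
  list(pass = min(d) <= max_distance, distance = min(d))
}

#' Call Tpi strain from a TpiE4 sequence
#'
#' The strain-diagnostic site is gTpi183Y: C marks the corn-strain allele
#' (`TpiC`), T the rice-strain (`TpiR`), and the ambiguity code Y the
#' simultaneous display of both in a heterozygous male (`TpiH`).
#'
#' @param x TpiE4 sequence (character, may contain IUPAC codes) or anchor.
#' @inheritParams call_coi_strain
#' @return `"TpiC"`, `"TpiR"`, `"TpiH"`, `"unknown"` or `"failed"`.
#' @export
call_tpi_strain <- function(x, panel = default_panel()) {
  a <- tryCatch(as_anchor(x, panel, "TpiE4"),
                fawstrain_unalignable = function(e) NULL)
  if (is.null(a)) return(flagged("failed", "unalignable"))
  b <- site_base(a, site_position(panel, "gTpi183Y"))
  if (is.na(b)) return(flagged("failed", "site-183-in-gap"))
  switch(b, C = "TpiC", T = "TpiR", Y = "TpiH",
         flagged("unknown", paste0("unexpected-code-at-183-", b)))
}

tpie4_class_names <- c("TpiCa1/TpiCa2" = "C-YY",
                       "TpiCa1/TpiRa1" = "H-CC",
                       "TpiCa2/TpiRa1" = "H-YY")

#' Resolve a TpiE4 genotype, including heterozygote decoding
#'
#' An unambiguous allele vector matching a panel haplotype is a hemizygous or
#' homozygous call (`Ca1`, `Ca2`, `Ra1`). A vector containing two-allele
#' ambiguity codes is decoded as the unique unordered pair of panel
#' haplotypes whose site-wise IUPAC union equals the observed vector; the
#' three African heterozygote classes are `C-YY` (= Ca1/Ca2), `H-CC`
#' (= Ca1/Ra1) and `H-YY` (= Ca2/Ra1). Vectors consistent with no single
#' haplotype and no pair are `ambiguous`; so are vectors with more than one
#' consistent pair (impossible with the three-haplotype African panel but
#' guarded for extended panels, with all candidates attached).
#'
#' @inheritParams call_tpi_strain
#' @return Genotype label; `"ambiguous"` (attribute `candidates` when
#'   several pairs fit); or `"failed"` when any diagnostic site is unmapped
#'   or carries an unexpected code (e.g. N).
#' @export
assign_tpie4_genotype <- function(x, panel = default_panel()) {
  a <- tryCatch(as_anchor(x, panel, "TpiE4"),
                fawstrain_unalignable = function(e) NULL)
  if (is.null(a)) return(flagged("failed", "unalignable"))
  st <- panel_sites(panel, "TpiE4")
  v <- stats::setNames(vapply(st$position, function(p) {
    b <- site_base(a, p); if (is.na(b)) "" else b
  }, ""), st$label)
  if (any(v == "")) return(flagged("failed", "panel-site-in-gap"))
  ## only codes admitting a subset of the site's documented alleles are scorable
  admissible <- mapply(function(code, alleles) {
    code %in% names(IUPAC_CODES) &&
      all(iupac_expand(code) %in% strsplit(alleles, "")[[1]])
  }, v, st$alleles)
  if (!all(admissible)) return(flagged("failed", "unscorable-code-at-panel-site"))

  labs <- panel$haplotypes$label[panel$haplotypes$segment == "TpiE4"]
  vecs <- lapply(labs, function(l) haplotype_vector(panel, l))
  names(vecs) <- labs

  if (all(is_unambiguous_base(v))) {
    hit <- labs[vapply(vecs, function(h) all(h == v), TRUE)]
    if (length(hit) == 1L) return(sub("^Tpi", "", hit))
    return(flagged("ambiguous", "matches-no-single-haplotype"))
  }
  pairs <- utils::combn(labs, 2L, simplify = FALSE)
  fits <- vapply(pairs, function(pr) {
    u <- mapply(iupac_merge, vecs[[pr[1]]], vecs[[pr[2]]])
    all(u == v)
  }, TRUE)
  if (sum(fits) == 1L) {
    pr <- sort(pairs[[which(fits)]])
    key <- paste(pr, collapse = "/")
    cls <- tpie4_class_names[key]
    return(if (is.na(cls)) key else unname(cls))
  }
  if (sum(fits) > 1L) {
    return(structure("ambiguous",
                     candidates = vapply(pairs[fits], paste, "", collapse = "/")))
  }
  flagged("ambiguous", "matches-no-haplotype-pair")
}

#' Tpi strain implied by a TpiE4 genotype label
#'
#' @param genotype Genotype label(s) from [assign_tpie4_genotype()].
#' @return `"TpiC"`, `"TpiR"`, `"TpiH"` or `"unknown"` (vectorised).
#' @export
genotype_strain <- function(genotype) {
  vapply(as.character(genotype), function(g) {
    switch(g,
           Ca1 = , Ca2 = , `C-YY` = "TpiC",
           Ra1 = "TpiR",
           `H-CC` = , `H-YY` = "TpiH",
           "unknown")
  }, "", USE.NAMES = FALSE)
}

#' Assign a TpiI4 intron haplotype
#'
#' The query is anchored to the intron core (intron nucleotides 10-172 in
#' reference coordinates). The base at the poor-signal site gTpiI4\[131\]R is
#' forced to the consensus G before matching. A sequence with any remaining
#' IUPAC ambiguity inside the core, or with a deletion in the core, or with
#' insertion evidence incompatible with any single panel haplotype, is called
#' `heterozygous` (such specimens are excluded from unambiguous-haplotype
#' counts downstream). Otherwise an exact match of the core sequence plus
#' insertion features to a panel haplotype returns its label, and no match
#' returns `novel`.
#'
#' @param x TpiI4 sequence (character) or anchor.
#' @inheritParams call_coi_strain
#' @param indel_tol Positional/length tolerance (bp) when matching an
#'   observed insertion to a panel insertion feature. Default 10.
#' @return Haplotype label, `"heterozygous"`, `"novel"` or `"failed"`.
#' @export
assign_tpii4_haplotype <- function(x, panel = default_panel(), indel_tol = 10L) {
  a <- tryCatch(as_anchor(x, panel, "TpiI4"),
                fawstrain_unalignable = function(e) NULL)
  if (is.null(a)) return(flagged("failed", "unalignable"))
  core <- a$query_base
  unmapped <- is.na(core) & !a$deleted
  if (any(unmapped)) return(flagged("failed", "core-not-covered"))
  if (any(a$deleted)) return("heterozygous")
  ## force the poor-signal site to consensus before ambiguity screening
  force_at <- site_position(panel, "gTpiI4[131]R") - a$origin_offset + 1L
  core[force_at] <- "G"
  if (!all(is_unambiguous_base(core))) return("heterozygous")
  obs <- paste(core, collapse = "")

  labs <- panel$haplotypes$label[panel$haplotypes$segment == "TpiI4"]
  seg <- panel_segment(panel, "TpiI4")
  for (l in labs) {
    hs <- seq_chars(haplotype_sequence(panel, l, with_indels = FALSE))
    hs[force_at] <- "G"
    if (paste(hs, collapse = "") != obs) next
    want <- haplotype_indels(panel, l)
    have <- a$insertions
    if (nrow(want) != nrow(have)) next
    if (nrow(want) == 0L) return(l)
    want_len <- vapply(seq_len(nrow(want)),
                       function(j) nchar(panel$insertions[[want$seqid[j]]]), 0L)
    ok <- all(abs(sort(have$ref_pos) - sort(want$position)) <= indel_tol) &&
      all(abs(sort(have$length) - sort(want_len)) <= indel_tol)
    if (ok) return(l)
  }
  if (nrow(a$insertions) > 0L &&
      !any(vapply(labs, function(l) nrow(haplotype_indels(panel, l)) > 0L, TRUE)))
    return("heterozygous")
  "novel"
}

#' Classify specimens across all three marker segments
#'
#' Runs the full per-specimen classification (COI strain, COIB haplotype and
#' h-configuration, species QC, TpiE4 strain/genotype, TpiI4 haplotype) and
#' returns one row per specimen. Sequences absent for a marker yield failed
#' calls for that marker only. Identical sequences are classified once and
#' the result reused, so large simulated collections remain fast.
#'
#' @param coib,tpie4,tpii4 Named character vectors (or `DNAStringSet`s) of
#'   sequences; names are specimen ids. Any may be `NULL`.
#' @param metadata Data frame with columns `specimen_id`, `collection`,
#'   `source_type` (`male_trap`/`larva`); extra columns are carried through.
#' @param panel A `marker_panel`.
#' @return A data frame of specimen calls with columns `specimen_id`,
#'   `collection`, `source_type`, `coib_haplotype`, `coi_strain`, `h_config`,
#'   `tpie4_genotype`, `tpi_strain`, `tpii4_call`, `qc_flags`.
#' @export
classify_specimens <- function(coib = NULL, tpie4 = NULL, tpii4 = NULL,
                               metadata, panel = default_panel()) {
  stopifnot(all(c("specimen_id", "collection", "source_type") %in% names(metadata)))
  ids <- as.character(metadata$specimen_id)
  coib <- as_named_chr(coib); tpie4 <- as_named_chr(tpie4); tpii4 <- as_named_chr(tpii4)

  memo_call <- function(seqs, fn) {
    res <- list()
    if (length(seqs)) {
      uniq <- unique(unname(seqs))
      per <- lapply(uniq, fn)
      res <- stats::setNames(per[match(unname(seqs), uniq)], names(seqs))
    }
    function(id) if (!is.null(res[[id]])) res[[id]] else list()
  }

  coib_full <- memo_call(coib, function(s) {
    qc <- species_qc(s, panel)
    list(strain = call_coi_strain(s, panel),
         hap = assign_coib_haplotype(s, panel),
         h = coib_h_config(s, panel),
         species_ok = qc$pass, species_dist = qc$distance)
  })
  tpie4_full <- memo_call(tpie4, function(s) {
    list(genotype = assign_tpie4_genotype(s, panel),
         strain = call_tpi_strain(s, panel))
  })
  tpii4_full <- memo_call(tpii4, function(s) list(call = assign_tpii4_haplotype(s, panel)))

  rows <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    cb <- coib_full(id); te <- tpie4_full(id); ti <- tpii4_full(id)
    flags <- character()
    if (!is.null(cb$species_ok) && isFALSE(cb$species_ok)) flags <- c(flags, "species-check-failed")
    for (piece in list(cb$strain, cb$hap, cb$h, te$genotype, te$strain, ti$call))
      flags <- c(flags, attr(piece, "qc"))
    strain <- if (is.null(cb$strain)) "failed" else as.character(cb$strain)
    geno <- if (is.null(te$genotype)) "failed" else as.character(te$genotype)
    tpi_strain <- genotype_strain(geno)
    if (tpi_strain == "unknown" && !is.null(te$strain) &&
        !as.character(te$strain) %in% c("failed", "unknown"))
      tpi_strain <- as.character(te$strain)
    data.frame(
      specimen_id = id,
      collection = as.character(metadata$collection[i]),
      source_type = as.character(metadata$source_type[i]),
      coib_haplotype = if (is.null(cb$hap)) "failed" else as.character(cb$hap),
      coi_strain = if (strain %in% c("CS", "RS")) strain else "unknown",
      h_config = if (is.null(cb$h)) "failed" else as.character(cb$h),
      tpie4_genotype = geno,
      tpi_strain = tpi_strain,
      tpii4_call = if (is.null(ti$call)) "failed" else as.character(ti$call),
      qc_flags = paste(unique(flags), collapse = ","),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

as_named_chr <- function(x) {
  if (is.null(x)) return(character())
  out <- stats::setNames(toupper(as.character(x)), names(x))
  out
}
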