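#' Read sequences from a FASTA file with per-record validation
#'
#' Records are uppercased and validated against the IUPAC nucleotide
#' alphabet; records containing other characters are rejected individually
#' (with a message) while the remaining records are kept.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences; rejected record ids in the
#'   `rejected` attribute.
#' @export
read_sequences <- function(path) {
  if (is.na(path) || !file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  seqs <- toupper(as.character(raw))
  ok <- vapply(seqs, function(s) all(strsplit(s, "")[[1]] %in% names(IUPAC_CODES)), TRUE)
  if (any(!ok))
    message("rejected ", sum(!ok), " record(s) with non-IUPAC characters: ",
            paste(ids[!ok], collapse = ", "))
  structure(stats::setNames(seqs[ok], ids[ok]), rejected = ids[!ok])
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_sequences <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  invisible(path)
}

#' Read a specimen metadata table
#'
#' Tab-separated, with header columns `specimen_id`, `collection`,
#' `source_type` (plus optional `country`, `year`, `host_class`).
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_specimen_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "collection", "source_type")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  bad <- !md$source_type %in% c("male_trap", "larva")
  if (any(bad)) stop("unknown source_type values: ",
                     paste(unique(md$source_type[bad]), collapse = ", "))
  md
}

extdata <- function(...) system.file("extdata", ..., package = "fawstrain")

#' Packaged COIB haplotype counts from the 13-collection African survey
#'
#' Observed specimen counts per COIB haplotype (CSa1, CSa2, RSa1-RSa4) for
#' the 13 sub-Saharan collections, transcribed from the published survey.
#'
#' @return Data frame, one row per collection.
#' @export
african_coib_counts <- function() utils::read.delim(extdata("african_coib_counts.tsv"))

#' Packaged TpiE4 genotype counts from the 13-collection African survey
#'
#' Observed specimen counts per TpiE4 genotype class (Ca1, Ca2, Ra1, C-YY,
#' H-CC, H-YY; columns `CYY`, `HCC`, `HYY`) with each collection's source
#' type, transcribed from the published survey.
#'
#' @return Data frame, one row per collection.
#' @export
african_tpie4_counts <- function() utils::read.delim(extdata("african_tpie4_counts.tsv"))

#' Packaged collection metadata for the African survey
#'
#' @return Data frame: `collection`, `country`, `year`, `source_type`, `n`.
#' @export
african_collections <- function() utils::read.delim(extdata("african_collections.tsv"))

#' Run the full marker analysis pipeline
#'
#' Orchestrates classification, tabulation, sex-linkage adjustment,
#' frequency summaries, the regional comparison and the strain-configuration
#' table, writing plain TSV artifacts into an output directory. Inputs may
#' be file paths (FASTA / TSV) or in-memory objects.
#'
#' @param coib,tpie4,tpii4 Named sequence vectors or FASTA paths (any may be
#'   `NULL`).
#' @param metadata Specimen metadata data frame or TSV path.
#' @param out_dir Output directory (created if needed).
#' @param panel A `marker_panel` or panel directory path.
#' @param groups Collections forming the focal group of the regional
#'   comparison; default the western collections `TOGa`, `TOGb`, `STP`.
#' @param var_equal,alpha Passed to [compare_regions()].
#' @return Invisibly, a list with `calls`, `counts`, `adjusted`,
#'   `frequencies`, `comparison`, `config_table` and the file paths written.
#' @export
run_pipeline <- function(coib = NULL, tpie4 = NULL, tpii4 = NULL, metadata,
                         out_dir, panel = default_panel(),
                         groups = c("TOGa", "TOGb", "STP"),
                         var_equal = FALSE, alpha = 0.05) {
  if (is.character(panel) && length(panel) == 1L) panel <- read_marker_panel(panel)
  load_seqs <- function(x) if (is.character(x) && length(x) == 1L && file.exists(x))
    read_sequences(x) else x
  coib <- load_seqs(coib); tpie4 <- load_seqs(tpie4); tpii4 <- load_seqs(tpii4)
  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- read_specimen_metadata(metadata)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }

  calls <- classify_specimens(coib = coib, tpie4 = tpie4, tpii4 = tpii4,
                              metadata = metadata, panel = panel)
  counts <- lapply(split(calls, calls$collection), tabulate_collection)

  coib_labels <- panel$haplotypes$label[panel$haplotypes$segment == "COIB"]
  coib_df <- data.frame(collection = names(counts))
  for (l in coib_labels)
    coib_df[[sub("^COI-", "", l)]] <- vapply(counts, function(cc)
      if (l %in% names(cc$coib)) cc$coib[[l]] else 0L, 0L)
  tpie4_df <- data.frame(
    collection = names(counts),
    source_type = vapply(counts, function(cc) cc$source_type, ""),
    Ca1 = vapply(counts, function(cc) cc$tpie4[["Ca1"]], 0L),
    Ca2 = vapply(counts, function(cc) cc$tpie4[["Ca2"]], 0L),
    Ra1 = vapply(counts, function(cc) cc$tpie4[["Ra1"]], 0L),
    CYY = vapply(counts, function(cc) cc$tpie4[["C-YY"]], 0L),
    HCC = vapply(counts, function(cc) cc$tpie4[["H-CC"]], 0L),
    HYY = vapply(counts, function(cc) cc$tpie4[["H-YY"]], 0L))
  adjusted <- adjust_tpi_table(tpie4_df)

  cs_cols <- intersect(c("CSa1", "CSa2"), names(coib_df))
  freq <- list(
    coi_cs = frequency_summary(coib_df, cs_cols),
    tpi_c_adj = frequency_summary(adjusted, c("Ca1_raw", "Ca2_raw"),
                                  c("Ca1_raw", "Ca2_raw", "Ra1_raw")),
    tpi_ca2_adj = frequency_summary(adjusted, "Ca2_raw",
                                    c("Ca1_raw", "Ca2_raw", "Ra1_raw")))
  comparison <- NULL
  have <- intersect(groups, names(freq$coi_cs$freqs))
  rest <- setdiff(names(freq$coi_cs$freqs), have)
  if (length(have) >= 2L && length(rest) >= 2L)
    comparison <- compare_regions(freq$coi_cs, have, rest,
                                  var_equal = var_equal, alpha = alpha)

  cfg <- strain_configuration(calls$coi_strain, calls$tpi_strain)
  config_table <- as.data.frame(table(collection = calls$collection,
                                      category = cfg$category))

  files <- c(
    tsv(calls, "specimen_calls.tsv"),
    tsv(coib_df, "coib_counts.tsv"),
    tsv(adjusted, "tpie4_adjusted_counts.tsv"),
    tsv(data.frame(quantity = vapply(freq, function(f) f$quantity, ""),
                   mean = vapply(freq, function(f) f$mean, 0),
                   sd = vapply(freq, function(f) f$sd, 0),
                   n = vapply(freq, function(f) f$n, 0L)),
        "frequency_summary.tsv"),
    tsv(config_table, "strain_configurations.tsv"))
  if (!is.null(comparison))
    files <- c(files, tsv(data.frame(
      group_a = paste(comparison$group_a, collapse = ","),
      group_b = paste(comparison$group_b, collapse = ","),
      t = comparison$t, df = comparison$df, p = comparison$p,
      mean_a = comparison$mean_a, mean_b = comparison$mean_b,
      letter_a = comparison$letters[["a"]], letter_b = comparison$letters[["b"]]),
      "regional_comparison.tsv"))

  invisible(list(calls = calls, counts = counts, adjusted = adjusted,
                 frequencies = freq, comparison = comparison,
                 config_table = config_table, files = files))
}
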