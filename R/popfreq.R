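#' Round half away from zero
#'
#' Reported adjusted chromosome counts use commercial (half-up) rounding,
#' not banker's rounding: 58.5 -> 59, 12.5 -> 13.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

TPIE4_CLASSES <- c("Ca1", "Ca2", "Ra1", "C-YY", "H-CC", "H-YY")
CONFIG_CELLS <- c("COI-CS TpiC", "COI-CS TpiR", "COI-CS TpiH",
                  "COI-RS TpiC", "COI-RS TpiR", "COI-RS TpiH")

#' Tabulate specimen calls for one collection
#'
#' Counts per-marker categories from a block of specimen calls. Specimens
#' with a failed or ambiguous call for a marker are excluded from that
#' marker's counts only; specimens failing the species check are excluded
#' from all counts.
#'
#' @param calls Data frame from [classify_specimens()], all rows sharing one
#'   collection label.
#' @return A `collection_counts` object: `collection`, `source_type`,
#'   `n_total`, `coib` (named counts per haplotype label), `tpie4` (counts
#'   over the six genotype classes), `tpii4` (counts per intron haplotype
#'   plus `heterozygous`), `config` (counts over the six strain-configuration
#'   cells), `excluded` (per-marker exclusion tallies).
#' @export
tabulate_collection <- function(calls) {
  if (length(unique(calls$collection)) != 1L)
    stop("calls span more than one collection; tabulate each separately")
  n_total <- nrow(calls)
  species_bad <- grepl("species-check-failed", calls$qc_flags)
  calls <- calls[!species_bad, , drop = FALSE]

  count_of <- function(x, keep = NULL, drop = c("failed", "novel", "ambiguous")) {
    x <- x[!x %in% drop]
    if (!is.null(keep)) x <- x[x %in% keep]
    if (length(x) == 0L) return(stats::setNames(integer(), character()))
    tab <- table(x)
    stats::setNames(as.integer(tab), names(tab))
  }
  coib <- count_of(calls$coib_haplotype)
  tpie4 <- count_of(calls$tpie4_genotype, keep = TPIE4_CLASSES)
  tpie4 <- stats::setNames(
    vapply(TPIE4_CLASSES, function(k) if (k %in% names(tpie4)) tpie4[[k]] else 0L, 0L),
    TPIE4_CLASSES)
  tpii4 <- count_of(calls$tpii4_call, drop = c("failed", "novel"))

  cfg <- strain_configuration(calls$coi_strain, calls$tpi_strain)
  cfg_keep <- cfg$category != "excluded"
  config <- stats::setNames(
    vapply(CONFIG_CELLS, function(cell) sum(cfg$cell[cfg_keep] == cell), 0L),
    CONFIG_CELLS)

  structure(list(
    collection = calls$collection[1],
    source_type = calls$source_type[1],
    n_total = n_total,
    coib = coib, tpie4 = tpie4, tpii4 = tpii4, config = config,
    excluded = c(
      species = sum(species_bad),
      coib = n_total - sum(species_bad) - sum(coib),
      tpie4 = n_total - sum(species_bad) - sum(tpie4),
      tpii4 = n_total - sum(species_bad) - sum(tpii4),
      config = n_total - sum(species_bad) - sum(config))),
    class = "collection_counts")
}

#' @export
print.collection_counts <- function(x, ...) {
  cat("Collection", x$collection, sprintf("(%s, n = %d)\n", x$source_type, x$n_total))
  cat("  COIB: ", paste(names(x$coib), x$coib, sep = "=", collapse = " "), "\n")
  cat("  TpiE4:", paste(names(x$tpie4), x$tpie4, sep = "=", collapse = " "), "\n")
  cat("  TpiI4:", paste(names(x$tpii4), x$tpii4, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Sex-linkage adjustment of TpiE4 specimen counts to chromosome counts
#'
#' Tpi is Z-linked: males carry two copies, females one. The adjusted
#' (chromosome-scale) allele counts are
#' `Ca1 = m x Ca1 + C-YY + H-CC`, `Ca2 = m x Ca2 + C-YY + H-YY`,
#' `Ra1 = m x Ra1 + H-CC + H-YY`, where the multiplier `m` is 2 for
#' male-only pheromone-trap collections and `1 + sex_ratio` (1.5 under the
#' default 1:1 assumption) for larval collections of unknown sex; each
#' heterozygous specimen (necessarily male) contributes one chromosome to
#' each constituent allele. Reported counts are rounded half-up.
#'
#' @param counts A `collection_counts` object, or a named numeric vector
#'   with elements `Ca1`, `Ca2`, `Ra1`, `C-YY` (or `CYY`), `H-CC` (`HCC`),
#'   `H-YY` (`HYY`).
#' @param source_type `"male_trap"` or `"larva"`; taken from `counts` when it
#'   is a `collection_counts`.
#' @param sex_ratio Assumed male fraction in larval collections (default
#'   0.5, giving the 1.5 multiplier).
#' @return An `adjusted_counts` object with `multiplier`, `raw` (real-valued
#'   counts), `reported` (rounded), `total_chromosomes`.
#' @export
adjust_tpi_counts <- function(counts, source_type = NULL, sex_ratio = 0.5) {
  label <- NA_character_
  if (inherits(counts, "collection_counts")) {
    label <- counts$collection
    if (is.null(source_type)) source_type <- counts$source_type
    counts <- counts$tpie4
  }
  names(counts) <- sub("^CYY$", "C-YY", sub("^HCC$", "H-CC", sub("^HYY$", "H-YY", names(counts))))
  miss <- setdiff(TPIE4_CLASSES, names(counts))
  if (length(miss)) stop("missing TpiE4 classes: ", paste(miss, collapse = ", "))
  if (is.null(source_type) || !source_type %in% c("male_trap", "larva"))
    stop("source_type must be 'male_trap' or 'larva'")
  m <- if (source_type == "male_trap") 2 else 1 + sex_ratio
  raw <- c(
    Ca1 = m * counts[["Ca1"]] + counts[["C-YY"]] + counts[["H-CC"]],
    Ca2 = m * counts[["Ca2"]] + counts[["C-YY"]] + counts[["H-YY"]],
    Ra1 = m * counts[["Ra1"]] + counts[["H-CC"]] + counts[["H-YY"]])
  structure(list(collection = label, multiplier = m, raw = raw,
                 reported = round_half_up(raw),
                 total_chromosomes = sum(raw)),
            class = "adjusted_counts")
}

#' @export
print.adjusted_counts <- function(x, ...) {
  cat(sprintf("Adjusted Tpi chromosome counts (x%g)%s:\n", x$multiplier,
              if (is.na(x$collection)) "" else paste0(" for ", x$collection)))
  print(data.frame(raw = x$raw, reported = x$reported))
  invisible(x)
}

#' Apply the sex-linkage adjustment to a table of collections
#'
#' @param df Data frame with columns `collection`, `source_type` and the six
#'   TpiE4 class counts (`Ca1`, `Ca2`, `Ra1`, `CYY`, `HCC`, `HYY`), as in the
#'   packaged survey fixture.
#' @inheritParams adjust_tpi_counts
#' @return `df` with added columns `Ca1_raw`..`Ra1_raw`, `Ca1_adj`..`Ra1_adj`
#'   (reported, rounded half-up) and `total_chromosomes`.
#' @export
adjust_tpi_table <- function(df, sex_ratio = 0.5) {
  res <- lapply(seq_len(nrow(df)), function(i) {
    v <- c(Ca1 = df$Ca1[i], Ca2 = df$Ca2[i], Ra1 = df$Ra1[i],
           `C-YY` = df$CYY[i], `H-CC` = df$HCC[i], `H-YY` = df$HYY[i])
    adjust_tpi_counts(v, df$source_type[i], sex_ratio = sex_ratio)
  })
  df$Ca1_raw <- vapply(res, function(a) a$raw[["Ca1"]], 0)
  df$Ca2_raw <- vapply(res, function(a) a$raw[["Ca2"]], 0)
  df$Ra1_raw <- vapply(res, function(a) a$raw[["Ra1"]], 0)
  df$Ca1_adj <- vapply(res, function(a) a$reported[["Ca1"]], 0)
  df$Ca2_adj <- vapply(res, function(a) a$reported[["Ca2"]], 0)
  df$Ra1_adj <- vapply(res, function(a) a$reported[["Ra1"]], 0)
  df$total_chromosomes <- vapply(res, function(a) a$total_chromosomes, 0)
  df
}

#' Mitochondrial-nuclear strain configuration of a specimen
#'
#' Classifies the joint COI / Tpi strain call into the six configuration
#' cells: Concordant (COI-CS TpiC, COI-RS TpiR), Discordant (COI-CS TpiR,
#' COI-RS TpiC) and Heterozygous (COI-CS TpiH, COI-RS TpiH). Records with
#' either strain unknown are `excluded`.
#'
#' @param coi_strain Vector over `{CS, RS, unknown}`.
#' @param tpi_strain Vector over `{TpiC, TpiR, TpiH, unknown}`.
#' @return Data frame with `category` and `cell`.
#' @export
strain_configuration <- function(coi_strain, tpi_strain) {
  stopifnot(length(coi_strain) == length(tpi_strain))
  cat_of <- function(a, b) {
    if (!a %in% c("CS", "RS") || !b %in% c("TpiC", "TpiR", "TpiH"))
      return(c("excluded", NA_character_))
    cell <- paste0("COI-", a, " ", b)
    category <- if (b == "TpiH") "Heterozygous"
    else if ((a == "CS") == (b == "TpiC")) "Concordant" else "Discordant"
    c(category, cell)
  }
  out <- t(mapply(cat_of, as.character(coi_strain), as.character(tpi_strain)))
  data.frame(category = out[, 1], cell = out[, 2], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-collection frequencies with unweighted mean and SD
#'
#' Computes, for each collection (row), the proportion of the selected
#' category among a denominator set of categories, then summarises with the
#' unweighted arithmetic mean over collections (each collection one unit,
#' not pooled over specimens) and the sample (n-1) standard deviation.
#' Collections with a zero denominator are omitted with a warning.
#'
#' @param df Data frame with a `collection` column and numeric category
#'   columns (e.g. the packaged survey fixtures, or output of
#'   [adjust_tpi_table()]).
#' @param quantity Column name (or vector of column names summed together)
#'   forming the numerator.
#' @param denominator Character vector of column names forming the
#'   denominator; default: all numeric columns.
#' @return A `frequency_summary`: `quantity`, `freqs` (named per-collection
#'   proportions), `mean`, `sd`, `n`.
#' @export
frequency_summary <- function(df, quantity, denominator = NULL) {
  num_cols <- names(df)[vapply(df, is.numeric, TRUE)]
  if (is.null(denominator)) denominator <- num_cols
  stopifnot(all(quantity %in% num_cols), all(denominator %in% num_cols))
  num <- rowSums(df[, quantity, drop = FALSE])
  den <- rowSums(df[, denominator, drop = FALSE])
  keep <- den > 0
  if (any(!keep))
    warning("omitting collections with zero denominator: ",
            paste(df$collection[!keep], collapse = ", "))
  freqs <- stats::setNames(num[keep] / den[keep], df$collection[keep])
  structure(list(quantity = paste(quantity, collapse = "+"),
                 freqs = freqs, mean = mean(freqs),
                 sd = stats::sd(freqs), n = sum(keep)),
            class = "frequency_summary")
}

#' @export
print.frequency_summary <- function(x, digits = 3, ...) {
  cat(sprintf("%s: mean %.2f +/- %.2f over %d collections\n",
              x$quantity, x$mean, x$sd, x$n))
  print(round(x$freqs, digits))
  invisible(x)
}

#' Two-group regional comparison of per-collection frequencies
#'
#' Two-sided t-test on per-collection proportions, Welch (unequal variance)
#' by default, comparing a named group of collections against another
#' (typically the remaining collections). Significance letters are assigned
#' at `alpha`: the groups share the letter `a` when not significantly
#' different, otherwise get `a` and `b`.
#'
#' @param x A `frequency_summary` or a named numeric vector of
#'   per-collection proportions.
#' @param group_a,group_b Character vectors of collection labels; each must
#'   have at least 2 members. `group_b = NULL` takes all remaining
#'   collections.
#' @param var_equal Use the pooled-variance Student flavour instead of Welch.
#' @param alpha Significance level for the letters (default 0.05).
#' @return A `region_comparison`: `t`, `df`, `p`, group means/sds/sizes,
#'   `letters`.
#' @export
compare_regions <- function(x, group_a, group_b = NULL, var_equal = FALSE,
                            alpha = 0.05) {
  freqs <- if (inherits(x, "frequency_summary")) x$freqs else x
  if (is.null(group_b)) group_b <- setdiff(names(freqs), group_a)
  fa <- freqs[intersect(names(freqs), group_a)]
  fb <- freqs[intersect(names(freqs), group_b)]
  if (length(fa) < 2L || length(fb) < 2L)
    stop("each group needs at least 2 collections for a t-test")
  tt <- stats::t.test(fa, fb, var.equal = var_equal)
  p <- tt$p.value
  structure(list(
    group_a = names(fa), group_b = names(fb),
    t = unname(tt$statistic), df = unname(tt$parameter), p = p,
    mean_a = mean(fa), mean_b = mean(fb),
    sd_a = stats::sd(fa), sd_b = stats::sd(fb),
    n_a = length(fa), n_b = length(fb),
    alpha = alpha,
    letters = if (p < alpha) c(a = "a", b = "b") else c(a = "a", b = "a")),
    class = "region_comparison")
}

#' @export
print.region_comparison <- function(x, ...) {
  cat(sprintf("t = %.3f, df = %.2f, p = %.3g (letters: %s/%s at alpha = %g)\n",
              x$t, x$df, x$p, x$letters["a"], x$letters["b"], x$alpha))
  cat(sprintf("  group a (n=%d): mean %.3f sd %.3f  [%s]\n", x$n_a, x$mean_a,
              x$sd_a, paste(x$group_a, collapse = ", ")))
  cat(sprintf("  group b (n=%d): mean %.3f sd %.3f\n", x$n_b, x$mean_b, x$sd_b))
  invisible(x)
}

#' Pooled (specimen-weighted) share of a category
#'
#' Counts are pooled across collections before dividing, in contrast to the
#' unweighted across-collection mean of [frequency_summary()]. The percent
#' is rounded half-up to an integer.
#'
#' @param df Counts data frame (one row per collection).
#' @param numerator Column name(s) forming the numerator.
#' @param denominator Column names forming the denominator class set.
#' @return List with `proportion`, `percent` (integer), `numerator_total`,
#'   `denominator_total`.
#' @export
pooled_shares <- function(df, numerator, denominator) {
  num <- sum(df[, numerator, drop = FALSE])
  den <- sum(df[, denominator, drop = FALSE])
  if (den <= 0) stop("empty denominator class set")
  list(proportion = num / den,
       percent = round_half_up(100 * num / den),
       numerator_total = num, denominator_total = den)
}
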