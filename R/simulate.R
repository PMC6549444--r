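#' Configuration for the synthetic collection generator
#'
#' Defaults emulate the continental survey the package analyses: 13
#' collections with the published collection sizes and source types (one
#' male pheromone-trap collection, the rest larval), COIB haplotype and Tpi
#' allele frequencies set to the survey's across-collection means, a 1:1 sex
#' ratio in larval collections, and independent mitochondrial-nuclear draws
#' (the marker decoupling observed in the invasive range). Z-linkage is
#' respected: females carry one Tpi allele, males two, drawn independently
#' from the allele frequency vector (random mating).
#'
#' @param collections Data frame with columns `collection`, `n`,
#'   `source_type`; default: the packaged 13-collection layout.
#' @param coib_freq Named frequencies over panel COIB haplotypes.
#' @param tpi_freq Named frequencies over the Tpi alleles `Ca1`, `Ca2`,
#'   `Ra1` (chromosome basis).
#' @param tpii4_freq Named list: for each Tpi allele, frequencies of its
#'   linked TpiI4 intron haplotypes.
#' @param coupling `"independent"` (COIB haplotype drawn from `coib_freq`
#'   regardless of the Tpi genotype) or `"discordance"` (the specimen's COI
#'   strain class disagrees with its Tpi-derived strain class with
#'   probability `discordance_prob`; the COIB haplotype is then drawn within
#'   the selected strain).
#' @param discordance_prob Probability of mito-nuclear disagreement under
#'   `coupling = "discordance"`.
#' @param sex_ratio Male fraction in larval collections (default 0.5);
#'   male-trap collections are all male.
#' @param fail_prob Named per-marker sequencing-failure probabilities
#'   (`COIB`, `TpiE4`, `TpiI4`), default 0.
#' @param site_error Per-site error rate on emitted sequences (default 0).
#' @return A `sim_config` object.
#' @export
sim_config <- function(collections = NULL,
                       coib_freq = c("COI-CSa1" = 0.33, "COI-CSa2" = 0.01,
                                     "COI-RSa1" = 0.63, "COI-RSa2" = 0.02,
                                     "COI-RSa3" = 0.005, "COI-RSa4" = 0.005),
                       tpi_freq = c(Ca1 = 0.59, Ca2 = 0.31, Ra1 = 0.10),
                       tpii4_freq = list(
                         Ca1 = c(TpiI4Ca1a = 0.997, TpiI4Ca1b = 0.003),
                         Ca2 = c(TpiI4Ca2a = 0.75, TpiI4Ca2b = 0.22, TpiI4Ca2c = 0.03),
                         Ra1 = c(TpiI4Ra1a = 1)),
                       coupling = c("independent", "discordance"),
                       discordance_prob = 0,
                       sex_ratio = 0.5,
                       fail_prob = c(COIB = 0, TpiE4 = 0, TpiI4 = 0),
                       site_error = 0) {
  coupling <- match.arg(coupling)
  if (is.null(collections)) {
    cc <- african_collections()
    collections <- data.frame(collection = cc$collection, n = cc$n,
                              source_type = cc$source_type)
  }
  check_freq <- function(f, what) {
    if (abs(sum(f) - 1) > 1e-9 || any(f < 0))
      stop(what, " frequencies must be nonnegative and sum to 1")
  }
  check_freq(coib_freq, "COIB")
  check_freq(tpi_freq, "Tpi allele")
  for (al in names(tpii4_freq)) check_freq(tpii4_freq[[al]], paste("TpiI4 |", al))
  if (!all(names(tpi_freq) %in% names(tpii4_freq)))
    stop("tpii4_freq must provide intron frequencies for every Tpi allele")
  stopifnot(discordance_prob >= 0, discordance_prob <= 1,
            sex_ratio >= 0, sex_ratio <= 1,
            all(fail_prob >= 0 & fail_prob <= 1),
            site_error >= 0, site_error <= 1,
            all(collections$n >= 0))
  structure(list(collections = collections, coib_freq = coib_freq,
                 tpi_freq = tpi_freq, tpii4_freq = tpii4_freq,
                 coupling = coupling, discordance_prob = discordance_prob,
                 sex_ratio = sex_ratio, fail_prob = fail_prob,
                 site_error = site_error),
            class = "sim_config")
}

draw_from <- function(freq, n) sample(names(freq), n, replace = TRUE, prob = freq)

apply_site_error <- function(seq, rate) {
  if (rate <= 0) return(seq)
  s <- seq_chars(seq)
  hit <- which(stats::runif(length(s)) < rate & s %in% c("A", "C", "G", "T"))
  for (i in hit) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1L)
  paste(s, collapse = "")
}

## Consensus Sanger signal of two Tpi alleles on one chromatograph:
## IUPAC codes at substitution differences; if the alleles differ by an
## insertion feature, the superimposed traces are unreadable downstream of
## the indel point, emitted as N from there on.
merge_allele_seqs <- function(s1, s2, indel_at = NULL) {
  a <- seq_chars(s1); b <- seq_chars(s2)
  stopifnot(length(a) == length(b))
  out <- mapply(function(x, y) if (x == y) x else iupac_merge(x, y), a, b)
  if (!is.null(indel_at) && indel_at <= length(out))
    out[indel_at:length(out)] <- "N"
  paste(out, collapse = "")
}

#' Simulate one collection of specimens
#'
#' Draws latent per-specimen state (sex, one or two Tpi alleles with linked
#' intron haplotypes, a mitochondrial COIB haplotype), then emits the
#' amplicon consensus sequences the wet pipeline would observe: male
#' heterozygotes appear as a single sequence with IUPAC codes at every site
#' where the two alleles differ. Failed markers are omitted from the output.
#' Fully reproducible given the RNG state (set a seed before calling, or use
#' [simulate_study()]).
#'
#' @param cfg A [sim_config()].
#' @param collection Collection label (row of `cfg$collections`).
#' @param panel A `marker_panel`.
#' @return List with `sequences` (named character vectors per marker),
#'   `metadata` (specimen table) and `truth` (latent states and realized
#'   chromosome allele counts).
#' @export
simulate_collection <- function(cfg, collection, panel = default_panel()) {
  row <- match(collection, cfg$collections$collection)
  if (is.na(row)) stop("unknown collection: ", collection)
  n <- cfg$collections$n[row]
  source_type <- cfg$collections$source_type[row]
  ids <- sprintf("%s_%04d", collection, seq_len(n))

  sex <- if (source_type == "male_trap") rep("M", n)
  else ifelse(stats::runif(n) < cfg$sex_ratio, "M", "F")

  allele1 <- draw_from(cfg$tpi_freq, n)
  allele2 <- ifelse(sex == "M", draw_from(cfg$tpi_freq, n), NA_character_)
  intron_of <- function(al) {
    out <- rep(NA_character_, length(al))
    for (a in names(cfg$tpii4_freq)) {
      k <- which(!is.na(al) & al == a)
      if (length(k)) out[k] <- draw_from(cfg$tpii4_freq[[a]], length(k))
    }
    out
  }
  intron1 <- intron_of(allele1)
  intron2 <- intron_of(allele2)

  tpi_class <- ifelse(is.na(allele2) | allele1 == allele2,
                      ifelse(allele1 == "Ra1", "R", "C"),
                      ifelse(allele1 == "Ra1" | allele2 == "Ra1", "H", "C"))
  if (cfg$coupling == "independent") {
    coib_hap <- draw_from(cfg$coib_freq, n)
  } else {
    concordant <- ifelse(tpi_class == "H",
                         ifelse(stats::runif(n) < 0.5, "corn", "rice"),
                         ifelse(tpi_class == "C", "corn", "rice"))
    flip <- stats::runif(n) < cfg$discordance_prob
    strain <- ifelse(flip, ifelse(concordant == "corn", "rice", "corn"), concordant)
    coib_hap <- vapply(strain, function(s) {
      labs <- names(cfg$coib_freq)
      keep <- vapply(labs, function(l) haplotype_strain(panel, l) == s, TRUE)
      f <- cfg$coib_freq[keep]
      sample(names(f), 1L, prob = f)
    }, "", USE.NAMES = FALSE)
  }

  exon_seq <- function(al) haplotype_sequence(panel, paste0("Tpi", al))
  tpie4 <- vapply(seq_len(n), function(i) {
    if (is.na(allele2[i]) || allele1[i] == allele2[i]) exon_seq(allele1[i])
    else merge_allele_seqs(exon_seq(allele1[i]), exon_seq(allele2[i]))
  }, "")

  seg_i4 <- panel_segment(panel, "TpiI4")
  core_seq <- function(h) haplotype_sequence(panel, h, with_indels = FALSE)
  tpii4 <- vapply(seq_len(n), function(i) {
    h1 <- intron1[i]; h2 <- intron2[i]
    if (is.na(h2) || h1 == h2) return(haplotype_sequence(panel, h1))
    i1 <- haplotype_indels(panel, h1); i2 <- haplotype_indels(panel, h2)
    indel_at <- NULL
    if (nrow(i1) != nrow(i2) || (nrow(i1) && !identical(i1, i2))) {
      pos <- min(c(i1$position, i2$position)) - seg_i4$origin_offset + 1L
      indel_at <- max(pos, 1L)
    }
    merge_allele_seqs(core_seq(h1), core_seq(h2), indel_at)
  }, "")

  coib <- vapply(coib_hap, function(h) haplotype_sequence(panel, h), "",
                 USE.NAMES = FALSE)

  if (cfg$site_error > 0) {
    coib <- vapply(coib, apply_site_error, "", rate = cfg$site_error, USE.NAMES = FALSE)
    tpie4 <- vapply(tpie4, apply_site_error, "", rate = cfg$site_error, USE.NAMES = FALSE)
    tpii4 <- vapply(tpii4, apply_site_error, "", rate = cfg$site_error, USE.NAMES = FALSE)
  }

  keep_marker <- function(p) stats::runif(n) >= p
  keep <- list(COIB = keep_marker(cfg$fail_prob[["COIB"]]),
               TpiE4 = keep_marker(cfg$fail_prob[["TpiE4"]]),
               TpiI4 = keep_marker(cfg$fail_prob[["TpiI4"]]))

  alleles_obs <- c(allele1, allele2[!is.na(allele2)])
  truth_counts <- stats::setNames(
    vapply(names(cfg$tpi_freq), function(a) sum(alleles_obs == a), 0L),
    names(cfg$tpi_freq))

  list(
    sequences = list(
      COIB = stats::setNames(coib, ids)[keep$COIB],
      TpiE4 = stats::setNames(tpie4, ids)[keep$TpiE4],
      TpiI4 = stats::setNames(tpii4, ids)[keep$TpiI4]),
    metadata = data.frame(
      specimen_id = ids, collection = collection, source_type = source_type,
      country = collection, year = NA_integer_, host_class = "CS-host",
      stringsAsFactors = FALSE),
    truth = list(
      specimens = data.frame(specimen_id = ids, sex = sex,
                             allele1 = allele1, allele2 = allele2,
                             intron1 = intron1, intron2 = intron2,
                             coib_hap = coib_hap, stringsAsFactors = FALSE),
      allele_counts = truth_counts,
      n_chromosomes = sum(!is.na(allele2)) * 2L + sum(is.na(allele2))))
}

#' Simulate a whole study (all configured collections)
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; all randomness flows from it.
#' @param panel A `marker_panel`.
#' @return List with concatenated `sequences`, `metadata`, and per-collection
#'   `truth`.
#' @export
simulate_study <- function(cfg, seed, panel = default_panel()) {
  set.seed(seed)
  per <- lapply(cfg$collections$collection, function(cl)
    simulate_collection(cfg, cl, panel))
  names(per) <- cfg$collections$collection
  list(
    sequences = list(
      COIB = do.call(c, unname(lapply(per, function(x) x$sequences$COIB))),
      TpiE4 = do.call(c, unname(lapply(per, function(x) x$sequences$TpiE4))),
      TpiI4 = do.call(c, unname(lapply(per, function(x) x$sequences$TpiI4)))),
    metadata = do.call(rbind, c(unname(lapply(per, function(x) x$metadata)),
                                list(make.row.names = FALSE))),
    truth = lapply(per, function(x) x$truth))
}

#' End-to-end parameter recovery on simulated data
#'
#' Simulates the configured collections, classifies every emitted sequence,
#' tabulates and applies the sex-linkage adjustment, and compares the
#' adjusted-count allele-frequency estimates with the generating (realized)
#' frequencies; the binomial standard error uses the realized chromosome
#' count.
#'
#' @inheritParams simulate_study
#' @return List with `calls` (specimen calls), `counts` (per-collection
#'   `collection_counts`), `config_table` (pooled strain-configuration
#'   counts), and `recovery` (data frame per Tpi allele: estimated vs true
#'   frequency, standard error, z-score).
#' @export
end_to_end_recovery <- function(cfg, seed, panel = default_panel()) {
  sim <- simulate_study(cfg, seed, panel)
  calls <- classify_specimens(coib = sim$sequences$COIB,
                              tpie4 = sim$sequences$TpiE4,
                              tpii4 = sim$sequences$TpiI4,
                              metadata = sim$metadata, panel = panel)
  counts <- lapply(split(calls, calls$collection), tabulate_collection)
  adj <- lapply(counts, function(cc) adjust_tpi_counts(cc, sex_ratio = cfg$sex_ratio))
  est_counts <- Reduce(`+`, lapply(adj, function(a) a$raw))
  est_freq <- est_counts / sum(est_counts)

  truth_counts <- Reduce(`+`, lapply(sim$truth, function(t) t$allele_counts))
  true_freq <- truth_counts / sum(truth_counts)
  se <- sqrt(pmax(true_freq * (1 - true_freq), 1e-12) / sum(truth_counts))

  cfg_tab <- strain_configuration(calls$coi_strain, calls$tpi_strain)
  config_table <- table(factor(cfg_tab$category,
                               levels = c("Concordant", "Discordant", "Heterozygous", "excluded")))

  list(calls = calls, counts = counts,
       config_table = config_table,
       recovery = data.frame(
         allele = names(est_freq),
         estimated = as.numeric(est_freq),
         true = as.numeric(true_freq[names(est_freq)]),
         se = as.numeric(se[names(est_freq)]),
         z = as.numeric((est_freq - true_freq[names(est_freq)]) / se[names(est_freq)]),
         row.names = NULL))
}
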