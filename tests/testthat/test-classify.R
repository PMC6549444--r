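coib_of <- function(lab) haplotype_sequence(panel, lab)
site_idx <- function(segment, pos) {
  off <- panel$segments$origin_offset[panel$segments$name == segment]
  pos - off + 1
}

test_that("COI strain calls follow the mCOI1164D rule", {
  expect_equal(call_coi_strain(coib_of("COI-RSa1")), "RS")          # T at 1164
  expect_equal(as.character(call_coi_strain(coib_of("COI-CSa1"))), "CS")  # G
  expect_equal(as.character(call_coi_strain(coib_of("COI-CSa2"))), "CS")  # A
  # C at 1164 has not been found in the species -> unknown, flagged
  qc <- call_coi_strain(mutate_at(coib_of("COI-CSa1"), site_idx("COIB", 1164), "C"))
  expect_equal(as.character(qc), "unknown")
  expect_match(attr(qc, "qc"), "unobserved")
  # ambiguity at 1164 -> failed
  amb <- call_coi_strain(mutate_at(coib_of("COI-CSa1"), site_idx("COIB", 1164), "R"))
  expect_equal(as.character(amb), "failed")
})

test_that("h-configuration is the two-site lookup, rice is not-applicable", {
  expect_equal(coib_h_config(coib_of("COI-CSa2")), "h2")  # A1164 G1287
  expect_equal(coib_h_config(coib_of("COI-CSa1")), "h4")  # G1164 G1287
  expect_equal(coib_h_config(coib_of("COI-RSa1")), "not-applicable")
  h1 <- mutate_at(mutate_at(coib_of("COI-CSa1"), site_idx("COIB", 1164), "A"),
                  site_idx("COIB", 1287), "A")
  expect_equal(coib_h_config(h1), "h1")
  h3 <- mutate_at(coib_of("COI-CSa1"), site_idx("COIB", 1287), "A")
  expect_equal(coib_h_config(h3), "h3")
  # h-config in {h1..h4} <=> strain CS, on every panel haplotype
  for (l in panel$haplotypes$label[panel$haplotypes$segment == "COIB"]) {
    h <- coib_h_config(coib_of(l))
    s <- as.character(call_coi_strain(coib_of(l)))
    expect_equal(h %in% c("h1", "h2", "h3", "h4"), s == "CS", info = l)
  }
})

test_that("COIB haplotype assignment matches exactly or reports novel", {
  for (l in panel$haplotypes$label[panel$haplotypes$segment == "COIB"])
    expect_equal(as.character(assign_coib_haplotype(coib_of(l))), l)
  # one mismatch at a diagnostic site vs every panel entry -> novel;
  # mismatch counts verified against an exhaustive panel scan
  q <- mutate_at(coib_of("COI-RSa1"), site_idx("COIB", 1197), "A")
  got <- assign_coib_haplotype(q)
  expect_equal(as.character(got), "novel")
  v <- attr(got, "vector")
  oracle <- vapply(panel$haplotypes$label[panel$haplotypes$segment == "COIB"],
                   function(l) sum(haplotype_vector(panel, l) != v), 0L)
  expect_equal(attr(got, "mismatches"), oracle)
  expect_equal(min(oracle), 1L)
  # ambiguity at a panel site -> failed (mitochondrial, heterozygosity unexpected)
  expect_equal(as.character(assign_coib_haplotype(
    mutate_at(coib_of("COI-RSa1"), site_idx("COIB", 1125), "Y"))), "failed")
})

test_that("species QC passes within one substitution of the panel", {
  expect_true(species_qc(coib_of("COI-CSa1"))$pass)
  expect_equal(species_qc(coib_of("COI-CSa1"))$distance, 0L)
  one_off <- mutate_at(coib_of("COI-RSa1"), 10, other_base(substr(coib_of("COI-RSa1"), 10, 10)))
  expect_true(species_qc(one_off)$pass)
  expect_equal(species_qc(one_off)$distance, 1L)
  # five substitutions vs everything -> fail; distance equals a brute-force scan
  q <- coib_of("COI-CSa1")
  idx <- c(5, 15, 25, 35, 45)  # away from diagnostic sites
  for (i in idx) q <- mutate_at(q, i, other_base(substr(q, i, i)))
  got <- species_qc(q)
  expect_false(got$pass)
  oracle <- min(vapply(panel$haplotypes$label[panel$haplotypes$segment == "COIB"],
                       function(l) {
                         a <- strsplit(haplotype_sequence(panel, l), "")[[1]]
                         b <- strsplit(q, "")[[1]]
                         sum(a != b)
                       }, 0L))
  expect_equal(got$distance, oracle)
  expect_equal(got$distance, 5L)
})

test_that("Tpi strain calls follow the gTpi183Y rule", {
  expect_equal(call_tpi_strain(haplotype_sequence(panel, "TpiCa1")), "TpiC")
  expect_equal(call_tpi_strain(haplotype_sequence(panel, "TpiRa1")), "TpiR")
  het <- het_consensus(haplotype_sequence(panel, "TpiCa1"),
                       haplotype_sequence(panel, "TpiRa1"))
  expect_equal(call_tpi_strain(het), "TpiH")
})

test_that("TpiE4 genotype decoding is a left inverse of the IUPAC union", {
  labs <- panel$haplotypes$label[panel$haplotypes$segment == "TpiE4"]
  class_of <- c("TpiCa1/TpiCa2" = "C-YY", "TpiCa1/TpiRa1" = "H-CC",
                "TpiCa2/TpiRa1" = "H-YY")
  # singletons decode to themselves
  for (l in labs)
    expect_equal(as.character(assign_tpie4_genotype(haplotype_sequence(panel, l))),
                 sub("^Tpi", "", l))
  # every unordered pair encodes (union) then decodes back to exactly that pair
  for (pr in utils::combn(labs, 2, simplify = FALSE)) {
    enc <- het_consensus(haplotype_sequence(panel, pr[1]),
                         haplotype_sequence(panel, pr[2]))
    expect_equal(as.character(assign_tpie4_genotype(enc)),
                 unname(class_of[paste(sort(pr), collapse = "/")]))
  }
})

test_that("unscorable codes and vectors matching nothing are handled", {
  s <- haplotype_sequence(panel, "TpiCa1")
  expect_equal(as.character(assign_tpie4_genotype(mutate_at(s, 183, "N"))), "failed")
  # Y at 192 only (not 198): consistent with no singleton and no pair
  expect_equal(as.character(assign_tpie4_genotype(mutate_at(s, 192, "Y"))), "ambiguous")
})

test_that("genotype-derived strain agrees with the direct gTpi183 call", {
  labs <- panel$haplotypes$label[panel$haplotypes$segment == "TpiE4"]
  seqs <- c(lapply(labs, function(l) haplotype_sequence(panel, l)),
            lapply(utils::combn(labs, 2, simplify = FALSE), function(pr)
              het_consensus(haplotype_sequence(panel, pr[1]),
                            haplotype_sequence(panel, pr[2]))))
  for (s in seqs) {
    g <- genotype_strain(as.character(assign_tpie4_genotype(s)))
    expect_equal(g, as.character(call_tpi_strain(s)))
  }
})

test_that("TpiI4 calls follow the core rules (site 131 forced, ambiguity = het)", {
  core_labs <- panel$haplotypes$label[panel$haplotypes$segment == "TpiI4"]
  for (l in core_labs)
    expect_equal(assign_tpii4_haplotype(haplotype_sequence(panel, l)), l)
  ref <- haplotype_sequence(panel, "TpiI4Ca1a")
  i131 <- site_idx("TpiI4", 131)
  # R at the poor-signal site is forced to consensus G and still called
  expect_equal(assign_tpii4_haplotype(mutate_at(ref, i131, "R")), "TpiI4Ca1a")
  # one Y elsewhere in the core -> heterozygous
  expect_equal(assign_tpii4_haplotype(mutate_at(ref, 50, "Y")), "heterozygous")
  # rule-by-rule reference oracle over a batch of perturbed cores
  rule_oracle <- function(s) {
    ch <- strsplit(s, "")[[1]]
    ch[i131] <- "G"
    if (any(!ch %in% c("A", "C", "G", "T"))) return("heterozygous")
    obs <- paste(ch, collapse = "")
    for (l in core_labs) {
      h <- strsplit(haplotype_sequence(panel, l, with_indels = FALSE), "")[[1]]
      h[i131] <- "G"
      if (paste(h, collapse = "") == obs &&
          nrow(fawstrain:::haplotype_indels(panel, l)) == 0) return(l)
    }
    "novel"
  }
  set.seed(11)
  for (rep in 1:20) {
    s <- ref
    k <- sample(0:2, 1)
    for (i in sample(setdiff(seq_len(nchar(ref)), i131), k))
      s <- mutate_at(s, i, sample(c("Y", "R", other_base(substr(s, i, i))), 1))
    expect_equal(assign_tpii4_haplotype(s), rule_oracle(s), info = s)
  }
})

test_that("classification is deterministic and assembles full specimen calls", {
  md <- data.frame(specimen_id = c("s1", "s2", "s3"),
                   collection = "X", source_type = "larva")
  coib <- c(s1 = coib_of("COI-CSa1"), s2 = coib_of("COI-RSa1"), s3 = coib_of("COI-RSa2"))
  tpie4 <- c(s1 = haplotype_sequence(panel, "TpiCa1"),
             s2 = het_consensus(haplotype_sequence(panel, "TpiCa1"),
                                haplotype_sequence(panel, "TpiRa1")))
  calls1 <- classify_specimens(coib = coib, tpie4 = tpie4, metadata = md)
  calls2 <- classify_specimens(coib = coib, tpie4 = tpie4, metadata = md)
  expect_identical(calls1, calls2)
  expect_equal(calls1$coi_strain, c("CS", "RS", "RS"))
  expect_equal(calls1$tpie4_genotype, c("Ca1", "H-CC", "failed"))
  expect_equal(calls1$tpi_strain, c("TpiC", "TpiH", "unknown"))
  expect_equal(calls1$h_config, c("h4", "not-applicable", "not-applicable"))
})
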