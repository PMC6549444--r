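rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

test_that("TN93 distance is zero on identical sequences and symmetric", {
  set.seed(1)
  a <- rand_seq(200)
  expect_equal(tn93_distance(a, a), 0)
  b <- mutate_at(a, c(3, 50, 120), c("A", "C", "G"))
  expect_equal(tn93_distance(a, b), tn93_distance(b, a))
  expect_error(tn93_distance(substr(a, 1, 10), substr(a, 1, 10)), "comparable sites")
})

test_that("TN93 reduces to the transversion-only closed form at equal base frequencies", {
  # 25% of each base in the pool, differences all transversions:
  # d = -1/2 log(1-Q) - 1/4 log(1-2Q)
  block <- function(n) paste(rep(c("A", "C", "G", "T"), n / 4), collapse = "")
  a <- block(200)
  # A<->C at 8 positions spread over A-sites, compensated to keep frequencies equal:
  # swap A->C at 4 sites and C->A at 4 sites (all transversions)
  ch <- strsplit(a, "")[[1]]
  ia <- which(ch == "A")[1:4]; ic <- which(ch == "C")[1:4]
  b <- mutate_at(a, c(ia, ic), c(rep("C", 4), rep("A", 4)))
  Q <- 8 / 200
  closed <- -0.5 * log(1 - Q) - 0.25 * log(1 - 2 * Q)
  expect_equal(tn93_distance(a, b), closed, tolerance = 1e-10)
})

test_that("TN93 equals the hand-evaluated formula on a fixed 100-bp pair", {
  # deterministic pair: 3 A<->G, 2 C<->T, 1 transversion on a fixed backbone
  set.seed(99)
  a <- rand_seq(100)
  ch <- strsplit(a, "")[[1]]
  iag <- which(ch == "A")[1:3]
  ict <- which(ch == "C")[1:2]
  itv <- which(ch == "T")[1]
  b <- mutate_at(a, c(iag, ict, itv), c(rep("G", 3), rep("T", 2), "G"))
  # hand evaluation from the pooled pair
  pool <- c(strsplit(a, "")[[1]], strsplit(b, "")[[1]])
  g <- c(A = mean(pool == "A"), C = mean(pool == "C"),
         G = mean(pool == "G"), T = mean(pool == "T"))
  gR <- g[["A"]] + g[["G"]]; gY <- g[["C"]] + g[["T"]]
  P1 <- 3 / 100; P2 <- 2 / 100; Q <- 1 / 100
  k1 <- 2 * g[["A"]] * g[["G"]] / gR
  k2 <- 2 * g[["C"]] * g[["T"]] / gY
  k3 <- 2 * (gR * gY - g[["A"]] * g[["G"]] * gY / gR - g[["C"]] * g[["T"]] * gR / gY)
  hand <- -k1 * log(1 - P1 / k1 - Q / (2 * gR)) -
    k2 * log(1 - P2 / k2 - Q / (2 * gY)) - k3 * log(1 - Q / (2 * gR * gY))
  expect_equal(tn93_distance(a, b), hand, tolerance = 1e-12)
  # cross-check against the independent reference implementation
  m <- rbind(strsplit(a, "")[[1]], strsplit(b, "")[[1]])
  rownames(m) <- c("a", "b")
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(m), model = "TN93",
                                 pairwise.deletion = TRUE))["a", "b"]
  expect_equal(tn93_distance(a, b), unname(ref), tolerance = 1e-8)
})

test_that("TN93 is nondecreasing in the number of differing sites", {
  set.seed(5)
  a <- rand_seq(300)
  prev <- 0
  s <- a
  for (k in 1:10) {
    i <- 20 * k
    s <- mutate_at(s, i, other_base(substr(s, i, i)))
    d <- tn93_distance(a, s)
    expect_gte(d, prev)
    prev <- d
  }
})

test_that("pairwise deletion excludes gap and ambiguity columns", {
  a <- "AAAACCCCGGGGTTTTAAAACCCCGGGGTTTT"
  b <- sub("^AAAA", "-YAA", a)  # one gap, one ambiguity
  expect_equal(tn93_distance(a, b, min_sites = 10), 0)
})

test_that("neighbor joining recovers additive trees exactly", {
  # 3 tips: unique topology, three-point branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, dimnames = list(letters[1:3], letters[1:3]))
  t3 <- nj_tree(d3)
  expect_equal(sort(t3$tip.label), c("a", "b", "c"))
  expect_equal(as.matrix(ape::cophenetic.phylo(t3))[letters[1:3], letters[1:3]], d3)

  # 4-taxon additive matrix: exact topology and branch lengths
  # tree ((a:1,b:2):1.5,(c:0.5,d:3):0);
  gen <- ape::read.tree(text = "((a:1,b:2):1.5,c:0.5,d:3);")
  d4 <- as.matrix(ape::cophenetic.phylo(gen))
  t4 <- nj_tree(d4)
  expect_equal(as.matrix(ape::cophenetic.phylo(t4))[rownames(d4), colnames(d4)],
               d4, tolerance = 1e-9)
  expect_equal(ape::dist.topo(ape::unroot(t4), ape::unroot(gen)), structure(0, names = "PH85"),
               ignore_attr = TRUE)

  # 5-tip random additive matrices: path lengths reproduce the input
  # (four-point condition) and topology matches the independent reference
  set.seed(8)
  for (rep in 1:5) {
    gen5 <- ape::rtree(5, rooted = FALSE)
    gen5$edge.length <- stats::runif(nrow(gen5$edge), 0.2, 2)
    d5 <- as.matrix(ape::cophenetic.phylo(gen5))
    t5 <- nj_tree(d5)
    expect_equal(as.matrix(ape::cophenetic.phylo(t5))[rownames(d5), colnames(d5)],
                 d5, tolerance = 1e-8)
    expect_equal(as.numeric(ape::dist.topo(t5, ape::nj(d5))), 0)
  }
})

test_that("neighbor joining validates input and clamps negative branches", {
  bad <- matrix(c(0, 1, 1, 0), 2)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric")
  d <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  d[1, 2] <- d[2, 1] <- 2.5  # violates triangle tightness -> negative 3-point length
  t <- nj_tree(d)
  expect_true(all(t$edge.length >= 0))
})

test_that("tie-breaking is deterministic: same matrix, same newick", {
  d <- matrix(1, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  diag(d) <- 0
  n1 <- ape::write.tree(nj_tree(d))
  n2 <- ape::write.tree(nj_tree(d[c(3, 1, 2, 6, 5, 4), c(3, 1, 2, 6, 5, 4)]))
  expect_identical(n1, ape::write.tree(nj_tree(d)))
  expect_identical(sort(nj_tree(d)$tip.label), letters[1:6])
  expect_identical(n1, n2)  # label order in the matrix does not matter
})

test_that("clade composition walks nested clades outward from the focal tip", {
  txt <- "(((focal:1,p1:1):1,(p2:1,p3:1):1):1,(o1:1,o2:1):1,(o3:1,o4:1):1);"
  tree <- ape::read.tree(text = txt)
  ann <- data.frame(tip = c("focal", "p1", "p2", "p3", "o1", "o2", "o3", "o4"),
                    host_class = c("unknown", "RS-host", "RS-host", "RS-host",
                                   "CS-host", "CS-host", "CS-host", "CS-host"),
                    coi_strain = c("unknown", "RS", "RS", "RS", "CS", "CS", "CS", "CS"))
  cc <- clade_composition(tree, ann, "focal")
  expect_equal(cc$headline$n_members, 1)        # the cherry partner
  expect_equal(cc$headline[["host_RS-host"]], 1.0)
  expect_equal(cc$report[["host_RS-host"]][2], 1.0)  # next clade: p1,p2,p3
  expect_equal(cc$report$n_members, c(1, 3, 7))
  # fractions lie in [0,1] and sum to 1 over each closed vocabulary
  hostcols <- paste0("host_", c("CS-host", "RS-host", "unknown"))
  expect_true(all(abs(rowSums(cc$report[hostcols]) - 1) < 1e-12))

  # star tree: the smallest containing clade is the whole tree
  star <- ape::read.tree(text = "(f:1,a:1,b:1,c:1);")
  ann2 <- data.frame(tip = c("f", "a", "b", "c"),
                     host_class = c("unknown", "CS-host", "CS-host", "RS-host"),
                     coi_strain = c("unknown", "CS", "CS", "RS"))
  cs <- clade_composition(star, ann2, "f")
  expect_equal(nrow(cs$report), 1)
  expect_equal(cs$headline[["host_CS-host"]], 2 / 3)
  expect_error(clade_composition(star, ann2, "zz"), "not in tree")
})

test_that("clade fractions equal a naive extract-and-recount traversal", {
  set.seed(21)
  tree <- ape::rtree(12)
  ann <- data.frame(tip = tree$tip.label,
                    host_class = sample(c("CS-host", "RS-host", "unknown"), 12, TRUE),
                    coi_strain = sample(c("CS", "RS", "unknown"), 12, TRUE))
  focal <- tree$tip.label[5]
  cc <- clade_composition(tree, ann, focal)
  ntip <- length(tree$tip.label)
  node <- match(focal, tree$tip.label)
  k <- 0
  repeat {
    parent <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(parent) == 0) break
    node <- parent; k <- k + 1
    tips <- if (node == ntip + 1) tree$tip.label else
      ape::extract.clade(tree, node)$tip.label
    members <- setdiff(tips, focal)
    expect_equal(cc$report$n_members[k], length(members))
    for (h in c("CS-host", "RS-host", "unknown")) {
      naive <- mean(ann$host_class[match(members, ann$tip)] == h)
      expect_equal(cc$report[[paste0("host_", h)]][k], naive)
    }
  }
  expect_equal(k, nrow(cc$report))
})

test_that("duplicate sequences collapse to unique haplotypes", {
  seqs <- c(x1 = "ACGT", x2 = "ACGT", y = "AGGT")
  u <- collapse_duplicates(seqs)
  expect_equal(length(u), 2)
  expect_equal(attr(u, "members")$x1, c("x1", "x2"))
})
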