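test_that("ABBA/BABA counting matches a hand-countable fixture", {
  taxa <- c("P1", "P2", "P3", "O")
  aln <- matrix(c(
    "A", "A", "A", "A",   # constant
    "A", "C", "C", "A",   # ABBA
    "G", "T", "G", "T",   # BABA (derived = G relative to O = T)
    "A", "C", "C", "A",   # ABBA
    "A", "C", "G", "A",   # three alleles: excluded
    "A", "-", "C", "A",   # gap: excluded
    "C", "C", "A", "A",   # BBAA: neither
    "A", "A", "C", "A"),  # P3 singleton: neither
    nrow = 4, dimnames = list(taxa, NULL))
  expect_identical(count_patterns_4taxon(aln, taxa), c(ABBA = 2L, BABA = 1L))
  flat <- matrix("G", 4, 20, dimnames = list(taxa, NULL))
  expect_identical(count_patterns_4taxon(flat, taxa), c(ABBA = 0L, BABA = 0L))
  expect_error(count_patterns_4taxon(aln, taxa[1:3]), "4 taxa")
})

test_that("D statistic arithmetic and degenerate input", {
  expect_equal(d_stat(25, 25), 0)
  expect_equal(d_stat(30, 10), 0.5)
  expect_error(d_stat(0, 0), "undefined")
})

test_that("swapping P1 and P2 negates D exactly", {
  set.seed(901)
  net <- species_network("(((P1:1,P2:1):1,P3:2):2,O:4);", outgroup = "O")
  taxa <- c("P1", "P2", "P3", "O")
  cnt <- simulate_pattern_counts(net, taxa, 150, 300, theta = 0.05)
  aln <- counts_to_alignment(cnt, taxa)
  ab <- count_patterns_4taxon(aln, taxa)
  ba <- count_patterns_4taxon(aln, c("P2", "P1", "P3", "O"))
  expect_identical(unname(ab[c("ABBA", "BABA")]), unname(ba[c("BABA", "ABBA")]))
  expect_equal(d_stat(ab[1], ab[2]), -d_stat(ba[1], ba[2]))
})

test_that("ILS-only data give ABBA approximately equal to BABA", {
  set.seed(902)
  net <- species_network("(((P1:1,P2:1):1,P3:2):2,O:4);", outgroup = "O")
  taxa <- c("P1", "P2", "P3", "O")
  cnt <- simulate_pattern_counts(net, taxa, 600, 500, theta = 0.05)
  pc <- count_patterns_4taxon(counts_to_alignment(cnt, taxa), taxa)
  n <- sum(pc)
  expect_gt(n, 100)  # enough informative sites for the check to mean something
  expect_lt(abs(pc[["ABBA"]] - pc[["BABA"]]) / n, 3 / sqrt(n))
})

test_that("weighted block jackknife matches brute-force delete-one recomputation", {
  set.seed(903)
  G <- 20
  abba <- rpois(G, 40) + 1L
  baba <- rpois(G, 30) + 1L
  res <- weighted_block_jackknife(abba, baba)
  ## independent recomputation (Busing et al. delete-m_j jackknife)
  m <- abba + baba; n <- sum(m)
  D <- (sum(abba) - sum(baba)) / n
  Dj <- sapply(seq_len(G), function(j)
    (sum(abba[-j]) - sum(baba[-j])) / (sum(m[-j])))
  h <- n / m
  thJ <- G * D - sum((1 - m / n) * Dj)
  se <- sqrt(sum((h * D - (h - 1) * Dj - thJ)^2 / (h - 1)) / G)
  expect_equal(res$D, D, tolerance = 1e-12)
  expect_equal(res$SE, se, tolerance = 1e-12)
  expect_equal(res$Z, D / se, tolerance = 1e-12)
  ## equal weights reduce to the classical delete-one jackknife
  res_eq <- weighted_block_jackknife(rep(12, 8), c(9, 11, 10, 8, 12, 9, 10, 11))
  m2 <- rep(12, 8) + c(9, 11, 10, 8, 12, 9, 10, 11)
  expect_true(is.finite(res_eq$Z))
})

test_that("degenerate jackknife inputs are flagged", {
  r <- weighted_block_jackknife(rep(10, 5), rep(5, 5))
  expect_true(r$degenerate)
  expect_identical(r$Z, Inf)
  expect_error(weighted_block_jackknife(10, 5), "2 blocks")
})

test_that("contiguity test detects a clustered run and rejects degenerate input", {
  set.seed(904)
  r <- contiguity_test(101:110, 1000, n_perm = 800)
  expect_equal(r$observed, 9)
  expect_lt(r$p, 0.01)
  expect_error(contiguity_test(integer(0), 100), "contiguity")
  expect_error(contiguity_test(1:100, 100), "contiguity")
  ## uniformly random flags: p behaves like a null p-value
  ps <- replicate(40, {
    fl <- sample.int(400, 25)
    contiguity_test(fl, 400, n_perm = 200)$p
  })
  expect_gt(mean(ps > 0.05), 0.6)
  expect_gt(stats::sd(ps), 0.05)
})

## ---- D_FOIL ----------------------------------------------------------------

test_that("D_FOIL pattern counting tallies derived patterns by outgroup polarity", {
  taxa <- c("P1", "P2", "P3", "P4", "O")
  aln <- matrix(c(
    "A", "A", "A", "A", "A",
    "C", "A", "C", "A", "A",   # BABA
    "C", "A", "C", "A", "A",   # BABA
    "A", "G", "G", "G", "A",   # ABBB
    "T", "T", "T", "T", "C"),  # BBBB
    nrow = 5, dimnames = list(taxa, NULL))
  cnt <- count_patterns_dfoil(aln, taxa)
  expect_equal(cnt[["BABA"]], 2L)
  expect_equal(cnt[["ABBB"]], 1L)
  expect_equal(cnt[["BBBB"]], 1L)
  expect_equal(sum(cnt), 5L)
})

test_that("component antisymmetries hold exactly under within-pair swaps", {
  set.seed(905)
  net <- dfoil_net(pulses = data.frame(time = 0.5, donor = "P3",
                                       recipient = "P1", gamma = 0.3))
  taxa <- c("P1", "P2", "P3", "P4", "O")
  cnt <- simulate_pattern_counts(net, taxa, 250, 300, theta = 0.05)
  aln <- counts_to_alignment(cnt, taxa)
  base <- dfoil_components(count_patterns_dfoil(aln, taxa), alpha = 1)
  sw34 <- dfoil_components(count_patterns_dfoil(
    aln, c("P1", "P2", "P4", "P3", "O")), alpha = 1)
  expect_equal(sw34$D[1:2], -base$D[1:2], tolerance = 1e-12)  # DFO, DIL flip
  sw12 <- dfoil_components(count_patterns_dfoil(
    aln, c("P2", "P1", "P3", "P4", "O")), alpha = 1)
  expect_equal(sw12$D[3:4], -base$D[3:4], tolerance = 1e-12)  # DFI, DOL flip
})

test_that("signature lookup is a pure function with an unclassified fallback", {
  expect_identical(dfoil_classify("0000"), "none")
  expect_identical(dfoil_classify("+0+0"), "recent:P3=>P1")
  expect_identical(dfoil_classify("++00"), "ancestral:P3<->anc(P1,P2)")
  expect_identical(dfoil_classify("+-+-"), "unclassified")
})

test_that("the taxon-depth precondition is enforced against the species tree", {
  net <- dfoil_net()
  aln <- list(matrix("A", 5, 10,
                     dimnames = list(c("P1", "P2", "P3", "P4", "O"), NULL)))
  expect_error(dfoil_scan(aln, c("P3", "P4", "P1", "P2", "O"), net = net),
               "more recent")
})

test_that("modal window signatures reproduce the shipped table rows", {
  ## scaled-down check on three contrasting scenarios; the full scenario
  ## sweep runs with the acceptance suite
  set.seed(906)
  taxa <- c("P1", "P2", "P3", "P4", "O")
  cases <- list(
    none = list(pulse = NULL, sig = "0000"),
    recent = list(pulse = data.frame(time = 0.5, donor = "P3",
                                     recipient = "P1", gamma = 0.3),
                  sig = "+0+0"),
    ancestral = list(pulse = data.frame(time = 1.5, donor = "P1+P2",
                                        recipient = "P3", gamma = 0.3),
                     sig = "++00"))
  for (cs in cases) {
    net <- dfoil_net(pulses = cs$pulse)
    sigs <- replicate(12, {
      cnt <- simulate_pattern_counts(net, taxa, 250, 200, theta = 0.02)
      comp <- dfoil_components(cnt16_from_full(cnt, taxa), alpha = 0.01)
      paste(comp$sign, collapse = "")
    })
    modal <- names(sort(table(sigs), decreasing = TRUE))[1]
    expect_identical(modal, cs$sig)
  }
})
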