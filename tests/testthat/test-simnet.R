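test_that("species network construction validates its inputs", {
  expect_error(species_network("((A:1,B:1):1,C:2);", outgroup = "Z"),
               "outgroup")
  expect_error(species_network("(((A:1,B:1):1,C:2):1,O:3);", outgroup = "C"),
               "root")
  expect_error(triplet_net() |> (\(n) species_network(n$tree, outgroup = "C",
    pulses = data.frame(time = 3, donor = "A", recipient = "B", gamma = 0.1)))(),
    "lifespan")
  expect_error(species_network("((A:1,B:1):1,C:2);", outgroup = "C",
    pulses = data.frame(time = 0.5, donor = "A", recipient = "B", gamma = 1.2)),
    "gamma")
  net <- triplet_net()
  expect_s3_class(net, "species_network")
  expect_output(print(net), "outgroup")
})

test_that("MSC triplet topology probabilities match the closed form", {
  expect_equal(unname(msc_topology_probs(0)[1, ]), rep(1 / 3, 3))
  expect_equal(unname(msc_topology_probs(1e9)[1, ]), c(1, 0, 0))
  p <- msc_topology_probs(0.5184)
  expect_equal(unname(p[1, ]), c(0.6030183, 0.1984908, 0.1984908),
               tolerance = 1e-6)
  expect_equal(rowSums(msc_topology_probs(c(0.1, 0.7, 2))), rep(1, 3))
  expect_equal(unname(msc_topology_probs(2)[, "minor1"]),
               unname(msc_topology_probs(2)[, "minor2"]))
  expect_error(msc_topology_probs(-0.1), "non-negative")
})

test_that("simulated topology-class frequencies match the analytic MSC law", {
  set.seed(401)
  for (T in c(0.25, 1, 2)) {
    net <- triplet_net(T)
    n <- 20000
    cls <- character(n)
    for (i in seq_len(n)) cls[i] <- sample_gene_tree(net, focal = c("A", "B", "C"))$class
    obs <- c(sum(cls %in% c("type0", "type1")), sum(cls == "type2"),
             sum(cls == "type3"))
    expected <- msc_topology_probs(T)[1, ]
    chi <- stats::chisq.test(obs, p = expected)
    expect_gt(chi$p.value, 0.001)
  }
})

test_that("pairwise TMRCA in a single population has mean one coalescent unit", {
  net <- species_network("((A:0.0001,B:0.0001):5,C:5.0001);", outgroup = "C")
  set.seed(402)
  tm <- replicate(20000, sample_gene_tree(net)$coal_times["A", "B"])
  se <- stats::sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 1.0001), 3 * se)
})

test_that("hybrid node with extreme gamma degenerates to a tree", {
  nwk <- "((((H:1,A:1):1,B:2):1,C:3):2,O:5);"
  ## gamma = 1: H always enters parent1 (A); frequencies follow the backbone
  net1 <- species_network(nwk, outgroup = "O",
                          hybrid = list(taxon = "H", parent1 = "A",
                                        parent2 = "B", gamma = 1))
  set.seed(403)
  cls <- replicate(4000, sample_gene_tree(net1, focal = c("H", "A", "B"))$class)
  p_ha <- mean(cls %in% c("type0", "type1"))
  expect_gt(p_ha, msc_topology_probs(1)[1, 1] - 3 * sqrt(0.25 / 4000) - 0.02)
  ## gamma = 0: H always derives from parent2 (B)
  net0 <- species_network(nwk, outgroup = "O",
                          hybrid = list(taxon = "H", parent1 = "A",
                                        parent2 = "B", gamma = 0))
  cls0 <- replicate(4000, sample_gene_tree(net0, focal = c("H", "B", "A"))$class)
  expect_gt(mean(cls0 %in% c("type0", "type1")), 0.70)
})

test_that("gene trees are ultrametric with the network leaf set", {
  net <- study_net()
  set.seed(404)
  for (i in 1:20) {
    g <- sample_gene_tree(net)
    expect_setequal(g$tree$tip.label, net$taxa)
    expect_true(ape::is.ultrametric(g$tree, tol = 1e-8))
  }
})

test_that("branch-length mixture generator obeys its contracts", {
  set.seed(405)
  x <- sample_triplet_branch_lengths(20000, 0, 0.7, 3)
  expect_lt(abs(mean(x) - 0.7), 3 * 0.7 / sqrt(20000))
  y <- sample_triplet_branch_lengths(500, 1, 1, 5)
  expect_gte(min(y), 5)
  expect_error(sample_triplet_branch_lengths(10, -0.1, 1, 0), "p_intro")
  expect_error(sample_triplet_branch_lengths(10, 0.5, 0, 0), "lambda")
  expect_error(sample_triplet_branch_lengths(10, 0.5, 1, -1), "C")
})

test_that("JC sequence evolution matches its closed-form divergence", {
  tr <- ape::read.tree(text = "(a:0.12,b:0.08);")
  set.seed(406)
  aln <- evolve_sequences(tr, 30000, theta = NA)
  p <- mean(aln[1, ] != aln[2, ])
  p_exp <- 0.75 * (1 - exp(-4 * 0.2 / 3))
  expect_lt(abs(p - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 30000))
  ## theta = 0: no substitutions at all
  g <- sample_gene_tree(triplet_net())
  a0 <- evolve_sequences(g$tree, 50, theta = 0)
  expect_true(all(a0 == matrix(a0[1, ], nrow(a0), ncol(a0), byrow = TRUE)))
})

test_that("sequence evolution is deterministic under a fixed seed", {
  net <- triplet_net()
  run <- function() {
    set.seed(77)
    gt <- sample_gene_tree(net)
    evolve_sequences(gt$tree, 500, theta = 0.05)
  }
  expect_identical(run(), run())
})

test_that("pattern probabilities agree with brute-force state enumeration", {
  set.seed(407)
  tr <- ape::read.tree(text = "(((A:0.07,B:0.11):0.05,C:0.2):0.08,O:0.3);")
  expect_equal(tree_pattern_probs(tr), brute_pattern_probs(tr), tolerance = 1e-12)
  ## random branch lengths: normalization property
  for (i in 1:5) {
    tr$edge.length <- stats::runif(nrow(tr$edge), 0, 0.5)
    p <- tree_pattern_probs(tr)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
  ## all branch lengths zero: only the four constant patterns, 1/4 each
  tr$edge.length[] <- 0
  p0 <- tree_pattern_probs(tr)
  const <- 1 + (0:3) * (1 + 4 + 16 + 64)
  expect_equal(p0[const], rep(0.25, 4))
  expect_equal(sum(p0[-const]), 0)
})

test_that("simulate_genome writes a consistent, reproducible bundle", {
  net <- study_net()
  gm <- random_gene_models(3, c(chr1 = 15000, chr2 = 15000), seed = 5)
  cfg <- sim_config(n_windows = 30, window_len = 1000, theta = 0.02, seed = 11,
                    n_chrom = 2, gene_models = gm)
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_genome(cfg, net, out_dir = d1)
  s2 <- simulate_genome(cfg, net, out_dir = d2)
  ## truth intervals partition each chromosome without overlap
  for (ch in unique(s1$truth$chrom)) {
    tt <- s1$truth[s1$truth$chrom == ch, ]
    tt <- tt[order(tt$start), ]
    expect_equal(tt$start, c(0, utils::head(tt$end, -1)))
  }
  ## no pulses: nothing introgressed
  expect_false(any(s1$truth$introgressed))
  ## per-window truth label equals the classifier applied to the stored tree
  fs <- list(F = "G2", S = "G1", G = "G3")
  map <- c(type0 = "Tree1", type1 = "Tree1", type2 = "Tree2", type3 = "Tree3")
  for (w in seq_len(nrow(s1$truth))) {
    got <- root_and_classify(s1$trees[[w]], "O",
                             list(F = "G2", S = "G1", G = "G3"))
    expect_identical(got, unname(map[s1$truth$class[w]]))
  }
  ## byte-identical outputs under the same seed
  for (f in c("truth.bed", "genes.gff3", "gene_trees.nwk",
              file.path("windows", "window_000001.fa"),
              file.path("windows", "window_000030.fa"))) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("an empty simulation still produces well-formed outputs", {
  net <- triplet_net()
  cfg <- sim_config(n_windows = 0, seed = 1)
  d <- tempfile()
  s <- simulate_genome(cfg, net, out_dir = d)
  expect_equal(nrow(s$truth), 0)
  expect_equal(nrow(read_bed(file.path(d, "truth.bed"))), 0)
  g <- read_gff3(file.path(d, "genes.gff3"))
  expect_equal(nrow(g), 0)
  expect_identical(readLines(file.path(d, "genes.gff3"))[1], "##gff-version 3")
  unlink(d, recursive = TRUE)
})

test_that("introgression pulses mark windows and respect gamma = 0", {
  pulses <- data.frame(time = 0.5, donor = "S", recipient = "F", gamma = 0)
  net <- study_net(pulses = pulses)
  cfg <- sim_config(n_windows = 15, window_len = 200, theta = 0.01, seed = 3)
  s <- simulate_genome(cfg, net)
  expect_false(any(s$truth$introgressed))
  pulses$gamma <- 0.9
  net2 <- study_net(pulses = pulses)
  s2 <- simulate_genome(sim_config(n_windows = 15, window_len = 200,
                                   theta = 0.01, seed = 3), net2)
  expect_true(any(s2$truth$introgressed))
  expect_true(all(s2$truth$origin[s2$truth$introgressed] == "S"))
})
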