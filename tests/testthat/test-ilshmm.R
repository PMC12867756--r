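hmm_fixture <- function(s = 1e-3, pi = c(0.5, 0.2, 0.15, 0.15)) {
  coalhmm_params(tau1 = 0.004, tau2 = 0.008, theta_anc = 0.005,
                 s = s, pi = pi)
}

test_that("parameter constructor enforces the state-symmetry invariant", {
  expect_error(coalhmm_params(0.004, 0.008, 0.005, s = 1e-3,
                              pi = c(0.5, 0.2, 0.2, 0.1)),
               "pi\\[type2\\]")
  p <- hmm_fixture()
  expect_equal(rowSums(p$transition), rep(1, 4), ignore_attr = TRUE)
  ## pi is the stationary vector of the transition matrix
  expect_equal(as.numeric(p$pi %*% p$transition), as.numeric(p$pi))
  ## each emission vector is a distribution over the 256 site patterns
  expect_equal(rowSums(p$emission), rep(1, 4), ignore_attr = TRUE)
})

test_that("state emissions agree with brute-force enumeration", {
  p <- hmm_fixture()
  for (k in 1:4) {
    expect_equal(as.numeric(p$emission[k, ]),
                 brute_pattern_probs(p$trees[[k]], tip_order = p$taxa),
                 tolerance = 1e-12)
  }
})

test_that("forward log-likelihood equals brute-force path enumeration", {
  p <- hmm_fixture(s = 0.02)
  set.seed(1001)
  for (L in c(4, 7)) {
    mos <- simulate_mosaic(p, L)
    idx <- pattern_index(mos$aln, p$taxa)
    fb <- forward_backward(idx, p)
    expect_equal(fb$loglik, brute_hmm_loglik(idx, p), tolerance = 1e-9)
    expect_equal(rowSums(fb$posterior), rep(1, L), tolerance = 1e-12)
  }
})

test_that("a nearly frozen chain decodes the generating state everywhere", {
  p <- hmm_fixture(s = 1e-9)
  set.seed(1002)
  ## force a pure type0 path by drawing from the type0 emission row only
  pat <- sample.int(256, 3000, replace = TRUE, prob = p$emission[1, ])
  fb <- forward_backward(pat, p)
  expect_gt(min(fb$posterior[, "type0"]), 0.99)
})

test_that("posterior decoding recovers most true ILS sites on self mosaics", {
  p <- hmm_fixture(s = 2e-3, pi = c(0.4, 0.2, 0.2, 0.2))
  mos <- simulate_mosaic(p, 60000, seed = 1003)
  fb <- forward_backward(mos$aln, p)
  calls <- call_ils_sites(fb$posterior)
  truly_ils <- mos$states %in% c(3, 4)
  expect_gt(sum(truly_ils), 5000)
  expect_gte(mean(calls[truly_ils]), 0.85)
})

test_that("mean called segment length decreases as the switch rate grows", {
  set.seed(1004)
  mean_lens <- vapply(c(1e-4, 1e-3, 1e-2), function(s) {
    p <- hmm_fixture(s = s, pi = c(0.4, 0.2, 0.2, 0.2))
    mos <- simulate_mosaic(p, 60000)
    fb <- forward_backward(mos$aln, p)
    seg <- merge_segments(call_ils_sites(fb$posterior))
    mean(seg$end - seg$start)
  }, 0)
  expect_true(all(diff(mean_lens) < 0))
})

test_that("Baum-Welch recovers switch rate and stationary mass within 20%", {
  ## coalescent times chosen so the four state genealogies are well separated
  truth <- coalhmm_params(0.002, 0.012, 0.008, s = 5e-3,
                          pi = c(0.4, 0.2, 0.2, 0.2))
  mos <- simulate_mosaic(truth, 200000, seed = 1005)
  init <- coalhmm_params(0.002, 0.012, 0.008, s = 2e-2,
                         pi = c(0.3, 0.3, 0.2, 0.2))
  fit <- fit_hmm_em(mos$aln, init, max_iter = 50, tol = 1e-4)
  expect_true(all(diff(fit$trace) > -1e-6))   # monotone EM
  expect_lt(abs(fit$params$s - 5e-3) / 5e-3, 0.2)
  expect_lt(abs(fit$params$pi[["type0"]] - 0.4) / 0.4, 0.2)
  expect_lt(abs(fit$params$pi[["type2"]] - 0.2) / 0.2, 0.2)
  ## the truth is a near-stationary point: initialising there moves almost
  ## nothing (log-likelihood gain of a few units at most, s essentially fixed)
  fit0 <- fit_hmm_em(pattern_index(mos$aln, truth$taxa), truth,
                     max_iter = 20, tol = 1e-4)
  expect_lt(fit0$trace[length(fit0$trace)] - fit0$trace[1], 20)
  expect_lt(abs(fit0$params$s - 5e-3) / 5e-3, 0.1)
})

test_that("degenerate alignments are rejected by the EM fitter", {
  init <- hmm_fixture()
  flat <- matrix("A", 4, 2000, dimnames = list(init$taxa, NULL))
  expect_error(fit_hmm_em(flat, init), "degenerate")
  expect_error(fit_hmm_em(matrix("A", 4, 10, dimnames = list(init$taxa, NULL)),
                          init), "1000")
})

test_that("ILS site calls apply the posterior threshold to type2+type3", {
  post <- rbind(c(0.1, 0.1, 0.5, 0.3),
                c(0.5, 0.5, 0.0, 0.0),
                c(0.2, 0.2, 0.3, 0.3))
  colnames(post) <- c("type0", "type1", "type2", "type3")
  expect_identical(call_ils_sites(post), c(TRUE, FALSE, TRUE))
  expect_identical(call_ils_sites(post, threshold = 1.0), rep(FALSE, 3))
})

test_that("segment merging fuses runs across small gaps", {
  calls <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  s0 <- merge_segments(calls, max_gap = 0)
  expect_equal(s0$start, c(0, 4)); expect_equal(s0$end, c(3, 6))
  s1 <- merge_segments(calls, max_gap = 1)
  expect_equal(s1$start, 0); expect_equal(s1$end, 6)
  expect_equal(nrow(merge_segments(rep(FALSE, 10))), 0)
  off <- merge_segments(calls, offset = 100)
  expect_equal(off$start, c(100, 104))
})

test_that("segment statistics reproduce hand-computed toy answers", {
  ils <- data.frame(start = c(0, 800), end = c(700, 1584))    # 700 and 784 bp
  non <- data.frame(start = c(2000, 4000), end = c(3500, 5500))
  st <- segment_stats(ils, non, genome_len = 10000)
  expect_equal(st$mean_len, 742)
  expect_equal(st$genome_fraction, 1484 / 10000)
  ## identical length samples: Welch p = 1
  eq <- segment_stats(data.frame(start = 0, end = 100),
                      data.frame(start = 50, end = 150), genome_len = 1000)
  expect_equal(eq$welch_p, 1)
  ## a 89 bp / 1000 bp genome gives the 8.9% fraction
  st89 <- segment_stats(data.frame(start = c(0, 40), end = c(39, 90)),
                        data.frame(start = c(100, 500), end = c(200, 600)),
                        genome_len = 1000)
  expect_equal(st89$genome_fraction, 0.089)
  ## coding fraction uses the CDS length as denominator
  cds <- data.frame(start = c(0, 2000), end = c(100, 2100))
  stc <- segment_stats(ils, non, genome_len = 10000, cds_intervals = cds)
  expect_equal(stc$coding_fraction, 100 / 200)
  expect_error(segment_stats(ils, non, genome_len = 0), "positive")
})

test_that("ILS segments are shorter than non-ILS segments on decoded mosaics", {
  p <- hmm_fixture(s = 2e-3, pi = c(0.55, 0.15, 0.15, 0.15))  # pi_type0 > 0.5
  mos <- simulate_mosaic(p, 60000, seed = 1006)
  fb <- forward_backward(mos$aln, p)
  calls <- call_ils_sites(fb$posterior)
  ils <- merge_segments(calls)
  non <- merge_segments(!calls)
  st <- segment_stats(ils, non, genome_len = length(calls))
  expect_lt(st$mean_len, st$mean_len_non_ils)
  expect_lt(st$welch_p, 0.05)
})

test_that("chromosome aggregation contrasts the X against autosomes", {
  segs <- data.frame(chrom = c("chr1", "chr2", "chr3", "chrX"),
                     start = 0, end = c(100, 110, 90, 100))
  lens <- c(chr1 = 1e4, chr2 = 1.1e4, chr3 = 0.9e4, chrX = 1e4)
  cls <- c(chr1 = "autosome", chr2 = "autosome", chr3 = "autosome",
           chrX = "X")
  r <- chrom_aggregation(segs, lens, cls)
  expect_equal(unname(r$ratio_x_autosome), 1)
  expect_gt(r$p, 0.5)
  ## doubled density on the X is detected in the ratio
  segs2 <- segs; segs2$end[4] <- 200
  r2 <- chrom_aggregation(segs2, lens, cls)
  expect_equal(unname(r2$ratio_x_autosome), 2)
  expect_error(chrom_aggregation(segs, lens, rep("autosome", 4)), "X")
  r0 <- chrom_aggregation(segs[0, ], lens, cls)
  expect_true(r0$degenerate)
})

test_that("suppressing discordant genealogies in CDS lowers the coding ILS share", {
  ## purifying-selection switch: CDS-overlapping windows are concordant
  net <- triplet_net(0.15)   # short internal branch: plenty of ILS elsewhere
  gm <- data.frame(gene = "g1", chrom = "chr1", strand = "+",
                   start = 0, end = 10000)
  cfg <- sim_config(n_windows = 60, window_len = 500, theta = 0.01, seed = 77,
                    gene_models = gm, suppress_ils_in_cds = TRUE)
  sim <- simulate_genome(cfg, net)
  in_cds <- sim$truth$start < 10000
  dis <- sim$truth$class %in% c("type2", "type3")
  expect_equal(sum(dis & in_cds), 0)
  expect_gt(sum(dis & !in_cds), 0)
})
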