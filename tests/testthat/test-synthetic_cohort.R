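test_that("toy genome generation is deterministic with uniform composition", {
  cfg <- sim_config(genome = c(chr1 = 1e6), seed = 7, n_peaks = 50)
  g1 <- generate_toy_genome(cfg)
  g2 <- generate_toy_genome(cfg)
  expect_identical(as.character(g1$seq), as.character(g2$seq))
  expect_equal(g1$sizes, c(chr1 = 1000000L))
  comp <- Biostrings::alphabetFrequency(g1$seq)[1, c("A", "C", "G", "T")]
  expect_true(all(abs(comp / 1e6 - 0.25) < 0.005))
  expect_error(generate_toy_genome(sim_config(genome = c(chr1 = 0))),
               "genome")
  ## bias 1 skips sequence unless forced
  cfg0 <- sim_config(seed = 7, end_motif_bias = 1)
  expect_null(generate_toy_genome(cfg0)$seq)
  expect_false(is.null(generate_toy_genome(cfg0, force_seq = TRUE)$seq))
})

test_that("peak catalogs have exact sharing, disjoint packing and planted subsets", {
  cfg <- sim_config(seed = 3)
  cat <- generate_peak_catalog(cfg)
  tumor <- cat$catalogs$tumor; immune <- cat$catalogs$immune
  expect_equal(length(tumor), 1000)
  expect_equal(length(immune), 1000)
  shared <- intersect(names(tumor), names(immune))
  expect_equal(length(shared), 200)     # shared_fraction 0.2, exact
  expect_true(all(startsWith(shared, "shared_")))
  ## all intervals pairwise disjoint, even across catalogs
  all_gr <- c(tumor, immune[setdiff(names(immune), shared)])
  expect_true(IRanges::isDisjoint(all_gr))
  ## 1 kb extensions stay disjoint by construction
  expect_true(IRanges::isDisjoint(extend_intervals(all_gr, 1000)))
  ## planted subset lies inside the immune catalog, outside the shared part
  expect_true(all(cat$planted$region_id %in% names(immune)))
  expect_false(any(cat$planted$region_id %in% shared))
  expect_equal(nrow(cat$planted), 100)
  expect_equal(sum(cat$planted$direction == "increased"), 50)
  ## zero sharing gives disjoint catalogs
  cat0 <- generate_peak_catalog(sim_config(seed = 3, shared_fraction = 0))
  expect_length(intersect(names(cat0$catalogs$tumor),
                          names(cat0$catalogs$immune)), 0)
  ## infeasible packing errors
  expect_error(generate_peak_catalog(
    sim_config(genome = c(chr1 = 1e5), n_peaks = 1000)), "packing")
})

test_that("fragment length model reproduces mode, components and comb period", {
  set.seed(1)
  lm <- sim_config()$length_model
  lens <- sample_fragment_lengths(2e5, lm)
  d <- length_distribution(lens)
  expect_equal(d$mode, 167)
  expect_true(all(lens >= 50))
  ## no sub-nucleosomal component -> essentially no mass in 80-140
  lm0 <- utils::modifyList(lm, list(w_sub = 0))
  lens0 <- sample_fragment_lengths(1e5, lm0)
  expect_lt(mean(lens0 >= 80 & lens0 <= 140), 0.005)
  ## configured comb period is recovered by the periodicity estimator
  for (p in c(9.0, 10.0, 11.5)) {
    lensp <- sample_fragment_lengths(
      5e5, utils::modifyList(lm, list(comb_period = p)))
    est <- subnucleosomal_period(length_distribution(lensp))
    expect_true(est$periodic)
    expect_lt(abs(est$period - p), 0.3)
  }
})

test_that("fragment placement concentrates at peaks only when p_open > 0", {
  g <- c(chr1 = 2e6)
  peaks <- region_set("chr1", seq(1e5, 1.9e6, by = 2e5),
                      seq(1e5, 1.9e6, by = 2e5) + 300, genome = g)
  em <- sim_config()$enrichment_model
  set.seed(2)
  ## p_open = 0: midpoints uniform (chi-square GOF over 20 equal bins)
  fr0 <- place_fragments(rep(167L, 2e4), peaks, rep(1, length(peaks)),
                         utils::modifyList(em, list(p_open = 0)), g)
  mids <- (fr0$start + fr0$end) %/% 2
  gof <- chisq.test(table(cut(mids, seq(0, 2e6, length.out = 21))))
  expect_gt(gof$p.value, 0.01)
  ## p_open = 1: midpoints inside peak +/- 500 bp
  fr1 <- place_fragments(rep(167L, 2e4), peaks, rep(1, length(peaks)),
                         utils::modifyList(em, list(p_open = 1)), g)
  mids1 <- (fr1$start + fr1$end) %/% 2
  centers <- (GenomicRanges::start(peaks) - 1 + GenomicRanges::end(peaks)) %/% 2
  near <- sapply(mids1, function(m) min(abs(m - centers)) <= 650)
  expect_gt(mean(near), 0.99)
})

test_that("metaplot of simulated fragments peaks at the open-chromatin centers", {
  coh <- default_cohort()
  fr <- coh$samples$healthy_01
  tr <- coverage_track(fr, coh$genome, target_depth = 1e7)
  prof <- metaplot(tr, coh$truth$catalogs$immune, flank = 1000)
  mid <- which(prof$offset == 0)
  edge <- mean(prof$value[c(1:50, length(prof$value) - 0:49)])
  expect_gt(prof$value[mid], 2 * edge)   # clear central enrichment
  ## local maximum at offset 0 relative to +/- 400-600 bp troughs
  trough <- mean(prof$value[abs(abs(prof$offset) - 500) <= 50])
  expect_gt(prof$value[mid], trough)
})

test_that("5' end bias enriches CC dinucleotides and respects strand", {
  cfg <- sim_config(genome = c(chr1 = 2e5), seed = 5, n_peaks = 20)
  toy <- generate_toy_genome(cfg, force_seq = TRUE)
  set.seed(9)
  fr <- make_fragments("chr1", sample(100:150000, 2e4, replace = TRUE), 0,
                       strand = sample(c("+", "-"), 2e4, replace = TRUE))
  fr$end <- fr$start + 167L
  ## bias 1 is a no-op
  expect_equal(apply_end_bias(data.table::copy(fr), toy$seq, 1), fr)
  ## bias 5 lifts the aggregate CCNN frequency above the uniform 1/16
  set.seed(10)
  frb <- apply_end_bias(data.table::copy(fr), toy$seq, 5)
  prof <- end_motif_frequencies(frb, toy$seq)
  expect_gt(prof$class_freq[["CCNN"]], 1 / 16 + 0.02)
  ## minus-strand 5' motif is read reverse-complemented from the end
  seq <- c(chr1 = "AAAACCGGTTTTAAAACCGGTTTT")
  fr_minus <- make_fragments("chr1", 2L, 8L, strand = "-")
  pr <- end_motif_frequencies(fr_minus, seq, k = 4)
  ## forward [4,8) = "CCGG"; reverse complement = "CCGG"
  expect_equal(unname(pr$freq["CCGG"]), 1)
})

test_that("cohort simulation is deterministic with exact counts and tumor mixing", {
  cfg <- sim_config(genome = c(chr1 = 2e6, chr2 = 2e6), n_peaks = 100,
                    n_diff = 10, n_healthy = 2, n_cancer = 2,
                    fragments_per_sample = 2e4, seed = 11)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$samples, c2$samples)
  expect_identical(c1$truth$samples, c2$truth$samples)
  expect_true(all(sapply(c1$samples, nrow) == 2e4))
  expect_equal(c1$truth$samples$label, c(rep("healthy", 2), rep("cancer", 2)))
  tf <- c1$truth$samples$tumor_fraction
  expect_true(all(tf[1:2] == 0) && all(tf[3:4] >= 0.01 & tf[3:4] <= 0.03))
  ## written outputs are byte-identical too
  d1 <- tempfile(); d2 <- tempfile()
  simulate_cohort(cfg, outdir = d1); simulate_cohort(cfg, outdir = d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  ## fixed tumor fraction: realized tumor-source fraction within binomial bounds
  cfg_tf <- sim_config(genome = c(chr1 = 2e6, chr2 = 2e6), n_peaks = 100,
                       n_diff = 10, n_healthy = 0, n_cancer = 1,
                       fragments_per_sample = 1e5,
                       tumor_fraction_range = c(0.02, 0.02), seed = 12,
                       end_motif_bias = 1)
  ctf <- simulate_cohort(cfg_tf)
  frac <- ctf$truth$samples$n_tumor_fragments / 1e5
  expect_lt(abs(frac - 0.02), 0.0015)
})
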