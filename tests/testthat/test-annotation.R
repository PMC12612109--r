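test_that("gene models validate strand consistency and interval blocks", {
  expect_error(gene_model("g", "c", "+", 100L, 50L), "inconsistent")
  expect_error(gene_model("g", "c", "-", 50L, 100L), "inconsistent")
  expect_error(gene_model("g", "c", "+", 100L, 500L, exons = "600-700"),
               "outside")
  gm <- toy_genes()
  expect_equal(nrow(gm), 3)
  tmp <- tempfile()
  data.table::fwrite(data.table::data.table(
    gene_id = "gX", chrom = "chr1", strand = "+", tss = 100L, tes = 900L,
    exons = "100-200,800-900", cds = "150-200", utr5 = "100-150",
    utr3 = "800-900"), tmp, sep = "\t")
  gm2 <- read_gene_model(tmp)
  expect_equal(gm2$exons[[1]][2, ], c(800L, 900L))
})

test_that("element classification follows the documented windows", {
  gm <- toy_genes()
  g <- c(chrA = 100000L, chrB = 60000L)
  reg <- region_set(
    c("chrA", "chrA", "chrA", "chrA", "chrA", "chrA"),
    c(20050L, 18450L, 80000L, 24100L, 25500L, 30500L),
    c(20150L, 18550L, 80100L, 24200L, 25600L, 30600L),
    genome = g,
    id = c("at_tss", "up15", "desert", "in_cds", "intronic", "downstream"))
  calls <- classify_regions(reg, gm)
  expect_equal(calls$category,
               c("promoter", "promoter", "distal intergenic", "gene body",
                 "gene body", "downstream"))
  expect_equal(calls$subcategory[1], "TSS +/- 500 bp")     # midpoint TSS+100
  expect_equal(calls$subcategory[2], "Upstream 1-2 kb")    # midpoint TSS-1500
  expect_equal(calls$subcategory[4], "CDS")
  expect_equal(calls$subcategory[5], "intron")
  expect_equal(calls$gene_id[1], "g1")
  ## every region receives exactly one top-level category
  expect_false(anyNA(calls$category))
})

test_that("classification matches the brute-force oracle on randomized regions", {
  set.seed(61)
  n <- 40
  strand <- sample(c("+", "-"), n, replace = TRUE)
  ## random gene spans 3-15 kb, strand-consistent
  lo <- sample(5000:80000, n)
  span <- sample(3000:15000, n)
  blocks <- function(i, which) {
    a <- with_seed_local(1000 + i, lo[i] + sort(sample(100:(span[i] - 100), 6)))
    switch(which,
           exons = sprintf("%d-%d,%d-%d,%d-%d", a[1], a[2], a[3], a[4],
                           a[5], a[6]),
           cds = sprintf("%d-%d", a[3], a[4]),
           utr5 = sprintf("%d-%d", a[1], a[2]),
           utr3 = sprintf("%d-%d", a[5], a[6]))
  }
  gm <- gene_model(
    gene_id = sprintf("g%02d", 1:n),
    chrom = sample(c("chrA", "chrB"), n, replace = TRUE),
    strand = strand,
    tss = ifelse(strand == "+", lo, lo + span),
    tes = ifelse(strand == "+", lo + span, lo),
    exons = vapply(1:n, blocks, "", which = "exons"),
    cds = vapply(1:n, blocks, "", which = "cds"),
    utr5 = vapply(1:n, blocks, "", which = "utr5"),
    utr3 = vapply(1:n, blocks, "", which = "utr3"))
  g <- c(chrA = 100000L, chrB = 100000L)
  starts <- sample(0:99000, 1000, replace = TRUE)
  widths <- sample(50:800, 1000, replace = TRUE)
  reg <- region_set(sample(c("chrA", "chrB"), 1000, replace = TRUE),
                    starts, pmin(starts + widths, 100000L), genome = g)
  calls <- classify_regions(reg, gm)
  chrom <- as.character(GenomicRanges::seqnames(reg))
  s0 <- GenomicRanges::start(reg) - 1L
  e0 <- GenomicRanges::end(reg)
  gm_chrom <- gm$chrom
  for (i in seq_along(reg)) {
    sel <- gm_chrom == chrom[i]
    ora <- oracle_classify(s0[i], e0[i], gm[sel, ])
    expect_identical(calls$category[i], ora$category)
    expect_identical(calls$subcategory[i],
                     if (is.null(ora$subcategory)) NA_character_
                     else as.character(ora$subcategory))
    expect_identical(calls$gene_id[i], as.character(ora$gene))
  }
  ## element distribution equals direct tabulation
  dist <- element_distribution(calls)
  top <- dist[dist$level == "category", ]
  expect_equal(sum(top$pct_all), 100, tolerance = 1e-9)
  expect_equal(stats::setNames(top$n, top$category)[names(table(calls$category))],
               stats::setNames(as.integer(table(calls$category)),
                               names(table(calls$category))))
  expect_equal(nrow(element_distribution(calls[0, ])), 0)
})

test_that("mirroring the genome leaves classifications invariant", {
  L <- 100000L
  gm_all <- toy_genes()
  gm <- gm_all[gm_all$chrom == "chrA", ]
  mirror_blocks <- function(m) {
    if (nrow(m) == 0) return("")
    out <- cbind(L - m[, 2], L - m[, 1])
    out <- out[order(out[, 1]), , drop = FALSE]
    paste(sprintf("%d-%d", out[, 1], out[, 2]), collapse = ",")
  }
  gmm <- gene_model(
    gene_id = gm$gene_id, chrom = gm$chrom,
    strand = ifelse(gm$strand == "+", "-", "+"),
    tss = L - 1L - gm$tss, tes = L - 1L - gm$tes,
    exons = vapply(gm$exons, mirror_blocks, ""),
    cds = vapply(gm$cds, mirror_blocks, ""),
    utr5 = vapply(gm$utr5, mirror_blocks, ""),
    utr3 = vapply(gm$utr3, mirror_blocks, ""))
  set.seed(62)
  s0 <- sample(0:99000, 300, replace = TRUE)
  w <- 2 * sample(25:400, 300, replace = TRUE) + 1  # odd widths mirror exactly
  e0 <- pmin(s0 + w, L)
  g <- c(chrA = L)
  reg <- region_set("chrA", s0, e0, genome = g)
  reg_m <- region_set("chrA", L - e0, L - s0, genome = g)
  calls <- classify_regions(reg, gm)
  calls_m <- classify_regions(reg_m, gmm)
  expect_equal(calls_m$category, calls$category)
  expect_equal(calls_m$subcategory, calls$subcategory)
  expect_equal(calls_m$gene_id, calls$gene_id)
})

test_that("nearest gene respects the distance cutoff and tie rule", {
  gm <- gene_model(c("a2", "a1", "b1"), c("chrA", "chrA", "chrA"),
                   c("+", "+", "+"), c(10000L, 30000L, 500000L),
                   c(15000L, 35000L, 505000L))
  g <- c(chrA = 1000000L)
  reg <- region_set("chrA", c(19950L, 250000L, 450000L),
                    c(20050L, 250100L, 450100L), genome = g,
                    id = c("tie", "far", "within"))
  ng <- nearest_gene(reg, gm, max_dist = 1e5)
  ## midpoint 20000 is 10000 from both TSS: lexicographically smaller id wins
  expect_equal(ng$gene_id[1], "a1")
  ## nearest TSS over 200 kb away exceeds the cutoff
  expect_true(is.na(ng$gene_id[2]))
  ## ~50 kb away is assigned
  expect_equal(ng$gene_id[3], "b1")
  expect_equal(ng$distance[3], 500000L - 450050L)
})

test_that("TSS distance histogram is strand-aware and conserves mass", {
  gm <- gene_model(c("p", "m"), c("chrA", "chrA"), c("+", "-"),
                   c(10000L, 50000L), c(20000L, 40000L))
  g <- c(chrA = 100000L)
  reg <- region_set("chrA", c(9990L, 48990L, 95000L),
                    c(10010L, 49010L, 95100L), genome = g,
                    id = c("at_p", "down_m", "far"))
  h <- tss_distance_histogram(reg, gm, breaks = seq(-1e5, 1e5, 1e4),
                              max_dist = 2e4)
  ## region at the + TSS: distance 0; 1 kb downstream of the - TSS: +1000
  expect_equal(sort(h$distances), c(0L, 1000L))
  expect_equal(h$n_assigned, 2)
  expect_equal(h$n_unassigned, 1)
  expect_equal(sum(h$counts), h$n_assigned)
})
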