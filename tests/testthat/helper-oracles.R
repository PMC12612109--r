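## Independent brute-force oracles and shared fixtures for the test suite.
## Oracles are written as plain, direct arithmetic so they stay independent
## of the implementation paths they check.

## per-base pileup by explicit looping over fragments
oracle_pileup <- function(frags, genome, target_depth) {
  cov <- lapply(genome, function(L) numeric(L))
  for (i in seq_len(nrow(frags))) {
    ch <- frags$chrom[i]
    idx <- (frags$start[i] + 1):frags$end[i]
    cov[[ch]][idx] <- cov[[ch]][idx] + 1
  }
  lapply(cov, function(v) v * target_depth / nrow(frags))
}

## step-by-step TMM: sorted-trim sets, delta-method weights, geomean rescale
oracle_tmm <- function(y, N) {
  p75 <- sapply(seq_len(ncol(y)), function(s) quantile(y[, s], 0.75) / N[s])
  ref <- which.min(abs(p75 - mean(p75)))
  f <- numeric(ncol(y))
  for (s in seq_len(ncol(y))) {
    keep0 <- y[, s] > 0 & y[, ref] > 0
    o <- y[keep0, s]; r <- y[keep0, ref]
    M <- log2((o / N[s]) / (r / N[ref]))
    A <- 0.5 * log2((o / N[s]) * (r / N[ref]))
    w <- 1 / ((N[s] - o) / (N[s] * o) + (N[ref] - r) / (N[ref] * r))
    if (max(abs(M)) < 1e-6) { f[s] <- 1; next }
    n <- length(M)
    lo <- floor(n * 0.3) + 1; hi <- n + 1 - lo
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    inM <- rank(M) >= lo & rank(M) <= hi
    inA <- rank(A) >= loA & rank(A) <= hiA
    sel <- inM & inA
    f[s] <- 2^(sum(M[sel] * w[sel]) / sum(w[sel]))
  }
  f / exp(mean(log(f)))
}

## direct binomial two-sided split test (phi = 0 limit)
oracle_binom_split <- function(sA, t, nA, nB) {
  if (t == 0) return(1)
  pA <- nA / (nA + nB)
  lo <- pbinom(sA, t, pA)
  hi <- 1 - pbinom(sA - 1, t, pA)
  min(1, 2 * min(lo, hi))
}

## hand Benjamini-Hochberg
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  adj[o] <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[o[i]] <- min(adj[o[i]], adj[o[i + 1]])
  pmin(adj, 1)
}

## top-k RMS leading-logFC distance matrix from a logCPM matrix
oracle_mds_dist <- function(L, top_k) {
  ns <- ncol(L)
  D <- matrix(0, ns, ns)
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    d <- abs(L[, i] - L[, j])
    d <- d[order(d, decreasing = TRUE)][seq_len(min(top_k, length(d)))]
    D[i, j] <- sqrt(mean(d^2))
  }
  D
}

## direct re-derivation of the element classification conventions
oracle_classify <- function(s0, e0, genes) {
  mid <- (s0 + e0) %/% 2
  hit <- function(w1, w2) s0 <= w2 && (e0 - 1) >= w1
  cand <- data.frame(gene = character(), cat = character(),
                     stringsAsFactors = FALSE)
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    if (g$strand == "+") {
      prom <- c(g$tss - 2000, g$tss + 500); down <- c(g$tes + 1, g$tes + 2000)
    } else {
      prom <- c(g$tss - 500, g$tss + 2000); down <- c(g$tes - 2000, g$tes - 1)
    }
    body <- c(min(g$tss, g$tes), max(g$tss, g$tes))
    cat <- if (hit(prom[1], prom[2])) "promoter"
      else if (hit(down[1], down[2])) "downstream"
      else if (hit(body[1], body[2])) "gene body"
      else NA
    if (!is.na(cat))
      cand <- rbind(cand, data.frame(gene = g$gene_id, cat = cat))
  }
  if (nrow(cand) == 0)
    return(list(category = "distal intergenic", subcategory = NA, gene = NA))
  for (level in c("promoter", "downstream", "gene body")) {
    sub <- cand[cand$cat == level, ]
    if (nrow(sub) == 0) next
    dd <- abs(mid - genes$tss[match(sub$gene, genes$gene_id)])
    g <- genes[genes$gene_id == sub$gene[order(dd, sub$gene)[1]], ]
    subcat <- NA
    if (level == "promoter") {
      d <- if (g$strand == "+") mid - g$tss else g$tss - mid
      subcat <- if ((s0 <= g$tss && g$tss < e0) || d >= 0) "TSS +/- 500 bp"
        else if (d > -500) "Upstream < 500 bp"
        else if (d > -1000) "Upstream 0.5-1 kb"
        else "Upstream 1-2 kb"
    } else if (level == "gene body") {
      anyhit <- function(m) nrow(m) > 0 &&
        any(s0 <= m[, 2] - 1 & e0 - 1 >= m[, 1])
      subcat <- if (anyhit(g$utr5[[1]])) "5' UTR"
        else if (anyhit(g$utr3[[1]])) "3' UTR"
        else if (anyhit(g$cds[[1]])) "CDS"
        else if (anyhit(g$exons[[1]])) "other exon"
        else "intron"
    }
    return(list(category = level, subcategory = subcat, gene = g$gene_id))
  }
}

## small reusable fixtures -------------------------------------------------

toy_genome <- c(chrA = 100000L, chrB = 60000L)

toy_genes <- function() {
  gene_model(
    gene_id = c("g1", "g2", "g3"),
    chrom = c("chrA", "chrA", "chrB"),
    strand = c("+", "-", "+"),
    tss = c(20000L, 60000L, 10000L),
    tes = c(30000L, 50000L, 15000L),
    exons = c("20000-20500,24000-24800,29000-30000",
              "50000-50900,55000-55500,59000-60000",
              "10000-11000,14000-15000"),
    cds = c("24000-24800,29000-29500", "55000-55500", "14000-14500"),
    utr5 = c("20000-20500", "59000-60000", "10000-11000"),
    utr3 = c("29500-30000", "50000-50900", ""))
}

## cached cohorts shared across test files (built once per test run)
.cohort_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.cohort_cache$default))
    .cohort_cache$default <- simulate_cohort(sim_config(seed = 1))
  .cohort_cache$default
}

classification_cohort <- function() {
  if (is.null(.cohort_cache$cls))
    .cohort_cache$cls <- simulate_cohort(sim_config_classification(seed = 1))
  .cohort_cache$cls
}

sample_labels <- function(cohort) {
  stats::setNames(cohort$truth$samples$label, cohort$truth$samples$sample)
}

## combined-catalog (10 kb expanded) feature matrix of the classification
## cohort, built once and shared between files
m4_features <- function() {
  if (is.null(.cohort_cache$fm_m4)) {
    coh <- classification_cohort()
    comb <- merge_region_sets(list(coh$truth$catalogs$tumor,
                                   coh$truth$catalogs$immune))
    .cohort_cache$fm_m4 <- build_feature_matrix(
      coh$samples, extend_intervals(comb, 1e4), coh$genome,
      labels = sample_labels(coh))
  }
  .cohort_cache$fm_m4
}

## evaluate under a temporary seed without disturbing the ambient RNG state
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

## small deterministic fragment table
make_fragments <- function(chrom, start, end, mapq = 60L, strand = "+") {
  data.table::data.table(chrom = chrom, start = as.integer(start),
                         end = as.integer(end),
                         mapq = as.integer(rep_len(mapq, length(chrom))),
                         strand = rep_len(strand, length(chrom)))
}
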