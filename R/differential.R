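#' TMM normalization factors
#'
#' Trimmed mean of M-values scaling factors for a fragment count matrix.
#' For each sample against the reference, M (log2 ratio of proportions)
#' and A (mean log2 abundance) are computed over regions with positive
#' counts in both; the top and bottom 30% by M and 5% by A are discarded;
#' the factor is 2 to the precision-weighted mean of the surviving M
#' values, with weights from the asymptotic binomial (delta-method)
#' variance. Factors are rescaled to geometric mean 1. The automatic
#' reference is the sample whose upper-quartile count proportion is
#' closest to the mean upper-quartile proportion.
#'
#' @param m A `count_matrix` ([count_fragments_in_regions()]) or a plain
#'   integer matrix (then `lib_sizes` must be supplied).
#' @param ref Reference sample id, or `NULL` for automatic selection.
#' @param lib_sizes Named library sizes when `m` is a plain matrix;
#'   defaults to column sums.
#' @param trim_m,trim_a Two-sided trim fractions for M and A.
#' @return A `norm_factors`: list with `factors` (named, geometric mean
#'   1), `effective_lib` (library size x factor), `ref`.
#' @export
tmm_factors <- function(m, ref = NULL, lib_sizes = NULL,
                        trim_m = 0.3, trim_a = 0.05) {
  if (inherits(m, "count_matrix")) {
    y <- m$counts; N <- m$lib_sizes
  } else {
    y <- as.matrix(m)
    N <- if (is.null(lib_sizes)) colSums(y) else lib_sizes[colnames(y)]
  }
  if (ncol(y) < 2) stop("TMM needs at least two samples")
  if (is.null(colnames(y))) colnames(y) <- paste0("s", seq_len(ncol(y)))
  if (is.null(names(N))) names(N) <- colnames(y)
  if (is.null(ref)) {
    f75 <- apply(y, 2, function(col) stats::quantile(col, 0.75)) / N
    ref <- colnames(y)[which.min(abs(f75 - mean(f75)))]
  }
  stopifnot(ref %in% colnames(y))
  yr <- y[, ref]; nR <- N[[ref]]
  one_factor <- function(obs, nO) {
    pos <- obs > 0 & yr > 0
    if (!any(pos)) stop("no regions with positive counts in both sample and reference")
    o <- obs[pos]; r <- yr[pos]
    M <- log2((o / nO) / (r / nR))
    A <- (log2(o / nO) + log2(r / nR)) / 2
    v <- (nO - o) / (nO * o) + (nR - r) / (nR * r)
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    f <- 2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
    if (!is.finite(f)) 1 else f
  }
  f <- vapply(colnames(y), function(s) one_factor(y[, s], N[[s]]), numeric(1))
  f <- f / exp(mean(log(f)))
  structure(list(factors = f, effective_lib = N[colnames(y)] * f, ref = ref,
                 trim_m = trim_m, trim_a = trim_a),
            class = "norm_factors")
}

#' Pooled method-of-moments common dispersion
#'
#' Common negative-binomial dispersion for the exact test, estimated by
#' moments: counts are scaled to a common effective library size, and for
#' every (region, group) pair with at least two samples the statistic
#' `(s^2 - mu) / mu^2` is computed from the group mean and variance. The
#' common dispersion is the median over all such pairs, floored at 0.
#' Simple, fully specified, and adequate for a shared-dispersion exact
#' test; it is a pluggable component.
#'
#' @param m A `count_matrix` or counts matrix.
#' @param groups Factor/character of group labels per sample (>= 2
#'   samples in at least one group).
#' @param factors A `norm_factors` from [tmm_factors()]; identity factors
#'   when `NULL`.
#' @return A `dispersion_estimate`: list with `dispersion` (phi >= 0) and
#'   `method`.
#' @export
estimate_common_dispersion <- function(m, groups, factors = NULL) {
  y <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  N <- if (inherits(m, "count_matrix")) m$lib_sizes else colSums(y)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(y))
  eff <- if (is.null(factors)) N else factors$effective_lib
  common <- exp(mean(log(eff)))
  z <- sweep(y, 2, common / eff, "*")
  vals <- c()
  for (g in unique(groups)) {
    cols <- groups == g
    if (sum(cols) < 2) next
    mu <- rowMeans(z[, cols, drop = FALSE])
    s2 <- apply(z[, cols, drop = FALSE], 1, stats::var)
    ok <- mu > 0
    vals <- c(vals, pmax(0, (s2[ok] - mu[ok]) / mu[ok]^2))
  }
  if (!length(vals)) stop("dispersion estimation needs a group with >= 2 samples")
  structure(list(dispersion = max(0, stats::median(vals)),
                 method = "pooled_mom"),
            class = "dispersion_estimate")
}

## conditional two-sided exact p for a group-sum split under shared NB
exact_split_p <- function(sA, t, nA, nB, phi) {
  if (t == 0) return(1)
  s <- 0:t
  if (phi < 1e-12) {
    pr <- stats::dbinom(s, t, nA / (nA + nB))
  } else {
    mu <- t / (nA + nB)
    pr <- stats::dnbinom(s, size = nA / phi, mu = nA * mu) *
      stats::dnbinom(t - s, size = nB / phi, mu = nB * mu)
    tot <- sum(pr)
    if (tot == 0) return(1)
    pr <- pr / tot
  }
  lo <- sum(pr[s <= sA])
  hi <- sum(pr[s >= sA])
  min(1, 2 * min(lo, hi))
}

#' Negative-binomial exact test for differential enrichment
#'
#' Two-group exact test on fragment counts at regions, the test behind
#' "differentially enriched loci at p < 0.05". Counts are scaled to a
#' common effective library size (geometric mean of the TMM-effective
#' sizes, rounded half-to-even for platform stability). Under the null the
#' group-A sum given the total follows the convolution of negative
#' binomials with shared mean and dispersion `phi`; the two-sided p-value
#' doubles the smaller tail (ties included), capped at 1. At `phi = 0`
#' this reduces to an exact binomial split test.
#'
#' @param m A `count_matrix`.
#' @param groups Group labels per sample (character/factor, two levels).
#' @param group_a Label of the test group (numerator of the fold change,
#'   e.g. `"cancer"`); the other label is the reference.
#' @param factors A `norm_factors`; identity when `NULL`.
#' @param dispersion A `dispersion_estimate`, or a number (phi >= 0).
#' @return A `differential_result` data.frame: `region`, `logFC` (log2,
#'   pseudocount 0.5, group A vs rest), `logCPM`, `pvalue`; regions
#'   carried in attribute `regions`.
#' @export
nb_exact_test <- function(m, groups, group_a, factors = NULL,
                          dispersion = 0) {
  y <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  N <- if (inherits(m, "count_matrix")) m$lib_sizes else colSums(y)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(y), group_a %in% groups)
  phi <- if (inherits(dispersion, "dispersion_estimate"))
    dispersion$dispersion else as.numeric(dispersion)
  stopifnot(phi >= 0)
  a <- groups == group_a
  b <- !a
  if (!any(a) || !any(b)) stop("both groups must be non-empty")
  if (is.null(rownames(y))) rownames(y) <- paste0("region_", seq_len(nrow(y)))
  eff <- if (is.null(factors)) N else factors$effective_lib
  common <- exp(mean(log(eff)))
  z <- round(sweep(y, 2, common / eff, "*"))  # round half to even
  nA <- sum(a); nB <- sum(b)
  sA <- rowSums(z[, a, drop = FALSE])
  tot <- sA + rowSums(z[, b, drop = FALSE])
  p <- vapply(seq_len(nrow(z)), function(i)
    exact_split_p(sA[i], tot[i], nA, nB, phi), numeric(1))
  logFC <- log2((rowMeans(z[, a, drop = FALSE]) + 0.5) /
                  (rowMeans(z[, b, drop = FALSE]) + 0.5))
  logCPM <- rowMeans(log2(1e6 * sweep(y + 0.5, 2, eff + 1, "/")))
  res <- data.frame(region = rownames(y), logFC = logFC, logCPM = logCPM,
                    pvalue = p, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(res) <- c("differential_result", "data.frame")
  attr(res, "regions") <- if (inherits(m, "count_matrix")) m$regions else NULL
  attr(res, "group_a") <- group_a
  res
}

#' Call differential regions
#'
#' Benjamini-Hochberg adjustment over all tested regions, then direction
#' calls at the chosen threshold: `increased` when (p or FDR) < alpha and
#' logFC > 0, `decreased` when < alpha and logFC < 0, otherwise `ns`
#' (strict inequalities; logFC exactly 0 is never called).
#'
#' @param results A `differential_result` from [nb_exact_test()].
#' @param alpha Significance threshold.
#' @param use_fdr Threshold the BH-adjusted FDR instead of the raw p.
#' @return List with `table` (results plus `fdr` and `direction`
#'   columns), and `increased` / `decreased` (region-id vectors; `GRanges`
#'   subsets when the result carries regions).
#' @export
call_differential <- function(results, alpha = 0.05, use_fdr = FALSE) {
  stopifnot(inherits(results, "differential_result"))
  tab <- as.data.frame(results)
  tab$fdr <- stats::p.adjust(tab$pvalue, method = "BH")
  crit <- if (use_fdr) tab$fdr else tab$pvalue
  tab$direction <- ifelse(crit < alpha & tab$logFC > 0, "increased",
                          ifelse(crit < alpha & tab$logFC < 0, "decreased",
                                 "ns"))
  regions <- attr(results, "regions")
  pick <- function(dir) {
    ids <- tab$region[tab$direction == dir]
    if (!is.null(regions)) regions[ids] else ids
  }
  list(table = tab, increased = pick("increased"), decreased = pick("decreased"))
}

#' Leading-logFC multidimensional scaling
#'
#' Pairwise sample distances as the root-mean-square of the `top_k`
#' largest absolute log2 differences in logCPM (pseudocount 0.5, effective
#' library sizes), followed by classical (Torgerson) metric scaling. This
#' is the standard "leading logFC" MDS view of a count matrix.
#'
#' @param m A `count_matrix`.
#' @param factors A `norm_factors`; identity when `NULL`.
#' @param top_k Number of top regions per pair (default 500; capped at
#'   the region count with a note).
#' @return List with `coords` (samples x 2), `eig_shares` (variance share
#'   of the two axes), `dist` (full distance matrix).
#' @export
mds_coordinates <- function(m, factors = NULL, top_k = 500) {
  y <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  N <- if (inherits(m, "count_matrix")) m$lib_sizes else colSums(y)
  if (ncol(y) < 3) stop("MDS needs at least three samples")
  eff <- if (is.null(factors)) N else factors$effective_lib
  if (top_k > nrow(y)) {
    message("top_k exceeds region count; using all ", nrow(y), " regions")
    top_k <- nrow(y)
  }
  L <- log2(1e6 * sweep(y + 0.5, 2, eff + 1, "/"))
  ns <- ncol(y)
  D <- matrix(0, ns, ns, dimnames = list(colnames(y), colnames(y)))
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    d <- sort(abs(L[, i] - L[, j]), decreasing = TRUE)[seq_len(top_k)]
    D[i, j] <- D[j, i] <- sqrt(mean(d^2))
  }
  sc <- stats::cmdscale(D, k = 2, eig = TRUE)
  eig_pos <- sc$eig[sc$eig > 0]
  list(coords = sc$points, eig_shares = sc$eig[1:2] / sum(eig_pos), dist = D)
}
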