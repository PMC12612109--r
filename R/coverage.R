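#' Depth-normalized fragment coverage track
#'
#' Computes per-base fragment coverage (each fragment contributes 1 to every
#' base it spans) and rescales it so totals correspond to a fixed fragment
#' depth: all values are multiplied by `target_depth / n_fragments`. The
#' conventional target of ten million fragments makes tracks from libraries
#' of different depths directly comparable.
#'
#' @param fragments Fragment data.frame ([read_fragments()]).
#' @param genome Named vector of chromosome lengths (bp).
#' @param resolution Bp per track element. 1 keeps per-base values; larger
#'   values average per-base coverage over consecutive windows.
#' @param target_depth Fragment depth the track is scaled to (default 1e7).
#' @return A `coverage_track`: list with `cov` (numeric `RleList`, one run
#'   per chromosome at `resolution` bp/element), `resolution`,
#'   `scale_factor`, `n_fragments`, `genome`, `target_depth`.
#' @details Zero input fragments is an error: the scale factor would be
#'   undefined.
#' @seealso [write_bedgraph()], [metaplot()]
#' @export
coverage_track <- function(fragments, genome, resolution = 1,
                           target_depth = 1e7) {
  stopifnot(target_depth > 0, resolution >= 1)
  n <- nrow(fragments)
  if (n == 0) stop("cannot build a coverage track from zero fragments")
  gr <- fragments_to_granges(fragments, genome)
  cov <- GenomicRanges::coverage(gr)
  ## keep every genome chromosome, fragment-free ones as all-zero
  cov <- cov[names(genome)]
  scale_factor <- target_depth / n
  cov <- cov * scale_factor
  resolution <- as.integer(resolution)
  if (resolution > 1L) {
    cov <- methods::as(lapply(names(genome), function(ch) {
      L <- as.integer(genome[[ch]])
      s <- seq.int(1L, L, by = resolution)
      e <- pmin(s + resolution - 1L, L)
      v <- IRanges::Views(cov[[ch]], start = s, end = e)
      S4Vectors::Rle(IRanges::viewMeans(v))
    }), "RleList")
    names(cov) <- names(genome)
  }
  structure(list(cov = cov, resolution = resolution,
                 scale_factor = scale_factor, n_fragments = n,
                 genome = genome, target_depth = target_depth),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$genome), "chromosome(s),",
      "resolution", x$resolution, "bp,",
      x$n_fragments, "fragments scaled to", format(x$target_depth,
                                                   scientific = FALSE),
      sprintf("(scale factor %.4g)\n", x$scale_factor))
  invisible(x)
}

#' Export a coverage track as bedGraph
#'
#' bedGraph is the text interchange format for coverage; runs of equal value
#' become single records.
#'
#' @param track A `coverage_track` (resolution 1).
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$resolution != 1)
    stop("bedGraph export expects a resolution-1 track")
  gr <- methods::as(track$cov, "GRanges")
  gr <- gr[gr$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Count fragments in regions by the midpoint rule
#'
#' Builds the region-by-sample count matrix used for differential testing.
#' A fragment is assigned to the region containing its midpoint
#' (`floor((start+end)/2)`, 0-based); since a midpoint lies in at most one
#' region of a non-overlapping set, counts over a genome tiling partition
#' the library exactly. Library size is the total number of fragments in
#' the sample, whether or not they fall in any region.
#'
#' @param samples Named list; each element either a fragment data.frame or
#'   a path readable by [read_fragments()].
#' @param regions A non-overlapping named `GRanges` (as produced by
#'   [extend_intervals()] + [merge_region_sets()] or [bin_genome()]).
#'   Overlapping regions are an error: merge them first so that counts stay
#'   library-size consistent.
#' @param rule `"midpoint"` (default) or `"any"` (count a fragment in every
#'   region it overlaps by >= 1 bp; for sensitivity analysis only).
#' @param min_mapq Mapping-quality filter applied when reading paths.
#' @return A `count_matrix`: list with `counts` (integer matrix, regions x
#'   samples), `lib_sizes` (named), `regions` (the `GRanges`).
#' @export
count_fragments_in_regions <- function(samples, regions, rule = c("midpoint", "any"),
                                       min_mapq = 0) {
  rule <- match.arg(rule)
  if (is.null(names(samples)) || anyDuplicated(names(samples)))
    stop("'samples' must be a uniquely named list")
  if (rule == "midpoint" && !IRanges::isDisjoint(regions))
    stop("regions overlap; merge them (merge_region_sets) before midpoint counting")
  n_reg <- length(regions)
  counts <- matrix(0L, nrow = n_reg, ncol = length(samples),
                   dimnames = list(names(regions), names(samples)))
  lib_sizes <- stats::setNames(integer(length(samples)), names(samples))
  for (j in seq_along(samples)) {
    frags <- samples[[j]]
    if (is.character(frags)) frags <- read_fragments(frags, min_mapq = min_mapq)
    lib_sizes[j] <- nrow(frags)
    if (nrow(frags) == 0 || n_reg == 0) next
    if (rule == "midpoint") {
      mid <- fragment_midpoints(frags)
      q <- GenomicRanges::GRanges(frags$chrom,
                                  IRanges::IRanges(mid + 1L, width = 1L))
    } else {
      q <- GenomicRanges::GRanges(frags$chrom,
                                  IRanges::IRanges(frags$start + 1L, frags$end))
    }
    counts[, j] <- GenomicRanges::countOverlaps(regions, q)
  }
  structure(list(counts = counts, lib_sizes = lib_sizes, regions = regions),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "regions x", ncol(x$counts),
      "samples; library sizes", paste(range(x$lib_sizes), collapse = "-"), "\n")
  invisible(x)
}
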