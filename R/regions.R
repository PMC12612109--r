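#' Construct a region set
#'
#' A region set is a [GenomicRanges::GRanges] with unique names (region ids)
#' and `seqlengths` describing the genome. Inputs are BED-style 0-based
#' half-open coordinates; the stored object follows the usual 1-based closed
#' GRanges convention.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 0-based half-open.
#' @param genome Named vector of chromosome lengths (bp).
#' @param id Optional character vector of unique region ids; autogenerated
#'   (`region_1`, ...) when `NULL`.
#' @return A named `GRanges` with seqlengths set.
#' @export
region_set <- function(chrom, start, end, genome, id = NULL) {
  stopifnot(length(start) == length(end))
  chrom <- rep_len(as.character(chrom), length(start))
  if (is.null(id)) id <- paste0("region_", seq_along(chrom))
  if (anyDuplicated(id)) stop("region ids must be unique within a set")
  miss <- setdiff(unique(chrom), names(genome))
  if (length(miss))
    stop("chromosomes absent from genome: ", paste(miss, collapse = ", "))
  if (any(start < 0) || any(end <= start))
    stop("regions require 0 <= start < end")
  if (any(end > unname(genome[as.character(chrom)])))
    stop("region end exceeds chromosome length")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)),
    seqlengths = genome[order(names(genome))])
  names(gr) <- id
  gr
}

#' Read / write chromosome sizes
#'
#' Two-column tab-separated table: chromosome name, length in bp.
#'
#' @param path File path.
#' @return `read_chrom_sizes`: named integer vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  stats::setNames(as.integer(dt[[2]]), as.character(dt[[1]]))
}

#' @rdname read_chrom_sizes
#' @param genome Named vector of chromosome lengths.
#' @export
write_chrom_sizes <- function(genome, path) {
  data.table::fwrite(data.table::data.table(names(genome), unname(genome)),
                     path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED file as a region set
#'
#' @param path BED3/BED6 file.
#' @param genome Named vector of chromosome lengths.
#' @return A named `GRanges` (ids from the BED name column when present,
#'   autogenerated otherwise).
#' @export
read_bed <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "BED")
  ids <- if (!is.null(gr$name) && !anyNA(gr$name) && !anyDuplicated(gr$name))
    gr$name else paste0("region_", seq_along(gr))
  region_set(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
             genome = genome, id = ids)
}

#' Write a region set as BED
#'
#' Region ids go in the BED name column; an optional `score` metadata column
#' is carried through.
#'
#' @param regions A named `GRanges`.
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  gr <- regions
  gr$name <- names(gr)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Resize intervals to a fixed width about their midpoints
#'
#' Each interval is replaced by a `width`-bp interval centered on its
#' midpoint (`floor((start + end) / 2)` in 0-based coordinates). Intervals
#' running off a chromosome edge are slid back inside; when `width` exceeds
#' the chromosome length the interval is clipped to the whole chromosome
#' with a warning. Ids and order are preserved. This implements the "extend
#' peaks to 1 kb" / "expand loci to 10 kb" operations used before counting
#' and feature extraction, keeping all regions equal width.
#'
#' @param regions A named `GRanges` with seqlengths (see [region_set()]).
#' @param width Target width in bp (> 0).
#' @return A `GRanges` with the same names and length.
#' @export
extend_intervals <- function(regions, width) {
  stopifnot(width > 0)
  width <- as.integer(width)
  chrlen <- GenomeInfoDb::seqlengths(regions)
  if (anyNA(chrlen)) stop("regions must carry seqlengths")
  L <- unname(chrlen[as.character(GenomicRanges::seqnames(regions))])
  s0 <- GenomicRanges::start(regions) - 1L
  e0 <- GenomicRanges::end(regions)
  mid <- (s0 + e0) %/% 2L
  ns <- mid - width %/% 2L
  ne <- ns + width
  ## slide into bounds, then clip to whole chromosome if still too wide
  shift_r <- pmax(0L, -ns)
  ns <- ns + shift_r; ne <- ne + shift_r
  shift_l <- pmax(0L, ne - L)
  ns <- pmax(0L, ns - shift_l); ne <- ne - shift_l
  if (any(width > L)) {
    warning(sum(width > L), " interval(s) clipped to whole chromosome ",
            "(width exceeds chromosome length)")
    ne <- pmin(ne, L)
  }
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(regions),
    ranges = IRanges::IRanges(start = ns + 1L, end = ne),
    seqlengths = chrlen)
  names(out) <- names(regions)
  out
}

#' Merge region sets into a unified, non-overlapping set
#'
#' Takes the union of the input sets and coalesces overlapping or book-ended
#' intervals, producing the kind of unified peak set used for merged
#' differential analysis. Output is sorted by (chrom, start) with fresh
#' sequential ids; the number of input intervals absorbed by coalescing is
#' attached as attribute `n_absorbed`.
#'
#' @param sets A list of `GRanges` sharing one genome (identical
#'   seqlengths).
#' @param id_prefix Prefix for the new ids.
#' @return A named, disjoint `GRanges`.
#' @export
merge_region_sets <- function(sets, id_prefix = "merged") {
  stopifnot(is.list(sets), length(sets) >= 1)
  sl <- GenomeInfoDb::seqlengths(sets[[1]])
  for (s in sets[-1]) {
    sl2 <- GenomeInfoDb::seqlengths(s)
    if (!identical(sl[sort(names(sl))], sl2[sort(names(sl2))]))
      stop("region sets to merge must share one genome (seqlengths differ)")
  }
  all_gr <- suppressWarnings(do.call(c, lapply(sets, GenomicRanges::granges)))
  merged <- GenomicRanges::reduce(GenomicRanges::sort(all_gr),
                                  min.gapwidth = 1L)
  names(merged) <- paste0(id_prefix, "_", seq_along(merged))
  attr(merged, "n_absorbed") <- length(all_gr) - length(merged)
  merged
}

#' Tile a genome into fixed-size bins
#'
#' Consecutive `[k*bin, (k+1)*bin)` windows per chromosome, the final window
#' truncated at the chromosome end. Used for whole-genome feature matrices
#' at 10 kb resolution.
#'
#' @param genome Named vector of chromosome lengths (bp).
#' @param bin Bin size in bp (> 0).
#' @return A named `GRanges` tiling the genome (ids `bin_1`, ...).
#' @export
bin_genome <- function(genome, bin) {
  stopifnot(bin > 0)
  bin <- as.integer(bin)
  chroms <- names(genome)
  pieces <- lapply(chroms, function(ch) {
    L <- as.integer(genome[[ch]])
    s0 <- seq.int(0L, L - 1L, by = bin)
    e0 <- pmin(s0 + bin, L)
    GenomicRanges::GRanges(ch, IRanges::IRanges(start = s0 + 1L, end = e0))
  })
  gr <- suppressWarnings(do.call(c, pieces))
  GenomeInfoDb::seqlengths(gr) <- genome[GenomeInfoDb::seqlevels(gr)]
  names(gr) <- paste0("bin_", seq_along(gr))
  gr
}
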