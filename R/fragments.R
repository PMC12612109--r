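#' Read a cfDNA fragment file
#'
#' Reads tab-separated per-fragment records in the dialect used by cfDNA
#' fragmentation databases: one line per sequenced fragment with columns
#' chrom, start, end, mapq, strand. Coordinates are BED-style 0-based
#' half-open, so fragment length is simply `end - start`. Files may be plain
#' text or gzip-compressed; extra columns beyond the fifth are ignored.
#'
#' @param path Path to the fragment file (`.tsv`, `.bed`-like, optionally
#'   `.gz`).
#' @param min_mapq Minimum mapping quality; fragments below it are dropped.
#'   Defaults to 0 (no filter), since fragment-level deposits typically
#'   already reflect the producer's alignment filtering.
#' @return A `data.table` with columns `chrom` (character), `start`, `end`
#'   (integer, 0-based half-open), `mapq` (integer), `strand` (`"+"` or
#'   `"-"`), in file order.
#' @details Malformed lines abort with an error naming the first offending
#'   line number: non-numeric coordinates, `end <= start` (zero-length or
#'   inverted fragments), negative `mapq`, or a strand symbol other than
#'   `+`/`-`.
#' @seealso [write_fragments()], [fragments_to_granges()]
#' @export
read_fragments <- function(path, min_mapq = 0) {
  if (!file.exists(path)) stop("fragment file not found: ", path)
  empty <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), mapq = integer(),
                                  strand = character())
  if (file.size(path) == 0) return(empty)
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    lines <- readLines(con)
    if (length(lines) == 0) return(empty)
    dt <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                            fill = TRUE, colClasses = list(character = 1),
                            showProgress = FALSE)
  } else {
    dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                            colClasses = list(character = 1),
                            showProgress = FALSE)
  }
  if (nrow(dt) == 0) return(empty)
  if (ncol(dt) < 5)
    stop("fragment file must have >= 5 tab-separated columns (chrom, start, end, mapq, strand): ",
         path)
  dt <- dt[, 1:5]
  data.table::setnames(dt, c("chrom", "start", "end", "mapq", "strand"))
  start <- suppressWarnings(as.integer(dt$start))
  end <- suppressWarnings(as.integer(dt$end))
  mapq <- suppressWarnings(as.integer(dt$mapq))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("non-numeric fragment coordinates at line ", bad[1], " of ", path)
  bad <- which(end <= start)
  if (length(bad))
    stop("fragment with end <= start (length <= 0) at line ", bad[1], " of ", path)
  bad <- which(is.na(mapq) | mapq < 0)
  if (length(bad))
    stop("missing or negative mapq at line ", bad[1], " of ", path)
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad))
    stop("unknown strand symbol '", dt$strand[bad[1]], "' at line ", bad[1],
         " of ", path)
  out <- data.table::data.table(chrom = as.character(dt$chrom), start = start,
                                end = end, mapq = mapq,
                                strand = as.character(dt$strand))
  out[out$mapq >= min_mapq, ]
}

#' Write fragments to a tab-separated file
#'
#' Inverse of [read_fragments()]: writes chrom/start/end/mapq/strand with no
#' header. A `.gz` suffix triggers gzip compression.
#'
#' @param fragments A data.frame with columns `chrom`, `start`, `end`,
#'   `mapq`, `strand` (0-based half-open coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  stopifnot(all(c("chrom", "start", "end", "mapq", "strand") %in%
                  colnames(fragments)))
  dt <- data.table::as.data.table(
    fragments[, c("chrom", "start", "end", "mapq", "strand")])
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Convert fragments to GRanges
#'
#' Translates 0-based half-open fragment records into the 1-based closed
#' convention of [GenomicRanges::GRanges] used by interval operations.
#'
#' @param fragments A fragment data.frame as returned by [read_fragments()].
#' @param genome Optional named vector of chromosome lengths (bp). When
#'   given, it is attached as `seqlengths` and fragments exceeding
#'   chromosome bounds raise an error.
#' @return A `GRanges` with a `mapq` metadata column.
#' @export
fragments_to_granges <- function(fragments, genome = NULL) {
  if (!is.null(genome)) {
    miss <- setdiff(unique(fragments$chrom), names(genome))
    if (length(miss))
      stop("fragments on chromosomes absent from genome: ",
           paste(miss, collapse = ", "))
    over <- fragments$end > unname(genome[fragments$chrom])
    if (any(over))
      stop(sum(over), " fragment(s) extend beyond chromosome bounds")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = fragments$chrom,
    ranges = IRanges::IRanges(start = fragments$start + 1L,
                              end = fragments$end),
    strand = fragments$strand,
    mapq = fragments$mapq,
    seqlengths = genome)
  gr
}

#' Fragment midpoints
#'
#' Midpoint of each fragment in 0-based coordinates,
#' `floor((start + end) / 2)`. Used by the midpoint counting rule.
#'
#' @param fragments A fragment data.frame.
#' @return Integer vector of 0-based midpoint positions.
#' @keywords internal
fragment_midpoints <- function(fragments) {
  as.integer((fragments$start + fragments$end) %/% 2L)
}
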