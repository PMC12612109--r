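#' Build a gene model table
#'
#' One representative transcript per gene, in 0-based half-open
#' coordinates. `tss`/`tes` are single positions consistent with strand
#' (for `-` genes the TSS is the larger coordinate). Exon, CDS and UTR
#' intervals are given as block strings `"start-end,start-end"`.
#'
#' @param gene_id,chrom,strand,tss,tes Vectors, one entry per gene.
#' @param exons,cds,utr5,utr3 Block strings per gene (may be "" for
#'   none).
#' @return A `gene_model` data.table with parsed list-columns of 2-column
#'   matrices.
#' @export
gene_model <- function(gene_id, chrom, strand, tss, tes,
                       exons = "", cds = "", utr5 = "", utr3 = "") {
  n <- length(gene_id)
  stopifnot(!anyDuplicated(gene_id), all(strand %in% c("+", "-")))
  bad <- ifelse(strand == "+", tss >= tes, tss <= tes)
  if (any(bad))
    stop("TSS/TES inconsistent with strand for gene(s): ",
         paste(gene_id[bad], collapse = ", "))
  parse_blocks <- function(s) {
    lapply(s, function(x) {
      if (is.na(x) || x == "") return(matrix(integer(), ncol = 2))
      parts <- strsplit(strsplit(x, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
      m <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE)
      if (any(m[, 2] <= m[, 1])) stop("malformed interval block: ", x)
      m
    })
  }
  dt <- data.table::data.table(
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    strand = as.character(strand), tss = as.integer(tss),
    tes = as.integer(tes),
    exons = parse_blocks(rep_len(exons, n)),
    cds = parse_blocks(rep_len(cds, n)),
    utr5 = parse_blocks(rep_len(utr5, n)),
    utr3 = parse_blocks(rep_len(utr3, n)))
  span_lo <- pmin(dt$tss, dt$tes); span_hi <- pmax(dt$tss, dt$tes)
  for (col in c("exons", "cds", "utr5", "utr3")) {
    out <- vapply(seq_len(n), function(i) {
      m <- dt[[col]][[i]]
      ## blocks are half-open; a block may end one past the TES position
      nrow(m) > 0 && (min(m[, 1]) < span_lo[i] ||
                        max(m[, 2]) > span_hi[i] + 1L)
    }, logical(1))
    if (any(out))
      stop(col, " intervals outside gene span for gene(s): ",
           paste(dt$gene_id[out], collapse = ", "))
  }
  class(dt) <- c("gene_model", class(dt))
  dt
}

#' Read a gene model TSV
#'
#' Columns: gene_id, chrom, strand, tss, tes, exons, cds, utr5, utr3
#' (header required; block columns as `"start-end,start-end"`, 0-based
#' half-open).
#'
#' @param path File path.
#' @return A `gene_model`.
#' @export
read_gene_model <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("chrom", "strand")))
  for (col in c("exons", "cds", "utr5", "utr3"))
    if (!col %in% names(dt)) dt[[col]] <- ""
  gene_model(dt$gene_id, dt$chrom, dt$strand, dt$tss, dt$tes,
             dt$exons, dt$cds, dt$utr5, dt$utr3)
}

## strand-aware genomic windows for one gene, 0-based inclusive positions
gene_windows <- function(g) {
  if (g$strand == "+") {
    list(promoter = c(g$tss - 2000L, g$tss + 500L),
         downstream = c(g$tes + 1L, g$tes + 2000L))
  } else {
    list(promoter = c(g$tss - 500L, g$tss + 2000L),
         downstream = c(g$tes - 2000L, g$tes - 1L))
  }
}

## >=1 bp intersection of region [s0, e0) with closed position window [w1, w2]
olap <- function(s0, e0, w) s0 <= w[2] && (e0 - 1L) >= w[1]

## signed strand-aware distance of a position to the TSS (negative = upstream)
signed_tss_dist <- function(pos, tss, strand) {
  if (strand == "+") pos - tss else tss - pos
}

classify_one <- function(s0, e0, genes_chr) {
  mid <- (s0 + e0) %/% 2L
  if (nrow(genes_chr) == 0)
    return(list(category = "distal intergenic", subcategory = NA_character_,
                gene_id = NA_character_))
  cand_cat <- character(nrow(genes_chr))
  for (k in seq_len(nrow(genes_chr))) {
    g <- genes_chr[k, ]
    w <- gene_windows(g)
    span <- c(min(g$tss, g$tes), max(g$tss, g$tes))
    cand_cat[k] <-
      if (olap(s0, e0, w$promoter)) "promoter"
      else if (olap(s0, e0, w$downstream)) "downstream"
      else if (olap(s0, e0, span)) "gene body"
      else ""
  }
  for (cat in c("promoter", "downstream", "gene body")) {
    hits <- which(cand_cat == cat)
    if (!length(hits)) next
    d <- abs(mid - genes_chr$tss[hits])
    best <- hits[order(d, genes_chr$gene_id[hits])[1]]
    g <- genes_chr[best, ]
    sub <- NA_character_
    if (cat == "promoter") {
      dmid <- signed_tss_dist(mid, g$tss, g$strand)
      contains_tss <- s0 <= g$tss && g$tss < e0
      sub <-
        if (contains_tss || dmid >= 0) "TSS +/- 500 bp"
        else if (dmid > -500) "Upstream < 500 bp"
        else if (dmid > -1000) "Upstream 0.5-1 kb"
        else "Upstream 1-2 kb"
    } else if (cat == "gene body") {
      ov_any <- function(m) nrow(m) > 0 &&
        any(s0 <= m[, 2] - 1L & (e0 - 1L) >= m[, 1])
      other_exon <- g$exons[[1]]
      sub <-
        if (ov_any(g$utr5[[1]])) "5' UTR"
        else if (ov_any(g$utr3[[1]])) "3' UTR"
        else if (ov_any(g$cds[[1]])) "CDS"
        else if (ov_any(other_exon)) "other exon"
        else "intron"
    }
    return(list(category = cat, subcategory = sub, gene_id = g$gene_id))
  }
  list(category = "distal intergenic", subcategory = NA_character_,
       gene_id = NA_character_)
}

#' Classify regions into genomic elements
#'
#' Assigns each region one top-level category with precedence
#' promoter > downstream > gene body > distal intergenic, using
#' strand-aware windows: promoter spans TSS-2000 to TSS+500 in
#' transcription coordinates (subdivided into Upstream 1-2 kb,
#' Upstream 0.5-1 kb, Upstream < 500 bp, and TSS +/- 500 bp by the
#' strand-aware midpoint distance, with regions containing the TSS always
#' TSS +/- 500 bp); downstream spans the 2000 bp beyond the TES; gene
#' body is the remaining gene span, subcategorized by >= 1 bp overlap
#' against 5' UTR, 3' UTR, CDS and other-exon intervals (that precedence),
#' else intron. Among genes offering the winning category, the nearest
#' TSS (by region midpoint) wins, ties broken by smallest gene id.
#'
#' @param regions A named `GRanges`.
#' @param genes A `gene_model`.
#' @return data.table: `region_id`, `category`, `subcategory`, `gene_id`.
#' @export
classify_regions <- function(regions, genes) {
  stopifnot(inherits(genes, "gene_model"))
  chrom <- as.character(GenomicRanges::seqnames(regions))
  s0 <- GenomicRanges::start(regions) - 1L
  e0 <- GenomicRanges::end(regions)
  by_chr <- split(genes, genes$chrom)
  res <- lapply(seq_along(regions), function(i) {
    gc <- by_chr[[chrom[i]]]
    if (is.null(gc)) gc <- genes[0, ]
    classify_one(s0[i], e0[i], gc)
  })
  data.table::data.table(
    region_id = names(regions),
    category = vapply(res, `[[`, character(1), "category"),
    subcategory = vapply(res, `[[`, character(1), "subcategory"),
    gene_id = vapply(res, `[[`, character(1), "gene_id"))
}

#' Nearest gene within a distance cutoff
#'
#' Distance is `|region midpoint - TSS|` over genes on the same
#' chromosome; the minimizing gene is returned when the distance is at
#' most `max_dist` (default 100 kb), ties broken by smallest gene id.
#'
#' @param regions A named `GRanges`.
#' @param genes A `gene_model`.
#' @param max_dist Maximum assignment distance in bp.
#' @return data.table: `region_id`, `gene_id` (NA when none), `distance`.
#' @export
nearest_gene <- function(regions, genes, max_dist = 1e5) {
  stopifnot(max_dist >= 0)
  chrom <- as.character(GenomicRanges::seqnames(regions))
  mid <- (GenomicRanges::start(regions) - 1L +
            GenomicRanges::end(regions)) %/% 2L
  gene_id <- rep(NA_character_, length(regions))
  dist <- rep(NA_integer_, length(regions))
  gchrom <- genes$chrom  # plain vectors: avoid data.table column scoping
  for (i in seq_along(regions)) {
    sel <- gchrom == chrom[i]
    g <- genes[sel, ]
    if (nrow(g) == 0) next
    d <- abs(mid[i] - g$tss)
    best <- order(d, g$gene_id)[1]
    if (d[best] <= max_dist) {
      gene_id[i] <- g$gene_id[best]
      dist[i] <- d[best]
    }
  }
  data.table::data.table(region_id = names(regions), gene_id = gene_id,
                         distance = dist)
}

#' Element category distribution
#'
#' Counts and percentages per top-level category and, within promoter and
#' gene body, per subcategory. Percentages are reported against both the
#' full region count (`pct_all`) and the parent category count
#' (`pct_within`).
#'
#' @param calls Output of [classify_regions()].
#' @return data.table: `level`, `category`, `subcategory`, `n`,
#'   `pct_all`, `pct_within`.
#' @export
element_distribution <- function(calls) {
  if (nrow(calls) == 0)
    return(data.table::data.table(level = character(), category = character(),
                                  subcategory = character(), n = integer(),
                                  pct_all = numeric(), pct_within = numeric()))
  n_all <- nrow(calls)
  top <- calls[, .N, by = "category"]
  out <- data.table::data.table(level = "category", category = top$category,
                                subcategory = NA_character_, n = top$N,
                                pct_all = 100 * top$N / n_all,
                                pct_within = 100 * top$N / n_all)
  for (cat in c("promoter", "gene body")) {
    sub <- calls[calls$category == cat, ]
    if (nrow(sub) == 0) next
    st <- sub[, .N, by = "subcategory"]
    out <- rbind(out, data.table::data.table(
      level = "subcategory", category = cat, subcategory = st$subcategory,
      n = st$N, pct_all = 100 * st$N / n_all,
      pct_within = 100 * st$N / nrow(sub)))
  }
  out
}

#' Histogram of region distances to assigned TSS
#'
#' Signed strand-aware distance (negative upstream, positive downstream in
#' transcription direction) from each region midpoint to its nearest
#' gene's TSS, for regions with an assignment within `max_dist`.
#'
#' @param regions A named `GRanges`.
#' @param genes A `gene_model`.
#' @param breaks Numeric bin boundaries passed to [cut()] (covering the
#'   `[-max_dist, max_dist]` range).
#' @param max_dist Assignment cutoff in bp.
#' @return List with `counts` (named by bin), `distances` (per assigned
#'   region), `n_assigned`, `n_unassigned`.
#' @export
tss_distance_histogram <- function(regions, genes,
                                   breaks = seq(-1e5, 1e5, by = 1e4),
                                   max_dist = 1e5) {
  ng <- nearest_gene(regions, genes, max_dist = max_dist)
  chrom <- as.character(GenomicRanges::seqnames(regions))
  mid <- (GenomicRanges::start(regions) - 1L +
            GenomicRanges::end(regions)) %/% 2L
  ok <- !is.na(ng$gene_id)
  g_idx <- match(ng$gene_id[ok], genes$gene_id)
  signed <- ifelse(genes$strand[g_idx] == "+",
                   mid[ok] - genes$tss[g_idx],
                   genes$tss[g_idx] - mid[ok])
  cuts <- cut(signed, breaks = breaks, include.lowest = TRUE)
  list(counts = table(cuts), distances = signed,
       n_assigned = sum(ok), n_unassigned = sum(!ok))
}
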