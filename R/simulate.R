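#' Simulation configuration for synthetic cfDNA cohorts
#'
#' Bundles every knob of the cohort simulator. The defaults encode the
#' chromatin structure the pipeline is designed to detect: a chromatosome
#' fragment-length mode at 167 bp with a di-nucleosome shoulder at 334 bp, a
#' 10.4 bp cosine comb over the sub-nucleosomal 80-140 bp range, positional
#' enrichment at cell-type-specific open-chromatin peaks with phased
#' flanking nucleosomes at +/-185 bp, a 5' CC end-motif bias, and cancer
#' samples as a two-source mixture with per-sample tumor fraction drawn
#' uniformly from 1-3%.
#'
#' @param genome Named vector of chromosome lengths (bp).
#' @param n_peaks Open-chromatin peaks per cell-type catalog.
#' @param peak_width Length-2 range; widths drawn uniformly within it.
#' @param shared_fraction Fraction of each catalog shared with the other
#'   (identical intervals), emulating partially overlapping tumor and
#'   immune open-chromatin landscapes.
#' @param n_diff Number of differential regions planted in the immune
#'   catalog (half increased, half decreased in cancer samples).
#' @param diff_fold Fold change applied to the within-catalog placement
#'   weight of planted regions in cancer samples (increased regions get
#'   `diff_fold`, decreased ones `1/diff_fold`).
#' @param diff_penetrance Probability that a given cancer sample expresses
#'   a given planted region's fold change (drawn independently per sample
#'   and region). 1 reproduces a homogeneous cancer class; values below 1
#'   emulate inter-patient heterogeneity of tumor-associated chromatin,
#'   where each patient's cfDNA shifts only a subset of the
#'   cancer-associated loci.
#' @param n_healthy,n_cancer Samples per class.
#' @param fragments_per_sample Fragments emitted per sample.
#' @param tumor_fraction_range Length-2 range of per-sample tumor fraction
#'   (proportion of fragments drawn from the tumor catalog in cancer
#'   samples).
#' @param length_model List: `mu_mono`, `scale_mono` (discrete-Laplace
#'   location/scale of the chromatosome mode), `mu_di`, `scale_di`, `w_di`
#'   (di-nucleosome component), `w_sub`, `sub_range`, `comb_period`,
#'   `comb_amplitude` (sub-nucleosomal comb component), `min_length`.
#' @param enrichment_model List: `p_open` (probability a fragment is
#'   peak-associated), `w_center`, `center_sd`, `flank_offset`, `flank_sd`
#'   (midpoint offset mixture: peak center plus phased flanking nucleosomes
#'   at `+/-flank_offset`).
#' @param end_motif_bias Multiplicative sampling weight for candidate 5'
#'   ends whose first two reference bases are CC; 1 disables the bias (and
#'   no genome sequence is generated).
#' @param end_bias_window Candidate 5' shift half-window (bp) used by
#'   [apply_end_bias()].
#' @param seed Master seed; every random draw in the simulator derives from
#'   it (keep it below 2e6 so derived per-sample seeds stay within integer
#'   range).
#' @return A `sim_config` list.
#' @seealso [simulate_cohort()], [sim_config_classification()]
#' @export
sim_config <- function(genome = c(chr1 = 5e6, chr2 = 5e6),
                       n_peaks = 1000,
                       peak_width = c(200, 500),
                       shared_fraction = 0.2,
                       n_diff = 100,
                       diff_fold = 2,
                       diff_penetrance = 1,
                       n_healthy = 6,
                       n_cancer = 6,
                       fragments_per_sample = 2e5,
                       tumor_fraction_range = c(0.01, 0.03),
                       length_model = list(),
                       enrichment_model = list(),
                       end_motif_bias = 4,
                       end_bias_window = 3,
                       seed = 1) {
  lm_def <- list(mu_mono = 167, scale_mono = 6, mu_di = 334, scale_di = 15,
                 w_di = 0.15, w_sub = 0.10, sub_range = c(80L, 140L),
                 comb_period = 10.4, comb_amplitude = 0.6, min_length = 50L)
  em_def <- list(p_open = 0.4, w_center = 0.5, center_sd = 60,
                 flank_offset = 185, flank_sd = 40)
  lm <- utils::modifyList(lm_def, length_model)
  em <- utils::modifyList(em_def, enrichment_model)
  stopifnot(all(genome > 0),
            n_peaks >= 1, length(peak_width) == 2, peak_width[1] <= peak_width[2],
            shared_fraction >= 0, shared_fraction <= 1,
            n_diff >= 0, diff_fold > 0,
            fragments_per_sample > 0,
            length(tumor_fraction_range) == 2,
            tumor_fraction_range[1] >= 0,
            tumor_fraction_range[1] <= tumor_fraction_range[2],
            tumor_fraction_range[2] <= 1,
            lm$w_di >= 0, lm$w_sub >= 0, lm$w_di + lm$w_sub <= 1,
            lm$comb_period >= 8, lm$comb_period <= 15,
            em$p_open >= 0, em$p_open <= 1,
            diff_penetrance > 0, diff_penetrance <= 1,
            end_motif_bias > 0, seed == round(seed), abs(seed) < 2e6)
  structure(list(genome = genome, n_peaks = as.integer(n_peaks),
                 peak_width = as.integer(peak_width),
                 shared_fraction = shared_fraction,
                 n_diff = as.integer(n_diff), diff_fold = diff_fold,
                 diff_penetrance = diff_penetrance,
                 n_healthy = as.integer(n_healthy),
                 n_cancer = as.integer(n_cancer),
                 fragments_per_sample = as.integer(fragments_per_sample),
                 tumor_fraction_range = tumor_fraction_range,
                 length_model = lm, enrichment_model = em,
                 end_motif_bias = end_motif_bias,
                 end_bias_window = as.integer(end_bias_window),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Classification-scale simulation preset
#'
#' A 30 vs 30 cohort preset for the gradient-boosted classification
#' protocol: a large sizes-only genome (two 50 Mb chromosomes) with sparse
#' catalogs, so matched random background regions almost surely sample
#' signal-free territory, as they do on a real genome where discriminative
#' loci cover a tiny fraction of sequence. End-motif bias is disabled (no
#' genome sequence is needed for region-level coverage features) and the
#' open-chromatin placement probability is lowered to keep per-peak
#' enrichment moderate on the sparse catalogs.
#'
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_classification <- function(...) {
  args <- list(genome = c(chr1 = 5e8, chr2 = 5e8),
               n_peaks = 150, n_diff = 40, diff_fold = 2,
               diff_penetrance = 0.5,
               n_healthy = 30, n_cancer = 30,
               enrichment_model = list(p_open = 0.03),
               end_motif_bias = 1)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

## evaluate code under a derived seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Generate a toy genome
#'
#' I.i.d. uniform A/C/G/T sequence for each configured chromosome,
#' deterministic given the master seed. When `end_motif_bias == 1` in the
#' config the sequence is skipped (`seq = NULL`) since nothing downstream
#' reads it.
#'
#' @param config A `sim_config`.
#' @param force_seq Generate sequence even when the end bias is off.
#' @return List with `sizes` (named integer vector) and `seq`
#'   (`DNAStringSet` or `NULL`).
#' @export
generate_toy_genome <- function(config, force_seq = FALSE) {
  if (any(config$genome <= 0)) stop("zero-length chromosome in genome spec")
  sizes <- stats::setNames(as.integer(config$genome), names(config$genome))
  seq <- NULL
  if (config$end_motif_bias != 1 || force_seq) {
    seq <- with_seed(config$seed * 1000L + 999L, {
      s <- lapply(sizes, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""))
      Biostrings::DNAStringSet(unlist(s))
    })
    names(seq) <- names(sizes)
  }
  list(sizes = sizes, seq = seq)
}

#' Generate tumor and immune open-chromatin catalogs
#'
#' Lays out non-overlapping peaks by partitioning the genome into equal
#' slots and placing one peak per used slot, keeping a margin from slot
#' edges so that adjacent peaks stay more than 1 kb apart (1 kb-extended
#' peaks remain disjoint within and across catalogs). Slots are assigned at
#' random to tumor-only, immune-only, and shared roles; shared intervals
#' appear identically in both catalogs. A planted differential subset is
#' drawn from the immune-only peaks: half marked `increased` (placement
#' weight `diff_fold` in cancer samples), half `decreased` (`1/diff_fold`).
#'
#' @param config A `sim_config`.
#' @return List with `catalogs` (named list of `GRanges`: `tumor`,
#'   `immune`), `planted` (data.table: region_id, catalog, direction,
#'   fold), and `weights` (per-catalog placement weight vectors for healthy
#'   and cancer samples).
#' @export
generate_peak_catalog <- function(config) {
  g <- config$genome
  n_shared <- as.integer(round(config$shared_fraction * config$n_peaks))
  n_only <- config$n_peaks - n_shared
  n_total <- 2L * n_only + n_shared
  margin <- 520L  # keeps 1 kb extensions of neighboring peaks disjoint
  ## slots per chromosome, proportional to length
  n_slot <- pmax(1L, as.integer(round(n_total * g / sum(g))))
  while (sum(n_slot) != n_total) {  # fix rounding drift on the largest chrom
    k <- which.max(g)
    n_slot[k] <- n_slot[k] + sign(n_total - sum(n_slot))
  }
  slot_len <- as.integer(g) %/% n_slot
  if (any(slot_len < config$peak_width[2] + 2L * margin + 2L))
    stop("infeasible packing: peaks x widths do not fit the genome ",
         "with the required spacing")
  with_seed(config$seed * 1000L + 998L, {
    chrom <- rep(names(g), n_slot)
    slot_start <- unlist(lapply(seq_along(g), function(i)
      (seq_len(n_slot[i]) - 1L) * slot_len[i]), use.names = FALSE)
    this_len <- rep(slot_len, n_slot)
    width <- sample(seq.int(config$peak_width[1], config$peak_width[2]),
                    n_total, replace = TRUE)
    off <- margin + floor(stats::runif(n_total) *
                            (this_len - width - 2L * margin))
    s0 <- slot_start + as.integer(off)
    e0 <- s0 + width
    role <- sample(rep(c("tumor", "immune", "shared"),
                       c(n_only, n_only, n_shared)))
    id <- character(n_total)
    for (r in c("tumor", "immune", "shared"))
      id[role == r] <- paste0(r, "_", seq_len(sum(role == r)))
    all_gr <- region_set(chrom, s0, e0, genome = g, id = id)
    tumor <- all_gr[role %in% c("tumor", "shared")]
    immune <- all_gr[role %in% c("immune", "shared")]
    immune_only_ids <- id[role == "immune"]
    if (config$n_diff > length(immune_only_ids))
      stop("n_diff exceeds the number of immune-only peaks")
    planted_ids <- sample(immune_only_ids, config$n_diff)
    n_up <- ceiling(config$n_diff / 2)
    planted <- data.table::data.table(
      region_id = planted_ids,
      catalog = "immune",
      direction = rep(c("increased", "decreased"),
                      c(n_up, config$n_diff - n_up)),
      fold = rep(c(config$diff_fold, 1 / config$diff_fold),
                 c(n_up, config$n_diff - n_up)))
    w_immune_healthy <- stats::setNames(rep(1, length(immune)), names(immune))
    w_immune_cancer <- w_immune_healthy
    w_immune_cancer[planted$region_id] <- planted$fold
    w_tumor <- stats::setNames(rep(1, length(tumor)), names(tumor))
    list(catalogs = list(tumor = tumor, immune = immune),
         planted = planted,
         weights = list(tumor = w_tumor,
                        immune_healthy = w_immune_healthy,
                        immune_cancer = w_immune_cancer))
  })
}

#' Sample fragment lengths from the cfDNA length model
#'
#' Mixture of three components: a discrete-Laplace chromatosome mode at
#' `mu_mono` (default 167 bp), a discrete-Laplace di-nucleosome mode at
#' `mu_di` (default 334 bp), and a sub-nucleosomal component supported on
#' `sub_range` (default 80-140 bp) whose mass follows
#' `1 + comb_amplitude * cos(2*pi*(l - lo)/comb_period)`, reproducing the
#' ~10-11 bp periodicity of sub-nucleosomal cfDNA. Lengths below
#' `min_length` are clamped.
#'
#' @param n Number of draws.
#' @param length_model Length-model list (see [sim_config()]).
#' @return Integer vector of fragment lengths (bp).
#' @export
sample_fragment_lengths <- function(n, length_model = sim_config()$length_model) {
  lm <- length_model
  w_mono <- 1 - lm$w_di - lm$w_sub
  comp <- sample.int(3L, n, replace = TRUE, prob = c(w_mono, lm$w_di, lm$w_sub))
  len <- integer(n)
  rdlaplace <- function(k, mu, b) {
    ## difference of geometrics: discrete Laplace with scale b
    p <- 1 - exp(-1 / b)
    as.integer(mu) + stats::rgeom(k, p) - stats::rgeom(k, p)
  }
  n1 <- sum(comp == 1L); n2 <- sum(comp == 2L); n3 <- sum(comp == 3L)
  if (n1) len[comp == 1L] <- rdlaplace(n1, lm$mu_mono, lm$scale_mono)
  if (n2) len[comp == 2L] <- rdlaplace(n2, lm$mu_di, lm$scale_di)
  if (n3) {
    lo <- lm$sub_range[1]; hi <- lm$sub_range[2]
    grid <- seq.int(lo, hi)
    w <- 1 + lm$comb_amplitude * cos(2 * pi * (grid - lo) / lm$comb_period)
    len[comp == 3L] <- sample(grid, n3, replace = TRUE, prob = w)
  }
  pmax(len, as.integer(lm$min_length))
}

#' Place fragments on the genome
#'
#' With probability `p_open` a fragment is peak-associated: a peak is drawn
#' from the catalog proportionally to `weights` and the fragment midpoint
#' from a mixture centered at the peak center (`w_center`, sd `center_sd`)
#' or at the phased flanking-nucleosome offsets `+/-flank_offset` (sd
#' `flank_sd`). Otherwise the midpoint is uniform over the genome. Strand
#' is uniform. Fragments that would cross a chromosome edge are redrawn
#' (bounded retries, then error).
#'
#' @param lengths Integer vector of fragment lengths.
#' @param catalog Named `GRanges` of peaks.
#' @param weights Placement weight per peak (same order/names as
#'   `catalog`).
#' @param enrichment_model Enrichment-model list (see [sim_config()]).
#' @param genome Named vector of chromosome lengths.
#' @param max_retries Redraw rounds for out-of-bounds fragments.
#' @return data.table with `chrom`, `start`, `end` (0-based half-open),
#'   `strand`.
#' @export
place_fragments <- function(lengths, catalog, weights, enrichment_model,
                            genome, max_retries = 50L) {
  em <- enrichment_model
  n <- length(lengths)
  peak_chrom <- as.character(GenomicRanges::seqnames(catalog))
  peak_mid <- (GenomicRanges::start(catalog) - 1L +
                 GenomicRanges::end(catalog)) %/% 2L
  chrom <- character(n)
  mid <- numeric(n)
  draw <- function(idx) {
    k <- length(idx)
    if (!k) return()
    open <- stats::runif(k) < em$p_open
    ko <- sum(open)
    if (ko) {
      pk <- sample.int(length(catalog), ko, replace = TRUE, prob = weights)
      u <- stats::runif(ko)
      offs <- numeric(ko)
      ctr <- u < em$w_center
      offs[ctr] <- stats::rnorm(sum(ctr), 0, em$center_sd)
      fl <- !ctr
      side <- sign(stats::runif(sum(fl)) - 0.5)
      offs[fl] <- stats::rnorm(sum(fl), side * em$flank_offset, em$flank_sd)
      chrom[idx[open]] <<- peak_chrom[pk]
      mid[idx[open]] <<- peak_mid[pk] + round(offs)
    }
    kb <- k - ko
    if (kb) {
      ch <- sample(names(genome), kb, replace = TRUE, prob = genome)
      chrom[idx[!open]] <<- ch
      mid[idx[!open]] <<- floor(stats::runif(kb) * genome[ch])
    }
  }
  draw(seq_len(n))
  start <- mid - lengths %/% 2
  end <- start + lengths
  for (r in seq_len(max_retries)) {
    bad <- which(start < 0 | end > genome[chrom])
    if (!length(bad)) break
    draw(bad)
    start[bad] <- mid[bad] - lengths[bad] %/% 2
    end[bad] <- start[bad] + lengths[bad]
  }
  if (any(start < 0 | end > genome[chrom]))
    stop("could not place fragments within chromosome bounds after ",
         max_retries, " retries")
  data.table::data.table(chrom = chrom, start = as.integer(start),
                         end = as.integer(end),
                         strand = sample(c("+", "-"), n, replace = TRUE))
}

#' Apply a 5' CC end-motif bias
#'
#' For each fragment, candidate placements shifted by `-window..window` bp
#' are weighted by `bias` when the two reference bases at the candidate 5'
#' end are CC (read from the plus strand at `start` for `+` fragments; for
#' `-` fragments the 5' end is at `end`, and its reverse-complemented
#' dinucleotide is CC exactly when the forward-strand bases `[end-2, end)`
#' are GG). One candidate is sampled per fragment; `bias = 1` leaves the
#' input distribution untouched.
#'
#' @param fragments data.table with `chrom`, `start`, `end`, `strand`.
#' @param genome_seq Named character vector or `DNAStringSet` of
#'   chromosome sequences.
#' @param bias Multiplicative weight for CC 5' ends (>= 1 typical).
#' @param window Candidate shift half-window in bp.
#' @return The fragments with shifted `start`/`end`.
#' @export
apply_end_bias <- function(fragments, genome_seq, bias, window = 3L) {
  if (bias == 1) return(fragments)
  if (methods::is(genome_seq, "DNAStringSet"))
    genome_seq <- stats::setNames(as.character(genome_seq), names(genome_seq))
  n <- nrow(fragments)
  shifts <- seq.int(-window, window)
  chrlen <- stats::setNames(nchar(genome_seq), names(genome_seq))
  w_total <- numeric(n)
  cum <- matrix(0, n, length(shifts))
  plus <- fragments$strand == "+"
  for (j in seq_along(shifts)) {
    sh <- shifts[j]
    ## 0-based position of the first base of the 5' dinucleotide
    pos0 <- ifelse(plus, fragments$start + sh, fragments$end + sh - 2L)
    valid <- fragments$start + sh >= 0 &
      fragments$end + sh <= chrlen[fragments$chrom]
    din <- rep(NA_character_, n)
    for (ch in unique(fragments$chrom)) {
      k <- which(fragments$chrom == ch & valid)
      if (length(k))
        din[k] <- substring(genome_seq[[ch]], pos0[k] + 1L, pos0[k] + 2L)
    }
    hit <- !is.na(din) & ifelse(plus, din == "CC", din == "GG")
    w <- ifelse(valid, ifelse(hit, bias, 1), 0)
    w_total <- w_total + w
    cum[, j] <- w_total
  }
  u <- stats::runif(n) * w_total
  pick <- rowSums(cum < u) + 1L
  sh <- shifts[pick]
  fragments$start <- fragments$start + sh
  fragments$end <- fragments$end + sh
  fragments
}

#' Simulate a cfDNA cohort
#'
#' Healthy samples draw all peak-associated fragments from the immune
#' catalog; cancer samples draw a per-sample tumor fraction
#' `tf ~ Uniform(tumor_fraction_range)` of fragments from the tumor catalog
#' and `1 - tf` from the immune catalog, with planted differential regions'
#' placement weights scaled by their fold change in the expressing fraction
#' of cancer samples (`diff_penetrance`). Fragment lengths,
#' placements, strands and (when enabled) 5' end-motif bias follow the
#' config. All randomness derives from the master seed plus the sample
#' index, so output is fully deterministic.
#'
#' @param config A `sim_config`.
#' @param outdir Optional directory; when given, per-sample fragment TSVs,
#'   the toy genome (FASTA when sequence is generated, plus a chrom.sizes
#'   file), catalog BED files and a truth table are written there.
#' @return List with `samples` (named list of fragment data.tables),
#'   `truth` (list: `samples` table with label and tumor fraction,
#'   `planted` table, `catalogs`), `genome` (sizes), `sequence`
#'   (`DNAStringSet` or `NULL`), and `config`.
#' @export
simulate_cohort <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  toy <- generate_toy_genome(config)
  cat <- generate_peak_catalog(config)
  ids <- c(sprintf("healthy_%02d", seq_len(config$n_healthy)),
           sprintf("cancer_%02d", seq_len(config$n_cancer)))
  labels <- rep(c("healthy", "cancer"), c(config$n_healthy, config$n_cancer))
  samples <- vector("list", length(ids))
  names(samples) <- ids
  tf_real <- numeric(length(ids))
  nt_real <- integer(length(ids))
  for (i in seq_along(ids)) {
    res <- with_seed(config$seed * 1000L + i, {
      n <- config$fragments_per_sample
      lens <- sample_fragment_lengths(n, config$length_model)
      if (labels[i] == "healthy") {
        fr <- place_fragments(lens, cat$catalogs$immune,
                              cat$weights$immune_healthy,
                              config$enrichment_model, toy$sizes)
        list(fr = fr, tf = 0, nt = 0L)
      } else {
        tf <- stats::runif(1, config$tumor_fraction_range[1],
                           config$tumor_fraction_range[2])
        w_immune <- cat$weights$immune_healthy
        expressed <- stats::runif(nrow(cat$planted)) < config$diff_penetrance
        w_immune[cat$planted$region_id[expressed]] <-
          cat$planted$fold[expressed]
        from_tumor <- stats::runif(n) < tf
        nt <- sum(from_tumor)
        chrom <- character(n); s0 <- integer(n); e0 <- integer(n)
        strand <- character(n)
        fill <- function(mask, part) {
          chrom[mask] <<- part$chrom; s0[mask] <<- part$start
          e0[mask] <<- part$end; strand[mask] <<- part$strand
        }
        if (nt)
          fill(from_tumor,
               place_fragments(lens[from_tumor], cat$catalogs$tumor,
                               cat$weights$tumor,
                               config$enrichment_model, toy$sizes))
        if (n - nt)
          fill(!from_tumor,
               place_fragments(lens[!from_tumor], cat$catalogs$immune,
                               w_immune, config$enrichment_model, toy$sizes))
        list(fr = data.table::data.table(chrom = chrom, start = s0,
                                         end = e0, strand = strand),
             tf = tf, nt = nt)
      }
    })
    samples[[i]] <- res$fr
    tf_real[i] <- res$tf
    nt_real[i] <- res$nt
    if (config$end_motif_bias != 1)
      samples[[i]] <- with_seed(config$seed * 1000L + 500000L + i,
                                apply_end_bias(samples[[i]], toy$seq,
                                               config$end_motif_bias,
                                               config$end_bias_window))
    samples[[i]]$mapq <- 60L
    data.table::setcolorder(samples[[i]],
                            c("chrom", "start", "end", "mapq", "strand"))
  }
  truth <- list(
    samples = data.table::data.table(sample = ids, label = labels,
                                     tumor_fraction = tf_real,
                                     n_tumor_fragments = nt_real),
    planted = cat$planted,
    catalogs = cat$catalogs)
  out <- list(samples = samples, truth = truth, genome = toy$sizes,
              sequence = toy$seq, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(ids))
      write_fragments(samples[[i]], file.path(outdir, paste0(ids[i], ".tsv")))
    write_chrom_sizes(toy$sizes, file.path(outdir, "genome.chrom.sizes"))
    if (!is.null(toy$seq))
      Biostrings::writeXStringSet(toy$seq, file.path(outdir, "genome.fa"))
    write_bed(cat$catalogs$tumor, file.path(outdir, "catalog_tumor.bed"))
    write_bed(cat$catalogs$immune, file.path(outdir, "catalog_immune.bed"))
    data.table::fwrite(truth$samples, file.path(outdir, "truth_samples.tsv"),
                       sep = "\t")
    data.table::fwrite(truth$planted, file.path(outdir, "truth_planted.tsv"),
                       sep = "\t")
  }
  out
}
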