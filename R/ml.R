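#' Region-level coverage feature matrix
#'
#' One row per sample, one feature per region: the mean depth-normalized
#' coverage over the region's bases, extracted from a per-sample
#' [coverage_track()]. Features are ordered deterministically by
#' (chrom, start); regions with no coverage contribute 0, never missing
#' values.
#'
#' @param samples Named list of fragment data.frames or file paths.
#' @param regions A named `GRanges` of feature regions (overlap allowed).
#' @param genome Named vector of chromosome lengths.
#' @param labels Optional class label per sample (named or in `samples`
#'   order).
#' @param target_depth Depth the coverage is normalized to.
#' @param min_mapq Mapping-quality filter for file inputs.
#' @return A `feature_matrix`: list with `x` (samples x features),
#'   `regions` (sorted `GRanges`), `labels`.
#' @export
build_feature_matrix <- function(samples, regions, genome, labels = NULL,
                                 target_depth = 1e7, min_mapq = 0) {
  if (is.null(names(samples)) || anyDuplicated(names(samples)))
    stop("'samples' must be a uniquely named list")
  ord <- GenomicRanges::order(regions)
  regions <- regions[ord]
  x <- matrix(0, nrow = length(samples), ncol = length(regions),
              dimnames = list(names(samples), names(regions)))
  chrom <- as.character(GenomicRanges::seqnames(regions))
  for (j in seq_along(samples)) {
    frags <- samples[[j]]
    if (is.character(frags)) frags <- read_fragments(frags, min_mapq = min_mapq)
    track <- coverage_track(frags, genome, resolution = 1,
                            target_depth = target_depth)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      v <- IRanges::Views(track$cov[[ch]],
                          start = GenomicRanges::start(regions)[i],
                          end = GenomicRanges::end(regions)[i])
      x[j, i] <- IRanges::viewMeans(v)
    }
  }
  if (!is.null(labels)) {
    labels <- if (!is.null(names(labels))) labels[names(samples)]
              else stats::setNames(labels, names(samples))
  }
  structure(list(x = x, regions = regions, labels = labels),
            class = "feature_matrix")
}

#' Matched random background regions
#'
#' Random genomic intervals matched in number and size to a template set:
#' the multiset of interval lengths is preserved exactly, placements are
#' uniform over the allowed chromosomes subject to no pairwise overlap
#' (rejection sampling with a retry cap), and mitochondrial / unplaced /
#' random-scaffold / Y chromosomes are excluded. Deterministic given the
#' seed. Used as the control feature space for classification.
#'
#' @param template A `GRanges` whose widths are reproduced.
#' @param genome Named vector of chromosome lengths.
#' @param excluded_chroms Chromosome names excluded outright; names
#'   starting `chrUn` or ending `_random` are always excluded.
#' @param seed Integer seed.
#' @param max_retries Per-interval rejection cap.
#' @return A named `GRanges` (`bg_1`, ...), sorted, on allowed
#'   chromosomes only.
#' @export
random_background <- function(template, genome,
                              excluded_chroms = c("chrM", "chrY"),
                              seed = 1, max_retries = 1000) {
  widths <- GenomicRanges::width(template)
  allowed <- genome[!(names(genome) %in% excluded_chroms |
                        grepl("^chrUn", names(genome)) |
                        grepl("_random$", names(genome)))]
  if (length(allowed) == 0) stop("no allowed chromosomes left")
  if (sum(widths) > sum(allowed))
    stop("infeasible: template length ", sum(widths),
         " exceeds allowed genome length ", sum(allowed))
  with_seed(seed, {
    ord <- order(widths, decreasing = TRUE)  # large intervals first packs best
    placed_chrom <- character(length(widths))
    placed_s0 <- integer(length(widths))
    acc <- stats::setNames(
      lapply(names(allowed), function(.) IRanges::IRanges()), names(allowed))
    for (w in ord) {
      wd <- widths[w]
      valid <- allowed[allowed >= wd]
      if (length(valid) == 0)
        stop("interval of length ", wd, " exceeds every allowed chromosome")
      done <- FALSE
      for (r in seq_len(max_retries)) {
        ch <- sample(names(valid), 1, prob = valid - wd + 1)
        s0 <- floor(stats::runif(1) * (valid[[ch]] - wd + 1))
        cand <- IRanges::IRanges(s0 + 1, s0 + wd)
        if (IRanges::countOverlaps(cand, acc[[ch]]) == 0) {
          acc[[ch]] <- c(acc[[ch]], cand)
          placed_chrom[w] <- ch
          placed_s0[w] <- as.integer(s0)
          done <- TRUE
          break
        }
      }
      if (!done)
        stop("could not place all intervals without overlap after ",
             max_retries, " retries (packing too dense)")
    }
    out <- region_set(placed_chrom, placed_s0, placed_s0 + widths,
                      genome = genome,
                      id = paste0("bg_", seq_along(widths)))
    GenomicRanges::sort(out)
  })
}

#' Training configuration for the boosted-tree classifier
#'
#' Binary logistic gradient-boosted trees with histogram split finding,
#' depth 6, 100 boosting rounds, gamma 0, AUC-PR early stopping with
#' patience 15 on the held-out test set, and a hyperparameter grid over
#' learning rate 0.05-0.65, L2 penalty 1-10 and positive-class weight
#' 0.8-1. The grid point maximizing balanced accuracy (ties broken by the
#' validation score, the best test-set AUC-PR before stopping) is
#' selected.
#'
#' @param split_fraction Training fraction of the stratified split.
#' @param max_depth,nrounds,gamma,tree_method,eval_metric Booster
#'   settings.
#' @param learning_rate_grid,lambda_grid,scale_pos_weight_grid Grids.
#' @param early_stopping Patience in rounds.
#' @param cv_folds Folds for [cross_validate()] (3-10).
#' @param standardize Standardize features using training-set mean/sd.
#' @param seed Seed for the split and the booster.
#' @return A `train_config` list.
#' @export
train_config <- function(split_fraction = 0.7,
                         max_depth = 6, nrounds = 100, gamma = 0,
                         tree_method = "hist", eval_metric = "aucpr",
                         learning_rate_grid = seq(0.05, 0.65, by = 0.1),
                         lambda_grid = c(1, 5, 10),
                         scale_pos_weight_grid = c(0.8, 0.9, 1.0),
                         early_stopping = 15,
                         cv_folds = 5,
                         standardize = FALSE,
                         seed = 1) {
  stopifnot(split_fraction > 0, split_fraction < 1,
            length(learning_rate_grid) >= 1, length(lambda_grid) >= 1,
            length(scale_pos_weight_grid) >= 1,
            cv_folds >= 3, cv_folds <= 10)
  structure(list(split_fraction = split_fraction, max_depth = max_depth,
                 nrounds = nrounds, gamma = gamma, tree_method = tree_method,
                 eval_metric = eval_metric,
                 learning_rate_grid = learning_rate_grid,
                 lambda_grid = lambda_grid,
                 scale_pos_weight_grid = scale_pos_weight_grid,
                 early_stopping = early_stopping, cv_folds = cv_folds,
                 standardize = standardize, seed = as.integer(seed)),
            class = "train_config")
}

roc_auc <- function(labels, scores, positive) {
  r <- pROC::roc(response = factor(labels == positive, c(FALSE, TRUE)),
                 predictor = scores, levels = c(FALSE, TRUE),
                 direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

fit_one <- function(dtrain, dtest, params, config) {
  m <- xgboost::xgb.train(
    params = c(params,
               list(objective = "binary:logistic",
                    max_depth = config$max_depth, gamma = config$gamma,
                    tree_method = config$tree_method,
                    eval_metric = config$eval_metric,
                    nthread = 1, seed = config$seed)),
    data = dtrain, nrounds = config$nrounds,
    evals = list(test = dtest),
    early_stopping_rounds = config$early_stopping, verbose = 0)
  best_iter <- as.integer(xgboost::xgb.attr(m, "best_iteration"))
  best_score <- as.numeric(xgboost::xgb.attr(m, "best_score"))
  if (!length(best_iter) || is.na(best_iter)) best_iter <- config$nrounds
  if (!length(best_score)) best_score <- NA_real_
  list(model = m, best_iteration = best_iter, best_score = best_score)
}

stratified_split <- function(labels, fraction, seed) {
  with_seed(seed, {
    train <- logical(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_tr <- round(fraction * length(idx))
      train[sample(idx, n_tr)] <- TRUE
    }
    train
  })
}

#' Train and evaluate the boosted-tree classifier
#'
#' Stratified 70/30 split, grid search with AUC-PR early stopping on the
#' test set, selection by (balanced accuracy, validation score), then a
#' full metric report for the selected model including stratified k-fold
#' cross-validation and gain-based feature importances. Deterministic
#' given the config seed (single-threaded histogram boosting).
#'
#' @param features A `feature_matrix` with two-class `labels`.
#' @param config A `train_config`.
#' @param positive Positive-class label (default `"cancer"`; falls back
#'   to the lexicographically larger label when absent).
#' @param run_cv Also run [cross_validate()] with the selected
#'   hyperparameters.
#' @return A `model_report`: balanced accuracy, ROC AUC, validation
#'   score, confusion matrix, sensitivity/specificity/precision, chosen
#'   hyperparameters, best iteration, per-fold CV table, ranked
#'   importances, the fitted booster, and the split.
#' @export
train_classifier <- function(features, config = train_config(),
                             positive = "cancer", run_cv = TRUE) {
  stopifnot(inherits(features, "feature_matrix"))
  labels <- features$labels
  if (is.null(labels)) stop("feature matrix carries no class labels")
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2) stop("exactly two classes required")
  if (!positive %in% classes) positive <- classes[2]
  if (min(table(labels)) < 2) stop("need >= 2 samples per class")
  y <- as.integer(labels == positive)
  train <- stratified_split(as.character(labels), config$split_fraction,
                            config$seed)
  if (length(unique(y[train])) < 2 || length(unique(y[!train])) < 2)
    stop("a class is absent from the train or test split")
  x <- features$x
  if (config$standardize) {
    mu <- colMeans(x[train, , drop = FALSE])
    sg <- apply(x[train, , drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    x <- sweep(sweep(x, 2, mu), 2, sg, "/")
  }
  dtrain <- xgboost::xgb.DMatrix(x[train, , drop = FALSE], label = y[train])
  dtest <- xgboost::xgb.DMatrix(x[!train, , drop = FALSE], label = y[!train])
  grid <- expand.grid(eta = config$learning_rate_grid,
                      lambda = config$lambda_grid,
                      scale_pos_weight = config$scale_pos_weight_grid,
                      KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    fit <- fit_one(dtrain, dtest,
                   list(eta = grid$eta[g], lambda = grid$lambda[g],
                        scale_pos_weight = grid$scale_pos_weight[g]),
                   config)
    p <- stats::predict(fit$model, dtest)  # honors the early-stopped best iteration
    pred <- as.integer(p >= 0.5)
    tp <- sum(pred == 1 & y[!train] == 1)
    tn <- sum(pred == 0 & y[!train] == 0)
    fp <- sum(pred == 1 & y[!train] == 0)
    fn <- sum(pred == 0 & y[!train] == 1)
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    bal <- (sens + spec) / 2
    cand <- list(fit = fit, params = grid[g, ], bal = bal, p = p,
                 conf = matrix(c(tn, fp, fn, tp), 2, 2,
                               dimnames = list(predicted = c("neg", "pos"),
                                               truth = c("neg", "pos"))),
                 sens = sens, spec = spec,
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
    if (is.null(best) || cand$bal > best$bal ||
        (cand$bal == best$bal &&
           isTRUE(cand$fit$best_score > best$fit$best_score)))
      best <- cand
  }
  auc <- roc_auc(as.character(labels[!train]),
                 best$p, positive)
  cv <- NULL
  if (run_cv)
    cv <- cross_validate(features, config, params = as.list(best$params))
  imp <- xgboost::xgb.importance(model = best$fit$model)
  structure(list(balanced_accuracy = best$bal, roc_auc = auc,
                 validation_score = best$fit$best_score,
                 confusion = best$conf,
                 sensitivity = best$sens, specificity = best$spec,
                 precision = best$precision,
                 best_params = as.list(best$params),
                 best_iteration = best$fit$best_iteration,
                 cv = cv, importance = imp, model = best$fit$model,
                 positive = positive,
                 train_ids = rownames(features$x)[train],
                 test_ids = rownames(features$x)[!train],
                 test_scores = stats::setNames(best$p,
                                               rownames(features$x)[!train]),
                 regions = features$regions,
                 n_features = ncol(features$x)),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf(paste0("model_report: %d features; balanced accuracy %.3f, ",
                     "ROC AUC %.3f, validation (best AUC-PR) %.3f\n"),
              x$n_features, x$balanced_accuracy, x$roc_auc,
              x$validation_score))
  cat("  params: eta", x$best_params$eta, "lambda", x$best_params$lambda,
      "scale_pos_weight", x$best_params$scale_pos_weight,
      "best iteration", x$best_iteration, "\n")
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Stratified folds over the full sample set; per fold the model is
#' trained on the remainder with AUC-PR early stopping monitored on the
#' fold, recording the best AUC-PR and the round achieving it.
#'
#' @param features A `feature_matrix` with labels.
#' @param config A `train_config` (`cv_folds` folds).
#' @param params Hyperparameters (`eta`, `lambda`, `scale_pos_weight`);
#'   defaults to the first grid point.
#' @param k Number of folds; overrides `config$cv_folds`.
#' @param positive Positive-class label.
#' @return List with `folds` (data.table: fold, best_aucpr, best_round),
#'   `mean_aucpr`, `sd_aucpr`.
#' @export
cross_validate <- function(features, config = train_config(), params = NULL,
                           k = NULL, positive = "cancer") {
  stopifnot(inherits(features, "feature_matrix"))
  labels <- as.character(features$labels)
  classes <- sort(unique(labels))
  stopifnot(length(classes) == 2)
  if (!positive %in% classes) positive <- classes[2]
  if (is.null(k)) k <- config$cv_folds
  if (k > min(table(labels)))
    stop("k = ", k, " exceeds the smaller class size; ",
         "stratified folds are impossible")
  if (is.null(params))
    params <- list(eta = config$learning_rate_grid[1],
                   lambda = config$lambda_grid[1],
                   scale_pos_weight = config$scale_pos_weight_grid[1])
  params <- params[c("eta", "lambda", "scale_pos_weight")]
  y <- as.integer(labels == positive)
  fold <- integer(length(y))
  fold[] <- with_seed(config$seed + 1L, {
    f <- integer(length(y))
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  res <- data.table::data.table(fold = seq_len(k), best_aucpr = NA_real_,
                                best_round = NA_integer_)
  for (fk in seq_len(k)) {
    tr <- fold != fk
    dtrain <- xgboost::xgb.DMatrix(features$x[tr, , drop = FALSE],
                                   label = y[tr])
    dtest <- xgboost::xgb.DMatrix(features$x[!tr, , drop = FALSE],
                                  label = y[!tr])
    fit <- fit_one(dtrain, dtest, params, config)
    res$best_aucpr[fk] <- fit$best_score
    res$best_round[fk] <- fit$best_iteration
  }
  list(folds = res, mean_aucpr = mean(res$best_aucpr),
       sd_aucpr = stats::sd(res$best_aucpr))
}

#' Ranked feature importances mapped to regions
#'
#' Features with nonzero gain from the trained booster, ranked by total
#' gain and mapped back to their genomic intervals; optionally annotated
#' with the nearest gene.
#'
#' @param report A `model_report`.
#' @param top_n Truncate to the top n features (`NULL` keeps all nonzero
#'   gain features).
#' @param genes Optional `gene_model` for nearest-gene annotation.
#' @param max_dist Nearest-gene cutoff (bp).
#' @return data.table: rank, feature, gain, chrom, start, end (0-based
#'   half-open), and gene_id/distance when `genes` is given.
#' @export
feature_importance <- function(report, top_n = NULL, genes = NULL,
                               max_dist = 1e5) {
  stopifnot(inherits(report, "model_report"))
  imp <- report$importance
  if (is.null(imp) || nrow(imp) == 0)
    return(data.table::data.table(rank = integer(), feature = character(),
                                  gain = numeric()))
  out <- data.table::data.table(rank = seq_len(nrow(imp)),
                                feature = imp$Feature, gain = imp$Gain)
  if (!is.null(top_n)) out <- out[seq_len(min(top_n, nrow(out))), ]
  regions <- report$regions
  if (!is.null(regions)) {
    hit <- regions[out$feature]
    out$chrom <- as.character(GenomicRanges::seqnames(hit))
    out$start <- GenomicRanges::start(hit) - 1L
    out$end <- GenomicRanges::end(hit)
    if (!is.null(genes)) {
      ng <- nearest_gene(hit, genes, max_dist = max_dist)
      out$gene_id <- ng$gene_id
      out$gene_distance <- ng$distance
    }
  }
  out
}

#' Compare classification feature spaces
#'
#' Trains the classifier on the four canonical feature spaces plus a
#' matched random-background control: (1) whole-genome coverage in
#' `bin_size` bins; (2) `expand`-bp windows at the tumor open-chromatin
#' catalog; (3) the same at the immune catalog; (4) the combined
#' catalogs; and a control of random regions matched in number and size
#' to the combined space. Coverage is extracted once per sample across
#' all spaces.
#'
#' @param cohort A [simulate_cohort()] result (or an equivalent list with
#'   `samples`, `genome`, and `truth$samples` / `truth$catalogs`).
#' @param config A `train_config`.
#' @param expand Width (bp) peaks are expanded to (default 10 kb).
#' @param bin_size Whole-genome bin size (default 10 kb).
#' @param models Subset of `c("whole_genome", "tumor_peaks",
#'   "immune_peaks", "combined", "background")` to run.
#' @param target_depth Coverage normalization depth.
#' @return List with `reports` (named `model_report`s) and `table`
#'   (data.table summary).
#' @export
model_comparison <- function(cohort, config = train_config(),
                             expand = 1e4, bin_size = 1e4,
                             models = c("whole_genome", "tumor_peaks",
                                        "immune_peaks", "combined",
                                        "background"),
                             target_depth = 1e7) {
  genome <- cohort$genome
  labels <- stats::setNames(cohort$truth$samples$label,
                            cohort$truth$samples$sample)
  combined_raw <- merge_region_sets(list(cohort$truth$catalogs$tumor,
                                         cohort$truth$catalogs$immune),
                                    id_prefix = "combined")
  spaces <- list()
  if ("whole_genome" %in% models)
    spaces$whole_genome <- bin_genome(genome, bin_size)
  if ("tumor_peaks" %in% models)
    spaces$tumor_peaks <- extend_intervals(cohort$truth$catalogs$tumor, expand)
  if ("immune_peaks" %in% models)
    spaces$immune_peaks <- extend_intervals(cohort$truth$catalogs$immune,
                                            expand)
  if (any(c("combined", "background") %in% models))
    spaces$combined <- extend_intervals(combined_raw, expand)
  if ("background" %in% models)
    spaces$background <- random_background(spaces$combined, genome,
                                           seed = config$seed)
  ## one coverage pass across all spaces
  all_regions <- suppressWarnings(do.call(c, unname(lapply(
    names(spaces), function(nm) {
      gr <- spaces[[nm]]
      names(gr) <- paste0(nm, "|", names(gr))
      gr
    }))))
  fm_all <- build_feature_matrix(cohort$samples, all_regions, genome,
                                 labels = labels,
                                 target_depth = target_depth)
  tag <- sub("\\|.*$", "", colnames(fm_all$x))
  reports <- list()
  for (nm in setdiff(names(spaces),
                     if (!"combined" %in% models) "combined" else character())) {
    cols <- tag == nm
    fm <- structure(list(x = fm_all$x[, cols, drop = FALSE],
                         regions = stats::setNames(
                           fm_all$regions[cols],
                           sub("^[^|]*\\|", "",
                               names(fm_all$regions[cols]))),
                         labels = fm_all$labels),
                    class = "feature_matrix")
    colnames(fm$x) <- names(fm$regions)
    reports[[nm]] <- train_classifier(fm, config, run_cv = FALSE)
  }
  tab <- data.table::rbindlist(lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.table::data.table(model = nm, n_features = r$n_features,
                           balanced_accuracy = r$balanced_accuracy,
                           roc_auc = r$roc_auc,
                           validation_score = r$validation_score)
  }))
  list(reports = reports, table = tab)
}
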