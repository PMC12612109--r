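test_that("feature matrix equals a brute-force coverage mean", {
  g <- c(chrA = 20000L)
  set.seed(71)
  frs <- lapply(1:3, function(i) {
    s <- sample(0:19000, 200, replace = TRUE)
    make_fragments("chrA", s, pmin(s + sample(80:400, 200, TRUE), 20000L))
  })
  names(frs) <- paste0("s", 1:3)
  reg <- region_set("chrA", c(1000L, 5000L, 9000L, 13000L, 17000L),
                    c(2000L, 6000L, 10000L, 14000L, 18000L), genome = g)
  fm <- build_feature_matrix(frs, reg, g, target_depth = 1e4)
  for (j in 1:3) {
    ora <- oracle_pileup(frs[[j]], g, 1e4)$chrA
    for (k in 1:5) {
      idx <- (GenomicRanges::start(reg)[k]):(GenomicRanges::end(reg)[k])
      expect_equal(unname(fm$x[j, k]), mean(ora[idx]))
    }
  }
  ## uniform coverage yields a constant feature; empty regions yield 0 not NA
  flat <- list(u = make_fragments("chrA", 0L, 20000L))
  fmu <- build_feature_matrix(flat, reg, g, target_depth = 1)
  expect_true(all(fmu$x == 1))
  empty_reg <- region_set("chrA", 19900L, 19990L, g)
  fme <- build_feature_matrix(list(s = frs[[1]][1:2, ]), empty_reg, g)
  expect_false(anyNA(fme$x))
})

test_that("random backgrounds preserve lengths, avoid overlap and exclusions", {
  g <- c(chr1 = 5e7, chr2 = 5e7, chrM = 20000L, chrY = 1e6,
         chrUn_x = 1e6, chr1_random = 1e6)
  set.seed(72)
  w <- rep(10000L, 500)
  template <- region_set("chr1", seq(0, by = 20000, length.out = 500),
                         seq(0, by = 20000, length.out = 500) + w,
                         genome = g)
  bg <- random_background(template, g, seed = 9)
  expect_equal(length(bg), 500)
  expect_equal(sort(GenomicRanges::width(bg)),
               sort(GenomicRanges::width(template)))
  expect_true(IRanges::isDisjoint(bg))
  expect_false(any(as.character(GenomicRanges::seqnames(bg)) %in%
                     c("chrM", "chrY", "chrUn_x", "chr1_random")))
  ## deterministic under seed, different across seeds
  bg2 <- random_background(template, g, seed = 9)
  expect_equal(GenomicRanges::start(bg), GenomicRanges::start(bg2))
  expect_false(identical(
    GenomicRanges::start(random_background(template, g, seed = 10)),
    GenomicRanges::start(bg)))
  ## single interval and infeasible templates
  one <- random_background(template[1], g, seed = 1)
  expect_equal(GenomicRanges::width(one), 10000L)
  big <- region_set("chr1", 0L, 4e7, c(chr1 = 5e7))
  expect_error(random_background(c(big, big, big), c(chr1 = 5e7)),
               "infeasible")
})

test_that("classifier separates separable data and is deterministic", {
  set.seed(73)
  n <- 40
  ## f1 is constant within class: separable for any split between 0 and 10
  x <- cbind(f1 = rep(c(0, 10), each = n / 2),
             f2 = rnorm(n))
  rownames(x) <- paste0("s", 1:n)
  g <- c(chrA = 1e6)
  reg <- region_set("chrA", c(0L, 1000L), c(500L, 1500L), g,
                    id = c("f1", "f2"))
  fm <- structure(list(x = x, regions = reg,
                       labels = stats::setNames(
                         rep(c("healthy", "cancer"), each = n / 2),
                         rownames(x))),
                  class = "feature_matrix")
  cfg <- train_config(learning_rate_grid = c(0.1, 0.3), lambda_grid = 1,
                      scale_pos_weight_grid = 1, seed = 5)
  rep1 <- train_classifier(fm, cfg)
  expect_equal(rep1$balanced_accuracy, 1)
  expect_equal(rep1$roc_auc, 1)
  expect_equal(rep1$balanced_accuracy,
               (rep1$sensitivity + rep1$specificity) / 2)
  expect_equal(sum(rep1$confusion), length(rep1$test_ids))
  ## single informative feature carries all the gain
  imp <- feature_importance(rep1)
  expect_equal(imp$feature[1], "f1")
  expect_equal(sum(imp$gain), 1, tolerance = 1e-6)
  ## determinism
  rep2 <- train_classifier(fm, cfg)
  expect_equal(rep1$test_scores, rep2$test_scores)
  expect_equal(rep1$best_params, rep2$best_params)
  ## labels must exist and be two-class
  fm_bad <- fm; fm_bad$labels <- NULL
  expect_error(train_classifier(fm_bad, cfg), "labels")
})

test_that("cross-validation guards stratification and scores separable data", {
  set.seed(74)
  n <- 24
  x <- cbind(f1 = rep(c(0, 10), each = n / 2), f2 = rnorm(n))
  rownames(x) <- paste0("s", 1:n)
  fm <- structure(list(x = x, regions = NULL,
                       labels = stats::setNames(
                         rep(c("healthy", "cancer"), each = n / 2),
                         rownames(x))),
                  class = "feature_matrix")
  cfg <- train_config(learning_rate_grid = 0.3, lambda_grid = 1,
                      scale_pos_weight_grid = 1, cv_folds = 3, seed = 5)
  cv <- cross_validate(fm, cfg)
  expect_equal(nrow(cv$folds), 3)
  expect_equal(cv$mean_aucpr, 1, tolerance = 0.01)
  ## duplicated samples give near-identical fold scores
  xdup <- x[rep(c(1:6, 13:18), 2), ]
  rownames(xdup) <- paste0("d", 1:24)
  fmd <- fm; fmd$x <- xdup
  fmd$labels <- stats::setNames(rep(rep(c("healthy", "cancer"), each = 6), 2),
                                rownames(xdup))
  cvd <- cross_validate(fmd, cfg)
  expect_lt(cvd$sd_aucpr, 0.05)
  ## k beyond the smaller class size is refused
  expect_error(cross_validate(fm, cfg, k = 13), "class size")
})

test_that("permuted labels destroy classifier signal", {
  fm <- m4_features()
  lab <- fm$labels
  cfg <- train_config(learning_rate_grid = 0.3, lambda_grid = 1,
                      scale_pos_weight_grid = 1, seed = 1)
  aucs <- vapply(1:3, function(k) {
    fmp <- fm
    set.seed(100 + k)
    fmp$labels <- stats::setNames(sample(as.character(lab)), names(lab))
    train_classifier(fmp, cfg, run_cv = FALSE)$roc_auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("model comparison ranks catalog-guided spaces above the control", {
  coh <- classification_cohort()
  cfg <- train_config(learning_rate_grid = c(0.1, 0.3, 0.5),
                      lambda_grid = c(1, 5),
                      scale_pos_weight_grid = 1, seed = 1)
  mc <- model_comparison(coh, cfg,
                         models = c("tumor_peaks", "immune_peaks",
                                    "combined", "background"))
  tab <- mc$table
  get <- function(m, col) tab[[col]][tab$model == m]
  ## combined catalogs perform at least as well as either alone (small slack)
  expect_gte(get("combined", "balanced_accuracy"),
             max(get("tumor_peaks", "balanced_accuracy"),
                 get("immune_peaks", "balanced_accuracy")) - 0.02)
  ## the immune catalog carries the planted signal; it beats the control
  expect_gt(get("immune_peaks", "roc_auc"), get("background", "roc_auc"))
  expect_gt(get("combined", "roc_auc"), get("background", "roc_auc"))
  ## deterministic given the seed
  expect_equal(get("combined", "roc_auc"),
               train_classifier(m4_features(), cfg, run_cv = FALSE)$roc_auc)
})
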