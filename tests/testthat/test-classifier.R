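test_that("training is seeded, reproducible, and validates its inputs", {
  subs <- small_cohort()
  fs <- extract_features(subs[[1]]$scan)
  m1 <- train_classifier(list(fs), list(subs[[1]]$labels),
                         rf_config(num_trees = 20, n_per_class = 200),
                         seed = 7)
  m2 <- train_classifier(list(fs), list(subs[[1]]$labels),
                         rf_config(num_trees = 20, n_per_class = 200),
                         seed = 7)
  p1 <- classify_voxels(m1, fs)
  p2 <- classify_voxels(m2, fs)
  expect_identical(p1$p, p2$p)
  expect_equal(rowSums(p1$p), rep(1, nrow(p1$p)), tolerance = 1e-12)
  # feature-count mismatch
  fs_bad <- fs; fs_bad$X <- fs$X[, 1:10]
  expect_error(classify_voxels(m1, fs_bad), "feature count")
})

test_that("a class missing from the training labels raises an informative error", {
  subs <- small_cohort()
  s <- subs[[1]]
  lab <- s$labels
  lab$labels[lab$labels == 3L] <- 0L  # delete the right lens
  fs <- extract_features(s$scan)
  expect_error(train_classifier(list(fs), list(lab), rf_config(num_trees = 5),
                                seed = 1),
               "lens_right")
})

test_that("the pipeline reproduces a noiseless phantom segmented against itself", {
  cfg <- small_cfg(noise_sd = 0)
  set.seed(31)
  s <- render_subject(cfg, "SELF")
  fs <- extract_features(s$scan)
  model <- train_classifier(list(fs), list(s$labels),
                            rf_config(n_per_class = 500), seed = 3)
  seg <- segment_scan(s$scan, list(s), model, seg_config(), features = NULL)
  for (cls in 1:6)
    expect_gte(dice(seg$labels == cls, s$labels$labels == cls), 0.95)
  # the voxel classifier alone recovers essentially every eye voxel (sides
  # pooled, since local features carry no laterality); specificity outside
  # the eyes is the atlas product's job
  p <- classify_voxels(model, fs)
  lab <- array(max.col(p$p, "first") - 1L, dim(s$labels$labels))
  for (cls in list(c(1, 2), c(3, 4), c(5, 6))) {
    truth_cls <- s$labels$labels %in% cls
    recall <- sum(lab[truth_cls] %in% cls) / sum(truth_cls)
    expect_gte(recall, 0.95)
  }
})

test_that("shuffled training labels drive held-out PS Dice to chance", {
  subs <- small_cohort()
  tr <- subs[[2]]
  te <- subs[[3]]
  lab_shuf <- tr$labels
  set.seed(5)
  lab_shuf$labels <- array(sample(as.integer(tr$labels$labels)),
                           dim(tr$labels$labels))
  fs <- extract_features(tr$scan)
  model <- train_classifier(list(fs), list(lab_shuf),
                            rf_config(num_trees = 50, n_per_class = 400),
                            seed = 1)
  p <- classify_voxels(model, extract_features(te$scan))
  lab <- array(max.col(p$p, "first") - 1L, dim(te$labels$labels))
  expect_lt(dice(lab == 1, te$labels$labels == 1), 0.5)
})

test_that("label noise in training never improves held-out Dice", {
  cfg <- small_cfg()
  set.seed(21)
  subs <- lapply(1:3, function(i) render_subject(cfg, sprintf("N%d", i)))
  te <- render_subject(cfg, "TEST")
  fss <- lapply(subs, function(s) extract_features(s$scan))
  te_fs <- extract_features(te$scan)
  flip_labels <- function(lm, rate, seed) {
    if (rate == 0) return(lm)
    set.seed(seed)
    lab <- as.integer(lm$labels)
    n <- length(lab)
    pick <- sample(n, round(rate * n))
    lab[pick] <- (lab[pick] + sample(1:6, length(pick), replace = TRUE)) %% 7L
    lm$labels <- array(lab, dim(lm$labels))
    lm
  }
  rf <- rf_config(num_trees = 40, n_per_class = 300)
  mean_dice_at <- function(rate, seed) {
    labs <- lapply(seq_along(subs),
                   function(i) flip_labels(subs[[i]]$labels, rate,
                                           seed + i))
    model <- train_classifier(fss, labs, rf, seed = seed)
    seg <- segment_scan(te$scan,
                        purrr::map2(subs, labs,
                                    function(s, l) list(scan = s$scan,
                                                        labels = l)),
                        model, seg_config(rf = rf), features = te_fs)
    mean(oculometry:::dice_per_class(seg, te$labels)$dice)
  }
  for (seed in c(101, 202, 303)) {
    d <- vapply(c(0, 0.1, 0.3), mean_dice_at, numeric(1), seed = seed)
    expect_gte(d[1], d[2] - 0.005)
    expect_gte(d[2], d[3] - 0.005)
  }
})
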