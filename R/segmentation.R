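#' Registration settings
#'
#' Controls the intensity-based registration used to transfer atlas labels.
#' The default is an affine transform estimated from intensity moments
#' (centroid and second-moment matching of the bright ocular fluid) and then
#' refined by minimizing the mean-squared intensity difference on a
#' downsampled grid (Nelder-Mead). Moment matching alone is available with
#' `refine = FALSE`; `family = "translation"` restricts to centroid matching.
#'
#' @param family `"affine"` (default) or `"translation"`.
#' @param bright_threshold Intensity above which voxels count as ocular fluid
#'   for the moment estimate.
#' @param refine Run the MSE refinement stage?
#' @param downsample Integer downsampling factor for the first refinement
#'   stage (the second runs at half that, minimum 2).
#' @param maxit,maxit2 Maximum Nelder-Mead iterations for the coarse and
#'   fine refinement stages.
#' @param interpolation Label resampling: `"linear"` warps the one-hot label
#'   encoding with trilinear weights (soft probabilities, default) or
#'   `"nearest"`.
#' @param min_overlap Minimum fraction of the target's bright voxels that must
#'   map inside the atlas grid; below this the registration is flagged as
#'   diverged and the atlas is excluded from fusion.
#' @return A list of class `reg_config`.
#' @export
reg_config <- function(family = c("affine", "translation"),
                       bright_threshold = 650, refine = TRUE,
                       downsample = 4L, maxit = 150L, maxit2 = 150L,
                       interpolation = c("linear", "nearest"),
                       min_overlap = 0.5) {
  structure(list(family = match.arg(family),
                 bright_threshold = bright_threshold, refine = refine,
                 downsample = as.integer(downsample),
                 maxit = as.integer(maxit), maxit2 = as.integer(maxit2),
                 interpolation = match.arg(interpolation),
                 min_overlap = min_overlap),
            class = "reg_config")
}

# cached smoothed/downsampled pyramid used by the registration refinement;
# computing it once per subject avoids repeating the smoothing for every
# atlas-target pair
scan_pyramid <- function(scan, levels = c(4L, 2L)) {
  dims <- grid_dim(scan)
  out <- lapply(unique(levels), function(ds)
    smooth_downsample(as.numeric(scan$data), dims, ds))
  names(out) <- as.character(unique(levels))
  out
}

sqrtm_sym <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 1e-12))) %*% t(e$vectors)
}

bright_moments <- function(scan, threshold) {
  idx <- which(scan$data > threshold)
  if (length(idx) < 10) return(NULL)
  ijk <- arrayInd(idx, dim(scan$data)) - 1
  w <- vox_to_world(scan, ijk)
  list(mu = colMeans(w), sigma = stats::cov(w), n = length(idx))
}

# voxel->world and world->voxel 3x4 affine pieces
v2w <- function(grid) list(A = grid$orientation %*% diag(grid$spacing),
                           b = grid$origin)
w2v <- function(grid) {
  A <- diag(1 / grid$spacing) %*% t(grid$orientation)
  list(A = A, b = -A %*% grid$origin)
}

smooth_downsample <- function(vol, dims, ds) {
  if (ds > 1) {
    k <- gauss_kernel(ds / 2, 1, 0)
    v <- conv3_sep(vol, dims, k, k, k)
    arr <- array(v, dims)
    arr[seq(1, dims[1], by = ds), seq(1, dims[2], by = ds),
        seq(1, dims[3], by = ds), drop = FALSE]
  } else {
    array(vol, dims)
  }
}

#' Register one atlas to a target scan and warp its labels
#'
#' Estimates the spatial transform from the target to the atlas (affine by
#' default; see [reg_config()]) and resamples the atlas label map into the
#' target grid as per-class probabilities: trilinear interpolation of the
#' one-hot label encoding (soft) or nearest-neighbour indicators. Identity
#' inputs return the atlas labels unchanged.
#'
#' @param atlas_scan,atlas_labels The atlas [scan_volume()] and its
#'   [ocular_label_map()].
#' @param target_scan The target [scan_volume()].
#' @param config A [reg_config()].
#' @param atlas_pyramid,target_pyramid Optional precomputed refinement
#'   pyramids (internal caching for repeated registrations).
#' @return A list of class `warped_atlas`: `weights` (voxels x 7 per-class
#'   probability matrix on the target grid, or `NULL` when diverged),
#'   `diverged`, `world_transform` (`A`, `t` mapping target-world to
#'   atlas-world mm), and `mse`.
#' @export
register_atlas <- function(atlas_scan, atlas_labels, target_scan,
                           config = reg_config(), atlas_pyramid = NULL,
                           target_pyramid = NULL) {
  stopifnot(inherits(atlas_scan, "scan_volume"),
            inherits(target_scan, "scan_volume"))
  if (!grid_compatible(atlas_scan, atlas_labels))
    abort("atlas scan and atlas labels are on different grids")
  K <- length(ocular_codebook())
  mt <- bright_moments(target_scan, config$bright_threshold)
  ma <- bright_moments(atlas_scan, config$bright_threshold)
  diverged_out <- function() {
    structure(list(weights = NULL, diverged = TRUE, world_transform = NULL,
                   mse = NA_real_), class = "warped_atlas")
  }
  if (is.null(mt) || is.null(ma)) return(diverged_out())

  # world-space initialization: w_a = Aw (w_t - mu_t) + mu_a
  if (config$family == "affine") {
    Aw <- sqrtm_sym(ma$sigma) %*% solve(sqrtm_sym(mt$sigma))
  } else {
    Aw <- diag(3)
  }
  tw <- as.numeric(ma$mu - Aw %*% mt$mu)

  # compose into voxel space: v_a = M v_t + m
  va <- w2v(atlas_scan); vt <- v2w(target_scan)
  M <- va$A %*% Aw %*% vt$A
  m <- as.numeric(va$A %*% (Aw %*% vt$b + tw) + va$b)

  dims_t <- grid_dim(target_scan); dims_a <- grid_dim(atlas_scan)
  mse <- NA_real_
  if (config$refine) {
    # multi-resolution MSE refinement: coarse-to-fine pyramid ending at
    # half resolution
    levels <- unique(c(config$downsample, max(2L, config$downsample %/% 2L)))
    if (is.null(target_pyramid))
      target_pyramid <- scan_pyramid(target_scan, levels)
    if (is.null(atlas_pyramid))
      atlas_pyramid <- scan_pyramid(atlas_scan, levels)
    maxits <- c(config$maxit, config$maxit2)
    for (li in seq_along(levels)) {
      ds <- levels[li]
      tg_d <- target_pyramid[[as.character(ds)]]
      at_d <- atlas_pyramid[[as.character(ds)]]
      dims_td <- dim(tg_d); dims_ad <- dim(at_d)
      fill <- stats::median(at_d)
      obj <- function(p) {
        Mi <- matrix(p[1:9], 3, 3)
        mi <- p[10:12]
        r <- affine_resample_cpp(as.numeric(at_d), dims_ad, dims_td,
                                 Mi, mi, fill = fill)
        mean((r - as.numeric(tg_d))^2)
      }
      p0 <- c(as.numeric(M), m / ds)
      fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                          control = list(maxit = maxits[li],
                                         reltol = 1e-7))
      if (is.finite(fit$value) && fit$value <= obj(p0)) {
        M <- matrix(fit$par[1:9], 3, 3)
        m <- fit$par[10:12] * ds
        mse <- fit$value
      }
    }
  }

  # overlap check on the target's bright voxels
  idx <- which(target_scan$data > config$bright_threshold)
  if (length(idx) > 4000) idx <- idx[seq(1, length(idx), length.out = 4000)]
  ijk <- arrayInd(idx, dims_t) - 1
  mapped <- ijk %*% t(M) + matrix(m, nrow(ijk), 3, byrow = TRUE)
  inside <- mapped[, 1] >= 0 & mapped[, 1] <= dims_a[1] - 1 &
    mapped[, 2] >= 0 & mapped[, 2] <= dims_a[2] - 1 &
    mapped[, 3] >= 0 & mapped[, 3] <= dims_a[3] - 1
  if (mean(inside) < config$min_overlap) return(diverged_out())

  Wm <- warp_labels_onehot_cpp(as.integer(atlas_labels$labels), dims_a,
                               dims_t, M, m, K,
                               nearest = config$interpolation == "nearest")
  colnames(Wm) <- names(ocular_codebook())
  # recover the world transform implied by the (possibly refined) voxel map
  wa <- v2w(atlas_scan); wt <- w2v(target_scan)
  Aw_out <- wa$A %*% M %*% wt$A
  tw_out <- as.numeric(wa$A %*% (M %*% wt$b + m) + wa$b)
  structure(list(weights = Wm, diverged = FALSE,
                 world_transform = list(A = Aw_out, t = tw_out),
                 mse = mse,
                 grid = list(dim = dims_t, spacing = target_scan$spacing,
                             origin = target_scan$origin,
                             orientation = target_scan$orientation)),
            class = "warped_atlas")
}

new_class_prob_map <- function(p, grid) {
  structure(list(p = p, dim = grid$dim, spacing = grid$spacing,
                 origin = grid$origin, orientation = grid$orientation),
            class = "class_prob_map")
}

#' @export
print.class_prob_map <- function(x, ...) {
  cat("<class_prob_map>", nrow(x$p), "voxels x", ncol(x$p), "classes\n")
  invisible(x)
}

#' Fuse warped atlas label sets into a class-probability map
#'
#' Per-voxel class frequency across the (non-diverged) warped atlases,
#' normalized to sum to 1. Diverged registrations are excluded with a
#' warning.
#'
#' @param warped A list of [register_atlas()] results (or bare voxels x 7
#'   weight matrices sharing a grid).
#' @return A `class_prob_map` (voxels x 7 probability matrix plus grid
#'   metadata).
#' @export
fuse_atlases <- function(warped) {
  if (length(warped) == 0) abort("no warped atlases to fuse")
  is_obj <- vapply(warped, inherits, logical(1), "warped_atlas")
  if (any(is_obj)) {
    div <- vapply(warped[is_obj], function(w) w$diverged, logical(1))
    if (any(div))
      warn(sprintf("excluding %d diverged registration(s) from fusion",
                   sum(div)))
  }
  mats <- list(); grid <- NULL
  for (w in warped) {
    if (inherits(w, "warped_atlas")) {
      if (w$diverged) next
      mats <- c(mats, list(w$weights))
      grid <- grid %||% w$grid
    } else {
      mats <- c(mats, list(w))
    }
  }
  if (length(mats) == 0) abort("all registrations diverged; nothing to fuse")
  acc <- mats[[1]]
  if (length(mats) > 1) for (i in 2:length(mats)) acc <- acc + mats[[i]]
  acc <- acc / rowSums(acc)
  if (is.null(grid))
    grid <- list(dim = c(nrow(acc), 1L, 1L), spacing = c(1, 1, 1),
                 origin = c(0, 0, 0), orientation = diag(3))
  new_class_prob_map(acc, grid)
}

#' Random-forest settings for the voxel classifier
#'
#' @param num_trees Number of trees (default 100).
#' @param mtry Features tried per split; default `floor(sqrt(48)) = 6`.
#' @param min_node_size Minimal node size (1 = fully grown trees).
#' @param n_per_class Voxels sampled per class per training subject
#'   (class-balanced subsampling; capped at 20000).
#' @param boundary_frac Fraction of each class's sample drawn from label
#'   boundary voxels (a voxel whose 6-neighbourhood contains another class).
#'   Class boundaries are where segmentation decisions happen, so enriching
#'   them makes a small sample far more informative than uniform sampling.
#' @param sample_fraction Fraction of the training rows bagged per tree
#'   (drawn without replacement when below 1).
#' @param num_threads Threads for ranger (1 keeps runs deterministic).
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(num_trees = 100L, mtry = NULL, min_node_size = 5L,
                      n_per_class = 800L, boundary_frac = 0.5,
                      sample_fraction = 0.5, num_threads = 1L) {
  structure(list(num_trees = as.integer(num_trees), mtry = mtry,
                 min_node_size = as.integer(min_node_size),
                 n_per_class = as.integer(min(n_per_class, 20000L)),
                 boundary_frac = boundary_frac,
                 sample_fraction = sample_fraction,
                 num_threads = as.integer(num_threads)),
            class = "rf_config")
}

# voxels whose 6-neighbourhood contains a different label
boundary_voxels <- function(lab) {
  d <- dim(lab)
  b <- array(FALSE, d)
  shift1 <- function(a, ax, by) {
    idx <- rep(list(quote(expr = )), 3)
    idx[[ax]] <- pmin(pmax(seq_len(d[ax]) + by, 1L), d[ax])
    do.call(`[`, c(list(a), idx))
  }
  for (ax in 1:3) for (s in c(-1L, 1L)) b <- b | (shift1(lab, ax, s) != lab)
  b
}

# class-balanced subsample with boundary enrichment: per class, up to
# boundary_frac of the rows come from label-boundary voxels; large classes
# are subsampled without replacement, rare classes (e.g. the ~84-voxel lens)
# are oversampled with replacement so class priors stay flat
sample_training_rows <- function(feature_stack, label_map, n_per_class,
                                 boundary_frac = 0.5, candidates = NULL) {
  lab <- as.integer(label_map$labels)
  bnd <- as.vector(boundary_voxels(label_map$labels))
  keep_idx <- integer()
  for (code in unname(ocular_codebook())) {
    idx <- which(lab == code)
    if (!is.null(candidates)) idx <- intersect(idx, candidates)
    if (length(idx) == 0) next
    ib <- idx[bnd[idx]]
    nb <- min(length(ib), round(n_per_class * boundary_frac))
    nu <- n_per_class - nb
    pick <- c(if (nb > 0) sample(ib, nb) else integer(),
              if (length(idx) >= nu) sample(idx, nu)
              else sample(idx, nu, replace = TRUE))
    keep_idx <- c(keep_idx, pick)
  }
  list(X = feature_stack$X[keep_idx, , drop = FALSE], y = lab[keep_idx])
}

# margin (voxels) needed so cropped-box features equal full-volume features
feature_margin <- function(spacing, scales = c(1, 1.6, 4)) {
  as.integer(ceiling(3.5 * max(scales) / min(spacing))) + 1L
}

crop_box <- function(idx_arr, dims, margin) {
  lo <- pmax(apply(idx_arr, 2, min) - margin, 1L)
  hi <- pmin(apply(idx_arr, 2, max) + margin, dims)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

crop_scan <- function(scan, box) {
  arr <- scan$data[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2],
                   box$lo[3]:box$hi[3], drop = FALSE]
  scan_volume(arr, spacing = scan$spacing,
              origin = scan$origin +
                as.numeric(scan$orientation %*%
                             (scan$spacing * (box$lo - 1))),
              orientation = scan$orientation, subject_id = scan$subject_id)
}

# linear indices in the cropped box for global linear indices
global_to_local <- function(idx, dims, box) {
  a <- arrayInd(idx, dims)
  bd <- box$hi - box$lo + 1L
  (a[, 1] - box$lo[1] + 1L) +
    (a[, 2] - box$lo[2]) * bd[1] +
    (a[, 3] - box$lo[3]) * bd[1] * bd[2]
}

# one feature pass per training subject, restricted to a box around the
# labelled anatomy (plus the feature-support margin, so features match the
# full-volume computation exactly); background rows are drawn from the same
# box, matching the region the classifier is evaluated on at test time
subject_training_sample <- function(scan, labels, rf) {
  dims <- grid_dim(scan)
  fg <- which(labels$labels > 0L)
  if (length(fg) == 0) abort("label map has no foreground")
  box <- crop_box(arrayInd(fg, dims), dims, feature_margin(scan$spacing))
  sub_scan <- crop_scan(scan, box)
  sub_lab <- ocular_label_map(
    labels$labels[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2],
                  box$lo[3]:box$hi[3], drop = FALSE],
    spacing = sub_scan$spacing, origin = sub_scan$origin,
    orientation = sub_scan$orientation)
  fs <- extract_features(sub_scan)
  sample_training_rows(fs, sub_lab, rf$n_per_class, rf$boundary_frac)
}

#' Train the random-forest voxel classifier
#'
#' Trains a probability forest mapping each voxel's 48-feature vector to a
#' 7-class probability vector, using ground-truth segmentation labels.
#' Training voxels are subsampled per class per subject (class-balanced) and
#' the whole procedure is seeded and reproducible.
#'
#' @param feature_stacks List of [extract_features()] results (one per
#'   training subject).
#' @param label_maps List of matching [ocular_label_map()]s.
#' @param config An [rf_config()].
#' @param seed Integer seed.
#' @return An object of class `voxel_classifier`.
#' @export
train_classifier <- function(feature_stacks, label_maps,
                             config = rf_config(), seed = 1L) {
  if (length(feature_stacks) != length(label_maps) ||
      length(feature_stacks) == 0)
    abort("need matching non-empty lists of feature stacks and label maps")
  set.seed(seed)
  samples <- purrr::map2(feature_stacks, label_maps, sample_training_rows,
                         n_per_class = config$n_per_class,
                         boundary_frac = config$boundary_frac)
  train_classifier_from_samples(samples, config, seed)
}

# internal: train from pre-sampled {X, y} lists (used by cross_validate so
# each subject's features are extracted only once)
train_classifier_from_samples <- function(samples, config = rf_config(),
                                          seed = 1L) {
  X <- do.call(rbind, purrr::map(samples, "X"))
  y <- unlist(purrr::map(samples, "y"))
  codes <- ocular_codebook()
  missing <- setdiff(unname(codes), unique(y))
  if (length(missing))
    abort(paste0("classes absent from training data: ",
                 paste(names(codes)[match(missing, codes)], collapse = ", ")))
  yf <- factor(y, levels = unname(codes))
  forest <- ranger::ranger(
    x = X, y = yf, probability = TRUE,
    num.trees = config$num_trees,
    mtry = config$mtry %||% floor(sqrt(ncol(X))),
    min.node.size = config$min_node_size,
    sample.fraction = config$sample_fraction,
    replace = config$sample_fraction >= 1,
    num.threads = config$num_threads, seed = seed, verbose = FALSE)
  structure(list(forest = forest, feature_names = colnames(X),
                 classes = unname(codes), config = config, seed = seed),
            class = "voxel_classifier")
}

#' @export
print.voxel_classifier <- function(x, ...) {
  cat("<voxel_classifier>", x$forest$num.trees, "trees,",
      length(x$feature_names), "features\n")
  invisible(x)
}

predict_probs <- function(model, X) {
  if (ncol(X) != length(model$feature_names))
    abort(sprintf("feature count mismatch: model expects %d, got %d",
                  length(model$feature_names), ncol(X)))
  p <- predict(model$forest, data = X,
               num.threads = model$config$num_threads)$predictions
  # ranger orders columns by factor level = codebook order
  colnames(p) <- names(ocular_codebook())
  p
}

apply_background_bias <- function(p, background_bias) {
  if (background_bias <= 0 || background_bias > 1)
    abort("`background_bias` must be in (0, 1]")
  if (background_bias < 1) {
    p[, 1] <- p[, 1] * background_bias
    p <- p / rowSums(p)
  }
  p
}

#' Classify voxels with a trained forest, down-weighting background
#'
#' Applies the voxel classifier to a feature stack and multiplies the
#' background-class probability by `background_bias` before renormalizing.
#' The bias prevents interior eye voxels that locally resemble background
#' from being over-ruled; `background_bias = 1` is a no-op.
#'
#' @param model A [train_classifier()] result.
#' @param feature_stack An [extract_features()] result.
#' @param background_bias Multiplier in (0, 1] on the background probability.
#' @return A `class_prob_map` over the feature stack's grid.
#' @export
classify_voxels <- function(model, feature_stack, background_bias = 0.9) {
  p <- predict_probs(model, feature_stack$X)
  p <- apply_background_bias(p, background_bias)
  new_class_prob_map(p, list(dim = feature_stack$dim,
                             spacing = feature_stack$spacing,
                             origin = feature_stack$origin,
                             orientation = feature_stack$orientation))
}

#' Combine atlas and classifier probability maps into a segmentation
#'
#' Multiplies the two per-voxel class-probability maps elementwise — after
#' adding a small probability floor to the atlas map so that atlas zeros
#' cannot annihilate classifier evidence — and takes the per-voxel argmax as
#' the final label. Ties break deterministically toward the lower class code
#' (background first).
#'
#' @param atlas_map,classifier_map `class_prob_map`s on the same grid.
#' @param floor_eps Additive floor on the atlas probabilities (default 0.01).
#' @return An [ocular_label_map()].
#' @export
combine_maps <- function(atlas_map, classifier_map, floor_eps = 0.01) {
  if (!identical(dim(atlas_map$p), dim(classifier_map$p)) ||
      !identical(atlas_map$dim, classifier_map$dim))
    abort("atlas and classifier maps are on different grids")
  prod <- (atlas_map$p + floor_eps) * classifier_map$p
  lab <- max.col(prod, ties.method = "first") - 1L
  ocular_label_map(array(lab, atlas_map$dim), spacing = atlas_map$spacing,
                   origin = atlas_map$origin,
                   orientation = atlas_map$orientation)
}

#' Segmentation pipeline settings
#'
#' @param reg A [reg_config()].
#' @param rf An [rf_config()].
#' @param background_bias Background down-weight for [classify_voxels()].
#' @param floor_eps Atlas probability floor for [combine_maps()].
#' @param roi_prob,roi_sigma The classifier is evaluated only where the
#'   Gaussian-smoothed (sigma `roi_sigma` mm) fused non-background probability
#'   exceeds `roi_prob`; everything else is background. This is a
#'   computational restriction only — the margin is several voxels wide.
#' @param n_atlases Maximum number of atlases fused per target (a
#'   deterministic, evenly spaced subset of the available atlases);
#'   `NULL` uses all of them.
#' @param oracle If `TRUE` the pipeline predicts the ground-truth labels
#'   (upper-bound control for testing the evaluation plumbing).
#' @return A list of class `seg_config`.
#' @export
seg_config <- function(reg = reg_config(), rf = rf_config(),
                       background_bias = 0.9, floor_eps = 0.01,
                       roi_prob = 1e-4, roi_sigma = 2, n_atlases = 12L,
                       oracle = FALSE) {
  structure(list(reg = reg, rf = rf, background_bias = background_bias,
                 floor_eps = floor_eps, roi_prob = roi_prob,
                 roi_sigma = roi_sigma,
                 n_atlases = if (!is.null(n_atlases)) as.integer(n_atlases),
                 oracle = oracle),
            class = "seg_config")
}

#' Segment one scan with atlas fusion times voxel classification
#'
#' Registers every atlas to the target, fuses the warped labels into an atlas
#' probability map, evaluates the random-forest classifier (with background
#' bias) inside the atlas-supported region, multiplies the two maps and takes
#' the per-voxel argmax.
#'
#' @param scan Target [scan_volume()].
#' @param atlases List of atlases, each a list with elements `scan` and
#'   `labels`.
#' @param model A trained [train_classifier()] model.
#' @param config A [seg_config()].
#' @param features Optional precomputed [extract_features()] for `scan`.
#' @return An [ocular_label_map()] with attribute `n_roi` (number of voxels
#'   the classifier evaluated).
#' @export
segment_scan <- function(scan, atlases, model, config = seg_config(),
                         features = NULL) {
  if (!is.null(config$n_atlases) && length(atlases) > config$n_atlases)
    atlases <- atlases[round(seq(1, length(atlases),
                                 length.out = config$n_atlases))]
  levels <- unique(c(config$reg$downsample,
                     max(2L, config$reg$downsample %/% 2L)))
  target_pyr <- if (config$reg$refine) scan_pyramid(scan, levels) else NULL
  warped <- purrr::map(atlases, function(a)
    register_atlas(a$scan, a$labels, scan, config$reg,
                   atlas_pyramid = a$pyramid, target_pyramid = target_pyr))
  fused <- fuse_atlases(warped)
  dims <- grid_dim(scan)

  eye_p <- 1 - fused$p[, 1]
  k <- lapply(scan$spacing, function(h) gauss_kernel(config$roi_sigma, h, 0))
  eye_s <- conv3_sep(eye_p, dims, k[[1]], k[[2]], k[[3]])
  roi <- which(eye_s > config$roi_prob)

  labels <- array(0L, dims)
  if (length(roi) > 0) {
    if (is.null(features)) {
      # features are computed on a box around the ROI (plus the feature
      # support margin, so they equal the full-volume values on the ROI)
      box <- crop_box(arrayInd(roi, dims), dims,
                      feature_margin(scan$spacing))
      features <- extract_features(crop_scan(scan, box))
      rows <- global_to_local(roi, dims, box)
    } else {
      rows <- roi
    }
    p_cls <- predict_probs(model, features$X[rows, , drop = FALSE])
    p_cls <- apply_background_bias(p_cls, config$background_bias)
    prod <- (fused$p[roi, , drop = FALSE] + config$floor_eps) * p_cls
    labels[roi] <- max.col(prod, ties.method = "first") - 1L
  }
  out <- ocular_label_map(labels, spacing = scan$spacing,
                          origin = scan$origin,
                          orientation = scan$orientation,
                          subject_id = scan$subject_id)
  attr(out, "n_roi") <- length(roi)
  out
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; 1 is perfect overlap. By documented convention
#' two empty masks have Dice 1.
#'
#' @param mask_a,mask_b Logical (or 0/1) arrays on the same grid.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' a <- array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1))
#' b <- array(c(TRUE, FALSE, TRUE, FALSE), c(4, 1, 1))
#' dice(a, b)
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    abort("masks are on different grids")
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

dice_per_class <- function(pred, truth) {
  codes <- ocular_codebook()
  eye <- codes[names(codes) != "background"]
  purrr::map_dfr(names(eye), function(nm) {
    tibble(class = nm,
           dice = dice(pred$labels == eye[[nm]], truth$labels == eye[[nm]]))
  })
}

assign_folds <- function(n, k, groups = NULL) {
  if (k > n) abort("k exceeds the number of subjects")
  if (k < 2) abort("k must be at least 2")
  folds <- integer(n)
  if (is.null(groups)) groups <- rep("all", n)
  for (g in unique(groups)) {
    idx <- sample(which(groups == g))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' k-fold cross-validation of the segmentation pipeline
#'
#' Splits the labelled cohort into `k` seeded folds (stratified by refraction
#' group when available). In each fold the training split provides both the
#' atlases and the classifier's training voxels; every test subject is
#' segmented with [segment_scan()] and scored with per-class Dice against its
#' ground truth. The report gives the mean and SD per class over all test
#' subjects in all folds.
#'
#' @param cohort List of subjects, each a list with `scan`, `labels`, and
#'   optionally `id` and `group`.
#' @param k Number of folds (default 3).
#' @param config A [seg_config()].
#' @param seed Integer seed controlling folds, subsampling, and the forest.
#' @param return_predictions Keep each test subject's predicted label map?
#' @return An object of class `dice_report`: `summary` (class, mean, SD, n),
#'   `per_subject` (subject x class Dice), `folds`, and (optionally)
#'   `predictions`.
#' @export
cross_validate <- function(cohort, k = 3L, config = seg_config(), seed = 1L,
                           return_predictions = FALSE) {
  n <- length(cohort)
  set.seed(seed)
  groups <- purrr::map_chr(cohort, function(s) s$group %||% "all")
  ids <- purrr::imap_chr(cohort, function(s, i) s$id %||% sprintf("S%04d", i))
  folds <- assign_folds(n, k, groups)

  samples <- NULL
  if (!config$oracle) {
    # one feature pass per subject to draw its class-balanced training rows,
    # plus the cached registration pyramid reused across folds
    levels <- unique(c(config$reg$downsample,
                       max(2L, config$reg$downsample %/% 2L)))
    for (i in seq_len(n)) {
      if (config$reg$refine && is.null(cohort[[i]]$pyramid))
        cohort[[i]]$pyramid <- scan_pyramid(cohort[[i]]$scan, levels)
    }
    samples <- purrr::map(cohort, function(s)
      subject_training_sample(s$scan, s$labels, config$rf))
  }

  predictions <- if (return_predictions) vector("list", n) else NULL
  res <- purrr::map_dfr(seq_len(k), function(f) {
    train_idx <- which(folds != f)
    test_idx <- which(folds == f)
    model <- NULL
    if (!config$oracle)
      model <- train_classifier_from_samples(samples[train_idx], config$rf,
                                             seed = seed + f)
    purrr::map_dfr(test_idx, function(i) {
      pred <- if (config$oracle) cohort[[i]]$labels
              else segment_scan(cohort[[i]]$scan, cohort[train_idx], model,
                                config)
      if (return_predictions) predictions[[i]] <<- pred
      dd <- dice_per_class(pred, cohort[[i]]$labels)
      dd$subject_id <- ids[i]
      dd$fold <- f
      dd
    })
  })

  summary <- res |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(mean_dice = mean(.data$dice), sd_dice = sd(.data$dice),
                     n = dplyr::n(), .groups = "drop")
  structure(list(summary = summary, per_subject = res,
                 folds = tibble(subject_id = ids, fold = folds,
                                group = groups),
                 predictions = predictions,
                 k = k, seed = seed),
            class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat("<dice_report>", x$k, "folds,", nrow(x$folds), "subjects\n")
  print(x$summary)
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `dice_report`.
#' @param ... Unused.
#' @export
tidy.dice_report <- function(x, ...) x$summary

#' @rdname cross_validate
#' @param object A `dice_report`.
#' @export
autoplot.dice_report <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$class, y = .data$mean_dice)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(0, .data$mean_dice - .data$sd_dice),
      ymax = pmin(1, .data$mean_dice + .data$sd_dice)), width = 0.2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Dice similarity coefficient") +
    ggplot2::theme_minimal()
}
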