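small_dataset <- function(n = 8, size = 40) {
  suppressWarnings(generate_dataset(
    n, dir = NULL, seed = 2,
    benign = patch_params("benign", size = size),
    malignant = patch_params("malignant", size = size, n_blobs = c(8, 12))
  ))
}

test_that("feature tables carry one row per image and level", {
  ds <- small_dataset()
  levels <- c(0, 0.2, 0.4)
  feats <- compute_topo_features(ds$images, ds$manifest$label,
                                 levels = levels)
  expect_named(feats, c("image_id", "filter_level", "pi", "pe", "label",
                        "betti"))
  expect_equal(nrow(feats), length(ds$images) * length(levels))
  expect_equal(sort(unique(feats$filter_level)), levels)
  # Betti counts never increase with the filter level
  by_img <- split(feats, feats$image_id)
  for (b in by_img) {
    expect_true(all(diff(b$betti[order(b$filter_level)]) <= 0))
  }
  # empty post-filter diagrams fall back to the zero-feature convention
  expect_true(all(feats$pi >= 0 & feats$pe >= 0))
})

test_that("features computed from a manifest equal in-memory features", {
  dir <- withr::local_tempdir()
  ds <- suppressWarnings(generate_dataset(5, dir = dir, seed = 3,
                         benign = patch_params("benign", size = 32),
                         malignant = patch_params("malignant", size = 32,
                                                  n_blobs = c(5, 8))))
  from_disk <- compute_topo_features(ds$manifest, levels = c(0, 0.3))
  in_mem <- compute_topo_features(ds$images, ds$manifest$label,
                                  levels = c(0, 0.3))
  expect_equal(from_disk, in_mem)
})

test_that("the sweep covers the full grid deterministically", {
  ds <- small_dataset()
  feats <- compute_topo_features(ds$images, ds$manifest$label,
                                 levels = c(0, 0.1, 0.2, 0.3, 0.4, 0.5))
  res <- run_sweep(feats, classifiers = c("svm", "knn", "dt"), seed = 0)
  expect_equal(nrow(res), 6 * 3 * 3)  # levels x feature sets x classifiers
  expect_equal(nrow(dplyr::distinct(res[, c("filter_level", "feature_set",
                                            "classifier")])),
               nrow(res))
  # every row satisfies the result invariants
  expect_true(all(res$tp + res$tn + res$fp + res$fn == res$n))
  expect_equal(res$ca, 100 * (res$tp + res$tn) / res$n)
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  # byte-identical rerun under the same seed
  res2 <- run_sweep(feats, classifiers = c("svm", "knn", "dt"), seed = 0)
  expect_identical(res, res2)
})

test_that("perfectly separable features yield a perfect sweep", {
  feats <- tidyr::expand_grid(
    image_id = sprintf("img_%02d", 1:20),
    filter_level = c(0, 0.2)
  )
  feats$label <- ifelse(as.integer(sub("img_", "", feats$image_id)) <= 10,
                        "benign", "malignant")
  feats$pi <- ifelse(feats$label == "malignant", 50, 0) +
    seq_len(nrow(feats)) * 1e-3
  feats$pe <- ifelse(feats$label == "malignant", 5, 0)
  res <- run_sweep(feats, feature_sets = list(concat = c("pi", "pe")),
                   classifiers = c("svm", "knn"), seed = 1)
  expect_true(all(res$ca == 100))
  expect_true(all(res$auc == 1))
})

test_that("scatter plots build and write for full, subset and empty tables", {
  ds <- small_dataset(n = 5, size = 32)
  feats <- compute_topo_features(ds$images, ds$manifest$label,
                                 levels = c(0, 0.3))
  p <- plot_feature_scatter(feats)
  expect_s3_class(p, "ggplot")
  file <- withr::local_tempfile(fileext = ".png")
  plot_feature_scatter(feats, levels = 0.3, file = file)
  expect_true(file.exists(file))
  expect_gt(file.size(file), 0)
  # empty table: a valid (empty-panel) plot, no crash
  expect_s3_class(plot_feature_scatter(feats[0, ]), "ggplot")
})

test_that("results tables round-trip through the CSV schema", {
  ds <- small_dataset(n = 5, size = 32)
  feats <- compute_topo_features(ds$images, ds$manifest$label,
                                 levels = c(0, 0.3))
  res <- run_sweep(feats, classifiers = "knn", seed = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(res, path, dataset = "synthetic")
  back <- utils::read.csv(path)
  expect_named(back, c("dataset", "filter_level", "feature_set", "classifier",
                       "ca", "ca_se", "auc", "tp", "tn", "fp", "fn"))
  expect_equal(nrow(back), nrow(res))
  expect_equal(back$ca, res$ca)
})
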