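test_that("the worked-example image has the exact known diagrams", {
  img <- figure4_fixture()
  expect_equal(dim(img), c(7L, 11L))
  pd0 <- compute_persistence(img, dims = 0)
  expect_equal(nrow(pd0), 1L)
  expect_equal(pd0$birth, 100)
  expect_equal(pd0$death, Inf)
  pd1 <- compute_persistence(img, dims = 1)
  key <- dplyr::arrange(pd1, birth)
  expect_equal(key$birth, c(120, 150))
  expect_equal(key$death, c(210, 185))
  expect_equal(sort(pd1$lifespan), c(35, 90))
  expect_equal(max_lifespan(pd1), 90)
})

test_that("patch generation is bit-identical for a fixed seed", {
  p <- patch_params("benign", size = 64)
  a <- generate_patch(p, seed = 5)
  b <- generate_patch(p, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, generate_patch(p, seed = 6)))
  expect_true(all(a == round(a)))
  expect_true(all(a >= 0 & a <= 255))
})

test_that("a noise-free single blob creates one loop with lifespan near its uplift", {
  p <- patch_params("benign", size = 50, bg_sd = 0, n_blobs = c(1, 1),
                    uplift = c(100, 100))
  for (seed in 1:5) {
    pd <- compute_persistence(generate_patch(p, seed), dims = 1)
    expect_equal(nrow(pd), 1L, info = paste("seed", seed))
    # taper width is 2 px; ring sits at the background level
    expect_lt(abs(pd$lifespan - 100), 3)
  }
})

test_that("malignant patches carry more loops than benign ones", {
  # unfiltered counts are noise-dominated and similar; after 20-30%
  # filtering benign diagrams keep only their few long-lived blobs
  p_b <- patch_params("benign"); p_m <- patch_params("malignant")
  n <- 15
  betti_b <- betti_m <- filt_b <- filt_m <- numeric(n)
  for (i in seq_len(n)) {
    pd_b <- compute_persistence(generate_patch(p_b, seed = 100 + i), dims = 1)
    pd_m <- compute_persistence(generate_patch(p_m, seed = 200 + i), dims = 1)
    betti_b[i] <- nrow(pd_b); betti_m[i] <- nrow(pd_m)
    filt_b[i] <- nrow(filter_diagram(pd_b, 0.3))
    filt_m[i] <- nrow(filter_diagram(pd_m, 0.3))
  }
  expect_lt(mean(filt_b), mean(filt_m))
  expect_lt(mean(filt_b), 8)   # few long-lived points, about the blob count
  expect_gt(mean(filt_m), 12)  # many retained shorter-lived points
})

test_that("feature class means are ordered benign < malignant after filtering", {
  n <- 12
  imgs <- c(
    lapply(seq_len(n), function(i)
      generate_patch(patch_params("benign"), seed = 300 + i)),
    lapply(seq_len(n), function(i)
      generate_patch(patch_params("malignant"), seed = 400 + i))
  )
  labels <- rep(c("benign", "malignant"), each = n)
  feats <- compute_topo_features(imgs, labels, levels = c(0.1, 0.2, 0.3))
  means <- dplyr::summarise(
    dplyr::group_by(feats, label, filter_level),
    pi = mean(pi), pe = mean(pe), .groups = "drop"
  )
  for (f in c(0.1, 0.2, 0.3)) {
    b <- means[means$label == "benign" & means$filter_level == f, ]
    m <- means[means$label == "malignant" & means$filter_level == f, ]
    expect_lt(b$pi, m$pi)
    expect_lt(b$pe, m$pe)
  }
})

test_that("generate_dataset writes patches plus a faithful manifest", {
  dir <- withr::local_tempdir()
  ds <- suppressWarnings(generate_dataset(5, dir = dir, seed = 1,
                         benign = patch_params("benign", size = 32),
                         malignant = patch_params("malignant", size = 32,
                                                  n_blobs = c(5, 8))))
  expect_equal(nrow(ds$manifest), 10L)
  expect_equal(sum(ds$manifest$label == "benign"), 5L)
  expect_true(all(file.exists(ds$manifest$path)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  # written files decode back to the in-memory patches
  for (i in c(1L, 10L)) {
    expect_identical(read_gray_image(ds$manifest$path[i]),
                     ds$images[[ds$manifest$image_id[i]]])
  }
  # same seed reproduces the dataset exactly
  ds2 <- suppressWarnings(generate_dataset(5, dir = NULL, seed = 1,
                          benign = patch_params("benign", size = 32),
                          malignant = patch_params("malignant", size = 32,
                                                   n_blobs = c(5, 8))))
  expect_identical(ds$images, ds2$images)
})

test_that("infeasible non-overlap placement warns and falls back to overlap", {
  cramped <- patch_params("benign", size = 24, radius = c(6, 7),
                          n_blobs = c(2, 2))
  expect_warning(generate_patch(cramped, seed = 1), "overlap")
})
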