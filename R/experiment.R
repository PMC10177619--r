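#' Topological features of every image in a dataset, at several filter levels
#'
#' For each image: compute the H1 sublevel persistence diagram, filter it at
#' each requested level (fraction of the diagram's maximum lifespan), and
#' vectorise the filtered diagram into the persistence-image and
#' persistent-entropy scalars. Diagrams left empty by filtering map to
#' `pi = 0, pe = 0`.
#'
#' @param x Either a manifest data frame with columns `image_id`, `path`,
#'   `label` (images read from disk), or a named list of image matrices (in
#'   which case `labels` must be supplied).
#' @param labels Class labels, required when `x` is a list of images.
#' @param levels Filter fractions in `[0, 1)`.
#' @param sigma,weight,region Passed to [persistence_image()].
#' @return A tibble with columns `image_id`, `filter_level`, `pi`, `pe`,
#'   `label` and `betti` (points surviving the filter).
#' @export
compute_topo_features <- function(x, labels = NULL,
                                  levels = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                                  sigma = 1, weight = "persistence",
                                  region = NULL) {
  if (is.data.frame(x)) {
    stopifnot(all(c("image_id", "path", "label") %in% names(x)))
    ids <- x$image_id
    labels <- x$label
    imgs <- lapply(x$path, read_gray_image)
  } else {
    stopifnot(is.list(x), !is.null(labels), length(labels) == length(x))
    ids <- if (!is.null(names(x))) names(x) else
      sprintf("img_%03d", seq_along(x))
    imgs <- x
  }
  for (f in levels) check_level(f)
  purrr::map_dfr(seq_along(imgs), function(i) {
    pd <- compute_persistence(imgs[[i]], dims = 1)
    purrr::map_dfr(levels, function(f) {
      fpd <- filter_diagram(pd, f)
      feats <- topo_features(fpd, sigma = sigma, weight = weight,
                             region = region)
      dplyr::bind_cols(
        tibble(image_id = ids[[i]], filter_level = f),
        feats,
        tibble(label = labels[[i]], betti = nrow(fpd))
      )
    })
  })
}

#' Run the full evaluation sweep
#'
#' Evaluates every combination of filter level, feature set and classifier
#' by 5-fold (by default) stratified cross-validation on per-image
#' topological features, pooling out-of-fold predictions. Folds are drawn
#' once per sweep from `seed`, so every cell sees the same partition.
#'
#' @param features A feature table from [compute_topo_features()].
#' @param feature_sets Named list of character vectors of feature columns;
#'   default PI-only, PE-only, and the concatenated pair.
#' @param classifiers Classifier kinds, a subset of
#'   `c("nn", "svm", "knn", "dt")`.
#' @param k Cross-validation folds.
#' @param seed Integer seed (folds and network initialisation).
#' @return A tibble with one row per (filter_level, feature_set, classifier)
#'   cell: `ca`, `ca_se`, `auc`, `tp`, `tn`, `fp`, `fn`, `n`.
#' @export
run_sweep <- function(features,
                      feature_sets = list(pi = "pi", pe = "pe",
                                          concat = c("pi", "pe")),
                      classifiers = c("nn", "svm", "knn", "dt"),
                      k = 5L, seed = 0L) {
  stopifnot(all(c("image_id", "filter_level", "pi", "pe", "label") %in%
                  names(features)))
  levels <- sort(unique(features$filter_level))
  first <- features[features$filter_level == levels[1L], ]
  folds <- stratified_folds(first$label, k = k, seed = seed)
  names(folds) <- first$image_id
  grid <- tidyr::expand_grid(
    filter_level = levels,
    feature_set = names(feature_sets),
    classifier = classifiers
  )
  purrr::pmap_dfr(grid, function(filter_level, feature_set, classifier) {
    sub <- features[features$filter_level == filter_level, ]
    sub <- sub[match(names(folds), sub$image_id), ]  # align with folds
    cols <- feature_sets[[feature_set]]
    cv <- run_cv(sub[, cols, drop = FALSE], sub$label,
                 classifier = classifier, folds = unname(folds), seed = seed)
    dplyr::bind_cols(
      tibble(filter_level = filter_level, feature_set = feature_set),
      glance(cv)[, c("classifier", "n", "ca", "ca_se", "auc",
                     "tp", "tn", "fp", "fn")]
    )
  })
}

#' Scatter plot of persistent entropy against persistence image
#'
#' One panel per filter level, points coloured by class — the standard way
#' to inspect how lifespan filtering separates benign from malignant
#' feature clouds.
#'
#' @param features A feature table from [compute_topo_features()].
#' @param levels Filter levels to show; default all present.
#' @param file Optional output path; when given the plot is also written
#'   (via [ggplot2::ggsave()]) and the path returned invisibly.
#' @return A ggplot object (invisibly when `file` is given).
#' @export
plot_feature_scatter <- function(features, levels = NULL, file = NULL) {
  stopifnot(all(c("filter_level", "pi", "pe") %in% names(features)))
  if (!is.null(levels)) {
    features <- features[features$filter_level %in% levels, ]
  }
  p <- ggplot2::ggplot(features,
                       ggplot2::aes(x = .data$pi, y = .data$pe)) +
    ggplot2::facet_wrap(~filter_level, scales = "free",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Persistence image (PI)", y = "Persistent entropy (PE)")
  if ("label" %in% names(features) && nrow(features) > 0L) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$label),
                                 alpha = 0.8)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.8)
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 8, height = 5, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Write a sweep results table as CSV
#'
#' Columns: `dataset,filter_level,feature_set,classifier,ca,ca_se,auc,tp,tn,fp,fn`.
#'
#' @param results A results tibble from [run_sweep()].
#' @param path Output CSV path.
#' @param dataset Dataset name recorded in the first column.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, dataset = "synthetic") {
  out <- dplyr::bind_cols(tibble(dataset = rep(dataset, nrow(results))),
                          results[, c("filter_level", "feature_set",
                                      "classifier", "ca", "ca_se", "auc",
                                      "tp", "tn", "fp", "fn")])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
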