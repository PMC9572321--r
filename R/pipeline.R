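#' Pipeline configuration
#'
#' Settings for the end-to-end run: synthetic scene and class profiles,
#' segmentation and co-occurrence parameters, feature selection mode,
#' classifier protocol and the master seed, which propagates to every
#' stochastic stage (generation, splits, selection folds, network
#' initialization).
#'
#' @param per_class images generated per class.
#' @param profiles list of four [class_color_profile()].
#' @param scene a [scene_config()]; its seed is overridden by `seed`.
#' @param preprocess a [preprocess_config()].
#' @param glcm a [glcm_config()].
#' @param selection `"sfs"` to run [sfs_quadratic()], `"fixed"` to use
#'   `fixed_subset` as-is.
#' @param fixed_subset feature names used when `selection = "fixed"`;
#'   default the 16-feature reference subset.
#' @param max_features cap for SFS.
#' @param cv_folds folds of the SFS criterion.
#' @param hidden_range hidden sizes scanned for the network.
#' @param max_epochs network training epochs cap.
#' @param seed master seed.
#' @param out_dir optional directory for artifacts (feature CSV, selection
#'   trace, evaluation reports, scan report, manifest with content
#'   hashes).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(per_class = 40,
                            profiles = default_profiles(),
                            scene = scene_config(),
                            preprocess = preprocess_config(),
                            glcm = glcm_config(),
                            selection = c("sfs", "fixed"),
                            fixed_subset = optimum_features(),
                            max_features = 16L,
                            cv_folds = 5L,
                            hidden_range = 2:20,
                            max_epochs = 400L,
                            seed = 1L,
                            out_dir = NULL) {
  selection <- match.arg(selection)
  scene$seed <- as.integer(seed)
  structure(list(per_class = per_class, profiles = profiles, scene = scene,
                 preprocess = preprocess, glcm = glcm,
                 selection = selection, fixed_subset = fixed_subset,
                 max_features = max_features, cv_folds = cv_folds,
                 hidden_range = hidden_range, max_epochs = max_epochs,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full grading pipeline
#'
#' Generate (or accept) a labelled image set, segment every image, extract
#' the 285-feature table, choose a feature subset, fit the LDA and QDA
#' classifiers under an 80:20 stratified split, scan network structures
#' under a 60:20:20 split, and evaluate everything (whole-dataset scope,
#' mirroring the reference protocol, plus test-only).
#'
#' @param cfg a [pipeline_config()].
#' @param set optional pre-built `labeled_image_set` (skips generation).
#' @return List with `set`, `masks`, `mask_jaccard`, `features`,
#'   `selection`, `subset`, `models` (lda, qda, ann scan), and `reports`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), set = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(set))
    set <- generate_dataset(cfg$profiles, cfg$per_class, cfg$scene)

  masks <- vector("list", length(set$images))
  jac <- numeric(length(set$images))
  for (i in seq_along(set$images)) {
    masks[[i]] <- tryCatch(
      preprocess_pipeline(set$images[[i]], cfg$preprocess)$mask,
      error = function(e) stop("preprocess failed for image ", i, ": ",
                               conditionMessage(e)))
    jac[i] <- if (is.null(set$masks[[i]])) NA_real_
              else jaccard(masks[[i]], set$masks[[i]])
  }

  features <- extract_table(set, cfg$glcm, masks = masks)

  if (cfg$selection == "sfs") {
    trace <- sfs_quadratic(features, max_features = cfg$max_features,
                           cv_folds = cfg$cv_folds, seed = cfg$seed)
    subset <- trace$selected
  } else {
    resolve_feature_names(cfg$fixed_subset)
    trace <- NULL
    subset <- cfg$fixed_subset
  }

  split2 <- split_config(c(train = 0.8, test = 0.2), seed = cfg$seed)
  part2 <- split_assign(features$class, split2)
  train2 <- features[part2 == "train", , drop = FALSE]
  lda <- fit_discriminant(train2, subset, kind = "lda")
  qda <- fit_discriminant(train2, subset, kind = "qda")

  split3 <- split_config(c(train = 0.6, validation = 0.2, test = 0.2),
                         seed = cfg$seed)
  scan <- scan_structures(features, subset, cfg$hidden_range, split3,
                          train_config(max_epochs = cfg$max_epochs,
                                       seed = cfg$seed))

  reports <- list(
    lda = evaluate_classifier(lda, features),
    qda = evaluate_classifier(qda, features),
    ann = evaluate_classifier(scan$best_model, features),
    lda_test = evaluate_classifier(lda, features, "test_only", part2),
    qda_test = evaluate_classifier(qda, features, "test_only", part2),
    ann_test = evaluate_classifier(scan$best_model, features, "test_only"))

  res <- list(set = set, masks = masks, mask_jaccard = jac,
              features = features, selection = trace, subset = subset,
              models = list(lda = lda, qda = qda, scan = scan),
              reports = reports, config = cfg)
  if (!is.null(cfg$out_dir)) .write_artifacts(res, cfg$out_dir)
  res
}

.write_artifacts <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(res$features, file.path(dir, "features.csv"))
  if (!is.null(res$selection))
    write_selection_trace(res$selection, file.path(dir, "selection.json"))
  utils::write.csv(res$models$scan$report, file.path(dir, "ann_scan.csv"),
                   row.names = FALSE)
  for (nm in names(res$reports))
    write_report(res$reports[[nm]], file.path(dir, paste0(nm, ".json")))
  serialize_model(res$models$lda, file.path(dir, "model_lda.json"))
  serialize_model(res$models$qda, file.path(dir, "model_qda.json"))
  serialize_model(res$models$scan$best_model,
                  file.path(dir, "model_ann.json"))
  files <- setdiff(list.files(dir, full.names = TRUE),
                   file.path(dir, "manifest.json"))
  man <- data.frame(file = basename(files),
                    md5 = unname(tools::md5sum(files)),
                    stringsAsFactors = FALSE)
  jsonlite::write_json(list(seed = res$config$seed, files = man),
                       file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(dir)
}

#' Serialize / restore a fitted classifier as JSON
#'
#' Supports `discrim` and `ripeness_ann` models; the round trip preserves
#' predictions exactly up to JSON numeric formatting (full precision is
#' written).
#'
#' @param model a fitted model.
#' @param path JSON path.
#' @return `serialize_model` the path invisibly; `deserialize_model` the
#'   restored model.
#' @export
serialize_model <- function(model, path) {
  if (inherits(model, "discrim")) {
    payload <- list(type = "discrim",
                    model = unclass(model))
  } else if (inherits(model, "ripeness_ann")) {
    keep <- c("n_input", "n_hidden", "n_output", "weights",
              "input_scaling", "feature_subset", "classes",
              "best_epoch", "validation_mse")
    payload <- list(type = "ripeness_ann", model = unclass(model)[keep])
  } else stop("unsupported model type")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname serialize_model
#' @export
deserialize_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- p$model
  if (p$type == "discrim") {
    m$class_means <- as.matrix(m$class_means)
    if (m$kind == "lda") {
      m$covariances <- list(pooled = as.matrix(m$covariances$pooled))
    } else {
      m$covariances <- lapply(m$covariances, as.matrix)
    }
    class(m) <- "discrim"
  } else if (p$type == "ripeness_ann") {
    m$weights$W1 <- as.matrix(m$weights$W1)
    m$weights$W2 <- as.matrix(m$weights$W2)
    class(m) <- "ripeness_ann"
  } else stop("unsupported model type in ", path)
  m
}
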