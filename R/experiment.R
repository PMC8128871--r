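#' Expand a model grid
#'
#' The model grid is the cross-product of colour space, dictionary size,
#' quantizer and pooling regime; each point gets a readable model id built
#' from its values (the historical numeric model-id scheme is not
#' reproducible, so ids are free text).
#'
#' @param colour colour spaces to include.
#' @param vocsize dictionary sizes.
#' @param quantizer quantizers.
#' @param pooling pooling regimes: `"none"`, `"temporal"`, `"categorical"`,
#'   `"both"`.
#' @return data frame with one row per model configuration.
#' @export
model_grid <- function(colour = c("greyscale", "rgb", "hsv"),
                       vocsize = c(200L, 500L),
                       quantizer = "kdtree",
                       pooling = c("none", "both")) {
  stopifnot(all(pooling %in% c("none", "temporal", "categorical", "both")))
  g <- expand.grid(colour = colour, vocsize = vocsize, quantizer = quantizer,
                   pooling = pooling, stringsAsFactors = FALSE)
  if (nrow(g) == 0L) stopf("no models configured")
  g$model_id <- sprintf("%s-%d-%s-%s", g$quantizer, g$vocsize, g$colour, g$pooling)
  g[c("model_id", "vocsize", "colour", "quantizer", "pooling")]
}

pooling_for <- function(regime, taxonomy = trap_taxonomy()) {
  pooling_scheme(categorical = regime %in% c("categorical", "both"),
                 temporal = regime %in% c("temporal", "both"),
                 taxonomy = taxonomy)
}

set_fingerprint <- function(set) {
  sprintf("n=%d;labels=%s;pixsum=%.0f", length(set$patches),
          paste(sort(unique(set$info$label)), collapse = ","),
          sum(vapply(set$patches, sum, numeric(1))))
}

#' Run a model grid end to end
#'
#' For every grid point: apply the pooling regime to the training and test
#' labels, split the training data 75/25 into model-fitting and
#' optimization parts (stratified), build the dictionary and SVM on the
#' fitting part, evaluate on the optimization part (logged) and on the
#' held-out test set, and write the confusion matrix and metrics.  A
#' failure in one grid point is logged and does not abort the others.
#' Outputs carry no timestamps, so re-running with the same manifest
#' reproduces them byte-identically.
#'
#' @param grid a [model_grid()] data frame.
#' @param train_set,test_set labelled `subimage_set`s.
#' @param out_dir output directory (created if needed).
#' @param rng_seed master seed; each grid point derives its own seed from
#'   it.
#' @param sift a [sift_params()].
#' @param normalization BoVW normalization.
#' @param split_fraction model-fitting share of the training data.
#' @param lambda,epochs SVM hyperparameters.
#' @param taxonomy unpooled class taxonomy.
#' @return invisibly, a list with `results` (per-model list: report,
#'   confusion matrix, status), `log` (data frame), and `manifest`.
#' @export
run_experiment <- function(grid, train_set, test_set, out_dir,
                           rng_seed = 1L, sift = sift_params(),
                           normalization = "l1", split_fraction = 0.75,
                           lambda = 1e-4, epochs = 50L,
                           taxonomy = trap_taxonomy()) {
  if (nrow(grid) == 0L) stopf("no models configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  log_rows <- list()
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      scheme <- pooling_for(row$pooling, taxonomy)
      tr <- apply_pooling(train_set, scheme)
      te <- apply_pooling(test_set, scheme)
      classes <- intersect(pooled_taxonomy(scheme), unique(tr$info$label))
      cfg <- bovw_config(colour_space = row$colour, vocsize = row$vocsize,
                         quantizer = row$quantizer,
                         normalization = normalization, sift = sift,
                         lambda = lambda, epochs = epochs,
                         seed = rng_seed + i)
      parts <- split_train_opt(tr, split_fraction, rng_seed = rng_seed + i)
      model <- train_bovw_classifier(parts$model, cfg, class_order = classes)
      opt_pred <- predict_bovw(model, parts$optimization)
      opt_cm <- confusion_matrix(parts$optimization$info$label, opt_pred$label,
                                 classes)
      pred <- predict_bovw(model, te)
      cm <- confusion_matrix(te$info$label, pred$label, classes)
      report <- precision_recall(cm)
      write_confusion_matrix(cm, file.path(out_dir,
                                           paste0(row$model_id, "-confusion.tsv")))
      list(status = "ok", report = report, confusion = cm,
           opt_report = precision_recall(opt_cm), model = model)
    }, error = function(e) list(status = "failed", error = conditionMessage(e)))
    secs <- proc.time()[["elapsed"]] - t0
    log_rows[[i]] <- data.frame(model_id = row$model_id, status = res$status,
                                seconds = round(secs, 2),
                                n_train = length(train_set$patches),
                                n_test = length(test_set$patches),
                                error = res$error %||% "")
    results[[row$model_id]] <- res
  }
  # one report file per pooling taxonomy (pooled and unpooled class sets differ)
  for (regime_pool in split(seq_len(nrow(grid)),
                            grid$pooling %in% c("categorical", "both"))) {
    ids <- grid$model_id[regime_pool]
    ok <- ids[vapply(results[ids], function(r) r$status == "ok", logical(1))]
    if (length(ok)) {
      tag <- if (grid$pooling[regime_pool[1]] %in% c("categorical", "both"))
        "pooled" else "unpooled"
      render_report(lapply(results[ok], `[[`, "report"),
                    file.path(out_dir, paste0("report-", tag, ".txt")))
    }
  }
  log_df <- do.call(rbind, log_rows)
  utils::write.table(log_df, file.path(out_dir, "run-log.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- list(rng_seed = as.integer(rng_seed),
                   grid = lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, ])),
                   normalization = normalization,
                   split_fraction = split_fraction,
                   lambda = lambda, epochs = as.integer(epochs),
                   sift = unclass(sift),
                   train_fingerprint = set_fingerprint(train_set),
                   test_fingerprint = set_fingerprint(test_set),
                   r_version = R.version.string,
                   package_version = as.character(utils::packageVersion("trapbovw")))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  invisible(list(results = results, log = log_df, manifest = manifest))
}

#' Run an experiment from a YAML config file
#'
#' The config mirrors [model_grid()] plus a `synthetic:` section describing
#' the generated datasets, e.g.:
#' ```yaml
#' seed: 7
#' grid:
#'   colour: [greyscale, rgb]
#'   vocsize: [200]
#'   quantizer: [kdtree]
#'   pooling: [none, both]
#' synthetic:
#'   train_per_class: 40
#'   test_per_class: 20
#'   test_decay: 0
#' ```
#'
#' @param config_path YAML file path.
#' @param out_dir output directory.
#' @return see [run_experiment()].
#' @export
run_experiment_config <- function(config_path, out_dir) {
  cfg <- yaml::read_yaml(config_path)
  seed <- as.integer(cfg$seed %||% 1L)
  g <- cfg$grid %||% list()
  grid <- model_grid(colour = unlist(g$colour) %||% "greyscale",
                     vocsize = as.integer(unlist(g$vocsize) %||% 200L),
                     quantizer = unlist(g$quantizer) %||% "kdtree",
                     pooling = unlist(g$pooling) %||% "none")
  syn <- cfg$synthetic %||% list()
  n_train <- as.integer(syn$train_per_class %||% 40L)
  n_test <- as.integer(syn$test_per_class %||% 20L)
  taxonomy <- trap_taxonomy()
  counts_tr <- stats::setNames(rep(n_train, length(taxonomy)), taxonomy)
  counts_te <- stats::setNames(rep(n_test, length(taxonomy)), taxonomy)
  train_set <- generate_dataset(counts_tr, rng_seed = seed,
                                dataset_tag = "Lab0d")
  test_set <- generate_dataset(counts_te,
                               decay_levels = as.numeric(syn$test_decay %||% 0),
                               decay_probs = rep(1, length(syn$test_decay %||% 0)),
                               rng_seed = seed + 1L, dataset_tag = "Lab0d")
  run_experiment(grid, train_set, test_set, out_dir, rng_seed = seed,
                 epochs = as.integer(cfg$epochs %||% 50L))
}
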