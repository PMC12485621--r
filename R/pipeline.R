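#' Build a run configuration
#'
#' One configuration object drives the end-to-end pipeline. Exactly one
#' input source must be given: `table` (a path to a haplotype CSV/TSV, or a
#' `haplotype_table` object) or `simulation` (a [simulation_config()]).
#'
#' @param table input haplotype table (path or object), labeled.
#' @param simulation a [simulation_config()] generating the input instead.
#' @param panel a [marker_panel()] (or panel JSON path) used when reading
#'   `table`; default [default_panel()].
#' @param train_fraction stratified split fraction (default 0.8).
#' @param balance downsample the training partition to the smallest class
#'   (default `TRUE`); the test partition keeps natural proportions.
#' @param feature_mode `"full"` one-hot features (default) or
#'   `"one_per_marker"`.
#' @param architectures subset of `c("ovr", "ovo")`.
#' @param algorithm base-classifier family (`"logistic"`,
#'   `"random_forest"`, `"xgboost"`) or `"auto"` (per-expert best family;
#'   one-vs-rest only).
#' @param tune_budget SMBO evaluations per expert (0 = family defaults, no
#'   tuning).
#' @param calibration_folds out-of-fold calibration folds.
#' @param temperature attention softmax temperature.
#' @param meta a [meta_network_config()].
#' @param seed master integer seed; every stage derives its seed from it.
#' @param outdir optional output directory; when given, models, predictions,
#'   the report and a manifest are written there.
#' @return an object of class `run_config`.
#' @export
run_config <- function(table = NULL, simulation = NULL, panel = default_panel(),
                       train_fraction = 0.8, balance = TRUE,
                       feature_mode = c("full", "one_per_marker"),
                       architectures = c("ovr", "ovo"),
                       algorithm = "logistic", tune_budget = 0L,
                       calibration_folds = 5L, temperature = 1,
                       meta = meta_network_config(), seed = 1L,
                       outdir = NULL) {
  if (is.null(table) == is.null(simulation)) {
    stop("exactly one input source (table or simulation) must be given")
  }
  feature_mode <- match.arg(feature_mode)
  architectures <- match.arg(architectures, several.ok = TRUE)
  if (is.character(panel)) panel <- read_panel(panel)
  structure(
    list(table = table, simulation = simulation, panel = panel,
         train_fraction = train_fraction, balance = isTRUE(balance),
         feature_mode = feature_mode, architectures = architectures,
         algorithm = algorithm, tune_budget = as.integer(tune_budget),
         calibration_folds = as.integer(calibration_folds),
         temperature = temperature, meta = meta, seed = as.integer(seed),
         outdir = outdir),
    class = "run_config"
  )
}

resolve_input_table <- function(config) {
  if (!is.null(config$simulation)) return(generate_table(config$simulation))
  if (inherits(config$table, "haplotype_table")) return(config$table)
  read_haplotype_table(config$table, panel = config$panel)
}

# Tune (or default) per-expert specs for a family; "auto" handled by fit_ovr.
resolve_specs <- function(config, X, labels, k) {
  if (identical(config$algorithm, "auto")) return("auto")
  if (config$tune_budget < 1L) {
    return(classifier_spec(config$algorithm, seed = config$seed))
  }
  lapply(seq_len(k) - 1L, function(c) {
    tune_hyperparameters(X, as.integer(labels == c),
                         algorithm = config$algorithm,
                         n_folds = 3L, budget = config$tune_budget,
                         seed = config$seed + 100L + c)
  })
}

#' Run the pipeline end-to-end
#'
#' Load or simulate the input table; quality-control (complete profiles
#' only); stratified 80:20-style split; optionally downsample the training
#' partition to the smallest class; train the requested architectures on
#' the identical training partition; evaluate both on the identical test
#' partition. Identical configurations yield identical reports.
#'
#' @param config a [run_config()].
#' @return a run report (list): per-architecture metrics, confusion
#'   matrices, misclassification summaries, classifier counts, the OvO
#'   pairwise-accuracy matrix, the OvR importance ranking and attention
#'   weights, plus split bookkeeping. Trained model objects are attached in
#'   `$models` (dropped from any JSON serialization).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tab <- resolve_input_table(config)
  tab <- filter_complete(tab)
  if (n_profiles(tab) == 0L) stop("stage preprocess: no complete profiles")
  split <- stratified_split(tab, config$train_fraction, seed = config$seed)
  train <- if (config$balance) downsample_to_min(split$train, seed = config$seed + 1L) else split$train
  test <- split$test

  encoding <- encode_labels(train)
  labels <- encode(encoding, train$data$Population)
  vocab <- build_vocabulary(train)
  X <- one_hot_encode(train, vocab)
  k <- length(encoding$classes)

  report_out <- list(
    classes = encoding$classes,
    n_train = n_profiles(train), n_test = n_profiles(test),
    feature_count = ncol(X), seed = config$seed
  )
  models <- list()
  test_labels <- test$data$Population

  if ("ovr" %in% config$architectures) {
    specs <- resolve_specs(config, X, labels, k)
    m <- train_ovr_attention(
      train, specs = if (identical(specs, "auto")) "auto" else specs,
      feature_mode = config$feature_mode,
      calibration_folds = config$calibration_folds,
      temperature = config$temperature, meta = config$meta,
      seed = config$seed
    )
    pred <- predict_population(m, test, unseen = "zero")
    cm <- confusion(test_labels, pred$predicted, encoding)
    report_out$ovr <- list(
      n_classifiers = count_classifiers(k, "ovr"),
      metrics = strip_report(report(cm)),
      confusion = unclass(cm),
      misclassification = misclassification_summary(cm, top_n = 5L),
      attention_weights = stats::setNames(as.numeric(m$attention),
                                          encoding$classes),
      top_features = lapply(importance_ranking(m$ensemble), utils::head, 3L)
    )
    models$ovr <- m
    report_out$predictions_ovr <- pred$table
  }
  if ("ovo" %in% config$architectures) {
    algo <- if (identical(config$algorithm, "auto")) "logistic" else config$algorithm
    m <- train_ovo_stacking(
      train, specs = classifier_spec(algo, seed = config$seed),
      feature_mode = config$feature_mode,
      calibration_folds = min(config$calibration_folds, 3L),
      meta = config$meta, seed = config$seed
    )
    pred <- stack_predict(m, test, unseen = "zero")
    cm <- confusion(test_labels, pred$predicted, encoding)
    X_test <- model_design_matrix(m, test, unseen = "zero")
    pam <- pairwise_accuracy(m$ensemble, X_test,
                             encode(encoding, test_labels))
    report_out$ovo <- list(
      n_classifiers = count_classifiers(k, "ovo"),
      metrics = strip_report(report(cm)),
      confusion = unclass(cm),
      misclassification = misclassification_summary(cm, top_n = 5L),
      pairwise_accuracy = unclass(pam)
    )
    models$ovo <- m
    report_out$predictions_ovo <- pred$table
  }

  if (!is.null(config$outdir)) write_run_outputs(config, report_out, models)
  report_out$models <- models
  report_out
}

strip_report <- function(rep) {
  list(accuracy = rep$accuracy, per_class = rep$per_class,
       macro = as.list(rep$macro), weighted = as.list(rep$weighted))
}

#' Train and evaluate both architectures on one split
#'
#' Convenience wrapper enforcing an apples-to-apples comparison: both the
#' one-vs-rest attention model and the one-vs-one stacking model are
#' trained on the identical training partition and evaluated with the same
#' evaluation module on the identical test partition.
#'
#' @param config a [run_config()]; its `architectures` field is overridden
#'   to both.
#' @return the [run_experiment()] report, containing `ovr` and `ovo`
#'   sections.
#' @export
compare_architectures <- function(config) {
  config$architectures <- c("ovr", "ovo")
  run_experiment(config)
}

# ---- persistence ------------------------------------------------------------

report_json <- function(report_out) {
  drop <- intersect(names(report_out), c("models"))
  jsonlite::toJSON(report_out[setdiff(names(report_out), drop)],
                   auto_unbox = TRUE, digits = I(10), na = "null",
                   pretty = TRUE)
}

write_run_outputs <- function(config, report_out, models) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  writeLines(report_json(report_out), file.path(config$outdir, "report.json"))
  for (arch in names(models)) {
    save_model(models[[arch]], file.path(config$outdir, paste0("model_", arch)))
    pred <- report_out[[paste0("predictions_", arch)]]
    utils::write.csv(pred, file.path(config$outdir,
                                     paste0("predictions_", arch, ".csv")),
                     row.names = FALSE)
  }
  manifest <- list(
    package = "ystrancestry",
    version = as.character(utils::packageVersion("ystrancestry")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    algorithm = config$algorithm,
    tune_budget = config$tune_budget,
    train_fraction = config$train_fraction,
    balance = config$balance,
    feature_mode = config$feature_mode,
    architectures = config$architectures,
    temperature = config$temperature,
    meta = unclass(config$meta)
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(config$outdir)
}

#' Persist / restore a trained model
#'
#' Writes a model directory: panel, label encoding, vocabulary, attention
#' weights, calibration parameters and meta-network weights as JSON.
#' Linear (logistic) experts round-trip entirely through JSON
#' (coefficients); tree-based experts (random forest, gradient boosting)
#' are stored in their implementations' native serialization (`.rds`),
#' noted in the model manifest.
#'
#' @param model an `ovr_attention_model` or `ovo_stacking_model`.
#' @param dir output directory (created).
#' @return `dir` (for `save_model`); the restored model (for
#'   `load_model`).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  is_ovr <- inherits(model, "ovr_attention_model")
  write_panel(model$panel, file.path(dir, "panel.json"))
  jsonlite::write_json(
    list(classes = model$encoding$classes,
         feature_mode = model$feature_mode,
         selected_features = model$selected_features,
         kind = if (is_ovr) "ovr_attention" else "ovo_stacking",
         seed = model$seed),
    file.path(dir, "model.json"), auto_unbox = TRUE, null = "null", pretty = TRUE
  )
  jsonlite::write_json(
    list(locus_copy = model$vocab$locus_copy, allele = model$vocab$allele),
    file.path(dir, "vocabulary.json"), pretty = TRUE
  )
  if (is_ovr) {
    jsonlite::write_json(
      list(weights = as.numeric(model$attention),
           metrics = attr(model$attention, "metrics"),
           mi = attr(model$attention, "mi"),
           temperature = attr(model$attention, "temperature")),
      file.path(dir, "attention.json"), digits = NA, pretty = TRUE
    )
  }
  experts <- if (is_ovr) model$ensemble$experts else model$ensemble$models
  serial <- lapply(seq_along(experts), function(i) {
    e <- experts[[i]]
    base <- list(
      calibration = list(A = e$calibration$A, B = e$calibration$B),
      algorithm = e$model$algorithm
    )
    if (e$model$algorithm == "logistic") {
      base$a0 <- as.numeric(e$model$model$a0)
      base$beta <- as.numeric(e$model$model$beta[, 1L])
      base$features <- e$model$feature_names
    } else {
      rds <- sprintf("expert_%02d.rds", i)
      saveRDS(e$model, file.path(dir, rds))
      base$rds <- rds
    }
    base
  })
  names(serial) <- if (is_ovr) model$ensemble$classes else names(experts)
  jsonlite::write_json(serial, file.path(dir, "experts.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(sizes = model$meta$sizes, k = model$meta$k,
         config = unclass(model$meta$config),
         feature_names = model$meta$feature_names,
         params = lapply(model$meta$params, function(p) {
           list(W = as.numeric(p$W), b = p$b)  # W column-major, dims in sizes
         })),
    file.path(dir, "meta_network.json"), digits = NA, pretty = TRUE,
    auto_unbox = FALSE
  )
  if (is_ovr) {
    jsonlite::write_json(
      list(metrics = as.numeric(model$ensemble$metrics),
           mi_scores = as.numeric(model$ensemble$mi_scores),
           feature_sds = as.numeric(model$ensemble$feature_sds),
           feature_names = model$ensemble$feature_names),
      file.path(dir, "ensemble.json"), digits = NA, pretty = TRUE
    )
  } else {
    jsonlite::write_json(
      list(pairs = lapply(model$ensemble$models, function(m) {
             list(i = m$i, j = m$j, n_train = m$n_train)
           }),
           feature_names = model$ensemble$feature_names),
      file.path(dir, "ensemble.json"), auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta_info <- jsonlite::read_json(file.path(dir, "model.json"),
                                   simplifyVector = TRUE)
  panel <- read_panel(file.path(dir, "panel.json"))
  voc <- jsonlite::read_json(file.path(dir, "vocabulary.json"),
                             simplifyVector = TRUE)
  vocab <- structure(
    list(locus_copy = voc$locus_copy, allele = as.character(voc$allele),
         feature = paste0(voc$locus_copy, "_", voc$allele), panel = panel),
    class = "allele_vocabulary"
  )
  encoding <- label_encoding(meta_info$classes)
  experts_json <- jsonlite::read_json(file.path(dir, "experts.json"),
                                      simplifyVector = FALSE)
  restore_model <- function(e) {
    if (!is.null(e$rds)) return(readRDS(file.path(dir, e$rds)))
    structure(
      list(algorithm = "linear_coef",
           a0 = e$a0, beta = unlist(e$beta),
           feature_names = unlist(e$features)),
      class = "binary_model"
    )
  }
  mj <- jsonlite::read_json(file.path(dir, "meta_network.json"),
                            simplifyVector = FALSE)
  sizes <- as.integer(unlist(mj$sizes))
  meta_model <- structure(
    list(params = lapply(seq_along(mj$params), function(l) {
           p <- mj$params[[l]]
           list(W = matrix(as.numeric(unlist(p$W)), sizes[l], sizes[l + 1L]),
                b = as.numeric(unlist(p$b)))
         }),
         sizes = sizes, k = as.integer(unlist(mj$k)),
         config = meta_network_config(
           hidden_sizes = as.integer(unlist(mj$config$hidden_sizes)),
           epochs = as.integer(unlist(mj$config$epochs)),
           learning_rate = as.numeric(unlist(mj$config$learning_rate)),
           seed = as.integer(unlist(mj$config$seed))
         ),
         feature_names = as.character(unlist(mj$feature_names))),
    class = "meta_network"
  )
  ens_json <- jsonlite::read_json(file.path(dir, "ensemble.json"),
                                  simplifyVector = TRUE)
  if (identical(meta_info$kind, "ovr_attention")) {
    att <- jsonlite::read_json(file.path(dir, "attention.json"),
                               simplifyVector = TRUE)
    experts <- lapply(seq_along(experts_json), function(i) {
      e <- experts_json[[i]]
      list(class = names(experts_json)[i],
           model = restore_model(e),
           calibration = structure(list(A = e$calibration$A,
                                        B = e$calibration$B),
                                   class = "calibration_params"))
    })
    ensemble <- structure(
      list(experts = experts, classes = encoding$classes,
           k = length(encoding$classes),
           feature_names = unlist(ens_json$feature_names),
           feature_sds = stats::setNames(as.numeric(ens_json$feature_sds),
                                         unlist(ens_json$feature_names)),
           metrics = as.numeric(ens_json$metrics),
           mi_scores = as.numeric(ens_json$mi_scores)),
      class = "ovr_ensemble"
    )
    weights <- structure(as.numeric(att$weights), class = "attention_weights",
                         metrics = att$metrics, mi = att$mi,
                         temperature = att$temperature)
    structure(
      list(panel = panel, encoding = encoding, vocab = vocab,
           feature_mode = meta_info$feature_mode,
           selected_features = meta_info$selected_features,
           ensemble = ensemble, attention = weights, meta = meta_model,
           seed = meta_info$seed),
      class = "ovr_attention_model"
    )
  } else {
    pairs <- ens_json$pairs
    models <- lapply(seq_along(experts_json), function(i) {
      e <- experts_json[[i]]
      list(i = pairs[[i]]$i, j = pairs[[i]]$j,
           model = restore_model(e),
           calibration = structure(list(A = e$calibration$A,
                                        B = e$calibration$B),
                                   class = "calibration_params"),
           n_train = pairs[[i]]$n_train)
    })
    names(models) <- names(experts_json)
    ensemble <- structure(
      list(models = models, classes = encoding$classes,
           k = length(encoding$classes),
           feature_names = unlist(ens_json$feature_names)),
      class = "ovo_ensemble"
    )
    structure(
      list(panel = panel, encoding = encoding, vocab = vocab,
           feature_mode = meta_info$feature_mode,
           selected_features = meta_info$selected_features,
           ensemble = ensemble, meta = meta_model, seed = meta_info$seed),
      class = "ovo_stacking_model"
    )
  }
}
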