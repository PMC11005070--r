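# End-to-end screening study: simulate -> indexes -> split -> train -> evaluate.
#
# All learned components (ectatic-index weights, normative percentile model,
# normalization cutoffs, perceptron weights) are fitted on the training
# partition only; test scans are only ever touched by the frozen model.

#' Default configuration of a synthetic screening study
#'
#' @param n_per_class Named vector of eyes per class.
#' @param seed Master seed; every random stage derives from it.
#' @param grid A [polar_grid()].
#' @param train_fraction Training proportion of each class.
#' @param mlp_grid List of training configurations for
#'   [hyperparameter_search()]; a single entry trains one network.
#' @param class_weights Optional per-class sample weights for training
#'   (`NULL`, the default, mirrors plain unweighted backpropagation).
#' @return A `run_config` list.
#' @export
default_run_config <- function(n_per_class = c(Abn = 100, Kcn = 100,
                                               MyPO = 100, Normal = 100,
                                               SKcn = 100),
                               seed = 1L, grid = polar_grid(),
                               train_fraction = 0.70,
                               mlp_grid = list(list(hidden = 15L,
                                                    learning_rate = 0.05,
                                                    momentum = 0.9,
                                                    sigma = 1,
                                                    max_epochs = 3000L)),
                               class_weights = NULL) {
  structure(list(n_per_class = n_per_class, seed = as.integer(seed),
                 grid = grid, train_fraction = train_fraction,
                 mlp_grid = mlp_grid, class_weights = class_weights),
            class = "run_config")
}

# md5 checksum of an R object via its canonical serialization
object_checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2L, xdr = TRUE)
  close(con)
  unname(tools::md5sum(f))
}

#' Run a full synthetic screening study
#'
#' Executes the whole chain: cohort generation from the class priors;
#' stratified 70/30 split; training of the ectatic-index weights and of the
#' normative percentile model (profiles and cutoffs) on the training
#' partition only; index computation; perceptron training (grid search when
#' several configurations are given); and test-set evaluation (confusion
#' matrix, per-class metrics, per-index AUC with Hosmer grades for the
#' normal-vs-keratoconus and normal-vs-suspect contrasts). Deterministic
#' from the single seed; the manifest records per-stage checksums and two
#' runs with the same configuration produce identical manifests.
#'
#' @param config A [default_run_config()] list.
#' @param verbose Print per-stage progress.
#' @return An object of class `kc_study`: `model` (the winning [mlp_fit()]
#'   network), `ei_weights`, `normative`, `confusion`, `metrics`,
#'   `auc_normal_kcn`, `auc_normal_skcn`, `index_table` (train + test),
#'   `search_report`, `manifest`, `timings`.
#' @export
run_screening_study <- function(config = default_run_config(),
                                verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- Sys.time()
  stage_time <- c()
  tick <- function(stage) {
    stage_time[[stage]] <<- as.numeric(Sys.time() - t_start, units = "secs")
  }
  plan <- cohort_plan(config$n_per_class, config$seed)
  say("cohort: %d eyes (%s)", nrow(plan),
      paste(names(config$n_per_class), config$n_per_class, sep = "=",
            collapse = ", "))
  split <- stratified_split(plan$class, config$train_fraction,
                            seed = config$seed + 17L)
  # ---- pass 1: training scans only -------------------------------------
  feats <- vector("list", nrow(plan))
  for (i in split$train) {
    scan <- generate_cornea(plan$class[i],
                            sample_phenotype_params(plan$class[i],
                                                    plan$scan_seed[i]),
                            grid = config$grid, seed = plan$scan_seed[i],
                            laterality = plan$laterality[i],
                            scan_id = plan$scan_id[i])
    feats[[i]] <- compute_scan_features(scan)
  }
  tick("train_features")
  say("training features: %d scans (%.1f s)", length(split$train),
      stage_time[["train_features"]])
  tr_cls <- plan$class[split$train]
  tr_feats <- feats[split$train]
  # ectatic-index weights: training normals + keratoconus eyes
  nk <- tr_cls %in% c("Normal", "Kcn")
  if (length(unique(tr_cls[nk])) < 2L)
    stop("stage ei_weights: training partition lacks Normal or Kcn eyes")
  ei_w_f <- train_ei_weights(lapply(tr_feats[nk], `[[`, "spec_f"),
                             tr_cls[nk], side = "anterior")
  ei_w_b <- train_ei_weights(lapply(tr_feats[nk], `[[`, "spec_b"),
                             tr_cls[nk], side = "posterior")
  # normative profiles from the training normals
  is_norm <- tr_cls == "Normal"
  norm_profiles <- lapply(tr_feats[is_norm], `[[`, "pti_profile")
  norm_epi <- lapply(tr_feats[is_norm], `[[`, "epi_profile")
  profile_model <- list(pti_p95 = NULL, epi_pti_p95 = NULL)
  tmp_norm <- normative_percentiles(data.frame(x = 0), norm_profiles,
                                    norm_epi)
  profile_model$pti_p95 <- tmp_norm$pti_p95
  profile_model$epi_pti_p95 <- tmp_norm$epi_pti_p95
  # assemble training index table, then percentiles + cutoffs on it
  tr_tab <- as.data.frame(do.call(rbind, lapply(
    tr_feats, assemble_index_vector, ei_w_f = ei_w_f, ei_w_b = ei_w_b,
    normative = profile_model)))
  normative <- normative_percentiles(tr_tab[is_norm, ], norm_profiles,
                                     norm_epi,
                                     cohort_id = "training-normals",
                                     seed = config$seed)
  cutoffs <- feature_cutoffs(as.matrix(tr_tab))
  tick("training_models")
  say("ectatic-index weights, normative model and cutoffs fitted")
  # ---- perceptron training (training partition only) -------------------
  grid_cfgs <- lapply(seq_along(config$mlp_grid), function(i) {
    cfg <- config$mlp_grid[[i]]
    cfg$seed <- cfg$seed %||% (config$seed + 29L + i)
    cfg
  })
  # ---- pass 2: test scans against the frozen components ----------------
  for (i in split$test) {
    scan <- generate_cornea(plan$class[i],
                            sample_phenotype_params(plan$class[i],
                                                    plan$scan_seed[i]),
                            grid = config$grid, seed = plan$scan_seed[i],
                            laterality = plan$laterality[i],
                            scan_id = plan$scan_id[i])
    feats[[i]] <- compute_scan_features(scan)
  }
  te_tab <- as.data.frame(do.call(rbind, lapply(
    feats[split$test], assemble_index_vector, ei_w_f = ei_w_f,
    ei_w_b = ei_w_b, normative = profile_model)))
  tick("test_features")
  classes <- intersect(DIAGNOSTIC_CLASSES, unique(plan$class))
  y_tr <- factor(tr_cls, levels = classes)
  y_te <- factor(plan$class[split$test], levels = classes)
  search <- hyperparameter_search(as.matrix(tr_tab), y_tr,
                                  as.matrix(te_tab), y_te, grid_cfgs,
                                  cutoffs = cutoffs,
                                  class_weights = config$class_weights)
  model <- search$model
  tick("mlp_training")
  say("perceptron trained (%d configuration%s)", length(grid_cfgs),
      if (length(grid_cfgs) > 1) "s" else "")
  # ---- evaluation ------------------------------------------------------
  pred <- predict(model, as.matrix(te_tab))$class
  cm <- confusion_matrix(y_te, pred, classes = classes)
  metrics <- metrics_table(cm)
  all_tab <- rbind(cbind(tr_tab, partition = "train",
                         class = as.character(y_tr),
                         scan_id = plan$scan_id[split$train]),
                   cbind(te_tab, partition = "test",
                         class = as.character(y_te),
                         scan_id = plan$scan_id[split$test]))
  auc_nk <- if (all(c("Normal", "Kcn") %in% y_te))
    auc_table(te_tab, as.character(y_te), "Kcn", "Normal") else NULL
  auc_ns <- if (all(c("Normal", "SKcn") %in% y_te))
    auc_table(te_tab, as.character(y_te), "SKcn", "Normal") else NULL
  tick("evaluation")
  manifest <- list(
    package_version = as.character(utils::packageVersion("kcscreen")),
    config_checksum = object_checksum(config[c("n_per_class", "seed",
                                               "train_fraction",
                                               "mlp_grid")]),
    stages = list(
      cohort_plan = object_checksum(plan),
      split = object_checksum(split),
      ei_weights = object_checksum(list(ei_w_f, ei_w_b)),
      normative = object_checksum(normative),
      train_indexes = object_checksum(tr_tab),
      test_indexes = object_checksum(te_tab),
      model = object_checksum(model[c("weights", "biases", "cutoffs")]),
      confusion = object_checksum(cm$counts)))
  out <- list(model = model,
              ei_weights = list(anterior = ei_w_f, posterior = ei_w_b),
              normative = normative, cutoffs = cutoffs,
              confusion = cm, metrics = metrics,
              auc_normal_kcn = auc_nk, auc_normal_skcn = auc_ns,
              index_table = all_tab, labels = plan$class, split = split,
              search_report = search$report, manifest = manifest,
              timings = stage_time, config = config)
  class(out) <- "kc_study"
  out
}

#' @export
print.kc_study <- function(x, ...) {
  cat("Synthetic keratoconus screening study\n")
  cat(sprintf("  cohort: %d eyes, %d train / %d test\n",
              length(x$labels), length(x$split$train),
              length(x$split$test)))
  print(x$confusion)
  cat("\nPer-class metrics:\n")
  print(round(x$metrics, 4))
  invisible(x)
}

#' @export
summary.kc_study <- function(object, ...) {
  print(object)
  if (!is.null(object$auc_normal_kcn)) {
    cat("\nPer-index AUC, Normal vs Kcn (test set):\n")
    print(object$auc_normal_kcn, row.names = FALSE)
  }
  invisible(object)
}

#' Save a trained screening model bundle
#'
#' Writes the frozen components needed to classify new scans — perceptron
#' layer sizes, weights and biases, activation steepness, normalization
#' cutoffs, class order, ectatic-index weights and the normative percentile
#' model — as a single JSON file.
#'
#' @param study A `kc_study` (or a list with `model`, `ei_weights`,
#'   `normative`, `cutoffs`).
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
save_model_bundle <- function(study, path) {
  m <- study$model
  bundle <- list(
    format = "kcscreen-bundle",
    version = 1L,
    package_version = as.character(utils::packageVersion("kcscreen")),
    layer_sizes = m$layer_sizes,
    sigma = m$sigma,
    classes = m$classes,
    weights = lapply(m$weights, function(w) as.data.frame(w)),
    biases = m$biases,
    cutoffs = as.data.frame(study$cutoffs),
    ei_weights = lapply(study$ei_weights, function(w)
      list(alpha1 = as.list(w$alpha1), alpha2 = as.list(w$alpha2),
           side = w$side)),
    normative = list(
      percentiles = as.data.frame(study$normative$percentiles),
      pti_p95 = study$normative$pti_p95,
      epi_pti_p95 = study$normative$epi_pti_p95,
      provenance = study$normative$provenance))
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a screening model bundle
#'
#' @param path JSON path written by [save_model_bundle()].
#' @return List with `model` (`kc_mlp`), `ei_weights`, `normative`.
#' @export
load_model_bundle <- function(path) {
  if (!file.exists(path)) stop("bundle file does not exist: ", path)
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(b$format) || b$format != "kcscreen-bundle")
    stop("not a kcscreen model bundle: ", path)
  if (is.null(b$version) || b$version != 1L)
    stop("unsupported bundle version: ", b$version)
  cutoffs <- as.matrix(b$cutoffs)
  rownames(cutoffs) <- c("low", "high")
  model <- list(layer_sizes = b$layer_sizes,
                weights = lapply(b$weights, as.matrix),
                biases = lapply(b$biases, as.numeric),
                sigma = b$sigma, cutoffs = cutoffs, classes = b$classes,
                training_log = numeric(0),
                config = list())
  class(model) <- "kc_mlp"
  mk_ei <- function(w) {
    out <- list(alpha1 = unlist(w$alpha1), alpha2 = unlist(w$alpha2),
                side = w$side, n_train = NA_integer_)
    class(out) <- "ei_weights"
    out
  }
  normative <- list(percentiles = as.matrix(b$normative$percentiles),
                    pti_p95 = lapply(b$normative$pti_p95, as.numeric),
                    epi_pti_p95 = lapply(b$normative$epi_pti_p95,
                                         as.numeric),
                    provenance = b$normative$provenance)
  class(normative) <- "normative_model"
  list(model = model,
       ei_weights = lapply(b$ei_weights, mk_ei),
       normative = normative)
}

#' Classify a single scan with a trained model bundle
#'
#' Computes the 19-index vector of the scan, runs the perceptron, and
#' reports the winner-take-all class, the raw per-class outputs, and the
#' normality flag of every index against the normative percentile ranges.
#'
#' @param bundle A [load_model_bundle()] result (or `kc_study`).
#' @param scan A [corneal_scan()] (or path to a scan file).
#' @return List with `class`, `outputs`, `indexes` and `flags` (19 named
#'   normal/borderline/abnormal strings).
#' @export
classify_scan <- function(bundle, scan) {
  if (is.character(scan)) scan <- read_scan(scan)
  if (inherits(bundle, "kc_study"))
    bundle <- list(model = bundle$model,
                   ei_weights = bundle$ei_weights,
                   normative = bundle$normative)
  v <- compute_index_vector(scan, bundle$ei_weights$anterior,
                            bundle$ei_weights$posterior, bundle$normative)
  pred <- predict(bundle$model, rbind(as.numeric(v)))
  pct <- bundle$normative$percentiles
  flags <- vapply(INDEX_NAMES, function(ix)
    normality_flag(v[[ix]], stats::setNames(pct[, ix],
                                            rownames(pct))),
    character(1))
  list(class = as.character(pred$class), outputs = drop(pred$outputs),
       indexes = v, flags = flags)
}
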