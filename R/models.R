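# Per-residue-type weighted gradient-boosted classifiers.
#
# One binary classifier per standard amino-acid type, each trained on the
# rows of that type only, with the positive (AFR) class up-weighted by
# scale_pos_weight (default "auto" = n_FR / n_AFR of the training subset).

#' Model configuration
#'
#' Boosting knobs mirror the conventional search bounds: depth 3-10,
#' learning rate 0.001-0.5, iterations 100-1000.  Defaults are library-style
#' defaults plus automatic positive-class weighting; no hyperparameter
#' search is performed.
#'
#' @param scale_pos_weight Positive real, or `"auto"` (n_neg/n_pos per
#'   subset).
#' @param iterations Number of boosting rounds.
#' @param depth Maximum tree depth.
#' @param learning_rate Shrinkage.
#' @param l2_leaf_reg L2 regularisation on leaf values.
#' @param seed Integer seed recorded in the config (the learner itself is
#'   deterministic).
#' @param feature_manifest Character vector of feature column names, or NULL
#'   to use all descriptor columns at training time.
#' @return List of class `allo_model_config`.
#' @export
model_config <- function(scale_pos_weight = "auto", iterations = 200L,
                         depth = 4L, learning_rate = 0.1, l2_leaf_reg = 3.0,
                         seed = 1L, feature_manifest = NULL) {
  stopifnot(identical(scale_pos_weight, "auto") ||
              (is.numeric(scale_pos_weight) && scale_pos_weight > 0))
  if (!(depth >= 1 && depth <= 10))
    stop("model_config: depth must lie in [1, 10]")
  if (!(learning_rate >= 0.001 && learning_rate <= 0.5))
    stop("model_config: learning_rate must lie in [0.001, 0.5]")
  if (!(iterations >= 1 && iterations <= 1000))
    stop("model_config: iterations must lie in [1, 1000]")
  structure(list(scale_pos_weight = scale_pos_weight,
                 iterations = as.integer(iterations), depth = as.integer(depth),
                 learning_rate = learning_rate, l2_leaf_reg = l2_leaf_reg,
                 seed = as.integer(seed), feature_manifest = feature_manifest),
            class = "allo_model_config")
}

#' Split a descriptor table by residue type
#'
#' @param table Descriptor table with a `res_name` column.
#' @return List with `subsets` (named list of sub-tables, standard types
#'   only) and `excluded` (data.frame res_name, n for non-standard rows).
#' @export
partition_by_residue_type <- function(table) {
  std <- table$res_name %in% .aa_three
  excl <- table(table$res_name[!std])
  subsets <- split(as.data.frame(table)[std, , drop = FALSE],
                   table$res_name[std])
  list(subsets = subsets,
       excluded = data.frame(res_name = names(excl), n = as.integer(excl),
                             stringsAsFactors = FALSE))
}

#' Positive-class weight from class counts
#'
#' @param n_pos,n_neg AFR and FR row counts.
#' @return n_neg / n_pos.
#' @export
class_weight <- function(n_pos, n_neg) {
  if (n_pos <= 0) stop("cannot train: no AFR rows for this residue type")
  n_neg / n_pos
}

#' Mean binary log-loss
#'
#' L = -(1/N) sum y log(p) + (1-y) log(1-p), probabilities clipped to
#' \[1e-15, 1-1e-15\].
#'
#' @param y Binary labels (0/1 or "FR"/"AFR").
#' @param y_hat Predicted probabilities.
#' @return Non-negative scalar.
#' @export
log_loss <- function(y, y_hat) {
  if (length(y) == 0) stop("log_loss: empty input")
  if (is.character(y) || is.factor(y)) y <- as.integer(as.character(y) == "AFR")
  stopifnot(length(y) == length(y_hat))
  p <- pmin(pmax(y_hat, 1e-15), 1 - 1e-15)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

.fit_gbt <- function(X, y, weights, config) {
  .gbt_fit_cpp(X, as.numeric(y), as.numeric(weights),
               config$iterations, config$depth, config$learning_rate,
               config$l2_leaf_reg, 1e-3, 64L)
}

.feature_matrix <- function(table, features) {
  miss <- setdiff(features, names(table))
  if (length(miss) > 0)
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  as.matrix(as.data.frame(table)[, features, drop = FALSE])
}

#' Train the per-residue-type classifier ensemble
#'
#' @param subsets Named list of per-type descriptor sub-tables (see
#'   [partition_by_residue_type()]), or a full descriptor table (it is
#'   partitioned internally).
#' @param config [model_config()].
#' @return Object of class `allo_ensemble`: `models` (per-type boosted
#'   trees), `config`, `features` (manifest), `training_stats`, `skipped`.
#' @export
train_ensemble <- function(subsets, config = model_config()) {
  if (is.data.frame(subsets)) {
    if (is.null(config$feature_manifest))
      config$feature_manifest <- descriptor_columns(subsets)
    subsets <- partition_by_residue_type(subsets)$subsets
  }
  if (is.null(config$feature_manifest))
    stop("train_ensemble: config$feature_manifest required when passing ",
         "pre-partitioned subsets")
  features <- config$feature_manifest
  models <- list(); stats <- list(); skipped <- character(0)
  for (rn in names(subsets)) {
    tb <- subsets[[rn]]
    y <- as.integer(tb$label == "AFR")
    if (sum(y) == 0 || sum(1 - y) == 0) { skipped <- c(skipped, rn); next }
    spw <- if (identical(config$scale_pos_weight, "auto"))
      class_weight(sum(y), sum(1 - y)) else config$scale_pos_weight
    w <- ifelse(y == 1, spw, 1)
    X <- .feature_matrix(tb, features)
    models[[rn]] <- .fit_gbt(X, y, w, config)
    stats[[rn]] <- data.frame(res_name = rn, n = length(y), n_afr = sum(y),
                              n_fr = sum(1 - y), scale_pos_weight = spw,
                              stringsAsFactors = FALSE)
  }
  if (length(models) == 0)
    stop("train_ensemble: no residue type had both classes")
  structure(list(models = models, config = config, features = features,
                 training_stats = do.call(rbind, stats), skipped = skipped),
            class = "allo_ensemble")
}

#' @export
print.allo_ensemble <- function(x, ...) {
  cat(sprintf("<allo_ensemble> %d residue-type model(s) [%s], %d feature(s)\n",
              length(x$models), paste(names(x$models), collapse = ", "),
              length(x$features)))
  invisible(x)
}

#' Predict AFR probabilities for a descriptor table
#'
#' Each row is routed to its residue-type model; rows of types without a
#' model receive `NA` probability and label FR.
#'
#' @param ensemble [train_ensemble()] result.
#' @param table Descriptor table whose columns cover the feature manifest.
#' @param threshold Decision threshold on probability (default 0.5).
#' @return data.frame identity, res_name, probability, predicted_label.
#' @export
predict_residues <- function(ensemble, table, threshold = 0.5) {
  tb <- as.data.frame(table)
  if (nrow(tb) == 0)
    return(data.frame(identity = character(0), res_name = character(0),
                      probability = numeric(0), predicted_label = character(0),
                      stringsAsFactors = FALSE))
  prob <- rep(NA_real_, nrow(tb))
  for (rn in names(ensemble$models)) {
    rows <- which(tb$res_name == rn)
    if (length(rows) == 0) next
    X <- .feature_matrix(tb[rows, , drop = FALSE], ensemble$features)
    prob[rows] <- stats::plogis(.gbt_margin_cpp(ensemble$models[[rn]], X))
  }
  data.frame(identity = tb$identity, res_name = tb$res_name,
             probability = prob,
             predicted_label = ifelse(!is.na(prob) & prob >= threshold,
                                      "AFR", "FR"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-descriptor importance of the ensemble
#'
#' `attribution`: per-path split attribution (Saabas-style contributions on
#' the margin scale), summarised as the mean absolute contribution of each
#' feature over the supplied rows.  `permutation`: mean drop in ROC-AUC over
#' `k` label-preserving shuffles of each feature column.
#'
#' @param ensemble [train_ensemble()] result.
#' @param table Descriptor table with labels.
#' @param method `"attribution"` or `"permutation"`.
#' @param seed Seed for the permutation shuffles.
#' @param k Number of shuffles per feature (permutation method).
#' @return List with `per_model` (matrix res_type x feature) and
#'   `ensemble_mean` (named vector, mean over models with rows present).
#' @export
feature_importance <- function(ensemble, table,
                               method = c("attribution", "permutation"),
                               seed = 1L, k = 10L) {
  method <- match.arg(method)
  tb <- as.data.frame(table)
  stopifnot(nrow(tb) > 0)
  feats <- ensemble$features
  per <- matrix(NA_real_, nrow = length(ensemble$models),
                ncol = length(feats),
                dimnames = list(names(ensemble$models), feats))
  for (rn in names(ensemble$models)) {
    rows <- which(tb$res_name == rn)
    if (length(rows) == 0) next
    X <- .feature_matrix(tb[rows, , drop = FALSE], feats)
    if (method == "attribution") {
      contrib <- .gbt_contrib_cpp(ensemble$models[[rn]], X)
      per[rn, ] <- colMeans(abs(contrib[, seq_along(feats), drop = FALSE]))
    } else {
      y <- as.integer(tb$label[rows] == "AFR")
      if (sum(y) == 0 || sum(1 - y) == 0) next
      base_auc <- roc_auc(y, stats::plogis(
        .gbt_margin_cpp(ensemble$models[[rn]], X)))
      set.seed(seed)
      for (f in seq_along(feats)) {
        drops <- numeric(k)
        for (r in seq_len(k)) {
          Xp <- X
          Xp[, f] <- X[sample.int(nrow(X)), f]
          drops[r] <- base_auc - roc_auc(y, stats::plogis(
            .gbt_margin_cpp(ensemble$models[[rn]], Xp)))
        }
        per[rn, f] <- max(0, mean(drops))
      }
    }
  }
  list(per_model = per,
       ensemble_mean = colMeans(per, na.rm = TRUE))
}

# ---- persistence ----

#' Save an ensemble as a plain-text model directory
#'
#' Layout: `manifest.json` (feature order, config, training stats) plus
#' `models/<RES>.json`, one JSON tree dump per residue type.
#'
#' @param ensemble [train_ensemble()] result.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(file.path(dir, "models"), recursive = TRUE, showWarnings = FALSE)
  manifest <- list(features = ensemble$features,
                   config = unclass(ensemble$config),
                   training_stats = ensemble$training_stats,
                   skipped = ensemble$skipped,
                   residue_types = names(ensemble$models))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (rn in names(ensemble$models)) {
    m <- ensemble$models[[rn]]
    # doubles as %.17g strings: split thresholds are data values, so the
    # round trip must be bit-exact or boundary rows change routing
    ser <- list(
      base_score = sprintf("%.17g", m$base_score),
      n_features = m$n_features,
      trees = lapply(m$trees, function(tr) list(
        feature = as.integer(tr$feature),
        threshold = sprintf("%.17g", tr$threshold),
        left = as.integer(tr$left), right = as.integer(tr$right),
        value = sprintf("%.17g", tr$value),
        leaf = as.logical(tr$leaf))))
    jsonlite::write_json(ser, file.path(dir, "models", paste0(rn, ".json")),
                         auto_unbox = FALSE)
  }
  invisible(dir)
}

#' Load an ensemble saved by [save_ensemble()]
#' @param dir Model directory.
#' @return `allo_ensemble`.
#' @export
load_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  models <- list()
  for (rn in manifest$residue_types) {
    m <- jsonlite::read_json(file.path(dir, "models", paste0(rn, ".json")),
                             simplifyVector = FALSE)
    trees <- lapply(m$trees, function(tr) list(
      feature = as.integer(unlist(tr$feature)),
      threshold = as.numeric(unlist(tr$threshold)),
      left = as.integer(unlist(tr$left)),
      right = as.integer(unlist(tr$right)),
      value = as.numeric(unlist(tr$value)),
      leaf = as.logical(unlist(tr$leaf))))
    models[[rn]] <- list(base_score = as.numeric(m$base_score[[1]]),
                         trees = trees,
                         n_features = as.integer(m$n_features[[1]]))
  }
  cfg <- manifest$config
  config <- model_config(scale_pos_weight = cfg$scale_pos_weight,
                         iterations = cfg$iterations, depth = cfg$depth,
                         learning_rate = cfg$learning_rate,
                         l2_leaf_reg = cfg$l2_leaf_reg, seed = cfg$seed,
                         feature_manifest = manifest$features)
  structure(list(models = models, config = config,
                 features = manifest$features,
                 training_stats = manifest$training_stats,
                 skipped = manifest$skipped),
            class = "allo_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
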