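# Chain-centric splitting, DCC site-level evaluation, residue-level
# classification metrics, and pocket-coverage auditing.

#' Chain-centric train/validation/test split
#'
#' Shuffles composite chain keys ("PDBcode_chain") with the given seed and
#' partitions them: validation and test sizes are `round(fraction * n)`,
#' the remainder goes to train.  Every key lands in exactly one subset.
#'
#' @param keys Character vector of unique composite chain keys.
#' @param fractions Numeric length-3 (train, validation, test), summing to 1
#'   within 0.01.
#' @param seed Integer seed.
#' @return List of class `allo_split`: `assignment` (named character
#'   vector), `sizes`, `fractions_requested`, `fractions_achieved`.
#' @export
chain_centric_split <- function(keys, fractions = c(0.5, 0.25, 0.25),
                                seed = 1L) {
  if (anyDuplicated(keys)) stop("chain_centric_split: duplicate keys")
  stopifnot(length(fractions) == 3, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 0.01)
    stop("chain_centric_split: fractions must sum to 1 (tolerance 0.01)")
  n <- length(keys)
  n_val <- round(fractions[2] * n)
  n_test <- round(fractions[3] * n)
  n_train <- n - n_val - n_test
  if (n_train < 0) stop("chain_centric_split: fractions leave no train rows")
  perm <- .with_seed(seed, sample.int(n))
  shuffled <- keys[perm]
  assignment <- setNames(rep(c("train", "validation", "test"),
                             c(n_train, n_val, n_test)), shuffled)
  assignment <- assignment[keys]
  structure(list(assignment = assignment,
                 sizes = c(train = n_train, validation = n_val, test = n_test),
                 fractions_requested = fractions,
                 fractions_achieved = c(n_train, n_val, n_test) / n),
            class = "allo_split")
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Distance Center Center (DCC) between predicted and true residue sets
#'
#' Euclidean distance between the heavy-atom centroids of the predicted and
#' the true site residues.  Returns `NA` when the predicted set is empty
#' (the "no prediction" case).
#'
#' @param pred_residues,true_residues Character vectors of residue
#'   identities.
#' @param structure `allo_structure` containing all named residues.
#' @return Distance in Angstrom, or `NA_real_`.
#' @export
dcc <- function(pred_residues, true_residues, structure) {
  if (length(pred_residues) == 0) return(NA_real_)
  if (length(true_residues) == 0) stop("dcc: empty true residue set")
  res <- polymer_residues(structure)
  miss <- setdiff(c(pred_residues, true_residues), names(res))
  if (length(miss) > 0)
    stop("dcc: residue(s) missing from structure: ",
         paste(head(miss, 5), collapse = ", "))
  cp <- centroid(do.call(rbind, res[pred_residues]))
  ct <- centroid(do.call(rbind, res[true_residues]))
  sqrt(sum((cp - ct)^2))
}

#' DCC success rate
#'
#' @param dcc_values Numeric vector of DCC values, `NA` = no prediction.
#' @param cutoff Success threshold, Angstrom (default 4).
#' @param undefined_policy `"exclude"` drops NA values from the denominator
#'   (mirrors "N/A" handling); `"count_as_failure"` keeps them as misses.
#' @return Percentage in \[0, 100\].
#' @export
success_rate <- function(dcc_values, cutoff = 4.0,
                         undefined_policy = c("exclude", "count_as_failure")) {
  undefined_policy <- match.arg(undefined_policy)
  if (length(dcc_values) == 0) stop("success_rate: empty input")
  hits <- sum(dcc_values <= cutoff, na.rm = TRUE)
  denom <- if (undefined_policy == "exclude") sum(!is.na(dcc_values))
           else length(dcc_values)
  if (denom == 0) return(NA_real_)
  100 * hits / denom
}

#' ROC-AUC by the rank (Mann-Whitney) statistic
#' @param y Binary labels (0/1 or "FR"/"AFR").
#' @param scores Numeric scores.
#' @return AUC in \[0, 1\]; `NA` if one class is absent.
#' @export
roc_auc <- function(y, scores) {
  if (is.character(y) || is.factor(y)) y <- as.integer(as.character(y) == "AFR")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Residue-level classification metrics
#'
#' @param y True labels (0/1 or "FR"/"AFR").
#' @param scores Predicted probabilities (NA treated as 0 = confident FR).
#' @param threshold Decision threshold.
#' @return List of class `allo_metrics`: tp, tn, fp, fn, accuracy,
#'   precision, recall, f1, mcc, roc_auc (mcc/roc_auc `NA` when a class is
#'   absent).
#' @export
classification_metrics <- function(y, scores, threshold = 0.5) {
  if (is.character(y) || is.factor(y)) y <- as.integer(as.character(y) == "AFR")
  if (length(y) != length(scores))
    stop("classification_metrics: length mismatch")
  s <- ifelse(is.na(scores), 0, scores)
  pred <- as.integer(s >= threshold)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  metrics_from_counts(tp, fp, fn, tn, roc_auc = roc_auc(y, s))
}

#' Metrics from confusion-matrix counts
#' @param tp,fp,fn,tn Confusion counts.
#' @param roc_auc Optional AUC to attach.
#' @return `allo_metrics` list.
#' @export
metrics_from_counts <- function(tp, fp, fn, tn, roc_auc = NA_real_) {
  n <- tp + fp + fn + tn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- f1_score(precision, recall)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (isTRUE(denom > 0)) (tp * tn - fp * fn) / denom else NA_real_
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = if (n > 0) (tp + tn) / n else NA_real_,
                 precision = precision, recall = recall, f1 = f1, mcc = mcc,
                 roc_auc = roc_auc),
            class = "allo_metrics")
}

#' F1 score from precision and recall
#' @param precision,recall Rates in \[0, 1\].
#' @return 2PR/(P+R), `NA` if undefined.
#' @export
f1_score <- function(precision, recall) {
  if (is.na(precision) || is.na(recall) || precision + recall == 0)
    return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' @export
print.allo_metrics <- function(x, ...) {
  cat(sprintf(
    "<metrics> n=%d  P=%.4f R=%.4f F1=%.4f MCC=%.4f AUC=%.4f\n",
    x$tp + x$tn + x$fp + x$fn, x$precision, x$recall, x$f1, x$mcc, x$roc_auc))
  invisible(x)
}

#' Pocket-coverage audit of AFR residues
#'
#' Counts how many labelled AFRs fall inside any externally supplied pocket
#' residue set of their chain.
#'
#' @param afr_sets Named list: chain key -> character vector of AFR residue
#'   identities.
#' @param pocket_sets Named list: chain key -> list of pocket residue-sets
#'   (each a character vector).  Chains absent here count with empty
#'   pockets (warning).
#' @return List n_in, n_out, percent_out.
#' @export
pocket_coverage <- function(afr_sets, pocket_sets) {
  missing_chains <- setdiff(names(afr_sets), names(pocket_sets))
  if (length(missing_chains) > 0)
    warning("pocket_coverage: no pockets for chain(s) ",
            paste(missing_chains, collapse = ", "), "; counted as outside")
  n_in <- 0L; n_out <- 0L
  for (ch in names(afr_sets)) {
    in_pocket <- unique(unlist(pocket_sets[[ch]]))
    inside <- afr_sets[[ch]] %in% in_pocket
    n_in <- n_in + sum(inside); n_out <- n_out + sum(!inside)
  }
  list(n_in = n_in, n_out = n_out,
       percent_out = percent_outside(n_in, n_out))
}

#' Percentage of AFRs outside any pocket
#' @param n_in,n_out Counts of AFRs inside / outside pockets.
#' @return 100 * n_out / (n_in + n_out).
#' @export
percent_outside <- function(n_in, n_out) {
  if (n_in + n_out == 0) return(NA_real_)
  100 * n_out / (n_in + n_out)
}

#' Read pocket residue sets from TSV
#'
#' Neutral importer for third-party pocket-detector output: tab-separated
#' columns `chain`, `pocket_id`, `identity` (residue identity string).
#'
#' @param path TSV file.
#' @return Named list chain -> list of pocket residue-identity vectors.
#' @export
read_pocket_sets <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chain", "pocket_id", "identity")
  if (!all(need %in% names(tab)))
    stop("read_pocket_sets: TSV must have columns ",
         paste(need, collapse = ", "))
  lapply(split(tab, tab$chain),
         function(b) lapply(split(b$identity, b$pocket_id), unique))
}
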