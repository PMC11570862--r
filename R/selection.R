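# Descriptor selection: Pearson-correlation pruning followed by two-sample
# Kolmogorov-Smirnov filtering (in that order).

#' Selection configuration
#'
#' @param rho_max Maximum allowed pairwise |Pearson correlation| (default
#'   0.7; pairs with |rho| exactly at the threshold are kept).
#' @param alpha KS significance level (default 0.05).
#' @param correction Multiple-testing correction: `"none"` (default) or
#'   `"benjamini_hochberg"`.
#' @return List of class `allo_selection_config`.
#' @export
selection_config <- function(rho_max = 0.7, alpha = 0.05,
                             correction = c("none", "benjamini_hochberg")) {
  stopifnot(rho_max > 0, rho_max <= 1, alpha > 0, alpha < 1)
  structure(list(rho_max = rho_max, alpha = alpha,
                 correction = match.arg(correction)),
            class = "allo_selection_config")
}

#' Greedy correlation pruning
#'
#' While any pair of surviving columns has |rho| above `rho_max`, drop from
#' the worst pair the member with the larger mean absolute correlation to
#' all other surviving columns (ties: drop the later column).  Zero-variance
#' columns are treated as uncorrelated with everything (kept, with warning).
#'
#' @param x Numeric data.frame/matrix of descriptor columns (rows =
#'   residues), or a descriptor table (its descriptor columns are used).
#' @param rho_max Threshold on |rho|.
#' @return List with `kept` (column names) and `dropped` (data.frame
#'   descriptor, partner, rho).
#' @export
correlation_prune <- function(x, rho_max = 0.7) {
  x <- .numeric_descriptor_frame(x)
  stopifnot(nrow(x) >= 2)
  cols <- names(x)
  sds <- vapply(x, stats::sd, numeric(1))
  if (any(sds == 0 | is.na(sds)))
    warning("correlation_prune: constant column(s) kept as uncorrelated: ",
            paste(cols[sds == 0 | is.na(sds)], collapse = ", "))
  C <- suppressWarnings(abs(stats::cor(x)))
  C[!is.finite(C)] <- 0
  diag(C) <- 0
  alive <- rep(TRUE, length(cols))
  dropped <- data.frame(descriptor = character(0), partner = character(0),
                        rho = numeric(0), stringsAsFactors = FALSE)
  repeat {
    Ca <- C[alive, alive, drop = FALSE]
    if (length(Ca) == 0 || max(Ca) <= rho_max) break
    idx <- which(Ca == max(Ca), arr.ind = TRUE)[1, ]
    pair <- which(alive)[idx]
    mean_cor <- vapply(pair, function(k)
      mean(C[k, alive & seq_along(alive) != k]), numeric(1))
    # drop larger mean |rho|; ties -> later column in input order
    loser <- if (mean_cor[1] > mean_cor[2]) pair[1]
             else if (mean_cor[2] > mean_cor[1]) pair[2]
             else max(pair)
    winner <- setdiff(pair, loser)
    dropped <- rbind(dropped, data.frame(
      descriptor = cols[loser], partner = cols[winner],
      rho = C[loser, winner], stringsAsFactors = FALSE))
    alive[loser] <- FALSE
  }
  list(kept = cols[alive], dropped = dropped)
}

#' Kolmogorov-Smirnov class-separation filter
#'
#' Two-sample KS test of each descriptor's AFR values against its FR values;
#' a descriptor is kept iff its (optionally BH-corrected) p-value is below
#' `alpha`.  The exact p-value is used when the smaller class has fewer than
#' 25 rows, the asymptotic approximation otherwise.
#'
#' @param x Numeric descriptor columns (see [correlation_prune()]).
#' @param labels Character/factor vector, "AFR"/"FR", one per row.
#' @param config [selection_config()].
#' @return List with `kept` (column names) and `ks_stats` (data.frame
#'   descriptor, D, p, p_adj, kept).
#' @export
ks_filter <- function(x, labels, config = selection_config()) {
  x <- .numeric_descriptor_frame(x)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(x))
  n_pos <- sum(labels == "AFR"); n_neg <- sum(labels == "FR")
  if (n_pos == 0 || n_neg == 0)
    stop("ks_filter: both classes must be present (AFR=", n_pos,
         ", FR=", n_neg, ")")
  if (min(n_pos, n_neg) < 8)
    stop("ks_filter: need >= 8 rows per class")
  exact <- min(n_pos, n_neg) < 25
  res <- lapply(names(x), function(cc) {
    a <- x[[cc]][labels == "AFR"]; f <- x[[cc]][labels == "FR"]
    kt <- suppressWarnings(stats::ks.test(a, f, exact = exact))
    c(D = unname(kt$statistic), p = kt$p.value)
  })
  D <- vapply(res, `[[`, numeric(1), "D")
  p <- vapply(res, `[[`, numeric(1), "p")
  p_adj <- if (config$correction == "benjamini_hochberg")
    stats::p.adjust(p, "BH") else p
  kept <- p_adj < config$alpha
  list(kept = names(x)[kept],
       ks_stats = data.frame(descriptor = names(x), D = D, p = p,
                             p_adj = p_adj, kept = kept,
                             stringsAsFactors = FALSE))
}

#' Full selection pipeline: correlation pruning then KS filtering
#'
#' @param table Descriptor table (or numeric frame plus `labels`).
#' @param labels Labels; defaults to `table$label`.
#' @param config [selection_config()].
#' @return List of class `allo_selection_report`: `kept`, `dropped_by_correlation`,
#'   `ks_stats`, `config`.
#' @export
select_descriptors <- function(table, labels = table$label,
                               config = selection_config()) {
  x <- .numeric_descriptor_frame(table)
  cp <- correlation_prune(x, config$rho_max)
  ks <- ks_filter(x[cp$kept], labels, config)
  structure(list(kept = ks$kept,
                 dropped_by_correlation = cp$dropped,
                 ks_stats = ks$ks_stats,
                 config = config),
            class = "allo_selection_report")
}

#' @export
print.allo_selection_report <- function(x, ...) {
  cat(sprintf("<selection report> kept %d descriptor(s); %d dropped by |rho| > %.2f; %d dropped by KS (alpha=%.3g)\n",
              length(x$kept), nrow(x$dropped_by_correlation), x$config$rho_max,
              sum(!x$ks_stats$kept), x$config$alpha))
  invisible(x)
}

#' Normal Q-Q points of a sample
#'
#' Order statistics paired with standard-normal quantiles at (i - 0.5)/n;
#' data only, no rendering.
#'
#' @param values Numeric sample (n >= 3).
#' @return data.frame with columns `theoretical`, `sample`.
#' @export
qq_points <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  stopifnot(n >= 3)
  data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
             sample = sort(values))
}

.numeric_descriptor_frame <- function(x) {
  if (inherits(x, "allo_descriptor_table") ||
      (is.data.frame(x) && any(c("identity", "label") %in% names(x))))
    x <- as.data.frame(x)[, descriptor_columns(x), drop = FALSE]
  as.data.frame(x)
}
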