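# Pipeline orchestration: label -> describe -> split -> select (train rows
# only) -> train -> evaluate, with provenance and deterministic seeds.

#' Run configuration
#'
#' @param afr_cutoff AFR distance rule, Angstrom (default 5).
#' @param dcc_cutoff DCC success threshold, Angstrom (default 4).
#' @param threshold Decision threshold on predicted probability (default 0.5).
#' @param split_fractions Train/validation/test fractions.
#' @param seed Integer seed (split shuffling and any stochastic step).
#' @param selection [selection_config()].
#' @param model [model_config()].
#' @param descriptor Named list of descriptor parameters (see
#'   [compute_descriptor_table()]).
#' @param na_policy DCC undefined policy: "exclude" or "count_as_failure".
#' @return List of class `allo_run_config`.
#' @export
run_config <- function(afr_cutoff = 5.0, dcc_cutoff = 4.0, threshold = 0.5,
                       split_fractions = c(0.5, 0.25, 0.25), seed = 1L,
                       selection = selection_config(), model = model_config(),
                       descriptor = list(),
                       na_policy = c("exclude", "count_as_failure")) {
  stopifnot(afr_cutoff > 0, dcc_cutoff > 0, threshold > 0)
  structure(list(afr_cutoff = afr_cutoff, dcc_cutoff = dcc_cutoff,
                 threshold = threshold, split_fractions = split_fractions,
                 seed = as.integer(seed), selection = selection,
                 model = model, descriptor = descriptor,
                 na_policy = match.arg(na_policy)),
            class = "allo_run_config")
}

#' Train the pipeline end to end on holo structures
#'
#' Labels every polymer residue, computes the descriptor panel, splits
#' chains (chain-centric), fits the selection on the training rows only,
#' trains the per-residue-type ensemble on the training rows, and reports
#' validation metrics.
#'
#' @param structures List of holo `allo_structure` objects (each with a
#'   modulator group), or entry lists accepted by [build_dataset()].
#' @param config [run_config()].
#' @param out_dir Optional directory for artifacts (model dir, tables,
#'   provenance JSON).
#' @return List of class `allo_run`: `ensemble`, `selection`, `split`,
#'   `table` (descriptor table with labels), `labels`,
#'   `validation_metrics`.
#' @export
run_train <- function(structures, config = run_config(), out_dir = NULL) {
  if (length(structures) == 0) stop("run_train: empty structure list")
  if (inherits(structures, "allo_structure")) structures <- list(structures)
  entries <- lapply(structures, function(s)
    if (inherits(s, "allo_structure")) list(holo = s) else s)
  structs <- lapply(entries, function(e)
    if (is.character(e$holo)) read_structure(e$holo) else e$holo)
  labels <- build_dataset(entries, distance_cutoff = config$afr_cutoff,
                          compute_lasa_values = FALSE)
  table <- compute_descriptor_table(structs, labels, config$descriptor)
  split <- chain_centric_split(unique(table$chain_key),
                               config$split_fractions, config$seed)
  subset_of <- split$assignment[table$chain_key]
  train_tab <- table[subset_of == "train", , drop = FALSE]
  if (nrow(train_tab) == 0) stop("run_train: empty training split")
  sel <- select_descriptors(train_tab, config = config$selection)
  features <- if (length(sel$kept) > 0) sel$kept
              else descriptor_columns(table) # degenerate: keep all, warn
  if (length(sel$kept) == 0)
    warning("run_train: KS filter kept no descriptor; using full panel")
  mcfg <- config$model
  mcfg$feature_manifest <- features
  ensemble <- train_ensemble(as.data.frame(train_tab), mcfg)
  val_tab <- table[subset_of == "validation", , drop = FALSE]
  val_metrics <- NULL
  if (nrow(val_tab) > 0) {
    pred <- predict_residues(ensemble, val_tab, config$threshold)
    val_metrics <- classification_metrics(val_tab$label, pred$probability,
                                          config$threshold)
  }
  run <- structure(list(ensemble = ensemble, selection = sel, split = split,
                        table = table, labels = labels,
                        validation_metrics = val_metrics, config = config),
                   class = "allo_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_ensemble(ensemble, file.path(out_dir, "ensemble"))
    write_descriptor_table(table, file.path(out_dir, "descriptors.tsv"))
    writeLines(features, file.path(out_dir, "feature_manifest.txt"))
    jsonlite::write_json(
      list(config = .serialise_config(config),
           split = as.list(split$assignment),
           kept_features = features),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  run
}

.serialise_config <- function(config) {
  lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
}

#' Evaluate a trained ensemble on held-out holo structures
#'
#' Produces the per-chain DCC table, success rates under both undefined-DCC
#' policies, and residue-level metrics overall and per residue type.
#'
#' @param run `allo_run` from [run_train()] (or a list with `ensemble` and
#'   `config`).
#' @param structures List of holo `allo_structure` test structures.
#' @param labels Optional precomputed label table; computed if NULL.
#' @param table Optional precomputed descriptor table.
#' @return List of class `allo_evaluation`: `dcc_table`, `success_rate`
#'   (exclude policy), `success_rate_fail_policy`, `metrics_overall`,
#'   `metrics_per_type`, `predictions`.
#' @export
run_evaluate <- function(run, structures, labels = NULL, table = NULL) {
  config <- run$config
  if (inherits(structures, "allo_structure")) structures <- list(structures)
  if (is.null(labels))
    labels <- build_dataset(lapply(structures, function(s) list(holo = s)),
                            distance_cutoff = config$afr_cutoff,
                            compute_lasa_values = FALSE)
  if (is.null(table))
    table <- compute_descriptor_table(structures, labels, config$descriptor)
  pred <- predict_residues(run$ensemble, table, config$threshold)
  m <- match(table$identity, labels$identity)
  truth <- labels$label[m]
  dcc_rows <- list()
  for (s in structures) {
    for (ck in unique(table$chain_key[table$chain_key %in%
                                      paste0(s$id, "_", s$atoms$chain)])) {
      rows <- table$chain_key == ck
      true_set <- table$identity[rows & truth == "AFR"]
      pred_set <- pred$identity[rows & pred$predicted_label == "AFR"]
      d <- if (length(true_set) == 0) NA_real_
           else dcc(pred_set, true_set, s)
      dcc_rows[[length(dcc_rows) + 1]] <-
        data.frame(chain_key = ck, n_true = length(true_set),
                   n_pred = length(pred_set), dcc = d,
                   success = !is.na(d) & d <= config$dcc_cutoff,
                   stringsAsFactors = FALSE)
    }
  }
  dcc_table <- do.call(rbind, dcc_rows)
  overall <- classification_metrics(truth, pred$probability, config$threshold)
  per_type <- lapply(split(seq_len(nrow(table)), table$res_name), function(ix) {
    classification_metrics(truth[ix], pred$probability[ix], config$threshold)
  })
  structure(list(
    dcc_table = dcc_table,
    success_rate = success_rate(dcc_table$dcc, config$dcc_cutoff, "exclude"),
    success_rate_fail_policy = success_rate(dcc_table$dcc, config$dcc_cutoff,
                                            "count_as_failure"),
    metrics_overall = overall, metrics_per_type = per_type,
    predictions = pred), class = "allo_evaluation")
}

#' Write an evaluation report to disk
#' @param evaluation `allo_evaluation`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_evaluation <- function(evaluation, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dt <- evaluation$dcc_table
  dt$dcc <- ifelse(is.na(dt$dcc), "N/A", sprintf("%.2f", dt$dcc))
  utils::write.table(dt, file.path(dir, "dcc.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  per <- do.call(rbind, lapply(names(evaluation$metrics_per_type), function(rn) {
    m <- evaluation$metrics_per_type[[rn]]
    data.frame(Residue = rn, F1 = m$f1, MCC = m$mcc, Recall = m$recall,
               Precision = m$precision, stringsAsFactors = FALSE)
  }))
  utils::write.table(per, file.path(dir, "metrics_per_type.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(success_rate = evaluation$success_rate,
         success_rate_fail_policy = evaluation$success_rate_fail_policy,
         metrics_overall = unclass(evaluation$metrics_overall)),
    file.path(dir, "report.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(dir)
}

# ---- command-line interface ----

#' Command-line entry point
#'
#' Subcommands: `simulate` (write synthetic fixtures + label TSV),
#' `label`, `train`, `evaluate`.  Flags: `--seed`, `--threshold`,
#' `--dcc-cutoff`, `--na-policy`, `--out`, `--n-fixtures`.  Returns exit
#' code 0 on success, 2 on contract violations.
#'
#' @param args Character vector (default: command-line arguments).
#' @return Integer exit code, invisibly.
#' @export
allo_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (length(args) == 0) stop("usage: alloscan <simulate|label|train|evaluate> ...")
    cmd <- args[1]; rest <- args[-1]
    opt <- function(name, default) {
      hit <- which(rest == paste0("--", name))
      if (length(hit) == 1 && hit < length(rest)) rest[hit + 1] else default
    }
    seed <- as.integer(opt("seed", "1"))
    out <- opt("out", "alloscan_out")
    switch(cmd,
      simulate = {
        n_fix <- as.integer(opt("n-fixtures", "5"))
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        labs <- list()
        for (k in seq_len(n_fix)) {
          fx <- make_labelled_fixture(seed = seed + k - 1)
          write_pdb(fx, file.path(out, paste0(fx$id, ".pdb")))
          lb <- label_residues(fx, compute_lasa_values = FALSE)
          lb$structure <- fx$id
          labs[[k]] <- lb
        }
        utils::write.table(do.call(rbind, labs),
                           file.path(out, "labels.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        message("wrote ", n_fix, " fixtures to ", out)
      },
      label = {
        path <- rest[!startsWith(rest, "--")][1]
        if (is.na(path)) stop("label: need a structure file")
        s <- read_structure(path)
        tb <- label_residues(s)
        utils::write.table(tb, file.path(out), sep = "\t", quote = FALSE,
                           row.names = FALSE)
      },
      train = {
        files <- rest[!startsWith(rest, "--")]
        if (length(files) == 0) stop("train: need holo structure files")
        structs <- lapply(files, read_structure)
        cfg <- run_config(seed = seed,
                          threshold = as.numeric(opt("threshold", "0.5")))
        run_train(structs, cfg, out_dir = out)
        message("model written to ", out)
      },
      evaluate = {
        files <- rest[!startsWith(rest, "--")]
        model_dir <- opt("model", NULL)
        if (is.null(model_dir)) stop("evaluate: need --model <dir>")
        ens <- load_ensemble(model_dir)
        cfg <- run_config(seed = seed,
                          threshold = as.numeric(opt("threshold", "0.5")),
                          dcc_cutoff = as.numeric(opt("dcc-cutoff", "4")),
                          na_policy = opt("na-policy", "exclude"))
        ev <- run_evaluate(list(ensemble = ens, config = cfg),
                           lapply(files, read_structure))
        write_evaluation(ev, out)
        message("evaluation written to ", out)
      },
      stop("unknown subcommand: ", cmd))
    0L
  }, error = function(e) { message("error: ", conditionMessage(e)); 2L })
  invisible(code)
}
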