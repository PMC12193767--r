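# Fit reports (one statistics row per subset), the end-to-end training
# pipeline, and the file-level `cmd_*` entry points used by the command-line
# wrapper in inst/cli/.

#' Per-subset fit report
#'
#' Evaluates a fitted model on all four subsets of a split and returns one
#' row per subset with the statistics block `n, R2, CCC, IIC, CII, Q2, CCCP,
#' RMSE, F, N_A` (N_A = number of active attributes present in that subset).
#' The validation row is computed from the already-final model, which never
#' saw validation data during optimization or fitting.
#'
#' @param model A `cw_model`.
#' @param split The `cw_split` the model was trained on.
#' @return Data.frame with rows `A`, `P`, `C`, `V`.
#' @export
fit_report <- function(model, split) {
  stopifnot(inherits(model, "cw_model"), inherits(split, "cw_split"))
  rows <- lapply(.subset_names, function(s) {
    sub <- split[[s]]
    calc <- predict(model, sub$smiles)
    sb <- stat_block(sub$endpoint, calc,
                     n_active = count_active_attributes(model$table, sub))
    cbind(data.frame(set = toupper(substr(s, 1L, 1L)), stringsAsFactors = FALSE),
          sb[c("n", "R2", "CCC", "IIC", "CII", "Q2", "CCCP", "RMSE", "F", "N_A")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Train models on a split
#'
#' Full pipeline over one split: Monte Carlo optimization (one or more
#' independent probes) on the active/passive/calibration subsets, final
#' regression fit, and per-probe fit reports.  The validation subset enters
#' only at report time, after each model is final.
#'
#' @param split A `cw_split`.
#' @param cfg A [tf_config()].
#' @param n_probes Number of independent optimization probes.
#' @return List with `models`, `tables`, `traces`, `reports` (all lists of
#'   length `n_probes`) and `cfg`.
#' @export
train_split <- function(split, cfg, n_probes = 1L) {
  probes <- run_probes(split$active, split$passive, split$calibration,
                       cfg, n_probes)
  models <- lapply(probes$tables, function(tbl) fit_model(split, tbl))
  reports <- lapply(models, function(m) fit_report(m, split))
  list(models = models, tables = probes$tables, traces = probes$traces,
       reports = reports, cfg = cfg)
}

.write_report_csv <- function(report, path) {
  out <- report
  num_cols <- setdiff(names(out), c("set", "n", "N_A"))
  for (cn in num_cols) out[[cn]] <- round(out[[cn]], 3)  # 3 decimals in reports
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "-")
  invisible(path)
}

#' Split a dataset file into assignment files
#'
#' Reads a molecule table, draws `n_splits` independent four-subset splits,
#' and writes one assignment CSV (`id,subset`) per split plus a manifest of
#' the derived seeds.  Re-running with the same inputs and seed reproduces
#' the files byte-exactly.
#'
#' @param input Path to the molecule table.
#' @param n_splits Number of splits (>= 1).
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed).
#' @param format Table format, see [read_molecule_table()].
#' @return Character vector of the assignment-file paths, invisibly.
#' @export
cmd_split <- function(input, n_splits, seed, out_dir = ".", format = "csv") {
  if (n_splits < 1L) stop("usage error: n_splits must be >= 1", call. = FALSE)
  records <- read_molecule_table(input, format)
  splits <- make_splits(records, n_splits, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(splits), function(i) {
    p <- file.path(out_dir, sprintf("split_%d.csv", i))
    write_split_assignment(splits[[i]], p)
    p
  }, character(1L))
  writeLines(
    c("# smilescw split manifest",
      paste("master_seed", seed),
      paste("n_splits", n_splits),
      vapply(seq_along(splits), function(i) {
        paste("split", i, "seed", splits[[i]]$seed)
      }, character(1L))),
    file.path(out_dir, "split_manifest.txt")
  )
  invisible(paths)
}

#' Train from files
#'
#' Reads a molecule table and a split-assignment file, optimizes `probes`
#' independent models, and writes per-probe model files
#' (`model_probe_<i>.txt`), per-probe fit reports
#' (`report_probe_<i>.csv`, columns `set,n,R2,CCC,IIC,CII,Q2,CCCP,RMSE,F,N_A`
#' at 3 decimals) and a run manifest with the resolved configuration.
#'
#' @param input Path to the molecule table.
#' @param split_file Path to an assignment CSV from [cmd_split()].
#' @param variant Target function, `"TF0"`-`"TF3"`.
#' @param threshold_T,epochs_N,seed Passed to [tf_config()].
#' @param probes Number of independent probes.
#' @param out_dir Output directory.
#' @param format Table format.
#' @return The [train_split()] result, invisibly.
#' @export
cmd_train <- function(input, split_file, variant = "TF3", threshold_T = 5L,
                      epochs_N = 15L, probes = 3L, seed = 1L,
                      out_dir = ".", format = "csv") {
  records <- read_molecule_table(input, format)
  split <- apply_split_assignment(records, split_file)
  cfg <- tf_config(variant = variant, threshold_T = threshold_T,
                   epochs_N = epochs_N, seed = seed)
  fit <- train_split(split, cfg, n_probes = probes)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(probes)) {
    write_model(fit$models[[i]], file.path(out_dir, sprintf("model_probe_%d.txt", i)))
    .write_report_csv(fit$reports[[i]],
                      file.path(out_dir, sprintf("report_probe_%d.csv", i)))
  }
  writeLines(
    c("# smilescw run manifest",
      paste("timestamp", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      paste("version", as.character(utils::packageVersion("smilescw"))),
      paste("input", input),
      paste("split_file", split_file),
      vapply(names(cfg), function(f) paste(f, cfg[[f]]), character(1L)),
      paste("probes", probes),
      vapply(seq_len(probes), function(i) {
        paste("probe", i, "seed", cfg$seed + i - 1L)
      }, character(1L))),
    file.path(out_dir, "run_manifest.txt")
  )
  invisible(fit)
}

#' Predict from files
#'
#' Applies a saved model to a molecule table and writes a CSV with columns
#' `id, smiles, DCW, predicted, Dj, in_domain, error`.  A row whose SMILES
#' cannot be tokenized gets its error message recorded and `NA` values; the
#' run continues.
#'
#' @param model_file Path to a model written by [write_model()].
#' @param input Path to the molecule table (an `endpoint` column is not
#'   required here; if absent it is filled with `NA` before reading).
#' @param out Output CSV path.
#' @param format Table format.
#' @return The prediction data.frame, invisibly.
#' @export
cmd_predict <- function(model_file, input, out, format = "csv") {
  model <- read_model(model_file)
  df <- switch(format,
    csv = utils::read.csv(input, stringsAsFactors = FALSE),
    tsv = utils::read.delim(input, stringsAsFactors = FALSE),
    smi = utils::read.table(input, header = FALSE, stringsAsFactors = FALSE,
                            col.names = c("smiles", "id")),
    stop("unknown format ", format, call. = FALSE)
  )
  names(df) <- tolower(names(df))
  if (!all(c("id", "smiles") %in% names(df))) {
    stop("schema error: need columns id, smiles in ", input, call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(df)), function(i) {
    s <- as.character(df$smiles[i])
    res <- tryCatch({
      d <- dcw(s, model$table)
      dom <- in_domain(model, s)
      data.frame(id = df$id[i], smiles = s, DCW = d,
                 predicted = model$c0 + model$c1 * d,
                 Dj = dom$defect, in_domain = dom$in_domain,
                 error = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(id = df$id[i], smiles = s, DCW = NA_real_,
                 predicted = NA_real_, Dj = NA_real_, in_domain = NA,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  pred <- do.call(rbind, rows)
  utils::write.csv(pred, out, row.names = FALSE)
  invisible(pred)
}

#' Mechanistic-interpretation table from probe models
#'
#' Combines two or more probe model files into an interpretation table: one
#' row per non-blocked attribute with its correlation weight in every probe,
#' its A/P/C frequencies and statistical defect d_k, and its role (promoter
#' of endpoint increase / decrease, or unclear).  Rows are ordered increase
#' block first, then decrease, then unclear, by descending active-training
#' frequency within each block.
#'
#' @param model_files Character vector of >= 2 model file paths.
#' @param out Optional output CSV path.
#' @return The interpretation data.frame (weights at 3 decimals in the CSV;
#'   full precision in the returned object), invisibly when written.
#' @export
cmd_interpret <- function(model_files, out = NULL) {
  if (length(model_files) < 2L) {
    stop("need at least 2 probe models for interpretation", call. = FALSE)
  }
  models <- lapply(model_files, read_model)
  tables <- lapply(models, `[[`, "table")
  ref <- models[[1L]]$defects
  counts <- stats::setNames(as.integer(ref$n_active), ref$attribute)
  roles <- classify_attributes(tables, counts = counts)
  idx <- match(roles$attribute, ref$attribute)
  roles$N_A <- ifelse(is.na(idx), 0L, ref$n_active[idx])
  roles$N_P <- ifelse(is.na(idx), 0L, ref$n_passive[idx])
  roles$N_C <- ifelse(is.na(idx), 0L, ref$n_calibration[idx])
  roles$d_k <- ifelse(is.na(idx), 0, ref$dk[idx])
  if (!is.null(out)) {
    fmt <- roles
    for (cn in grep("^cw_probe_", names(fmt), value = TRUE)) {
      fmt[[cn]] <- round(fmt[[cn]], 3)
    }
    fmt$d_k <- round(fmt$d_k, 4)
    utils::write.csv(fmt, out, row.names = FALSE, quote = FALSE)
    return(invisible(roles))
  }
  roles
}
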