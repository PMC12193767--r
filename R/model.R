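# Final one-descriptor regression pLC50 = C0 + C1 * DCW(T, N), the
# statistical-defect applicability domain, and multi-probe attribute
# classification.

#' Statistical defect of one attribute
#'
#' The defect d_k measures how unevenly an attribute is distributed over the
#' active training (A), passive training (P) and calibration (C) subsets:
#' the sum over the three subset pairs of the absolute probability difference
#' divided by the summed frequencies,
#' `|P - P'|/(N + N') + |P - P''|/(N + N'') + |P' - P''|/(N' + N'')`.
#' An addend whose frequency sum is zero contributes nothing, so an
#' attribute absent everywhere has defect 0, as does one with identical
#' prevalence in all three subsets.
#'
#' @param freqs Integer vector of length 3: frequencies (molecules
#'   containing the attribute) in A, P, C.
#' @param probs Numeric vector of length 3: the corresponding prevalences
#'   (frequency / subset size), each in `[0, 1]`.
#' @return Non-negative defect value.
#' @export
defect_dk <- function(freqs, probs) {
  stopifnot(length(freqs) == 3L, length(probs) == 3L,
            all(freqs >= 0), all(probs >= 0 & probs <= 1))
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  total <- 0
  for (pr in pairs) {
    fs <- freqs[pr[1L]] + freqs[pr[2L]]
    if (fs > 0) total <- total + abs(probs[pr[1L]] - probs[pr[2L]]) / fs
  }
  total
}

# Defect table over all attributes seen in A/P/C (presence counts).
.defect_table <- function(split) {
  cnt_a <- attribute_counts(split$active, "presence")
  cnt_p <- attribute_counts(split$passive, "presence")
  cnt_c <- attribute_counts(split$calibration, "presence")
  keys <- sort(unique(c(names(cnt_a), names(cnt_p), names(cnt_c))))
  get <- function(cnt, k) {
    v <- cnt[k]
    ifelse(is.na(v), 0L, as.integer(v))
  }
  n_a <- vapply(keys, function(k) get(cnt_a, k), integer(1L))
  n_p <- vapply(keys, function(k) get(cnt_p, k), integer(1L))
  n_c <- vapply(keys, function(k) get(cnt_c, k), integer(1L))
  p_a <- n_a / nrow(split$active)
  p_p <- n_p / nrow(split$passive)
  p_c <- n_c / nrow(split$calibration)
  dk <- vapply(seq_along(keys), function(i) {
    defect_dk(c(n_a[i], n_p[i], n_c[i]), c(p_a[i], p_p[i], p_c[i]))
  }, numeric(1L))
  data.frame(attribute = keys, n_active = n_a, n_passive = n_p,
             n_calibration = n_c, p_active = p_a, p_passive = p_p,
             p_calibration = p_c, dk = dk,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit the final one-descriptor regression
#'
#' Ordinary least squares of endpoint on DCW over the active training set:
#' `endpoint = C0 + C1 * DCW`.  The fitted model also carries the
#' per-attribute statistical-defect table (computed from the A/P/C presence
#' frequencies) and the mean molecular defect over the active training set,
#' which calibrates the applicability domain.
#'
#' @param split A `cw_split`.
#' @param table A `cw_table` of optimized correlation weights.
#' @return An object of class `cw_model` with elements `c0`, `c1`, `table`,
#'   `threshold_T`, `defects` (data.frame), `mean_defect`.
#' @export
fit_model <- function(split, table) {
  stopifnot(inherits(split, "cw_split"), inherits(table, "cw_table"))
  act <- split$active
  if (nrow(act) < 3L) stop("need at least 3 active-training records", call. = FALSE)
  d <- dcw(act$smiles, table)
  if (stats::sd(d) == 0) {
    stop("fit error: constant descriptor on the active training set", call. = FALSE)
  }
  c1 <- stats::cov(act$endpoint, d) / stats::var(d)
  c0 <- mean(act$endpoint) - c1 * mean(d)
  model <- structure(
    list(c0 = c0, c1 = c1, table = table, threshold_T = table$threshold_T,
         defects = .defect_table(split), mean_defect = NA_real_),
    class = "cw_model"
  )
  dj <- vapply(act$smiles, function(s) smiles_defect(model, s), numeric(1L),
               USE.NAMES = FALSE)
  model$mean_defect <- mean(dj)
  model
}

#' @export
print.cw_model <- function(x, ...) {
  cat("SMILES correlation-weight model\n")
  cat(sprintf("  endpoint = %.4f + %.4f * DCW(T=%s)\n", x$c0, x$c1, x$threshold_T))
  cat(sprintf("  %d weighted attributes (%d blocked), mean defect %.4g\n",
              length(x$table$weights), length(x$table$blocked), x$mean_defect))
  invisible(x)
}

#' Predict the endpoint for new molecules
#'
#' @param object A `cw_model`.
#' @param smiles Character vector of SMILES strings.
#' @param ... Unused.
#' @return Numeric vector `C0 + C1 * DCW(smiles)`.
#' @export
predict.cw_model <- function(object, smiles, ...) {
  object$c0 + object$c1 * dcw(smiles, object$table)
}

#' Statistical defect of a molecule
#'
#' The molecular defect D_j is the sum of d_k over the *distinct* non-blocked
#' attributes present in the SMILES; repeated occurrences of one attribute
#' count once.  Attributes unknown to the model contribute nothing.
#'
#' @param model A `cw_model`.
#' @param smiles A single SMILES string.
#' @return Non-negative defect value.
#' @export
smiles_defect <- function(model, smiles) {
  keys <- names(smiles_attributes(smiles))
  keys <- keys[keys %in% names(model$table$weights) &
               !(keys %in% model$table$blocked)]
  if (!length(keys)) return(0)
  dk <- model$defects$dk[match(keys, model$defects$attribute)]
  sum(dk, na.rm = TRUE)
}

#' Applicability-domain decision
#'
#' A molecule falls inside the applicability domain iff its statistical
#' defect is strictly below twice the mean defect of the active training
#' set: `D_j < 2 * mean_defect`.  A molecule sitting exactly on the boundary
#' is out of domain.
#'
#' @param model A `cw_model`.
#' @param smiles Character vector of SMILES strings.
#' @return Data.frame with columns `smiles`, `defect` and logical
#'   `in_domain`.
#' @export
in_domain <- function(model, smiles) {
  dj <- vapply(smiles, function(s) smiles_defect(model, s), numeric(1L),
               USE.NAMES = FALSE)
  data.frame(smiles = smiles, defect = dj,
             in_domain = dj < 2 * model$mean_defect,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify attributes across optimization probes
#'
#' Compares the sign of each non-blocked attribute's correlation weight
#' across independent probes: positive in every probe -> promoter of
#' endpoint increase; negative in every probe -> promoter of decrease;
#' mixed signs (or an exact zero in any probe) -> unclear role.
#'
#' @param probes List of at least two `cw_table` objects from [run_probes()].
#' @param counts Optional named frequency vector (typically active-training
#'   presence counts) used to order attributes within each role block.
#' @return Data.frame with columns `attribute`, `role`
#'   (`"promoter_increase"`, `"promoter_decrease"` or `"unclear"`) and one
#'   `cw_probe_<i>` column per probe, ordered increase block first, then
#'   decrease, then unclear, each by descending frequency when `counts` is
#'   given.
#' @export
classify_attributes <- function(probes, counts = NULL) {
  if (length(probes) < 2L) {
    stop("need at least 2 probes to classify attribute roles", call. = FALSE)
  }
  stopifnot(all(vapply(probes, inherits, logical(1L), "cw_table")))
  keys <- sort(unique(unlist(lapply(probes, function(p) {
    setdiff(names(p$weights), p$blocked)
  }))))
  cw <- vapply(probes, function(p) {
    v <- p$weights[keys]
    v[is.na(v)] <- 0
    unname(v)
  }, numeric(length(keys)))
  cw <- matrix(cw, nrow = length(keys))
  role <- apply(cw, 1L, function(v) {
    if (all(v > 0)) "promoter_increase"
    else if (all(v < 0)) "promoter_decrease"
    else "unclear"
  })
  out <- data.frame(attribute = keys, role = role, stringsAsFactors = FALSE)
  for (p in seq_along(probes)) out[[paste0("cw_probe_", p)]] <- cw[, p]
  freq <- if (is.null(counts)) rep(0L, length(keys)) else {
    v <- counts[keys]
    v[is.na(v)] <- 0L
    as.integer(v)
  }
  role_rank <- match(out$role, c("promoter_increase", "promoter_decrease", "unclear"))
  out <- out[order(role_rank, -freq, out$attribute), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Save / load a fitted model as plain text
#'
#' The file stores the regression coefficients, threshold, mean defect and
#' the full weight/defect table at full double precision, so a re-loaded
#' model predicts bit-exactly.
#'
#' @param model A `cw_model`.
#' @param path File path.
#' @return `write_model` returns `path` invisibly; `read_model` a
#'   `cw_model`.
#' @export
write_model <- function(model, path) {
  num <- function(x) sprintf("%.17g", x)
  keys <- sort(unique(c(names(model$table$weights), model$defects$attribute)))
  w <- model$table$weights[keys]
  w[is.na(w)] <- 0
  di <- match(keys, model$defects$attribute)
  geti <- function(col) {
    v <- model$defects[[col]][di]
    v[is.na(v)] <- 0L
    as.integer(v)
  }
  dk <- model$defects$dk[di]
  dk[is.na(dk)] <- 0
  # keys that appear only in the defect table (never weighted, i.e. absent
  # from the active training set) are marked blocked so that a re-loaded
  # model excludes them from descriptor sums and molecular defects alike
  eff_blocked <- keys %in% model$table$blocked |
    !(keys %in% names(model$table$weights))
  df <- data.frame(
    key = keys, cw = num(unname(w)),
    blocked = as.integer(eff_blocked),
    n_active = geti("n_active"), n_passive = geti("n_passive"),
    n_calibration = geti("n_calibration"), dk = num(dk),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# smilescw model",
               paste("c0", num(model$c0)),
               paste("c1", num(model$c1)),
               paste("threshold_T", model$threshold_T),
               paste("mean_defect", num(model$mean_defect)),
               "[attributes]"), con)
  utils::write.table(df, con, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  sep <- which(lines == "[attributes]")
  if (!length(sep)) stop("not a smilescw model file: ", path, call. = FALSE)
  header <- lines[seq_len(sep - 1L)]
  getv <- function(field) {
    ln <- header[grepl(paste0("^", field, " "), header)]
    if (!length(ln)) stop("model file missing field ", field, call. = FALSE)
    sub(paste0("^", field, " "), "", ln[1L])
  }
  df <- utils::read.table(text = lines[(sep + 1L):length(lines)], header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(key = "character"))
  # prevalences are reconstructible only up to the stored frequencies; the
  # defect values themselves are stored, which is what prediction-time AD uses
  defects <- data.frame(
    attribute = df$key, n_active = df$n_active, n_passive = df$n_passive,
    n_calibration = df$n_calibration, p_active = NA_real_,
    p_passive = NA_real_, p_calibration = NA_real_, dk = as.numeric(df$dk),
    stringsAsFactors = FALSE
  )
  table <- new_weight_table(
    weights = stats::setNames(as.numeric(df$cw), df$key),
    blocked = df$key[df$blocked == 1L],
    threshold_T = suppressWarnings(as.integer(getv("threshold_T")))
  )
  structure(
    list(c0 = as.numeric(getv("c0")), c1 = as.numeric(getv("c1")),
         table = table, threshold_T = table$threshold_T,
         defects = defects, mean_defect = as.numeric(getv("mean_defect"))),
    class = "cw_model"
  )
}
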