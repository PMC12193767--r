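# Correlation-weight tables, rare-attribute blocking, and the optimal
# descriptor DCW(T, N) = sum of correlation weights over all single-atom and
# neighbour-pair attribute occurrences of a molecule.

#' Attribute frequencies over a record set
#'
#' Counts how often each attribute key occurs in a set of molecules.  The
#' default (`"presence"`) counts the number of molecules containing the
#' attribute at least once, which is the frequency used both for
#' rare-attribute blocking and for the applicability-domain probabilities;
#' `"occurrence"` counts total occurrences with multiplicity.
#'
#' @param records Records data.frame (needs a `smiles` column).
#' @param mode `"presence"` (default) or `"occurrence"`.
#' @return Named integer vector of counts keyed by 12-character attribute key.
#' @export
attribute_counts <- function(records, mode = c("presence", "occurrence")) {
  mode <- match.arg(mode)
  env <- new.env(parent = emptyenv())
  for (s in records$smiles) {
    a <- smiles_attributes(s)
    add <- if (mode == "presence") rep(1L, length(a)) else as.integer(a)
    nm <- names(a)
    for (k in seq_along(nm)) {
      prev <- if (is.null(env[[nm[k]]])) 0L else env[[nm[k]]]
      env[[nm[k]]] <- prev + add[k]
    }
  }
  keys <- sort(ls(env))
  out <- vapply(keys, function(k) env[[k]], integer(1L))
  names(out) <- keys
  out
}

#' Rare-attribute blocklist
#'
#' An attribute is rare -- and its correlation weight is forced to zero --
#' if its frequency in the active training set is strictly less than the
#' threshold `T`.  With `T = 0` nothing is blocked.
#'
#' @param counts_active Named counts from [attribute_counts()] on the active
#'   training set.
#' @param threshold_T Non-negative integer threshold.
#' @return Character vector of blocked attribute keys.
#' @export
build_blocklist <- function(counts_active, threshold_T) {
  stopifnot(threshold_T >= 0)
  names(counts_active)[counts_active < threshold_T]
}

#' Construct a correlation-weight table
#'
#' @param weights Named numeric vector of correlation weights (CW), keyed by
#'   12-character attribute key.  Attributes without an entry contribute 0 to
#'   the descriptor.
#' @param blocked Character vector of blocked (rare) keys; their effective
#'   weight is 0 regardless of any entry in `weights`.
#' @param threshold_T The blocking threshold the table was built with.
#' @param seed Optional seed of the optimization run that produced it.
#' @return An object of class `cw_table`.
#' @export
new_weight_table <- function(weights, blocked = character(),
                             threshold_T = NA_integer_, seed = NA_integer_) {
  stopifnot(is.numeric(weights), !is.null(names(weights)),
            all(nzchar(names(weights))), all(is.finite(weights)))
  structure(
    list(weights = weights, blocked = as.character(blocked),
         threshold_T = as.integer(threshold_T), seed = as.integer(seed)),
    class = "cw_table"
  )
}

#' @export
print.cw_table <- function(x, ...) {
  cat("Correlation-weight table: ", length(x$weights), " attributes (",
      length(x$blocked), " blocked), T = ", x$threshold_T, "\n", sep = "")
  invisible(x)
}

# effective weight vector for a set of keys: 0 for blocked or absent keys
.effective_weights <- function(table, keys) {
  w <- unname(table$weights[keys])
  w[is.na(w)] <- 0
  w[keys %in% table$blocked] <- 0
  w
}

#' Optimal descriptor DCW of one or more molecules
#'
#' Sums the correlation weight of every attribute occurrence (single atoms
#' and neighbour pairs, with multiplicity) of each molecule.  Blocked and
#' unknown attributes contribute zero.
#'
#' @param smiles Character vector of SMILES strings.
#' @param table A `cw_table`.
#' @return Numeric vector of descriptor values, one per input SMILES.
#' @export
dcw <- function(smiles, table) {
  stopifnot(inherits(table, "cw_table"))
  vapply(smiles, function(s) {
    a <- smiles_attributes(s)
    sum(.effective_weights(table, names(a)) * as.numeric(a))
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Number of active (non-rare) attributes present in a record set
#'
#' Counts the distinct attribute keys that occur in `records`, carry a
#' correlation weight in `table`, and are not blocked.  This is the
#' N_A statistic reported per subset in fit reports.
#'
#' @param table A `cw_table`.
#' @param records Records data.frame.
#' @return Integer count.
#' @export
count_active_attributes <- function(table, records) {
  keys <- unique(unlist(lapply(records$smiles, function(s) names(smiles_attributes(s)))))
  sum(keys %in% names(table$weights) & !(keys %in% table$blocked))
}

#' Write / read a correlation-weight file
#'
#' Plain-text serialization of a weight table: one row per attribute with its
#' 12-character key, correlation weight (full double precision), blocked flag
#' and, when supplied, its presence counts in the active training, passive
#' training and calibration sets.
#'
#' @param table A `cw_table`.
#' @param path File path.
#' @param counts Optional list with named count vectors `active`, `passive`,
#'   `calibration` (as from [attribute_counts()]).
#' @return `write_weight_table` returns `path` invisibly; `read_weight_table`
#'   returns a `cw_table`.
#' @export
write_weight_table <- function(table, path, counts = NULL) {
  keys <- sort(unique(c(names(table$weights), table$blocked)))
  w <- table$weights[keys]
  w[is.na(w)] <- 0
  cnt <- function(set) {
    if (is.null(counts)) return(rep(NA_integer_, length(keys)))
    v <- counts[[set]][keys]
    v[is.na(v)] <- 0L
    as.integer(v)
  }
  df <- data.frame(
    key = keys,
    cw = sprintf("%.17g", unname(w)),
    blocked = as.integer(keys %in% table$blocked),
    count_active = cnt("active"),
    count_passive = cnt("passive"),
    count_calibration = cnt("calibration"),
    stringsAsFactors = FALSE
  )
  header <- c(sprintf("# smilescw weight table"),
              sprintf("# threshold_T %s", table$threshold_T),
              sprintf("# seed %s", table$seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_weight_table
#' @export
read_weight_table <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  getv <- function(field) {
    ln <- meta[grepl(paste0("^# ", field, " "), meta)]
    if (!length(ln)) return(NA_integer_)
    suppressWarnings(as.integer(sub(paste0("^# ", field, " "), "", ln[1L])))
  }
  df <- utils::read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(key = "character"))
  new_weight_table(
    weights = stats::setNames(as.numeric(df$cw), df$key),
    blocked = df$key[df$blocked == 1L],
    threshold_T = getv("threshold_T"),
    seed = getv("seed")
  )
}
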