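# Reading molecule/endpoint tables and the four-subset split protocol:
# active training (builds the model), passive training (inspects it during
# building), calibration (steers global parameters and the predictive-potential
# criteria), validation (never seen until the model is final).

#' Read a molecule/endpoint table
#'
#' Reads a delimited table of molecules with columns `id`, `smiles` and
#' `endpoint` (case-insensitive; the endpoint is a continuous value such as
#' pLC50, the negative decadic logarithm of LC50 in mM/L).  Rows whose
#' endpoint is missing/non-finite or whose SMILES cannot be tokenized are
#' dropped with a warning that reports how many were lost.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"tsv"` (with header `id,smiles,endpoint` in any
#'   order), or `"smi"`: header-less whitespace-delimited lines
#'   `smiles id endpoint`.
#' @return A data.frame with character columns `id`, `smiles` and numeric
#'   `endpoint`; one row per retained molecule.
#' @export
read_molecule_table <- function(path, format = c("csv", "tsv", "smi")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- switch(format,
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    tsv = utils::read.delim(path, stringsAsFactors = FALSE),
    smi = utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                            col.names = c("smiles", "id", "endpoint"))
  )
  if (nrow(df) == 0L) stop("invalid input: empty table in ", path, call. = FALSE)
  names(df) <- tolower(names(df))
  need <- c("id", "smiles", "endpoint")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  df <- df[need]
  df$id <- as.character(df$id)
  df$smiles <- as.character(df$smiles)
  df$endpoint <- suppressWarnings(as.numeric(df$endpoint))
  if (anyDuplicated(df$id)) {
    stop("duplicate-id error: ", paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_endpoint <- !is.finite(df$endpoint)
  bad_smiles <- vapply(df$smiles, function(s) {
    inherits(tryCatch(smiles_tokenize(s), error = identity), "error")
  }, logical(1L), USE.NAMES = FALSE)
  drop <- bad_endpoint | bad_smiles
  if (any(drop)) {
    warning(sum(drop), " row(s) dropped (", sum(bad_endpoint),
            " missing/non-finite endpoint, ", sum(bad_smiles & !bad_endpoint),
            " untokenizable SMILES)", call. = FALSE)
    df <- df[!drop, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("invalid input: no usable rows in ", path, call. = FALSE)
  rownames(df) <- NULL
  df
}

.subset_names <- c("active", "passive", "calibration", "validation")

# Subset sizes for n records: every subset gets floor(n/4); the r = n mod 4
# leftovers go to the active training set (ceil(r/2)) and the calibration set
# (floor(r/2)).  For n = 311 this gives A=79, C=78, P=77, V=77.
.split_sizes <- function(n) {
  q <- n %/% 4L
  r <- n %% 4L
  c(active = q + ceiling(r / 2), passive = q,
    calibration = q + floor(r / 2), validation = q)
}

#' Randomly split records into the four modelling subsets
#'
#' Divides the records into four disjoint subsets of approximately equal
#' size: active training, passive training, calibration and validation.
#' The assignment (and the order within each subset) is a seeded random
#' shuffle, so the same seed always reproduces the same split.
#'
#' @param records Data.frame with columns `id`, `smiles`, `endpoint`.
#' @param seed Integer seed controlling the shuffle.
#' @return An object of class `cw_split`: a list with elements `active`,
#'   `passive`, `calibration`, `validation` (each a records data.frame) and
#'   `seed`.
#' @export
make_split <- function(records, seed) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  if (n < 8L) stop("invalid input: need at least 8 records to split", call. = FALSE)
  if (anyDuplicated(records$id)) stop("duplicate-id error in records", call. = FALSE)
  sizes <- .split_sizes(n)
  perm <- withr::with_seed(seed, sample.int(n))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  parts <- lapply(seq_along(sizes), function(k) {
    out <- records[perm[starts[k]:ends[k]], , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(parts) <- names(sizes)
  structure(c(parts, list(seed = as.integer(seed))), class = "cw_split")
}

#' @export
print.cw_split <- function(x, ...) {
  ns <- vapply(.subset_names, function(s) nrow(x[[s]]), integer(1L))
  cat("Four-subset split (seed ", x$seed, "): ",
      paste(sprintf("%s=%d", substr(.subset_names, 1, 1), ns), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Repeated independent splits
#'
#' Produces `n_splits` independent four-subset splits with seeds derived from
#' `master_seed` (seed `master_seed + i` for split `i`).  Two splits with an
#' identical validation-set membership are considered a collision and the
#' later one is re-drawn with a shifted seed.
#'
#' @param records Records data.frame.
#' @param n_splits Number of splits (>= 1); the full protocol uses 5.
#' @param master_seed Integer master seed.
#' @return List of `cw_split` objects.
#' @export
make_splits <- function(records, n_splits, master_seed) {
  if (n_splits < 1L) stop("invalid input: n_splits must be >= 1", call. = FALSE)
  out <- vector("list", n_splits)
  seen_validation <- list()
  for (i in seq_len(n_splits)) {
    seed_i <- as.integer(master_seed) + i
    repeat {
      sp <- make_split(records, seed_i)
      vid <- sort(sp$validation$id)
      clash <- any(vapply(seen_validation, identical, logical(1L), y = vid))
      if (!clash) break
      seed_i <- seed_i + 7919L  # re-draw on validation-set collision
    }
    seen_validation[[i]] <- sort(sp$validation$id)
    out[[i]] <- sp
  }
  out
}

#' Write / read a split assignment file
#'
#' A split assignment file is a two-column CSV (`id`, `subset`) that records
#' which subset each molecule belongs to, so a published split can be reused
#' bit-exactly.
#'
#' @param split A `cw_split`.
#' @param path Output/input path.
#' @return `write_split_assignment` returns `path` invisibly;
#'   `apply_split_assignment` returns a `cw_split` (with `seed = NA`) built by
#'   joining the assignment onto `records`.
#' @export
write_split_assignment <- function(split, path) {
  df <- do.call(rbind, lapply(.subset_names, function(s) {
    data.frame(id = split[[s]]$id, subset = s, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param records Records data.frame whose ids the assignment refers to.
#' @rdname write_split_assignment
#' @export
apply_split_assignment <- function(records, path) {
  asg <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "subset") %in% names(asg))) {
    stop("schema error: assignment file needs columns id, subset", call. = FALSE)
  }
  asg$id <- as.character(asg$id)
  if (!all(asg$subset %in% .subset_names)) {
    stop("invalid subset label in assignment file", call. = FALSE)
  }
  missing_ids <- setdiff(asg$id, records$id)
  if (length(missing_ids)) {
    stop("assignment refers to unknown id(s): ",
         paste(utils::head(missing_ids, 5L), collapse = ", "), call. = FALSE)
  }
  parts <- lapply(.subset_names, function(s) {
    ids <- asg$id[asg$subset == s]
    out <- records[match(ids, records$id), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(parts) <- .subset_names
  structure(c(parts, list(seed = NA_integer_)), class = "cw_split")
}
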