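# SMILES "atoms": the tokenization units the attribute alphabet is built from.
# A token is one character or an inseparable character group; the
# multi-character groups recognised outside brackets are listed below and can
# be extended via the `two_char_elements` argument of smiles_tokenize().

.default_two_char_elements <- c("Cl", "Br", "Si", "Se")

#' Tokenize a SMILES string into SMILES atoms
#'
#' Splits a SMILES string into the units ("SMILES atoms") from which
#' attributes are built: one symbol, or a group of symbols that cannot be
#' considered separately.  Inseparable groups are: two-letter element symbols
#' (`Cl`, `Br`, `Si`, `Se` by default), the chirality mark `@@`, a `%`
#' two-digit ring-closure label, and an entire bracket expression
#' `[...]` taken as a single token.
#'
#' Concatenating the returned tokens always reproduces the input string.
#' The dot disconnection symbol `.` is rejected because it is reserved as
#' the padding character of attribute keys; strip salts/components upstream.
#'
#' @param smiles A single non-empty SMILES string (no whitespace).
#' @param two_char_elements Character vector of two-letter element symbols
#'   recognised as single tokens outside brackets.
#' @return Character vector of tokens, in reading order.
#' @examples
#' smiles_tokenize("ClCCl")      # "Cl" "C" "Cl"
#' smiles_tokenize("c1ccccc1")   # eight single-character tokens
#' smiles_tokenize("C[N+](C)C")  # bracket body is one token
#' @export
smiles_tokenize <- function(smiles, two_char_elements = .default_two_char_elements) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    stop("`smiles` must be a single string", call. = FALSE)
  }
  if (!nzchar(smiles)) {
    stop("invalid input: empty SMILES string", call. = FALSE)
  }
  if (grepl("[[:space:]]", smiles)) {
    stop("invalid input: SMILES contains whitespace", call. = FALSE)
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  out <- character(n)  # at most n tokens
  k <- 0L
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == ".") {
      stop("invalid input: '.' (disconnection) is not supported; ",
           "supply single-component SMILES", call. = FALSE)
    }
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) {
        stop("malformed SMILES: unbalanced '[' in \"", smiles, "\"", call. = FALSE)
      }
      tok <- paste(chars[i:j], collapse = "")
      i <- j + 1L
    } else if (ch == "]") {
      stop("malformed SMILES: unmatched ']' in \"", smiles, "\"", call. = FALSE)
    } else if (ch == "%") {
      if (i + 2L > n || !all(chars[(i + 1L):(i + 2L)] %in% as.character(0:9))) {
        stop("malformed SMILES: '%' must be followed by two digits in \"",
             smiles, "\"", call. = FALSE)
      }
      tok <- paste(chars[i:(i + 2L)], collapse = "")
      i <- i + 3L
    } else if (ch == "@" && i < n && chars[i + 1L] == "@") {
      tok <- "@@"
      i <- i + 2L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% two_char_elements) {
      tok <- paste0(ch, chars[i + 1L])
      i <- i + 2L
    } else {
      tok <- ch
      i <- i + 1L
    }
    k <- k + 1L
    out[k] <- tok
  }
  out[seq_len(k)]
}

# Left-justify a token in a 4-character field padded with '.'.
# Tokens longer than 4 characters (long bracket bodies such as "[NH3+]") are
# mapped to a stable overflow code: first three characters plus '#'.  Distinct
# long tokens sharing their first three characters therefore collide; the
# 12-character key dialect fixes the field width, so this is unavoidable.
.pad4 <- function(token) {
  nc <- nchar(token)
  if (nc > 4L) {
    token <- paste0(substr(token, 1L, 3L), "#")
    nc <- 4L
  }
  paste0(token, strrep(".", 4L - nc))
}

# byte-wise "a > b" on equal-length ASCII strings (locale-independent)
.byte_gt <- function(a, b) {
  ia <- utf8ToInt(a)
  ib <- utf8ToInt(b)
  d <- ia - ib
  nz <- which(d != 0L)
  length(nz) > 0L && d[nz[1L]] > 0L
}

#' Attribute key for a single SMILES atom
#'
#' Serializes one token as a 12-character dotted key: the token left-justified
#' in a 4-character field, padded with `.` to 12 characters
#' (e.g. `"Cl.........."`).
#'
#' @param token A token as returned by [smiles_tokenize()].
#' @return A 12-character key string.
#' @export
attr_key_single <- function(token) {
  stopifnot(is.character(token), length(token) == 1L, nzchar(token))
  paste0(.pad4(token), strrep(".", 8L))
}

#' Attribute key for a pair of neighbouring SMILES atoms
#'
#' Serializes an unordered pair of neighbouring tokens as a 12-character key:
#' two 4-character dotted fields followed by four `.` characters.  The field
#' order is canonical -- descending byte value of the padded fields -- so the
#' key does not depend on which neighbour is written first
#' (e.g. both `("1","c")` and `("c","1")` give `"c...1......."`).
#'
#' @param a,b Tokens.
#' @return A 12-character key string.
#' @export
attr_key_pair <- function(a, b) {
  fa <- .pad4(a)
  fb <- .pad4(b)
  if (.byte_gt(fb, fa)) {
    tmp <- fa; fa <- fb; fb <- tmp
  }
  paste0(fa, fb, "....")
}

#' Extract the attribute multiset of a SMILES string
#'
#' Returns every attribute occurrence of a molecule: one single-atom key per
#' token and one pair key per adjacent token pair, counted with multiplicity.
#' A molecule with `n` tokens therefore contributes `n` single occurrences
#' and `n - 1` pair occurrences.
#'
#' @inheritParams smiles_tokenize
#' @return Named integer vector: names are 12-character attribute keys,
#'   values their multiplicities in this molecule.
#' @examples
#' smiles_attributes("CC")  # C........... x2, C...C....... x1
#' @export
smiles_attributes <- function(smiles, two_char_elements = .default_two_char_elements) {
  toks <- smiles_tokenize(smiles, two_char_elements)
  n <- length(toks)
  singles <- vapply(toks, attr_key_single, character(1L), USE.NAMES = FALSE)
  keys <- singles
  if (n > 1L) {
    pairs <- mapply(attr_key_pair, toks[-n], toks[-1L], USE.NAMES = FALSE)
    keys <- c(keys, pairs)
  }
  tab <- table(keys)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# Count matrix (molecules x keys) of attribute multiplicities, for the
# requested key set only.  Workhorse of the optimizer and of dcw().
.attribute_matrix <- function(smiles_vec, keys) {
  M <- matrix(0, nrow = length(smiles_vec), ncol = length(keys),
              dimnames = list(NULL, keys))
  for (i in seq_along(smiles_vec)) {
    a <- smiles_attributes(smiles_vec[i])
    idx <- match(names(a), keys)
    keep <- !is.na(idx)
    if (any(keep)) M[i, idx[keep]] <- a[keep]
  }
  M
}
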