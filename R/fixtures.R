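# Synthetic token-string "molecules" with a known additive ground truth.
# The generator emulates the structure of a SMILES/endpoint modelling table:
# each molecule is a random token string over a small vocabulary (with
# parentheses and ring digits emitted only in matched pairs, so tokenization
# round-trips), and its endpoint is a noisy linear function of known
# per-attribute ground-truth weights.  This makes every stage of the pipeline
# testable end to end -- tokenization, blocking, optimization, regression,
# applicability domain -- without any external dataset.

#' Specification of a synthetic fixture dataset
#'
#' @param n_molecules Number of molecules.
#' @param vocabulary Token vocabulary.  Parentheses and ring digits are
#'   handled structurally (emitted in matched pairs); everything else is
#'   sampled freely.
#' @param length_range Integer `c(min, max)` number of free tokens per
#'   molecule (before structural insertions), `min >= 2`.
#' @param true_weights Named numeric vector mapping attribute keys to their
#'   ground-truth contribution to the endpoint.
#' @param true_c0,true_c1 Intercept and slope of the ground-truth relation
#'   `endpoint = c0 + c1 * sum(true-weight contributions) + noise`.
#' @param noise_sd Gaussian noise standard deviation (>= 0), on the endpoint
#'   (pLC50-like) scale.
#' @param seed Integer seed; generation is fully deterministic per spec.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_molecules, vocabulary, length_range, true_weights,
                         true_c0 = 0, true_c1 = 1, noise_sd = 0.2, seed = 1L) {
  stopifnot(n_molecules >= 1L, length(vocabulary) >= 1L,
            length(length_range) == 2L, length_range[1L] >= 2L,
            length_range[1L] <= length_range[2L],
            is.numeric(true_weights), !is.null(names(true_weights)),
            noise_sd >= 0)
  structure(
    list(n_molecules = as.integer(n_molecules),
         vocabulary = as.character(vocabulary),
         length_range = as.integer(length_range),
         true_weights = true_weights,
         true_c0 = true_c0, true_c1 = true_c1,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Default fixture specification
#'
#' The reference study conditions of the package's validation experiments:
#' 400 molecules over a 10-token vocabulary (`C c N O Cl S = 1 ( )`), 8-20
#' free tokens each, endpoint noise 0.2 on the pLC50-like scale.  The
#' ground-truth weights are fixed constants in `[-1, 1]` chosen to echo the
#' qualitative chemistry of aquatic-toxicity models: halogens, sulfur,
#' aromatic carbon and unsaturation raise the endpoint; nitrogen, oxygen and
#' branching lower it.
#'
#' @param n_molecules,noise_sd,seed Overridable; see [fixture_spec()].
#' @return A `fixture_spec`.
#' @export
default_fixture_spec <- function(n_molecules = 400L, noise_sd = 0.2, seed = 101L) {
  singles <- c("C" = 0.10, "c" = 0.45, "N" = -0.85, "O" = -0.55,
               "Cl" = 0.95, "S" = 0.80, "=" = 0.35, "1" = 0.25,
               "(" = -0.15, ")" = -0.15)
  tw <- stats::setNames(unname(singles),
                        vapply(names(singles), attr_key_single, character(1L)))
  tw[attr_key_pair("c", "1")] <- 0.40
  tw[attr_key_pair("N", "(")] <- -0.45
  tw[attr_key_pair("O", "(")] <- -0.30
  fixture_spec(
    n_molecules = n_molecules,
    vocabulary = c("C", "c", "N", "O", "Cl", "S", "=", "1", "(", ")"),
    length_range = c(8L, 20L),
    true_weights = tw,
    true_c0 = 0, true_c1 = 1,
    noise_sd = noise_sd, seed = seed
  )
}

# one token string: free tokens sampled i.i.d., then 0-2 paren pairs and
# 0-2 ring-digit pairs inserted at random slots ('(' always before ')')
.gen_tokens <- function(spec) {
  ring_digits <- intersect(spec$vocabulary, as.character(1:9))
  has_paren <- all(c("(", ")") %in% spec$vocabulary)
  free <- setdiff(spec$vocabulary, c("(", ")", ring_digits))
  if (!length(free)) stop("generation error: vocabulary has no free tokens", call. = FALSE)
  n_free <- sample(spec$length_range[1L]:spec$length_range[2L], 1L)
  toks <- sample(free, n_free, replace = TRUE)
  insert <- function(toks, tok, pos) append(toks, tok, after = pos - 1L)
  if (length(ring_digits)) {
    for (r in seq_len(sample(0:2, 1L))) {
      d <- sample(ring_digits, 1L)
      pos <- sort(sample(2:(length(toks) + 1L), 2L))
      toks <- insert(toks, d, pos[2L])
      toks <- insert(toks, d, pos[1L])
    }
  }
  if (has_paren) {
    for (r in seq_len(sample(0:2, 1L))) {
      pos <- sort(sample(2:(length(toks) + 1L), 2L))
      toks <- insert(toks, ")", pos[2L])
      toks <- insert(toks, "(", pos[1L])
    }
  }
  toks
}

#' Generate a synthetic dataset
#'
#' Draws `spec$n_molecules` token strings and endpoints
#' `true_c0 + true_c1 * sum(true_weights over attribute occurrences) +
#' N(0, noise_sd)`.  Every generated string is verified to tokenize back to
#' exactly the tokens it was built from (an ambiguous vocabulary is an
#' error), so the additive ground truth is exact: with `noise_sd = 0` the
#' true weights reproduce the endpoints to machine precision.
#'
#' @param spec A [fixture_spec()].
#' @return Records data.frame with columns `id`, `smiles`, `endpoint`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  true_table <- new_weight_table(spec$true_weights, threshold_T = 0L)
  withr::with_seed(spec$seed, {
    smiles <- character(spec$n_molecules)
    for (i in seq_len(spec$n_molecules)) {
      toks <- .gen_tokens(spec)
      s <- paste(toks, collapse = "")
      if (!identical(smiles_tokenize(s), toks)) {
        stop("generation error: vocabulary is ambiguous under tokenization (\"",
             s, "\")", call. = FALSE)
      }
      smiles[i] <- s
    }
    signal <- dcw(smiles, true_table)
    endpoint <- spec$true_c0 + spec$true_c1 * signal +
      stats::rnorm(spec$n_molecules, 0, spec$noise_sd)
    data.frame(id = sprintf("M%04d", seq_len(spec$n_molecules)),
               smiles = smiles, endpoint = endpoint,
               stringsAsFactors = FALSE)
  })
}

#' Skew an attribute's prevalence across the subsets of a split
#'
#' Rebuilds a four-subset split so that molecules containing a given
#' attribute are redistributed with a controlled imbalance, creating a known
#' non-zero statistical defect.  `enrichment = 0` equalizes the attribute's
#' prevalence across subsets (defect near 0); `enrichment = 1` concentrates
#' every carrier in the active training set (maximal defect, and an error if
#' they do not fit).  Intermediate values interpolate the share of carriers
#' sent to the active set.  Subset sizes are preserved; the result is a
#' permutation of the original membership.
#'
#' @param split A `cw_split`.
#' @param attribute A 12-character attribute key.
#' @param enrichment Number in `[0, 1]`.
#' @param seed Seed for the within-group shuffles.
#' @return A new `cw_split`.
#' @export
perturb_split <- function(split, attribute, enrichment, seed = 1L) {
  stopifnot(inherits(split, "cw_split"), enrichment >= 0, enrichment <= 1)
  all_records <- do.call(rbind, lapply(.subset_names, function(s) split[[s]]))
  rownames(all_records) <- NULL
  sizes <- vapply(.subset_names, function(s) nrow(split[[s]]), integer(1L))
  has_attr <- vapply(all_records$smiles, function(s) {
    attribute %in% names(smiles_attributes(s))
  }, logical(1L), USE.NAMES = FALSE)
  m <- sum(has_attr)
  if (m == 0L) stop("attribute ", attribute, " occurs in no molecule", call. = FALSE)

  # carriers sent to the active set: m/4 at enrichment 0, all at enrichment 1
  n_to_active <- round(m * (1 + 3 * enrichment) / 4)
  if (n_to_active > sizes[["active"]]) {
    stop("generation error: enrichment ", enrichment, " impossible (",
         n_to_active, " carriers > active size ", sizes[["active"]], ")",
         call. = FALSE)
  }
  rest <- m - n_to_active
  other <- c("passive", "calibration", "validation")
  base <- rest %/% 3L
  extra <- rest %% 3L
  carrier_quota <- c(active = n_to_active,
                     passive = base + as.integer(extra >= 1L),
                     calibration = base + as.integer(extra >= 2L),
                     validation = base)
  if (any(carrier_quota > sizes)) {
    stop("generation error: enrichment ", enrichment,
         " incompatible with subset sizes", call. = FALSE)
  }
  withr::with_seed(seed, {
    carriers <- sample(which(has_attr))
    fillers <- sample(which(!has_attr))
    parts <- list()
    ci <- 1L
    fi <- 1L
    for (s in .subset_names) {
      k <- carrier_quota[[s]]
      take <- integer(0)
      if (k > 0L) {
        take <- carriers[ci:(ci + k - 1L)]
        ci <- ci + k
      }
      nf <- sizes[[s]] - k
      if (nf > 0L) {
        take <- c(take, fillers[fi:(fi + nf - 1L)])
        fi <- fi + nf
      }
      part <- all_records[sample(take), , drop = FALSE]
      rownames(part) <- NULL
      parts[[s]] <- part
    }
    structure(c(parts, list(seed = split$seed)), class = "cw_split")
  })
}
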