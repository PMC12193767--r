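# Monte Carlo optimization of correlation weights.  A plain accept-if-not-
# worse hill-climb: each epoch visits every non-blocked attribute once in
# seeded-random order, perturbs its weight, and keeps the move iff the target
# function does not decrease.  The validation set is never an input here.
#
# Target functions:
#   TF0 = r_AT + r_PT - |r_AT - r_PT| * tf0_coeff
#   TF1 = TF0 + IIC(calibration)  * criterion_coeff
#   TF2 = TF0 + CII(calibration)  * criterion_coeff
#   TF3 = TF0 + CCCP(calibration) * criterion_coeff
# r_AT / r_PT are the Pearson correlations of observed endpoint vs. DCW on
# the active and passive training sets; the criterion term is evaluated on
# calibration-set predictions from the active-set regression, refreshed after
# every proposal.

#' Target-function configuration
#'
#' Collects every tunable of a Monte Carlo run.  Defaults mirror the
#' package's standard protocol: threshold `T = 5`, `N = 15` epochs, TF0
#' balance coefficient 0.1 and criterion coefficient 0.3.
#'
#' @param variant One of `"TF0"`, `"TF1"` (IIC), `"TF2"` (CII),
#'   `"TF3"` (CCCP).
#' @param threshold_T Rare-attribute blocking threshold (frequency in the
#'   active training set below which a weight is frozen at zero).
#' @param epochs_N Number of epochs; one epoch is one full pass over the
#'   non-blocked attributes.
#' @param tf0_coeff Weight of the `|r_AT - r_PT|` penalty in TF0.
#' @param criterion_coeff Weight of the IIC/CII/CCCP term in TF1-TF3.
#' @param step_size Half-width of the uniform weight perturbation; a proposal
#'   is `CW + step_size * u`, `u ~ U(-1, 1)`.
#' @param seed Integer seed; fixes the proposal stream and visit order.
#' @param init `"ones"` starts every non-blocked weight at 1.0 (the initial
#'   descriptor is then an attribute count); `"uniform"` draws starts from
#'   `U(-1, 1)`.
#' @param count_mode Frequency definition for blocking, see
#'   [attribute_counts()].
#' @return An object of class `tf_config` (a list).
#' @export
tf_config <- function(variant = c("TF0", "TF1", "TF2", "TF3"),
                      threshold_T = 5L, epochs_N = 15L,
                      tf0_coeff = 0.1, criterion_coeff = 0.3,
                      step_size = 0.6, seed = 1L,
                      init = c("ones", "uniform"),
                      count_mode = c("presence", "occurrence")) {
  variant <- match.arg(variant)
  init <- match.arg(init)
  count_mode <- match.arg(count_mode)
  stopifnot(epochs_N >= 1L, threshold_T >= 0L,
            tf0_coeff >= 0, criterion_coeff >= 0, step_size > 0)
  structure(
    list(variant = variant, threshold_T = as.integer(threshold_T),
         epochs_N = as.integer(epochs_N), tf0_coeff = tf0_coeff,
         criterion_coeff = criterion_coeff, step_size = step_size,
         seed = as.integer(seed), init = init, count_mode = count_mode),
    class = "tf_config"
  )
}

#' Read a target-function configuration from a YAML file
#'
#' Unknown fields are rejected; missing fields take the [tf_config()]
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `tf_config`.
#' @export
tf_config_from_file <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(tf_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    stop("unknown config field(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  do.call(tf_config, vals)
}

# TF0 combination of the two training-set correlations
.tf_combine <- function(r_at, r_pt, tf0_coeff = 0.1) {
  r_at + r_pt - abs(r_at - r_pt) * tf0_coeff
}

# Target-function value from precomputed descriptor vectors.
# Errors (constant descriptor, degenerate criterion) propagate; the optimizer
# maps them to a rejected move.
.tf_value <- function(cfg, y_active, d_active, y_passive, d_passive,
                      y_calibration, d_calibration) {
  if (stats::sd(d_active) == 0 || stats::sd(d_passive) == 0) {
    stop("undefined statistic: constant descriptor on a training subset",
         call. = FALSE)
  }
  r_at <- stats::cor(y_active, d_active)
  r_pt <- stats::cor(y_passive, d_passive)
  tf <- .tf_combine(r_at, r_pt, cfg$tf0_coeff)
  if (cfg$variant != "TF0") {
    v <- stats::var(d_active) * (length(d_active) - 1) / length(d_active)
    b1 <- mean((y_active - mean(y_active)) * (d_active - mean(d_active))) / v
    b0 <- mean(y_active) - b1 * mean(d_active)
    calc <- b0 + b1 * d_calibration
    crit <- switch(cfg$variant,
      TF1 = iic(y_calibration, calc),
      TF2 = cii(y_calibration, calc),
      TF3 = cccp(y_calibration, calc)
    )
    tf <- tf + crit * cfg$criterion_coeff
  }
  tf
}

#' Evaluate a target function for a weight table
#'
#' Computes TF0-TF3 for given subsets and weights, exactly as the optimizer
#' scores a state: training-set correlations of endpoint vs. DCW, plus (for
#' TF1-TF3) the calibration-set criterion on predictions from the active-set
#' regression.
#'
#' @param cfg A [tf_config()].
#' @param active,passive,calibration Records data.frames.
#' @param table A `cw_table`.
#' @return The target-function value (scalar).
#' @export
target_function <- function(cfg, active, passive, calibration, table) {
  stopifnot(inherits(cfg, "tf_config"), inherits(table, "cw_table"))
  .tf_value(cfg,
            active$endpoint, dcw(active$smiles, table),
            passive$endpoint, dcw(passive$smiles, table),
            calibration$endpoint, dcw(calibration$smiles, table))
}

#' Optimize correlation weights by Monte Carlo hill-climb
#'
#' Builds the blocklist from the active training set at `cfg$threshold_T`,
#' initializes the non-blocked weights, and runs `cfg$epochs_N` epochs.  Each
#' epoch visits every non-blocked attribute once in seeded-random order and
#' proposes `CW' = CW + step_size * u` with `u ~ U(-1, 1)`; the move is kept
#' iff the target function does not decrease (ties accepted).  Proposals that
#' make a statistic undefined are rejected.  The run is fully deterministic
#' for a fixed configuration, and only the active, passive and calibration
#' subsets are ever read -- validation data cannot leak in through this
#' interface.
#'
#' @param active,passive,calibration Records data.frames.
#' @param cfg A [tf_config()].
#' @return List with elements `table` (the optimized `cw_table`) and `trace`
#'   (class `cw_trace`: `accepted_moves`, `tf_values` at the initial state
#'   and after each accepted move, `epoch_tf`, `final_tf`).
#' @export
cw_optimize <- function(active, passive, calibration, cfg) {
  stopifnot(inherits(cfg, "tf_config"))
  counts <- attribute_counts(active, cfg$count_mode)
  blocked <- build_blocklist(counts, cfg$threshold_T)
  keys <- setdiff(names(counts), blocked)
  if (length(keys) == 0L) {
    stop("optimization impossible: every attribute is blocked (T = ",
         cfg$threshold_T, ")", call. = FALSE)
  }
  m_active <- .attribute_matrix(active$smiles, keys)
  m_passive <- .attribute_matrix(passive$smiles, keys)
  m_calibration <- .attribute_matrix(calibration$smiles, keys)
  y_active <- active$endpoint
  y_passive <- passive$endpoint
  y_calibration <- calibration$endpoint
  n_keys <- length(keys)

  res <- withr::with_seed(cfg$seed, {
    w <- if (cfg$init == "ones") rep(1, n_keys) else stats::runif(n_keys, -1, 1)
    d_active <- drop(m_active %*% w)
    d_passive <- drop(m_passive %*% w)
    d_calibration <- drop(m_calibration %*% w)
    tf_cur <- .tf_value(cfg, y_active, d_active, y_passive, d_passive,
                        y_calibration, d_calibration)
    tf_values <- numeric(n_keys * cfg$epochs_N + 1L)
    tf_values[1L] <- tf_cur
    n_acc <- 0L
    epoch_tf <- numeric(cfg$epochs_N)
    for (epoch in seq_len(cfg$epochs_N)) {
      for (j in sample.int(n_keys)) {
        delta <- cfg$step_size * stats::runif(1L, -1, 1)
        prop_active <- d_active + delta * m_active[, j]
        prop_passive <- d_passive + delta * m_passive[, j]
        prop_calibration <- d_calibration + delta * m_calibration[, j]
        tf_new <- tryCatch(
          .tf_value(cfg, y_active, prop_active, y_passive, prop_passive,
                    y_calibration, prop_calibration),
          error = function(e) NA_real_
        )
        if (!is.na(tf_new) && tf_new >= tf_cur) {
          w[j] <- w[j] + delta
          d_active <- prop_active
          d_passive <- prop_passive
          d_calibration <- prop_calibration
          tf_cur <- tf_new
          n_acc <- n_acc + 1L
          tf_values[n_acc + 1L] <- tf_cur
        }
      }
      epoch_tf[epoch] <- tf_cur
    }
    list(w = w, tf_values = tf_values[seq_len(n_acc + 1L)],
         accepted = n_acc, epoch_tf = epoch_tf, final_tf = tf_cur)
  })

  weights <- stats::setNames(res$w, keys)
  # blocked keys are carried with weight 0 so reports can list them
  if (length(blocked)) {
    weights <- c(weights, stats::setNames(rep(0, length(blocked)), blocked))
  }
  table <- new_weight_table(weights, blocked = blocked,
                            threshold_T = cfg$threshold_T, seed = cfg$seed)
  trace <- structure(
    list(accepted_moves = res$accepted, tf_values = res$tf_values,
         epoch_tf = res$epoch_tf, final_tf = res$final_tf),
    class = "cw_trace"
  )
  list(table = table, trace = trace)
}

#' @export
print.cw_trace <- function(x, ...) {
  cat("Monte Carlo trace: ", x$accepted_moves, " accepted moves, final TF = ",
      format(x$final_tf, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Independent optimization probes
#'
#' Runs `n_probes` independent Monte Carlo optimizations that differ only in
#' their seed (`cfg$seed + probe - 1`).  Comparing the sign of each
#' attribute's weight across probes is the basis of the mechanistic
#' interpretation (see [classify_attributes()]).
#'
#' @inheritParams cw_optimize
#' @param n_probes Number of probes (>= 1).
#' @return List with elements `tables` (list of `cw_table`) and `traces`.
#' @export
run_probes <- function(active, passive, calibration, cfg, n_probes = 3L) {
  stopifnot(n_probes >= 1L)
  runs <- lapply(seq_len(n_probes), function(p) {
    cfg_p <- cfg
    cfg_p$seed <- cfg$seed + p - 1L
    cw_optimize(active, passive, calibration, cfg_p)
  })
  list(tables = lapply(runs, `[[`, "table"),
       traces = lapply(runs, `[[`, "trace"))
}
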