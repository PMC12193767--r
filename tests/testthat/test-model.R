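exact_split <- function(table, c0 = 2, c1 = 3, n = 40L, seed = 5L) {
  rec <- generate_dataset(tiny_spec(n = n, noise_sd = 0, seed = seed))
  rec$endpoint <- c0 + c1 * dcw(rec$smiles, table)
  make_split(rec, seed = 1L)
}

weight_table_for <- function(records, seed = 1L) {
  keys <- names(attribute_counts(records))
  new_weight_table(withr::with_seed(seed,
    stats::setNames(stats::runif(length(keys), -1, 1), keys)))
}

test_that("the final regression recovers an exact linear relation", {
  rec <- generate_dataset(tiny_spec(n = 40L, noise_sd = 0, seed = 5L))
  tab <- weight_table_for(rec)
  sp <- exact_split(tab)
  m <- fit_model(sp, tab)
  expect_equal(m$c0, 2, tolerance = 1e-10)
  expect_equal(m$c1, 3, tolerance = 1e-10)
  expect_equal(predict(m, sp$active$smiles), sp$active$endpoint, tolerance = 1e-10)
})

test_that("fitting matches ordinary least squares", {
  rec <- generate_dataset(tiny_spec(n = 60L, seed = 9L))
  tab <- weight_table_for(rec, seed = 2L)
  sp <- make_split(rec, seed = 3L)
  m <- fit_model(sp, tab)
  ols <- stats::lm(endpoint ~ d, data = data.frame(
    endpoint = sp$active$endpoint, d = dcw(sp$active$smiles, tab)))
  expect_equal(unname(stats::coef(ols)), c(m$c0, m$c1), tolerance = 1e-10)
  # intercept identity: c0 = mean(endpoint) - c1 * mean(descriptor)
  d <- dcw(sp$active$smiles, tab)
  expect_equal(m$c0, mean(sp$active$endpoint) - m$c1 * mean(d), tolerance = 1e-12)
})

test_that("prediction is affine in the descriptor and scale-compensated", {
  rec <- generate_dataset(tiny_spec(n = 40L, seed = 4L))
  tab <- weight_table_for(rec)
  sp <- make_split(rec, seed = 2L)
  m <- fit_model(sp, tab)
  s <- rec$smiles[1L]
  expect_equal(predict(m, s), m$c0 + m$c1 * dcw(s, tab), tolerance = 1e-12)
  # a molecule of only unknown attributes has DCW 0 and predicts c0
  expect_identical(dcw("[Xx][Xx]", m$table), 0)
  expect_equal(predict(m, "[Xx][Xx]"), m$c0)
  # doubling every weight while halving c1 leaves predictions unchanged
  m2 <- m
  m2$table <- new_weight_table(m$table$weights * 2, blocked = m$table$blocked)
  m2$c1 <- m$c1 / 2
  expect_equal(predict(m2, rec$smiles[1:10]), predict(m, rec$smiles[1:10]),
               tolerance = 1e-12)
})

test_that("attribute defects follow the three-pair formula", {
  expect_equal(defect_dk(c(2L, 1L, 1L), c(0.5, 0.25, 0.5)),
               0.25 / 3 + 0 / 3 + 0.25 / 2, tolerance = 1e-12)
  expect_identical(defect_dk(c(3L, 3L, 3L), c(0.2, 0.2, 0.2)), 0)
  expect_identical(defect_dk(c(0L, 0L, 0L), c(0, 0, 0)), 0)
  # symmetric under any permutation of the (frequency, probability) pairs
  withr::with_seed(17L, for (i in 1:20) {
    f <- sample(0:10, 3L, replace = TRUE)
    p <- ifelse(f == 0L, 0, stats::runif(3L))
    base <- defect_dk(f, p)
    for (perm in list(c(2L, 1L, 3L), c(3L, 2L, 1L), c(2L, 3L, 1L))) {
      expect_equal(defect_dk(f[perm], p[perm]), base, tolerance = 1e-12)
    }
  })
})

test_that("molecular defects sum distinct non-blocked attributes once", {
  rec <- generate_dataset(tiny_spec(n = 60L, seed = 6L))
  sp <- make_split(rec, seed = 2L)
  tab <- weight_table_for(rec)
  m <- fit_model(sp, tab)
  s <- rec$smiles[1L]
  keys <- names(smiles_attributes(s))  # names are distinct by construction
  keys <- keys[keys %in% names(m$table$weights) & !(keys %in% m$table$blocked)]
  want <- sum(m$defects$dk[match(keys, m$defects$attribute)], na.rm = TRUE)
  expect_equal(smiles_defect(m, s), want, tolerance = 1e-12)

  # blocking every attribute forces defect 0
  m_blk <- m
  m_blk$table <- new_weight_table(m$table$weights,
                                  blocked = names(m$table$weights))
  expect_identical(smiles_defect(m_blk, s), 0)
})

test_that("the applicability-domain boundary is strict", {
  fake <- structure(list(
    c0 = 0, c1 = 1,
    table = new_weight_table(c("C..........." = 1)),
    threshold_T = 0L,
    defects = data.frame(attribute = "C...........", n_active = 5L,
                         n_passive = 5L, n_calibration = 5L,
                         p_active = 0.5, p_passive = 0.5, p_calibration = 0.5,
                         dk = 0.1, stringsAsFactors = FALSE),
    mean_defect = 0.05
  ), class = "cw_model")
  # "C" carries exactly dk = 0.1 = 2 * mean_defect: on the boundary, excluded
  dom <- in_domain(fake, c("C", "OO"))
  expect_equal(dom$defect, c(0.1, 0))
  expect_identical(dom$in_domain, c(FALSE, TRUE))
})

test_that("out-of-domain counts match an enumeration oracle", {
  rec <- generate_dataset(tiny_spec(n = 80L, seed = 12L))
  sp <- make_split(rec, seed = 5L)
  tab <- weight_table_for(rec)
  m <- fit_model(sp, tab)
  dom <- in_domain(m, rec$smiles)
  manual <- vapply(rec$smiles, function(s) {
    keys <- names(smiles_attributes(s))
    keys <- keys[keys %in% names(m$table$weights) & !(keys %in% m$table$blocked)]
    sum(m$defects$dk[match(keys, m$defects$attribute)], na.rm = TRUE)
  }, numeric(1L), USE.NAMES = FALSE)
  expect_equal(dom$defect, manual, tolerance = 1e-12)
  expect_identical(sum(!dom$in_domain), sum(!(manual < 2 * m$mean_defect)))
  # repeated calls are stable
  expect_identical(in_domain(m, rec$smiles), dom)
})

test_that("attribute roles require a consistent sign across probes", {
  keys <- c("Cl..........", "N...........", "c...1.......")
  mk <- function(w) new_weight_table(stats::setNames(w, keys))
  probes <- list(mk(c(1.433, -0.885, 0.5)),
                 mk(c(0.096, -0.481, -0.1)),
                 mk(c(0.788, -0.966, 0.3)))
  roles <- classify_attributes(probes)
  get <- function(k) roles$role[roles$attribute == k]
  expect_identical(get("Cl.........."), "promoter_increase")
  expect_identical(get("N..........."), "promoter_decrease")
  expect_identical(get("c...1......."), "unclear")
  # an exact zero in any probe is unclear under the strict sign rule
  probes0 <- list(mk(c(1, 1, 0)), mk(c(1, 1, 0.5)))
  expect_identical(classify_attributes(probes0)$role[
    classify_attributes(probes0)$attribute == "c...1......."], "unclear")
  expect_error(classify_attributes(probes[1L]), "at least 2")
  # ordering: increase block first, then decrease, then unclear
  expect_identical(roles$role, c("promoter_increase", "promoter_decrease", "unclear"))
})

test_that("models round-trip through their text serialization", {
  rec <- generate_dataset(tiny_spec(n = 60L, seed = 8L))
  sp <- make_split(rec, seed = 4L)
  opt <- cw_optimize(sp$active, sp$passive, sp$calibration, tiny_cfg(epochs_N = 2L))
  m <- fit_model(sp, opt$table)
  path <- tempfile(fileext = ".txt")
  write_model(m, path)
  back <- read_model(path)
  expect_identical(back$c0, m$c0)
  expect_identical(back$c1, m$c1)
  expect_identical(back$mean_defect, m$mean_defect)
  expect_identical(predict(back, rec$smiles), predict(m, rec$smiles))
  expect_identical(in_domain(back, rec$smiles), in_domain(m, rec$smiles))
})
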