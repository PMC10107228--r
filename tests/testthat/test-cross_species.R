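test_that("behaviour series report proportions or counts per scan", {
  scans <- make_scans(list(
    s1 = list(capuchin = c("V", "V", "V", "F"), squirrel = c("OOS", "OOS")),
    s2 = list(capuchin = c("F", "F"), squirrel = c("V", "F"))
  ))
  comps <- scan_compositions(scans)

  v_prop <- behaviour_series(comps, "capuchin", "V", "proportion")
  expect_equal(v_prop$value[v_prop$scan_id == "s1"], 0.75)

  # a species with no visible individual is absent, not 0
  sq_prop <- behaviour_series(comps, "squirrel", "V", "proportion")
  expect_false("s1" %in% sq_prop$scan_id)

  v_count <- behaviour_series(comps, "capuchin", "V", "count")
  expect_equal(v_count$value[v_count$scan_id == "s1"], 3)
  expect_true("s1" %in% behaviour_series(comps, "squirrel", "V", "count")$scan_id)
})

test_that("cross-correlations are Pearson r per cell with undefined markers", {
  # squirrel proportions copy capuchin proportions -> diagonal r = 1
  set.seed(11)
  copy_scans <- lapply(1:6, function(i) {
    beh <- sample(c(rep("V", i), rep("F", 7 - i)))
    list(capuchin = beh, squirrel = beh)
  })
  names(copy_scans) <- paste0("s", 1:6)
  comps <- scan_compositions(make_scans(copy_scans))
  cc <- cross_correlation(comps)
  d <- diagonal_correlations(cc)
  expect_equal(d$r[d$behaviour %in% c("V", "F")], c(1, 1))

  # constant series -> undefined, never 0
  const_scans <- lapply(1:4, function(i) {
    list(capuchin = c("V", "F"), squirrel = c("V", if (i <= 2) "F" else "L"))
  })
  names(const_scans) <- paste0("s", 1:4)
  cc2 <- cross_correlation(scan_compositions(make_scans(const_scans)))
  expect_true(is.na(diagonal_correlations(cc2)$r[1]))

  # anti-phase 4-scan fixture: r = -1 on the vigilance cell
  anti <- lapply(1:4, function(i) {
    list(capuchin = c(rep("V", i), rep("F", 5 - i)),
         squirrel = c(rep("V", 5 - i), rep("F", i)))
  })
  names(anti) <- paste0("s", 1:4)
  cc3 <- cross_correlation(scan_compositions(make_scans(anti)))
  expect_equal(diagonal_correlations(cc3)$r[1], -1)

  # fewer than three paired scans: not computable
  few <- scan_compositions(make_scans(list(
    s1 = list(capuchin = c("V", "F"), squirrel = c("V", "F")),
    s2 = list(capuchin = c("F", "V"), squirrel = c("F", "V"))
  )))
  expect_true(all(is.na(cross_correlation(few)$r)))
})

test_that("exchanging the species transposes the correlation matrix", {
  sim <- generate_scans(synthetic_config(seed = 13, n_scans = 40,
                                         kappa_between = 0.5))
  comps <- scan_compositions(sim$scans)
  swapped <- dplyr::mutate(
    comps,
    species = ifelse(species == "capuchin", "squirrel", "capuchin")
  )
  m <- as.matrix(cross_correlation(comps))
  m_swapped <- as.matrix(cross_correlation(swapped))
  expect_equal(unname(m_swapped), unname(t(m)))
})

test_that("shuffle-split preserves the pooled multiset and the species sizes", {
  out <- shuffle_split(c("A", "A", "A", "A"), c("B", "B", "C"), seed = 1)
  expect_length(out$capuchin, 4)
  expect_length(out$squirrel, 3)
  expect_equal(sort(c(out$capuchin, out$squirrel)),
               sort(c("A", "A", "A", "A", "B", "B", "C")))

  # single-category multiset: output identical to input
  same <- shuffle_split(rep("V", 3), rep("V", 2), seed = 2)
  expect_equal(same, list(capuchin = rep("V", 3), squirrel = rep("V", 2)))

  # empty partner
  expect_equal(shuffle_split("V", character(0), seed = 3),
               list(capuchin = "V", squirrel = character(0)))
  expect_equal(lengths(shuffle_split(character(0), character(0))),
               c(capuchin = 0L, squirrel = 0L))

  # random multisets: conservation for arbitrary sizes
  set.seed(5)
  for (i in 1:50) {
    cap <- sample(analysed_behaviours(), sample(0:8, 1), replace = TRUE)
    sq <- sample(analysed_behaviours(), sample(0:8, 1), replace = TRUE)
    mix <- shuffle_split(cap, sq)
    expect_length(mix$capuchin, length(cap))
    expect_length(mix$squirrel, length(sq))
    expect_equal(sort(c(mix$capuchin, mix$squirrel)), sort(c(cap, sq)))
  }
})

test_that("shuffling twice is distributionally identical to shuffling once", {
  # pooled list A A B | C: the squirrel slot is A w.p. 1/2, B or C w.p. 1/4
  expected <- c(A = 0.5, B = 0.25, C = 0.25)
  draw <- function(twice) {
    once <- shuffle_split(c("A", "A", "B"), "C")
    if (twice) once <- shuffle_split(once$capuchin, once$squirrel)
    once$squirrel
  }
  set.seed(17)
  single <- table(factor(replicate(2000, draw(FALSE)), names(expected)))
  double <- table(factor(replicate(2000, draw(TRUE)), names(expected)))
  expect_gt(stats::chisq.test(single, p = expected)$p.value, 0.001)
  expect_gt(stats::chisq.test(double, p = expected)$p.value, 0.001)
})

test_that("the vectorized shuffle-split null matches a literal re-implementation", {
  sim <- generate_scans(synthetic_config(
    seed = 19, n_scans = 16,
    group_sizes = list(west = c(capuchin = 6, squirrel = 4),
                       east = c(capuchin = 5, squirrel = 5)),
    kappa_between = 0.3, p_oos = 0.1
  ))
  comps <- scan_compositions(sim$scans)

  fast <- simulate_crosscorr_null(comps, n_iterations = 400, seed = 23)
  set.seed(23)
  brute <- crosscorr_null_brute(comps, n_iterations = 400)

  for (b in seq_len(5)) {
    f <- fast$draws[, b]
    g <- brute[, b]
    if (all(is.na(f)) || all(is.na(g))) {
      expect_equal(all(is.na(f)), all(is.na(g)))
      next
    }
    se <- sqrt(stats::sd(f, na.rm = TRUE)^2 / sum(!is.na(f)) +
                 stats::sd(g, na.rm = TRUE)^2 / sum(!is.na(g)))
    expect_lt(abs(mean(f, na.rm = TRUE) - mean(g, na.rm = TRUE)),
              4 * se + 0.02)
  }
})

test_that("shuffle-split null is seeded and flags degenerate data", {
  sim <- generate_scans(synthetic_config(seed = 29, n_scans = 20))
  comps <- scan_compositions(sim$scans)
  a <- simulate_crosscorr_null(comps, n_iterations = 30, seed = 7)
  b <- simulate_crosscorr_null(comps, n_iterations = 30, seed = 7)
  expect_identical(a$draws, b$draws)
  expect_equal(dim(a$draws), c(30, 5)) # 5 x iterations null correlations

  # a dataset with a single behaviour everywhere is entirely non-computable
  flat <- make_scans(lapply(setNames(1:5, paste0("s", 1:5)), function(i) {
    list(capuchin = rep("V", 3), squirrel = rep("V", 2))
  }))
  res <- simulate_crosscorr_null(scan_compositions(flat),
                                 n_iterations = 20, seed = 1)
  expect_true(all(is.na(res$p_values)))
  expect_false(any(tidy(res)$computable))
})

test_that("coupling drives the cross-species test as designed", {
  shared <- dplyr::bind_rows(
    as_sampling_weights(c(0.468, 0.234, 0.118, 0.106, 0.073), "capuchin"),
    as_sampling_weights(c(0.468, 0.234, 0.118, 0.106, 0.073), "squirrel")
  )

  # full between-species coupling with identical budgets: the mixed group
  # really is one group, so the observed diagonal sits inside the null
  one_group <- generate_scans(synthetic_config(
    seed = 31, weights = shared,
    kappa_within = c(capuchin = 0.5, squirrel = 0.5),
    kappa_between = 1
  ))
  res1 <- simulate_crosscorr_null(scan_compositions(one_group$scans),
                                  n_iterations = 400, seed = 3)
  # with five simultaneous 95% bands one excursion is expected by chance
  # (P(>=2 outside) ~ 2%), so require at least four of five inside
  inside <- vapply(analysed_behaviours(), function(b) {
    if (is.na(res1$observed[b])) {
      return(NA)
    }
    q <- stats::quantile(res1$draws[, b], c(0.025, 0.975), na.rm = TRUE)
    res1$observed[b] > q[1] && res1$observed[b] < q[2]
  }, logical(1))
  expect_gte(sum(inside, na.rm = TRUE), 4)
  expect_true(all(res1$p_values > 0.01, na.rm = TRUE))

  # no between-species coupling but strong within-species coupling:
  # observed coordination falls below the pooled null
  independent <- generate_scans(synthetic_config(
    seed = 37,
    kappa_within = c(capuchin = 0.8, squirrel = 0.8),
    kappa_between = 0
  ))
  res0 <- simulate_crosscorr_null(scan_compositions(independent$scans),
                                  n_iterations = 400, seed = 5)
  adequate <- c("V", "F", "L", "R") # squirrel playing is near-absent
  expect_true(all(res0$p_values[adequate] < 0.05))
})
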