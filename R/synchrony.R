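# Per-scan behavioural synchrony (Simpson's diversity over behaviour counts),
# species sampling weights, and the weighted-resampling randomization null.

#' Behavioural synchrony index of one scan
#'
#' The per-scan synchrony index is Simpson's diversity over the behaviour
#' counts of the visible individuals:
#' \deqn{BS = \sum_i n_i (n_i - 1) / (N (N - 1))}
#' where \eqn{n_i} is the number of visible individuals engaged in behaviour
#' \eqn{i} and \eqn{N = \sum_i n_i}. It equals the probability that two
#' distinct visible individuals drawn at random from the scan are performing
#' the same behaviour: 1 means every visible individual is doing the same
#' thing, 0 means no two individuals share a behaviour. With fewer than two
#' visible individuals the index is undefined and `NA` is returned (such
#' scans are excluded from all summaries).
#'
#' @param counts Non-negative numeric vector of per-behaviour counts.
#' @return A value in `[0, 1]`, or `NA_real_` when fewer than two individuals
#'   are visible.
#' @export
#' @examples
#' bs_index(c(5, 0, 0, 0, 0)) # full synchrony
#' bs_index(c(1, 1, 1, 1, 1)) # full asynchrony
#' bs_index(c(4, 2, 1))       # 14/42
bs_index <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0), all(counts == floor(counts)))
  n <- sum(counts)
  if (n < 2) {
    return(NA_real_)
  }
  sum(counts * (counts - 1)) / (n * (n - 1))
}

#' Add the synchrony index to a composition table
#'
#' Computes [bs_index()] for every row of a composition table (see
#' [scan_compositions()]) and appends it as a `bs` column. Rows with
#' `n_visible < 2` get `NA`.
#'
#' @param comps A composition tibble with the five behaviour-count columns.
#' @return `comps` with an additional `bs` column.
#' @export
behavioural_synchrony <- function(comps) {
  m <- as.matrix(comps[analysed_behaviours()])
  n <- rowSums(m)
  bs <- rowSums(m * (m - 1)) / (n * (n - 1))
  bs[n < 2] <- NA_real_
  dplyr::mutate(comps, bs = bs)
}

#' Per-scan synchrony series for a species or the combined group
#'
#' Collects the per-scan synchrony scores for one species, or for the
#' combined mixed-species group (`scope = "combined"`), in which case the two
#' species' behaviour counts in each scan are summed before the index is
#' applied. Scans failing the minimum-N rule (fewer than `min_n` visible
#' individuals) are excluded and counted.
#'
#' @param comps A composition tibble from [scan_compositions()].
#' @param scope A species label or `"combined"`.
#' @param min_n Minimum visible individuals for a defined score (default 2;
#'   below 2 the index denominator vanishes).
#' @return A tibble of class `synchrony_series` with columns `scan_id`,
#'   `group`, `bs`, plus attributes `scope`, `min_n` and `n_excluded`.
#'   Use [glance()] for the mean/s.d. summary.
#' @export
#' @examples
#' example_scans() |>
#'   scan_compositions() |>
#'   synchrony_series("combined") |>
#'   glance()
synchrony_series <- function(comps, scope, min_n = 2) {
  scope <- rlang::arg_match(scope, c(species_levels(), "combined"))
  if (scope == "combined") {
    comps <- comps |>
      dplyr::group_by(.data$scan_id, .data$group) |>
      dplyr::summarise(
        dplyr::across(dplyr::all_of(analysed_behaviours()), sum),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        n_visible = rowSums(dplyr::pick(dplyr::all_of(analysed_behaviours())))
      )
  } else {
    comps <- dplyr::filter(comps, .data$species == scope)
  }
  scored <- behavioural_synchrony(comps)
  keep <- !is.na(scored$bs) & scored$n_visible >= min_n
  out <- scored |>
    dplyr::filter(keep) |>
    dplyr::select(dplyr::all_of(c("scan_id", "group", "bs")))
  if (nrow(out) == 0) {
    abort(
      paste0("No scan passes the minimum-N rule for scope '", scope, "'"),
      class = "scansync_empty_result"
    )
  }
  structure(
    out,
    scope = scope, min_n = min_n, n_excluded = sum(!keep),
    class = c("synchrony_series", class(out))
  )
}

#' @exportS3Method generics::glance
glance.synchrony_series <- function(x, ...) {
  tibble::tibble(
    scope = attr(x, "scope"),
    n_scans = nrow(x),
    n_excluded = attr(x, "n_excluded"),
    mean_bs = mean(x$bs),
    sd_bs = if (nrow(x) > 1) sd(x$bs) else 0
  )
}

#' Species sampling weights (activity budget)
#'
#' The sampling weights of a species are the marginal proportions of the five
#' analysed behaviours across all its scan records, pooled over groups. They
#' parameterize the within-species randomization null: under the null, scan
#' behaviours are independent draws from this activity budget.
#'
#' @param comps A composition tibble from [scan_compositions()].
#' @param species Optional species label; default computes weights for every
#'   species with at least one analysed-behaviour record.
#' @return A tibble of class `sampling_weights` with columns `species`,
#'   `behaviour`, `weight`; weights sum to 1 per species.
#' @export
sampling_weights <- function(comps, species = NULL) {
  totals <- comps |>
    tidyr::pivot_longer(
      dplyr::all_of(analysed_behaviours()),
      names_to = "behaviour", values_to = "n"
    ) |>
    dplyr::group_by(.data$species, .data$behaviour) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop_last") |>
    dplyr::mutate(total = sum(.data$n)) |>
    dplyr::ungroup()
  if (!is.null(species)) {
    species <- rlang::arg_match(species, species_levels())
    totals <- dplyr::filter(totals, .data$species == !!species)
    if (nrow(totals) == 0 || all(totals$total == 0)) {
      abort_validation(
        paste0("No analysed-behaviour records for species '", species, "'")
      )
    }
  }
  out <- totals |>
    dplyr::filter(.data$total > 0) |>
    dplyr::mutate(
      weight = .data$n / .data$total,
      behaviour = factor(.data$behaviour, levels = analysed_behaviours())
    ) |>
    dplyr::arrange(.data$species, .data$behaviour) |>
    dplyr::mutate(behaviour = as.character(.data$behaviour)) |>
    dplyr::select(dplyr::all_of(c("species", "behaviour", "weight")))
  structure(out, class = c("sampling_weights", class(out)))
}

#' Construct sampling weights from a numeric vector
#'
#' Turns a user-supplied vector of five behaviour proportions (for example a
#' published, rounded activity budget) into a `sampling_weights` table.
#' Rounded vectors that do not sum exactly to 1 are renormalized so they can
#' be used as sampling probabilities.
#'
#' @param weights Numeric vector of length 5, ordered V, F, L, R, P (or named
#'   by behaviour code).
#' @param species Species label the weights describe.
#' @return A `sampling_weights` tibble.
#' @export
#' @examples
#' as_sampling_weights(c(0.468, 0.234, 0.118, 0.106, 0.073), "capuchin")
as_sampling_weights <- function(weights, species) {
  species <- rlang::arg_match(species, species_levels())
  stopifnot(is.numeric(weights), length(weights) == 5, all(weights >= 0),
            sum(weights) > 0)
  if (!is.null(names(weights))) {
    stopifnot(setequal(names(weights), analysed_behaviours()))
    weights <- weights[analysed_behaviours()]
  }
  out <- tibble::tibble(
    species = species,
    behaviour = analysed_behaviours(),
    weight = as.numeric(weights) / sum(weights)
  )
  structure(out, class = c("sampling_weights", class(out)))
}

# Extract one species' weights as a named numeric vector in V,F,L,R,P order.
weights_vector <- function(weights, species = NULL) {
  if (is.numeric(weights)) {
    stopifnot(length(weights) == 5)
    if (!is.null(names(weights))) weights <- weights[analysed_behaviours()]
    return(setNames(as.numeric(weights), analysed_behaviours()))
  }
  stopifnot(is.data.frame(weights))
  if (!is.null(species)) {
    weights <- dplyr::filter(weights, .data$species == !!species)
  }
  if (dplyr::n_distinct(weights$species) != 1) {
    abort_validation("weights must describe exactly one species here")
  }
  setNames(
    weights$weight[match(analysed_behaviours(), weights$behaviour)],
    analysed_behaviours()
  )
}

#' Expected synchrony under the randomization null
#'
#' Closed-form mean of the within-species null: when each scan's behaviours
#' are independent draws with category probabilities \eqn{p_i}, the expected
#' synchrony index is \eqn{\sum_i p_i^2}, independent of the number of
#' visible individuals. The weights are used exactly as given (a published,
#' rounded vector is not renormalized here), so the value is the literal
#' sum of squares.
#'
#' @param weights A numeric vector of five behaviour proportions, or a
#'   `sampling_weights` tibble (one row of output per species).
#' @return A single value in `[0, 1]`, or for a multi-species weights table a
#'   tibble with columns `species` and `expected_bs`.
#' @export
#' @examples
#' expected_synchrony(rep(0.2, 5)) # uniform budget -> 0.2
expected_synchrony <- function(weights) {
  if (is.numeric(weights)) {
    stopifnot(length(weights) == 5, all(weights >= 0))
    return(sum(weights^2))
  }
  stopifnot(is.data.frame(weights))
  weights |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(expected_bs = sum(.data$weight^2), .groups = "drop")
}

#' Weighted-resampling null for within-species synchrony
#'
#' Simulates the randomization null for within-species synchrony: in each
#' iteration, every observed scan is replaced by a random scan in which each
#' of its \eqn{N} visible individuals independently draws a behaviour with
#' the species' sampling-weight probabilities (the per-scan visible totals
#' are preserved from the data). The per-scan synchrony indices of the
#' simulated scans are averaged within each iteration; the iteration means
#' form the null distribution of the mean synchrony score.
#'
#' Scans with fewer than two visible individuals are excluded, mirroring the
#' minimum-N rule of the observed series.
#'
#' @param weights Five behaviour proportions (numeric vector or single-species
#'   `sampling_weights` tibble); renormalized to probabilities.
#' @param visible_counts Integer vector of per-scan visible totals \eqn{N},
#'   taken from the observed data.
#' @param n_iterations Number of simulated datasets (default 1000).
#' @param seed Optional integer seed; the same seed gives a bit-identical
#'   null. The caller's RNG state is preserved.
#' @return A `null_distribution` object holding the iteration means
#'   (`$stats`), the scheme label, iteration count and seed. `observed`,
#'   `p_value` and `direction` are filled by [within_species_test()].
#' @export
simulate_within_species_null <- function(weights, visible_counts,
                                         n_iterations = 1000, seed = NULL) {
  w <- weights_vector(weights)
  prob <- w / sum(w)
  stopifnot(n_iterations >= 1)
  vc <- as.integer(visible_counts)
  stopifnot(all(vc >= 0))
  excluded <- sum(vc < 2)
  vc <- vc[vc >= 2]
  if (length(vc) == 0) {
    abort_validation("All scans have fewer than two visible individuals")
  }

  stats <- with_preserved_seed(seed, {
    totals <- numeric(n_iterations)
    # one rmultinom call per distinct N: distributionally identical to
    # per-scan draws, orders of magnitude fewer RNG calls
    for (n_vis in sort(unique(vc))) {
      k <- sum(vc == n_vis)
      draws <- rmultinom(n_iterations * k, n_vis, prob)
      bs <- colSums(draws * (draws - 1)) / (n_vis * (n_vis - 1))
      totals <- totals + colSums(matrix(bs, nrow = k))
    }
    totals / length(vc)
  })

  new_null_distribution(
    scheme = "weighted_resampling",
    stats = stats,
    n_iterations = n_iterations,
    seed = seed,
    n_scans = length(vc),
    n_excluded = excluded
  )
}

new_null_distribution <- function(scheme, stats, n_iterations, seed,
                                  observed = NA_real_, p_value = NA_real_,
                                  direction = NA_character_, ...) {
  structure(
    list(
      scheme = scheme,
      stats = as.numeric(stats),
      n_iterations = n_iterations,
      observed = observed,
      p_value = p_value,
      direction = direction,
      seed = seed,
      ...
    ),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution: ", x$scheme, ">\n", sep = "")
  cat("  iterations: ", x$n_iterations,
      "  mean: ", signif(mean(x$stats, na.rm = TRUE), 4),
      "  range: [", signif(min(x$stats, na.rm = TRUE), 4), ", ",
      signif(max(x$stats, na.rm = TRUE), 4), "]\n", sep = "")
  if (!is.na(x$observed)) {
    cat("  observed: ", signif(x$observed, 4),
        "  p (", x$direction, "): ", x$p_value, "\n", sep = "")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.null_distribution <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$stats), statistic = x$stats)
}

#' @exportS3Method generics::glance
glance.null_distribution <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme,
    n_iterations = x$n_iterations,
    null_mean = mean(x$stats, na.rm = TRUE),
    null_sd = sd(x$stats, na.rm = TRUE),
    null_min = min(x$stats, na.rm = TRUE),
    null_max = max(x$stats, na.rm = TRUE),
    observed = x$observed,
    p_value = x$p_value,
    direction = x$direction
  )
}

#' Permutation p-value
#'
#' The proportion of null statistics at least as extreme as the observed
#' value: with `direction = "greater"`, the proportion of null values
#' `>= observed`; with `"less"`, the proportion `<= observed`. Ties count as
#' "as extreme" and no continuity correction is applied, so if 90% of the
#' null lies strictly below the observed value the p-value is 0.10.
#'
#' @param observed Observed statistic.
#' @param null_stats Numeric vector of null statistics (non-empty after
#'   removing `NA`).
#' @param direction `"greater"` (observed expected to exceed the null) or
#'   `"less"`.
#' @return A proportion in `[0, 1]`.
#' @export
permutation_pvalue <- function(observed, null_stats,
                               direction = c("greater", "less")) {
  direction <- rlang::arg_match(direction)
  null_stats <- null_stats[!is.na(null_stats)]
  if (length(null_stats) == 0) {
    abort_validation("null_stats must contain at least one defined value")
  }
  stopifnot(is.numeric(observed), length(observed) == 1, !is.na(observed))
  if (direction == "greater") {
    mean(null_stats >= observed)
  } else {
    mean(null_stats <= observed)
  }
}

#' Within-species synchrony permutation test
#'
#' The headline single-species test: the observed mean per-scan synchrony is
#' compared against the weighted-resampling null built from the species'
#' own sampling weights and per-scan visible totals. By default the test
#' direction is `"greater"` (is the group more synchronized than its
#' activity budget alone predicts?); both one-sided p-values are reported.
#'
#' @param comps A composition tibble from [scan_compositions()], or a raw
#'   scan-record tibble (compositions are derived automatically).
#' @param species Species label.
#' @param n_iterations Null iterations (default 1000).
#' @param seed Optional integer seed for a reproducible null.
#' @param direction Headline direction, `"greater"` (default) or `"less"`.
#' @param min_n Minimum visible individuals per scan (default 2).
#' @param weights Optional `sampling_weights` override; default weights are
#'   computed from the data, pooled over groups.
#' @return A `synchrony_test` object; see [glance()] for the one-row summary
#'   and [tidy()] for the per-scan scores.
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' sim <- generate_scans(cfg)
#' test <- within_species_test(sim$scans, "capuchin",
#'                             n_iterations = 200, seed = 42)
#' glance(test)
within_species_test <- function(comps, species, n_iterations = 1000,
                                seed = NULL, direction = c("greater", "less"),
                                min_n = 2, weights = NULL) {
  direction <- rlang::arg_match(direction)
  species <- rlang::arg_match(species, species_levels())
  if ("behaviour" %in% names(comps)) {
    comps <- scan_compositions(comps)
  }
  series <- synchrony_series(comps, scope = species, min_n = min_n)
  if (is.null(weights)) {
    weights <- sampling_weights(comps, species = species)
  }
  vc <- comps$n_visible[comps$species == species]
  null <- simulate_within_species_null(
    weights, vc,
    n_iterations = n_iterations, seed = seed
  )
  observed <- mean(series$bs)
  p_greater <- permutation_pvalue(observed, null$stats, "greater")
  p_less <- permutation_pvalue(observed, null$stats, "less")
  null$observed <- observed
  null$direction <- direction
  null$p_value <- if (direction == "greater") p_greater else p_less
  structure(
    list(
      species = species,
      series = series,
      weights = weights,
      null = null,
      observed_mean = observed,
      observed_sd = sd(series$bs),
      p_value = null$p_value,
      p_greater = p_greater,
      p_less = p_less,
      direction = direction,
      n_iterations = n_iterations,
      seed = seed
    ),
    class = "synchrony_test"
  )
}

#' @export
print.synchrony_test <- function(x, ...) {
  cat("Within-species synchrony test (", x$species, ")\n", sep = "")
  cat("  observed mean BS: ", signif(x$observed_mean, 4),
      " (s.d. ", signif(x$observed_sd, 4), ", ",
      nrow(x$series), " scans)\n", sep = "")
  cat("  null grand mean:  ", signif(mean(x$null$stats), 4),
      " [", signif(min(x$null$stats), 4), ", ",
      signif(max(x$null$stats), 4), "], ",
      x$n_iterations, " iterations\n", sep = "")
  cat("  p (", x$direction, "): ", format.pval(x$p_value, eps = 1e-4),
      "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.synchrony_test <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x$series), species = x$species,
                .before = 1)
}

#' @exportS3Method generics::glance
glance.synchrony_test <- function(x, ...) {
  tibble::tibble(
    species = x$species,
    n_scans = nrow(x$series),
    observed_mean = x$observed_mean,
    observed_sd = x$observed_sd,
    null_mean = mean(x$null$stats),
    null_sd = sd(x$null$stats),
    null_min = min(x$null$stats),
    null_max = max(x$null$stats),
    p_value = x$p_value,
    p_greater = x$p_greater,
    p_less = x$p_less,
    direction = x$direction,
    n_iterations = x$n_iterations
  )
}
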