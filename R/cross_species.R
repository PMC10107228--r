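# Between-species synchrony: behaviour-frequency series across scans,
# Pearson cross-correlations, and the pooled shuffle-split randomization null.

#' Per-scan frequency series of one behaviour for one species
#'
#' Across scans, the occurrence of a behaviour within a species, either as
#' the proportion of that species' visible individuals engaged in it
#' (`mode = "proportion"`, comparable across unequal group sizes) or as the
#' raw count (`mode = "count"`). In proportion mode, scans in which the
#' species has no visible individual are omitted (the proportion is
#' undefined), never reported as 0.
#'
#' @param comps A composition tibble from [scan_compositions()].
#' @param species Species label.
#' @param behaviour One of the five analysed behaviour codes.
#' @param mode `"proportion"` or `"count"`.
#' @return A tibble with columns `scan_id`, `group`, `value`.
#' @export
behaviour_series <- function(comps, species, behaviour,
                             mode = c("proportion", "count")) {
  mode <- rlang::arg_match(mode)
  species <- rlang::arg_match(species, species_levels())
  behaviour <- rlang::arg_match(behaviour, analysed_behaviours())
  rows <- dplyr::filter(comps, .data$species == !!species)
  value <- rows[[behaviour]]
  if (mode == "proportion") {
    keep <- rows$n_visible > 0
    rows <- rows[keep, ]
    value <- value[keep] / rows$n_visible
  }
  tibble::tibble(scan_id = rows$scan_id, group = rows$group, value = value)
}

# Per-group scans-by-behaviour value matrices for both species.
# Proportion mode keeps only scans where both species are visible.
species_value_matrices <- function(comps, mode, min_scans = 3) {
  split(comps, comps$group) |>
    purrr::imap(function(gc, group) {
      wide <- lapply(species_levels(), function(sp) {
        rows <- dplyr::filter(gc, .data$species == sp) |>
          dplyr::arrange(.data$scan_id)
        m <- as.matrix(rows[analysed_behaviours()])
        rownames(m) <- rows$scan_id
        list(m = m, n = rows$n_visible)
      })
      names(wide) <- species_levels()
      shared <- intersect(rownames(wide$capuchin$m), rownames(wide$squirrel$m))
      mats <- lapply(wide, function(x) {
        idx <- match(shared, rownames(x$m))
        m <- x$m[idx, , drop = FALSE]
        n <- x$n[idx]
        if (mode == "proportion") {
          keep <- NULL
          m <- m / n
        }
        list(m = m, n = n)
      })
      if (mode == "proportion") {
        keep <- mats$capuchin$n > 0 & mats$squirrel$n > 0
        mats <- lapply(mats, function(x) {
          list(m = x$m[keep, , drop = FALSE], n = x$n[keep])
        })
      }
      mats$group <- group
      mats$n_scans <- nrow(mats$capuchin$m)
      mats
    })
}

# Pearson r between columns, with zero-variance columns giving NA (undefined,
# never 0). Returns a 5x5 matrix indexed (capuchin behaviour, squirrel beh.).
safe_cor <- function(a, b) {
  out <- matrix(NA_real_, ncol(a), ncol(b),
                dimnames = list(colnames(a), colnames(b)))
  if (nrow(a) < 3) {
    return(out)
  }
  ok_a <- apply(a, 2, function(x) sd(x) > 0)
  ok_b <- apply(b, 2, function(x) sd(x) > 0)
  if (any(ok_a) && any(ok_b)) {
    out[ok_a, ok_b] <- cor(a[, ok_a, drop = FALSE], b[, ok_b, drop = FALSE])
  }
  out
}

aggregate_r <- function(values, aggregation) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    return(NA_real_)
  }
  if (aggregation == "fisher_z") {
    # clamp |r| = 1 away from the atanh pole
    z <- atanh(pmin(pmax(values, -1 + 1e-12), 1 - 1e-12))
    tanh(mean(z))
  } else {
    mean(values)
  }
}

#' Cross-species behaviour correlation matrix
#'
#' Pearson correlations, across scans, between every capuchin behaviour
#' series and every squirrel-monkey behaviour series. Correlations are
#' computed separately per group (west/east) over the scans in which both
#' species appear, then aggregated across groups: `"mean_r"` (unweighted
#' mean of the per-group coefficients, the default) or `"fisher_z"`
#' (Fisher-z average). Cells where either series has zero variance, or a
#' group has fewer than three paired scans, are undefined (`NA`), never 0.
#'
#' @inheritParams behaviour_series
#' @param aggregation `"mean_r"` or `"fisher_z"`.
#' @return A tibble of class `crosscorr_matrix` with columns
#'   `capuchin_behaviour`, `squirrel_behaviour`, `r`, `n_scans` (summed over
#'   groups); the per-group matrices are in attribute `per_group`. Use
#'   [as.matrix()] for the 5x5 form and [autoplot()] for a heatmap.
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 7, kappa_between = 0.8)
#' comps <- scan_compositions(generate_scans(cfg)$scans)
#' cross_correlation(comps)
cross_correlation <- function(comps, mode = c("proportion", "count"),
                              aggregation = c("mean_r", "fisher_z")) {
  mode <- rlang::arg_match(mode)
  aggregation <- rlang::arg_match(aggregation)
  groups <- species_value_matrices(comps, mode)
  per_group <- purrr::map(groups, function(g) {
    r <- safe_cor(g$capuchin$m, g$squirrel$m)
    tibble::tibble(
      group = g$group,
      capuchin_behaviour = rep(analysed_behaviours(), times = 5),
      squirrel_behaviour = rep(analysed_behaviours(), each = 5),
      r = as.vector(r),
      n_scans = g$n_scans
    )
  }) |>
    purrr::list_rbind()
  out <- per_group |>
    dplyr::group_by(.data$capuchin_behaviour, .data$squirrel_behaviour) |>
    dplyr::summarise(
      r = aggregate_r(.data$r, aggregation),
      n_scans = sum(.data$n_scans),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      capuchin_behaviour = factor(.data$capuchin_behaviour,
                                  levels = analysed_behaviours()),
      squirrel_behaviour = factor(.data$squirrel_behaviour,
                                  levels = analysed_behaviours())
    ) |>
    dplyr::arrange(.data$squirrel_behaviour, .data$capuchin_behaviour) |>
    dplyr::mutate(dplyr::across(dplyr::ends_with("behaviour"), as.character))
  structure(
    out,
    mode = mode, aggregation = aggregation, per_group = per_group,
    class = c("crosscorr_matrix", class(out))
  )
}

#' @export
as.matrix.crosscorr_matrix <- function(x, ...) {
  m <- matrix(NA_real_, 5, 5,
              dimnames = list(capuchin = analysed_behaviours(),
                              squirrel = analysed_behaviours()))
  m[cbind(x$capuchin_behaviour, x$squirrel_behaviour)] <- x$r
  m
}

#' Same-behaviour (diagonal) cross-correlations
#'
#' @param x A `crosscorr_matrix`.
#' @return A tibble with columns `behaviour`, `r`, `n_scans`.
#' @export
diagonal_correlations <- function(x) {
  x |>
    dplyr::filter(.data$capuchin_behaviour == .data$squirrel_behaviour) |>
    dplyr::transmute(
      behaviour = .data$capuchin_behaviour,
      r = .data$r,
      n_scans = .data$n_scans
    ) |>
    tibble::as_tibble()
}

#' Pooled shuffle-split of one scan's behaviours
#'
#' The randomization move behind the between-species null: the behaviours of
#' both species in one scan are pooled into a single list, the list is
#' shuffled uniformly at random, and the first block of the shuffled list
#' (of the original capuchin size) is handed back to the capuchins, the
#' remainder to the squirrel monkeys. The pooled multiset is preserved
#' exactly and each species keeps its original number of individuals — the
#' mixed-species group is treated as one group.
#'
#' @param capuchin,squirrel Character vectors of behaviour codes (multisets;
#'   may be empty).
#' @param seed Optional integer seed (caller RNG state preserved).
#' @return A list with elements `capuchin` and `squirrel`.
#' @export
#' @examples
#' shuffle_split(c("A", "A", "A", "A"), c("B", "B", "C"), seed = 1)
shuffle_split <- function(capuchin, squirrel, seed = NULL) {
  capuchin <- as.character(capuchin)
  squirrel <- as.character(squirrel)
  pooled <- c(capuchin, squirrel)
  if (length(pooled) > 1) {
    pooled <- with_preserved_seed(seed, sample(pooled))
  }
  list(
    capuchin = pooled[seq_len(length(capuchin))],
    squirrel = pooled[seq_len(length(squirrel)) + length(capuchin)]
  )
}

#' Shuffle-split randomization null for between-species synchrony
#'
#' Tests whether the five same-behaviour cross-species correlations could
#' arise if the mixed-species group behaved as one group. Each iteration
#' applies [shuffle_split()] independently to every scan (pooling both
#' species' visible behaviours, shuffling, and re-partitioning by the
#' original species counts), recomputes the five diagonal correlations over
#' all scans with the same per-group aggregation as the observed matrix, and
#' stores them — `n_iterations` iterations give `5 * n_iterations` null
#' correlations. Per behaviour, a one-sided permutation p-value compares the
#' observed correlation with its null draws (default direction `"less"`:
#' observed coordination below what pooling predicts, i.e. asynchrony).
#'
#' @inheritParams cross_correlation
#' @param n_iterations Number of shuffled datasets (default 1000).
#' @param seed Optional integer seed; same seed, bit-identical null.
#' @param direction `"less"` (default) or `"greater"`.
#' @return A `crosscorr_null` object; [tidy()] returns the per-behaviour
#'   summary table (observed r, null mean/s.d./max/min, p-value) and
#'   [tidy(x, draws = TRUE)] the raw null draws. Behaviours whose observed or
#'   null correlations are undefined (zero variance) are flagged
#'   non-computable, never reported as 0.
#' @export
simulate_crosscorr_null <- function(comps, mode = c("proportion", "count"),
                                    n_iterations = 1000, seed = NULL,
                                    direction = c("less", "greater"),
                                    aggregation = c("mean_r", "fisher_z")) {
  mode <- rlang::arg_match(mode)
  direction <- rlang::arg_match(direction)
  aggregation <- rlang::arg_match(aggregation)
  stopifnot(n_iterations >= 1)

  observed <- cross_correlation(comps, mode = mode, aggregation = aggregation)
  obs_diag <- diagonal_correlations(observed)

  # flatten the analysed records once; each iteration permutes behaviours
  # within scans and re-splits positionally (first block -> capuchins)
  long <- comps |>
    tidyr::pivot_longer(
      dplyr::all_of(analysed_behaviours()),
      names_to = "behaviour", values_to = "n"
    ) |>
    dplyr::filter(.data$n > 0) |>
    dplyr::arrange(.data$group, .data$scan_id,
                   match(.data$species, species_levels())) |>
    tidyr::uncount(.data$n)

  scan_tbl <- comps |>
    dplyr::select(dplyr::all_of(c("scan_id", "group", "species", "n_visible"))) |>
    tidyr::pivot_wider(names_from = "species", values_from = "n_visible",
                       values_fill = 0L) |>
    dplyr::arrange(.data$group, .data$scan_id)
  for (sp in species_levels()) {
    if (!sp %in% names(scan_tbl)) scan_tbl[[sp]] <- 0L
  }

  scan_int <- match(long$scan_id, scan_tbl$scan_id)
  beh_int <- match(long$behaviour, analysed_behaviours())
  ord0 <- order(scan_int)
  scan_int <- scan_int[ord0]
  beh_int <- beh_int[ord0]
  n_rec <- length(beh_int)
  n_scan <- nrow(scan_tbl)
  # position of each record inside its scan block; the split is positional
  pos <- sequence(tabulate(scan_int, nbins = n_scan)[sort(unique(scan_int))])
  is_cap <- pos <= scan_tbl$capuchin[scan_int]

  group_masks <- lapply(group_levels(), function(g) {
    idx <- which(scan_tbl$group == g)
    n_cap <- scan_tbl$capuchin[idx]
    n_sq <- scan_tbl$squirrel[idx]
    keep <- if (mode == "proportion") n_cap > 0 & n_sq > 0 else rep(TRUE, length(idx))
    list(scans = idx[keep], n_cap = n_cap[keep], n_sq = n_sq[keep])
  })
  names(group_masks) <- group_levels()

  cell_index <- (scan_int - 1L) * 10L + (!is_cap) * 5L + beh_int

  draws <- with_preserved_seed(seed, {
    out <- matrix(NA_real_, n_iterations, 5,
                  dimnames = list(NULL, analysed_behaviours()))
    for (it in seq_len(n_iterations)) {
      u <- stats::runif(n_rec)
      shuffled_beh <- beh_int[order(scan_int, u)]
      idx <- (scan_int - 1L) * 10L + (!is_cap) * 5L + shuffled_beh
      cnt <- tabulate(idx, nbins = 10L * n_scan)
      dim(cnt) <- c(5L, 2L, n_scan)
      per_group <- purrr::map(group_masks, function(gm) {
        if (length(gm$scans) == 0) {
          return(rep(NA_real_, 5))
        }
        a <- t(cnt[, 1L, gm$scans])
        b <- t(cnt[, 2L, gm$scans])
        if (mode == "proportion") {
          a <- a / gm$n_cap
          b <- b / gm$n_sq
        }
        colnames(a) <- colnames(b) <- analysed_behaviours()
        diag(safe_cor(a, b))
      })
      out[it, ] <- vapply(
        seq_len(5),
        function(b) aggregate_r(vapply(per_group, `[[`, numeric(1), b),
                                aggregation),
        numeric(1)
      )
    }
    out
  })

  p_values <- vapply(seq_len(5), function(b) {
    obs <- obs_diag$r[b]
    col <- draws[, b]
    if (is.na(obs) || all(is.na(col))) {
      return(NA_real_)
    }
    permutation_pvalue(obs, col, direction)
  }, numeric(1))

  structure(
    list(
      observed = setNames(obs_diag$r, obs_diag$behaviour),
      observed_matrix = observed,
      draws = draws,
      p_values = setNames(p_values, obs_diag$behaviour),
      n_undefined = colSums(is.na(draws)),
      direction = direction,
      mode = mode,
      aggregation = aggregation,
      n_iterations = n_iterations,
      seed = seed
    ),
    class = "crosscorr_null"
  )
}

#' @export
print.crosscorr_null <- function(x, ...) {
  cat("Between-species shuffle-split randomization (",
      x$n_iterations, " iterations, mode = ", x$mode,
      ", aggregation = ", x$aggregation, ")\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @rdname simulate_crosscorr_null
#' @param x A `crosscorr_null` object.
#' @param draws If `TRUE`, return the raw per-iteration null correlations
#'   (long tibble) instead of the summary table.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.crosscorr_null <- function(x, draws = FALSE, ...) {
  if (draws) {
    return(tibble::tibble(
      iteration = rep(seq_len(x$n_iterations), times = 5),
      behaviour = rep(analysed_behaviours(), each = x$n_iterations),
      r = as.vector(x$draws)
    ))
  }
  tibble::tibble(
    behaviour = analysed_behaviours(),
    observed_r = unname(x$observed),
    null_mean = colMeans(x$draws, na.rm = TRUE),
    null_sd = apply(x$draws, 2, sd, na.rm = TRUE),
    null_max = suppressWarnings(apply(x$draws, 2, max, na.rm = TRUE)),
    null_min = suppressWarnings(apply(x$draws, 2, min, na.rm = TRUE)),
    n_undefined = unname(x$n_undefined),
    p_value = unname(x$p_values),
    computable = !is.na(unname(x$p_values))
  ) |>
    dplyr::mutate(dplyr::across(
      dplyr::starts_with("null_"),
      ~ replace(.x, is.infinite(.x) | is.nan(.x), NA_real_)
    ))
}

#' @exportS3Method generics::glance
glance.crosscorr_null <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    aggregation = x$aggregation,
    direction = x$direction,
    n_iterations = x$n_iterations,
    n_behaviours_computable = sum(!is.na(x$p_values)),
    min_p = suppressWarnings(min(x$p_values, na.rm = TRUE))
  )
}
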