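# Fixture builders and independent oracles used across the suite.

# Build a scan-record tibble from compact per-scan behaviour vectors.
# `scans` is a list: list(scan_id = list(capuchin = c("V","F"), squirrel = ...))
# All scans in one group unless group is a named vector per scan.
make_scans <- function(scans, group = "west", enclosure = NA_character_) {
  rows <- list()
  for (sid in names(scans)) {
    g <- if (length(group) > 1) group[[sid]] else group
    for (sp in names(scans[[sid]])) {
      beh <- scans[[sid]][[sp]]
      if (length(beh) == 0) next
      enc <- if (is.list(enclosure)) enclosure[[sid]][[sp]] else enclosure
      rows[[paste(sid, sp)]] <- tibble::tibble(
        scan_id = sid,
        group = g,
        species = sp,
        individual_id = paste0(substr(sp, 1, 1), "_", sid, "_", seq_along(beh)),
        behaviour = beh,
        enclosure = rep_len(enc, length(beh)),
        timestamp = NA_character_
      )
    }
  }
  validate_scan_data(dplyr::bind_rows(rows))
}

# Independent oracle for the synchrony index: enumerate all unordered pairs
# of individuals and count the fraction sharing a behaviour.
bs_pair_oracle <- function(counts) {
  labels <- rep(seq_along(counts), times = counts)
  n <- length(labels)
  if (n < 2) {
    return(NA_real_)
  }
  pairs <- utils::combn(n, 2)
  mean(labels[pairs[1, ]] == labels[pairs[2, ]])
}

# Exhaustive-enumeration oracle for the expected synchrony index when N
# behaviours are drawn independently with probabilities p: sum over all
# multinomial outcomes of prob * BS.
expected_bs_enumeration <- function(p, n) {
  grid <- expand.grid(rep(list(0:n), length(p)))
  grid <- grid[rowSums(grid) == n, , drop = FALSE]
  sum(apply(grid, 1, function(cnt) {
    stats::dmultinom(cnt, size = n, prob = p) * bs_index(cnt)
  }))
}

# Brute-force shuffle-split null for the diagonal cross-correlations:
# literal per-scan shuffle_split() + recount + Pearson r, used as the
# independent cross-check of the vectorized implementation.
crosscorr_null_brute <- function(comps, n_iterations,
                                 mode = "proportion",
                                 aggregation = "mean_r") {
  beh <- analysed_behaviours()
  draws <- matrix(NA_real_, n_iterations, 5, dimnames = list(NULL, beh))
  expand <- function(row) rep(beh, times = as.integer(row[beh]))
  for (it in seq_len(n_iterations)) {
    per_group <- lapply(group_levels(), function(g) {
      gc <- comps[comps$group == g, , drop = FALSE]
      sids <- unique(gc$scan_id)
      if (length(sids) == 0) {
        return(rep(NA_real_, 5))
      }
      mats <- list(
        capuchin = matrix(0, length(sids), 5, dimnames = list(sids, beh)),
        squirrel = matrix(0, length(sids), 5, dimnames = list(sids, beh))
      )
      keep <- rep(TRUE, length(sids))
      for (i in seq_along(sids)) {
        rows <- gc[gc$scan_id == sids[i], , drop = FALSE]
        cap <- expand(rows[rows$species == "capuchin", , drop = FALSE])
        sq <- expand(rows[rows$species == "squirrel", , drop = FALSE])
        mixed <- shuffle_split(cap, sq)
        for (sp in species_levels()) {
          cnt <- table(factor(mixed[[sp]], levels = beh))
          n_sp <- length(mixed[[sp]])
          if (mode == "proportion") {
            if (n_sp == 0) keep[i] <- FALSE else mats[[sp]][i, ] <- cnt / n_sp
          } else {
            mats[[sp]][i, ] <- cnt
          }
        }
      }
      a <- mats$capuchin[keep, , drop = FALSE]
      b <- mats$squirrel[keep, , drop = FALSE]
      if (nrow(a) < 3) {
        return(rep(NA_real_, 5))
      }
      vapply(seq_len(5), function(j) {
        if (stats::sd(a[, j]) == 0 || stats::sd(b[, j]) == 0) {
          return(NA_real_)
        }
        stats::cor(a[, j], b[, j])
      }, numeric(1))
    })
    draws[it, ] <- vapply(seq_len(5), function(j) {
      vals <- vapply(per_group, `[[`, numeric(1), j)
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) {
        return(NA_real_)
      }
      if (aggregation == "fisher_z") {
        tanh(mean(atanh(pmin(pmax(vals, -1 + 1e-12), 1 - 1e-12))))
      } else {
        mean(vals)
      }
    }, numeric(1))
  }
  draws
}
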