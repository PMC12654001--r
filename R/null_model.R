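#' Permutation null-model configuration
#'
#' @param n_perm number of permutations N (default 10000).
#' @param seed master seed; each (prescription, category) pair draws from
#'   an independent sub-stream derived with [derive_seed()], so adding a
#'   prescription never perturbs another's null distribution.
#' @param alpha significance level (strict `p < alpha`; default 0.05).
#' @param keep_null keep the full null distribution of concordance rates
#'   in the result (for histogram export)? Default `FALSE`.
#' @return a `permutation_config` list.
#' @export
permutation_config <- function(n_perm = 10000, seed = 1, alpha = 0.05,
                               keep_null = FALSE) {
  stopifnot(n_perm >= 1, alpha > 0, alpha < 1)
  structure(
    list(
      n_perm = as.integer(n_perm), seed = as.integer(seed),
      alpha = alpha, keep_null = isTRUE(keep_null)
    ),
    class = "permutation_config"
  )
}

#' Concordance rate between predicted and gold-standard disease sets
#'
#' Percentage of the gold-standard list recovered by the prediction:
#' `100 * |predicted intersect gold| / |gold|`. The statistic is
#' normalized by the GOLD list size, not the predicted set size — the
#' predicted sets run to thousands of terms while gold lists are small,
#' and a full recovery of the gold list scores 100% regardless of how
#' many extra diseases the network predicts.
#'
#' @param predicted character vector of disease terms (normalized).
#' @param gold non-empty character vector of gold terms (normalized).
#' @return concordance in percent, in `[0, 100]`.
#' @export
concordance_rate <- function(predicted, gold) {
  gold <- unique(gold)
  if (length(gold) == 0) {
    stop("concordance_rate: empty gold-standard list (statistic undefined)",
      call. = FALSE
    )
  }
  100 * length(intersect(unique(predicted), gold)) / length(gold)
}

#' Sample a size-matched null disease set
#'
#' Draws a uniformly random subset of the background universe without
#' replacement, of the same size as the network-predicted set, using the
#' current RNG state.
#'
#' @param universe character vector of disease terms.
#' @param m subset size, `0 <= m <= |universe|`.
#' @param prescription optional id used in the error message.
#' @return character vector of `m` terms.
#' @export
sample_null_set <- function(universe, m, prescription = NULL) {
  if (m > length(universe)) {
    stop(sprintf(
      "cannot sample %d diseases from a universe of %d%s",
      m, length(universe),
      if (is.null(prescription)) "" else sprintf(" (prescription '%s')", prescription)
    ), call. = FALSE)
  }
  if (m == 0) {
    return(character(0))
  }
  universe[sample.int(length(universe), m, replace = FALSE)]
}

#' Empirical permutation p-value
#'
#' `p = (C + 1) / (N + 1)` where `C` counts null concordance rates
#' greater than OR EQUAL to the observed rate (ties count as
#' exceedances). The +1 correction treats the observed statistic as one
#' more draw from its own null, so `p` is never 0 and never below
#' `1/(N+1)`.
#'
#' @param observed observed concordance (percent).
#' @param null_rates numeric vector of N null concordance rates.
#' @return list with elements `p` and `C`.
#' @export
empirical_p <- function(observed, null_rates) {
  n <- length(null_rates)
  if (n == 0) {
    stop("empirical_p: empty null distribution", call. = FALSE)
  }
  C <- sum(null_rates >= observed)
  list(p = (C + 1) / (n + 1), C = as.integer(C))
}

#' Significance stars for an empirical p-value
#'
#' @param p p-value in `(0, 1]`.
#' @return `"***"` (p < 0.001), `"**"` (p < 0.01), `"*"` (p < 0.05) or `"ns"`.
#' @export
significance_label <- function(p) {
  vapply(p, function(pi) {
    if (pi < 0.001) {
      "***"
    } else if (pi < 0.01) {
      "**"
    } else if (pi < 0.05) {
      "*"
    } else {
      "ns"
    }
  }, character(1))
}

# One (prescription, category) permutation run; gold already normalized.
validate_one_category <- function(predicted, gold, universe, config,
                                  prescription, category) {
  m <- length(predicted)
  n_gold <- length(gold)
  N <- config$n_perm

  if (m == 0) {
    warning(sprintf(
      "prescription '%s', category '%s': empty predicted set; p = 1 by construction",
      prescription, category
    ), call. = FALSE)
  }
  observed <- if (m == 0) 0 else concordance_rate(predicted, gold)

  set.seed(derive_seed(config$seed, "null_model", prescription, category))
  U <- length(universe)
  gold_idx <- match(gold, universe)
  gold_idx <- gold_idx[!is.na(gold_idx)] # terms outside the universe can never be drawn
  null_rates <- numeric(N)
  if (m > 0 && length(gold_idx) > 0) {
    for (i in seq_len(N)) {
      smp <- sample.int(U, m, replace = FALSE)
      null_rates[i] <- sum(match(gold_idx, smp, nomatch = 0L) > 0L)
    }
    null_rates <- 100 * null_rates / n_gold
  }
  ep <- empirical_p(observed, null_rates)

  res <- data.frame(
    prescription_id = prescription,
    category = category,
    n_gold = n_gold,
    m_predicted = m,
    U = U,
    observed_pct = observed,
    null_mean_pct = mean(null_rates),
    null_sd_pct = stats::sd(null_rates),
    C = ep$C,
    p_value = ep$p,
    significant = ep$p < config$alpha,
    stars = significance_label(ep$p),
    stringsAsFactors = FALSE
  )
  list(row = res, null = if (config$keep_null) null_rates else NULL)
}

#' Permutation validation of a prescription's predicted diseases
#'
#' For every gold-standard category available for the prescription, tests
#' whether the observed concordance between the network-predicted disease
#' set and the gold list exceeds chance. The null distribution is built
#' by repeatedly sampling, without replacement, a random disease set of
#' the SAME SIZE as the predicted set from the background universe and
#' recomputing the concordance; the empirical p-value is
#' `(C + 1)/(N + 1)` with ties counted (see [empirical_p()]).
#' Significance is strict `p < alpha`. Fully reproducible: each
#' (prescription, category) pair uses its own derived sub-seed.
#'
#' @param network a `therapeutic_network` (from the final filtered
#'   knowledge base).
#' @param gold a `herbnet_gold`.
#' @param universe background universe of disease terms
#'   (`kb$disease_universe`).
#' @param config a [permutation_config()].
#' @return a `herbnet_validation` data.frame, one row per category, with
#'   columns prescription_id, category, n_gold, m_predicted, U,
#'   observed_pct, null_mean_pct, null_sd_pct, C, p_value, significant,
#'   stars. When `config$keep_null` is `TRUE` the per-category null
#'   distributions are attached as attribute `null_distributions`.
#' @export
validate_prescription <- function(network, gold, universe,
                                  config = permutation_config()) {
  stopifnot(
    inherits(network, "therapeutic_network"),
    inherits(gold, "herbnet_gold")
  )
  prescription <- network$prescription_id
  cats <- gold_categories(gold, prescription)
  if (length(cats) == 0) {
    stop(sprintf("no gold-standard entries for prescription '%s'", prescription),
      call. = FALSE
    )
  }
  predicted <- predicted_diseases(network)
  if (length(predicted) > length(universe)) {
    stop(sprintf(
      "prescription '%s': predicted set larger than the universe", prescription
    ), call. = FALSE)
  }
  rows <- list()
  nulls <- list()
  for (cat in cats) {
    g <- gold_terms(gold, prescription, cat)
    out <- validate_one_category(predicted, g, universe, config, prescription, cat)
    rows[[cat]] <- out$row
    if (!is.null(out$null)) {
      nulls[[paste(prescription, cat, sep = ":")]] <- out$null
    }
  }
  res <- do.call(rbind, unname(rows))
  rownames(res) <- NULL
  structure(res,
    null_distributions = if (length(nulls) > 0) nulls else NULL,
    class = c("herbnet_validation", "data.frame")
  )
}

#' Validate every prescription in a batch
#'
#' @param networks list of `therapeutic_network` objects.
#' @param gold a `herbnet_gold`.
#' @param universe background disease universe.
#' @param config a [permutation_config()].
#' @return a combined `herbnet_validation` data.frame.
#' @export
validate_prescriptions <- function(networks, gold, universe,
                                   config = permutation_config()) {
  parts <- lapply(networks, validate_prescription,
    gold = gold,
    universe = universe, config = config
  )
  res <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(res) <- NULL
  nulls <- do.call(c, unname(lapply(parts, attr, "null_distributions")))
  structure(res,
    null_distributions = if (length(nulls) > 0) nulls else NULL,
    class = c("herbnet_validation", "data.frame")
  )
}

#' @export
print.herbnet_validation <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  df$observed_pct <- round(df$observed_pct, 2)
  df$null_mean_pct <- round(df$null_mean_pct, 2)
  df$null_sd_pct <- round(df$null_sd_pct, 2)
  df$p_value <- round(df$p_value, digits)
  print.data.frame(df, ...)
  invisible(x)
}

#' @export
write_outputs.herbnet_validation <- function(x, directory, ...) {
  df <- as.data.frame(x)
  df$p_value <- sprintf("%.4f", df$p_value) # 4 d.p. in tables only, never internally
  df$observed_pct <- sprintf("%.2f", df$observed_pct)
  df$null_mean_pct <- sprintf("%.2f", df$null_mean_pct)
  df$null_sd_pct <- sprintf("%.2f", df$null_sd_pct)
  write_tsv(df, file.path(directory, "validation_results.tsv"))
  man <- manifest_entry("validation_results.tsv", nrow(df))
  nulls <- attr(x, "null_distributions")
  if (!is.null(nulls)) {
    nd <- data.frame(
      run = rep(names(nulls), lengths(nulls)),
      concordance_pct = unlist(nulls, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    write_tsv(nd, file.path(directory, "null_distributions.tsv"))
    man <- rbind(man, manifest_entry("null_distributions.tsv", nrow(nd)))
  }
  man
}
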