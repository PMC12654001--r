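#' Pre-ranked GSEA configuration
#'
#' Defaults follow common positive-mode practice for herb-target lists:
#' gene sets with fewer than 10 or more than 500 members (after
#' intersection with the ranked universe) are skipped, enrichment is
#' assessed for positive scores only, and nominal permutation p-values
#' below 0.05 flag a set as enriched before BH adjustment.
#'
#' @param min_size minimum effective gene-set size (default 10).
#' @param max_size maximum effective gene-set size (default 500).
#' @param p_cutoff nominal p-value cutoff for the enriched flag (default 0.05).
#' @param weight_exponent exponent applied to scores when weighting hits
#'   (default 1; 0 reduces to the unweighted Kolmogorov-Smirnov walk).
#' @param n_perm number of gene-label permutations (default 1000).
#' @param seed master seed; each gene set draws from its own derived
#'   sub-stream.
#' @return a `gsea_config` list.
#' @export
gsea_config <- function(min_size = 10, max_size = 500, p_cutoff = 0.05,
                        weight_exponent = 1, n_perm = 1000, seed = 1) {
  stopifnot(min_size >= 1, min_size <= max_size, n_perm >= 1,
            p_cutoff > 0, p_cutoff <= 1, weight_exponent >= 0)
  structure(
    list(
      min_size = as.integer(min_size), max_size = as.integer(max_size),
      p_cutoff = p_cutoff, weight_exponent = weight_exponent,
      n_perm = as.integer(n_perm), seed = as.integer(seed),
      score_type = "pos"
    ),
    class = "gsea_config"
  )
}

#' Dose-weighted composite gene scores for a prescription
#'
#' The ranking metric of the pre-ranked GSEA. For each gene g, evidence
#' scores of surviving ingredient-gene links are summed along every
#' herb -> ingredient -> gene path and weighted by the herb's dose in
#' grams:
#' `score(g) = sum_h dose_g(h) * sum_{i in h, (i,g) surviving} evidence(i, g)`.
#' Scores from all herbs of the prescription are summed into a single
#' comprehensive score per gene, reflecting the polypharmacological
#' action of the whole formula. Genes with no surviving path are absent
#' from the result. Scores are homogeneous of degree 1 in the doses.
#'
#' @param kb a filtered `herbnet_kb`.
#' @param prescription prescription id.
#' @return named numeric vector, gene id -> composite score (> 0).
#' @export
composite_gene_scores <- function(kb, prescription) {
  stopifnot(inherits(kb, "herbnet_kb"))
  comp <- kb$prescriptions[kb$prescriptions$prescription_id == prescription, ,
    drop = FALSE
  ]
  if (nrow(comp) == 0) {
    stop(sprintf("unknown prescription id: '%s'", prescription), call. = FALSE)
  }
  if (any(is.na(comp$dose_g))) {
    stop(sprintf(
      "prescription '%s': missing dose for herb(s) %s",
      prescription, paste(comp$herb_id[is.na(comp$dose_g)], collapse = ", ")
    ), call. = FALSE)
  }
  hi <- kb$herb_ingredient[kb$herb_ingredient$herb_id %in% comp$herb_id, ,
    drop = FALSE
  ]
  hi <- hi[hi$ingredient_id %in% kb$ingredients$ingredient_id, , drop = FALSE]
  paths <- merge(hi, kb$ingredient_gene, by = "ingredient_id")
  if (nrow(paths) == 0) {
    return(stats::setNames(numeric(0), character(0)))
  }
  paths$dose <- comp$dose_g[match(paths$herb_id, comp$herb_id)]
  contrib <- paths$dose * paths$evidence_score
  scores <- tapply(contrib, paths$gene_id, sum)
  stats::setNames(as.numeric(scores), names(scores))
}

#' Rank genes by descending composite score
#'
#' @param scores non-empty named numeric vector (gene id -> score >= 0).
#' @return a `ranked_gene_list` data.frame (`gene_id`, `score`) ordered
#'   by descending score, ties broken lexicographically by gene id so
#'   the ranking is deterministic.
#' @export
rank_genes <- function(scores) {
  if (length(scores) == 0) {
    stop("rank_genes: empty score mapping", call. = FALSE)
  }
  if (is.null(names(scores)) || any(names(scores) == "") || anyDuplicated(names(scores))) {
    stop("rank_genes: scores must be uniquely named by gene id", call. = FALSE)
  }
  ord <- order(-scores, names(scores))
  structure(
    data.frame(
      gene_id = names(scores)[ord],
      score = unname(scores[ord]),
      stringsAsFactors = FALSE
    ),
    class = c("ranked_gene_list", "data.frame")
  )
}

#' Running-sum enrichment score (positive mode)
#'
#' Walks the ranked list top to bottom. At a gene belonging to the set
#' (a hit), the running sum increases by `|score|^exponent` normalized by
#' the total hit weight; at a miss it decreases by `1/(L - |S|)`. The
#' enrichment score is the maximum of the running sum, floored at 0
#' (positive mode), and the leading edge ("core enrichment" genes) is
#' the hits at or before the position of that maximum. When the running
#' sum never rises above 0, ES = 0 and the leading edge is empty.
#'
#' @param ranked a `ranked_gene_list`.
#' @param gene_set character vector of gene ids.
#' @param weight_exponent score weighting exponent (default 1).
#' @return list with `es` in `[0, 1]`, `running_sum` (length-L numeric),
#'   `leading_edge` (character, ordered as in the ranked list) and
#'   `hits` (logical length L).
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  stopifnot(inherits(ranked, "ranked_gene_list"))
  L <- nrow(ranked)
  hits <- ranked$gene_id %in% gene_set
  k <- sum(hits)
  if (k == 0) {
    stop("enrichment_score: gene set does not intersect the ranked universe",
      call. = FALSE
    )
  }
  if (k == L) {
    stop("enrichment_score: gene set covers the whole ranked universe",
      call. = FALSE
    )
  }
  w <- abs(ranked$score)^weight_exponent
  hit_w <- w * hits
  total <- sum(hit_w)
  if (total == 0) {
    hit_w <- as.numeric(hits) # all-zero scores: fall back to equal hit weights
    total <- k
  }
  step <- hit_w / total
  step[!hits] <- -1 / (L - k)
  running <- cumsum(step)
  peak <- max(running)
  if (peak <= 1e-12) { # guards against float dust when the true peak is 0
    return(list(
      es = 0, running_sum = running,
      leading_edge = character(0), hits = hits
    ))
  }
  pos <- which.max(running)
  list(
    es = peak,
    running_sum = running,
    leading_edge = ranked$gene_id[seq_len(pos)][hits[seq_len(pos)]],
    hits = hits
  )
}

# ES from sorted hit positions only; O(k) per evaluation, used for the
# permutation null. The positive running-sum maximum is always attained
# at a hit position.
es_from_positions <- function(pos, w, L) {
  k <- length(pos)
  hw <- w[pos]
  total <- sum(hw)
  if (total == 0) {
    hw <- rep(1, k)
    total <- k
  }
  cum_hit <- cumsum(hw) / total
  miss_before <- (pos - seq_len(k)) / (L - k)
  peak <- max(cum_hit - miss_before)
  if (peak <= 1e-12) 0 else peak
}

#' Pre-ranked gene-set enrichment analysis
#'
#' For every gene set whose effective size (intersection with the ranked
#' universe) lies in `[min_size, max_size]`, computes the observed
#' running-sum enrichment score, a gene-label permutation null
#' (`n_perm` random same-size subsets of the ranked universe), the
#' empirical p-value `(C + 1)/(n_perm + 1)` with ties counted, the
#' normalized score NES = ES / mean(positive null ES), and BH q-values
#' across all retained sets. Sets outside the size window are recorded
#' as skipped. Seeded and fully reproducible.
#'
#' @param ranked a `ranked_gene_list`.
#' @param collection a `herbnet_gene_sets`.
#' @param config a [gsea_config()].
#' @return a `herbnet_gsea` data.frame with columns set_id, size, es,
#'   nes, p_value, q_value, enriched and leading_edge (list column);
#'   skipped sets in attribute `skipped`.
#' @export
gsea_preranked <- function(ranked, collection, config = gsea_config()) {
  stopifnot(
    inherits(ranked, "ranked_gene_list"),
    inherits(collection, "herbnet_gene_sets")
  )
  L <- nrow(ranked)
  universe <- ranked$gene_id
  w <- abs(ranked$score)^config$weight_exponent

  eff_sizes <- vapply(collection$sets, function(s) sum(universe %in% s), integer(1))
  retain <- eff_sizes >= config$min_size & eff_sizes <= config$max_size & eff_sizes < L
  skipped <- data.frame(
    set_id = names(collection$sets)[!retain],
    size = eff_sizes[!retain],
    reason = ifelse(eff_sizes[!retain] < config$min_size, "below min_size",
      ifelse(eff_sizes[!retain] >= L, "covers universe", "above max_size")
    ),
    stringsAsFactors = FALSE
  )
  ids <- names(collection$sets)[retain]
  if (length(ids) == 0) {
    warning("gsea_preranked: no gene set within the size window", call. = FALSE)
    empty <- data.frame(
      set_id = character(0), size = integer(0), es = numeric(0),
      nes = numeric(0), p_value = numeric(0), q_value = numeric(0),
      enriched = logical(0), stringsAsFactors = FALSE
    )
    empty$leading_edge <- list()
    return(structure(empty,
      skipped = skipped,
      class = c("herbnet_gsea", "data.frame")
    ))
  }

  rows <- vector("list", length(ids))
  ledges <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    id <- ids[j]
    obs <- enrichment_score(ranked, collection$sets[[id]], config$weight_exponent)
    k <- sum(obs$hits)
    set.seed(derive_seed(config$seed, "gsea", id))
    null_es <- numeric(config$n_perm)
    for (b in seq_len(config$n_perm)) {
      pos <- sort.int(sample.int(L, k, replace = FALSE))
      null_es[b] <- es_from_positions(pos, w, L)
    }
    C <- sum(null_es >= obs$es)
    p <- (C + 1) / (config$n_perm + 1)
    pos_null <- null_es[null_es > 0]
    nes <- if (length(pos_null) > 0) obs$es / mean(pos_null) else NA_real_
    rows[[j]] <- data.frame(
      set_id = id, size = k, es = obs$es, nes = nes,
      p_value = p, stringsAsFactors = FALSE
    )
    ledges[[j]] <- obs$leading_edge
  }
  res <- do.call(rbind, rows)
  res$q_value <- bh_adjust(res$p_value)
  res$enriched <- res$p_value < config$p_cutoff
  res$leading_edge <- ledges
  rownames(res) <- NULL
  structure(res, skipped = skipped, class = c("herbnet_gsea", "data.frame"))
}

#' @export
print.herbnet_gsea <- function(x, ...) {
  df <- as.data.frame(x)
  df$leading_edge <- vapply(df$leading_edge, function(le) {
    sprintf("%d gene(s)", length(le))
  }, character(1))
  print.data.frame(df, digits = 4, ...)
  sk <- attr(x, "skipped")
  if (!is.null(sk) && nrow(sk) > 0) {
    cat(sprintf("(%d set(s) skipped by the size filter)\n", nrow(sk)))
  }
  invisible(x)
}

#' Intersection of leading-edge genes across prescriptions
#'
#' Cross-analyzes the core enrichment genes of ONE shared gene set over
#' several prescriptions: the genes credited with driving the set's
#' enrichment in every prescription.
#'
#' @param results named list (prescription id -> `herbnet_gsea`).
#' @param set_id the shared gene-set id; must be present (not skipped)
#'   in every result.
#' @return character vector of common genes, with per-prescription
#'   leading-edge sizes attached as attribute `sizes`.
#' @export
leading_edge_intersection <- function(results, set_id) {
  stopifnot(length(results) >= 1)
  edges <- lapply(names(results) %||% seq_along(results), function(nm) {
    r <- results[[nm]]
    stopifnot(inherits(r, "herbnet_gsea"))
    i <- match(set_id, r$set_id)
    if (is.na(i)) {
      stop(sprintf(
        "leading_edge_intersection: set '%s' absent from result '%s'",
        set_id, nm
      ), call. = FALSE)
    }
    r$leading_edge[[i]]
  })
  common <- Reduce(intersect, edges)
  structure(sort(common), sizes = lengths(edges))
}

#' @export
write_outputs.ranked_gene_list <- function(x, directory, name = "ranked_list", ...) {
  f <- paste0(name, ".tsv")
  write_tsv(as.data.frame(x), file.path(directory, f))
  manifest_entry(f, nrow(x))
}

#' @export
write_outputs.herbnet_gsea <- function(x, directory, name = "gsea_results", ...) {
  df <- as.data.frame(x)
  df$leading_edge <- vapply(df$leading_edge, paste, character(1), collapse = ";")
  f <- paste0(name, ".tsv")
  write_tsv(df, file.path(directory, f))
  manifest_entry(f, nrow(df))
}
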