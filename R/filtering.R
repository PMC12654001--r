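#' Filtering configuration
#'
#' Parameters of the two-step knowledge-base refinement: the oral
#' bioavailability (OB) screen and Benjamini-Hochberg FDR control of
#' ingredient-gene association links.
#'
#' @param fdr_alpha FDR threshold; links are retained when the adjusted
#'   q-value is strictly below it. Default 0.05.
#' @param ob_numeric_cutoff optional numeric OB cutoff (percent scale).
#'   The default (`NULL`) screens on presence/absence of the score only:
#'   ingredients lacking an OB score are excluded, no numeric threshold
#'   is applied.
#' @param bh_scope scope of the BH adjustment; only `"global"` (one pass
#'   over all ingredient-gene links in the knowledge base, before any
#'   prescription-specific assembly) is implemented.
#' @return a `filter_config` list.
#' @export
filter_config <- function(fdr_alpha = 0.05, ob_numeric_cutoff = NULL,
                          bh_scope = "global") {
  stopifnot(
    is.numeric(fdr_alpha), length(fdr_alpha) == 1,
    fdr_alpha > 0, fdr_alpha < 1
  )
  bh_scope <- match.arg(bh_scope, "global")
  if (!is.null(ob_numeric_cutoff)) {
    stopifnot(is.numeric(ob_numeric_cutoff), length(ob_numeric_cutoff) == 1)
  }
  structure(
    list(
      fdr_alpha = fdr_alpha,
      ob_numeric_cutoff = ob_numeric_cutoff,
      bh_scope = bh_scope
    ),
    class = "filter_config"
  )
}

#' Oral-bioavailability screening
#'
#' Biological-relevance screen: ingredients lacking an OB score are
#' excluded (with an optional numeric cutoff on top, off by default).
#' Herb-ingredient memberships and ingredient-gene links incident to
#' removed ingredients are dropped. Counts of removed items are reported
#' as a message.
#'
#' @param kb a `herbnet_kb`.
#' @param config a [filter_config()].
#' @return a new, screened `herbnet_kb` (possibly with empty layers).
#' @export
screen_oral_bioavailability <- function(kb, config = filter_config()) {
  stopifnot(inherits(kb, "herbnet_kb"))
  ing <- kb$ingredients
  keep <- !is.na(ing$ob_score)
  if (!is.null(config$ob_numeric_cutoff)) {
    keep <- keep & ing$ob_score >= config$ob_numeric_cutoff
  }
  removed <- ing$ingredient_id[!keep]

  ing2 <- ing[keep, , drop = FALSE]
  hi2 <- kb$herb_ingredient[
    !(kb$herb_ingredient$ingredient_id %in% removed), ,
    drop = FALSE
  ]
  ig2 <- kb$ingredient_gene[
    !(kb$ingredient_gene$ingredient_id %in% removed), ,
    drop = FALSE
  ]
  message(sprintf(
    "OB screen: removed %d/%d ingredient(s), %d ingredient-gene link(s)",
    length(removed), nrow(ing), nrow(kb$ingredient_gene) - nrow(ig2)
  ))
  out <- kb
  out$ingredients <- `rownames<-`(ing2, NULL)
  out$herb_ingredient <- `rownames<-`(hi2, NULL)
  out$ingredient_gene <- `rownames<-`(ig2, NULL)
  out
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment: with m p-values sorted ascending,
#' `q_(i) = min(1, min_{j >= i} m * p_(j) / j)`, reported in the original
#' input order. Ties are handled by the sorted-position construction,
#' which is tie-safe. Backed by [stats::p.adjust()].
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`, non-empty.
#' @return numeric vector of q-values, aligned to the input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) {
    stop("bh_adjust: empty p-value vector", call. = FALSE)
  }
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("bh_adjust: p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' FDR filtering of ingredient-gene links
#'
#' Adjusts the raw association p-values of all ingredient-gene links in
#' one global BH pass and retains only links with q strictly below
#' `fdr_alpha`. Genes left with no inbound link are removed together with
#' their gene-disease pairs. The disease universe is deliberately NOT
#' shrunk: it remains the sampling population of the permutation null
#' model regardless of which links survive.
#'
#' @param kb an OB-screened `herbnet_kb`.
#' @param config a [filter_config()].
#' @return a new `herbnet_kb` whose surviving links carry their `q_value`.
#' @export
filter_ingredient_gene_links <- function(kb, config = filter_config()) {
  stopifnot(inherits(kb, "herbnet_kb"))
  ig <- kb$ingredient_gene
  out <- kb
  if (nrow(ig) == 0) {
    message("FDR filter: no links to test")
    return(out)
  }
  q <- ifelse(is.na(ig$q_value), NA_real_, ig$q_value)
  # recompute unless every link already carries a q (idempotent re-run)
  if (any(is.na(q))) {
    q <- bh_adjust(ig$p_value)
  }
  keep <- q < config$fdr_alpha
  ig2 <- ig[keep, , drop = FALSE]
  ig2$q_value <- q[keep]

  surviving_genes <- unique(ig2$gene_id)
  gd2 <- kb$gene_disease[kb$gene_disease$gene_id %in% surviving_genes, , drop = FALSE]
  message(sprintf(
    "FDR filter (BH, q < %g): retained %d/%d link(s), %d gene(s), %d gene-disease pair(s)",
    config$fdr_alpha, nrow(ig2), nrow(ig), length(surviving_genes), nrow(gd2)
  ))
  out$ingredient_gene <- `rownames<-`(ig2, NULL)
  out$gene_disease <- `rownames<-`(gd2, NULL)
  out
}

#' Two-step knowledge-base refinement
#'
#' Convenience wrapper: [screen_oral_bioavailability()] then
#' [filter_ingredient_gene_links()], the sequential protocol applied
#' before any network is assembled.
#'
#' @inheritParams filter_ingredient_gene_links
#' @return a filtered `herbnet_kb`.
#' @export
apply_filters <- function(kb, config = filter_config()) {
  filter_ingredient_gene_links(
    screen_oral_bioavailability(kb, config),
    config
  )
}
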