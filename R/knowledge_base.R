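#' Construct a SymMap-style knowledge base
#'
#' The knowledge base holds the relational layers a prescription network is
#' assembled from: prescription compositions with herb doses in grams,
#' herb-to-ingredient membership, ingredient records with an optional oral
#' bioavailability (OB) score on the percent scale, ingredient-to-gene
#' association links carrying a raw p-value and a non-negative evidence
#' score, gene-to-disease links, and the disease universe used as the
#' sampling population of the permutation null model.
#'
#' Disease terms are normalized on construction (see [normalize_term()]);
#' the universe defaults to the unique terms appearing in `gene_disease`
#' and must always contain them. Duplicate (herb, ingredient) pairs are
#' merged idempotently; duplicate (ingredient, gene) links are an error
#' because their p-value would be ambiguous.
#'
#' @param prescriptions data.frame with columns `prescription_id`,
#'   `herb_id`, `dose_g` (positive grams).
#' @param herb_ingredient data.frame with columns `herb_id`, `ingredient_id`.
#' @param ingredients data.frame with columns `ingredient_id`, `ob_score`
#'   (`NA` marks an absent OB score).
#' @param ingredient_gene data.frame with columns `ingredient_id`,
#'   `gene_id`, `p_value` in `[0, 1]`, `evidence_score` `>= 0` and
#'   optionally `q_value` (filled in by [filter_ingredient_gene_links()]).
#' @param gene_disease data.frame with columns `gene_id`, `disease_term`.
#' @param disease_universe optional character vector of disease terms; must
#'   be a superset of the terms in `gene_disease`.
#' @param synonyms optional data.frame (`term`, `canonical`) applied to all
#'   disease terms after normalization.
#' @return an object of class `herbnet_kb`.
#' @seealso [read_knowledge_tables()] to load from TSV files.
#' @export
knowledge_base <- function(prescriptions, herb_ingredient, ingredients,
                           ingredient_gene, gene_disease,
                           disease_universe = NULL, synonyms = NULL) {
  prescriptions <- as.data.frame(prescriptions)
  herb_ingredient <- as.data.frame(herb_ingredient)
  ingredients <- as.data.frame(ingredients)
  ingredient_gene <- as.data.frame(ingredient_gene)
  gene_disease <- as.data.frame(gene_disease)

  require_columns(prescriptions, c("prescription_id", "herb_id", "dose_g"), "prescriptions")
  require_columns(herb_ingredient, c("herb_id", "ingredient_id"), "herb_ingredient")
  require_columns(ingredients, c("ingredient_id", "ob_score"), "ingredients")
  require_columns(
    ingredient_gene,
    c("ingredient_id", "gene_id", "p_value", "evidence_score"), "ingredient_gene"
  )
  require_columns(gene_disease, c("gene_id", "disease_term"), "gene_disease")

  for (col in c("prescription_id", "herb_id")) {
    prescriptions[[col]] <- as.character(prescriptions[[col]])
  }
  herb_ingredient$herb_id <- as.character(herb_ingredient$herb_id)
  herb_ingredient$ingredient_id <- as.character(herb_ingredient$ingredient_id)
  ingredients$ingredient_id <- as.character(ingredients$ingredient_id)
  ingredients$ob_score <- as.numeric(ingredients$ob_score)
  ingredient_gene$ingredient_id <- as.character(ingredient_gene$ingredient_id)
  ingredient_gene$gene_id <- as.character(ingredient_gene$gene_id)
  ingredient_gene$p_value <- as.numeric(ingredient_gene$p_value)
  ingredient_gene$evidence_score <- as.numeric(ingredient_gene$evidence_score)
  if (!"q_value" %in% names(ingredient_gene)) {
    ingredient_gene$q_value <- NA_real_
  }
  gene_disease$gene_id <- as.character(gene_disease$gene_id)
  gene_disease$disease_term <- apply_synonyms(
    normalize_term(gene_disease$disease_term), synonyms
  )

  # doses
  if (any(is.na(prescriptions$dose_g)) || any(prescriptions$dose_g <= 0)) {
    stop("prescriptions: all doses must be positive", call. = FALSE)
  }
  dup <- duplicated(prescriptions[c("prescription_id", "herb_id")])
  if (any(dup)) {
    stop("prescriptions: duplicate (prescription, herb) rows", call. = FALSE)
  }

  # herb-ingredient pairs merge idempotently
  herb_ingredient <- unique(herb_ingredient)

  # ingredient records: merge exact duplicates, reject conflicting OB
  ingredients <- unique(ingredients)
  if (anyDuplicated(ingredients$ingredient_id)) {
    stop("ingredients: conflicting records for the same ingredient_id", call. = FALSE)
  }

  # ingredient-gene links
  p <- ingredient_gene$p_value
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("ingredient_gene: p_value must lie in [0, 1]", call. = FALSE)
  }
  if (any(is.na(ingredient_gene$evidence_score)) || any(ingredient_gene$evidence_score < 0)) {
    stop("ingredient_gene: evidence_score must be >= 0", call. = FALSE)
  }
  if (anyDuplicated(ingredient_gene[c("ingredient_id", "gene_id")])) {
    stop("ingredient_gene: duplicate (ingredient, gene) link (ambiguous p-value)",
      call. = FALSE
    )
  }

  gene_disease <- unique(gene_disease)

  if (is.null(disease_universe)) {
    disease_universe <- sort(unique(gene_disease$disease_term))
  } else {
    disease_universe <- sort(unique(apply_synonyms(
      normalize_term(disease_universe), synonyms
    )))
    missing <- setdiff(gene_disease$disease_term, disease_universe)
    if (length(missing) > 0) {
      stop(sprintf(
        "disease_universe must contain every term in gene_disease (missing: %s...)",
        missing[1]
      ), call. = FALSE)
    }
  }

  # referential warnings: herbs with doses but no ingredient memberships
  orphan <- setdiff(unique(prescriptions$herb_id), unique(herb_ingredient$herb_id))
  if (length(orphan) > 0) {
    warning(sprintf(
      "%d herb(s) in prescriptions have no ingredient links (orphan): %s",
      length(orphan), paste(utils::head(orphan, 5), collapse = ", ")
    ), call. = FALSE)
  }

  structure(
    list(
      prescriptions = prescriptions,
      herb_ingredient = herb_ingredient,
      ingredients = ingredients,
      ingredient_gene = ingredient_gene,
      gene_disease = gene_disease,
      disease_universe = disease_universe
    ),
    orphan_herbs = orphan,
    class = "herbnet_kb"
  )
}

#' @export
print.herbnet_kb <- function(x, ...) {
  cat("SymMap-style knowledge base (herbnet_kb)\n")
  cat(sprintf("  prescriptions : %d\n", length(unique(x$prescriptions$prescription_id))))
  cat(sprintf("  herbs         : %d\n", length(unique(x$prescriptions$herb_id))))
  ob_absent <- sum(is.na(x$ingredients$ob_score))
  cat(sprintf(
    "  ingredients   : %d (%d without OB score)\n",
    nrow(x$ingredients), ob_absent
  ))
  nq <- sum(!is.na(x$ingredient_gene$q_value))
  cat(sprintf(
    "  ingredient-gene links: %d%s\n", nrow(x$ingredient_gene),
    if (nq > 0) sprintf(" (FDR q attached to %d)", nq) else ""
  ))
  cat(sprintf("  gene-disease pairs   : %d\n", nrow(x$gene_disease)))
  cat(sprintf("  disease universe     : %d terms\n", length(x$disease_universe)))
  invisible(x)
}

#' Prescription identifiers in a knowledge base
#' @param kb a `herbnet_kb`.
#' @return character vector of prescription ids, sorted.
#' @export
prescription_ids <- function(kb) {
  stopifnot(inherits(kb, "herbnet_kb"))
  sort(unique(kb$prescriptions$prescription_id))
}
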