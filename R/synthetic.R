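#' Parameters of the synthetic knowledge-base generator
#'
#' The generator emulates the statistical structure of a SymMap-style
#' knowledge base: sparse bipartite layers, a share of ingredients
#' lacking an OB score, ingredient-gene raw p-values drawn from a
#' null/signal mixture, and gold-standard lists with a controllable
#' planted-overlap fraction. Defaults are a desk-scale preset (3
#' prescriptions of 4 herbs, 10 ingredients per herb, 500 genes, a
#' 2000-term disease universe) on which permutation validation with
#' N = 10000 runs in seconds.
#'
#' Signal p-values are Beta(a, 1) with a < 1 so the BH survival rate is
#' analytically tunable; null p-values are Uniform(0, 1).
#'
#' @param n_prescriptions number of prescriptions.
#' @param herbs_per_prescription herbs per prescription (disjoint pools).
#' @param ingredients_per_herb ingredients per herb.
#' @param n_genes size of the gene pool.
#' @param n_diseases size of the disease universe U.
#' @param ob_missing_fraction share of ingredients with an absent OB score.
#' @param ingredient_gene_density Bernoulli link density ingredient -> gene.
#' @param gene_disease_density Bernoulli link density gene -> disease.
#' @param signal_fraction mixture weight pi of signal links.
#' @param signal_beta_a Beta(a, 1) shape of signal p-values, a in (0, 1].
#' @param dose_range herb dose range in grams.
#' @param evidence_range evidence-score range of ingredient-gene links.
#' @param gold_sizes named integer vector of gold-list sizes per category
#'   (names among primary/secondary/all).
#' @param planted_overlap fraction of each prescription's gold terms
#'   guaranteed inside its predicted disease set; scalar or one value
#'   per prescription.
#' @param planted_core_size size of a shared high-scoring core gene set
#'   planted into every prescription (0 disables planting).
#' @param core_evidence evidence score of planted core links.
#' @param n_null_sets number of random gene sets emitted by
#'   [generate_gene_sets()].
#' @param null_set_sizes sizes of the random gene sets (values below the
#'   GSEA minimum exercise the size filter).
#' @param seed master seed; every table draws from its own derived
#'   sub-stream.
#' @return a `synth_params` list.
#' @export
synth_params <- function(n_prescriptions = 3,
                         herbs_per_prescription = 4,
                         ingredients_per_herb = 10,
                         n_genes = 500,
                         n_diseases = 2000,
                         ob_missing_fraction = 0.2,
                         ingredient_gene_density = 0.02,
                         gene_disease_density = 0.002,
                         signal_fraction = 0.2,
                         signal_beta_a = 0.1,
                         dose_range = c(2, 12),
                         evidence_range = c(0.1, 1),
                         gold_sizes = c(primary = 5, secondary = 3, all = 8),
                         planted_overlap = 0.8,
                         planted_core_size = 0,
                         core_evidence = 20,
                         n_null_sets = 8,
                         null_set_sizes = c(5, 12, 20, 30, 45),
                         seed = 1) {
  stopifnot(
    n_prescriptions >= 1, herbs_per_prescription >= 1,
    ingredients_per_herb >= 1, n_genes >= 1, n_diseases >= 1,
    ob_missing_fraction >= 0, ob_missing_fraction <= 1,
    ingredient_gene_density >= 0, ingredient_gene_density <= 1,
    gene_disease_density >= 0, gene_disease_density <= 1,
    signal_fraction >= 0, signal_fraction <= 1,
    signal_beta_a > 0, signal_beta_a <= 1,
    length(dose_range) == 2, dose_range[1] > 0, dose_range[1] <= dose_range[2],
    all(planted_overlap >= 0), all(planted_overlap <= 1),
    length(planted_overlap) %in% c(1, n_prescriptions),
    planted_core_size >= 0, planted_core_size <= n_genes
  )
  if (is.null(names(gold_sizes)) ||
    !all(names(gold_sizes) %in% c("primary", "secondary", "all"))) {
    stop("gold_sizes must be named with categories primary/secondary/all",
      call. = FALSE
    )
  }
  structure(as.list(environment()), class = "synth_params")
}

pad_id <- function(prefix, i, n) {
  sprintf("%s%0*d", prefix, max(4, nchar(n)), i)
}

#' Generate a synthetic SymMap-style knowledge base with ground truth
#'
#' Emits a fully valid [knowledge_base()] plus the ground truth needed to
#' test every downstream stage: which ingredient-gene links are signal,
#' which survive the OB screen and global BH filter at q < 0.05, each
#' prescription's true predicted disease set and composite gene scores
#' (re-derivable by running the pipeline), and the planted core genes.
#' Fixed seed gives byte-identical tables on re-generation.
#'
#' @param params a [synth_params()].
#' @return list with elements `kb` (a `herbnet_kb`) and `truth` (class
#'   `synth_truth`: `signal`, `surviving`, `predicted`, `scores`,
#'   `core_genes`).
#' @export
generate_knowledge_base <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  P <- params$n_prescriptions
  n_herbs <- P * params$herbs_per_prescription
  n_ing <- n_herbs * params$ingredients_per_herb

  presc_ids <- pad_id("presc", seq_len(P), P)
  herb_ids <- pad_id("herb", seq_len(n_herbs), n_herbs)
  ing_ids <- pad_id("ingr", seq_len(n_ing), n_ing)
  gene_ids <- pad_id("gene", seq_len(params$n_genes), params$n_genes)
  disease_ids <- pad_id("disease", seq_len(params$n_diseases), params$n_diseases)

  herb_of <- rep(presc_ids, each = params$herbs_per_prescription)
  ing_of_herb <- rep(herb_ids, each = params$ingredients_per_herb)

  set.seed(derive_seed(params$seed, "synth", "doses"))
  prescriptions <- data.frame(
    prescription_id = herb_of,
    herb_id = herb_ids,
    dose_g = round(stats::runif(n_herbs, params$dose_range[1], params$dose_range[2]), 1),
    stringsAsFactors = FALSE
  )
  herb_ingredient <- data.frame(
    herb_id = ing_of_herb, ingredient_id = ing_ids,
    stringsAsFactors = FALSE
  )

  set.seed(derive_seed(params$seed, "synth", "ob"))
  ob <- round(stats::runif(n_ing, 1, 100), 2)
  ob[stats::runif(n_ing) < params$ob_missing_fraction] <- NA_real_
  ingredients <- data.frame(
    ingredient_id = ing_ids, ob_score = ob,
    stringsAsFactors = FALSE
  )

  set.seed(derive_seed(params$seed, "synth", "ingredient_gene"))
  links <- list()
  for (i in seq_len(n_ing)) {
    n_links <- stats::rbinom(1, params$n_genes, params$ingredient_gene_density)
    if (n_links == 0) next
    g <- sort(sample.int(params$n_genes, n_links))
    links[[length(links) + 1]] <- data.frame(
      ingredient_id = ing_ids[i], gene_id = gene_ids[g],
      stringsAsFactors = FALSE
    )
  }
  ig <- do.call(rbind, links)
  n_link <- nrow(ig)
  signal <- stats::runif(n_link) < params$signal_fraction
  p <- stats::runif(n_link)
  if (any(signal)) {
    p[signal] <- stats::rbeta(sum(signal), params$signal_beta_a, 1)
  }
  ig$p_value <- p
  ig$evidence_score <- round(
    stats::runif(n_link, params$evidence_range[1], params$evidence_range[2]), 3
  )
  ig$signal <- signal

  core_genes <- character(0)
  if (params$planted_core_size > 0) {
    set.seed(derive_seed(params$seed, "synth", "core"))
    core_genes <- sort(sample(gene_ids, params$planted_core_size))
    extra <- list()
    for (pi in seq_len(P)) {
      presc_ing <- ing_ids[herb_of[match(ing_of_herb, herb_ids)] == presc_ids[pi]]
      presc_ing <- presc_ing[!is.na(ob[match(presc_ing, ing_ids)])]
      if (length(presc_ing) == 0) {
        stop(sprintf(
          "cannot plant core genes: prescription '%s' has no OB-scored ingredient",
          presc_ids[pi]
        ), call. = FALSE)
      }
      host <- sample(presc_ing, length(core_genes), replace = TRUE)
      extra[[pi]] <- data.frame(
        ingredient_id = host, gene_id = core_genes,
        p_value = 1e-12, evidence_score = params$core_evidence,
        signal = TRUE, stringsAsFactors = FALSE
      )
    }
    extra <- unique(do.call(rbind, extra))
    # planted links replace any pre-existing link for the same pair
    key <- function(d) paste(d$ingredient_id, d$gene_id)
    ig <- ig[!(key(ig) %in% key(extra)), , drop = FALSE]
    ig <- rbind(ig, extra)
  }
  rownames(ig) <- NULL

  set.seed(derive_seed(params$seed, "synth", "gene_disease"))
  gd <- list()
  for (g in seq_len(params$n_genes)) {
    n_dis <- stats::rbinom(1, params$n_diseases, params$gene_disease_density)
    if (n_dis == 0) next
    d <- sort(sample.int(params$n_diseases, n_dis))
    gd[[length(gd) + 1]] <- data.frame(
      gene_id = gene_ids[g], disease_term = disease_ids[d],
      stringsAsFactors = FALSE
    )
  }
  gene_disease <- do.call(rbind, gd)

  kb <- knowledge_base(
    prescriptions, herb_ingredient, ingredients,
    ig[c("ingredient_id", "gene_id", "p_value", "evidence_score")],
    gene_disease,
    disease_universe = disease_ids
  )

  # --- ground truth, derived by direct set algebra on the tables above ---
  ob_present <- ing_ids[!is.na(ob)]
  # the pipeline screens OB first, then adjusts the remaining links: mirror it
  screened <- ig$ingredient_id %in% ob_present
  q_screened <- rep(NA_real_, nrow(ig))
  q_screened[screened] <- stats::p.adjust(ig$p_value[screened], method = "BH")
  surviving <- screened & !is.na(q_screened) & q_screened < 0.05

  predicted <- list()
  scores <- list()
  for (pi in seq_len(P)) {
    herbs_p <- herb_ids[herb_of == presc_ids[pi]]
    ing_p <- ing_ids[ing_of_herb %in% herbs_p]
    ing_p <- intersect(ing_p, ob_present)
    rows <- surviving & ig$ingredient_id %in% ing_p
    genes_p <- unique(ig$gene_id[rows])
    predicted[[presc_ids[pi]]] <- sort(unique(
      gene_disease$disease_term[gene_disease$gene_id %in% genes_p]
    ))
    dose <- prescriptions$dose_g[match(
      ing_of_herb[match(ig$ingredient_id[rows], ing_ids)], herb_ids
    )]
    sc <- tapply(dose * ig$evidence_score[rows], ig$gene_id[rows], sum)
    scores[[presc_ids[pi]]] <- stats::setNames(as.numeric(sc), names(sc))
  }

  truth <- structure(
    list(
      signal = ig$signal,
      surviving = surviving,
      predicted = predicted,
      scores = scores,
      core_genes = core_genes
    ),
    class = "synth_truth"
  )
  list(kb = kb, truth = truth)
}

#' Generate a gold standard with planted overlap
#'
#' For every prescription and category, draws a gold list of the
#' configured size such that exactly `round(planted_overlap * n)` terms
#' lie inside the prescription's true predicted disease set and the
#' remainder is drawn from the universe outside it.
#'
#' @param kb the generated `herbnet_kb`.
#' @param truth the matching `synth_truth`.
#' @param params the [synth_params()] used for generation.
#' @return a `herbnet_gold`; per-term planted flags are attached as
#'   attribute `planted` (a data.frame).
#' @export
generate_gold_standard <- function(kb, truth, params) {
  stopifnot(inherits(kb, "herbnet_kb"), inherits(truth, "synth_truth"))
  presc <- names(truth$predicted)
  po <- rep(params$planted_overlap, length.out = length(presc))
  rows <- list()
  for (pi in seq_along(presc)) {
    pred <- truth$predicted[[presc[pi]]]
    outside <- setdiff(kb$disease_universe, pred)
    for (cat in names(params$gold_sizes)) {
      n <- as.integer(params$gold_sizes[[cat]])
      if (n > length(kb$disease_universe)) {
        stop(sprintf("gold size %d exceeds the disease universe", n), call. = FALSE)
      }
      k_in <- round(po[pi] * n)
      if (k_in > length(pred)) {
        stop(sprintf(
          "prescription '%s': cannot plant %d term(s) in a predicted set of %d",
          presc[pi], k_in, length(pred)
        ), call. = FALSE)
      }
      if (n - k_in > length(outside)) {
        stop(sprintf(
          "prescription '%s': universe too small outside the predicted set",
          presc[pi]
        ), call. = FALSE)
      }
      set.seed(derive_seed(params$seed, "gold", presc[pi], cat))
      terms <- c(
        if (k_in > 0) sample(pred, k_in) else character(0),
        if (n - k_in > 0) sample(outside, n - k_in) else character(0)
      )
      rows[[length(rows) + 1]] <- data.frame(
        prescription_id = presc[pi], category = cat, disease_term = terms,
        planted = rep(c(TRUE, FALSE), c(k_in, n - k_in)),
        stringsAsFactors = FALSE
      )
    }
  }
  df <- do.call(rbind, rows)
  gold <- gold_standard(df[c("prescription_id", "category", "disease_term")])
  attr(gold, "planted") <- df
  gold
}

#' Generate a gene-set collection with planted enrichment
#'
#' Emits a mix of random ("null") sets drawn uniformly from the scored
#' gene universe, one planted set per prescription enriched among that
#' prescription's top-scoring genes, and — when core genes were planted
#' in the knowledge base — one shared `core_pathway` set containing the
#' core genes of every prescription (the substrate for leading-edge
#' intersection analyses). Null-set sizes include values below the GSEA
#' minimum to exercise the size filter.
#'
#' @inheritParams generate_gold_standard
#' @return a `herbnet_gene_sets`.
#' @export
generate_gene_sets <- function(kb, truth, params) {
  stopifnot(inherits(truth, "synth_truth"))
  scored <- sort(unique(unlist(lapply(truth$scores, names), use.names = FALSE)))
  if (length(scored) == 0) {
    stop("no scored genes: nothing to build gene sets from", call. = FALSE)
  }
  sets <- list()
  desc <- character(0)

  set.seed(derive_seed(params$seed, "gmt", "null"))
  sizes <- rep(params$null_set_sizes, length.out = params$n_null_sets)
  for (j in seq_len(params$n_null_sets)) {
    sz <- sizes[j]
    if (sz > length(scored)) {
      stop(sprintf(
        "requested null set size %d exceeds the %d scored genes",
        sz, length(scored)
      ), call. = FALSE)
    }
    id <- sprintf("null_set_%02d", j)
    sets[[id]] <- sort(sample(scored, sz))
    desc <- c(desc, "random gene set")
  }

  for (p in names(truth$scores)) {
    sc <- truth$scores[[p]]
    if (length(sc) == 0) next
    top <- names(sort(sc, decreasing = TRUE))
    n_top <- max(1, ceiling(0.25 * length(top)))
    size <- min(max(10, n_top + 5), length(scored))
    set.seed(derive_seed(params$seed, "gmt", "planted", p))
    members <- unique(c(
      utils::head(top, n_top),
      sample(scored, max(0, size - n_top))
    ))
    id <- paste0("planted_", p)
    sets[[id]] <- sort(members)
    desc <- c(desc, sprintf("enriched among top-scored genes of %s", p))
  }

  if (length(truth$core_genes) > 0) {
    set.seed(derive_seed(params$seed, "gmt", "core"))
    pad <- setdiff(scored, truth$core_genes)
    n_pad <- min(12, length(pad))
    sets[["core_pathway"]] <- sort(unique(c(
      truth$core_genes,
      if (n_pad > 0) sample(pad, n_pad) else character(0)
    )))
    desc <- c(desc, "shared planted core gene set")
  }

  gene_set_collection(sets, descriptions = desc)
}

#' Generate a complete synthetic study
#'
#' Convenience bundle: knowledge base + ground truth, gold standard and
#' gene-set collection from one parameter set.
#'
#' @param params a [synth_params()].
#' @return list with `kb`, `truth`, `gold`, `gene_sets`, `params`.
#' @export
generate_study <- function(params = synth_params()) {
  gen <- generate_knowledge_base(params)
  gold <- generate_gold_standard(gen$kb, gen$truth, params)
  gene_sets <- generate_gene_sets(gen$kb, gen$truth, params)
  list(
    kb = gen$kb, truth = gen$truth, gold = gold,
    gene_sets = gene_sets, params = params
  )
}
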