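#' Visualization selection rule configuration
#'
#' The structural backbone shown in figures is the top fraction of nodes
#' per layer ranked by betweenness centrality: by default the top 1%,
#' reduced to the top 0.5% for any layer where the 1% selection would
#' exceed 50 nodes. The full network is always kept for analysis; the
#' selection is for display only.
#'
#' @param top_fraction primary per-layer fraction (default 0.01).
#' @param fallback_fraction reduced fraction used when the primary
#'   selection exceeds `cap` (default 0.005).
#' @param cap node-count trigger for the fallback (default 50).
#' @return a `viz_config` list.
#' @export
viz_config <- function(top_fraction = 0.01, fallback_fraction = 0.005, cap = 50) {
  stopifnot(
    fallback_fraction > 0, fallback_fraction <= top_fraction,
    top_fraction < 1, cap >= 1
  )
  structure(
    list(
      top_fraction = top_fraction,
      fallback_fraction = fallback_fraction,
      cap = as.integer(cap)
    ),
    class = "viz_config"
  )
}

layer_levels <- c("herb", "ingredient", "gene", "disease")

#' Assemble a prescription's four-layer therapeutic network
#'
#' Builds the directed herb -> ingredient -> gene -> disease graph for one
#' prescription from a filtered knowledge base: the prescription's herbs,
#' their surviving ingredients, genes reachable through surviving
#' ingredient-gene links, and the diseases linked to those genes. Dead-end
#' branches are pruned (genes with no disease link, then ingredients with
#' no remaining gene link), so every ingredient and gene node lies on at
#' least one root-to-disease path. The prescription root is implicit and
#' not exported as a node, keeping the four node classes aligned.
#'
#' @param kb a filtered `herbnet_kb` (see [apply_filters()]).
#' @param prescription prescription id present in `kb`.
#' @return an object of class `therapeutic_network` with elements
#'   `prescription_id`, `nodes` (id, layer), `edges` (from, to, from_layer,
#'   to_layer) and `predicted_diseases`.
#' @export
assemble_network <- function(kb, prescription) {
  stopifnot(inherits(kb, "herbnet_kb"))
  herbs <- kb$prescriptions$herb_id[kb$prescriptions$prescription_id == prescription]
  if (length(herbs) == 0) {
    stop(sprintf("unknown prescription id: '%s'", prescription), call. = FALSE)
  }
  herbs <- unique(herbs)

  hi <- kb$herb_ingredient[
    kb$herb_ingredient$herb_id %in% herbs &
      kb$herb_ingredient$ingredient_id %in% kb$ingredients$ingredient_id, ,
    drop = FALSE
  ]
  ig <- kb$ingredient_gene[
    kb$ingredient_gene$ingredient_id %in% hi$ingredient_id, ,
    drop = FALSE
  ]
  gd <- kb$gene_disease[kb$gene_disease$gene_id %in% ig$gene_id, , drop = FALSE]

  # prune dead ends: genes without diseases, then ingredients without genes
  ig <- ig[ig$gene_id %in% gd$gene_id, , drop = FALSE]
  hi <- hi[hi$ingredient_id %in% ig$ingredient_id, , drop = FALSE]

  layer_frame <- function(ids, layer) {
    data.frame(
      id = ids, layer = rep(layer, length(ids)),
      stringsAsFactors = FALSE
    )
  }
  nodes <- rbind(
    layer_frame(herbs, "herb"),
    layer_frame(sort(unique(hi$ingredient_id)), "ingredient"),
    layer_frame(sort(unique(ig$gene_id)), "gene"),
    layer_frame(sort(unique(gd$disease_term)), "disease")
  )
  if (anyDuplicated(nodes$id)) {
    stop("node identifiers collide across layers; disambiguate ids upstream",
      call. = FALSE
    )
  }
  edge_frame <- function(from, to, from_layer, to_layer) {
    data.frame(
      from = from, to = to,
      from_layer = rep(from_layer, length(from)),
      to_layer = rep(to_layer, length(from)),
      stringsAsFactors = FALSE
    )
  }
  edges <- rbind(
    edge_frame(hi$herb_id, hi$ingredient_id, "herb", "ingredient"),
    edge_frame(ig$ingredient_id, ig$gene_id, "ingredient", "gene"),
    edge_frame(gd$gene_id, gd$disease_term, "gene", "disease")
  )
  edges <- unique(edges)
  edges <- edges[order(edges$from_layer, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  predicted <- sort(unique(gd$disease_term))
  if (length(predicted) == 0) {
    warning(sprintf(
      "prescription '%s': empty predicted disease set (all branches filtered out)",
      prescription
    ), call. = FALSE)
  }
  structure(
    list(
      prescription_id = prescription,
      nodes = nodes,
      edges = edges,
      predicted_diseases = predicted
    ),
    class = "therapeutic_network"
  )
}

#' @export
print.therapeutic_network <- function(x, ...) {
  counts <- table(factor(x$nodes$layer, levels = layer_levels))
  cat(sprintf("Therapeutic network for prescription '%s'\n", x$prescription_id))
  cat(sprintf(
    "  nodes: %d herb | %d ingredient | %d gene | %d disease\n",
    counts["herb"], counts["ingredient"], counts["gene"], counts["disease"]
  ))
  cat(sprintf("  edges: %d\n", nrow(x$edges)))
  cat(sprintf("  predicted diseases: %d\n", length(x$predicted_diseases)))
  invisible(x)
}

#' Network-predicted disease set
#'
#' The predicted indication set of a prescription is all nodes of the
#' disease layer of its assembled network.
#'
#' @param network a `therapeutic_network`.
#' @return character vector of normalized disease terms.
#' @export
predicted_diseases <- function(network) {
  stopifnot(inherits(network, "therapeutic_network"))
  network$predicted_diseases
}

#' Convert a therapeutic network to an igraph object
#' @param network a `therapeutic_network`.
#' @return a directed [igraph::igraph] with vertex attribute `layer`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "therapeutic_network"))
  igraph::graph_from_data_frame(
    network$edges[c("from", "to")],
    directed = TRUE,
    vertices = network$nodes
  )
}

#' Betweenness centrality of every network node
#'
#' Exact betweenness on the directed layered graph: for each node, the
#' number of shortest directed paths between ordered node pairs passing
#' through it (unnormalized counts, fractional when shortest paths tie).
#'
#' @param network a `therapeutic_network`.
#' @return named numeric vector over all nodes (isolates score 0).
#' @export
betweenness_scores <- function(network) {
  g <- as_igraph(network)
  b <- igraph::betweenness(g, directed = TRUE, normalized = FALSE)
  b[network$nodes$id]
}

#' Per-layer visualization selection count
#'
#' Number of nodes selected from a layer of `layer_size` nodes:
#' `max(1, ceiling(top_fraction * layer_size))`, recomputed with
#' `fallback_fraction` whenever the primary count exceeds `cap`.
#'
#' @param layer_size integer vector of layer sizes.
#' @param config a [viz_config()].
#' @return integer vector of selection counts.
#' @export
visualization_count <- function(layer_size, config = viz_config()) {
  n1 <- pmax(1L, as.integer(ceiling(config$top_fraction * layer_size)))
  n2 <- pmax(1L, as.integer(ceiling(config$fallback_fraction * layer_size)))
  ifelse(n1 > config$cap, n2, n1)
}

#' Extract the betweenness-backbone visualization subnetwork
#'
#' Per layer, the top `visualization_count()` nodes by betweenness are
#' flagged (ties broken by betweenness descending then node id ascending,
#' so the selection is deterministic) and the induced subgraph is
#' returned. The full network is untouched: the reduction is applied
#' exclusively for display and never feeds any statistic.
#'
#' @param network a `therapeutic_network`.
#' @param config a [viz_config()].
#' @return list of class `herbnet_viz` with `subnetwork` (a
#'   `therapeutic_network` restricted to selected nodes) and `selection`
#'   (data.frame id, layer, betweenness, selected over all nodes).
#' @export
visualization_subset <- function(network, config = viz_config()) {
  stopifnot(inherits(network, "therapeutic_network"))
  b <- betweenness_scores(network)
  sel <- network$nodes
  sel$betweenness <- unname(b[sel$id])
  sel$selected <- FALSE
  for (layer in unique(sel$layer)) {
    idx <- which(sel$layer == layer)
    n <- visualization_count(length(idx), config)
    ord <- idx[order(-sel$betweenness[idx], sel$id[idx])]
    sel$selected[ord[seq_len(min(n, length(ord)))]] <- TRUE
  }
  keep <- sel$id[sel$selected]
  sub <- network
  sub$nodes <- `rownames<-`(network$nodes[network$nodes$id %in% keep, , drop = FALSE], NULL)
  sub$edges <- `rownames<-`(
    network$edges[network$edges$from %in% keep & network$edges$to %in% keep, ,
      drop = FALSE
    ], NULL
  )
  sub$predicted_diseases <- intersect(network$predicted_diseases, keep)
  structure(list(subnetwork = sub, selection = sel), class = "herbnet_viz")
}

#' Rank the most frequently represented predicted diseases
#'
#' Diseases of an assembled network ranked by support count, defined as
#' the in-degree of the disease node (number of distinct gene-to-disease
#' edges entering it); ties are broken lexicographically by term. When a
#' gold standard is supplied, each disease is annotated with the gold
#' categories (for this prescription) it belongs to.
#'
#' @param network a `therapeutic_network`.
#' @param k number of diseases to report (truncated to the available count).
#' @param gold optional `herbnet_gold`.
#' @return data.frame `disease_term`, `support`, `annotation`.
#' @export
top_k_diseases <- function(network, k = 20, gold = NULL) {
  stopifnot(inherits(network, "therapeutic_network"), k >= 1)
  gd <- network$edges[network$edges$from_layer == "gene", , drop = FALSE]
  if (nrow(gd) == 0) {
    return(data.frame(
      disease_term = character(0), support = integer(0),
      annotation = character(0), stringsAsFactors = FALSE
    ))
  }
  support <- table(gd$to)
  df <- data.frame(
    disease_term = names(support),
    support = as.integer(support),
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$support, df$disease_term), , drop = FALSE]
  df <- utils::head(df, k)
  df$annotation <- ""
  if (!is.null(gold)) {
    for (i in seq_len(nrow(df))) {
      cats <- gold$category[
        gold$prescription_id == network$prescription_id &
          gold$disease_term == df$disease_term[i]
      ]
      df$annotation[i] <- paste(intersect(c("primary", "secondary", "all"), cats),
        collapse = ","
      )
    }
  }
  rownames(df) <- NULL
  df
}

#' Summarize predicted disease counts across prescriptions
#'
#' @param networks list of `therapeutic_network` objects.
#' @return data.frame (`prescription_id`, `n_predicted`) with the
#'   arithmetic mean of the counts attached as attribute
#'   `mean_predicted`.
#' @export
network_summary <- function(networks) {
  stopifnot(length(networks) >= 1)
  df <- data.frame(
    prescription_id = vapply(networks, function(n) n$prescription_id, character(1)),
    n_predicted = vapply(networks, function(n) length(n$predicted_diseases), integer(1)),
    stringsAsFactors = FALSE
  )
  structure(df,
    mean_predicted = mean(df$n_predicted),
    class = c("herbnet_network_summary", "data.frame")
  )
}

#' @export
print.herbnet_network_summary <- function(x, ...) {
  print.data.frame(x, ...)
  cat(sprintf("mean predicted diseases: %.1f\n", attr(x, "mean_predicted")))
  invisible(x)
}

#' @export
write_outputs.therapeutic_network <- function(x, directory, name = NULL, ...) {
  stem <- name %||% paste0("network_", x$prescription_id)
  b <- betweenness_scores(x)
  g <- as_igraph(x)
  igraph::V(g)$betweenness <- unname(b[igraph::V(g)$name])

  graphml <- paste0(stem, ".graphml")
  igraph::write_graph(g, file.path(directory, graphml), format = "graphml")

  # SIF: source <tab> relation <tab> target, one edge per line
  sif <- paste0(stem, ".sif")
  rel <- paste0(x$edges$from_layer, "_", x$edges$to_layer)
  writeLines(paste(x$edges$from, rel, x$edges$to, sep = "\t"),
    file.path(directory, sif),
    useBytes = TRUE
  )

  attrs <- x$nodes
  attrs$betweenness <- unname(b[attrs$id])
  nodetsv <- paste0(stem, "_nodes.tsv")
  write_tsv(attrs, file.path(directory, nodetsv))

  rbind(
    manifest_entry(graphml, nrow(x$nodes)),
    manifest_entry(sif, nrow(x$edges)),
    manifest_entry(nodetsv, nrow(attrs))
  )
}

#' @export
write_outputs.herbnet_network_summary <- function(x, directory, ...) {
  write_tsv(as.data.frame(x), file.path(directory, "network_summary.tsv"))
  manifest_entry("network_summary.tsv", nrow(x))
}
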