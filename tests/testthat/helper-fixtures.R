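# Shared fixtures and independent brute-force oracles.

# Small knowledge base: 1 prescription, 2 herbs, 3 ingredients (one without
# an OB score), 4 genes, 5 diseases. p-values chosen so that the two
# smallest survive a global BH filter at 0.05.
tiny_kb <- function() {
  knowledge_base(
    prescriptions = data.frame(
      prescription_id = c("P1", "P1"),
      herb_id = c("HA", "HB"),
      dose_g = c(4, 2)
    ),
    herb_ingredient = data.frame(
      herb_id = c("HA", "HA", "HB"),
      ingredient_id = c("I1", "I2", "I3")
    ),
    ingredients = data.frame(
      ingredient_id = c("I1", "I2", "I3"),
      ob_score = c(30, NA, 55)
    ),
    ingredient_gene = data.frame(
      ingredient_id = c("I1", "I2", "I3", "I3"),
      gene_id = c("g1", "g2", "g1", "g3"),
      p_value = c(1e-5, 0.2, 2e-4, 0.9),
      evidence_score = c(0.5, 0.3, 1.0, 0.2)
    ),
    gene_disease = data.frame(
      gene_id = c("g1", "g1", "g2", "g3", "g4"),
      disease_term = c("colitis", "gastritis", "asthma", "dermatitis", "rhinitis")
    )
  )
}

write_kb_tables <- function(kb, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_outputs(kb, dir)
  tabs <- c(
    "prescriptions", "herb_ingredient", "ingredients",
    "ingredient_gene", "gene_disease"
  )
  stats::setNames(file.path(dir, paste0(tabs, ".tsv")), tabs)
}

# Hand-built therapeutic network (for closed-form betweenness cases).
make_network <- function(nodes, edges, prescription = "PX") {
  layer_of <- stats::setNames(nodes$layer, nodes$id)
  edges$from_layer <- unname(layer_of[edges$from])
  edges$to_layer <- unname(layer_of[edges$to])
  structure(
    list(
      prescription_id = prescription,
      nodes = nodes,
      edges = edges,
      predicted_diseases = sort(nodes$id[nodes$layer == "disease"])
    ),
    class = "therapeutic_network"
  )
}

random_layered_network <- function(sizes = c(3, 5, 6, 8), edge_prob = 0.4) {
  layers <- c("herb", "ingredient", "gene", "disease")
  ids <- lapply(seq_along(sizes), function(i) {
    paste0(substr(layers[i], 1, 1), seq_len(sizes[i]))
  })
  nodes <- data.frame(
    id = unlist(ids),
    layer = rep(layers, sizes),
    stringsAsFactors = FALSE
  )
  edges <- do.call(rbind, lapply(1:3, function(i) {
    grid <- expand.grid(from = ids[[i]], to = ids[[i + 1]], stringsAsFactors = FALSE)
    grid[runif(nrow(grid)) < edge_prob, , drop = FALSE]
  }))
  make_network(nodes, edges)
}

# Brute-force directed betweenness via all-pairs BFS path counting
# (independent of igraph's Brandes algorithm).
brute_betweenness <- function(network) {
  ids <- network$nodes$id
  n <- length(ids)
  adj <- lapply(ids, function(v) network$edges$to[network$edges$from == v])
  names(adj) <- ids
  dist <- matrix(Inf, n, n, dimnames = list(ids, ids))
  sigma <- matrix(0, n, n, dimnames = list(ids, ids))
  for (s in ids) {
    dist[s, s] <- 0
    sigma[s, s] <- 1
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      nxt <- character(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.infinite(dist[s, w])) {
            dist[s, w] <- d + 1
            nxt <- c(nxt, w)
          }
          if (dist[s, w] == d + 1) {
            sigma[s, w] <- sigma[s, w] + sigma[s, v]
          }
        }
      }
      frontier <- unique(nxt)
      d <- d + 1
    }
  }
  b <- stats::setNames(numeric(n), ids)
  for (v in ids) {
    for (s in ids) {
      for (t in ids) {
        if (s != v && t != v && s != t && is.finite(dist[s, t]) &&
          is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
          dist[s, v] + dist[v, t] == dist[s, t]) {
          b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  b
}

# Brute-force BH step-up: q_i = min(1, min over sorted ranks j >= rank(i)
# of m p_(j) / j), evaluated directly from the definition.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    ri <- which(ord == i)
    j <- ri:m
    q[i] <- min(1, m * p[ord[j]] / j)
  }
  q
}

# Brute-force positive-mode running-sum ES: explicit walk over the whole
# ranked list.
brute_es <- function(scores, hits, exponent = 1) {
  L <- length(scores)
  k <- sum(hits)
  w <- abs(scores)^exponent
  tot <- sum(w[hits])
  if (tot == 0) {
    w <- rep(1, L)
    tot <- k
  }
  run <- 0
  best <- 0
  best_at <- 0
  path <- numeric(L)
  for (i in seq_len(L)) {
    run <- if (hits[i]) run + w[i] / tot else run - 1 / (L - k)
    path[i] <- run
    if (run > best) {
      best <- run
      best_at <- i
    }
  }
  list(es = best, path = path, peak_at = best_at)
}
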