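test_that("network assembly builds the four layers and prunes dead ends", {
  kb <- knowledge_base(
    prescriptions = data.frame(prescription_id = "P1", herb_id = "H1", dose_g = 3),
    herb_ingredient = data.frame(herb_id = "H1", ingredient_id = "I1"),
    ingredients = data.frame(ingredient_id = "I1", ob_score = 30),
    ingredient_gene = data.frame(
      ingredient_id = "I1", gene_id = "g1", p_value = 1e-4, evidence_score = 1
    ),
    gene_disease = data.frame(
      gene_id = "g1", disease_term = c("d1", "d2")
    )
  )
  net <- assemble_network(suppressMessages(apply_filters(kb)), "P1")
  expect_equal(nrow(net$nodes), 5) # 1 herb + 1 ingredient + 1 gene + 2 diseases
  expect_setequal(predicted_diseases(net), c("d1", "d2"))
  expect_error(assemble_network(kb, "nope"), "unknown prescription")
})

test_that("a gene shared by two ingredients is a single node with in-degree 2", {
  kb <- knowledge_base(
    prescriptions = data.frame(prescription_id = "P1", herb_id = "H1", dose_g = 3),
    herb_ingredient = data.frame(
      herb_id = "H1", ingredient_id = c("I1", "I2")
    ),
    ingredients = data.frame(ingredient_id = c("I1", "I2"), ob_score = 30),
    ingredient_gene = data.frame(
      ingredient_id = c("I1", "I2"), gene_id = "g1",
      p_value = 1e-5, evidence_score = 1
    ),
    gene_disease = data.frame(gene_id = "g1", disease_term = "d1")
  )
  net <- assemble_network(suppressMessages(apply_filters(kb)), "P1")
  expect_equal(sum(net$nodes$layer == "gene"), 1)
  expect_equal(sum(net$edges$to == "g1"), 2)
})

test_that("a fully screened-out prescription yields an empty predicted set", {
  kb <- tiny_kb()
  kb$ingredients$ob_score <- NA_real_
  fkb <- suppressMessages(apply_filters(kb))
  expect_warning(net <- assemble_network(fkb, "P1"), "empty predicted")
  expect_length(predicted_diseases(net), 0)
})

test_that("assembled networks respect layer discipline and the universe", {
  gen <- suppressWarnings(generate_knowledge_base(synth_params(seed = 3)))
  fkb <- suppressMessages(apply_filters(gen$kb))
  allowed <- c(
    herb = "ingredient", ingredient = "gene", gene = "disease"
  )
  for (p in prescription_ids(fkb)) {
    net <- assemble_network(fkb, p)
    expect_true(all(net$edges$to_layer == allowed[net$edges$from_layer]))
    expect_true(all(predicted_diseases(net) %in% fkb$disease_universe))
    # no isolated ingredient or gene: each has an outgoing edge
    for (layer in c("ingredient", "gene")) {
      mid <- net$nodes$id[net$nodes$layer == layer]
      expect_true(all(mid %in% net$edges$from))
    }
  }
})

test_that("deleting a gene-disease pair never enlarges a predicted set", {
  gen <- suppressWarnings(generate_knowledge_base(synth_params(seed = 9)))
  fkb <- suppressMessages(apply_filters(gen$kb))
  p <- prescription_ids(fkb)[1]
  before <- predicted_diseases(assemble_network(fkb, p))
  set.seed(1)
  for (drop in sample(nrow(fkb$gene_disease), 5)) {
    kb2 <- fkb
    kb2$gene_disease <- kb2$gene_disease[-drop, ]
    after <- predicted_diseases(suppressWarnings(assemble_network(kb2, p)))
    expect_true(all(after %in% before))
  }
})

test_that("disease ranking uses gene in-degree with lexicographic tie-break", {
  nodes <- data.frame(
    id = c("h1", "i1", "g1", "g2", "g3", "dx", "dy", "dz"),
    layer = c("herb", "ingredient", rep("gene", 3), rep("disease", 3))
  )
  edges <- data.frame(
    from = c("h1", "i1", "i1", "i1", "g1", "g2", "g3", "g1", "g2", "g3"),
    to = c("i1", "g1", "g2", "g3", "dx", "dx", "dx", "dy", "dy", "dz")
  )
  net <- make_network(nodes, edges)
  top <- top_k_diseases(net, k = 2)
  expect_equal(top$disease_term, c("dx", "dy")) # 3 genes beat 2
  expect_equal(top$support, c(3L, 2L))

  # k larger than the disease count returns the full list
  expect_equal(nrow(top_k_diseases(net, k = 99)), 3)

  # tie at the cut: deterministic lexicographic order, identical on re-run
  edges2 <- rbind(edges, data.frame(from = "g1", to = "dz"))
  net2 <- make_network(nodes, edges2)
  t1 <- top_k_diseases(net2, k = 3)
  t2 <- top_k_diseases(net2, k = 3)
  expect_identical(t1, t2)
  expect_equal(t1$disease_term, c("dx", "dy", "dz")) # dy/dz tie broken by term

  # gold annotation flags category membership
  gold <- gold_standard(data.frame(
    prescription_id = "PX", category = c("primary", "all"),
    disease_term = c("dx", "dx")
  ))
  tg <- top_k_diseases(net, k = 1, gold = gold)
  expect_equal(tg$annotation, "primary,all")
})

test_that("betweenness matches closed forms and the brute-force oracle", {
  # chain herb -> ingredient -> gene: the middle node scores 1
  chain <- make_network(
    data.frame(id = c("a", "b", "c"), layer = c("herb", "ingredient", "gene")),
    data.frame(from = c("a", "b"), to = c("b", "c"))
  )
  b <- betweenness_scores(chain)
  expect_equal(unname(b[c("a", "b", "c")]), c(0, 1, 0))

  # star through a single ingredient: center mediates all herb-gene pairs
  star <- make_network(
    data.frame(
      id = c("h1", "h2", "h3", "m", "g1", "g2"),
      layer = c(rep("herb", 3), "ingredient", rep("gene", 2))
    ),
    data.frame(
      from = c("h1", "h2", "h3", "m", "m"),
      to = c("m", "m", "m", "g1", "g2")
    )
  )
  bs <- betweenness_scores(star)
  expect_equal(unname(bs["m"]), 3 * 2)
  expect_true(all(bs[setdiff(names(bs), "m")] == 0))

  # random layered graphs against the path-counting oracle
  set.seed(7)
  for (rep in 1:5) {
    net <- random_layered_network(sizes = c(3, 5, 6, 8), edge_prob = 0.4)
    expect_equal(
      betweenness_scores(net),
      brute_betweenness(net),
      tolerance = 1e-10
    )
  }
})

test_that("visualization selection obeys the 1%/0.5%/cap rule", {
  cfg <- viz_config()
  expect_equal(visualization_count(200, cfg), 2L) # ceil(2.0)
  expect_equal(visualization_count(6000, cfg), 30L) # 60 > 50 -> 0.5%
  expect_equal(visualization_count(1, cfg), 1L) # floor of one
  expect_equal(visualization_count(50, cfg), 1L)

  net <- random_layered_network(sizes = c(4, 20, 30, 120), edge_prob = 0.3)
  before <- net
  vs <- visualization_subset(net)
  # full network untouched
  expect_identical(net, before)
  # per-layer selected counts follow the rule
  sel <- vs$selection
  for (layer in unique(sel$layer)) {
    n_layer <- sum(sel$layer == layer)
    expect_equal(
      sum(sel$selected[sel$layer == layer]),
      visualization_count(n_layer, cfg)
    )
  }
  # induced subgraph: every edge endpoint is a selected node
  expect_true(all(vs$subnetwork$edges$from %in% vs$subnetwork$nodes$id))
  expect_true(all(vs$subnetwork$edges$to %in% vs$subnetwork$nodes$id))
  # selection is deterministic
  expect_identical(vs$selection, visualization_subset(net)$selection)
})

test_that("network summary reports per-prescription counts and their mean", {
  n1 <- make_network(
    data.frame(id = c("h", "i", "g", "d1", "d2"),
               layer = c("herb", "ingredient", "gene", "disease", "disease")),
    data.frame(from = c("h", "i", "g", "g"), to = c("i", "g", "d1", "d2")),
    prescription = "A"
  )
  n2 <- make_network(
    data.frame(id = c("h", "i", "g", "d1", "d2", "d3", "d4"),
               layer = c("herb", "ingredient", "gene", rep("disease", 4))),
    data.frame(
      from = c("h", "i", "g", "g", "g", "g"),
      to = c("i", "g", "d1", "d2", "d3", "d4")
    ),
    prescription = "B"
  )
  s <- network_summary(list(n1, n2))
  expect_equal(s$n_predicted, c(2L, 4L))
  expect_equal(attr(s, "mean_predicted"), 3.0)
  expect_equal(attr(network_summary(list(n1)), "mean_predicted"), 2.0)
})

test_that("network export writes GraphML, SIF and node attributes", {
  net <- random_layered_network(sizes = c(2, 3, 4, 5), edge_prob = 0.5)
  dir <- withr::local_tempdir()
  man <- write_outputs(net, dir)
  expect_true(all(file.exists(file.path(dir, man$file))))
  sif <- readLines(file.path(dir, grep("\\.sif$", man$file, value = TRUE)))
  expect_length(sif, nrow(net$edges))
  nodes <- utils::read.delim(file.path(dir, grep("nodes", man$file, value = TRUE)))
  expect_setequal(names(nodes), c("id", "layer", "betweenness"))
})
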