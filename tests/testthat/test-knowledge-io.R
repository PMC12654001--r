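test_that("knowledge tables load with strict validation", {
  kb <- tiny_kb()
  expect_s3_class(kb, "herbnet_kb")
  expect_length(kb$disease_universe, 5)
  expect_equal(sum(is.na(kb$ingredients$ob_score)), 1)
  expect_equal(nrow(kb$ingredient_gene), 4)

  dir <- withr::local_tempdir()
  paths <- write_kb_tables(kb, dir)
  kb2 <- read_knowledge_tables(paths)
  expect_equal(kb2$prescriptions, kb$prescriptions)
  expect_equal(kb2$herb_ingredient, kb$herb_ingredient)
  expect_equal(kb2$ingredients, kb$ingredients) # OB absence preserved
  expect_equal(kb2$gene_disease, kb$gene_disease)
  expect_equal(kb2$disease_universe, kb$disease_universe)
  expect_true(all(abs(kb2$ingredient_gene$p_value - kb$ingredient_gene$p_value) < 1e-12))
})

test_that("out-of-range and malformed inputs are load errors, not coercions", {
  kb <- tiny_kb()
  dir <- withr::local_tempdir()
  paths <- write_kb_tables(kb, dir)

  # p-value out of range
  ig <- utils::read.delim(paths[["ingredient_gene"]], colClasses = "character")
  ig$p_value[1] <- "1.5"
  utils::write.table(ig, paths[["ingredient_gene"]],
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  expect_error(read_knowledge_tables(paths), "p_value")

  # unparseable numeric
  ig$p_value[1] <- "not-a-number"
  utils::write.table(ig, paths[["ingredient_gene"]],
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  expect_error(read_knowledge_tables(paths), "unparseable")

  # missing required column named in the error
  ig$p_value <- NULL
  utils::write.table(ig, paths[["ingredient_gene"]],
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  expect_error(read_knowledge_tables(paths), "ingredient_gene.*p_value")
})

test_that("duplicate ingredient-gene links are rejected as ambiguous", {
  expect_error(
    knowledge_base(
      prescriptions = data.frame(prescription_id = "P1", herb_id = "H1", dose_g = 3),
      herb_ingredient = data.frame(herb_id = "H1", ingredient_id = "I1"),
      ingredients = data.frame(ingredient_id = "I1", ob_score = 10),
      ingredient_gene = data.frame(
        ingredient_id = c("I1", "I1"), gene_id = c("g1", "g1"),
        p_value = c(0.1, 0.2), evidence_score = c(1, 1)
      ),
      gene_disease = data.frame(gene_id = "g1", disease_term = "colitis")
    ),
    "duplicate"
  )
})

test_that("doses must be positive and duplicate herb-ingredient pairs merge", {
  expect_error(
    knowledge_base(
      prescriptions = data.frame(prescription_id = "P1", herb_id = "H1", dose_g = -1),
      herb_ingredient = data.frame(herb_id = "H1", ingredient_id = "I1"),
      ingredients = data.frame(ingredient_id = "I1", ob_score = 10),
      ingredient_gene = data.frame(
        ingredient_id = "I1", gene_id = "g1",
        p_value = 0.1, evidence_score = 1
      ),
      gene_disease = data.frame(gene_id = "g1", disease_term = "colitis")
    ),
    "positive"
  )
  kb <- knowledge_base(
    prescriptions = data.frame(prescription_id = "P1", herb_id = "H1", dose_g = 3),
    herb_ingredient = data.frame(
      herb_id = c("H1", "H1"), ingredient_id = c("I1", "I1")
    ),
    ingredients = data.frame(ingredient_id = "I1", ob_score = 10),
    ingredient_gene = data.frame(
      ingredient_id = "I1", gene_id = "g1", p_value = 0.1, evidence_score = 1
    ),
    gene_disease = data.frame(gene_id = "g1", disease_term = "colitis")
  )
  expect_equal(nrow(kb$herb_ingredient), 1)
})

test_that("a classic four-herb formula loads as four herb nodes", {
  herbs <- c(
    "Coptidis Rhizoma", "Scutellariae Radix",
    "Phellodendri Chinensis Cortex", "Gardeniae Fructus"
  )
  kb <- knowledge_base(
    prescriptions = data.frame(
      prescription_id = "Hwanglyeonhaedok-tang",
      herb_id = herbs, dose_g = c(4, 4, 4, 4)
    ),
    herb_ingredient = data.frame(
      herb_id = herbs, ingredient_id = paste0("I", 1:4)
    ),
    ingredients = data.frame(ingredient_id = paste0("I", 1:4), ob_score = 30),
    ingredient_gene = data.frame(
      ingredient_id = paste0("I", 1:4), gene_id = paste0("g", 1:4),
      p_value = 1e-6, evidence_score = 1
    ),
    gene_disease = data.frame(gene_id = paste0("g", 1:4), disease_term = "fever")
  )
  net <- assemble_network(apply_filters(kb), "Hwanglyeonhaedok-tang")
  expect_equal(sum(net$nodes$layer == "herb"), 4)
})

test_that("gold standard normalizes terms, drops duplicates, rejects bad categories", {
  g <- gold_standard(data.frame(
    prescription_id = "P1", category = "all", disease_term = "Colitis"
  ))
  expect_equal(gold_terms(g, "P1", "all"), "colitis")

  expect_error(
    gold_standard(data.frame(
      prescription_id = "P1", category = "tertiary", disease_term = "x"
    )),
    "tertiary"
  )

  # (P1, primary, X) and (P1, primary, x) collapse to one term with a warning
  expect_warning(
    g2 <- gold_standard(data.frame(
      prescription_id = c("P1", "P1"), category = "primary",
      disease_term = c("X", "x")
    )),
    "duplicate"
  )
  expect_equal(gold_terms(g2, "P1", "primary"), "x")

  # whitespace collapsing
  g3 <- gold_standard(data.frame(
    prescription_id = "P1", category = "all", disease_term = "  Chronic   Colitis "
  ))
  expect_equal(gold_terms(g3, "P1", "all"), "chronic colitis")
})

test_that("synonym tables canonicalize terms at load", {
  syn <- data.frame(term = "IBS", canonical = "irritable bowel syndrome")
  g <- gold_standard(
    data.frame(prescription_id = "P1", category = "all", disease_term = "IBS"),
    synonyms = syn
  )
  expect_equal(gold_terms(g, "P1", "all"), "irritable bowel syndrome")
})

test_that("GMT parsing handles sets, blanks, and malformed lines", {
  f <- withr::local_tempfile()
  writeLines(c("S1\tdesc\tg1\tg2", "S2\tother\tg3\t\tg4"), f)
  gs <- read_gene_sets(f)
  expect_equal(gs$sets$S1, c("g1", "g2"))
  expect_equal(gs$sets$S2, c("g3", "g4")) # blank gene field skipped
  expect_equal(length(gs), 2L)

  # empty file -> empty collection
  writeLines(character(0), f)
  expect_length(read_gene_sets(f)$sets, 0)

  # duplicate id
  writeLines(c("S1\td\tg1", "S1\td\tg2"), f)
  expect_error(read_gene_sets(f), "duplicate")

  # short line reported with its line number
  writeLines(c("S1\td\tg1", "S2\tonly-two-fields"), f)
  expect_error(read_gene_sets(f), "line 2")
})

test_that("write_outputs produces a manifest and byte-identical re-runs", {
  kb <- tiny_kb()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_outputs(kb, d1)
  m2 <- write_outputs(kb, d2)
  expect_setequal(
    m1$file,
    c(
      "prescriptions.tsv", "herb_ingredient.tsv", "ingredients.tsv",
      "ingredient_gene.tsv", "gene_disease.tsv", "disease_universe.tsv"
    )
  )
  expect_equal(m1$rows[m1$file == "gene_disease.tsv"], 5L)
  for (f in m1$file) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  # header-only table for an empty result
  empty_gold <- gold_standard(data.frame(
    prescription_id = character(0), category = character(0),
    disease_term = character(0)
  ))
  m3 <- write_outputs(empty_gold, d1)
  expect_equal(m3$rows, 0L)
  expect_length(readLines(file.path(d1, "gold_standard.tsv")), 1)
})
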