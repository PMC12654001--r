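# Readers and writers for the pipeline's tab-delimited exchange formats.
# All tables are UTF-8, tab-delimited, one header row (SymMap exports and
# Cytoscape imports are tab-friendly).

read_tsv_strict <- function(path, table) {
  if (!file.exists(path)) {
    stop(sprintf("table '%s': file not found: %s", table, path), call. = FALSE)
  }
  utils::read.delim(path,
    sep = "\t", header = TRUE, colClasses = "character",
    na.strings = NULL, quote = "", comment.char = "",
    check.names = TRUE, fileEncoding = "UTF-8"
  )
}

#' Read SymMap-style knowledge tables
#'
#' Loads the five relational tables into a validated [knowledge_base()].
#' Numeric columns are parsed strictly: a value that does not parse as a
#' number is a load error naming the table and column, never a silent
#' `NA`. The OB column may be blank (recorded as an absent score).
#'
#' @param paths named list or character vector of file paths with entries
#'   `prescriptions` (prescription_id, herb_id, dose_g),
#'   `herb_ingredient` (herb_id, ingredient_id),
#'   `ingredients` (ingredient_id, ob_score; ob_score may be blank),
#'   `ingredient_gene` (ingredient_id, gene_id, p_value, evidence_score,
#'   optionally q_value) and `gene_disease` (gene_id, disease_term).
#' @param disease_universe optional path to a one-column table
#'   (`disease_term`) enumerating the background universe; defaults to the
#'   terms present in `gene_disease`.
#' @param synonyms optional data.frame (`term`, `canonical`) applied to
#'   disease terms at load.
#' @return a `herbnet_kb`.
#' @export
read_knowledge_tables <- function(paths, disease_universe = NULL, synonyms = NULL) {
  paths <- as.list(paths)
  needed <- c(
    "prescriptions", "herb_ingredient", "ingredients",
    "ingredient_gene", "gene_disease"
  )
  missing <- setdiff(needed, names(paths))
  if (length(missing) > 0) {
    stop(sprintf("missing table path(s): %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }

  pres <- read_tsv_strict(paths$prescriptions, "prescriptions")
  require_columns(pres, c("prescription_id", "herb_id", "dose_g"), "prescriptions")
  pres$dose_g <- parse_numeric_strict(pres$dose_g, "prescriptions", "dose_g")

  hi <- read_tsv_strict(paths$herb_ingredient, "herb_ingredient")
  require_columns(hi, c("herb_id", "ingredient_id"), "herb_ingredient")

  ing <- read_tsv_strict(paths$ingredients, "ingredients")
  require_columns(ing, c("ingredient_id", "ob_score"), "ingredients")
  ing$ob_score <- parse_numeric_strict(ing$ob_score, "ingredients", "ob_score",
    allow_blank = TRUE
  )

  ig <- read_tsv_strict(paths$ingredient_gene, "ingredient_gene")
  require_columns(
    ig, c("ingredient_id", "gene_id", "p_value", "evidence_score"),
    "ingredient_gene"
  )
  ig$p_value <- parse_numeric_strict(ig$p_value, "ingredient_gene", "p_value")
  ig$evidence_score <- parse_numeric_strict(
    ig$evidence_score, "ingredient_gene", "evidence_score"
  )
  if ("q_value" %in% names(ig)) {
    ig$q_value <- parse_numeric_strict(ig$q_value, "ingredient_gene", "q_value",
      allow_blank = TRUE
    )
  }

  gd <- read_tsv_strict(paths$gene_disease, "gene_disease")
  require_columns(gd, c("gene_id", "disease_term"), "gene_disease")

  universe <- NULL
  if (!is.null(disease_universe)) {
    du <- read_tsv_strict(disease_universe, "disease_universe")
    require_columns(du, "disease_term", "disease_universe")
    universe <- du$disease_term
  }

  knowledge_base(pres, hi, ing, ig, gd,
    disease_universe = universe, synonyms = synonyms
  )
}

#' Construct a gold-standard indication set
#'
#' Curated clinically validated disease terms per prescription, classified
#' into the categories `primary` (direct symptoms or diseases targeted),
#' `secondary` (related comorbidities or complications) and `all` (for
#' prescriptions with a single well-defined therapeutic use). Terms are
#' normalized; duplicates within a (prescription, category) cell are
#' dropped with a warning.
#'
#' @param entries data.frame with columns `prescription_id`, `category`,
#'   `disease_term`.
#' @param synonyms optional synonym table (`term`, `canonical`).
#' @return an object of class `herbnet_gold` (a normalized data.frame).
#' @export
gold_standard <- function(entries, synonyms = NULL) {
  entries <- as.data.frame(entries)
  require_columns(
    entries, c("prescription_id", "category", "disease_term"),
    "gold_standard"
  )
  entries$prescription_id <- as.character(entries$prescription_id)
  entries$category <- as.character(entries$category)
  bad <- setdiff(unique(entries$category), c("primary", "secondary", "all"))
  if (length(bad) > 0) {
    stop(sprintf(
      "gold_standard: unknown category label(s): %s (allowed: primary, secondary, all)",
      paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  entries$disease_term <- apply_synonyms(
    normalize_term(entries$disease_term), synonyms
  )
  dup <- duplicated(entries[c("prescription_id", "category", "disease_term")])
  if (any(dup)) {
    warning(sprintf(
      "gold_standard: dropped %d duplicate term(s) after normalization",
      sum(dup)
    ), call. = FALSE)
    entries <- entries[!dup, , drop = FALSE]
  }
  if (any(entries$disease_term == "")) {
    stop("gold_standard: empty disease term after normalization", call. = FALSE)
  }
  rownames(entries) <- NULL
  structure(entries[c("prescription_id", "category", "disease_term")],
    class = c("herbnet_gold", "data.frame")
  )
}

#' Read a gold-standard indication table
#'
#' @param path TSV with columns `prescription_id`, `category`, `disease_term`.
#' @inheritParams gold_standard
#' @return a `herbnet_gold`.
#' @export
read_gold_standard <- function(path, synonyms = NULL) {
  df <- read_tsv_strict(path, "gold_standard")
  gold_standard(df, synonyms = synonyms)
}

#' Gold-standard terms for one prescription and category
#'
#' @param gold a `herbnet_gold`.
#' @param prescription prescription id.
#' @param category one of `"primary"`, `"secondary"`, `"all"`.
#' @return character vector of normalized terms (possibly empty).
#' @export
gold_terms <- function(gold, prescription, category) {
  stopifnot(inherits(gold, "herbnet_gold"))
  gold$disease_term[gold$prescription_id == prescription & gold$category == category]
}

#' Gold-standard categories available for a prescription
#' @inheritParams gold_terms
#' @return character vector of category labels present for `prescription`.
#' @export
gold_categories <- function(gold, prescription) {
  stopifnot(inherits(gold, "herbnet_gold"))
  cats <- unique(gold$category[gold$prescription_id == prescription])
  intersect(c("primary", "secondary", "all"), cats)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene ids; names are the
#'   set ids and must be unique; no set may be empty.
#' @param descriptions optional character vector of per-set descriptions
#'   (recycled `""` when absent).
#' @return an object of class `herbnet_gene_sets`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) > 0 && (is.null(names(sets)) || any(names(sets) == ""))) {
    stop("gene_set_collection: every set needs a name", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) {
    stop("gene_set_collection: duplicate set id", call. = FALSE)
  }
  sets <- lapply(sets, function(g) unique(as.character(g[!is.na(g) & g != ""])))
  if (any(lengths(sets) == 0)) {
    stop("gene_set_collection: empty gene set", call. = FALSE)
  }
  if (is.null(descriptions)) {
    descriptions <- rep("", length(sets))
  }
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions),
    class = "herbnet_gene_sets"
  )
}

#' @export
print.herbnet_gene_sets <- function(x, ...) {
  cat(sprintf(
    "Gene-set collection: %d set(s), sizes %s\n",
    length(x$sets),
    if (length(x$sets) > 0) {
      paste(range(lengths(x$sets)), collapse = "-")
    } else {
      "-"
    }
  ))
  invisible(x)
}

#' @export
length.herbnet_gene_sets <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `id`, `description`, then
#' gene ids. Blank gene fields are skipped; a line with fewer than three
#' fields is a parse error reported with its line number.
#'
#' @param path GMT file path.
#' @return a `herbnet_gene_sets`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("gene sets: file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0) {
    return(gene_set_collection(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop(sprintf("GMT parse error at line %d: fewer than 3 fields", short[1]),
      call. = FALSE
    )
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop(sprintf(
      "GMT: duplicate set id '%s'", ids[duplicated(ids)][1]
    ), call. = FALSE)
  }
  descs <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- ids
  gene_set_collection(sets, descriptions = descs)
}

#' Write a gene-set collection as GMT
#' @param collection a `herbnet_gene_sets`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(collection, path) {
  stopifnot(inherits(collection, "herbnet_gene_sets"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
      collapse = "\t"
    )
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE, na = "", fileEncoding = "UTF-8", eol = "\n"
  )
  invisible(path)
}

manifest_entry <- function(file, rows) {
  data.frame(file = file, rows = as.integer(rows), stringsAsFactors = FALSE)
}

#' Write pipeline products to a directory
#'
#' Writes any pipeline product (`herbnet_kb`, `herbnet_gold`,
#' `herbnet_validation`, `herbnet_gsea`, `therapeutic_network`,
#' `ranked_gene_list`, `herbnet_gene_sets`) as deterministic, tab-delimited
#' files (plus GraphML/SIF for networks) and returns a manifest listing
#' every artifact with its row count. Re-running with identical inputs
#' produces byte-identical files.
#'
#' @param x the object to write.
#' @param directory output directory (created if needed).
#' @param ... passed to methods (`name` overrides the file stem for
#'   networks and ranked lists).
#' @return data.frame manifest with columns `file` and `rows`.
#' @export
write_outputs <- function(x, directory, ...) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory)) {
      stop(sprintf("cannot create output directory: %s", directory), call. = FALSE)
    }
  }
  UseMethod("write_outputs")
}

#' @export
write_outputs.default <- function(x, directory, ...) {
  stop(sprintf("write_outputs: no writer for class '%s'", class(x)[1]), call. = FALSE)
}

#' @export
write_outputs.herbnet_kb <- function(x, directory, ...) {
  files <- c(
    prescriptions = "prescriptions.tsv",
    herb_ingredient = "herb_ingredient.tsv",
    ingredients = "ingredients.tsv",
    ingredient_gene = "ingredient_gene.tsv",
    gene_disease = "gene_disease.tsv"
  )
  man <- list()
  for (tab in names(files)) {
    p <- file.path(directory, files[[tab]])
    write_tsv(x[[tab]], p)
    man[[tab]] <- manifest_entry(files[[tab]], nrow(x[[tab]]))
  }
  du <- data.frame(disease_term = x$disease_universe, stringsAsFactors = FALSE)
  write_tsv(du, file.path(directory, "disease_universe.tsv"))
  man$universe <- manifest_entry("disease_universe.tsv", nrow(du))
  do.call(rbind, unname(man))
}

#' @export
write_outputs.herbnet_gold <- function(x, directory, ...) {
  write_tsv(as.data.frame(x), file.path(directory, "gold_standard.tsv"))
  manifest_entry("gold_standard.tsv", nrow(x))
}

#' @export
write_outputs.herbnet_gene_sets <- function(x, directory, ...) {
  write_gene_sets(x, file.path(directory, "gene_sets.gmt"))
  manifest_entry("gene_sets.gmt", length(x$sets))
}
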