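#' Pipeline configuration
#'
#' Bundles inputs and per-stage parameters for [run_pipeline()]. Inputs
#' may be given either as in-memory objects (`kb`, `gold`, `gene_sets`)
#' or as file paths (`table_paths` for [read_knowledge_tables()],
#' `gold_path`, `gmt_path`); objects win when both are present. The
#' master `seed` overrides the seeds of the permutation and GSEA
#' configurations so one integer reproduces a whole run.
#'
#' @param kb optional `herbnet_kb`.
#' @param gold optional `herbnet_gold`; when absent the validation stage
#'   is skipped with a warning.
#' @param gene_sets optional `herbnet_gene_sets`; when absent the GSEA
#'   stage is skipped with a warning.
#' @param table_paths named paths for [read_knowledge_tables()].
#' @param gold_path path to a gold-standard TSV.
#' @param gmt_path path to a GMT file.
#' @param out_dir output directory.
#' @param filter a [filter_config()].
#' @param permutation a [permutation_config()].
#' @param gsea a [gsea_config()].
#' @param viz a [viz_config()].
#' @param top_k length of the per-prescription disease ranking table.
#' @param seed master seed recorded in the manifest and pushed into the
#'   permutation and GSEA sub-seeds.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(kb = NULL, gold = NULL, gene_sets = NULL,
                            table_paths = NULL, gold_path = NULL, gmt_path = NULL,
                            out_dir = tempfile("herbnet_run_"),
                            filter = filter_config(),
                            permutation = permutation_config(),
                            gsea = gsea_config(),
                            viz = viz_config(),
                            top_k = 20,
                            seed = 1) {
  permutation$seed <- as.integer(seed)
  gsea$seed <- as.integer(seed)
  structure(
    list(
      kb = kb, gold = gold, gene_sets = gene_sets,
      table_paths = table_paths, gold_path = gold_path, gmt_path = gmt_path,
      out_dir = out_dir, filter = filter, permutation = permutation,
      gsea = gsea, viz = viz, top_k = top_k, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

stage_step <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      call. = FALSE
    )
  })
}

#' Run the full validation pipeline
#'
#' Executes the stages in order — load, filter (OB screen + BH FDR),
#' network assembly per prescription, permutation validation against the
#' gold standard, dose-weighted pre-ranked GSEA — writing each stage's
#' outputs before the next begins, and returns a manifest of every
#' written artifact. A missing gold standard or gene-set collection
#' skips only the corresponding stage. Stage outputs are pure functions
#' of (inputs, config, seed); re-running an identical configuration
#' yields identical tables.
#'
#' @param config a [pipeline_config()].
#' @return data.frame manifest (columns `file`, `rows`) with the run
#'   parameters attached as attribute `run_info`; also written to
#'   `manifest.tsv`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  kb <- stage_step("load", {
    if (!is.null(config$kb)) {
      config$kb
    } else if (!is.null(config$table_paths)) {
      read_knowledge_tables(config$table_paths)
    } else {
      stop("no knowledge base: supply 'kb' or 'table_paths'")
    }
  })
  gold <- config$gold
  if (is.null(gold) && !is.null(config$gold_path)) {
    gold <- stage_step("load", read_gold_standard(config$gold_path))
  }
  gene_sets <- config$gene_sets
  if (is.null(gene_sets) && !is.null(config$gmt_path)) {
    gene_sets <- stage_step("load", read_gene_sets(config$gmt_path))
  }

  manifest <- list()

  fkb <- stage_step("filter", apply_filters(kb, config$filter))
  manifest$kb <- write_outputs(fkb, file.path(out, "filtered_kb"))
  manifest$kb$file <- file.path("filtered_kb", manifest$kb$file)

  ids <- prescription_ids(fkb)
  networks <- stage_step("network", lapply(ids, function(p) assemble_network(fkb, p)))
  names(networks) <- ids
  for (p in ids) {
    m <- write_outputs(networks[[p]], file.path(out, "networks"))
    m$file <- file.path("networks", m$file)
    manifest[[paste0("net_", p)]] <- m

    topk <- top_k_diseases(networks[[p]], k = config$top_k, gold = gold)
    f <- file.path("networks", sprintf("top_diseases_%s.tsv", p))
    write_tsv(topk, file.path(out, f))
    manifest[[paste0("topk_", p)]] <- manifest_entry(f, nrow(topk))
  }
  summ <- network_summary(networks)
  manifest$summary <- write_outputs(summ, out)

  validation <- NULL
  if (is.null(gold)) {
    warning("no gold standard supplied: validation stage skipped", call. = FALSE)
  } else {
    with_gold <- ids[vapply(ids, function(p) {
      length(gold_categories(gold, p)) > 0
    }, logical(1))]
    validation <- stage_step("validate", validate_prescriptions(
      networks[with_gold], gold, fkb$disease_universe, config$permutation
    ))
    manifest$validation <- write_outputs(validation, out)
  }

  gsea_results <- NULL
  if (is.null(gene_sets)) {
    warning("no gene sets supplied: GSEA stage skipped", call. = FALSE)
  } else {
    gsea_results <- stage_step("gsea", {
      res <- list()
      for (p in ids) {
        scores <- composite_gene_scores(fkb, p)
        if (length(scores) == 0) {
          warning(sprintf("prescription '%s': no scored genes, GSEA skipped", p),
            call. = FALSE
          )
          next
        }
        ranked <- rank_genes(scores)
        m <- write_outputs(ranked, file.path(out, "gsea"),
          name = sprintf("ranked_list_%s", p)
        )
        m$file <- file.path("gsea", m$file)
        manifest[[paste0("rank_", p)]] <- m
        res[[p]] <- gsea_preranked(ranked, gene_sets, config$gsea)
        m <- write_outputs(res[[p]], file.path(out, "gsea"),
          name = sprintf("gsea_results_%s", p)
        )
        m$file <- file.path("gsea", m$file)
        manifest[[paste0("gsea_", p)]] <- m
      }
      res
    })
  }

  man <- do.call(rbind, unname(manifest))
  rownames(man) <- NULL
  run_info <- list(
    seed = config$seed,
    fdr_alpha = config$filter$fdr_alpha,
    n_perm = config$permutation$n_perm,
    gsea_n_perm = config$gsea$n_perm,
    prescriptions = ids,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  write_tsv(man, file.path(out, "manifest.tsv"))
  structure(man,
    run_info = run_info,
    networks = networks,
    validation = validation,
    gsea = gsea_results,
    class = c("herbnet_manifest", "data.frame")
  )
}

#' @export
print.herbnet_manifest <- function(x, ...) {
  info <- attr(x, "run_info")
  cat(sprintf(
    "herbnet pipeline run (seed %d, %d prescription(s), %.1f s)\n",
    info$seed, length(info$prescriptions), info$wall_time_s
  ))
  print.data.frame(as.data.frame(x), ...)
  invisible(x)
}
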