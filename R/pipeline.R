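default_alpha <- function(category) {
  # conventional gates: pathway collections at 0.01, GO-BP at 0.05
  if (identical(category, "pathway")) 0.01 else 0.05
}

#' Build a validated pipeline configuration
#'
#' @param genes_a,genes_b paths to the two disease gene lists.
#' @param collections list of annotation collections to test, each a list
#'   with `path` (GMT file), `category` and optionally `alpha` (defaults:
#'   0.01 for `"pathway"`, 0.05 otherwise).
#' @param ppi optional path to a PPI edge list; if `NULL` the network stages
#'   are skipped.
#' @param name_a,name_b disease labels.
#' @param min_overlap minimum term overlap entering enrichment testing.
#' @param method enrichment method, `"hypergeometric"` or `"ease"`.
#' @param min_degree guilt-by-association degree threshold.
#' @param edge_mode subnetwork edge mode, `"seed_incident"` or `"induced"`.
#' @param ppi_format edge-list dialect, `"tsv"` or `"sif"`.
#' @param outdir default output directory for [run_full_pipeline()].
#' @param seed optional integer recorded in the report (used by synthetic
#'   workflows).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(genes_a, genes_b, collections = list(),
                            ppi = NULL, name_a = "disease_a",
                            name_b = "disease_b", min_overlap = 2L,
                            method = c("hypergeometric", "ease"),
                            min_degree = 5L,
                            edge_mode = c("seed_incident", "induced"),
                            ppi_format = c("tsv", "sif"),
                            outdir = ".", seed = NULL) {
  method <- match.arg(method)
  edge_mode <- match.arg(edge_mode)
  ppi_format <- match.arg(ppi_format)
  if (min_overlap < 1L) stop_("min_overlap must be >= 1")
  if (min_degree < 1L) stop_("min_degree must be >= 1")
  if (length(collections) == 0L) {
    stop_("at least one annotation collection is required")
  }
  collections <- lapply(collections, function(cc) {
    if (is.null(cc$path)) stop_("every collection needs a 'path'")
    cc$category <- cc$category %||% "pathway"
    cc$alpha <- cc$alpha %||% default_alpha(cc$category)
    if (cc$alpha <= 0 || cc$alpha >= 1) stop_("collection alpha out of range")
    cc
  })
  structure(
    list(genes_a = genes_a, genes_b = genes_b, collections = collections,
         ppi = ppi, name_a = name_a, name_b = name_b,
         min_overlap = as.integer(min_overlap), method = method,
         min_degree = as.integer(min_degree), edge_mode = edge_mode,
         ppi_format = ppi_format, outdir = outdir, seed = seed),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Relative paths in the file are resolved against the directory containing
#' the config, so a fixture bundle is runnable from anywhere.
#'
#' @param path path to a YAML config.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_("config file not found: '%s'", path)
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  raw$genes_a <- resolve(raw$genes_a)
  raw$genes_b <- resolve(raw$genes_b)
  raw$ppi <- resolve(raw$ppi)
  raw$collections <- lapply(raw$collections, function(cc) {
    cc$path <- resolve(cc$path)
    cc
  })
  do.call(pipeline_config, raw)
}

run_stage <- function(label, expr) {
  tryCatch(expr, error = function(e) {
    stop_("pipeline stage '%s' failed: %s", label, conditionMessage(e))
  })
}

#' Run the full comorbidity analysis pipeline
#'
#' Executes, in order: gene-list loading, set overlap, per-collection
#' enrichment of both disease sets, enrichment comparison, PPI cleaning,
#' disease-subnetwork extraction and intersection, and guilt-by-association
#' candidate prediction; writes every table plus a JSON report to `outdir`.
#' If the config has no (existing) PPI file the network stages are skipped
#' with an explicit notice and the enrichment stages still complete. Before
#' returning, an internal audit re-reads the emitted tables and verifies
#' that the report counts match them.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @param outdir output directory; defaults to the config's.
#' @return object of class `pipeline_report` (also written as
#'   `report.json`): all summary counts, the file manifest, the package
#'   version, and an echo of the configuration actually used.
#' @export
run_full_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- outdir %||% config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- character(0)
  emit <- function(name) {
    files <<- c(files, name)
    file.path(outdir, name)
  }

  set_a <- run_stage("load_genes_a",
                     read_gene_list(config$genes_a, name = config$name_a))
  set_b <- run_stage("load_genes_b",
                     read_gene_list(config$genes_b, name = config$name_b))
  write_gene_list(set_a, emit("genes_a_normalized.txt"))
  write_gene_list(set_b, emit("genes_b_normalized.txt"))

  overlap <- run_stage("overlap", compare_gene_sets(set_a, set_b))
  write_overlap_report(overlap, emit("gene_overlap.tsv"))

  enrichment_counts <- list()
  for (cc in config$collections) {
    cat_lab <- cc$category
    coll <- run_stage(paste0("read_gmt_", cat_lab),
                      read_gmt(cc$path, category = cat_lab))
    ea <- run_stage(paste0("enrich_a_", cat_lab),
                    run_enrichment(set_a, coll, alpha = cc$alpha,
                                   min_overlap = config$min_overlap,
                                   method = config$method))
    eb <- run_stage(paste0("enrich_b_", cat_lab),
                    run_enrichment(set_b, coll, alpha = cc$alpha,
                                   min_overlap = config$min_overlap,
                                   method = config$method))
    cmp <- run_stage(paste0("compare_", cat_lab), compare_enrichments(ea, eb))
    write_enrichment_tsv(ea, emit(sprintf("enrichment_%s_a.tsv", cat_lab)))
    write_enrichment_tsv(eb, emit(sprintf("enrichment_%s_b.tsv", cat_lab)))
    cmp_tab <- rbind(
      cbind(status = rep("shared", nrow(cmp$shared)), cmp$shared),
      cbind(status = rep("a_specific", nrow(cmp$a_specific)), cmp$a_specific),
      cbind(status = rep("b_specific", nrow(cmp$b_specific)), cmp$b_specific)
    )
    for (col in c("p_a", "p_bh_a", "p_b", "p_bh_b")) {
      cmp_tab[[col]] <- ifelse(is.na(cmp_tab[[col]]), "NA",
                               sprintf("%.5e", cmp_tab[[col]]))
    }
    write_tsv(cmp_tab, emit(sprintf("comparison_%s.tsv", cat_lab)))
    jsonlite::write_json(
      list(category = cat_lab, alpha = cc$alpha,
           counts = as.list(cmp$counts),
           shared_terms = cmp$shared$term_name,
           a_specific_terms = cmp$a_specific$term_name,
           b_specific_terms = cmp$b_specific$term_name),
      emit(sprintf("comparison_%s.json", cat_lab)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    message(sprintf(
      "[%s] universe N = %d, BH family m = %d (A) / %d (B), alpha = %g",
      cat_lab, length(coll$universe), attr(ea, "m"), attr(eb, "m"), cc$alpha))
    enrichment_counts[[cat_lab]] <- list(
      alpha = cc$alpha, universe_size = length(coll$universe),
      tested_a = attr(ea, "m"), tested_b = attr(eb, "m"),
      significant_a = sum(ea$significant), significant_b = sum(eb$significant),
      shared = unname(cmp$counts[["shared"]]),
      a_specific = unname(cmp$counts[["a_specific"]]),
      b_specific = unname(cmp$counts[["b_specific"]]))
  }

  network_counts <- NULL
  if (is.null(config$ppi) || !file.exists(config$ppi %||% "")) {
    message("no PPI edge list configured or file missing; network stages skipped")
  } else {
    raw <- run_stage("read_ppi",
                     read_ppi_edges(config$ppi, format = config$ppi_format))
    net <- run_stage("clean_ppi", clean_ppi(raw))
    sub_a <- run_stage("subnetwork_a",
                       extract_disease_subnetwork(net, set_a,
                                                  mode = config$edge_mode))
    sub_b <- run_stage("subnetwork_b",
                       extract_disease_subnetwork(net, set_b,
                                                  mode = config$edge_mode))
    shared <- run_stage("intersect",
                        intersect_subnetworks(sub_a, sub_b, set_a, set_b))
    common_in_net <- intersect(overlap$shared, net$nodes)
    candidates <- run_stage("candidates",
                            predict_candidates(shared, common_in_net,
                                               set_a, set_b,
                                               min_degree = config$min_degree))
    write_edge_list(sub_a, emit("subnetwork_a.tsv"))
    write_edge_list(sub_b, emit("subnetwork_b.tsv"))
    write_edge_list(shared, emit("shared_subnetwork.tsv"))
    write_tsv(as.data.frame(candidates), emit("candidates.tsv"))
    message(sprintf("network: edge mode '%s', %d/%d common genes mapped",
                    config$edge_mode, length(common_in_net),
                    length(overlap$shared)))
    network_counts <- list(
      raw_records = nrow(raw$edges),
      nodes = length(net$nodes), edges = nrow(net$edges),
      seeds_a = length(sub_a$seeds), neighbors_a = length(sub_a$neighbors),
      edges_a = nrow(sub_a$edges),
      unmapped_seeds_a = length(sub_a$unmapped_seeds),
      seeds_b = length(sub_b$seeds), neighbors_b = length(sub_b$neighbors),
      edges_b = nrow(sub_b$edges),
      unmapped_seeds_b = length(sub_b$unmapped_seeds),
      shared_nodes = length(shared$nodes), shared_edges = nrow(shared$edges),
      role_counts = as.list(shared$role_counts),
      common_genes_in_network = length(common_in_net),
      min_degree = config$min_degree,
      candidates = nrow(candidates))
  }

  report <- structure(
    list(tool = "comorbnet",
         version = as.character(utils::packageVersion("comorbnet")),
         counts = list(
           genes_a = length(set_a), genes_b = length(set_b),
           shared_genes = overlap$counts[["shared"]],
           a_only_genes = overlap$counts[["a_only"]],
           b_only_genes = overlap$counts[["b_only"]],
           enrichment = enrichment_counts,
           network = network_counts),
         files = files,
         config = config[c("genes_a", "genes_b", "ppi", "name_a", "name_b",
                           "min_overlap", "method", "min_degree",
                           "edge_mode", "seed")]),
    class = "pipeline_report"
  )
  audit_outputs(report, outdir)
  jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

# re-read the emitted tables and check the report counts against them
audit_outputs <- function(report, outdir) {
  claim <- function(ok, what) {
    if (!ok) stop_("output audit failed: %s", what)
  }
  ov <- utils::read.delim(file.path(outdir, "gene_overlap.tsv"))
  claim(sum(ov$status == "shared") == report$counts$shared_genes,
        "shared gene count vs gene_overlap.tsv")
  claim(sum(ov$status == "a_only") == report$counts$a_only_genes,
        "a_only count vs gene_overlap.tsv")
  for (cat_lab in names(report$counts$enrichment)) {
    en <- report$counts$enrichment[[cat_lab]]
    for (side in c("a", "b")) {
      tab <- utils::read.delim(
        file.path(outdir, sprintf("enrichment_%s_%s.tsv", cat_lab, side)))
      claim(sum(tab$significant) == en[[paste0("significant_", side)]],
            sprintf("significant count in enrichment_%s_%s.tsv", cat_lab, side))
      claim(nrow(tab) == en[[paste0("tested_", side)]],
            sprintf("tested count in enrichment_%s_%s.tsv", cat_lab, side))
    }
    cmp <- utils::read.delim(file.path(outdir,
                                       sprintf("comparison_%s.tsv", cat_lab)))
    claim(sum(cmp$status == "shared") == en$shared,
          sprintf("shared term count in comparison_%s.tsv", cat_lab))
  }
  nw <- report$counts$network
  if (!is.null(nw)) {
    sh <- utils::read.delim(file.path(outdir, "shared_subnetwork.tsv"))
    claim(nrow(sh) == nw$shared_edges, "shared edge count")
    cand <- utils::read.delim(file.path(outdir, "candidates.tsv"))
    claim(nrow(cand) == nw$candidates, "candidate count")
  }
  invisible(TRUE)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> comorbnet %s\n", x$version))
  cat(sprintf("  gene sets: %d vs %d, %d shared\n", x$counts$genes_a,
              x$counts$genes_b, x$counts$shared_genes))
  for (cat_lab in names(x$counts$enrichment)) {
    en <- x$counts$enrichment[[cat_lab]]
    cat(sprintf("  %s: %d vs %d significant terms (%d shared, %d + %d specific)\n",
                cat_lab, en$significant_a, en$significant_b, en$shared,
                en$a_specific, en$b_specific))
  }
  nw <- x$counts$network
  if (!is.null(nw)) {
    cat(sprintf("  shared subnetwork: %d nodes, %d interactions; %d candidate gene(s) at degree >= %d\n",
                nw$shared_nodes, nw$shared_edges, nw$candidates,
                nw$min_degree))
  } else {
    cat("  network stages skipped\n")
  }
  invisible(x)
}
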