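# End-to-end orchestration: configuration, staged execution with
# provenance capture, and comparison of two networks (e.g. a protein and
# a gene co-expression network over the same genes).

#' Build a pipeline configuration
#'
#' Either `input` (paths to a matrix TSV, sample metadata TSV and
#' optionally a chromosome map and GMT collections) or `synthetic` (a
#' [synthetic_config()]) must be supplied. All analysis constants are
#' surfaced here with their standard defaults: the missingness cap (60
#' samples), the edge significance threshold (1e-8), the top-k edge count
#' (10000), the enrichment category-size window (5-2000) and the
#' assortativity eligibility floor (10 edges).
#'
#' @param input `NULL` or list with elements `matrix`, `metadata` and
#'   optionally `chromosomes`, `gmt` (character vector of GMT paths).
#' @param synthetic `NULL` or a [synthetic_config()].
#' @param max_missing missingness cap per protein, in samples.
#' @param complete_group group whose samples must be fully measured.
#' @param p_thresh,n_perm,top_k,dpi,dpi_tolerance,chi2_crit,min_points
#'   network-inference settings.
#' @param network_group samples used for network inference (`"tumor"`:
#'   contrasts aside, co-expression is estimated on tumors only since a
#'   handful of healthy samples cannot support it).
#' @param min_set_size,max_set_size,min_mapped enrichment settings.
#' @param assort_min_edges assortativity eligibility floor.
#' @param seed master seed; per-stage seeds are derived as
#'   `seed + stage_offset` (offsets 1 = simulation, 2 = rank transform,
#'   3 = null calibration) so stages can be rerun in isolation.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            max_missing = 60, complete_group = "healthy",
                            p_thresh = 1e-8, n_perm = 1e5, top_k = 10000,
                            dpi = FALSE, dpi_tolerance = 0,
                            chi2_crit = 7.815, min_points = 8,
                            network_group = "tumor",
                            min_set_size = 5, max_set_size = 2000,
                            min_mapped = 3, assort_min_edges = 10,
                            seed = 1) {
  if (is.null(input) && is.null(synthetic))
    stop("configuration needs either 'input' paths or a 'synthetic' block")
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_config"))
    synthetic <- do.call(synthetic_config, synthetic)
  cfg <- list(input = input, synthetic = synthetic,
              max_missing = max_missing, complete_group = complete_group,
              p_thresh = p_thresh, n_perm = n_perm, top_k = top_k,
              dpi = dpi, dpi_tolerance = dpi_tolerance,
              chi2_crit = chi2_crit, min_points = min_points,
              network_group = network_group,
              min_set_size = min_set_size, max_set_size = max_set_size,
              min_mapped = min_mapped, assort_min_edges = assort_min_edges,
              seed = seed)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Stages: (1) load or simulate the abundance matrix; (2) quality control
#' (missingness filter, flagged-sample removal, completeness in the
#' control group, median imputation); (3) differential expression;
#' (4) network inference on the tumor samples (rank transform, null
#' calibration, significance thresholding, optional DPI pruning, top-k
#' selection); (5) two-level community detection; (6) subcommunity
#' enrichment (when collections are given); (7) topology statistics.
#' All outputs are written to `outdir` as plain text together with a
#' provenance record; a rerun with the same config and seed reproduces
#' them bit-identically. A stage failure writes a `FAILED` marker naming
#' the stage and rethrows.
#'
#' @param cfg a [pipeline_config()].
#' @param outdir run directory (created).
#' @return invisibly, a list with the main in-memory objects
#'   (`matrix`, `de`, `null`, `network`, `network_topk`, `partition`,
#'   `enrichment`, `stats`).
#' @export
run_pipeline <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(c(paste("FAILED at stage:", stage), conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    truth <- NULL; chrom_map <- NULL; collections <- NULL
    checksums <- character(0)

    stage <- "input"
    if (!is.null(cfg$synthetic)) {
      sim_cfg <- cfg$synthetic
      sim_cfg$seed <- cfg$seed + 1
      ds <- generate_dataset(sim_cfg)
      m <- ds$matrix
      truth <- ds$truth
      chrom_map <- setNames(truth$chromosome, truth$protein)
      write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      flagged <- character(0)
    } else {
      md <- read_sample_metadata(cfg$input$metadata)
      m <- read_expression_matrix(cfg$input$matrix, metadata = md)
      flagged <- md$sample_id[md$flagged]
      if (!is.null(cfg$input$chromosomes))
        chrom_map <- read_chromosome_map(cfg$input$chromosomes)
      paths <- unlist(cfg$input)
      checksums <- tools::md5sum(paths[file.exists(paths)])
    }
    if (!is.null(cfg$input$gmt))
      collections <- unlist(lapply(cfg$input$gmt, read_gmt),
                            recursive = FALSE)

    stage <- "qc"
    n0 <- nrow(m$values)
    m <- filter_pgenes_by_missingness(m, cfg$max_missing)
    n1 <- nrow(m$values)
    if (length(flagged)) m <- drop_flagged_samples(m, flagged)
    m <- require_complete_in_group(m, cfg$complete_group)
    n2 <- nrow(m$values)
    m <- impute_missing(m)
    qc <- data.frame(step = c("input", "missingness_filter",
                              "complete_in_control", "imputed"),
                     n_proteins = c(n0, n1, n2, nrow(m$values)),
                     n_samples = c(NA, NA, NA, ncol(m$values)))
    write.table(qc, file.path(outdir, "qc_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    stage <- "diffexp"
    de <- de_analysis(m)
    write.table(as.data.frame(de), file.path(outdir, "de_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "network"
    net_samples <- samples_in_group(m, cfg$network_group)
    net_m <- expression_matrix(m$values[, net_samples, drop = FALSE],
                               m$group[net_samples])
    ranked <- copula_rank_transform(net_m, seed = cfg$seed + 2)
    null <- calibrate_null(ranked, n_perm = cfg$n_perm,
                           seed = cfg$seed + 3,
                           chi2_crit = cfg$chi2_crit,
                           min_points = cfg$min_points)
    net <- infer_network(ranked, null, p_thresh = cfg$p_thresh,
                         chi2_crit = cfg$chi2_crit,
                         min_points = cfg$min_points)
    if (isTRUE(cfg$dpi)) net <- apply_dpi(net, cfg$dpi_tolerance)
    write_edge_list(net, file.path(outdir, "edges_full.tsv"))
    net_topk <- top_k_edges(net, cfg$top_k)
    write_edge_list(net_topk, file.path(outdir, "edges_topk.tsv"))

    stage <- "communities"
    partition <- detect_communities(net_topk)
    partition <- subpartition(net_topk, partition)
    write_partition(partition, file.path(outdir, "partition.tsv"))

    stage <- "enrichment"
    enr <- NULL
    if (!is.null(collections)) {
      enr <- enrich_partition(partition, collections,
                              min_size = cfg$min_set_size,
                              max_size = cfg$max_set_size,
                              min_mapped = cfg$min_mapped)
      write.table(enr, file.path(outdir, "enrichment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      hm <- enrichment_heatmap_table(enr)
      write.table(hm, file.path(outdir, "enrichment_heatmap.tsv"),
                  sep = "\t", quote = FALSE, col.names = NA)
    }

    stage <- "stats"
    hist <- degree_distribution(net_topk)
    pfit <- fit_power_law(hist)
    signs <- setNames(de$sign, de$protein)
    assort <- expression_assortativity(net_topk, partition, signs,
                                       cfg$assort_min_edges)
    write.table(assort, file.path(outdir, "assortativity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ct <- if (!is.null(chrom_map)) classify_cis_trans(net_topk, chrom_map)
          else NULL
    comps <- component_sizes(net_topk)
    stats <- list(
      n_proteins = nrow(m$values),
      n_samples = ncol(m$values),
      n_edges_full = nrow(net$edges),
      n_edges_topk = nrow(net_topk$edges),
      degree_fit = if (!is.null(pfit))
        list(alpha = pfit$alpha, corr = pfit$corr,
             corr_abs = pfit$corr_abs, n_points = pfit$n_points),
      modularity_level1 = attr(partition, "q_level1"),
      n_communities = length(unique(partition$community)),
      n_subcommunities = length(unique(partition$subcommunity)),
      assortativity = assort,
      cis_trans = if (!is.null(ct))
        list(n_cis = ct$n_cis, n_trans = ct$n_trans,
             n_unmapped = ct$n_unmapped, cis_fraction = ct$cis_fraction),
      component_sizes = comps)
    if (!is.null(truth)) {
      sub_of <- setNames(partition$subcommunity, partition$protein)
      truth_in <- truth[truth$protein %in% partition$protein, ]
      stats$ari_level1 <- adjusted_rand_index(
        truth_in$module,
        partition$community[match(truth_in$protein, partition$protein)])
      stats$ari_level2 <- adjusted_rand_index(
        truth_in$submodule, unname(sub_of[truth_in$protein]))
    }
    jsonlite::write_json(stats, file.path(outdir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    stage <- "provenance"
    prov <- list(config = unclass(cfg), seed = cfg$seed,
                 package_version = as.character(utils::packageVersion("pcnet")),
                 r_version = R.version.string,
                 input_checksums = as.list(checksums),
                 null_model = list(a = null$a, b = null$b, r2 = null$r2,
                                   n_perm = null$n_perm,
                                   n_samples = null$n_samples,
                                   seed = null$seed))
    prov$config$synthetic <- if (!is.null(cfg$synthetic))
      unclass(cfg$synthetic)
    jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    invisible(list(matrix = m, de = de, null = null, network = net,
                   network_topk = net_topk, partition = partition,
                   enrichment = enr, stats = stats, truth = truth))
  }, error = on_fail)
}

#' Compare two co-expression networks
#'
#' Side-by-side summary of two edge lists (e.g. a protein and a gene
#' co-expression network): edge counts, edge-set overlap (Jaccard and
#' fraction of the smaller list shared), component sizes, and — when a
#' chromosome map is given — the cis/trans split of each.
#'
#' @param net_a,net_b `pcn_network` objects or paths to edge-list TSVs.
#' @param chrom_map optional named chromosome vector.
#' @return list of class `network_comparison`.
#' @export
compare_networks <- function(net_a, net_b, chrom_map = NULL) {
  if (is.character(net_a)) net_a <- read_edge_list(net_a)
  if (is.character(net_b)) net_b <- read_edge_list(net_b)
  key <- function(net) paste(pmin(net$edges$a, net$edges$b),
                             pmax(net$edges$a, net$edges$b))
  ka <- unique(key(net_a)); kb <- unique(key(net_b))
  shared <- length(intersect(ka, kb))
  res <- list(
    n_edges = c(a = length(ka), b = length(kb)),
    shared_edges = shared,
    jaccard = shared / length(union(ka, kb)),
    overlap_of_smaller = if (min(length(ka), length(kb)) > 0)
      shared / min(length(ka), length(kb)) else NA_real_,
    component_sizes = list(a = component_sizes(net_a),
                           b = component_sizes(net_b)))
  if (!is.null(chrom_map))
    res$cis_trans <- list(a = classify_cis_trans(net_a, chrom_map),
                          b = classify_cis_trans(net_b, chrom_map))
  structure(res, class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("networks: %d vs %d edges, %d shared (Jaccard %.3f)\n",
              x$n_edges["a"], x$n_edges["b"], x$shared_edges, x$jaccard))
  cat(sprintf("largest components: %d vs %d\n",
              x$component_sizes$a[1], x$component_sizes$b[1]))
  if (!is.null(x$cis_trans)) {
    cat(sprintf("cis fraction: %.4f vs %.4f\n",
                x$cis_trans$a$cis_fraction, x$cis_trans$b$cis_fraction))
  }
  invisible(x)
}
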