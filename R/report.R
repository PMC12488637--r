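#' Configuration for a full QC report
#'
#' Bundles every knob of the one-call report: input location (or an
#' in-memory dataset), thresholds, clustering parameters, entropy scale,
#' marker depths, cutoff percentile, optional noise experiments, output
#' directory and the master seed that propagates to every stochastic step.
#'
#' @param input a [cite_dataset()], or a path to an MTX-triplet directory,
#'   or a named list `list(rna_csv =, adt_csv =)` of dense CSVs.
#' @param cluster_tsv optional label TSV imported instead of clustering.
#' @param pair_map_tsv optional two-column TSV (`adt_id`, `gene_symbol`)
#'   overriding the dataset's ADT-gene map.
#' @param rna_thresholds,adt_thresholds [cell_filter_thresholds()] used for
#'   flag annotation (ADT default: no bounds).
#' @param resolution,n_hvgs,n_pcs clustering parameters
#'   (see [define_clusters()]).
#' @param entropy_scale `"normalized"` or `"raw"` for all reported
#'   entropies (both are stored in the CSVs regardless).
#' @param top_k_list marker depths evaluated by the specificity section.
#' @param cutoff_percentile percentile of the null entropy distribution.
#' @param n_null_genes,null_min_mean null-distribution settings
#'   (see [sample_null_genes()]).
#' @param run_noise run the two noise-injection experiments (slow; default
#'   FALSE).
#' @param noise_rna,noise_adt [noise_config()]s used when `run_noise`.
#' @param run_specificity run the marker-specificity cutoff section
#'   (default TRUE).
#' @param n_permutations permutations for every correlation p-value.
#' @param out_dir output directory for `report.md`, `figures/`, `results/`.
#' @param seed master seed.
#' @return a `report_config` list.
#' @export
report_config <- function(input, cluster_tsv = NULL, pair_map_tsv = NULL,
                          rna_thresholds = cell_filter_thresholds(),
                          adt_thresholds = cell_filter_thresholds(
                            min_n_feature = 0, max_n_feature = .Machine$integer.max,
                            max_percent_mito = 100, modality = "ADT"),
                          resolution = 0.8, n_hvgs = 2000, n_pcs = 30,
                          entropy_scale = c("normalized", "raw"),
                          top_k_list = c(10, 20, 30), cutoff_percentile = 5,
                          n_null_genes = 1000, null_min_mean = 5,
                          run_noise = FALSE,
                          noise_rna = NULL, noise_adt = NULL,
                          run_specificity = TRUE,
                          n_permutations = 999,
                          out_dir = "citeqc_report", seed = 1) {
  structure(list(
    input = input, cluster_tsv = cluster_tsv, pair_map_tsv = pair_map_tsv,
    rna_thresholds = rna_thresholds, adt_thresholds = adt_thresholds,
    resolution = resolution, n_hvgs = n_hvgs, n_pcs = n_pcs,
    entropy_scale = match.arg(entropy_scale),
    top_k_list = top_k_list, cutoff_percentile = cutoff_percentile,
    n_null_genes = n_null_genes, null_min_mean = null_min_mean,
    run_noise = run_noise, noise_rna = noise_rna, noise_adt = noise_adt,
    run_specificity = run_specificity,
    n_permutations = n_permutations, out_dir = out_dir, seed = seed),
    class = "report_config")
}

load_report_input <- function(config) {
  inp <- config$input
  ds <- if (inherits(inp, "cite_dataset")) {
    inp
  } else if (is.character(inp) && length(inp) == 1) {
    read_10x_mtx(inp)
  } else if (is.list(inp) && !is.null(inp$rna_csv)) {
    read_csv_dataset(inp$rna_csv, inp$adt_csv)
  } else {
    abort("input must be a cite_dataset, an MTX directory, or list(rna_csv=, adt_csv=)")
  }
  if (!is.null(config$pair_map_tsv)) {
    map <- readr::read_tsv(config$pair_map_tsv, show_col_types = FALSE,
                           col_names = c("adt_id", "gene_id"))
    ds$adt_to_gene <- stats::setNames(map$gene_id, map$adt_id)
  }
  ds
}

#' Run the complete markdown QC report
#'
#' Executes every diagnostic in order — count diagnostics without clusters,
#' then clustering (or label import), then cluster-conditional entropy,
#' cross-modality concordance and, optionally, the noise-injection
#' experiments and the marker-specificity cutoff — and renders a single
#' markdown document with one section per diagnostic: a figure, the
#' quantitative result and a short templated interpretation. Every number
#' printed in the markdown is also written to the machine-readable bundle
#' under `results/` (CSV per table plus one `results.json`). A failing
#' section is reported as failed in the document; the remaining sections
#' still render. A reproducibility footer records the configuration, seed
#' and package version.
#'
#' @param config a [report_config()].
#' @return invisibly, a list with `report` (markdown path), `results` (the
#'   bundle list also serialized to `results/results.json`) and `out_dir`.
#' @export
run_report <- function(config) {
  stopifnot(inherits(config, "report_config"))
  out <- config$out_dir
  figs <- file.path(out, "figures")
  resd <- file.path(out, "results")
  for (d in c(out, figs, resd)) dir.create(d, recursive = TRUE, showWarnings = FALSE)

  dataset <- load_report_input(config)
  md <- c("# CITE-seq quality control report", "",
          sprintf("- cells: %d; genes: %d; ADTs: %d", n_cells(dataset),
                  length(dataset$gene_ids), length(dataset$adt_ids)), "")
  results <- list()
  failed <- character(0)

  section <- function(title, fig_name, body_fn) {
    md <<- c(md, sprintf("## %s", title), "")
    res <- tryCatch(body_fn(), error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- c(failed, title)
      md <<- c(md, sprintf("**Section failed:** %s", conditionMessage(res)), "")
      return(invisible(NULL))
    }
    if (!is.null(res$plot)) {
      fp <- file.path(figs, paste0(fig_name, ".png"))
      suppressMessages(ggplot2::ggsave(fp, res$plot, width = 6, height = 4.5,
                                       dpi = 120))
      md <<- c(md, sprintf("![%s](figures/%s.png)", title, fig_name), "")
    }
    md <<- c(md, res$text, "")
    if (!is.null(res$value)) results[[fig_name]] <<- res$value
    invisible(res)
  }

  corr_text <- function(r, interp) {
    c(sprintf("Spearman rho = %.3f, permutation p = %.3g (%d permutations, %s; two-sided p = %.3g), n = %d cells.",
              r$rho, r$p_value, r$n_permutations, r$hypothesis, r$p_two_sided,
              r$n_cells),
      "", interp)
  }

  stats_rna <- flag_cells(per_cell_stats(dataset, "RNA"), config$rna_thresholds)
  has_adt <- length(dataset$adt_ids) > 0
  stats_adt <- if (has_adt) flag_cells(per_cell_stats(dataset, "ADT"),
                                       config$adt_thresholds)
  readr::write_csv(stats_rna, file.path(resd, "per_cell_stats_rna.csv"))
  if (has_adt) readr::write_csv(stats_adt, file.path(resd, "per_cell_stats_adt.csv"))

  # --- diagnostics without clusters -------------------------------------
  section("RNA read-count correlation", "rna_read_corr", function() {
    r <- count_feature_correlation(stats_rna, config$n_permutations,
                                   seed = config$seed + 101,
                                   thresholds = config$rna_thresholds)
    list(plot = autoplot(r), value = tidy(r),
         text = corr_text(r, paste(
           "In sound data the total RNA count rises with the number of detected",
           "genes; a weak or negative correlation points to systemic count problems.",
           sprintf("%d of %d cells pass the annotation thresholds.",
                   sum(stats_rna$pass), nrow(stats_rna)))))
  })
  section("ADT read-count correlation", "adt_read_corr", function() {
    if (!has_adt) abort("dataset has no ADT layer")
    r <- count_feature_correlation(stats_adt, config$n_permutations,
                                   seed = config$seed + 102,
                                   thresholds = config$adt_thresholds)
    list(plot = autoplot(r), value = tidy(r),
         text = corr_text(r, paste(
           "Total ADT molecules should rise with the number of detected tags;",
           "departures indicate problems in the antibody capture layer.")))
  })
  section("RNA mitochondrial-fraction correlation", "rna_mt_read_corr", function() {
    r <- mito_correlation(stats_rna, config$n_permutations,
                          seed = config$seed + 103,
                          thresholds = config$rna_thresholds)
    list(plot = autoplot(r), value = tidy(r),
         text = corr_text(r, paste(
           "The mitochondrial percentage should stay flat across detection depth;",
           "a strong dependence flags stressed or damaged cell populations.")))
  })

  # --- clustering --------------------------------------------------------
  clusters <- NULL
  markers <- NULL
  section("Cell clusters and marker genes", "clustering", function() {
    clusters <<- if (!is.null(config$cluster_tsv)) {
      import_clusters(dataset, config$cluster_tsv)
    } else {
      define_clusters(dataset, resolution = config$resolution,
                      n_hvgs = config$n_hvgs, n_pcs = config$n_pcs,
                      seed = config$seed)
    }
    markers <<- suppressWarnings(find_markers(dataset, clusters, top_k = 10))
    export_clusters(clusters, file.path(resd, "clusters.tsv"))
    readr::write_csv(markers, file.path(resd, "markers.csv"))
    sizes <- table(clusters$labels)
    list(value = glance(clusters),
         text = c(sprintf(
           "%d clusters (%s); sizes: %s. Top-10 markers per cluster identified by one-vs-rest rank-sum test.",
           clusters$n_clusters, clusters$source,
           paste(sprintf("%s: %d", names(sizes), sizes), collapse = ", "))))
  })
  if (is.null(clusters)) {
    abort("cluster definition failed; cluster-dependent sections cannot run (run the clustering step first)")
  }

  ent_scale <- config$entropy_scale
  ecol <- if (ent_scale == "normalized") "normalized_entropy" else "raw_entropy"

  # --- entropy sections --------------------------------------------------
  example_gene <- marker_genes(markers)[1]
  section(sprintf("RNA cluster distribution: %s", example_gene), "rna_dist",
          function() {
    norm <- normalize_counts(dataset, "RNA", "library_size")
    pr <- cluster_profile(as.vector(norm[, example_gene]), clusters, example_gene)
    e <- shannon_entropy(pr)
    readr::write_csv(pr$profile, file.path(resd, "rna_dist_profile.csv"))
    list(plot = autoplot(pr), value = e,
         text = sprintf(
           "Shannon entropy %.3f bits (normalized %.3f over %d clusters). Lower entropy means a more cluster-specific gene.",
           e$raw_entropy, e$normalized_entropy, e$n_clusters))
  })
  marker_entropy <- NULL
  section("Marker-gene entropy histogram", "multi_rna_hist", function() {
    marker_entropy <<- entropy_set(dataset, marker_genes(markers), clusters, "RNA")
    readr::write_csv(marker_entropy, file.path(resd, "entropy_markers.csv"))
    note <- attr(marker_entropy, "note")
    list(plot = plot_entropy_histogram(marker_entropy, ent_scale,
                                       title = "Marker-gene entropy"),
         value = list(median_entropy = median(marker_entropy[[ecol]], na.rm = TRUE),
                      n_features = nrow(marker_entropy)),
         text = c(sprintf("Median %s entropy of the %d marker genes: %.3f.",
                          ent_scale, nrow(marker_entropy),
                          median(marker_entropy[[ecol]], na.rm = TRUE)),
                  if (!is.null(note)) c("", paste("**Note:**", note))
                  else c("", "A histogram peak at high entropy would suggest the marker genes lack specificity.")))
  })
  section(sprintf("ADT cluster distribution: %s", dataset$adt_ids[1]), "adt_dist",
          function() {
    if (!has_adt) abort("dataset has no ADT layer")
    norm <- normalize_counts(dataset, "ADT", "library_size")
    pr <- cluster_profile(as.vector(norm[, 1]), clusters, dataset$adt_ids[1])
    e <- shannon_entropy(pr)
    readr::write_csv(pr$profile, file.path(resd, "adt_dist_profile.csv"))
    list(plot = autoplot(pr), value = e,
         text = sprintf(
           "Shannon entropy %.3f bits (normalized %.3f over %d clusters). Clusters come from RNA expression%s.",
           e$raw_entropy, e$normalized_entropy, e$n_clusters,
           if (clusters$source == "imported") " (imported labels)" else ""))
  })
  section("All-ADT entropy histogram", "multi_adt_hist", function() {
    if (!has_adt) abort("dataset has no ADT layer")
    ent <- entropy_set(dataset, dataset$adt_ids, clusters, "ADT")
    readr::write_csv(ent, file.path(resd, "entropy_adt.csv"))
    note <- attr(ent, "note")
    list(plot = plot_entropy_histogram(ent, ent_scale, title = "ADT entropy"),
         value = list(median_entropy = median(ent[[ecol]], na.rm = TRUE),
                      n_features = nrow(ent)),
         text = c(sprintf("Median %s entropy across %d ADTs: %.3f.",
                          ent_scale, nrow(ent), median(ent[[ecol]], na.rm = TRUE)),
                  if (!is.null(note)) c("", paste("**Note:**", note))
                  else c("", "A histogram peak at high entropy would suggest the ADT panel lacks cluster specificity.")))
  })

  # --- cross-modality ----------------------------------------------------
  section("RNA vs ADT detection correlation", "rna_adt_read_corr", function() {
    if (!has_adt) abort("dataset has no ADT layer")
    r <- rna_adt_count_correlation(stats_rna, stats_adt, config$n_permutations,
                                   seed = config$seed + 104)
    list(plot = autoplot(r), value = tidy(r),
         text = corr_text(r, paste(
           "The number of assayed proteins should rise with the number of assayed",
           "genes when both layers capture the same cells faithfully.")))
  })

  pairs_global <- NULL
  example_pair <- NULL
  section("Paired UMAP view of an ADT-gene pair", "rna_adt_umap_corr", function() {
    pr <- resolve_adt_pairs(dataset)
    if (nrow(pr) == 0) abort("no mapped ADT-gene pairs")
    example_pair <<- pr[1, ]
    u <- umap_pair_plot(dataset, example_pair$adt_id, example_pair$gene_id,
                        n_pcs = config$n_pcs, seed = config$seed)
    if (!is.null(u$plots)) {
      suppressMessages({
        ggplot2::ggsave(file.path(figs, "rna_adt_umap_rna.png"), u$plots$rna_umap,
                        width = 5, height = 4.5, dpi = 120)
        ggplot2::ggsave(file.path(figs, "rna_adt_umap_scatter.png"),
                        u$plots$scatter, width = 5, height = 4.5, dpi = 120)
      })
    }
    list(plot = if (!is.null(u$plots)) u$plots$adt_umap, value = u$correlation,
         text = c(sprintf(
           "Pair %s / %s: global Spearman rho = %.3f (p = %.3g). Both UMAP panels share one RNA-derived embedding (visualization only).",
           example_pair$adt_id, example_pair$gene_id,
           u$correlation$rho[1], u$correlation$p_value[1]),
           if (!is.null(u$plots))
             c("", "![RNA panel](figures/rna_adt_umap_rna.png)",
               "", "![scatter](figures/rna_adt_umap_scatter.png)")))
  })

  section("Per-cluster pair correlation", "rna_adt_cluster_corr", function() {
    if (is.null(example_pair)) abort("no mapped ADT-gene pairs")
    pc <- pair_correlation(dataset, example_pair$adt_id, example_pair$gene_id,
                           clusters = clusters,
                           n_permutations = config$n_permutations,
                           seed = config$seed + 105)
    readr::write_csv(pc, file.path(resd, "pair_cluster_corr.csv"))
    plt <- ggplot2::ggplot(pc, ggplot2::aes(.data$scope, .data$rho)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = NULL, y = "Spearman rho",
                    title = sprintf("%s vs %s per cluster",
                                    example_pair$adt_id, example_pair$gene_id)) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
    list(plot = plt, value = pc,
         text = "Cluster-restricted concordance of the example pair; clusters with fewer than 3 cells are skipped.")
  })

  section("Pair-correlation histogram", "rna_adt_hist", function() {
    pairs_global <<- all_pairs_correlation(
      dataset, clusters = clusters, n_permutations = config$n_permutations,
      seed = config$seed + 106)
    readr::write_csv(pairs_global, file.path(resd, "pair_correlations.csv"))
    g <- filter(pairs_global, .data$scope == "global")
    unmapped <- attr(pairs_global, "unmapped")
    list(plot = plot_pair_histogram(pairs_global), value = g,
         text = c(sprintf(
           "%d mapped pairs; median global rho = %.3f.", nrow(g), median(g$rho)),
           if (length(unmapped))
             sprintf("Unmapped ADTs (no cognate gene): %s.",
                     paste(unmapped, collapse = ", "))))
  })
  section("Per-cluster pair-correlation histograms", "rna_adt_cluster_hist",
          function() {
    if (is.null(pairs_global)) abort("pair correlations unavailable")
    cl <- filter(pairs_global, .data$scope != "global")
    list(plot = plot_pair_histogram(pairs_global, by_cluster = TRUE),
         value = summarise(group_by(cl, .data$scope),
                           median_rho = median(.data$rho), n_pairs = dplyr::n(),
                           .groups = "drop"),
         text = "Distribution of pair concordance within each cluster; covers every cluster with at least 3 cells.")
  })

  # --- validation / cutoff ----------------------------------------------
  if (config$run_noise) {
    section("Noise injection: correlation degradation", "noise_correlation",
            function() {
      nr <- config$noise_rna %||% noise_config("RNA", seed = config$seed + 201)
      ex <- correlation_degradation_experiment(dataset, nr)
      readr::write_csv(ex$metrics, file.path(resd, "noise_correlation.csv"))
      list(plot = autoplot(ex), value = glance(ex),
           text = "Mean nFeature-nCount correlation should fall as larger fractions of features are shuffled.")
    })
    section("Noise injection: entropy shift", "noise_entropy", function() {
      nr <- config$noise_rna %||% noise_config("RNA", seed = config$seed + 202)
      ex <- entropy_shift_experiment(dataset, nr, resolution = config$resolution)
      readr::write_csv(ex$metrics, file.path(resd, "noise_entropy.csv"))
      readr::write_csv(ex$shifts, file.path(resd, "noise_entropy_shifts.csv"))
      list(plot = autoplot(ex), value = ex$shifts,
           text = "The entropy distribution should shift right (one-sided rank-sum p per adjacent pair of fractions) as corruption grows.")
    })
  }

  if (config$run_specificity) {
    section("Marker specificity cutoff", "specificity", function() {
      null <- sample_null_genes(dataset, clusters, markers,
                                n = config$n_null_genes,
                                min_mean = config$null_min_mean,
                                scale = ent_scale, seed = config$seed + 301)
      cutoff <- entropy_cutoff(null, config$cutoff_percentile)
      need <- marker_genes(markers, top_k = max(config$top_k_list))
      ent_all <- entropy_set(dataset, need, clusters, "RNA")
      call <- classify_markers(markers, ent_all, cutoff,
                               top_k_list = config$top_k_list,
                               scale = ent_scale)
      readr::write_csv(tidy(null), file.path(resd, "null_entropy.csv"))
      readr::write_csv(call$calls, file.path(resd, "specificity_calls.csv"))
      readr::write_csv(call$summary, file.path(resd, "specificity_summary.csv"))
      list(plot = autoplot(call),
           value = list(cutoff = cutoff, summary = call$summary),
           text = c(sprintf(
             "Cutoff at the %gth percentile of %d null (expressed, non-differential) gene entropies: %.4g. Markers strictly below it are called specific.",
             config$cutoff_percentile, null$n, cutoff),
             "",
             paste(sprintf("top %d: %d/%d specific (%.0f%%)",
                           call$summary$top_k, call$summary$n_specific,
                           call$summary$n_markers,
                           100 * call$summary$fraction_specific),
                   collapse = "; ")))
    })
  }

  # --- footer ------------------------------------------------------------
  md <- c(md, "## Reproducibility", "",
          sprintf("- citeqc version: %s",
                  as.character(utils::packageVersion("citeqc"))),
          sprintf("- seed: %d", config$seed),
          sprintf("- entropy scale: %s; permutations: %d; resolution: %g",
                  config$entropy_scale, config$n_permutations, config$resolution),
          if (length(failed)) sprintf("- failed sections: %s",
                                      paste(failed, collapse = "; "))
          else "- all sections completed",
          "")

  report_path <- file.path(out, "report.md")
  writeLines(md, report_path)
  jsonlite::write_json(results, file.path(resd, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(report = report_path, results = results, out_dir = out,
                 failed = failed))
}
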