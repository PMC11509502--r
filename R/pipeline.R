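#' Pipeline run configuration
#'
#' Either real inputs (`intensity_path` + `design_path`, optional
#' `gmt_path`), the synthetic generator (`mode = "synthetic"`), or the
#' deterministic tabled appearance fixture (`mode = "fixture"`,
#' appearance-only: no intensities, so the differential-expression stages
#' are skipped).
#'
#' @param out_dir output directory (created if needed).
#' @param mode `"files"`, `"synthetic"` or `"fixture"`.
#' @param intensity_path,design_path,gmt_path input paths for
#'   `mode = "files"`; `gmt_path` optional.
#' @param synthetic a [synthetic_config()] for `mode = "synthetic"`.
#' @param id_column accession column name in the intensity TSV.
#' @param min_fraction uniqueness threshold (default 0.4).
#' @param transform `"raw"` or `"log2p1"`.
#' @param thresholds overabundance threshold grid.
#' @param seed root seed for all randomness (default 1).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       mode = c("files", "synthetic", "fixture"),
                       intensity_path = NULL, design_path = NULL,
                       gmt_path = NULL,
                       synthetic = synthetic_config(),
                       id_column = "Protein IDs",
                       min_fraction = 0.4,
                       transform = c("raw", "log2p1"),
                       thresholds = default_threshold_grid(),
                       seed = 1L) {
  mode <- match.arg(mode)
  transform <- match.arg(transform)
  if (mode == "files") {
    if (is.null(intensity_path) || is.null(design_path))
      stop("mode 'files' needs intensity_path and design_path")
  } else if (!is.null(intensity_path) || !is.null(design_path)) {
    stop("intensity/design paths conflict with mode '", mode, "'")
  }
  structure(list(out_dir = out_dir, mode = mode,
                 intensity_path = intensity_path,
                 design_path = design_path, gmt_path = gmt_path,
                 synthetic = synthetic, id_column = id_column,
                 min_fraction = min_fraction, transform = transform,
                 thresholds = thresholds, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full paired-proteome analysis pipeline
#'
#' Executes binarization, per-sample inventories, condition-unique
#' detection, three-way paired differential expression, overabundance and
#' PCA, min-rank list construction and (when gene sets are available)
#' ranked-list mHG enrichment. Writes every stage's TSV, static plots
#' (PDF), a machine-readable `summary.json`, and `run.log` into
#' `config$out_dir`. All randomness flows from `config$seed`; two runs with
#' identical config and seed produce byte-identical TSVs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with fields `summary`, `files` (named vector of
#'   written paths), and for synthetic runs `truth`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    writeLines(msg, log_con)
    message(msg)
  }
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  files <- character()
  put <- function(key, path) files[[key]] <<- path

  set.seed(config$seed)
  say("protpair ", as.character(utils::packageVersion("protpair")),
      " | R ", R.version.string)
  say("seed=", config$seed, " mode=", config$mode,
      " min_fraction=", config$min_fraction,
      " transform=", config$transform)

  truth <- NULL
  sets <- NULL
  intensities <- NULL
  if (config$mode == "files") {
    inputs <- stage("load", {
      list(m = read_intensity_table(config$intensity_path,
                                    id_column = config$id_column),
           d = read_design(config$design_path))
    })
    intensities <- inputs$m
    design <- inputs$d
    app <- stage("binarize", binarize(intensities))
    if (!is.null(config$gmt_path)) {
      sets <- stage("load gene sets", read_gene_sets(config$gmt_path))
    } else {
      say("no GMT supplied; enrichment stage will be skipped")
    }
  } else if (config$mode == "synthetic") {
    sim <- stage("simulate", generate_paired_proteome(config$synthetic))
    intensities <- sim$intensities
    design <- sim$design
    truth <- sim$truth
    sets <- stage("simulate annotation sets",
                  generate_annotation_sets(truth, config$synthetic))
    stage("write simulated inputs", {
      put("intensities", write_intensity_table(
        intensities, file.path(config$out_dir, "intensities.tsv"),
        id_column = config$id_column))
      put("design", write_design(design,
                                 file.path(config$out_dir, "design.csv")))
      put("gene_sets", write_gene_sets(
        sets, file.path(config$out_dir, "gene_sets.gmt")))
    })
    app <- stage("binarize", binarize(intensities))
  } else {
    fx <- stage("fixture", build_tables_fixture())
    app <- fx$appearance
    design <- fx$design
    say("fixture mode is appearance-only; differential expression, ",
        "overabundance and enrichment are skipped")
  }

  counts <- stage("per-sample counts", {
    counts <- per_sample_protein_counts(app)
    put("per_sample_counts", write_results_table(
      data.frame(sample_id = names(counts), n_proteins = counts),
      file.path(config$out_dir, "per_sample_counts.tsv")))
    grDevices::pdf(file.path(config$out_dir, "per_sample_counts.pdf"),
                   width = 7, height = 5)
    graphics::barplot(counts, las = 2, cex.names = 0.6,
                      ylab = "proteins observed",
                      main = "Per-sample protein inventory")
    grDevices::dev.off()
    put("per_sample_counts_plot",
        file.path(config$out_dir, "per_sample_counts.pdf"))
    counts
  })

  uniq <- stage("unique proteins", {
    u <- detect_unique_proteins(app, design,
                                min_fraction = config$min_fraction)
    put("unique_proteins", write_results_table(
      u, file.path(config$out_dir, "unique_proteins.tsv")))
    u
  })

  emb <- stage("binary PCA", {
    e <- pca_binary(app, n_components = 3L)
    put("embedding", write_results_table(
      data.frame(sample_id = e$sample_ids,
                 pc1 = e$coordinates[, 1L], pc2 = e$coordinates[, 2L],
                 pc3 = e$coordinates[, 3L]),
      file.path(config$out_dir, "embedding.tsv")))
    put("explained_variance", write_results_table(
      data.frame(component = paste0("pc", 1:3),
                 explained_variance_fraction = e$explained_variance_fractions),
      file.path(config$out_dir, "explained_variance.tsv")))
    grDevices::pdf(file.path(config$out_dir, "pca.pdf"), width = 6,
                   height = 6)
    in_a <- e$sample_ids %in% design$pairs$sample_a
    graphics::plot(e$coordinates[, 1L], e$coordinates[, 2L],
                   col = ifelse(in_a, "firebrick", "navy"), pch = 19,
                   xlab = "PC1", ylab = "PC2",
                   main = "PCA of binary appearance patterns")
    graphics::legend("topright", legend = c(design$condition_a,
                                            design$condition_b),
                     col = c("firebrick", "navy"), pch = 19)
    grDevices::dev.off()
    put("pca_plot", file.path(config$out_dir, "pca.pdf"))
    e
  })

  de <- NULL
  curve <- NULL
  ranked <- NULL
  enr <- NULL
  if (!is.null(intensities)) {
    de <- stage("differential expression", {
      t <- run_differential_expression(intensities, design,
                                       transform = config$transform)
      put("differential_expression", write_results_table(
        t, file.path(config$out_dir, "differential_expression.tsv")))
      t
    })
    curve <- stage("overabundance", {
      cv <- overabundance(de$w_p, thresholds = config$thresholds)
      put("overabundance", write_results_table(
        as.data.frame(cv), file.path(config$out_dir, "overabundance.tsv")))
      grDevices::pdf(file.path(config$out_dir, "overabundance.pdf"),
                     width = 6, height = 5)
      graphics::plot(cv$threshold, cv$ratio, log = "x", type = "b", pch = 19,
                     cex = 0.5, xlab = "p-value threshold",
                     ylab = "observed / expected",
                     main = "Overabundance (Wilcoxon p)")
      graphics::abline(h = 1, lty = 2)
      grDevices::dev.off()
      put("overabundance_plot", file.path(config$out_dir,
                                          "overabundance.pdf"))
      cv
    })
    stage("volcano", {
      v <- volcano_table(de, "wilcoxon")
      grDevices::pdf(file.path(config$out_dir, "volcano.pdf"), width = 6,
                     height = 5)
      graphics::plot(v$effect, v$neg_log10_p, pch = 19, cex = 0.4,
                     col = "grey30", xlab = "median paired difference (A - B)",
                     ylab = "-log10 p (Wilcoxon)", main = "Volcano")
      grDevices::dev.off()
      put("volcano_plot", file.path(config$out_dir, "volcano.pdf"))
    })
    ranked <- stage("min-rank list", {
      r <- min_rank_list(de)
      put("ranked_proteins", write_results_table(
        data.frame(rank = seq_along(r), protein_id = r),
        file.path(config$out_dir, "ranked_proteins.tsv")))
      r
    })
    if (!is.null(sets)) {
      enr <- stage("enrichment", {
        e <- enrich_ranked_list(ranked, sets)
        put("enrichment", write_results_table(
          e, file.path(config$out_dir, "enrichment.tsv")))
        e
      })
    }
  }

  summary <- stage("summary", {
    s <- summarize_run(app = app, design = design, unique_records = uniq,
                       de = de, ranked = ranked)
    jsonlite::write_json(s, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    put("summary", file.path(config$out_dir, "summary.json"))
    s
  })
  say("done; ", length(files), " output files in ", config$out_dir)
  invisible(list(summary = summary, files = files, truth = truth,
                 unique_proteins = uniq, differential = de,
                 enrichment = enr, embedding = emb, curve = curve,
                 per_sample_counts = counts))
}

#' Summarize a pipeline run
#'
#' Builds the machine-readable run summary: proteins observed at least once,
#' per-condition unique-protein counts, observed discovery counts and
#' plug-in FDR estimates at `alpha = 0.01` and `0.05` (Wilcoxon p), and the
#' top 10 min-rank proteins.
#'
#' @param app an [appearance_matrix()].
#' @param design a [paired_design()].
#' @param unique_records output of [detect_unique_proteins()].
#' @param de optional [run_differential_expression()] table.
#' @param ranked optional [min_rank_list()] output.
#' @return A named list (JSON-serializable).
#' @export
summarize_run <- function(app, design, unique_records, de = NULL,
                          ranked = NULL) {
  s <- list(
    n_proteins = length(app$protein_ids),
    n_samples = length(app$sample_ids),
    n_subjects = length(design$subjects),
    n_proteins_observed = sum(rowSums(app$bits) > 0L),
    unique_counts = list())
  for (cond in c(design$condition_a, design$condition_b))
    s$unique_counts[[cond]] <- sum(unique_records$condition == cond)
  if (!is.null(de)) {
    for (a in c(0.01, 0.05)) {
      key <- sprintf("alpha_%g", a)
      s[[paste0("observed_", key)]] <- sum(de$w_p <= a, na.rm = TRUE)
      s[[paste0("fdr_estimate_", key)]] <- fdr_at_threshold(de$w_p, a)
    }
  }
  if (!is.null(ranked))
    s$top_min_rank <- utils::head(ranked, 10L)
  s
}
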