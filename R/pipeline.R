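#' Default pipeline configuration
#'
#' Flat, fully serializable key-value configuration (see [read_config()] /
#' [write_config()]); a run's config plus seed reproduces its result tables
#' bit for bit.
#'
#' @return named list of scenario and analysis parameters.
#' @export
default_config <- function() {
  list(
    n_genes = 200,
    proportions = c(0.2, 0.2, 0.2, 0.1, 0.3),  # SBF,MBF,SFF,SWI5_ACE2,OTHER
    conditions = c("WT", "CDK_ON"),
    dt = 20, total_time = 360, noise_cv = 0.1,
    initial_phase = 0, initial_sd = 0.05, period = 100,
    dispersion_rate = 0.08, bud_phase = 0.25,
    period_grid = seq(40, 240, by = 10),
    alpha = 0.05, n_perm = 199, wt_period = 100,
    peak_ratio = 2, high = 0.6, low = 0.3,
    window_start_frac = 1.25, late_frac = 0.25, slope_tol = 0.1,
    pseudocount = 1,
    seed = 1)
}

config_sync <- function(config) {
  synchrony_model(initial_phase = config$initial_phase,
                  initial_sd = config$initial_sd, period = config$period,
                  dispersion_rate = config$dispersion_rate,
                  bud_phase = config$bud_phase)
}

config_thresholds <- function(config) {
  behavior_thresholds(alpha = config$alpha, peak_ratio = config$peak_ratio,
                      high = config$high, low = config$low,
                      window_start_frac = config$window_start_frac,
                      late_frac = config$late_frac,
                      slope_tol = config$slope_tol)
}

empty_df <- function(...) {
  cols <- list(...)
  as.data.frame(lapply(cols, function(cl) vector(cl, 0)),
                col.names = names(cols), stringsAsFactors = FALSE)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
}

## synthetic TF annotation derived from the generator's regulon memberships
regulon_annotations <- function(models) {
  regs <- vapply(models, function(m) m$regulon, character(1))
  ids <- vapply(models, function(m) m$gene_id, character(1))
  lapply(setdiff(unique(regs), "OTHER"), function(r)
    gene_set_annotation(r, ids[regs == r]))
}

#' Run the full simulation-and-analysis pipeline
#'
#' Executes simulate -> detect -> classify -> enrich -> report for the
#' configured conditions and writes all result tables, a provenance log, and
#' (when the `pheatmap` package is available) heat-map images into `out_dir`.
#' Rerunning with the same config reproduces every table byte for byte; the
#' provenance log is the only file carrying a timestamp.
#'
#' Artifacts: `sim_<cond>.tsv`, `budding_<cond>.tsv`, `calls_WT.tsv`,
#' `consensus.tsv`, `estimates_WT.tsv`, `labels_<cond>.tsv`, `overlap.tsv`,
#' `periods.tsv`, `enrichment_<cond>.tsv`, `annotations_synthetic.gmt`,
#' `ordering.tsv`, `norm_<cond>.tsv`, `config_used.txt`, `provenance.log`.
#'
#' @param config named list as from [default_config()] (partial lists are
#'   merged over the defaults).
#' @param out_dir output directory, created if needed.
#' @param quiet suppress progress messages.
#' @return (invisibly) named list of in-memory results.
#' @export
run_pipeline <- function(config = list(), out_dir, quiet = FALSE) {
  config <- utils::modifyList(default_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[oscarrest] ", ...)
  pth <- function(f) file.path(out_dir, f)

  ## -- simulate -------------------------------------------------------
  sims <- stage("simulate", {
    props <- stats::setNames(config$proportions, REGULONS)
    models <- scenario_gene_models(config$n_genes, props, seed = config$seed)
    sync <- config_sync(config)
    out <- list(models = models, sync = sync, matrices = list(),
                budding = list())
    for (i in seq_along(config$conditions)) {
      cond <- config$conditions[i]
      des <- experiment_design(cond, dt = config$dt,
                               total_time = config$total_time,
                               noise_cv = config$noise_cv,
                               seed = as.integer(config$seed + 101 * i))
      m <- simulate_experiment(models, sync, des)
      b <- simulate_budding(sync, des)
      write_matrix(m, pth(paste0("sim_", cond, ".tsv")))
      write_budding(b, pth(paste0("budding_", cond, ".tsv")))
      out$matrices[[cond]] <- m
      out$budding[[cond]] <- b
    }
    say("simulated ", length(models), " genes x ",
        length(config$conditions), " conditions")
    out
  })

  ## -- detect ---------------------------------------------------------
  det <- stage("detect", {
    wt <- sims$matrices[["WT"]]
    if (is.null(wt)) stop("conditions must include WT")
    res <- call_periodic(wt, config$period_grid, alpha = config$alpha,
                         n_perm = config$n_perm, seed = config$seed)
    write_table_tsv(res$calls, pth("calls_WT.tsv"))
    cons_df <- if (length(res$consensus$gene_ids))
      data.frame(gene_id = res$consensus$gene_ids, stringsAsFactors = FALSE)
    else empty_df(gene_id = "character")
    write_table_tsv(cons_df, pth("consensus.tsv"))
    est <- if (length(res$consensus$gene_ids))
      estimate_periods(wt, res$consensus$gene_ids, config$period_grid)
    else empty_df(gene_id = "character", period = "numeric",
                  peak_time = "numeric", power = "numeric",
                  boundary = "logical")
    write_table_tsv(est, pth("estimates_WT.tsv"))
    say("WT consensus: ", length(res$consensus$gene_ids), " periodic genes")
    list(wt = res, estimates = est)
  })

  ## -- classify -------------------------------------------------------
  arrest_conditions <- setdiff(config$conditions, "WT")
  cls <- stage("classify", {
    thr <- config_thresholds(config)
    labels <- list(); overlaps <- list(); period_rows <- list()
    for (cond in arrest_conditions) {
      m <- sims$matrices[[cond]]
      lab <- classify_matrix(m, config$wt_period, thr, config$period_grid,
                             n_perm = config$n_perm,
                             seed = config$seed)
      write_table_tsv(lab, pth(paste0("labels_", cond, ".tsv")))
      labels[[cond]] <- lab
      res_c <- call_periodic(m, config$period_grid, alpha = config$alpha,
                             n_perm = config$n_perm, seed = config$seed)
      if (length(det$wt$consensus$gene_ids)) {
        ov <- persistence_overlap(det$wt$consensus$gene_ids,
                                  res_c$consensus$gene_ids)
        overlaps[[cond]] <- data.frame(
          condition = cond, wt_set = ov$set_a_size,
          arrest_set = ov$set_b_size, intersection = ov$intersection,
          fraction_of_wt = ov$fraction_of_a, stringsAsFactors = FALSE)
        shared <- intersect(det$wt$consensus$gene_ids,
                            res_c$consensus$gene_ids)
        if (length(shared)) {
          est_c <- estimate_periods(m, shared, config$period_grid)
          cmp <- compare_periods(det$estimates, est_c)
          period_rows[[cond]] <- data.frame(
            condition = cond, median_wt = cmp$median_a,
            median_arrest = cmp$median_b,
            median_abs_diff = cmp$median_abs_diff,
            n_shared = cmp$n_shared, stringsAsFactors = FALSE)
        }
      }
    }
    ov_df <- if (length(overlaps)) do.call(rbind, overlaps)
      else empty_df(condition = "character", wt_set = "integer",
                    arrest_set = "integer", intersection = "integer",
                    fraction_of_wt = "numeric")
    pr_df <- if (length(period_rows)) do.call(rbind, period_rows)
      else empty_df(condition = "character", median_wt = "numeric",
                    median_arrest = "numeric", median_abs_diff = "numeric",
                    n_shared = "integer")
    write_table_tsv(ov_df, pth("overlap.tsv"))
    write_table_tsv(pr_df, pth("periods.tsv"))
    list(labels = labels, overlap = ov_df, periods = pr_df)
  })

  ## -- enrich ---------------------------------------------------------
  enr <- stage("enrich", {
    anns <- regulon_annotations(sims$models)
    write_gene_sets(anns, pth("annotations_synthetic.gmt"))
    universe <- vapply(sims$models, function(m) m$gene_id, character(1))
    out <- list()
    for (cond in arrest_conditions) {
      lab <- cls$labels[[cond]]
      clusters <- split(lab$gene_id, lab$label)
      tab <- cluster_overrepresentation(clusters, anns, universe,
                                        alpha = config$alpha)
      write_table_tsv(tab, pth(paste0("enrichment_", cond, ".tsv")))
      out[[cond]] <- tab
    }
    out
  })

  ## -- report ---------------------------------------------------------
  stage("report", {
    ordering <- order_by_peak_time(sims$matrices[["WT"]]$gene_ids,
                                   det$estimates)
    ord_df <- data.frame(gene_id = as.character(ordering),
                         rank = seq_along(ordering),
                         called = !(ordering %in% attr(ordering, "uncalled")),
                         stringsAsFactors = FALSE)
    write_table_tsv(ord_df, pth("ordering.tsv"))
    for (cond in config$conditions) {
      nm <- log2_relative_to_mean(sims$matrices[[cond]],
                                  pseudocount = config$pseudocount)
      ord_vals <- nm$values[as.character(ordering), , drop = FALSE]
      nm_ord <- time_series_matrix(ord_vals, as.character(ordering),
                                   nm$times, condition = cond,
                                   scale = "log2rel")
      write_matrix(nm_ord, pth(paste0("norm_", cond, ".tsv")))
      render_heatmap(nm_ord, pth(paste0("heatmap_", cond, ".png")))
    }
    NULL
  })

  ## -- provenance -----------------------------------------------------
  write_config(config, pth("config_used.txt"))
  writeLines(c(
    paste0("oscarrest version: ",
           as.character(utils::packageVersion("oscarrest"))),
    paste0("R version: ", R.version.string),
    paste0("seed: ", config$seed),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    "config:",
    paste0("  ", readLines(pth("config_used.txt")))),
    pth("provenance.log"))
  say("done: ", out_dir)
  invisible(list(config = config, sims = sims, detect = det,
                 classify = cls, enrich = enr))
}

## thin presentation layer: image bytes are not part of the analysis surface
render_heatmap <- function(norm_matrix, path) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) return(invisible(NULL))
  tryCatch({
    grDevices::png(path, width = 600, height = 800)
    on.exit(grDevices::dev.off(), add = TRUE)
    pheatmap::pheatmap(norm_matrix$values, cluster_rows = FALSE,
                       cluster_cols = FALSE, show_rownames = FALSE,
                       main = norm_matrix$condition)
  }, error = function(e) invisible(NULL))
  invisible(path)
}
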