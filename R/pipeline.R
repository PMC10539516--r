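#' Pipeline configuration
#'
#' Collects paths, stage toggles and every stage parameter (with the
#' package defaults) into a single list that round-trips losslessly through
#' JSON. Every random operation receives an explicit seed derived from
#' `seed`.
#'
#' @param vcf,meta input VCF and metadata TSV (either both or `simulate`).
#' @param out_dir output directory for stage reports.
#' @param simulate `NULL`, or a [sim_config] to generate the input instead
#'   of reading it.
#' @param simulate_kind `"cohort"` (default) or `"f1family"`: which
#'   generator produces the input when `simulate` is set.
#' @param stages character subset of
#'   `c("filter", "segfilter", "sexscan", "permtest", "assoc", "mapstats")`.
#' @param filter_params,segfilter_params,sexscan_params,permtest_params,assoc_params
#'   named lists of stage parameter overrides.
#' @param maps optional named list of linkage-map TSV paths
#'   (`male`, `female`, `averaged`) for marker placement and map summaries.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf = NULL, meta = NULL, out_dir = "radsexmap_out",
                            simulate = NULL, simulate_kind = "cohort",
                            stages = c("filter", "sexscan", "permtest",
                                       "assoc"),
                            filter_params = list(), segfilter_params = list(),
                            sexscan_params = list(), permtest_params = list(),
                            assoc_params = list(), maps = NULL, seed = 1L) {
  cfg <- list(vcf = vcf, meta = meta, out_dir = out_dir, simulate = simulate,
              simulate_kind = match.arg(simulate_kind, c("cohort", "f1family")),
              stages = stages, filter_params = filter_params,
              segfilter_params = segfilter_params,
              sexscan_params = sexscan_params,
              permtest_params = permtest_params, assoc_params = assoc_params,
              maps = maps, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Save / load a pipeline configuration as JSON
#' @param config a [pipeline_config].
#' @param path JSON path.
#' @return `save_config`: the path, invisibly; `load_config`: the config.
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  if (!is.null(cfg$simulate)) cfg$simulate <- unclass(cfg$simulate)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$simulate)) {
    cfg$simulate <- do.call(sim_config, cfg$simulate[
      setdiff(names(cfg$simulate), character(0))])
  }
  for (f in c("filter_params", "segfilter_params", "sexscan_params",
              "permtest_params", "assoc_params")) {
    if (is.null(cfg[[f]])) cfg[[f]] <- list()
    cfg[[f]] <- as.list(cfg[[f]])
  }
  cfg$stages <- as.character(cfg$stages)
  do.call(pipeline_config, cfg)
}

#' Run the whole pipeline
#'
#' Executes the configured stages in order — simulate (optional), generic
#' marker/sample filters, Mendelian segregation filter (F1 family data),
#' sex-linkage scan, permutation test, association scan, and map placement
#' — writing one TSV/JSON report per stage plus a combined JSON summary
#' under `config$out_dir`. A stage failure aborts with the stage name;
#' completed stage outputs are retained.
#'
#' @param config a [pipeline_config].
#' @return list with per-stage results and `summary` (also written to
#'   `summary.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  summary <- list(seed = config$seed, stages_run = character(0))
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- config$seed
    sim <- stage("simulate", {
      if (config$simulate_kind == "f1family") simulate_f1_family(sim_cfg)
      else simulate_sexed_cohort(sim_cfg)
    })
    x <- sim$matrix
    out$simulate <- sim
    summary$stages_run <- c(summary$stages_run, "simulate")
  } else {
    x <- stage("read", read_genotypes(config$vcf, config$meta))
  }

  if ("filter" %in% config$stages) {
    fr <- stage("filter", do.call(filter_markers,
                                  c(list(x), config$filter_params)))
    x <- filter_samples(fr$matrix)
    x <- dedupe_replicates(x)
    wtsv(fr$report, "filter_report.tsv")
    out$filter <- fr$report
    summary$stages_run <- c(summary$stages_run, "filter")
    summary$markers_after_filter <- nrow(x$geno)
  }

  if ("segfilter" %in% config$stages) {
    sf <- stage("segfilter", do.call(apply_segregation_filter,
                                     c(list(x), config$segfilter_params)))
    x <- sf$matrix
    wtsv(sf$assessments, "segregation_assessments.tsv")
    out$segfilter <- sf
    summary$stages_run <- c(summary$stages_run, "segfilter")
    summary$markers_after_segfilter <- nrow(x$geno)
  }

  adults <- x[, x$samples$role == "adult"]
  if ("sexscan" %in% config$stages) {
    sc <- stage("sexscan", do.call(scan_sex_linkage,
                                   c(list(adults), config$sexscan_params)))
    wtsv(sc$calls, "sexlink_calls.tsv")
    wtsv(sc$summary, "sexlink_summary.tsv")
    out$sexscan <- sc
    summary$stages_run <- c(summary$stages_run, "sexscan")
    summary$sexlink_counts <- stats::setNames(sc$summary$n_hits,
                                              paste0("m", sc$summary$method,
                                                     "_", sc$summary$system))
  }

  if ("permtest" %in% config$stages) {
    pt <- stage("permtest", do.call(run_permutation_test,
                                    c(list(adults, seed = config$seed + 1L),
                                      config$permtest_params)))
    wtsv(as.data.frame(pt), "permutation_summary.tsv")
    out$permtest <- pt
    summary$stages_run <- c(summary$stages_run, "permtest")
  }

  if ("assoc" %in% config$stages) {
    as_res <- stage("assoc", do.call(codominant_association,
                                     c(list(adults), config$assoc_params)))
    wtsv(as_res, "association_results.tsv")
    qq <- qq_observed_expected(as_res$p[!is.na(as_res$p)])
    wtsv(qq, "association_qq.tsv")
    out$assoc <- as_res
    summary$stages_run <- c(summary$stages_run, "assoc")
    summary$n_sex_associated <- sum(as_res$significant)
  }

  if (!is.null(config$maps) && !is.null(out$sexscan)) {
    placed <- stage("mapstats", {
      map <- read_linkage_map(config$maps[[1L]])
      ids <- unique(out$sexscan$calls$id[out$sexscan$calls$id_type == "marker"])
      locate_markers(map, ids)
    })
    wtsv(placed$table, "sex_marker_placement.tsv")
    out$placement <- placed
    summary$stages_run <- c(summary$stages_run, "mapstats")
    if (nrow(placed$summary)) {
      top <- placed$summary[which.max(placed$summary$n_hits), ]
      summary$top_lg <- top$lg
      summary$top_lg_span_cM <- c(top$span_min_cM, top$span_max_cM)
    }
  } else if (!is.null(out$sexscan) && !is.null(out$simulate) &&
             "pos_cM" %in% names(x$markers)) {
    # simulated data carries its own true map
    ids <- unique(out$sexscan$calls$id[out$sexscan$calls$id_type == "marker"])
    idx <- match(ids, x$markers$marker_id)
    idx <- idx[!is.na(idx)]
    if (length(idx)) {
      hits_lg <- x$markers$lg[idx]
      tab <- sort(table(hits_lg), decreasing = TRUE)
      summary$top_lg <- names(tab)[1L]
      on_top <- idx[hits_lg == names(tab)[1L]]
      summary$top_lg_span_cM <- range(x$markers$pos_cM[on_top])
    }
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(c(out, list(summary = summary)))
}
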