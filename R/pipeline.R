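# Orchestration: one config drives simulate/ingest -> heterosis -> DE ->
# classification -> enrichment -> ddCt, writing stage outputs plus a
# machine-readable run report. Fixed seed => byte-identical outputs.

#' Run the full reciprocal-cross analysis pipeline
#'
#' @param config A named list, or the path to a YAML file holding one.
#'   Recognised fields:
#'   \describe{
#'     \item{outdir}{Output directory (required).}
#'     \item{stages}{Character subset of `simulate`, `heterosis`, `de`,
#'       `classify`, `enrich`, `ddct`; default all applicable. An empty
#'       vector yields an empty report.}
#'     \item{seed}{Integer seed for the simulate stage (default 1).}
#'     \item{alpha}{Adjusted-p significance level (default 0.05).}
#'     \item{fpkm_threshold}{Mean-FPKM filter cutoff (default 1).}
#'     \item{t_variant}{Heterosis t reading, `"delta"` or `"sqrt2"`.}
#'     \item{group_map}{Named vector mapping external group labels.}
#'     \item{simulate}{List of [simulation_config()] arguments.}
#'     \item{counts, lengths, samples, phenotypes, gmt, ct_table}{Input
#'       paths when a stage ingests rather than simulates.}
#'     \item{ora_category}{Category fed to enrichment (default `"over"`).}
#'     \item{calibrator_group, reference_gene}{ddCt settings.}
#'   }
#' @return List of class `run_report` (also written to
#'   `outdir/report.json`): per-stage record counts, the echoed config and
#'   package version.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(stages = c("simulate", "heterosis", "de", "classify", "enrich",
                    "ddct"),
         seed = 1L, alpha = 0.05, fpkm_threshold = 1.0,
         t_variant = "delta", group_map = NULL, simulate = list(),
         ora_category = "over", calibrator_group = "P2",
         reference_gene = "GAPDH"),
    config, keep.null = TRUE)
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) stop("alpha must lie in (0, 1)",
                                              call. = FALSE)
  report <- list(package_version = as.character(utils::packageVersion("hetexpress")),
                 config = cfg[setdiff(names(cfg), "group_map")],
                 stages = list())
  if (length(cfg$stages) == 0) {
    class(report) <- "run_report"
    return(report)
  }
  if (is.null(cfg$outdir)) stop("config$outdir is required", call. = FALSE)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name) name %in% cfg$stages
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    out$seconds <- round(proc.time()[["elapsed"]] - t0, 3)
    report$stages[[name]] <<- out
    out
  }

  sim <- NULL; cm <- NULL; samples <- NULL; pheno <- NULL

  if (stage("simulate")) {
    run_stage("simulate", function() {
      scfg <- do.call(simulation_config, utils::modifyList(
        list(seed = cfg$seed), cfg$simulate))
      simdir <- file.path(cfg$outdir, "sim")
      write_simulation(scfg, simdir)
      sim <<- generate_counts(scfg)
      cm <<- sim$counts; samples <<- sim$samples
      pheno <<- generate_phenotypes(scfg)
      list(genes = nrow(cm$counts), samples = ncol(cm$counts),
           phenotype_records = nrow(pheno), outdir = simdir)
    })
  } else {
    if (!is.null(cfg$counts)) {
      cm <- read_count_matrix(cfg$counts, cfg$lengths)
      samples <- read_sample_sheet(cfg$samples, cfg$group_map)
    }
    if (!is.null(cfg$phenotypes))
      pheno <- read_phenotypes(cfg$phenotypes, cfg$group_map)
  }

  if (stage("heterosis") && !is.null(pheno)) {
    run_stage("heterosis", function() {
      sexes <- intersect(c("F", "M"), unique(pheno$sex))
      rep_tab <- do.call(rbind, lapply(sexes, function(sx) {
        r <- heterosis_report(pheno, sx, t_variant = cfg$t_variant)
        cbind(sex = sx, r)
      }))
      utils::write.table(rep_tab, file.path(cfg$outdir, "heterosis.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(rows = nrow(rep_tab),
           significant = sum(rep_tab$p_value < cfg$alpha))
    })
  }

  de <- NULL
  if (stage("de") && !is.null(cm)) {
    run_stage("de", function() {
      de <<- run_contrasts(cm, samples, fpkm_threshold = cfg$fpkm_threshold)
      for (nm in names(de$results)) {
        utils::write.table(de$results[[nm]],
                           file.path(cfg$outdir, paste0("de_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      degs <- vapply(de$results, function(r)
        sum(r$p_adjusted < cfg$alpha), 0L)
      list(genes_in = nrow(cm$counts),
           genes_filtered = de$n_filtered,
           genes_retained = length(de$retained_genes),
           degs_per_contrast = as.list(degs))
    })
  }

  calls <- list()
  if (stage("classify") && !is.null(de)) {
    run_stage("classify", function() {
      out <- list()
      for (cr in c("F1A", "F1B")) {
        cl <- classify_all(de, cr, cfg$alpha)
        calls[[cr]] <<- cl
        utils::write.table(cl,
                           file.path(cfg$outdir, paste0("modes_", cr, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        summ <- aggregate_categories(count_types(cl))
        out[[cr]] <- list(classified = nrow(cl),
                          type_counts = as.list(count_types(cl)),
                          category_counts = as.list(summ$counts),
                          nonadditive_pct = as.list(round(summ$proportions_pct, 2)))
      }
      shared <- shared_category_genes(calls$F1A, calls$F1B, "over")
      writeLines(shared, file.path(cfg$outdir, "shared_over_genes.txt"))
      out$shared_over <- length(shared)
      out
    })
  }

  if (stage("enrich") && !is.null(cfg$gmt) && length(calls) == 2) {
    run_stage("enrich", function() {
      sets <- read_gmt(cfg$gmt)
      universe <- de$retained_genes
      out <- list()
      for (cr in names(calls)) {
        study <- calls[[cr]]$gene_id[calls[[cr]]$category == cfg$ora_category]
        if (length(study) == 0) { out[[cr]] <- list(tested = 0L); next }
        enr <- hypergeom_ora(study, universe, sets)
        utils::write.table(enr,
                           file.path(cfg$outdir, paste0("ora_", cr, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        out[[cr]] <- list(tested = nrow(enr),
                          significant = significant_sets(enr, cfg$alpha))
      }
      out
    })
  }

  if (stage("ddct") && !is.null(cfg$ct_table)) {
    run_stage("ddct", function() {
      ct <- utils::read.delim(cfg$ct_table, stringsAsFactors = FALSE)
      fc <- ddct_fold_change(ct, cfg$calibrator_group, cfg$reference_gene)
      utils::write.table(fc, file.path(cfg$outdir, "fold_changes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(attr(fc, "group_summary"),
                         file.path(cfg$outdir, "fold_change_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(rows = nrow(fc))
    })
  }

  class(report) <- "run_report"
  jsonlite::write_json(unclass(report),
                       file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("hetexpress run report (", length(x$stages), " stage(s))\n", sep = "")
  for (nm in names(x$stages))
    cat(sprintf("  %-10s %ss\n", nm, x$stages[[nm]]$seconds))
  invisible(x)
}
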