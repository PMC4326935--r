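#' Run the full lifespan miRNA expression pipeline
#'
#' Orchestrates input (file-based or simulated), delta-Ct normalization,
#' five-class expression classification, post-adulthood aging analysis,
#' cytoband hot-spot scanning, and transition-pattern calling, writing
#' tabular outputs plus a JSON run summary that echoes every threshold
#' actually applied.
#'
#' `config` is a named list (or path to a YAML file) with fields:
#' \describe{
#'   \item{simulate}{logical; if TRUE, data come from
#'     [generate_dataset()] with overrides under `sim:`.}
#'   \item{ct_table, sample_meta}{input paths (required unless
#'     simulating).}
#'   \item{annotation, cytoband_map}{optional annotation paths; when
#'     simulating, a synthetic annotation with planted hot spots is used
#'     instead.}
#'   \item{control_id}{endogenous-control assay (default `"RNU48"`).}
#'   \item{censored_token, ct_max}{Ct reader settings.}
#'   \item{min_frac, alpha_family, adult_cutoff, bh_q,
#'     cluster_threshold, censor}{analysis parameters with the package
#'     defaults 0.30, 0.05, 35, 0.20, 5, `"impute"`.}
#'   \item{out_dir}{output directory; omit to skip writing files.}
#'   \item{seed}{simulation seed override.}
#' }
#'
#' @param config Named list or YAML path.
#' @param out_dir Output directory override.
#' @return Invisibly, a `run_report` list with elements `classes`,
#'   `summary`, `aging`, `band_table`, `hotspots`, `patterns`, `truth`
#'   (simulation only), and `config` (the effective settings).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config error: expected a list or a YAML path")
  defaults <- list(simulate = FALSE, control_id = "RNU48",
                   censored_token = "Undetermined", ct_max = 40,
                   min_frac = 0.30, alpha_family = 0.05, adult_cutoff = 35,
                   bh_q = 0.20, cluster_threshold = 5, censor = "impute",
                   groups = c("preterm", "adult"), seed = 1L,
                   out_dir = NULL, annotation = NULL, cytoband_map = NULL)
  cfg <- utils::modifyList(defaults, config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  num_ok <- function(x, lo, hi) is.numeric(x) && length(x) == 1 && x >= lo && x <= hi
  if (!num_ok(cfg$min_frac, 0, 1)) stop("config error: min_frac must lie in [0, 1]")
  if (!num_ok(cfg$alpha_family, 0, 1)) stop("config error: alpha_family must lie in (0, 1]")
  if (!num_ok(cfg$bh_q, 0, 1)) stop("config error: bh_q must lie in (0, 1)")

  loci <- NULL; truth <- NULL
  if (isTRUE(cfg$simulate)) {
    sim_args <- if (is.list(cfg$sim)) cfg$sim else list()
    if (!is.null(cfg$seed) && is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    sim_cfg <- do.call(simulation_config, sim_args)
    sim <- stage("simulate", generate_dataset(sim_cfg))
    ct <- sim$ct; meta <- sim$meta; truth <- sim$truth
    loci <- stage("simulate", generate_annotation(truth))
  } else {
    for (f in c("ct_table", "sample_meta")) {
      if (is.null(cfg[[f]]))
        stop("config error: '", f, "' is required unless simulate: true")
      if (!file.exists(cfg[[f]]))
        stop("config error: ", f, " path does not exist: ", cfg[[f]])
    }
    for (f in c("annotation", "cytoband_map"))
      if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
        stop("config error: ", f, " path does not exist: ", cfg[[f]])
    ct <- stage("read", read_ct_table(cfg$ct_table,
                                      censored_token = cfg$censored_token,
                                      ct_max = cfg$ct_max))
    meta <- stage("read", read_sample_meta(cfg$sample_meta))
    stage("read", validate_sample_meta(meta, ct))
    if (!is.null(cfg$annotation))
      loci <- stage("annotation",
                    load_annotation(cfg$annotation,
                                    cytoband_map = cfg$cytoband_map))
  }

  delta <- stage("normalize", delta_ct(ct, control_id = cfg$control_id))
  classes <- stage("classify",
                   assign_expression_classes(delta, meta, groups = cfg$groups,
                                             min_frac = cfg$min_frac,
                                             alpha_family = cfg$alpha_family,
                                             censor = cfg$censor))
  summ <- classification_summary(classes)

  aging <- NULL
  if (sum(meta$group == "adult") >= 4L)
    aging <- stage("aging",
                   aging_analysis(delta, meta, cutoff = cfg$adult_cutoff,
                                  q = cfg$bh_q, min_frac = cfg$min_frac,
                                  censor = cfg$censor))

  band_table <- NULL; hotspots <- NULL
  if (!is.null(loci)) {
    band_table <- stage("hotspots", chromosome_class_table(classes, loci))
    hotspots <- stage("hotspots",
                      find_hotspots(band_table,
                                    cluster_threshold = cfg$cluster_threshold))
  }

  patterns <- NULL
  if (any(meta$group == "child") && any(meta$group == "preterm") &&
      sum(meta$group == "adult") >= 4L) {
    detectable <- classes$mirna_id[classes$class != "nonexpressed"]
    patterns <- stage("patterns",
                      transition_patterns(delta, meta, mirnas = detectable,
                                          cutoff = cfg$adult_cutoff,
                                          min_frac = cfg$min_frac))
  }

  report <- structure(
    list(classes = classes, summary = summ, aging = aging,
         band_table = band_table, hotspots = hotspots, patterns = patterns,
         truth = truth, config = cfg),
    class = "run_report")
  if (!is.null(cfg$out_dir)) stage("write", write_report(report, cfg$out_dir))
  invisible(report)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) utils::write.table(as.data.frame(x),
                                           file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  tsv(report$classes, "classes.tsv")
  if (!is.null(report$aging)) tsv(report$aging, "aging.tsv")
  if (!is.null(report$hotspots)) tsv(report$hotspots, "hotspots.tsv")
  if (!is.null(report$patterns)) tsv(report$patterns, "patterns.tsv")
  cfg <- report$config
  counts <- table(report$classes$class)
  summary <- list(
    panel_size = report$summary$panel_size,
    n_detectable = attr(report$classes, "n_detectable"),
    n_differential = report$summary$n_differential,
    class_counts = as.list(stats::setNames(as.integer(counts), names(counts))),
    thresholds = list(
      min_frac = cfg$min_frac,
      alpha_family = cfg$alpha_family,
      alpha_per_test = attr(report$classes, "alpha_per_test"),
      adult_cutoff = cfg$adult_cutoff,
      bh_q = cfg$bh_q,
      bh_universe = if (!is.null(report$aging)) attr(report$aging, "universe_size"),
      bh_cutoff = if (!is.null(report$aging)) attr(report$aging, "bh_cutoff"),
      bh_n_pass = if (!is.null(report$aging)) attr(report$aging, "n_pass"),
      cluster_threshold = cfg$cluster_threshold,
      censor = cfg$censor),
    seed = cfg$seed,
    version = as.character(utils::packageVersion("mirlifespan")))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("mirlifespan run report\n")
  cat(sprintf("  panel: %d miRNAs, %d detectable, per-test alpha %.3g\n",
              x$summary$panel_size, attr(x$classes, "n_detectable"),
              attr(x$classes, "alpha_per_test")))
  print(x$summary$table, row.names = FALSE, digits = 3)
  if (!is.null(x$aging))
    cat(sprintf("  aging: %d BH discoveries (crude-p cutoff %.4g, universe %d)\n",
                attr(x$aging, "n_pass"), attr(x$aging, "bh_cutoff"),
                attr(x$aging, "universe_size")))
  if (!is.null(x$hotspots))
    cat(sprintf("  hot spots: %d\n", nrow(x$hotspots)))
  invisible(x)
}
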