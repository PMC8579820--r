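#' Config-driven analysis pipelines
#'
#' `run_signal()` chains tree + trait-table input into the per-variable
#' phylogenetic-signal and model-comparison report; `run_biogeo()` fits a
#' set of range-evolution models, compares nested pairs, writes per-node
#' marginal range probabilities and optionally summarises biogeographic
#' stochastic mappings under the best model. Both accept a config as a
#' YAML file path or an R list, write CSV outputs with a provenance
#' header (config hash, seed, package version) and return their results
#' invisibly-readable as a list.
#'
#' Config fields for `run_signal`: `tree` (Newick path), `traits` (CSV
#' path with a `species` column), `out_dir`.
#' For `run_biogeo`: `tree`, `geography` (lagrange-style path), `epochs`
#' (YAML path), `models` (character vector; default all six), `out_dir`,
#' `seed`, and optionally `bsm_n` (> 0 runs stochastic mapping under the
#' AIC-best model).
#'
#' @param config a list or a path to a YAML file.
#' @return `run_signal`: the report data frame. `run_biogeo`: list with
#'   `fits`, `comparison`, `marginals` and (optionally) `bsm`.
#' @name pipelines
NULL

load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  config
}

check_paths <- function(config, fields) {
  for (f in fields) {
    if (is.null(config[[f]])) stop("config lacks required field '", f, "'")
    if (!file.exists(config[[f]]))
      stop("config path '", f, "' does not exist: ", config[[f]])
  }
}

provenance_header <- function(config, seed = NULL) {
  h <- sum(utf8ToInt(paste(deparse(config), collapse = "")) *
             seq_along(utf8ToInt(paste(deparse(config), collapse = "")))) %%
    .Machine$integer.max
  c(sprintf("# nicherange %s", as.character(utils::packageVersion("nicherange"))),
    sprintf("# config_hash %d", h),
    sprintf("# seed %s", if (is.null(seed)) "NA" else as.character(seed)))
}

write_report_csv <- function(df, file, header) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}

#' @rdname pipelines
#' @export
run_signal <- function(config) {
  config <- load_config(config)
  check_paths(config, c("tree", "traits"))
  tree <- parse_newick(file = config$tree)
  traits <- utils::read.csv(config$traits, stringsAsFactors = FALSE)
  if (!"species" %in% names(traits)) stop("trait table lacks a 'species' column")
  if (ncol(traits) < 2 || nrow(traits) == 0) stop("trait table is empty")
  report <- signal_report(tree, traits)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_csv(report, file.path(config$out_dir, "signal_report.csv"),
                     provenance_header(config))
  }
  report
}

#' @rdname pipelines
#' @export
run_biogeo <- function(config) {
  config <- load_config(config)
  check_paths(config, c("tree", "geography", "epochs"))
  models <- if (is.null(config$models)) biogeo_model_kinds
            else unlist(config$models)
  bad <- setdiff(models, biogeo_model_kinds)
  if (length(bad))
    stop("unknown model(s): ", paste(bad, collapse = ", "),
         "; valid names: ", paste(biogeo_model_kinds, collapse = ", "))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  tree <- parse_newick(file = config$tree, require_bifurcating = TRUE)
  geo <- read_geography(config$geography)
  epochs <- read_epochs(config$epochs)
  if (epochs$boundaries[1] < tree$root_age)
    stop("epochs do not cover the tree: oldest boundary ",
         epochs$boundaries[1], " Ma < root age ", tree$root_age, " Ma")
  fits <- lapply(models, function(m)
    fit_biogeo(tree, geo$ranges, m, epochs))
  names(fits) <- models
  comparison <- if (sum(grepl("\\+J$", models)) > 0)
    compare_biogeo_models(fits) else NULL
  aics <- vapply(fits, function(f) f$AIC, numeric(1))
  best <- fits[[which.min(aics)]]
  n <- tree$n_tips
  marg <- data.frame(node = seq_len(n + tree$phy$Nnode),
                     best$marginals, check.names = FALSE)
  out <- list(fits = fits, comparison = comparison, marginals = marg,
              best = best$kind)
  if (!is.null(config$bsm_n) && config$bsm_n > 0) {
    bsm <- run_bsm(best, n = config$bsm_n, seed = seed)
    out$bsm <- bsm$summary
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- provenance_header(config, seed)
    if (!is.null(comparison))
      write_report_csv(comparison,
                       file.path(config$out_dir, "model_comparison.csv"), hdr)
    write_report_csv(marg, file.path(config$out_dir, "node_marginals.csv"), hdr)
    if (!is.null(out$bsm))
      write_report_csv(out$bsm, file.path(config$out_dir, "bsm_summary.csv"),
                       hdr)
  }
  out
}
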