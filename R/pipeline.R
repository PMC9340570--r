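#' Run the full sparsity-selection pipeline
#'
#' Executes (optionally) simulate, then infer, select, and — when a
#' gold-standard network is available — evaluate, writing every intermediate
#' artifact plus a JSON manifest into `outdir`. The run is deterministic for
#' a fixed config and seed.
#'
#' `config` is a named list (or a path to a JSON file holding one) with:
#' \describe{
#'   \item{simulate}{optional list: `n_genes`, `sparsity`, `tf_fraction`,
#'     `replicates`, `snr` (or `noise` = "low"/"high"); when present the
#'     expression, design and truth are generated rather than read.}
#'   \item{expr, design, truth}{TSV paths (truth optional), used when
#'     `simulate` is absent.}
#'   \item{method}{"lasso", "ridge" or "tree".}
#'   \item{min_lpg, max_lpg}{sweep bounds in links per gene (default 1, 5).}
#'   \item{seed}{integer; recorded in the manifest.}
#' }
#'
#' @param config named list or path to a JSON config file.
#' @param outdir output directory (created if missing).
#' @return the manifest as a list, invisibly; written to
#'   `outdir/manifest.json` along with `curves.tsv` and the selected
#'   network's edge list.
#' @export
run_pipeline <- function(config, outdir = ".") {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  method <- match.arg(config$method %||% "lasso", c("lasso", "ridge", "tree"))
  min_lpg <- config$min_lpg %||% 1
  max_lpg <- config$max_lpg %||% 5
  if (min_lpg > max_lpg) abort("min_lpg must be <= max_lpg")
  seed <- config$seed %||% 1L
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    snr <- sim$snr %||% snr_preset(sim$noise %||% "low")
    inform(sprintf("stage=simulate genes=%s sparsity=%s replicates=%s snr=%s",
                   sim$n_genes %||% 100, sim$sparsity %||% 1.75,
                   sim$replicates %||% 3, snr))
    truth <- generate_true_network(
      n_genes = sim$n_genes %||% 100,
      sparsity = sim$sparsity %||% 1.75,
      tf_fraction = sim$tf_fraction %||% 0.53,
      seed = seed)
    design <- make_design(nrow(truth), sim$replicates %||% 3,
                          genes = rownames(truth))
    y <- add_noise(simulate_expression(truth, design), snr = snr,
                   seed = seed + 1L)
    write_network(truth, file.path(outdir, "truth.tsv"))
    write_matrix(design, file.path(outdir, "design.tsv"))
    write_matrix(y, file.path(outdir, "expression.tsv"))
  } else {
    if (is.null(config$expr) || is.null(config$design)) {
      abort("config needs either `simulate` or both `expr` and `design` paths")
    }
    y <- read_matrix(config$expr)
    design <- read_matrix(config$design)
    if (!is.null(config$truth)) {
      truth <- read_network(config$truth, genes = rownames(y))
    }
  }

  inform(sprintf("stage=infer method=%s shape=%dx%d range=[%s,%s]",
                 method, nrow(y), ncol(y), min_lpg, max_lpg))
  sweep <- switch(method,
    lasso = infer_lasso_sweep(y, design, min_lpg, max_lpg),
    ridge = infer_ridge_sweep(y, design, min_lpg, max_lpg),
    tree = infer_tree_sweep(y, min_lpg = min_lpg, max_lpg = max_lpg,
                            seed = seed))

  inform(sprintf("stage=select candidates=%d", length(sweep)))
  result <- grnic_scores(sweep, design, y)
  readr::write_tsv(result$table, file.path(outdir, "curves.tsv"),
                   progress = FALSE)
  write_network(sweep$candidates[[result$selected_index]],
                file.path(outdir, "selected_network.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("grnic")),
    seed = seed,
    config = config[setdiff(names(config), "seed")],
    method = method,
    n_genes = result$n_genes,
    n_candidates = length(sweep),
    selected_index = result$selected_index,
    selected_link_count = result$selected_link_count,
    selected_sparsity = result$selected_sparsity)

  if (!is.null(truth)) {
    inform("stage=evaluate")
    ev <- evaluate_sweep(sweep, truth, result)
    readr::write_tsv(ev$table, file.path(outdir, "evaluation.tsv"),
                     progress = FALSE)
    manifest$selected_f1 <- ev$selected_f1
    manifest$max_f1 <- ev$max_f1
    manifest$sparsity_true <- ev$sparsity_true
    manifest$sparsity_max_f1 <- ev$sparsity_max_f1
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
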