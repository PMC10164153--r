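#' Run the full prediction pipeline from a configuration
#'
#' Executes the stages in order -- data loading (or synthetic generation),
#' similarity construction, restart-random-walk diffusion, stacked
#' autoencoder attribute features, feature integration, scoring, and
#' optionally cross-validation -- and writes the score matrix, ranked pair
#' list, CV results and a run manifest to \code{out_dir}. Fails fast with a
#' stage-tagged error.
#'
#' @param config a named list (or path to a YAML file mirroring it) with
#'   elements:
#'   \describe{
#'     \item{input}{either \code{list(associations = path, format = ...)}
#'       or \code{list(synthetic = list(...))} with [synthetic_spec()]
#'       fields.}
#'     \item{drug_structural_csv, microbe_functional_csv}{optional labeled
#'       square similarity CSVs; cosine fallback used when absent.}
#'     \item{seed}{integer master seed (default 42).}
#'     \item{rwr, sae}{optional overrides of [rwr_config()] /
#'       [sae_config()] fields.}
#'     \item{cv}{optional overrides of [cv_config()] fields; CV is skipped
#'       when \code{config$cv} is \code{NULL} and \code{run_cv} is FALSE.}
#'     \item{run_cv}{logical, run cross-validation (default TRUE).}
#'     \item{ablation}{logical, also run the attention ablation.}
#'     \item{out_dir}{output directory; created if missing. \code{NULL}
#'       skips all file output.}
#'   }
#' @return list: \code{dataset}, \code{scores} (\code{mda_scores}),
#'   \code{ranked} (top pairs), \code{cv} (\code{mda_cv_result} or NULL),
#'   \code{ablation} (or NULL), \code{manifest}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_mdassoc("reading YAML configs requires the yaml package",
                   "mdassoc_io_error")
    }
    config <- yaml::read_yaml(config)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_mdassoc(paste0("[stage ", name, "] ", conditionMessage(e)),
                   class(e)[1])
    })
  }
  seed <- if (is.null(config$seed)) 42L else as.integer(config$seed)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  # -- data ----------------------------------------------------------------
  loaded <- stage("data_io", {
    inp <- config$input
    if (is.null(inp)) stop("config$input is required")
    if (!is.null(inp$synthetic)) {
      sp <- do.call(synthetic_spec, inp$synthetic)
      gen <- generate_synthetic(sp)
      list(ds = gen$dataset,
           truth = gen[c("drug_blocks", "microbe_blocks")])
    } else if (!is.null(inp$associations)) {
      ds <- load_associations(
        inp$associations,
        format = if (is.null(inp$format)) "auto" else inp$format,
        header = !isFALSE(inp$header))
      list(ds = ds, truth = NULL)
    } else {
      stop("config$input must name `associations` or `synthetic`")
    }
  })
  ds <- loaded$ds
  truth <- loaded$truth
  Sr <- stage("data_io", {
    if (is.null(config$drug_structural_csv)) NULL else
      load_similarity(config$drug_structural_csv, "drug", "structural",
                      ds$drug_ids)
  })
  Fm <- stage("data_io", {
    if (is.null(config$microbe_functional_csv)) NULL else
      load_similarity(config$microbe_functional_csv, "microbe", "functional",
                      ds$microbe_ids)
  })
  timings["data_io"] <- tic() - t0

  pipeline <- pipeline_config(
    rwr = do.call(rwr_config, config$rwr %||% list()),
    sae = do.call(sae_config, config$sae %||% list()),
    standardize = isTRUE(config$standardize)
  )

  # -- full-data scoring ---------------------------------------------------
  t1 <- tic()
  res <- stage("scoring", compute_scores(ds$S, pipeline, Sr = Sr, Fm = Fm,
                                         seed = seed))
  ranked <- rank_pairs(res$scores, ds, exclude_known = TRUE,
                       top_n = config$top_n %||% 100L)
  timings["scoring"] <- tic() - t1

  # -- cross-validation ----------------------------------------------------
  cv_res <- NULL; abl <- NULL
  if (!isFALSE(config$run_cv)) {
    t2 <- tic()
    cvc <- do.call(cv_config, utils::modifyList(list(seed = seed),
                                                config$cv %||% list()))
    if (isTRUE(config$ablation)) {
      abl <- stage("evaluation",
                   ablation_attention(ds, pipeline, cvc, Sr = Sr, Fm = Fm))
      cv_res <- abl$with_attention
    } else {
      cv_res <- stage("evaluation", run_cv(ds, pipeline, cvc, Sr = Sr, Fm = Fm))
    }
    timings["evaluation"] <- tic() - t2
  }

  manifest <- list(
    package = "mdassoc",
    version = as.character(utils::packageVersion("mdassoc")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config[setdiff(names(config), "out_dir")],
    fallback = as.list(res$fallback),
    input_digests = local({
      paths <- c(config$input$associations, config$drug_structural_csv,
                 config$microbe_functional_csv)
      paths <- paths[!vapply(paths, is.null, logical(1))]
      lapply(stats::setNames(paths, paths),
             function(p) unname(tools::md5sum(p)))
    }),
    stage_seconds = as.list(round(timings, 3)),
    n_drugs = length(ds$drug_ids),
    n_microbes = length(ds$microbe_ids),
    n_associations = sum(ds$S)
  )
  if (!is.null(cv_res)) {
    manifest$cv <- list(k = cv_res$config$cv$k,
                        mean_auc = cv_res$mean_auc,
                        std_auc = cv_res$std_auc,
                        per_fold_auc = cv_res$per_fold_auc)
  }
  if (!is.null(abl)) {
    manifest$ablation <- list(mean_delta = abl$mean_delta,
                              per_fold_delta = abl$per_fold_delta,
                              mean_auc_without = abl$without_attention$mean_auc)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    utils::write.csv(res$scores$values, file.path(od, "scores.csv"),
                     row.names = TRUE)
    utils::write.table(ranked, file.path(od, "ranked_pairs.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    if (!is.null(cv_res)) {
      jsonlite::write_json(manifest$cv, file.path(od, "cv.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  list(dataset = ds, scores = res$scores, ranked = ranked, cv = cv_res,
       ablation = abl, truth = truth, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
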