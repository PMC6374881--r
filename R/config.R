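#' Default pipeline configuration
#'
#' A nested list mirroring the YAML config file accepted by
#' [run_pipeline()].  Defaults reflect the benchmark-scale settings:
#' dictionary sizes 30/50/70 (150-dim fused vector), window size 35,
#' PCA dimension 60, SMOTE off, single RBF SVM configuration.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    paths = list(fasta = NULL, manifest = NULL, outdir = NULL),
    window = list(size = NULL, stride = 1L),
    sparse = list(K_list = c(30L, 50L, 70L), t0 = 5L, max_iter = 30L,
                  tol = 1e-4, seed = 1L),
    fusion = list(pooling = "mean", pca_dim = 60L, pca_scope = "global"),
    smote = list(mode = "off", k = 5L, seed = 1L, rounding = "half_up",
                 target_counts = NULL),
    classifier = list(kernel = "radial", cost = 10, gamma = "scale",
                      grid = FALSE, seed = 1L))
}

#' Read a YAML pipeline configuration
#'
#' Keys present in the file override [default_config()]; missing keys
#' keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return Nested configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_into <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge_into(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  merge_into(default_config(), user)
}

#' Run the full pipeline from a configuration
#'
#' Loads (or accepts) a dataset, fits the multilayer sparse-coding model
#' with [sparseloc_fit()], evaluates it by jackknife, and — when
#' `config$paths$outdir` is set — writes the fused feature table, the
#' dictionaries, the PCA model, the augmented table and the evaluation
#' report as plain-text artifacts, plus a run manifest with the seeds
#' and shapes of every stage.
#'
#' @param config Nested list as from [default_config()] /
#'   [read_config()].
#' @param dataset Optional [subloc_dataset]; when `NULL` it is loaded
#'   from `config$paths`.
#' @return The `"evaluation_report"`, with the fitted model attached as
#'   attribute `"model"`.
#' @export
run_pipeline <- function(config = default_config(), dataset = NULL) {
  if (is.null(dataset)) {
    if (is.null(config$paths$fasta) || is.null(config$paths$manifest))
      stop("stage load: no dataset given and no fasta/manifest paths in config")
    dataset <- load_dataset(config$paths$fasta, config$paths$manifest)
  }
  svm <- if (isTRUE(config$classifier$grid)) "grid"
         else svm_config(config$classifier$kernel, config$classifier$cost,
                         config$classifier$gamma)
  model <- sparseloc_fit(
    dataset,
    window_size = config$window$size, stride = config$window$stride,
    K_list = config$sparse$K_list, t0 = config$sparse$t0,
    max_iter = config$sparse$max_iter, ksvd_tol = config$sparse$tol,
    pca_dim = config$fusion$pca_dim, pooling = config$fusion$pooling,
    smote = if (config$smote$mode == "off") "off" else "global",
    smote_k = config$smote$k, smote_rounding = config$smote$rounding,
    target_counts = config$smote$target_counts,
    svm = svm, seed = config$sparse$seed)
  scope <- if (config$fusion$pca_scope == "strict" ||
               config$smote$mode == "strict") "strict" else "global"
  report <- sparseloc_jackknife(model, scope)

  outdir <- config$paths$outdir
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    ft <- model$features
    utils::write.table(
      data.frame(sequence_id = ft$ids, label = ft$labels,
                 synthetic = ft$synthetic, ft$scores),
      file.path(outdir, "features_pca.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    for (dct in model$dictionaries)
      write_dictionary(dct, file.path(outdir,
                                      sprintf("dictionary_K%d.tsv", dct$K)))
    write_pca(model$pca, file.path(outdir, "pca_model.tsv"))
    write_report(report, tsv = file.path(outdir, "report.tsv"),
                 json = file.path(outdir, "report.json"))
    manifest <- list(
      window = model$window[c("size", "stride")],
      K_list = model$K_list, t0 = model$t0,
      pca_dim = model$pca$retained_dim, smote = model$smote$mode,
      svm = list(kernel = model$svm_config$kernel,
                 cost = model$svm_config$cost),
      seed = model$seed, n_sequences = length(ft$ids),
      n_synthetic = sum(ft$synthetic),
      fused_dim = ncol(ft$fused), scope = scope)
    jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  attr(report, "model") <- model
  report
}

#' Sweep one pipeline parameter and record the jackknife accuracy
#'
#' Re-runs [run_pipeline()] for each candidate value of `window_size` or
#' `pca_dim`, holding everything else fixed — the accuracy-vs-parameter
#' curves used to pick the operating point.
#'
#' @param config Base configuration.
#' @param parameter `"window_size"` or `"pca_dim"`.
#' @param values Candidate values; illegal ones are skipped with a
#'   warning and reported as `NA`.
#' @param dataset Optional pre-loaded dataset.
#' @return Data frame with columns `value` and `OA`.
#' @export
sweep_parameter <- function(config, parameter = c("window_size", "pca_dim"),
                            values, dataset = NULL) {
  parameter <- match.arg(parameter)
  if (is.null(dataset))
    dataset <- load_dataset(config$paths$fasta, config$paths$manifest)
  bounds <- window_bounds(dataset)
  config$paths$outdir <- NULL
  oa <- vapply(values, function(v) {
    if (parameter == "window_size") {
      if (v < bounds[["low"]] || v > bounds[["high"]]) {
        warning("window_size ", v, " outside admissible range ",
                bounds[["low"]], "..", bounds[["high"]], "; skipped")
        return(NA_real_)
      }
      config$window$size <- v
    } else {
      if (v < 1 || v > sum(config$sparse$K_list)) {
        warning("pca_dim ", v, " out of range; skipped")
        return(NA_real_)
      }
      config$fusion$pca_dim <- v
    }
    run_pipeline(config, dataset)$overall_accuracy
  }, numeric(1))
  data.frame(value = values, OA = oa)
}

#' Serialize a dictionary as TSV
#'
#' Metadata (K, t0, seed, iterations) goes into `#`-prefixed header
#' lines; the atom matrix follows, one atom per row.
#'
#' @param dictionary A [sparse_dictionary()].
#' @param path Output path.
#' @export
write_dictionary <- function(dictionary, path) {
  stopifnot(inherits(dictionary, "sparse_dictionary"))
  hdr <- sprintf("# K\t%d\n# t0\t%s\n# seed\t%s\n# iterations\t%d",
                 dictionary$K, dictionary$t0, dictionary$seed,
                 dictionary$iterations)
  writeLines(hdr, path)
  utils::write.table(dictionary$D, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, append = TRUE)
  invisible(dictionary)
}

#' Read a dictionary serialized by [write_dictionary()]
#' @param path Path to the TSV file.
#' @return A [sparse_dictionary()].
#' @export
read_dictionary <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  val <- function(key) {
    strsplit(meta[grepl(paste0("^# ", key, "\t"), meta)], "\t")[[1]][2]
  }
  D <- as.matrix(utils::read.table(text = lines[!startsWith(lines, "#")],
                                   sep = "\t"))
  dimnames(D) <- NULL
  sparse_dictionary(D, t0 = as.integer(val("t0")),
                    iterations = as.integer(val("iterations")),
                    seed = as.integer(val("seed")))
}

#' Serialize a PCA model as TSV
#' @param model A `"pca_model"`.
#' @param path Output path.
#' @export
write_pca <- function(model, path) {
  stopifnot(inherits(model, "pca_model"))
  writeLines(sprintf("# retained_dim\t%d", model$retained_dim), path)
  utils::write.table(rbind(model$mean, model$components), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     append = TRUE)
  invisible(model)
}
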