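#' Run a declarative decoding experiment
#'
#' Executes the full pipeline -- simulate, split, whiten, train, evaluate,
#' optional sliding-window and permutation-importance analyses, paired
#' statistics across replicates -- from a single configuration, and writes
#' all tables plus a manifest (seeds, configuration, versions) to
#' `out_dir`. Reruns with an identical configuration produce identical
#' result tables. Each replicate is a freshly simulated dataset with its
#' own seed and plays the role of one subject in the paired signed-rank
#' comparisons.
#'
#' Configuration fields (YAML file or list; all optional):
#' \describe{
#'   \item{dataset}{`type` (a [benchmark_config()] name, or `"custom"` to
#'     build a plain [sim_config()]) plus any [sim_config()] overrides;
#'     `patterns` entries may be [planted_pattern()]s or plain lists of
#'     their arguments.}
#'   \item{replicates, seed}{number of simulated datasets; base seed
#'     (replicate r uses `seed + r - 1`).}
#'   \item{methods}{subset of `"lda_nn"`, `"lda_pca"`, `"nn"`.}
#'   \item{whiten, n_components, split_ratio, shrinkage}{pipeline knobs.}
#'   \item{nn}{[nn_config()] overrides.}
#'   \item{window_ms}{sliding-window length for the windowed analysis.}
#'   \item{analyses}{subset of `"windowed"`, `"pfi_temporal"`,
#'     `"pfi_spatial"`, `"pfi_spectral"`, `"pfi_temporospectral"`.}
#'   \item{pfi}{`n_permutations` for the importance runs.}
#' }
#'
#' @param config path to a YAML file, or an equivalent list.
#' @param out_dir output directory.
#' @param verbose print progress.
#' @return (invisibly) list with `accuracies` (data.frame), `stats`,
#'   `timecourses`, `pfi`, `manifest`.
#' @export
run_experiment <- function(config, out_dir, verbose = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    dataset = list(type = "standard"), replicates = 1L, seed = 1L,
    methods = c("lda_nn", "lda_pca"), whiten = TRUE, n_components = 16L,
    split_ratio = 0.2, shrinkage = "auto",
    nn = list(n_components = 16L, h1 = 256L, h2 = 48L, n_epochs = 300L),
    window_ms = 100, analyses = "windowed",
    pfi = list(n_permutations = 10L)
  )
  cfg <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  acc_rows <- list(); tc_rows <- list(); pfi_maps <- list()
  k <- NULL; n_val <- NULL
  for (r in seq_len(cfg$replicates)) {
    seed_r <- cfg$seed + r - 1L
    ds_args <- cfg$dataset; type <- ds_args$type %||% "standard"
    ds_args$type <- NULL
    if (!is.null(ds_args$patterns))
      ds_args$patterns <- lapply(ds_args$patterns, function(p)
        if (inherits(p, "planted_pattern")) p else
          do.call(planted_pattern, p))
    sim <- if (type == "custom")
      do.call(sim_config, c(list(seed = seed_r), ds_args))
    else
      do.call(benchmark_config, c(list(type = type, seed = seed_r),
                                  ds_args))
    gen <- generate_epochs(sim)
    ep <- gen$epochs
    split <- stratified_split(ep$labels, cfg$split_ratio, seed = seed_r)
    if (is.null(k)) {
      k <- n_classes(ep)
      n_val <- length(split$validation)
    }
    if (verbose) message("replicate ", r, ": ", type, " dataset, ",
                         length(split$train), "/",
                         length(split$validation), " split")

    nn_cfg <- do.call(nn_config, utils::modifyList(cfg$nn,
                                                   list(seed = seed_r)))
    models <- list()
    shared_nn <- NULL
    for (m in cfg$methods) {
      if (m %in% c("lda_nn", "nn") && !is.null(shared_nn)) {
        dec <- fit_decoder(ep, split, method = m, whiten = cfg$whiten,
                           n_components = cfg$n_components,
                           shrinkage = cfg$shrinkage, nn = nn_cfg,
                           nn_model = shared_nn)
      } else {
        dec <- fit_decoder(ep, split, method = m, whiten = cfg$whiten,
                           n_components = cfg$n_components,
                           shrinkage = cfg$shrinkage, nn = nn_cfg)
      }
      if (m %in% c("lda_nn", "nn") && is.null(shared_nn))
        shared_nn <- dec$nn_model
      models[[m]] <- dec
      acc_rows[[length(acc_rows) + 1L]] <- data.frame(
        replicate = r, method = m, scope = "full_epoch",
        accuracy = accuracy(dec, ep, split$validation))
    }

    if ("windowed" %in% cfg$analyses) {
      win <- round(cfg$window_ms / 1000 * ep$sfreq)
      spec <- sliding_windows(dim(ep$data)[3L], win, 1L)
      proj <- if (!is.null(models$lda_nn)) models$lda_nn$projection
        else fit_channel_pca(ep, split$train, cfg$n_components)
      whit <- if (!is.null(models$lda_nn)) models$lda_nn$whitener else NULL
      tc <- train_windowed(ep, split, spec, projection = proj,
                           whitener = whit, shrinkage = cfg$shrinkage)
      tc$replicate <- r
      tc_rows[[length(tc_rows) + 1L]] <- as.data.frame(tc)
      pk <- peak_accuracy(tc)
      acc_rows[[length(acc_rows) + 1L]] <- data.frame(
        replicate = r, method = if (!is.null(models$lda_nn)) "lda_nn"
          else "lda_pca",
        scope = "peak_window", accuracy = pk$accuracy)
    }

    ref <- models$lda_nn %||% models[[1L]]
    plan <- pfi_plan(cfg$pfi$n_permutations, seed = seed_r)
    for (mode in intersect(cfg$analyses,
                           c("pfi_temporal", "pfi_spatial", "pfi_spectral",
                             "pfi_temporospectral"))) {
      map <- switch(mode,
        pfi_temporal = temporal_pfi(ref, ep, split$validation, plan = plan),
        pfi_spatial = spatial_pfi(ref, ep, split$validation, plan = plan),
        pfi_spectral = spectral_pfi(ref, ep, split$validation, plan = plan),
        pfi_temporospectral =
          temporospectral_pfi(ref, ep, split$validation, plan = plan))
      map$replicate <- r
      pfi_maps[[mode]] <- rbind(pfi_maps[[mode]], as.data.frame(map))
    }
  }

  accuracies <- do.call(rbind, acc_rows)
  utils::write.csv(accuracies, file.path(out_dir, "accuracies.csv"),
                   row.names = FALSE)
  if (length(tc_rows))
    utils::write.csv(do.call(rbind, tc_rows),
                     file.path(out_dir, "timecourse.csv"),
                     row.names = FALSE)
  for (mode in names(pfi_maps))
    utils::write.csv(pfi_maps[[mode]],
                     file.path(out_dir, paste0(mode, ".csv")),
                     row.names = FALSE)

  # chance assessment + paired comparisons across replicates
  band <- chance_band(k, n_val)
  full <- accuracies[accuracies$scope == "full_epoch", ]
  by_method <- split(full$accuracy, full$method)
  stats_out <- list(
    chance = 1 / k, chance_band = as.list(band),
    at_chance = lapply(by_method, function(a)
      mean(a) >= band["lo"] && mean(a) <= band["hi"]),
    mean_accuracy = lapply(by_method, mean)
  )
  methods <- names(by_method)
  if (cfg$replicates >= 5 && length(methods) >= 2) {
    comps <- utils::combn(methods, 2, simplify = FALSE)
    stats_out$paired_tests <- lapply(comps, function(pr) {
      ht <- wilcoxon_signed_rank(by_method[[pr[1L]]], by_method[[pr[2L]]])
      list(comparison = paste(pr, collapse = " vs "),
           statistic = ht$statistic, p = ht$p,
           p_bonferroni = bonferroni(ht$p, length(comps)))
    })
  }
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  manifest <- list(
    package = "megdecode",
    package_version = as.character(utils::packageVersion("megdecode")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = cfg,
    replicate_seeds = cfg$seed + seq_len(cfg$replicates) - 1L
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(accuracies = accuracies, stats = stats_out,
                 timecourses = if (length(tc_rows))
                   do.call(rbind, tc_rows) else NULL,
                 pfi = pfi_maps, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
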