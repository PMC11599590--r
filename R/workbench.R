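## Configuration, end-to-end orchestration and reproducibility glue.

.CONFIG_SCHEMA <- "repairscape-config/1"

.default_config <- function() {
  list(
    schema = .CONFIG_SCHEMA,
    simulate = list(
      n_targets = 30L, lines = c("control", "Nbn", "Polq"),
      read_depth = 2000, n_replicates = 2L, n_timepoints = 1L, seed = 1L
    ),
    profile = list(min_reads = 100L, mh_min = 2L),
    lfc = list(pc = 0.001, control = "control"),
    mh = list(s_range = 2:6),
    cluster = list(n_neighbors = 15L, k = 4L, seed = 1L, min_lines = 2L,
                   method = "spectral"),
    predictor = list(line = "control", lambda = 0.01, seed = 1L,
                     test_frac = 0.1, maxit = 300L)
  )
}

#' Build a validated run configuration
#'
#' Starts from the package defaults (which match the stated defaults of
#' every stage) and merges overrides; unknown keys at either level are
#' rejected.
#'
#' @param ... named top-level sections (`simulate`, `profile`, `lfc`, `mh`,
#'   `cluster`, `predictor`), each a list of overrides.
#' @return a `run_config` list with a `schema` id.
#' @export
run_config <- function(...) {
  defaults <- .default_config()
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(over)) {
    if (sec == "schema") next
    bad2 <- setdiff(names(over[[sec]]), names(defaults[[sec]]))
    if (length(bad2)) {
      stop(sprintf("unknown key(s) in config section '%s': %s",
                   sec, paste(bad2, collapse = ", ")))
    }
    defaults[[sec]][names(over[[sec]])] <- over[[sec]]
  }
  structure(defaults, class = "run_config")
}

#' Write a machine-readable run manifest
#'
#' Records every emitted file with its md5 and size, the config (and its
#' hash), the seeds used, package and R versions, and wall time.
#'
#' @param out_dir artifact directory.
#' @param config the `run_config` used.
#' @param elapsed wall time in seconds.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, config, elapsed = NA_real_) {
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  paths <- file.path(out_dir, files)
  manifest <- list(
    schema = "repairscape-manifest/1",
    config = unclass(config),
    config_hash = .object_md5(unclass(config)),
    seeds = list(simulate = config$simulate$seed,
                 cluster = config$cluster$seed,
                 predictor = config$predictor$seed),
    files = lapply(stats::setNames(seq_along(files), files), function(i) {
      list(md5 = unname(tools::md5sum(paths[i])),
           bytes = unname(file.size(paths[i])))
    }),
    versions = list(repairscape = as.character(utils::packageVersion("repairscape")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    elapsed_seconds = elapsed
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.write_stage_tsv <- function(x, path, comment) {
  writeLines(c(comment, paste(names(x), collapse = "\t")), path)
  readr::write_tsv(tibble::as_tibble(x), path, append = TRUE, col_names = FALSE)
}

#' Run the full synthetic-screen analysis end to end
#'
#' simulate -> filter/pool -> category aggregation -> fold changes ->
#' microhomology fits -> LFC matrix/embedding/clustering -> predictor
#' training and held-out evaluation, writing every stage artifact plus a
#' manifest into `out_dir`. Stage failures abort with the failing stage
#' named; partial outputs are moved under `out_dir/failed`. Rerunning with
#' the same config reproduces the deterministic artifacts byte for byte.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with the in-memory stage results and the
#'   artifact paths.
#' @export
run_end_to_end <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  res <- tryCatch({
    sim_cfg <- config$simulate
    presets <- line_presets(read_depth = sim_cfg$read_depth,
                            n_replicates = sim_cfg$n_replicates)
    missing <- setdiff(sim_cfg$lines, names(presets))
    if (length(missing)) stop("no preset for line(s): ", paste(missing, collapse = ", "))
    params <- presets[sim_cfg$lines]
    params <- lapply(params, function(p) {
      p$n_timepoints <- sim_cfg$n_timepoints
      p
    })
    lib <- make_library(sim_cfg$n_targets, seed = sim_cfg$seed)
    sim <- sample_dataset(lib, params, seed = sim_cfg$seed, out_dir = out_dir)

    stage <- "profile"
    profiles <- filter_and_pool(sim$counts, min_reads = config$profile$min_reads)
    if (!nrow(profiles)) stop("no targets survive filtering")
    .write_stage_tsv(profiles, file.path(out_dir, "profiles.tsv"),
                     "# pooled outcome profiles; freq = count / total mutated reads")
    cats <- aggregate_categories(profiles, lib, mh_min = config$profile$mh_min)
    .write_stage_tsv(cats, file.path(out_dir, "categories.tsv"),
                     "# ten-category aggregates per (target, line)")

    stage <- "lfc"
    lfc <- lfc_table(profiles, lib, control = config$lfc$control,
                     pc = config$lfc$pc, unit = "category",
                     mh_min = config$profile$mh_min)
    .write_stage_tsv(lfc, file.path(out_dir, "lfc.tsv"),
                     sprintf("# category log2 fold changes vs %s; pseudocount %g (frequency units)",
                             config$lfc$control, config$lfc$pc))

    stage <- "mhfit"
    mhfits <- fit_mh_all(profiles, lib, s_range = config$mh$s_range,
                         mh_min = config$profile$mh_min)
    .write_stage_tsv(mhfits, file.path(out_dir, "mhfits.tsv"),
                     "# exponential microhomology law fits y = A * exp(B d)")

    stage <- "cluster"
    lmat <- build_lfc_matrix(profiles, lib, control = config$lfc$control,
                             pc = config$lfc$pc,
                             min_lines = config$cluster$min_lines,
                             mh_min = config$profile$mh_min)
    emb <- embed_lfc(lmat, n_neighbors = config$cluster$n_neighbors,
                     seed = config$cluster$seed, method = config$cluster$method)
    labels <- cluster_outcomes(emb, k = config$cluster$k,
                               seed = config$cluster$seed)
    emb_tab <- tibble::tibble(
      row = rownames(emb$coords), dim1 = emb$coords[, 1], dim2 = emb$coords[, 2],
      cluster = as.integer(labels)
    )
    .write_stage_tsv(emb_tab, file.path(out_dir, "embedding.tsv"),
                     sprintf("# 2-D %s embedding + k-means labels (k = %d)",
                             emb$method, config$cluster$k))
    comp <- cluster_composition(labels, lmat$meta$category, lmat$meta$ctrl_freq)
    .write_stage_tsv(tibble::as_tibble(as.data.frame.table(comp$e, responseName = "pct")),
                     file.path(out_dir, "composition_e.tsv"),
                     "# category distribution over clusters (columns sum to 100%)")
    .write_stage_tsv(tibble::as_tibble(as.data.frame.table(comp$f, responseName = "pct")),
                     file.path(out_dir, "composition_f.tsv"),
                     "# cluster composition by category (rows sum to 100%)")
    enr <- cluster_knockout_enrichment(labels, lmat)
    .write_stage_tsv(tibble::as_tibble(as.data.frame.table(enr, responseName = "enrichment")),
                     file.path(out_dir, "enrichment.tsv"),
                     "# mean cluster LFC minus overall mean, per knockout")

    stage <- "train"
    pline <- config$predictor$line
    pprof <- profiles[profiles$line == pline, ]
    split <- split_targets(unique(pprof$target),
                           test_frac = config$predictor$test_frac,
                           seed = config$predictor$seed)
    model <- train_predictor(lib[split$train],
                             pprof[pprof$target %in% split$train, ],
                             lambda = config$predictor$lambda,
                             seed = config$predictor$seed,
                             maxit = config$predictor$maxit,
                             mh_min = config$profile$mh_min)

    stage <- "evaluate"
    ev <- evaluate_predictor(model, lib[split$test],
                             pprof[pprof$target %in% split$test, ])
    preds <- dplyr::bind_rows(lapply(split$test, function(tid) {
      p <- predict_profile(model, lib[[tid]])
      p$target <- tid
      p[c("target", "outcome", "category", "p")]
    }))
    .write_stage_tsv(preds, file.path(out_dir, "predictions.tsv"),
                     sprintf("# predicted outcome profiles, %s model, held-out targets", pline))
    jsonlite::write_json(
      list(line = pline, mean_kl = mean(ev$per_target$kl),
           pearson = ev$pearson, n_test_targets = length(split$test)),
      file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA
    )

    list(library = lib, sim = sim, profiles = profiles, categories = cats,
         lfc = lfc, mhfits = mhfits, lfc_matrix = lmat, embedding = emb,
         labels = labels, model = model, evaluation = ev)
  }, error = function(e) {
    failed <- file.path(out_dir, "failed")
    dir.create(failed, showWarnings = FALSE)
    for (f in setdiff(list.files(out_dir), "failed")) {
      file.rename(file.path(out_dir, f), file.path(failed, f))
    }
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE)
  })
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  write_manifest(out_dir, config, elapsed)
  invisible(c(res, list(out_dir = out_dir)))
}
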