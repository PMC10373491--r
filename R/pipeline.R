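## End-to-end pipeline commands.  One JSON config drives every command;
## command-line flags (see inst/cli/gcnscreen.R) override config keys.
## Each command writes versioned artifacts plus a machine-readable run
## manifest (seed, config hash, metrics) into the output directory.

log_msg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

#' Read a pipeline run configuration
#'
#' The configuration is a single JSON object with keys `hotspots` (path to
#' a hotspot JSON), `selection` (path to a coordinate TSV; omit for the
#' bundled binding site), `properties` (path to a property table; omit for
#' the bundled set), `feature_ids`, `edge_mode`, `hidden`, `clusters`,
#' `train` (epochs, learning_rate, patience, aux_loss_weight, fractions),
#' `library` (l_max, n), `landscape` (epistatic_fraction, sigma,
#' distance_scale, baseline), `screen` (l_max, top_k), `fusion` (dim, leak,
#' channels, pool_type), `seed`, and `out_dir`.  Missing keys fall back to
#' package defaults; referenced files must exist at load time.
#'
#' @param path Path to the JSON config.
#' @param overrides Named list of keys replacing config values (CLI flags).
#' @return A run-config list (class `run_config`).
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "."
  cfg$edge_mode <- cfg$edge_mode %||% "inverse_distance"
  for (key in c("hotspots", "selection", "properties")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      abort(paste0("config key '", key, "': file not found: ", cfg[[key]]))
    }
  }
  if (is.null(cfg$hotspots)) abort("config must name a 'hotspots' JSON file")
  cfg$config_path <- path
  class(cfg) <- "run_config"
  cfg
}

## A configured library size larger than the combinatorial space cannot be
## sampled without duplicates; clamp to the space size with a logged note.
clamp_library_size <- function(n, hotspots, l_max) {
  space <- search_space_size(length(hotspots), l_max, length(hotspots$alphabet))
  if (n > space) {
    log_msg("requested library size ", n, " exceeds the combinatorial space; ",
            "using the full space of ", space, " variants")
    n <- space
  }
  as.integer(n)
}

load_config_objects <- function(cfg) {
  list(
    hotspots = read_hotspots(cfg$hotspots),
    selection = if (is.null(cfg$selection)) read_selection_tsv() else
      read_selection_tsv(cfg$selection),
    table = load_property_table(cfg$properties, ids = cfg$feature_ids)
  )
}

config_train <- function(cfg) {
  tr <- cfg$train %||% list()
  train_config(
    epochs = tr$epochs %||% 200,
    learning_rate = tr$learning_rate %||% 1e-4,
    patience = tr$patience %||% 40,
    aux_loss_weight = tr$aux_loss_weight %||% 1.0
  )
}

write_manifest <- function(cfg, command, outputs, metrics = list()) {
  manifest <- list(
    command = command,
    seed = cfg$seed,
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "config_path")]),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs,
    metrics = metrics
  )
  path <- file.path(cfg$out_dir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Pipeline commands
#'
#' Each command reads a [read_run_config()] object, performs one pipeline
#' stage and writes its artifacts plus a run manifest to `cfg$out_dir`.
#'
#' `run_space()` reports the combinatorial search-space size and, when the
#' config gives a library size `n`, the space coverage.
#'
#' @param cfg A [read_run_config()] object.
#' @return `run_space()` returns a tibble with `n_hot`, `l_max`,
#'   `aa_count`, `space`, and (when `n` is configured) `coverage_percent`,
#'   invisibly; it also prints the report.
#' @export
run_space <- function(cfg) {
  obj <- load_config_objects(cfg)
  l_max <- cfg$library$l_max %||% length(obj$hotspots)
  space <- search_space_size(length(obj$hotspots), l_max,
                             length(obj$hotspots$alphabet))
  out <- tibble::tibble(
    n_hot = length(obj$hotspots), l_max = l_max,
    aa_count = length(obj$hotspots$alphabet), space = space
  )
  cat("search space: C(", out$n_hot, ",", out$l_max, ") * ",
      out$aa_count, "^", out$l_max, " = ",
      format(space, scientific = FALSE, big.mark = ","), " variants\n", sep = "")
  if (!is.null(cfg$library$n)) {
    cov <- coverage_percent(cfg$library$n, space)
    out$n <- cfg$library$n
    out$coverage_percent <- cov
    cat("library of ", cfg$library$n, " examples covers ",
        format_coverage(cov), "% of the space\n", sep = "")
  }
  invisible(out)
}

#' @rdname run_space
#' @details `run_sample()` writes an unlabeled sampled library
#'   (`library.tsv`); `run_simulate()` generates a landscape and a labeled
#'   dataset (`dataset.tsv`, `landscape.json`); `run_train()` trains the
#'   graph model on the dataset (`checkpoint.rds`, `training_log.csv`);
#'   `run_screen()` screens the full space with the checkpoint
#'   (`screen_top.tsv`, `screen_histogram.tsv`); `run_fuse()` trains the
#'   embedding-fusion head on top of the frozen checkpoint
#'   (`fusion_checkpoint.rds`).
#' @export
run_sample <- function(cfg) {
  obj <- load_config_objects(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  l_max <- cfg$library$l_max %||% length(obj$hotspots)
  n <- clamp_library_size(cfg$library$n %||% 1000L, obj$hotspots, l_max)
  lib <- sample_library(obj$hotspots, l_max, n, seed = cfg$seed)
  path <- file.path(cfg$out_dir, "library.tsv")
  write_library(lib, path)
  log_msg("sampled ", n, " variants -> ", path)
  write_manifest(cfg, "sample", list(library = path),
                 list(n = n, l_max = l_max))
  invisible(lib)
}

#' @rdname run_space
#' @export
run_simulate <- function(cfg) {
  obj <- load_config_objects(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  ls_cfg <- cfg$landscape %||% list()
  land <- generate_landscape(
    obj$hotspots,
    epistatic_fraction = ls_cfg$epistatic_fraction %||% 0,
    sigma = ls_cfg$sigma %||% 0,
    seed = cfg$seed,
    baseline = ls_cfg$baseline %||% -10,
    selection = obj$selection,
    distance_scale = isTRUE(ls_cfg$distance_scale)
  )
  l_max <- cfg$library$l_max %||% length(obj$hotspots)
  n <- clamp_library_size(cfg$library$n %||% 1000L, obj$hotspots, l_max)
  ds <- make_dataset(land, obj$hotspots, l_max, n, seed = cfg$seed)
  ds_path <- file.path(cfg$out_dir, "dataset.tsv")
  land_path <- file.path(cfg$out_dir, "landscape.json")
  write_library(ds, ds_path)
  write_landscape(land, land_path)
  log_msg("simulated dataset of ", n, " labeled variants -> ", ds_path)
  write_manifest(cfg, "simulate",
                 list(dataset = ds_path, landscape = land_path),
                 list(n = n, l_max = l_max,
                      energy_range = range(ds$energy)))
  invisible(ds)
}

#' @rdname run_space
#' @export
run_train <- function(cfg) {
  obj <- load_config_objects(cfg)
  ds_path <- file.path(cfg$out_dir, "dataset.tsv")
  if (!file.exists(ds_path)) {
    abort(paste0("missing upstream artifact ", ds_path,
                 "; run the simulate command first"))
  }
  ds <- read_library(ds_path)
  if (!"energy" %in% names(ds)) abort("dataset.tsv lacks an 'energy' column")
  fractions <- cfg$train$fractions %||% c(0.8, 0.1, 0.1)
  fit <- gcn_train(
    ds, obj$hotspots, obj$selection, obj$table,
    edge_mode = cfg$edge_mode,
    hidden = cfg$hidden %||% 32L,
    clusters = cfg$clusters %||% 8L,
    config = config_train(cfg),
    fractions = fractions,
    seed = cfg$seed
  )
  ckpt <- file.path(cfg$out_dir, "checkpoint.rds")
  save_gcn(fit, ckpt)
  log_path <- file.path(cfg$out_dir, "training_log.csv")
  readr::write_csv(fit$history, log_path)
  metrics <- as.list(glance(fit)[, c("epochs_run", "best_epoch",
                                     "val_loss", "val_r2",
                                     "test_mse", "test_r2")])
  log_msg("trained model (best epoch ", fit$best_epoch, ") -> ", ckpt)
  write_manifest(cfg, "train",
                 list(checkpoint = ckpt, training_log = log_path), metrics)
  invisible(fit)
}

#' @rdname run_space
#' @export
run_screen <- function(cfg) {
  ckpt <- file.path(cfg$out_dir, "checkpoint.rds")
  if (!file.exists(ckpt)) {
    abort(paste0("missing upstream artifact ", ckpt,
                 "; run the train command first"))
  }
  fit <- load_gcn(ckpt)
  l_max <- cfg$screen$l_max %||% cfg$library$l_max %||%
    length(fit$context$hotspots)
  top_k <- cfg$screen$top_k %||% 10L
  scr <- gcn_screen(fit, l_max, top_k = top_k)
  top_path <- file.path(cfg$out_dir, "screen_top.tsv")
  hist_path <- file.path(cfg$out_dir, "screen_histogram.tsv")
  readr::write_tsv(as.data.frame(scr), top_path)
  readr::write_tsv(attr(scr, "histogram"), hist_path)
  log_msg("screened ", attr(scr, "space"), " variants; top-", top_k,
          " -> ", top_path)
  write_manifest(cfg, "screen",
                 list(top = top_path, histogram = hist_path),
                 list(space = attr(scr, "space"),
                      best_variant = scr$variant_name[1],
                      best_energy = scr$predicted_energy[1]))
  invisible(scr)
}

#' @rdname run_space
#' @export
run_fuse <- function(cfg) {
  ckpt <- file.path(cfg$out_dir, "checkpoint.rds")
  ds_path <- file.path(cfg$out_dir, "dataset.tsv")
  for (p in c(ckpt, ds_path)) {
    if (!file.exists(p)) {
      abort(paste0("missing upstream artifact ", p))
    }
  }
  fit <- load_gcn(ckpt)
  ds <- read_library(ds_path)
  fu_cfg <- cfg$fusion %||% list()
  leak <- fu_cfg$leak %||% 0
  land <- NULL
  if (leak > 0) {
    land_path <- file.path(cfg$out_dir, "landscape.json")
    if (!file.exists(land_path)) {
      abort("fusion leak > 0 requires landscape.json from the simulate command")
    }
    land <- read_landscape(land_path)
  }
  provider <- if (!is.null(fu_cfg$archive)) {
    embedding_provider_archive(fu_cfg$archive)
  } else {
    embedding_provider_synthetic(
      fit$context$hotspots, dim = fu_cfg$dim %||% 16L,
      seed = cfg$seed, leak = leak, params = land)
  }
  fu <- fusion_train(
    fit, ds, provider, config = config_train(cfg),
    channels = as.integer(fu_cfg$channels %||% c(4L, 8L)),
    pool_type = fu_cfg$pool_type %||% "avg",
    seed = cfg$seed
  )
  fu_path <- file.path(cfg$out_dir, "fusion_checkpoint.rds")
  saveRDS(fu, fu_path)
  log_msg("trained fusion head (best epoch ", fu$best_epoch, ") -> ", fu_path)
  write_manifest(cfg, "fuse", list(fusion_checkpoint = fu_path),
                 list(val_loss = min(fu$history$val_loss, na.rm = TRUE),
                      gcn_checksum = fu$gcn_checksum))
  invisible(fu)
}

#' @rdname run_space
#' @export
run_report <- function(cfg) {
  manifests <- list.files(cfg$out_dir, pattern = "^manifest_.*\\.json$",
                          full.names = TRUE)
  if (length(manifests) == 0) {
    abort(paste0("no run manifests found in ", cfg$out_dir))
  }
  for (m in manifests) {
    mf <- jsonlite::read_json(m, simplifyVector = TRUE)
    cat(mf$command, " (seed ", mf$seed, ", ", mf$timestamp, ")\n", sep = "")
    for (nm in names(mf$metrics)) {
      cat("  ", nm, ": ", paste(format(mf$metrics[[nm]]), collapse = " "),
          "\n", sep = "")
    }
  }
  invisible(manifests)
}
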