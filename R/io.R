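## Containers, tables, configuration and the pipeline driver.
##
## Trial/series containers are versioned, schema-validated R serialization
## files; all tables are UTF-8 TSV with header rows; configuration is YAML;
## provenance is JSON written beside every output.

CONTAINER_VERSION <- 1L

#' Write a trial set container
#'
#' @param trials an `esconn_trialset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(inherits(trials, "esconn_trialset"))
  obj <- unclass(trials)
  obj$.container <- "esconn_trialset"
  obj$.version <- CONTAINER_VERSION
  saveRDS(obj, path)
  invisible(path)
}

#' Read a trial set container
#'
#' Validates the container schema (array dimensions, sampling attributes,
#' onset index) and joins channel annotations by channel name. Unknown ROI
#' labels map to roi_group `"other"`. A channel table missing a recorded
#' channel is an error naming it; extra (unrecorded) table rows are accepted
#' with a warning.
#'
#' @param path container path.
#' @param channel_table optional data.frame (or TSV path) with columns
#'   `name`, `roi`, `roi_group`, `hemisphere`, `in_soz`, `in_white_matter`.
#' @return An `esconn_trialset`.
#' @export
read_trials <- function(path, channel_table = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$.container, "esconn_trialset"))
    stop("schema error: not a trial container (field '.container')")
  for (field in c("data", "fs", "t0_index", "channels")) {
    if (is.null(obj[[field]]))
      stop("schema error: missing field '", field, "'")
  }
  if (length(dim(obj$data)) != 3)
    stop("schema error: field 'data' must be a 3-d array (channels x trials x samples)")
  if (obj$t0_index < 1 || obj$t0_index > dim(obj$data)[3])
    stop("schema error: field 't0_index' outside the record")
  if (nrow(obj$channels) != dim(obj$data)[1])
    stop("schema error: field 'channels' has ", nrow(obj$channels),
         " rows for ", dim(obj$data)[1], " recorded channels")
  obj$.container <- NULL; obj$.version <- NULL
  trials <- structure(obj, class = "esconn_trialset")
  if (!is.null(channel_table)) {
    tab <- if (is.character(channel_table)) read_channels(channel_table)
           else channel_table
    missing <- setdiff(trials$channels$name, tab$name)
    if (length(missing) > 0)
      stop("channel table is missing recorded channels: ",
           paste(missing, collapse = ", "))
    extra <- setdiff(tab$name, trials$channels$name)
    if (length(extra) > 0)
      warning("channel table has unrecorded channels (ignored): ",
              paste(extra, collapse = ", "))
    tab <- tab[match(trials$channels$name, tab$name), ]
    tab$roi_group[!(tab$roi_group %in% c(ROI_GROUPS, "other"))] <- "other"
    rownames(tab) <- NULL
    trials$channels <- tab
  }
  trials
}

#' Read / write a channel annotation table (TSV)
#'
#' @param path TSV path.
#' @return Data.frame with the channel schema.
#' @export
read_channels <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("name", "roi", "roi_group", "hemisphere", "in_soz",
           "in_white_matter")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("channel table missing columns: ", paste(miss, collapse = ", "))
  tab$in_soz <- as.logical(tab$in_soz)
  tab$in_white_matter <- as.logical(tab$in_white_matter)
  tab
}

#' @rdname read_channels
#' @param tab channel data.frame.
#' @export
write_channels <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a features or statistics table (TSV)
#'
#' @param tab data.frame.
#' @param path output path.
#' @export
write_table_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

## Configuration schema: name -> c(type, required)
CONFIG_SCHEMA <- list(
  modality = c("character", TRUE),
  seed = c("numeric", TRUE),
  n_trials = c("numeric", FALSE),
  fs = c("numeric", FALSE),
  noise_sd = c("numeric", FALSE),
  artifact_rate = c("numeric", FALSE),
  channels_per_group = c("numeric", FALSE),
  stim_group = c("character", FALSE),
  n_runs = c("numeric", FALSE)
)

#' Read and validate a pipeline configuration (YAML)
#'
#' @param path YAML file path, or a list already in memory.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  for (key in names(CONFIG_SCHEMA)) {
    spec <- CONFIG_SCHEMA[[key]]
    if (is.null(cfg[[key]])) {
      if (isTRUE(as.logical(spec[2])))
        stop("config validation: missing required key '", key,
             "' (expected ", spec[1], ")")
      next
    }
    if (!inherits(cfg[[key]], spec[1]) &&
        !(spec[1] == "numeric" && is.numeric(cfg[[key]])))
      stop("config validation: key '", key, "' must be ", spec[1],
           ", got ", class(cfg[[key]])[1])
  }
  unknown <- setdiff(names(cfg), names(CONFIG_SCHEMA))
  if (length(unknown) > 0)
    warning("config: unknown keys ignored: ", paste(unknown, collapse = ", "))
  cfg
}

#' Write provenance metadata beside an output
#'
#' Records the configuration (and its MD5 hash), the master seed, the
#' package version and a timestamp as JSON.
#'
#' @param path output artifact path; provenance goes to
#'   `<path>.provenance.json`.
#' @param config configuration list.
#' @param seed master seed.
#' @param stage stage name.
#' @export
write_provenance <- function(path, config, seed, stage) {
  tmp <- tempfile(); on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE), tmp)
  prov <- list(stage = stage, seed = seed,
               config = config,
               config_md5 = unname(tools::md5sum(tmp)),
               package_version = as.character(utils::packageVersion("esconn")),
               written = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(prov)
}

#' Run the evoked-potential pipeline end to end
#'
#' Simulates (or loads) a trial set, screens trials, averages and
#' normalizes, extracts features, applies the significance test and writes
#' the per-channel feature table with provenance. Per-stage seeds are
#' derived deterministically from the master seed.
#'
#' @param config configuration list or YAML path (see [read_config()]).
#' @param out_dir output directory (created if needed).
#' @param trials optional pre-built `esconn_trialset`; otherwise simulated
#'   from the configuration and the default ground truth.
#' @return List with `features` (data.frame), `paths` of written artifacts.
#' @export
run_pipeline <- function(config, out_dir, trials = NULL) {
  cfg <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  if (is.null(trials)) {
    gt <- default_ep_ground_truth(
      artifact_rate = cfg$artifact_rate %||% 0.05)
    trials <- simulate_ep_trials(
      gt, n_trials = cfg$n_trials %||% 60, fs = cfg$fs %||% 8000,
      seed = derive_seed(seed, "simulate"),
      stim_group = cfg$stim_group %||% "medial",
      channels_per_group = cfg$channels_per_group %||% 2,
      noise_sd = cfg$noise_sd %||% 1)
  }
  trials_path <- file.path(out_dir, "trials.rds")
  write_trials(trials, trials_path)
  trials <- reject_trials(trials)
  ep <- average_normalize(trials)
  feats <- extract_features(ep)
  feats <- significance_test(ep, feats)
  feat_path <- file.path(out_dir, "ep_features.tsv")
  write_table_tsv(feats, feat_path)
  rej_path <- file.path(out_dir, "rejection_report.tsv")
  write_table_tsv(trials$rejection_report, rej_path)
  for (p in c(trials_path, feat_path, rej_path))
    write_provenance(p, cfg, seed, "ep-pipeline")
  list(features = feats,
       paths = list(trials = trials_path, features = feat_path,
                    rejection = rej_path))
}
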