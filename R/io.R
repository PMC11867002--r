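#' Write a recording to the native raw container
#'
#' The container is a triplet of files sharing a path prefix: `<prefix>.bin`
#' (float32 little-endian, channel-major sample matrix), `<prefix>.json`
#' (sample rate, channel ids, layout, dtype) and `<prefix>.events.tsv`
#' (tab-separated onset/duration/event_type/condition, '.' decimal).
#' Amplitudes are stored as float32, so values not representable in single
#' precision are rounded on write; a write/read cycle is bit-stable from the
#' second cycle on.
#'
#' @param raw a `raw_recording`.
#' @param prefix output path prefix (without extension).
#' @return the prefix, invisibly.
#' @export
write_raw <- function(raw, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  # channel-major: all samples of channel 1, then channel 2, ...
  writeBin(as.numeric(t(raw$data)), con, size = 4, endian = "little")
  lay <- raw$layout
  header <- list(
    format = "cyclicdbs-raw",
    dtype = "float32", byte_order = "little", order = "channel_major",
    sample_rate = raw$sample_rate,
    n_channels = nrow(raw$data), n_samples = ncol(raw$data),
    channel_ids = lay$channel_ids,
    positions = unname(apply(lay$positions, 1, as.numeric, simplify = FALSE)),
    hemisphere = unname(lay$hemisphere),
    adjacency_pairs = which(lay$adjacency & upper.tri(lay$adjacency),
                            arr.ind = TRUE) |> unname() |>
      apply(1, as.integer, simplify = FALSE),
    mirror_map = as.list(lay$mirror_map %||% stats::setNames(list(), NULL)),
    groups = lay$groups,
    ground_truth = raw$ground_truth)
  jsonlite::write_json(header, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  utils::write.table(as.data.frame(raw$events),
                     paste0(prefix, ".events.tsv"),
                     sep = "\t", dec = ".", row.names = FALSE,
                     quote = FALSE)
  invisible(prefix)
}

#' Read a recording from the native raw container
#'
#' @param prefix path prefix used by [write_raw()].
#' @return a `raw_recording`.
#' @export
read_raw <- function(prefix) {
  hpath <- paste0(prefix, ".json")
  if (!file.exists(hpath)) stop("missing sidecar file: ", hpath)
  h <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  for (field in c("sample_rate", "n_channels", "n_samples", "channel_ids",
                  "positions", "hemisphere")) {
    if (is.null(h[[field]]))
      stop("sidecar lacks required field \"", field, "\"")
  }
  bpath <- paste0(prefix, ".bin")
  if (!file.exists(bpath)) stop("missing data file: ", bpath)
  n <- h$n_channels * h$n_samples
  if (file.size(bpath) != 4 * n)
    stop("matrix size inconsistent with header: expected ", 4 * n,
         " bytes, found ", file.size(bpath))
  con <- file(bpath, "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", n = n, size = 4, endian = "little")
  data <- t(matrix(x, nrow = h$n_samples, ncol = h$n_channels))
  pos <- if (is.matrix(h$positions)) h$positions else
    do.call(rbind, h$positions)
  adj <- matrix(FALSE, h$n_channels, h$n_channels)
  ap <- h$adjacency_pairs
  if (length(ap) > 0) {
    ap <- if (is.matrix(ap)) ap else do.call(rbind, ap)
    adj[ap] <- TRUE
    adj[ap[, 2:1, drop = FALSE]] <- TRUE
  }
  mm <- unlist(h$mirror_map)
  layout <- sensor_layout(h$channel_ids, pos, adjacency = adj,
                          mirror_map = if (length(mm)) mm else NULL,
                          groups = lapply(h$groups, unlist))
  epath <- paste0(prefix, ".events.tsv")
  events <- if (file.exists(epath)) {
    tab <- utils::read.table(epath, header = TRUE, sep = "\t", dec = ".",
                             colClasses = c("numeric", "numeric",
                                            "character", "character"))
    do.call(event_table, tab)
  } else event_table()
  raw_recording(data, h$sample_rate, layout, events,
                ground_truth = h$ground_truth)
}

#' Read / write a run configuration
#'
#' Configurations are stored as YAML (`.yaml`/`.yml`) or JSON (`.json`),
#' chosen by file extension.
#'
#' @param config a named list (see [run_config()]).
#' @param path file path.
#' @return `read_run_config` returns the configuration list.
#' @export
write_run_config <- function(config, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(unclass(config), path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  } else stop("unsupported config format: ", path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unsupported config format: ", path)
  cfg
}

#' Write an array with a JSON sidecar
#'
#' Flat binary (float64 little-endian, first dimension fastest) plus a JSON
#' header carrying dimensions, dimension names and axis scales. Used for
#' time-frequency arrays.
#'
#' @param x numeric array.
#' @param prefix path prefix.
#' @param scales optional named list of per-dimension axis values.
#' @return the prefix (`write_array`) or the array with scales attached as
#'   attributes (`read_array`).
#' @export
write_array <- function(x, prefix, scales = NULL) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 8, endian = "little")
  jsonlite::write_json(list(format = "cyclicdbs-array", dtype = "float64",
                            dim = dim(x) %||% length(x), scales = scales),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_array
#' @export
read_array <- function(prefix) {
  h <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", n = prod(h$dim), size = 8,
               endian = "little")
  x <- array(x, dim = h$dim)
  attr(x, "scales") <- h$scales
  x
}
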