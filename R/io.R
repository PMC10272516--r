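## Configuration and the epochs container.
##
## The epochs container is a single JSON document with the groups
## data (trials x channels x samples), time, channels, geometry, events and
## history; numeric payloads are written with 17 significant digits so a
## write-read cycle reproduces every double bitwise.

config_defaults <- function() {
  list(
    seed = 1L,
    filter = list(evoked_band = c(0.1, 20), broad_band = c(0.1, 170),
                  notch = c(60, 120), order = 4),
    epoching = list(window = c(-1, 2), baseline = c(-0.1, 0)),
    artifact = list(z_variance = 3, z_amplitude = 5, z_kurtosis = 3),
    ecd = list(sigma_factor = 1.0, min_rad = 0.1, max_rad = 0.25,
               neighbor_distance_cap = 0.4, max_maxima = 5L,
               global_fraction = 0.10, hemisphere_fraction = 0.75,
               gof_min = 0.90, rv_max = 0.20,
               sigma_s = 0.010, sigma_t = 0.050, keep_fraction = 0.70,
               window = c(0.15, 0.6)),
    inverse = list(lambda2 = 3, alpha = 0.05),
    dics = list(reg = 0.10, n_perm = 10000L, alpha = 0.05,
                baseline_win = c(-0.5, -0.1), active_win = c(0.25, 0.65)),
    laterality = list(threshold = 0.1),
    geometry = list(n_sites = 102L, helmet_radius = 0.12,
                    head_radius = 0.09, grid_spacing = 0.008,
                    baseline = 0.0168))
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) document, validates every key against the default
#' configuration tree (unknown keys are an error, listing the valid keys at
#' that level) and fills missing entries with the defaults.  An empty or
#' missing file yields the full default configuration.
#'
#' @param path YAML/JSON file, or `NULL` for pure defaults.
#' @param overrides optional named list merged on top (validated the same
#'   way).
#' @return Nested configuration list with attribute `"provenance"`.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  defaults <- config_defaults()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  merge_checked <- function(base, new, where = "") {
    for (k in names(new)) {
      if (!k %in% names(base))
        stop(sprintf("unknown config key '%s%s'; valid keys here: %s",
                     where, k, paste(names(base), collapse = ", ")))
      if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
        if (!is.list(new[[k]]))
          stop(sprintf("config key '%s%s' must be a mapping", where, k))
        base[[k]] <- merge_checked(base[[k]], new[[k]],
                                   paste0(where, k, "."))
      } else {
        v <- new[[k]]
        if (is.list(v)) v <- unlist(v)
        if (!is.numeric(v) && !is.numeric(base[[k]]))
          base[[k]] <- v
        else if (is.numeric(v))
          base[[k]] <- if (is.integer(base[[k]])) as.integer(v) else as.numeric(v)
        else stop(sprintf("config key '%s%s' must be numeric", where, k))
      }
    }
    base
  }
  cfg <- merge_checked(defaults, user)
  if (!is.null(overrides)) cfg <- merge_checked(cfg, overrides, "")
  attr(cfg, "provenance") <- list(file = path, overrides = overrides,
                                  loaded = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  cfg
}

#' Write / read the epochs container
#'
#' JSON container with groups `data` (trials x channels x samples),
#' `time`, `channels`, `geometry` (sensor array + head, optional),
#' `events`, `truth` and `history`.  Doubles are serialized with 17
#' significant digits: a write-read cycle is bitwise exact.
#'
#' @param ep an [epochs()] object; `path` output file; `array`,`head`
#'   optional geometry to embed.
#' @return `read_epochs` returns `list(epochs = , array = , head = )`
#'   (geometry `NULL` when not embedded).
#' @export
write_epochs <- function(ep, path, array = NULL, head = NULL) {
  stopifnot(inherits(ep, "epochs"))
  obj <- list(schema = "meglat-epochs-v1",
              data = ep$data, time = ep$times, fs = ep$fs,
              channels = ep$channel_names,
              events = list(rejected = ep$rejected),
              truth = ep$truth,
              history = ep$history,
              geometry = if (!is.null(array)) list(
                site_pos = array$site_pos, site_normal = array$site_normal,
                ax1 = array$ax1, ax2 = array$ax2,
                baseline = array$baseline,
                helmet_radius = array$helmet_radius,
                center = array$center,
                channel_names = array$channel_names,
                channel_site = array$channel_site,
                channel_axis = array$channel_axis,
                head_center = head$center, head_radius = head$radius))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("data", "time", "fs", "channels", "history")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("epochs container is missing group(s): ", paste(miss, collapse = ", "))
  data <- obj$data
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("epochs container group 'data' must be a 3-d array")
  rej <- obj$events$rejected
  if (is.null(rej) || !length(rej))
    rej <- data.frame(trial = integer(), reason = character())
  truth <- obj$truth
  if (!is.null(truth$location)) truth$location <- as.numeric(truth$location)
  ep <- epochs(data = data, fs = obj$fs, times = as.numeric(obj$time),
               channel_names = obj$channels, truth = truth,
               rejected = as.data.frame(rej), history = obj$history)
  array <- NULL; head <- NULL
  if (!is.null(obj$geometry) && length(obj$geometry)) {
    gg <- obj$geometry
    array <- structure(list(site_pos = as.matrix(gg$site_pos),
                            site_normal = as.matrix(gg$site_normal),
                            ax1 = as.matrix(gg$ax1), ax2 = as.matrix(gg$ax2),
                            baseline = gg$baseline,
                            helmet_radius = gg$helmet_radius,
                            center = as.numeric(gg$center),
                            n_sites = nrow(as.matrix(gg$site_pos)),
                            channel_names = gg$channel_names,
                            channel_site = as.integer(gg$channel_site),
                            channel_axis = as.integer(gg$channel_axis)),
                       class = "sensor_array")
    head <- head_model(center = gg$head_center, radius = gg$head_radius)
  }
  list(epochs = ep, array = array, head = head)
}
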