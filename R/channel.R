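#' Uniformly sampled signal channel
#'
#' A \code{channel} is one uniformly sampled time series from a data logger:
#' sample values, the sampling rate, a physical unit, and an offset of the
#' first sample from the deployment clock origin. The time of sample
#' \eqn{i} (1-based) is \code{t0 + (i - 1) / rate} seconds. Values must be
#' finite: missing data are not representable, so loaders reject NaN/NA
#' rather than silently interpolating.
#'
#' @param values numeric vector of samples (all finite).
#' @param rate sampling rate in Hz (> 0).
#' @param units physical unit string, e.g. \code{"mV"} for ECG or
#'   \code{"m s-2"} for acceleration.
#' @param name channel label, e.g. \code{"ecg"} or \code{"accel_long"}.
#' @param t0 offset of the first sample from deployment start, in seconds.
#' @return an object of class \code{channel}.
#' @examples
#' ch <- channel(sin(2 * pi * 1 * (0:249) / 250), rate = 250, units = "mV",
#'               name = "ecg")
#' channel_duration(ch)
#' @export
channel <- function(values, rate, units = "", name = "", t0 = 0) {
  if (!is_scalar_number(rate) || rate <= 0)
    stop_validation("channel rate must be a positive finite number, got %s",
                    format(rate))
  if (!is.numeric(values))
    stop_validation("channel values must be numeric")
  values <- as.double(values)
  if (length(values) && any(!is.finite(values)))
    stop_validation("channel '%s' contains %d non-finite sample(s); gaps are not representable",
                    name, sum(!is.finite(values)))
  if (!is_scalar_number(t0))
    stop_validation("channel t0 must be a finite number")
  structure(list(name = as.character(name)[1], values = values,
                 rate = as.double(rate), units = as.character(units)[1],
                 t0 = as.double(t0)),
            class = "channel")
}

#' @rdname channel
#' @param ch a \code{channel}.
#' @export
channel_times <- function(ch) {
  ch$t0 + (seq_along(ch$values) - 1) / ch$rate
}

#' @rdname channel
#' @export
channel_duration <- function(ch) length(ch$values) / ch$rate

#' @export
print.channel <- function(x, ...) {
  cat(sprintf("<channel '%s'> %d samples @ %g Hz [%s], t0 = %g s (%.1f min)\n",
              x$name, length(x$values), x$rate, x$units, x$t0,
              channel_duration(x) / 60))
  invisible(x)
}

#' @export
length.channel <- function(x) length(x$values)

# ---- channel CSV on-disk format ---------------------------------------------

CHANNEL_HEADER_KEYS <- c("name", "rate_hz", "units", "t0_s")

#' Read a channel file
#'
#' The on-disk channel format is a plain-text file: a header block of lines
#' \code{"# key: value"} carrying \code{name}, \code{rate_hz}, \code{units}
#' and \code{t0_s}, followed by one numeric sample per line. The format is
#' deliberately inspectable and diffable; proprietary logger binaries are
#' out of scope.
#'
#' @param path path to a channel file.
#' @return a \code{\link{channel}}.
#' @seealso [write_channel()]
#' @export
read_channel <- function(path) {
  if (!file.exists(path)) stop_validation("channel file not found: %s", path)
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr_lines <- lines[is_hdr]
  m <- regmatches(hdr_lines, regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*?)\\s*$",
                                     hdr_lines))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop_validation("%s: malformed header line: '%s'", path,
                    hdr_lines[bad][1])
  keys <- vapply(m, `[`, "", 2L)
  vals <- vapply(m, `[`, "", 3L)
  if (anyDuplicated(keys))
    stop_validation("%s: duplicate header key '%s'", path,
                    keys[duplicated(keys)][1])
  missing <- setdiff(CHANNEL_HEADER_KEYS, keys)
  if (length(missing))
    stop_validation("%s: missing header key(s): %s", path,
                    paste(missing, collapse = ", "))
  hdr <- stats::setNames(as.list(vals), keys)

  body_idx <- which(!is_hdr & nzchar(trimws(lines)))
  body <- trimws(lines[body_idx])
  values <- suppressWarnings(as.numeric(body))
  if (length(values) && anyNA(values)) {
    i <- which(is.na(values))[1]
    stop_validation("%s: non-numeric sample '%s' at line %d", path,
                    body[i], body_idx[i])
  }
  rate <- suppressWarnings(as.numeric(hdr$rate_hz))
  if (is.na(rate)) stop_validation("%s: non-numeric rate_hz", path)
  t0 <- suppressWarnings(as.numeric(hdr$t0_s))
  if (is.na(t0)) stop_validation("%s: non-numeric t0_s", path)
  channel(values, rate = rate, units = hdr$units, name = hdr$name, t0 = t0)
}

#' Write a channel file
#'
#' Samples are printed at 17 significant digits, so a write/read round trip
#' reproduces values bit-for-bit. Refuses to overwrite an existing file
#' unless \code{force = TRUE}.
#'
#' @param ch a \code{\link{channel}}.
#' @param path destination path.
#' @param force overwrite an existing file?
#' @return \code{path}, invisibly.
#' @export
write_channel <- function(ch, path, force = FALSE) {
  stopifnot(inherits(ch, "channel"))
  if (file.exists(path) && !force)
    stop_validation("refusing to overwrite existing file %s (use force = TRUE)",
                    path)
  hdr <- c(sprintf("# name: %s", ch$name),
           sprintf("# rate_hz: %s", format_full(ch$rate)),
           sprintf("# units: %s", ch$units),
           sprintf("# t0_s: %s", format_full(ch$t0)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  if (length(ch$values)) writeLines(format_full(ch$values), con)
  invisible(path)
}

# ---- deployment records -----------------------------------------------------

PLACEMENTS <- c("A", "B", "C")
REQUIRED_CHANNELS <- c("ecg", "accel_long")

#' A turtle's deployment: channel bundle plus metadata
#'
#' Bundles the channels recorded on one animal with its identifiers. At
#' least an \code{"ecg"} and an \code{"accel_long"} (longitudinal
#' acceleration) channel are required; \code{"temperature"} and
#' \code{"depth"} are optional and carried through unanalyzed. All channels
#' share the deployment clock: t = 0 at record start, with per-channel
#' \code{t0} offsets for staggered starts.
#'
#' @param turtle_id animal identifier.
#' @param placement electrode placement label, one of \code{"A"},
#'   \code{"B"}, \code{"C"} (C is the placement with the negative electrode
#'   closest to the neck).
#' @param channels named list of \code{\link{channel}} objects.
#' @param body_mass_kg optional body mass (kg, > 0).
#' @param scl_cm optional straight carapace length (cm, > 0).
#' @return an object of class \code{deployment_record}.
#' @export
deployment_record <- function(turtle_id, placement, channels,
                              body_mass_kg = NULL, scl_cm = NULL) {
  placement <- as.character(placement)[1]
  if (!placement %in% PLACEMENTS)
    stop_validation("unknown electrode placement '%s' (expected A, B or C)",
                    placement)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop_validation("channels must be a named list")
  missing <- setdiff(REQUIRED_CHANNELS, names(channels))
  if (length(missing))
    stop_validation("incomplete deployment: missing required channel(s) %s",
                    paste(missing, collapse = ", "))
  for (nm in names(channels))
    if (!inherits(channels[[nm]], "channel"))
      stop_validation("channel '%s' is not a channel object", nm)
  for (v in list(body_mass_kg = body_mass_kg, scl_cm = scl_cm))
    if (!is.null(v) && (!is_scalar_number(v) || v <= 0))
      stop_validation("body_mass_kg / scl_cm must be positive if given")
  structure(list(turtle_id = as.character(turtle_id)[1],
                 placement = placement, channels = channels,
                 body_mass_kg = body_mass_kg, scl_cm = scl_cm),
            class = "deployment_record")
}

#' @export
print.deployment_record <- function(x, ...) {
  cat(sprintf("<deployment_record> turtle %s, placement %s\n", x$turtle_id,
              x$placement))
  for (ch in x$channels)
    cat("  ", format(ch$name, width = 12),
        sprintf("%9d samples @ %5g Hz [%s]\n", length(ch$values), ch$rate,
                ch$units))
  invisible(x)
}

#' Deployment record span in seconds
#'
#' End of the latest-running channel on the deployment clock.
#' @param record a \code{deployment_record}.
#' @export
deployment_end_s <- function(record) {
  max(vapply(record$channels,
             function(ch) ch$t0 + length(ch$values) / ch$rate, 0))
}

#' Load a deployment from a manifest
#'
#' The manifest is a YAML file naming the animal, its electrode placement,
#' optional morphometrics, and one channel file per channel (paths relative
#' to the manifest). All channel invariants are validated on load; sample
#' values are never altered (no resampling or unit conversion).
#'
#' @param manifest path to a manifest YAML file.
#' @return a \code{\link{deployment_record}}.
#' @seealso [write_deployment()]
#' @export
load_deployment <- function(manifest) {
  if (!file.exists(manifest))
    stop_validation("manifest not found: %s", manifest)
  m <- yaml::read_yaml(manifest)
  if (is.null(m$turtle_id) || is.null(m$placement))
    stop_validation("%s: manifest must name turtle_id and placement", manifest)
  if (is.null(m$channels) || !length(m$channels))
    stop_validation("%s: manifest names no channels", manifest)
  base <- dirname(manifest)
  chans <- lapply(m$channels, function(p) read_channel(file.path(base, p)))
  names(chans) <- names(m$channels)
  deployment_record(m$turtle_id, m$placement, chans,
                    body_mass_kg = m$body_mass_kg, scl_cm = m$scl_cm)
}

#' Write a deployment to a directory
#'
#' Writes one channel file per channel plus a \code{manifest.yml}; the
#' result can be re-loaded with \code{\link{load_deployment}} unchanged.
#'
#' @param record a \code{\link{deployment_record}}.
#' @param dir destination directory (created if needed).
#' @param force overwrite existing files?
#' @return the manifest path, invisibly.
#' @export
write_deployment <- function(record, dir, force = FALSE) {
  stopifnot(inherits(record, "deployment_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- stats::setNames(paste0(names(record$channels), ".csv"),
                           names(record$channels))
  for (nm in names(record$channels))
    write_channel(record$channels[[nm]], file.path(dir, files[[nm]]),
                  force = force)
  manifest <- file.path(dir, "manifest.yml")
  if (file.exists(manifest) && !force)
    stop_validation("refusing to overwrite %s (use force = TRUE)", manifest)
  m <- list(turtle_id = record$turtle_id, placement = record$placement,
            channels = as.list(files))
  if (!is.null(record$body_mass_kg)) m$body_mass_kg <- record$body_mass_kg
  if (!is.null(record$scl_cm)) m$scl_cm <- record$scl_cm
  yaml::write_yaml(m, manifest)
  invisible(manifest)
}
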