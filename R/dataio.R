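#' Recording containers for multimodal consumer-choice data
#'
#' An `eeg_recording` holds a channels x samples matrix in microvolts together
#' with channel names, the sampling rate and per-product trial annotations.
#' An `et_recording` holds per-sample gaze coordinates in screen pixels, a
#' validity flag (`FALSE` marks missing samples, e.g. during blinks), the
#' sampling rate, the screen size and trial annotations.
#'
#' Trial annotations are a data frame with columns `start`, `end` (0-based,
#' half-open sample ranges), `label` (1 = buy, 0 = no-buy) and `product_id`.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param channel_names character vector, one name per channel.
#' @param fs sampling rate in Hz.
#' @param subject_id subject identifier.
#' @param trials trial annotation data frame (see Details), or `NULL`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channel_names = NULL, fs = 300,
                          subject_id = "S01", trials = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(data)))
  dimnames(data) <- NULL
  rec <- structure(list(data = data, channel_names = channel_names,
                        fs = fs, subject_id = subject_id,
                        trials = normalize_trials(trials)),
                   class = "eeg_recording")
  validate_recording(rec)
  rec
}

#' @param gaze_x,gaze_y numeric vectors of gaze coordinates in pixels.
#' @param valid logical vector; `FALSE` marks missing samples.
#' @param screen_size integer vector `c(width, height)` in pixels.
#' @rdname eeg_recording
#' @return An object of class `et_recording`.
#' @export
et_recording <- function(gaze_x, gaze_y, valid = NULL, fs = 120,
                         screen_size = c(1920, 1080), subject_id = "S01",
                         trials = NULL) {
  if (length(gaze_x) != length(gaze_y))
    stop("gaze_x, gaze_y and valid must have equal length")
  if (is.null(valid)) valid <- !(is.na(gaze_x) | is.na(gaze_y))
  rec <- structure(list(gaze_x = as.numeric(gaze_x), gaze_y = as.numeric(gaze_y),
                        valid = as.logical(valid), fs = fs,
                        screen_size = as.numeric(screen_size),
                        subject_id = subject_id,
                        trials = normalize_trials(trials)),
                   class = "et_recording")
  validate_recording(rec)
  rec
}

#' Construct a single trial annotation
#'
#' @param start,end 0-based half-open sample range of the trial.
#' @param label 1 = buy, 0 = no-buy.
#' @param product_id product identifier string.
#' @return One-row trial annotation data frame.
#' @export
trial_annotation <- function(start, end, label, product_id = "P01") {
  if (start >= end) stop("trial must satisfy start < end")
  if (!label %in% c(0, 1)) stop("trial label must be 0 (no-buy) or 1 (buy)")
  data.frame(start = as.integer(start), end = as.integer(end),
             label = as.integer(label), product_id = as.character(product_id),
             stringsAsFactors = FALSE)
}

normalize_trials <- function(trials) {
  if (is.null(trials))
    return(data.frame(start = integer(), end = integer(), label = integer(),
                      product_id = character(), stringsAsFactors = FALSE))
  stopifnot(all(c("start", "end", "label") %in% names(trials)))
  if (is.null(trials$product_id))
    trials$product_id <- paste0("P", seq_len(nrow(trials)))
  trials[, c("start", "end", "label", "product_id")]
}

n_samples <- function(rec) {
  if (inherits(rec, "eeg_recording")) ncol(rec$data) else length(rec$gaze_x)
}

validate_recording <- function(rec) {
  if (rec$fs <= 0) stop("sampling rate fs must be positive")
  ns <- n_samples(rec)
  if (inherits(rec, "eeg_recording")) {
    if (nrow(rec$data) != length(rec$channel_names))
      stop("channel count (", nrow(rec$data), ") does not match the number of ",
           "declared channel names (", length(rec$channel_names), ")")
  } else {
    if (length(rec$gaze_x) != length(rec$gaze_y) ||
        length(rec$gaze_x) != length(rec$valid))
      stop("gaze_x, gaze_y and valid must have equal length")
    if (length(rec$screen_size) != 2 || any(rec$screen_size <= 0))
      stop("screen_size must be positive (width, height)")
    ok <- rec$valid
    if (any(is.na(rec$gaze_x[ok])) || any(is.na(rec$gaze_y[ok])))
      stop("samples flagged valid must have coordinates (NA found)")
    if (any(rec$gaze_x[ok] < 0 | rec$gaze_x[ok] >= rec$screen_size[1]) ||
        any(rec$gaze_y[ok] < 0 | rec$gaze_y[ok] >= rec$screen_size[2]))
      stop("valid gaze samples must lie within the screen bounds")
  }
  tr <- rec$trials
  if (nrow(tr)) {
    if (any(tr$start >= tr$end)) stop("trials must satisfy start < end")
    if (any(tr$start < 0) || any(tr$end > ns))
      stop("trial sample ranges must lie within [0, ", ns, ")")
    if (!all(tr$label %in% c(0L, 1L))) stop("trial labels must be 0 or 1")
  }
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s: %d channels x %d samples @ %g Hz, %d trials\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs, nrow(x$trials)))
  invisible(x)
}

#' @export
print.et_recording <- function(x, ...) {
  cat(sprintf("<et_recording> subject %s: %d samples @ %g Hz (%.1f%% valid), %d trials\n",
              x$subject_id, length(x$gaze_x), x$fs, 100 * mean(x$valid),
              nrow(x$trials)))
  invisible(x)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Read a recording from its on-disk layout
#'
#' Recordings live in one directory per subject: `eeg.csv` (one column per
#' channel, header row = channel names), `et.csv` (columns `t,x,y,valid`;
#' invalid rows keep empty x/y cells), `trials.csv` (columns
#' `stream,start,end,label,product_id`) and `meta.json` (sampling rates,
#' screen size, subject id).
#'
#' @param path subject directory.
#' @param kind `"eeg"` or `"et"`.
#' @return An `eeg_recording` or `et_recording`.
#' @export
read_recording <- function(path, kind = c("eeg", "et")) {
  kind <- match.arg(kind)
  if (!dir.exists(path)) stop("no such subject directory: ", path)
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("missing meta.json in ", path)
  meta <- jsonlite::fromJSON(meta_path)
  trials <- read_trials_csv(file.path(path, "trials.csv"), kind)
  if (kind == "eeg") {
    f <- file.path(path, "eeg.csv")
    if (!file.exists(f)) stop("missing eeg.csv in ", path)
    df <- utils::read.csv(f, check.names = FALSE)
    if (anyNA(df)) {
      bad <- which(apply(is.na(df), 1, any))[1]
      stop("malformed eeg.csv: non-numeric or missing value at data row ", bad)
    }
    fs <- as.numeric(meta$eeg_fs)
    if (is.null(meta$eeg_fs) || fs <= 0) stop("meta.json: eeg_fs must be positive")
    if (!is.null(meta$channel_names) &&
        length(meta$channel_names) != ncol(df))
      stop("eeg.csv has ", ncol(df), " data columns but ",
           length(meta$channel_names), " channel names are declared")
    eeg_recording(t(as.matrix(df)), channel_names = colnames(df), fs = fs,
                  subject_id = as.character(meta$subject_id), trials = trials)
  } else {
    f <- file.path(path, "et.csv")
    if (!file.exists(f)) stop("missing et.csv in ", path)
    df <- utils::read.csv(f)
    if (!all(c("x", "y", "valid") %in% names(df)))
      stop("malformed et.csv: expected columns t,x,y,valid")
    bad <- which(df$valid == 1 & (is.na(df$x) | is.na(df$y)))
    if (length(bad))
      stop("malformed et.csv: row ", bad[1], " is flagged valid but has missing coordinates")
    fs <- as.numeric(meta$et_fs)
    if (is.null(meta$et_fs) || fs <= 0) stop("meta.json: et_fs must be positive")
    et_recording(df$x, df$y, valid = df$valid == 1, fs = fs,
                 screen_size = as.numeric(meta$screen_size),
                 subject_id = as.character(meta$subject_id), trials = trials)
  }
}

read_trials_csv <- function(path, stream) {
  if (!file.exists(path))
    return(NULL)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$stream == stream, c("start", "end", "label", "product_id")]
  rownames(df) <- NULL
  df
}

#' Write a recording to the package's on-disk layout
#'
#' The inverse of [read_recording()]: numeric fields are written with full
#' precision so that write-then-read round-trips exactly.
#'
#' @param rec an `eeg_recording` or `et_recording`.
#' @param path subject directory (created if needed).
#' @return The subject directory path, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  if (file.exists(path) && !dir.exists(path))
    stop("cannot write recording: ", path, " exists and is not a directory")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  kind <- if (inherits(rec, "eeg_recording")) "eeg" else "et"
  meta_path <- file.path(path, "meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::fromJSON(meta_path) else list()
  meta$subject_id <- rec$subject_id
  if (kind == "eeg") {
    meta$eeg_fs <- rec$fs
    meta$channel_names <- rec$channel_names
    con <- file.path(path, "eeg.csv")
    lines <- c(paste(rec$channel_names, collapse = ","),
               apply(rec$data, 2, function(col) paste(fmt_num(col), collapse = ",")))
    writeLines(lines, con)
  } else {
    meta$et_fs <- rec$fs
    meta$screen_size <- rec$screen_size
    x <- ifelse(rec$valid, fmt_num(rec$gaze_x), "")
    y <- ifelse(rec$valid, fmt_num(rec$gaze_y), "")
    lines <- c("t,x,y,valid",
               paste(seq_along(x) - 1L, x, y, as.integer(rec$valid), sep = ","))
    writeLines(lines, file.path(path, "et.csv"))
  }
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  write_trials_csv(rec$trials, file.path(path, "trials.csv"), kind)
  invisible(path)
}

write_trials_csv <- function(trials, path, stream) {
  old <- if (file.exists(path)) utils::read.csv(path, stringsAsFactors = FALSE)
         else data.frame(stream = character(), start = integer(), end = integer(),
                         label = integer(), product_id = character(),
                         stringsAsFactors = FALSE)
  old <- old[old$stream != stream, , drop = FALSE]
  if (nrow(trials)) {
    add <- cbind(stream = stream, trials, stringsAsFactors = FALSE)
    old <- rbind(old, add)
  }
  utils::write.csv(old, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a whole dataset directory
#'
#' Reads every subject directory (any subdirectory containing `meta.json`)
#' under `dir` into the paired-recording structure consumed by
#' [run_experiment()].
#'
#' @param dir dataset directory, e.g. as written by [generate_dataset()].
#' @return List of per-subject `list(eeg =, et =)` recordings.
#' @export
read_dataset <- function(dir) {
  subs <- list.dirs(dir, recursive = FALSE)
  subs <- subs[file.exists(file.path(subs, "meta.json"))]
  if (!length(subs)) stop("no subject directories with meta.json under ", dir)
  lapply(subs, function(sd)
    list(eeg = read_recording(sd, "eeg"), et = read_recording(sd, "et")))
}

#' Extract one trial from a recording
#'
#' Returns the recording slice covering the trial's half-open sample range,
#' with the trial re-annotated at offset 0 and subject metadata propagated.
#' Sample values are copied untouched; no filtering happens here.
#'
#' @param rec an `eeg_recording` or `et_recording`.
#' @param trial a one-row trial data frame (e.g. from [trial_annotation()]
#'   or one row of `rec$trials`).
#' @return A recording slice of the same class with `end - start` samples.
#' @export
extract_trial <- function(rec, trial) {
  start <- trial$start[1]; end <- trial$end[1]
  ns <- n_samples(rec)
  if (start < 0 || end > ns || start >= end)
    stop("trial range [", start, ", ", end, ") out of bounds for a recording ",
         "with ", ns, " samples")
  idx <- (start + 1L):end
  tr <- trial_annotation(0L, end - start, trial$label[1], trial$product_id[1])
  if (inherits(rec, "eeg_recording")) {
    eeg_recording(rec$data[, idx, drop = FALSE], rec$channel_names, rec$fs,
                  rec$subject_id, tr)
  } else {
    et_recording(rec$gaze_x[idx], rec$gaze_y[idx], rec$valid[idx], rec$fs,
                 rec$screen_size, rec$subject_id, tr)
  }
}
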