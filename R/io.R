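#' Event table
#'
#' Experimental events: onset and duration in seconds plus a condition
#' label, mirroring a BIDS-style `events.tsv`.
#'
#' @param onset,duration Numeric vectors, seconds; durations >= 0.
#' @param condition Character vector of condition labels.
#' @return A data.frame of class `event_table` with columns `onset`,
#'   `duration`, `condition`, sorted by onset.
#' @export
event_table <- function(onset, duration, condition) {
  stopifnot(length(onset) == length(duration),
            length(onset) == length(condition),
            all(duration >= 0), all(onset >= 0))
  ev <- data.frame(onset = as.numeric(onset),
                   duration = as.numeric(duration),
                   condition = as.character(condition))
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Read / write event tables (BIDS-style TSV)
#'
#' Columns `onset`, `duration`, `trial_type` (read) or the `event_table`
#' columns (write; `condition` is written as `trial_type`).
#'
#' @param path File path.
#' @param events An [event_table()].
#' @return `read_events()` returns an [event_table()].
#' @export
read_events <- function(path) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(d)))
    stop("events file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  event_table(d$onset, d$duration, d$trial_type)
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  d <- data.frame(onset = events$onset, duration = events$duration,
                  trial_type = events$condition)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

od_colnames <- function(channel_ids, wavelengths) {
  c(paste0(channel_ids, "_", wavelengths[1]),
    paste0(channel_ids, "_", wavelengths[2]))
}

#' Read / write optical-density recordings as wide TSV
#'
#' Plain-text dialect: first column `time` (s), one column per channel and
#' wavelength named `<channel>_<wavelength>` (e.g. `CH1_695`). Both
#' wavelength planes must be present for every channel.
#'
#' @param path File path (`.tsv`/`.csv`, delimiter inferred).
#' @param rec An [optical_recording()].
#' @return `read_od_table()` returns an [optical_recording()].
#' @export
read_od_table <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  d <- utils::read.table(path, sep = sep, header = TRUE,
                         check.names = FALSE)
  time <- d[[1]]
  fs <- 1 / stats::median(diff(time))
  cols <- names(d)[-1]
  parts <- regmatches(cols, regexec("^(.*)_([0-9.]+)$", cols))
  if (any(lengths(parts) != 3))
    stop("optical-density columns must be named <channel>_<wavelength>",
         call. = FALSE)
  ch <- vapply(parts, `[`, "", 2)
  wl <- as.numeric(vapply(parts, `[`, "", 3))
  wls <- sort(unique(wl))
  if (length(wls) != 2) stop("expected exactly two wavelengths, found ",
                             length(wls), call. = FALSE)
  chans <- unique(ch)
  od <- array(NA_real_, c(nrow(d), length(chans), 2))
  for (k in 1:2) {
    idx <- match(paste0(chans, "_", wls[k]), cols)
    if (anyNA(idx)) stop("missing wavelength plane for some channels",
                         call. = FALSE)
    od[, , k] <- as.matrix(d[, idx + 1L, drop = FALSE])
  }
  optical_recording(od, fs, chans, wls)
}

#' @rdname read_od_table
#' @export
write_od_table <- function(rec, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  M <- dim(rec$od)[1]
  d <- data.frame(time = (seq_len(M) - 1) / rec$fs,
                  cbind(rec$od[, , 1], rec$od[, , 2]),
                  check.names = FALSE)
  names(d) <- c("time", od_colnames(rec$channel_ids, rec$wavelengths))
  utils::write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write hemoglobin series as wide TSV
#'
#' First column `time` (s), then `<channel>_hbo` and `<channel>_hbr`
#' columns in mM.
#'
#' @param path File path.
#' @param hb An [hb_series()].
#' @return `read_hb_table()` returns an [hb_series()].
#' @export
write_hb_table <- function(hb, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  M <- nrow(hb$hbo)
  d <- data.frame(time = (seq_len(M) - 1) / hb$fs, hb$hbo, hb$hbr,
                  check.names = FALSE)
  names(d) <- c("time", paste0(hb$channel_ids, "_hbo"),
                paste0(hb$channel_ids, "_hbr"))
  utils::write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hb_table
#' @export
read_hb_table <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  d <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE)
  fs <- 1 / stats::median(diff(d[[1]]))
  cols <- names(d)[-1]
  hbo_cols <- grep("_hbo$", cols, value = TRUE)
  chans <- sub("_hbo$", "", hbo_cols)
  hbo <- as.matrix(d[, paste0(chans, "_hbo"), drop = FALSE])
  hbr <- as.matrix(d[, paste0(chans, "_hbr"), drop = FALSE])
  hb_series(hbo, hbr, fs, chans)
}

#' Read / write a SNIRF-style HDF5 container
#'
#' Minimal reader and writer for the SNIRF layout used by fNIRS
#' acquisition software: `/nirs/data1/dataTimeSeries` (time x
#' measurement), `/nirs/data1/time`, one `measurementList<k>` group per
#' measurement column (source, detector and wavelength indices), and
#' `/nirs/probe` with `wavelengths`, `sourcePos3D` and `detectorPos3D`
#' (MNI mm). Only continuous-wave dual-wavelength data are supported.
#'
#' @param path HDF5 file path.
#' @param rec An [optical_recording()] with a [probe_layout()] attached
#'   (geometry is optional when writing).
#' @return `read_snirf()` returns an [optical_recording()] (with layout if
#'   the probe group holds positions).
#' @export
read_snirf <- function(path) {
  ls <- rhdf5::h5ls(path)
  time <- as.numeric(rhdf5::h5read(path, "/nirs/data1/time"))
  fs <- if (length(time) > 1) 1 / stats::median(diff(time)) else 1
  Y <- rhdf5::h5read(path, "/nirs/data1/dataTimeSeries")
  Y <- as.matrix(Y)
  if (nrow(Y) != length(time) && ncol(Y) == length(time)) Y <- t(Y)
  wl <- as.numeric(rhdf5::h5read(path, "/nirs/probe/wavelengths"))
  ml_names <- ls$name[grepl("^measurementList[0-9]+$", ls$name)]
  ml_names <- unique(ml_names)
  ml_names <- ml_names[order(as.integer(sub("measurementList", "", ml_names)))]
  src <- det <- wli <- integer(length(ml_names))
  for (k in seq_along(ml_names)) {
    g <- paste0("/nirs/data1/", ml_names[k])
    src[k] <- as.integer(rhdf5::h5read(path, paste0(g, "/sourceIndex")))
    det[k] <- as.integer(rhdf5::h5read(path, paste0(g, "/detectorIndex")))
    wli[k] <- as.integer(rhdf5::h5read(path, paste0(g, "/wavelengthIndex")))
  }
  pair_id <- paste0("S", src, "D", det)
  chans <- unique(pair_id)
  J <- length(chans)
  od <- array(NA_real_, c(nrow(Y), J, 2))
  for (k in seq_along(ml_names))
    od[, match(pair_id[k], chans), wli[k]] <- Y[, k]
  layout <- NULL
  if (any(ls$name == "sourcePos3D")) {
    sp <- t(as.matrix(rhdf5::h5read(path, "/nirs/probe/sourcePos3D")))
    dp <- t(as.matrix(rhdf5::h5read(path, "/nirs/probe/detectorPos3D")))
    if (ncol(sp) != 3) sp <- t(sp)
    if (ncol(dp) != 3) dp <- t(dp)
    pairs <- cbind(src, det)[wli == 1, , drop = FALSE]
    layout <- probe_layout(source_pos = sp, detector_pos = dp,
                           channel_pairs = pairs, channel_ids = chans)
  }
  optical_recording(od, fs, chans, wl, layout)
}

#' @rdname read_snirf
#' @export
write_snirf <- function(rec, path) {
  stopifnot(inherits(rec, "optical_recording"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write("1.0", path, "formatVersion")
  rhdf5::h5createGroup(path, "nirs")
  rhdf5::h5createGroup(path, "nirs/data1")
  rhdf5::h5createGroup(path, "nirs/probe")
  M <- dim(rec$od)[1]; J <- dim(rec$od)[2]
  Y <- cbind(rec$od[, , 1], rec$od[, , 2])
  rhdf5::h5write(Y, path, "nirs/data1/dataTimeSeries")
  rhdf5::h5write((seq_len(M) - 1) / rec$fs, path, "nirs/data1/time")
  lay <- rec$layout
  pairs <- if (!is.null(lay)) lay$channel_pairs else cbind(seq_len(J), seq_len(J))
  for (w in 1:2) for (j in seq_len(J)) {
    k <- (w - 1) * J + j
    g <- paste0("nirs/data1/measurementList", k)
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(as.integer(pairs[j, 1]), path, paste0(g, "/sourceIndex"))
    rhdf5::h5write(as.integer(pairs[j, 2]), path, paste0(g, "/detectorIndex"))
    rhdf5::h5write(as.integer(w), path, paste0(g, "/wavelengthIndex"))
    rhdf5::h5write("dOD", path, paste0(g, "/dataTypeLabel"))
  }
  rhdf5::h5write(rec$wavelengths, path, "nirs/probe/wavelengths")
  if (!is.null(lay)) {
    rhdf5::h5write(lay$source_pos, path, "nirs/probe/sourcePos3D")
    rhdf5::h5write(lay$detector_pos, path, "nirs/probe/detectorPos3D")
  }
  invisible(path)
}

#' Read / write a probe layout as TSV
#'
#' Long format with columns `label`, `type` (`source`, `detector` or
#' `channel`), `x`, `y`, `z` (MNI mm) and, for channel rows, `source` and
#' `detector` labels.
#'
#' @param path File path.
#' @param layout A [probe_layout()].
#' @return `read_layout()` returns a [probe_layout()].
#' @export
read_layout <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  src <- d[d$type == "source", ]
  det <- d[d$type == "detector", ]
  ch <- d[d$type == "channel", ]
  pairs <- cbind(match(ch$source, src$label), match(ch$detector, det$label))
  probe_layout(source_pos = as.matrix(src[, c("x", "y", "z")]),
               detector_pos = as.matrix(det[, c("x", "y", "z")]),
               channel_pairs = pairs, channel_ids = ch$label)
}

#' @rdname read_layout
#' @export
write_layout <- function(layout, path) {
  ns <- nrow(layout$source_pos); nd <- nrow(layout$detector_pos)
  d <- rbind(
    data.frame(label = paste0("S", seq_len(ns)), type = "source",
               layout$source_pos, source = "", detector = ""),
    data.frame(label = paste0("D", seq_len(nd)), type = "detector",
               layout$detector_pos, source = "", detector = ""),
    data.frame(label = layout$channel_ids, type = "channel",
               layout$channel_pos,
               source = paste0("S", layout$channel_pairs[, 1]),
               detector = paste0("D", layout$channel_pairs[, 2]))
  )
  names(d)[3:5] <- c("x", "y", "z")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write channel-wise contrast values as TSV
#'
#' @param con A `channel_contrast` (see [contrast_channels()]).
#' @param path File path.
#' @export
write_contrast_table <- function(con, path) {
  utils::write.table(
    data.frame(channel = names(con$w), w = as.numeric(con$w),
               subject = con$subject_id),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
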