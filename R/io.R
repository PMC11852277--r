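#' Read one channel from delimited text
#'
#' Accepts either a single column of samples (requires `fs`) or two
#' columns `time,value` on a uniform grid (fs inferred). A header line is
#' detected automatically.
#'
#' @param file Path to the channel file.
#' @param fs Sampling frequency in Hz (single-column files).
#' @param label Channel label; defaults to the file name stem.
#' @param units Unit string.
#' @return A [time_series].
#' @export
read_channel <- function(file, fs = NULL, label = NULL, units = "") {
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(file))
  first <- readLines(file, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  fields <- strsplit(trimws(first),
                     if (sep == ",") "," else "[;\t ]+")[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(fields))))
  d <- utils::read.table(file, header = has_header, sep = sep,
                         comment.char = "#")
  if (ncol(d) >= 2L) {
    tt <- d[[1L]]; x <- d[[2L]]
    dt <- diff(tt)
    if (max(abs(dt - dt[1L])) > 1e-6 * dt[1L])
      stop("time column is not uniformly sampled: ", file, call. = FALSE)
    time_series(x, 1 / dt[1L], label, t0 = tt[1L], units = units)
  } else {
    if (is.null(fs))
      stop("single-column channel file needs `fs`: ", file, call. = FALSE)
    time_series(d[[1L]], fs, label, units = units)
  }
}

#' Write one channel as delimited text
#'
#' Writes `time,value` pairs with a header so the file is self-describing
#' (the sampling frequency is recoverable from the time column).
#'
#' @param ts A [time_series].
#' @param file Output path.
#' @export
write_channel <- function(ts, file) {
  stopifnot(inherits(ts, "time_series"))
  utils::write.csv(as.data.frame(ts), file, row.names = FALSE)
  invisible(file)
}

#' Write a cohort to a directory tree
#'
#' One sub-directory per subject with single-column channel files, a YAML
#' sidecar per subject giving each channel's sampling frequency, class and
#' units, a cohort-level `manifest.csv` (subject, group, channel, class,
#' file, fs), and the ground-truth `ledger.csv`. This is the same format
#' [read_cohort()] and the command-line `analyze` entry point consume.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in cohort$subjects) {
    sdir <- file.path(dir, s$id)
    dir.create(sdir, showWarnings = FALSE)
    meta <- list()
    chans <- c(s$fnirs, s$eeg, list(ECG = s$ecg, Resp = s$resp))
    classes <- c(rep("fnirs", length(s$fnirs)),
                 rep("eeg", length(s$eeg)), "ecg", "respiration")
    for (i in seq_along(chans)) {
      ch <- chans[[i]]
      f <- file.path(sdir, paste0(ch$label, ".txt"))
      writeLines(formatC(ch$samples, format = "g", digits = 8), f)
      meta[[ch$label]] <- list(fs = ch$fs, class = classes[i],
                               units = ch$units)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s$id, group = s$group, channel = ch$label,
        class = classes[i], file = file.path(s$id, basename(f)),
        fs = ch$fs, stringsAsFactors = FALSE)
    }
    yaml::write_yaml(meta, file.path(sdir, "channels.yaml"))
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$ledger, file.path(dir, "ledger.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory containing `manifest.csv`.
#' @return A `cohort`-like list with `subjects`, `manifest` and (when
#'   present) `ledger`; no `spec` element, since files are the source.
#' @export
read_cohort <- function(dir) {
  mf_path <- file.path(dir, "manifest.csv")
  if (!file.exists(mf_path))
    stop("no manifest.csv in ", dir, call. = FALSE)
  mf <- utils::read.csv(mf_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "channel", "class", "file", "fs")
  missing_cols <- setdiff(need, names(mf))
  if (length(missing_cols))
    stop("manifest.csv lacks required field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  subjects <- list()
  for (sid in unique(mf$subject_id)) {
    rows <- mf[mf$subject_id == sid, ]
    s <- list(id = sid, group = rows$group[1L],
              fnirs = list(), eeg = list(), ecg = NULL, resp = NULL)
    for (r in seq_len(nrow(rows))) {
      path <- file.path(dir, rows$file[r])
      if (!file.exists(path))
        stop("channel file missing: ", path, call. = FALSE)
      ts <- read_channel(path, fs = rows$fs[r], label = rows$channel[r])
      switch(rows$class[r],
             fnirs = { s$fnirs[[rows$channel[r]]] <- ts },
             eeg = { s$eeg[[rows$channel[r]]] <- ts },
             ecg = { s$ecg <- ts },
             respiration = { s$resp <- ts },
             stop("unknown channel class: ", rows$class[r], call. = FALSE))
    }
    subjects[[sid]] <- structure(s, class = "subject_recording")
  }
  ledger_path <- file.path(dir, "ledger.csv")
  out <- list(subjects = subjects,
              manifest = unique(mf[, c("subject_id", "group")]),
              ledger = if (file.exists(ledger_path))
                utils::read.csv(ledger_path, stringsAsFactors = FALSE)
              else NULL)
  names(out$manifest) <- c("id", "group")
  structure(out, class = "cohort")
}
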