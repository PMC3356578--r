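#' Activity-count series
#'
#' Container for uniformly binned, non-negative activity counts (e.g.
#' wheel-running counts per 10-min epoch). Epoch `i` covers absolute time
#' `[start_h + (i-1)*epoch_min/60, start_h + i*epoch_min/60)`; the lighting
#' state of an epoch is the state at its start. A logical `gap` mask marks
#' epochs that were missing in the source file and zero-filled; metrics
#' exclude masked epochs from their denominators.
#'
#' @param counts numeric vector of non-negative counts.
#' @param epoch_min epoch length in minutes.
#' @param start_h absolute start time (hours from experiment start).
#' @param subject_id,group metadata labels.
#' @param gap logical vector marking zero-filled gap epochs (default none).
#' @return An object of class `activity_series`.
#' @export
activity_series <- function(counts, epoch_min, start_h = 0,
                            subject_id = "s1", group = NA_character_,
                            gap = NULL) {
  counts <- as.numeric(counts)
  if (length(counts) < 1L) stop("counts must have length >= 1")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (epoch_min <= 0) stop("epoch_min must be positive")
  if (is.null(gap)) gap <- rep(FALSE, length(counts))
  if (length(gap) != length(counts)) stop("gap mask length mismatch")
  structure(list(counts = counts, epoch_min = epoch_min, start_h = start_h,
                 subject_id = subject_id, group = group, gap = gap),
            class = "activity_series")
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf(
    "<activity_series> %s%s: %d epochs x %g min (%.1f days), start %g h\n",
    x$subject_id, if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
    length(x$counts), x$epoch_min,
    length(x$counts) * x$epoch_min / 1440, x$start_h))
  cat(sprintf("  total counts %g; %d gap epoch(s)\n",
              sum(x$counts), sum(x$gap)))
  invisible(x)
}

epoch_starts <- function(series) {
  series$start_h + (seq_along(series$counts) - 1L) * series$epoch_min / 60
}

epochs_per_day <- function(series) 1440 / series$epoch_min

# indices of epochs belonging to complete days fully covered by the series
complete_day_index <- function(series) {
  ep <- series$epoch_min / 60
  starts <- epoch_starts(series)
  days <- floor(starts / 24)
  full <- as.integer(names(which(table(days) == epochs_per_day(series))))
  list(days = full, idx = which(days %in% full), day_of = days)
}

#' Rebin an activity series to a coarser epoch
#'
#' Sums counts within each new bin. The new epoch must be a positive integer
#' multiple of the old one; a trailing partial bin is dropped. Total counts
#' are conserved up to that dropped bin. A rebinned epoch is gap-masked if
#' any constituent epoch was.
#'
#' @param series an [activity_series()].
#' @param new_epoch_min target epoch length, minutes.
#' @return An [activity_series()] with epoch `new_epoch_min`.
#' @export
rebin <- function(series, new_epoch_min) {
  k <- new_epoch_min / series$epoch_min
  if (k != round(k) || k < 1)
    stop("new_epoch_min must be a positive integer multiple of epoch_min")
  k <- as.integer(k)
  if (k == 1L) return(series)
  n <- (length(series$counts) %/% k) * k
  grp <- rep(seq_len(n %/% k), each = k)
  counts <- as.numeric(tapply(series$counts[seq_len(n)], grp, sum))
  gap <- as.logical(tapply(series$gap[seq_len(n)], grp, any))
  activity_series(counts, new_epoch_min, series$start_h,
                  series$subject_id, series$group, gap)
}

#' Fold a series into a cycle-by-bin matrix
#'
#' Reshapes the series into one row per complete cycle of `fold_period_h`
#' hours (an incomplete trailing cycle is excluded); the column means are the
#' across-cycle mean profile used by actograms, interdaily stability and the
#' periodogram.
#'
#' @param series an [activity_series()].
#' @param fold_period_h folding period in hours; `fold_period_h * 60` must be
#'   divisible by the epoch length.
#' @return An object of class `daily_matrix`: list with `mat`
#'   (cycles x bins), `fold_period_h`, `epoch_min`.
#' @export
fold_daily <- function(series, fold_period_h = 24) {
  k <- fold_period_h * 60 / series$epoch_min
  if (k != round(k)) stop("fold period must be a whole number of epochs")
  k <- as.integer(k)
  m <- length(series$counts) %/% k
  if (m < 1L) stop("series shorter than one fold cycle")
  mat <- matrix(series$counts[seq_len(m * k)], nrow = m, ncol = k,
                byrow = TRUE)
  structure(list(mat = mat, fold_period_h = fold_period_h,
                 epoch_min = series$epoch_min),
            class = "daily_matrix")
}

#' @export
print.daily_matrix <- function(x, ...) {
  cat(sprintf("<daily_matrix> %d cycle(s) x %d bins, folded at %g h\n",
              nrow(x$mat), ncol(x$mat), x$fold_period_h))
  invisible(x)
}

# ---- file formats -----------------------------------------------------------

iso_origin <- as.POSIXct("2000-01-01 00:00:00", tz = "UTC")

awd_epoch_codes <- c("1" = 0.25, "2" = 0.5, "4" = 1, "8" = 2, "20" = 5)

#' Read activity tables
#'
#' Two dialects are supported. `"long_csv"` is a long-format CSV with header
#' `subject_id,timestamp,counts` and ISO-8601 timestamps; one series is
#' returned per subject, the epoch length is inferred from the timestamp
#' spacing, and missing epochs are zero-filled and flagged in the series' gap
#' mask. `"awd"` is Actiwatch-style text: seven header lines (ID, start date,
#' start time, epoch code, age, serial, sex) followed by one count per line.
#'
#' @param path input file.
#' @param dialect `"long_csv"` or `"awd"`.
#' @return A list of [activity_series()] (one element for `"awd"`).
#' @export
read_activity_table <- function(path, dialect = c("long_csv", "awd")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "awd") return(list(read_awd(path)))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "timestamp", "counts")
  if (!all(req %in% names(df)))
    stop("long_csv must have columns: ", paste(req, collapse = ", "))
  if (any(df$counts < 0)) stop("negative counts in ", path)
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (any(is.na(ts))) stop("unparseable timestamps in ", path)
  origin <- min(ts)
  out <- lapply(split(seq_len(nrow(df)), df$subject_id), function(idx) {
    tsub <- ts[idx][order(ts[idx])]
    csub <- df$counts[idx][order(ts[idx])]
    if (length(tsub) > 1L) {
      d <- as.numeric(diff(tsub), units = "secs")
      ep_sec <- min(d)
      if (any(abs(d / ep_sec - round(d / ep_sec)) > 1e-6))
        stop("non-uniform timestamps for subject ", df$subject_id[idx][1])
      ep_min <- ep_sec / 60
      slots <- round(as.numeric(tsub - tsub[1], units = "secs") / ep_sec) + 1L
      n <- max(slots)
      counts <- numeric(n); gap <- rep(TRUE, n)
      counts[slots] <- csub; gap[slots] <- FALSE
    } else {
      ep_min <- 10; counts <- csub; gap <- FALSE
    }
    start_h <- as.numeric(tsub[1] - origin, units = "hours")
    activity_series(counts, ep_min, start_h,
                    subject_id = df$subject_id[idx][1],
                    group = if ("group" %in% names(df)) df$group[idx][1]
                            else NA_character_,
                    gap = gap)
  })
  unname(out)
}

read_awd <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 8L) stop("awd file too short: ", path)
  hdr <- lines[1:7]
  code <- trimws(hdr[4])
  if (!code %in% names(awd_epoch_codes))
    stop("unknown awd epoch code: ", code)
  counts <- suppressWarnings(as.numeric(trimws(lines[-(1:7)])))
  counts <- counts[!is.na(counts)]
  if (any(counts < 0)) stop("negative counts in ", path)
  start <- as.POSIXct(paste(trimws(hdr[2]), trimws(hdr[3])), tz = "UTC",
                      tryFormats = c("%d-%b-%Y %H:%M", "%Y-%m-%d %H:%M"))
  start_h <- if (is.na(start)) 0 else
    as.numeric(start - trunc(start, "days"), units = "hours")
  activity_series(counts, awd_epoch_codes[[code]], start_h,
                  subject_id = trimws(hdr[1]))
}

#' Write activity tables
#'
#' Inverse of [read_activity_table()]; `long_csv` output round-trips counts
#' exactly. Timestamps are synthesized from a fixed UTC origin plus each
#' series' start offset. AWD output requires an epoch length in the
#' Actiwatch code table (15 s, 30 s, 1 min, 2 min or 5 min).
#'
#' @param series_list a list of [activity_series()] (or a single series).
#' @param path output file.
#' @param dialect `"long_csv"` or `"awd"` (awd: first series only).
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(series_list, path,
                                 dialect = c("long_csv", "awd")) {
  dialect <- match.arg(dialect)
  if (inherits(series_list, "activity_series")) series_list <- list(series_list)
  if (dialect == "awd") {
    s <- series_list[[1]]
    code <- names(awd_epoch_codes)[match(s$epoch_min, awd_epoch_codes)]
    if (is.na(code)) stop("epoch ", s$epoch_min, " min not encodable as awd")
    start <- iso_origin + s$start_h * 3600
    writeLines(c(s$subject_id, format(start, "%d-%b-%Y"),
                 format(start, "%H:%M"), code, "0", "NA", "U",
                 format(s$counts, trim = TRUE, scientific = FALSE)), path)
    return(invisible(path))
  }
  rows <- lapply(series_list, function(s) {
    ts <- iso_origin + (s$start_h + (seq_along(s$counts) - 1L) *
                          s$epoch_min / 60) * 3600
    data.frame(subject_id = s$subject_id,
               timestamp = format(ts, "%Y-%m-%dT%H:%M:%S"),
               counts = s$counts,
               group = s$group)
  })
  df <- do.call(rbind, rows)
  if (all(is.na(df$group))) df$group <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
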