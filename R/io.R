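#' Read an RR-interval series from disk
#'
#' Supports plain RR text (one interval per line; blank lines and `#` comments
#' skipped) and CSV with a configurable RR column. Values are converted to
#' seconds according to `unit` (`"auto"` detects milliseconds from the median,
#' see [rr_series]).
#'
#' @param path input file.
#' @param format `"auto"` (by extension: `.csv` -> csv, else rr text),
#'   `"rr_text"` or `"csv"`.
#' @param unit `"auto"`, `"seconds"` or `"milliseconds"`.
#' @param rr_column for CSV input, the name or index of the RR column
#'   (default `"rr"`; falls back to the last numeric column).
#' @return An [rr_series] with `source_id = path`.
#' @export
read_rr <- function(path, format = c("auto", "rr_text", "csv"),
                    unit = "auto", rr_column = "rr") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "rr_text"
  if (format == "rr_text") {
    raw <- readLines(path, warn = FALSE)
    keep <- which(!grepl("^\\s*(#|$)", raw))
    vals <- suppressWarnings(as.numeric(trimws(raw[keep])))
    if (anyNA(vals)) {
      bad <- keep[which(is.na(vals))[1L]]
      stop("cannot parse RR value on line ", bad, " of ", path, ": '",
           raw[bad], "'")
    }
  } else {
    tab <- utils::read.csv(path)
    col <- if (is.numeric(rr_column)) rr_column else {
      hit <- match(tolower(rr_column), tolower(names(tab)))
      if (is.na(hit)) {
        num <- which(vapply(tab, is.numeric, TRUE))
        if (!length(num)) stop("no numeric RR column found in ", path)
        num[length(num)]
      } else hit
    }
    vals <- as.numeric(tab[[col]])
  }
  rr_series(vals, unit = unit, source_id = path)
}

#' RR intervals from beat annotation times
#'
#' Converts a strictly increasing sequence of beat times (seconds) into
#' successive differences. All beats are retained by default: ectopic-labeled
#' beats carry the compensated short-long structure the line detectors look
#' for, so the conventional NN-only cleaning must not be applied upstream of
#' this analysis. An opt-in filter supports comparisons with conventional
#' NN-interval processing.
#'
#' @param beat_times numeric vector of beat occurrence times in seconds.
#' @param beat_labels optional character labels per beat (e.g. Physionet
#'   annotation codes).
#' @param keep_labels `NULL` (default: keep everything) or a character vector
#'   of labels to retain; beats with other labels are dropped before
#'   differencing.
#' @return An [rr_series].
#' @export
intervals_from_annotations <- function(beat_times, beat_labels = NULL,
                                       keep_labels = NULL) {
  beat_times <- as.numeric(beat_times)
  if (!is.null(keep_labels)) {
    if (is.null(beat_labels) || length(beat_labels) != length(beat_times))
      stop("keep_labels given but beat_labels missing or wrong length")
    beat_times <- beat_times[beat_labels %in% keep_labels]
  }
  if (length(beat_times) < 3L)
    stop("need at least 3 beat times to form an RR series")
  d <- diff(beat_times)
  bad <- which(d <= 0)
  if (length(bad))
    stop("beat times not strictly increasing at index ", bad[1L] + 1L)
  rr_series(d, unit = "seconds", source_id = "annotations")
}

fmt12 <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "g"))
}

write_csv_stable <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  for (j in which(num)) out[[j]] <- fmt12(df[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write analysis outputs to a directory
#'
#' Writes `signature.json` and `signature.csv` (fixed signature row order),
#' `matches.csv` (beat index, line, cos theta, amplitude) and, when an order
#' scan is supplied, `phi_scan.csv`. Floats are serialized with 12 significant
#' digits so repeated runs with identical inputs produce byte-identical files.
#'
#' @param sig a `signature_vector` (or `NULL` to skip signature outputs).
#' @param out_dir output directory; created if missing.
#' @param scan optional `order_scan` data frame.
#' @param config optional list serialized to `run_config.json` for provenance.
#' @return Invisibly, the vector of files written.
#' @export
write_outputs <- function(sig, out_dir, scan = NULL, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  written <- character(0)
  if (!is.null(sig)) {
    stopifnot(inherits(sig, "signature_vector"))
    sig_df <- data.frame(line = names(sig$presences),
                         presence_percent = unname(sig$presences))
    sig_df <- rbind(sig_df,
                    data.frame(line = paste0("Phi_", sig$N),
                               presence_percent = sig$phi))
    p <- file.path(out_dir, "signature.csv")
    write_csv_stable(sig_df, p)
    written <- c(written, p)
    p <- file.path(out_dir, "signature.json")
    payload <- list(presences = as.list(signif(sig$presences, 12)),
                    phi = signif(sig$phi, 12), N = sig$N,
                    M_used = sig$M_used, config = sig$config)
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    written <- c(written, p)
    match_rows <- lapply(names(sig$details), function(nm) {
      m <- sig$details[[nm]]$matches
      if (!nrow(m)) return(NULL)
      data.frame(beat_index = m$window, line = nm, cos_theta = m$cos_theta,
                 amplitude = m$amplitude)
    })
    match_df <- do.call(rbind, match_rows)
    if (is.null(match_df))
      match_df <- data.frame(beat_index = integer(0), line = character(0),
                             cos_theta = numeric(0), amplitude = numeric(0))
    match_df <- match_df[order(match_df$beat_index, match_df$line), ,
                         drop = FALSE]
    p <- file.path(out_dir, "matches.csv")
    write_csv_stable(match_df, p)
    written <- c(written, p)
  }
  if (!is.null(scan)) {
    p <- file.path(out_dir, "phi_scan.csv")
    write_csv_stable(as.data.frame(scan), p)
    written <- c(written, p)
  }
  if (!is.null(config)) {
    p <- file.path(out_dir, "run_config.json")
    jsonlite::write_json(config, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    written <- c(written, p)
  }
  invisible(written)
}

#' Write an RR series as plain text
#'
#' One interval (seconds) per line, 12 significant digits; the format read
#' back by [read_rr].
#'
#' @param rr an [rr_series].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rr <- function(rr, path) {
  rr <- as_rr_series(rr)
  writeLines(fmt12(rr$intervals), path)
  invisible(path)
}
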