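#' Transmembrane topology of a protein
#'
#' A \code{tm_topology} is an ordered, non-overlapping set of transmembrane
#' helix ranges over a sequence, in 1-based inclusive coordinates (the UniProt
#' TRANSMEM convention). A GLUT-family transporter is expected to carry 12
#' helices; deviations from an expected count only warn.
#'
#' @param segments data frame with integer columns \code{start}, \code{end}
#'   and optional character \code{label}; may have zero rows.
#' @param source \code{"annotation"} (supplied ranges) or \code{"predicted"}
#'   (hydropathy fallback). Annotation always wins over prediction upstream.
#' @param seq_length optional sequence length to validate ranges against.
#' @return an object of class \code{tm_topology}.
#' @export
tm_topology <- function(segments, source = c("annotation", "predicted"),
                        seq_length = NULL) {
  source <- match.arg(source)
  if (is.null(segments) || nrow(segments) == 0L) {
    segments <- data.frame(start = integer(0), end = integer(0),
                           label = character(0), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("start", "end") %in% names(segments)))
    segments$start <- as.integer(segments$start)
    segments$end <- as.integer(segments$end)
    if (any(segments$start < 1L)) {
      stop("segment start must be >= 1", call. = FALSE)
    }
    if (any(segments$end < segments$start)) {
      i <- which(segments$end < segments$start)[1]
      stop(sprintf("segment %d has end (%d) < start (%d)",
                   i, segments$end[i], segments$start[i]), call. = FALSE)
    }
    segments <- segments[order(segments$start), , drop = FALSE]
    rownames(segments) <- NULL
    if (is.null(segments$label)) {
      segments$label <- paste0("TM", seq_len(nrow(segments)))
    }
    if (nrow(segments) > 1L &&
        any(segments$start[-1] <= segments$end[-nrow(segments)])) {
      stop("overlapping TM segments", call. = FALSE)
    }
    if (!is.null(seq_length) && any(segments$end > seq_length)) {
      stop("TM segment extends beyond sequence length ", seq_length,
           call. = FALSE)
    }
  }
  structure(list(segments = segments, source = source), class = "tm_topology")
}

#' @export
print.tm_topology <- function(x, ...) {
  cat(sprintf("<tm_topology> %d segment(s), source=%s\n",
              nrow(x$segments), x$source))
  if (nrow(x$segments) > 0) print(x$segments)
  invisible(x)
}

#' Number of residues covered by TM segments
#' @param topology a \code{\link{tm_topology}}.
#' @return integer count of TM residues.
#' @export
tm_residue_count <- function(topology) {
  stopifnot(inherits(topology, "tm_topology"))
  s <- topology$segments
  if (nrow(s) == 0L) return(0L)
  sum(s$end - s$start + 1L)
}

# Logical mask of length L: TRUE where inside a TM segment.
tm_mask <- function(topology, seq_length) {
  mask <- rep(FALSE, seq_length)
  s <- topology$segments
  for (i in seq_len(nrow(s))) mask[s$start[i]:s$end[i]] <- TRUE
  mask
}

#' Warn when a topology deviates from the expected helix count
#'
#' GLUT-like major-facilitator transporters span the membrane 12 times; a
#' different count is suspicious but not an error.
#' @param topology a \code{\link{tm_topology}}.
#' @param expected expected segment count (default 12).
#' @return invisibly, TRUE if the count matches.
#' @export
check_helix_count <- function(topology, expected = 12L) {
  n <- nrow(topology$segments)
  if (n != expected) {
    warning(sprintf("topology has %d TM segments; expected %d for a GLUT-like transporter",
                    n, expected), call. = FALSE)
  }
  invisible(n == expected)
}

#' Read TM topologies from a tab-separated table
#'
#' Columns: record id, start, end, optional helix label; 1-based inclusive
#' coordinates, one segment per row. Segments are sorted per id and validated
#' (no overlap, end >= start).
#'
#' @param path TSV path.
#' @return named list of \code{\link{tm_topology}} keyed by record id.
#' @export
parse_tm_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) == 0L) stop("empty TM table: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- vapply(parts, length, 0L)
  if (any(n_col < 3L)) {
    stop("TM table rows need at least 3 tab-separated columns (id, start, end)",
         call. = FALSE)
  }
  df <- data.frame(
    id = vapply(parts, `[[`, "", 1L),
    start = suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L))),
    end = suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L))),
    label = vapply(parts, function(p) if (length(p) >= 4L) p[[4L]] else NA_character_, ""),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$start) || anyNA(df$end)) {
    stop("non-integer coordinates in TM table", call. = FALSE)
  }
  out <- lapply(split(df, df$id), function(d) {
    cols <- if (anyNA(d$label)) c("start", "end") else c("start", "end", "label")
    tm_topology(d[cols], source = "annotation")
  })
  out[unique(df$id)]
}

#' Write TM topologies to a tab-separated table
#'
#' Inverse of \code{\link{parse_tm_table}}.
#' @param topologies named list of \code{\link{tm_topology}}.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
write_tm_table <- function(topologies, path) {
  stopifnot(length(topologies) > 0L, !is.null(names(topologies)))
  rows <- unlist(lapply(names(topologies), function(id) {
    s <- topologies[[id]]$segments
    sprintf("%s\t%d\t%d\t%s", id, s$start, s$end, s$label)
  }))
  writeLines(rows, path)
  invisible(path)
}

#' Read TRANSMEM features from a UniProt text-format entry
#'
#' Minimal reader limited to \code{FT TRANSMEM} feature lines
#' (\code{start..end} ranges); everything else in the entry is ignored.
#' @param path UniProt flat-text file.
#' @return a \code{\link{tm_topology}} with source \code{"annotation"}.
#' @export
read_uniprot_transmem <- function(path) {
  lines <- readLines(path)
  ft <- grep("^FT\\s+TRANSMEM\\s", lines, value = TRUE)
  if (length(ft) == 0L) {
    stop("no FT TRANSMEM lines found in ", path, call. = FALSE)
  }
  m <- regmatches(ft, regexec("TRANSMEM\\s+(\\d+)\\.\\.(\\d+)", ft))
  ok <- vapply(m, length, 0L) == 3L
  if (!any(ok)) stop("could not parse TRANSMEM ranges", call. = FALSE)
  starts <- vapply(m[ok], function(x) as.integer(x[2]), 0L)
  ends <- vapply(m[ok], function(x) as.integer(x[3]), 0L)
  tm_topology(data.frame(start = starts, end = ends,
                         label = paste0("TM", seq_along(starts))),
              source = "annotation")
}

#' Predict transmembrane segments from hydropathy
#'
#' Sliding-window Kyte-Doolittle scan: every position whose centred window
#' mean exceeds \code{threshold} marks its full window as transmembrane;
#' marked runs separated by at most \code{merge_gap} residues are merged and
#' runs shorter than \code{min_len} discarded. This is a fallback for
#' sequences without curated TRANSMEM annotation — supplied annotation always
#' takes precedence.
#'
#' @param seq amino-acid sequence string (canonical alphabet).
#' @param window odd window length (default 19, the classical TM setting).
#' @param threshold window-mean hydropathy cutoff (default 1.6).
#' @param min_len minimum retained segment length (default 15).
#' @param merge_gap merge runs separated by at most this many residues
#'   (default 3).
#' @return a \code{\link{tm_topology}} with source \code{"predicted"}.
#' @export
predict_tm_segments <- function(seq, window = 19, threshold = 1.6,
                                min_len = 15, merge_gap = 3) {
  seq <- check_canonical(seq)
  stopifnot(window %% 2 == 1, window >= 3, min_len >= 1, merge_gap >= 0)
  L <- nchar(seq)
  if (L < window) {
    stop(sprintf("sequence length %d shorter than window %d", L, window),
         call. = FALSE)
  }
  h <- KD_SCALE[strsplit(seq, "")[[1]]]
  half <- (window - 1L) %/% 2L
  # centred window means for valid centres (half+1)..(L-half)
  means <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 2))
  centres <- which(!is.na(means) & means > threshold)
  mask <- rep(FALSE, L)
  for (c0 in centres) {
    mask[max(1L, c0 - half):min(L, c0 + half)] <- TRUE
  }
  runs <- mask_to_runs(mask)
  # merge runs separated by small gaps
  if (nrow(runs) > 1L) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap <= merge_gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  runs <- runs[runs$end - runs$start + 1L >= min_len, , drop = FALSE]
  if (nrow(runs) > 0L) runs$label <- paste0("TM", seq_len(nrow(runs)))
  tm_topology(runs, source = "predicted", seq_length = L)
}

# TRUE-run extraction from a logical mask -> data.frame(start, end)
mask_to_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
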