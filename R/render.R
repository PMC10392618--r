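#' Render an annotated native-vs-variant alignment
#'
#' QTY substitution is positionally 1:1 (no indels are ever introduced), so
#' native and variant are compared column by column rather than via an
#' alignment algorithm. The rendering mirrors the published figure
#' conventions: a helix track marks transmembrane columns, the match line
#' carries \code{"|"} where residues are identical and \code{"*"} where they
#' differ, a marker track flags the substituted columns under the variant
#' line, and a ruler gives 1-based coordinates.
#'
#' @param variant a \code{qty_variant} from \code{\link{apply_qty}}.
#' @param width block width in columns (>= 10; default 60).
#' @param mark_tm draw the helix track (default TRUE).
#' @return object of class \code{alignment_view}: a list of blocks, each a
#'   named character vector of equal-width tracks (\code{helix},
#'   \code{native}, \code{match}, \code{variant}, \code{subs}, \code{ruler}).
#'   The concatenated \code{native} (resp. \code{variant}) track characters
#'   reproduce the sequences byte-for-byte; the total \code{"*"} count equals
#'   the number of substitution events.
#' @export
render_pairwise <- function(variant, width = 60, mark_tm = TRUE) {
  stopifnot(inherits(variant, "qty_variant"))
  if (width < 10) stop("width must be >= 10", call. = FALSE)
  nat <- strsplit(variant$native$sequence, "")[[1]]
  var <- strsplit(variant$variant_sequence, "")[[1]]
  L <- length(nat)
  tm <- tm_mask(variant$topology, L)
  sub <- rep(FALSE, L)
  sub[variant$events$position] <- TRUE

  helix <- ifelse(tm, "H", " ")
  match <- ifelse(nat == var, "|", "*")
  subs <- ifelse(sub, "^", " ")

  starts <- seq(1L, L, by = width)
  blocks <- lapply(starts, function(s) {
    e <- min(s + width - 1L, L)
    idx <- s:e
    pad <- e - s + 1L
    ruler <- formatC(e, width = pad)
    block <- c(
      helix = paste(helix[idx], collapse = ""),
      native = paste(nat[idx], collapse = ""),
      match = paste(match[idx], collapse = ""),
      variant = paste(var[idx], collapse = ""),
      subs = paste(subs[idx], collapse = ""),
      ruler = ruler
    )
    if (!mark_tm) block <- block[setdiff(names(block), "helix")]
    block
  })
  structure(list(blocks = blocks, width = width, id = variant$native$id,
                 n_events = nrow(variant$events)),
            class = "alignment_view")
}

#' @export
format.alignment_view <- function(x, ...) {
  labels <- c(helix = "helix  ", native = "native ", match = "       ",
              variant = "QTY    ", subs = "       ", ruler = "       ")
  out <- character(0)
  for (b in x$blocks) {
    out <- c(out, paste0(labels[names(b)], b), "")
  }
  paste(out, collapse = "\n")
}

#' @export
print.alignment_view <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Write an alignment view to a text file
#'
#' @param view an \code{alignment_view}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_alignment <- function(view, path) {
  stopifnot(inherits(view, "alignment_view"))
  writeLines(format(view), path)
  invisible(path)
}

#' HTML rendering
#'
#' @param x object to render.
#' @param ... passed to methods.
#' @return single character string of HTML.
#' @export
as_html <- function(x, ...) UseMethod("as_html")

#' HTML rendering of an alignment view
#'
#' Optional colour mode copying the figure conventions: helix columns blue,
#' substituted variant residues red, in a \code{<pre>} block.
#'
#' @param x an \code{alignment_view}.
#' @param ... unused.
#' @return single character string of HTML.
#' @export
as_html.alignment_view <- function(x, ...) {
  view <- x
  esc <- function(s) gsub(">", "&gt;", gsub("<", "&lt;", s))
  lines <- character(0)
  for (b in view$blocks) {
    if ("helix" %in% names(b)) {
      lines <- c(lines, paste0("<span style=\"color:blue\">", esc(b[["helix"]]), "</span>"))
    }
    lines <- c(lines, esc(b[["native"]]), esc(b[["match"]]))
    var_chars <- strsplit(b[["variant"]], "")[[1]]
    sub_chars <- strsplit(b[["subs"]], "")[[1]]
    var_html <- paste(ifelse(sub_chars == "^",
                             paste0("<span style=\"color:red\">", var_chars, "</span>"),
                             var_chars), collapse = "")
    lines <- c(lines, var_html, esc(b[["ruler"]]), "")
  }
  paste0("<pre>\n", paste(lines, collapse = "\n"), "\n</pre>\n")
}
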