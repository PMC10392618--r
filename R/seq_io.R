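#' Create a protein record
#'
#' A \code{protein_record} holds one named amino-acid sequence over the 20
#' canonical one-letter codes. Ambiguity codes (B, J, O, U, X, Z) are rejected
#' because downstream substitution statistics depend on exact residue counts.
#'
#' @param id short identifier (first word of a FASTA header).
#' @param sequence amino-acid sequence string; uppercased, whitespace stripped.
#' @param description free-text remainder of the header.
#' @param accession optional database accession (parsed from
#'   \code{db|ACC|NAME}-style ids when present).
#' @return An object of class \code{protein_record} with fields \code{id},
#'   \code{accession}, \code{description} and \code{sequence}.
#' @examples
#' protein_record("glut_like", "MVLLIVFTTGSA")
#' @export
protein_record <- function(id, sequence, description = "", accession = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- check_canonical(sequence, id = id)
  if (is.na(accession) && grepl("^[a-z]+\\|[^|]+\\|", id)) {
    accession <- strsplit(id, "|", fixed = TRUE)[[1]][2]
  }
  structure(
    list(id = id, accession = accession, description = description,
         sequence = sequence),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)%s\n", x$id, nchar(x$sequence),
              if (!is.na(x$accession)) paste0(" [", x$accession, "]") else ""))
  seq <- x$sequence
  shown <- if (nchar(seq) > 60) paste0(substr(seq, 1, 57), "...") else seq
  cat(" ", shown, "\n")
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Parses a standard FASTA file into a list of \code{\link{protein_record}}s,
#' preserving entry order. Sequences are uppercased and whitespace-stripped;
#' any residue outside the 20-letter canonical alphabet is an error naming the
#' offending position.
#'
#' @param path path to a FASTA file.
#' @return list of \code{protein_record}, one per entry.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  lapply(seq_along(set), function(i) {
    header <- headers[i]
    id <- sub("\\s.*$", "", header)
    desc <- sub("^\\S+\\s*", "", header)
    protein_record(id = id, sequence = as.character(set[[i]]),
                   description = desc)
  })
}

#' Write protein records to a FASTA file
#'
#' @param records non-empty list of \code{\link{protein_record}}.
#' @param path output path.
#' @param width line-wrap width for sequence lines (default 60).
#' @return invisibly, \code{path}.
#' @export
write_fasta <- function(records, path, width = 60) {
  if (inherits(records, "protein_record")) records <- list(records)
  if (length(records) == 0L) stop("no records to write", call. = FALSE)
  stopifnot(width >= 1)
  set <- Biostrings::AAStringSet(vapply(records, `[[`, "", "sequence"))
  names(set) <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, "")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
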