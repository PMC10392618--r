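#' Structure model container
#'
#' Holds one chain of residues with atom coordinates. \code{residues} is a
#' data frame (resno, aa, x, y, z) where x/y/z are the alpha-carbon
#' coordinates in angstroms and resno is strictly increasing; \code{atoms} is
#' a data frame (resno, atom, element, x, y, z) with the full atom records
#' (possibly CA-only for predicted-model traces).
#'
#' @param id model identifier.
#' @param chain chain identifier.
#' @param residues residue data frame as above.
#' @param atoms atom data frame as above (may be CA-only).
#' @return object of class \code{structure_model}.
#' @export
structure_model <- function(id, chain, residues, atoms) {
  stopifnot(is.data.frame(residues),
            all(c("resno", "aa", "x", "y", "z") %in% names(residues)))
  if (nrow(residues) == 0L) stop("structure has no residues", call. = FALSE)
  if (is.unsorted(residues$resno, strictly = TRUE)) {
    stop("residue numbers must be strictly increasing within the chain",
         call. = FALSE)
  }
  rownames(residues) <- NULL
  structure(list(id = id, chain = chain, residues = residues, atoms = atoms),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s chain %s: %d residues, %d atoms%s\n",
              x$id, x$chain, nrow(x$residues),
              if (is.null(x$atoms)) 0L else nrow(x$atoms),
              if (is_ca_only(x)) " (CA-only)" else ""))
  invisible(x)
}

#' Sequence of a structure model
#' @param model a \code{structure_model}.
#' @return one-letter sequence string.
#' @export
model_sequence <- function(model) {
  paste(model$residues$aa, collapse = "")
}

# TRUE when the atom table holds nothing beyond alpha-carbons.
is_ca_only <- function(model) {
  is.null(model$atoms) || all(model$atoms$atom == "CA")
}

#' Read a protein structure from a PDB file
#'
#' Fixed-column parser for standard ATOM records. Only the first MODEL is
#' read; HETATM (hetero) records are skipped; where alternate locations
#' exist, blank or "A" altloc is kept. Residue identity is mapped through
#' the standard three-to-one table (unknown residue names become "X" and are
#' dropped with a warning). Residues lacking an alpha-carbon are dropped with
#' a warning.
#'
#' @param path PDB file path.
#' @param chain optional chain id; default: the first chain encountered.
#' @return a \code{\link{structure_model}}.
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl) > 0L) lines <- lines[seq_len(endmdl[1] - 1L)]
  atom_lines <- lines[startsWith(lines, "ATOM  ")]
  if (length(atom_lines) == 0L) {
    stop("no ATOM records found in ", path, call. = FALSE)
  }
  fx <- function(a, b) trimws(substr(atom_lines, a, b))
  atoms <- data.frame(
    atom = fx(13, 16),
    altloc = fx(17, 17),
    resname = fx(18, 20),
    chain = fx(22, 22),
    resno = as.integer(fx(23, 26)),
    x = as.numeric(fx(31, 38)),
    y = as.numeric(fx(39, 46)),
    z = as.numeric(fx(47, 54)),
    element = fx(77, 78),
    stringsAsFactors = FALSE
  )
  atoms <- atoms[atoms$altloc %in% c("", "A"), , drop = FALSE]
  if (is.null(chain)) chain <- atoms$chain[1]
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  if (nrow(atoms) == 0L) {
    stop("no atoms for chain '", chain, "' in ", path, call. = FALSE)
  }
  # element fallback: first letter of the atom name
  miss <- !nzchar(atoms$element)
  atoms$element[miss] <- substr(gsub("[0-9]", "", atoms$atom[miss]), 1, 1)

  aa <- AA_THREE_TO_ONE[atoms$resname]
  unknown <- is.na(aa)
  if (any(unknown)) {
    warning("dropping ", length(unique(atoms$resno[unknown])),
            " residue(s) with non-standard names", call. = FALSE)
    atoms <- atoms[!unknown, , drop = FALSE]
    aa <- aa[!unknown]
  }
  atoms$aa <- unname(aa)

  ca <- atoms[atoms$atom == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  no_ca <- setdiff(unique(atoms$resno), ca$resno)
  if (length(no_ca) > 0L) {
    warning("dropping ", length(no_ca), " residue(s) without an alpha-carbon",
            call. = FALSE)
    atoms <- atoms[!atoms$resno %in% no_ca, , drop = FALSE]
  }
  if (nrow(ca) == 0L) stop("no parsable residues in ", path, call. = FALSE)
  residues <- data.frame(resno = ca$resno, aa = ca$aa,
                         x = ca$x, y = ca$y, z = ca$z,
                         stringsAsFactors = FALSE)
  structure_model(
    id = sub("\\.[^.]*$", "", basename(path)),
    chain = chain,
    residues = residues,
    atoms = atoms[c("resno", "atom", "element", "x", "y", "z")]
  )
}

#' Write a structure model as a PDB file
#'
#' Emits standard ATOM records (first model, single chain). Coordinates are
#' written with 3 decimals, the PDB precision.
#'
#' @param model a \code{structure_model}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  if (is.null(at)) {
    at <- data.frame(resno = model$residues$resno, atom = "CA", element = "C",
                     x = model$residues$x, y = model$residues$y,
                     z = model$residues$z, stringsAsFactors = FALSE)
  }
  aa_by_resno <- stats::setNames(model$residues$aa, model$residues$resno)
  res3 <- AA_ONE_TO_THREE[aa_by_resno[as.character(at$resno)]]
  rec <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(at)),
    ifelse(nchar(at$atom) < 4, paste0(" ", at$atom), at$atom),
    res3, model$chain, at$resno, at$x, at$y, at$z, at$element)
  writeLines(c(rec, "END"), path)
  invisible(path)
}

#' Pair residues between two structure models
#'
#' Establishes the residue correspondence used for superposition. Pairing
#' ignores residue identity, so QTY substitutions never break it.
#' \code{by_resnum} pairs residues sharing a residue number (tolerant of
#' gaps); \code{by_sequence} pairs equal-length chains position by position —
#' the default for native-vs-QTY models, whose numbering and length are
#' identical while identities differ.
#'
#' @param a,b \code{structure_model} objects.
#' @param mode \code{"by_sequence"} or \code{"by_resnum"}.
#' @return two-column integer matrix of paired row indices into
#'   \code{a$residues} and \code{b$residues}.
#' @export
pair_residues <- function(a, b, mode = c("by_sequence", "by_resnum")) {
  stopifnot(inherits(a, "structure_model"), inherits(b, "structure_model"))
  mode <- match.arg(mode)
  na <- nrow(a$residues); nb <- nrow(b$residues)
  if (na == 0L || nb == 0L) stop("empty structure model", call. = FALSE)
  if (mode == "by_sequence") {
    if (na != nb) {
      stop(sprintf("by_sequence pairing requires equal lengths (%d vs %d)",
                   na, nb), call. = FALSE)
    }
    cbind(a = seq_len(na), b = seq_len(nb))
  } else {
    common <- intersect(a$residues$resno, b$residues$resno)
    cbind(a = match(common, a$residues$resno),
          b = match(common, b$residues$resno))
  }
}

# n x 3 coordinate matrix of the alpha-carbons.
ca_coords <- function(model) {
  as.matrix(model$residues[, c("x", "y", "z")])
}
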