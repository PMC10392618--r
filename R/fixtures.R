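# Synthetic sequence/topology/structure generators. Everything is
# deterministic given a seed; seeds are applied locally so the caller's
# global random state is never consumed or disturbed.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Default TM composition: ~48% mass on L/I/V/F so synthetic TM variation
# rates land in the 44-50% band typical of GLUT transmembrane domains; the
# rest follows a helix-like background.
default_tm_composition <- function() {
  c(L = 0.12, I = 0.12, V = 0.12, F = 0.12,
    A = 0.09, G = 0.07, M = 0.04, W = 0.03, T = 0.06, S = 0.06,
    C = 0.02, Y = 0.04, P = 0.02, N = 0.02, Q = 0.02,
    E = 0.01, K = 0.01, R = 0.01, D = 0.01, H = 0.01)
}

# Polar-biased loop background.
default_loop_composition <- function() {
  c(S = 0.11, T = 0.08, N = 0.08, Q = 0.08, D = 0.09, E = 0.10,
    K = 0.10, R = 0.08, G = 0.10, P = 0.07, H = 0.04, A = 0.05, Y = 0.02)
}

#' Specification for a synthetic transporter fixture
#'
#' States the shape of an idealized multi-pass transporter: alternating
#' transmembrane blocks and loops with stated residue compositions. Defaults
#' emulate a 12-helix GLUT-like protein with 21-residue helices, 10-residue
#' loops and ~48% of transmembrane mass on the QTY-targeted residues.
#'
#' @param n_helices number of TM helices (default 12).
#' @param helix_len TM helix length in residues (default 21).
#' @param loop_len loop length in residues (default 10).
#' @param tm_composition named residue frequency vector for TM blocks
#'   (must sum to 1).
#' @param loop_composition named residue frequency vector for loops.
#' @param seed integer seed.
#' @return object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(n_helices = 12, helix_len = 21, loop_len = 10,
                         tm_composition = default_tm_composition(),
                         loop_composition = default_loop_composition(),
                         seed = 1L) {
  stopifnot(n_helices >= 1, helix_len >= 1, loop_len >= 1)
  for (comp in list(tm_composition, loop_composition)) {
    stopifnot(!is.null(names(comp)), all(names(comp) %in% AA_ALPHABET),
              abs(sum(comp) - 1) < 1e-6, all(comp >= 0))
  }
  structure(list(n_helices = as.integer(n_helices),
                 helix_len = as.integer(helix_len),
                 loop_len = as.integer(loop_len),
                 tm_composition = tm_composition,
                 loop_composition = loop_composition,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic transporter sequence and topology
#'
#' Builds loop + (helix + loop) x n_helices, drawing residues from the
#' stated compositions, and returns the sequence together with the exact TM
#' topology of the helix blocks. Deterministic given the spec's seed.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param id record id (default "synthetic_transporter").
#' @return list with elements \code{record} (\code{protein_record}) and
#'   \code{topology} (\code{tm_topology}, source annotation).
#' @export
synthetic_transporter <- function(spec = fixture_spec(),
                                  id = "synthetic_transporter") {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    draw <- function(n, comp) {
      paste(sample(names(comp), n, replace = TRUE, prob = comp), collapse = "")
    }
    parts <- character(0)
    starts <- integer(0)
    pos <- 0L
    for (h in seq_len(spec$n_helices)) {
      loop <- draw(spec$loop_len, spec$loop_composition)
      helix <- draw(spec$helix_len, spec$tm_composition)
      parts <- c(parts, loop, helix)
      pos <- pos + spec$loop_len
      starts <- c(starts, pos + 1L)
      pos <- pos + spec$helix_len
    }
    parts <- c(parts, draw(spec$loop_len, spec$loop_composition))
    seq <- paste(parts, collapse = "")
    topo <- tm_topology(
      data.frame(start = starts, end = starts + spec$helix_len - 1L,
                 label = paste0("TM", seq_len(spec$n_helices))),
      source = "annotation", seq_length = nchar(seq))
    list(record = protein_record(id, seq), topology = topo)
  })
}

#' Alpha-carbon trace of a canonical alpha helix
#'
#' Places one alpha-carbon per residue on an ideal alpha helix: 1.5 A rise
#' and 100 degrees rotation per residue on a 2.3 A radius, giving the
#' canonical ~3.8 A consecutive CA distance. Coordinates depend only on the
#' sequence length, never on residue identity — relabelling (e.g. QTY
#' substitution) leaves the geometry untouched, mirroring the premise that
#' hydrophobic and hydrophilic helices share the same backbone.
#'
#' @param sequence amino-acid sequence (canonical alphabet).
#' @param id model id (default "ideal_helix").
#' @param chain chain id (default "A").
#' @return CA-only \code{\link{structure_model}}. Coordinates are rounded to
#'   3 decimals (PDB precision) so file round trips are exact.
#' @export
ideal_helix_coords <- function(sequence, id = "ideal_helix", chain = "A") {
  sequence <- check_canonical(sequence)
  n <- nchar(sequence)
  i <- seq_len(n) - 1L
  ang <- i * 100 * pi / 180
  x <- round(2.3 * cos(ang), 3)
  y <- round(2.3 * sin(ang), 3)
  z <- round(1.5 * i, 3)
  residues <- data.frame(resno = seq_len(n),
                         aa = strsplit(sequence, "")[[1]],
                         x = x, y = y, z = z, stringsAsFactors = FALSE)
  atoms <- data.frame(resno = residues$resno, atom = "CA", element = "C",
                      x = x, y = y, z = z, stringsAsFactors = FALSE)
  structure_model(id, chain, residues, atoms)
}

#' Add Gaussian coordinate noise to a structure
#'
#' Independent normal displacement (sd \code{noise_sd} per axis) on every
#' alpha-carbon; atoms other than CA receive the same displacement as their
#' residue's CA so the residue moves rigidly. After optimal superposition
#' against the original, the expected RMSD approaches \code{noise_sd * sqrt(3)}
#' for large n.
#'
#' @param model a \code{structure_model}.
#' @param noise_sd displacement standard deviation per axis, in angstroms
#'   (>= 0).
#' @param seed integer seed (deterministic output).
#' @return perturbed \code{structure_model}. Coordinates rounded to 3
#'   decimals (PDB precision).
#' @export
perturb_structure <- function(model, noise_sd, seed = 1L) {
  stopifnot(inherits(model, "structure_model"), noise_sd >= 0)
  n <- nrow(model$residues)
  with_seed(seed, {
    shift <- matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
  })
  res <- model$residues
  res$x <- round(res$x + shift[, 1], 3)
  res$y <- round(res$y + shift[, 2], 3)
  res$z <- round(res$z + shift[, 3], 3)
  model$residues <- res
  if (!is.null(model$atoms)) {
    idx <- match(model$atoms$resno, res$resno)
    model$atoms$x <- round(model$atoms$x + shift[idx, 1], 3)
    model$atoms$y <- round(model$atoms$y + shift[idx, 2], 3)
    model$atoms$z <- round(model$atoms$z + shift[idx, 3], 3)
  }
  model
}

#' Write a complete fixture set to a directory
#'
#' Emits, for one synthetic transporter: the native FASTA, the TM table TSV,
#' an idealized CA-only native PDB (consecutive ideal helices laid end to
#' end) and a noise-perturbed "variant model" PDB — enough input to exercise
#' the whole pipeline offline.
#'
#' @param dir output directory (created if needed).
#' @param spec a \code{\link{fixture_spec}}.
#' @param noise_sd perturbation for the variant model (default 0.5 A).
#' @return invisibly, named character vector of the written paths.
#' @export
write_fixture_set <- function(dir, spec = fixture_spec(), noise_sd = 0.5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- synthetic_transporter(spec)
  paths <- c(
    fasta = file.path(dir, "native.fasta"),
    tm = file.path(dir, "native_tm.tsv"),
    pdb_native = file.path(dir, "native.pdb"),
    pdb_variant = file.path(dir, "variant_model.pdb")
  )
  write_fasta(list(st$record), paths[["fasta"]])
  topo <- list(st$topology); names(topo) <- st$record$id
  write_tm_table(topo, paths[["tm"]])
  native_model <- ideal_helix_coords(st$record$sequence, id = st$record$id)
  write_pdb(native_model, paths[["pdb_native"]])
  variant_seq <- apply_qty(st$record, st$topology)$variant_sequence
  variant_model <- ideal_helix_coords(variant_seq, id = paste0(st$record$id, "_QTY"))
  variant_model <- perturb_structure(variant_model, noise_sd, seed = spec$seed + 1L)
  write_pdb(variant_model, paths[["pdb_variant"]])
  invisible(paths)
}
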