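# Solvent-accessible surface area by Shrake-Rupley quadrature.
#
# Each atom is expanded by the probe radius; a deterministic golden-section
# spiral point set is placed on the expanded sphere and points falling inside
# any neighbouring expanded sphere are removed. No randomness: results are
# bit-stable across runs.

#' Deterministic points on the unit sphere (golden-section spiral)
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
golden_spiral_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# atom radii for SASA: element lookup with carbon fallback
atom_radii <- function(elements) {
  r <- VDW_RADII[elements]
  miss <- is.na(r)
  if (any(miss)) {
    warning("unknown element(s) ", paste(unique(elements[miss]), collapse = ","),
            "; using default radius ", VDW_DEFAULT, " A", call. = FALSE)
    r[miss] <- VDW_DEFAULT
  }
  unname(r)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere (default water, 1.4 A) over the structure and
#' integrates the accessible area of each atom's solvent-expanded sphere over
#' a deterministic spherical quadrature. Neighbour candidates come from
#' spatial binning at the maximum interaction distance. When the structure
#' carries only alpha-carbons (predicted-model traces), each residue is
#' approximated by a single sphere of radius 3.0 A and the result is flagged
#' \code{coarse}.
#'
#' @param structure a \code{\link{structure_model}}.
#' @param probe_radius probe radius in angstroms (default 1.4).
#' @param n_points quadrature points per atom (default 960).
#' @return object of class \code{sasa_result}: \code{per_atom_sasa},
#'   \code{per_residue_sasa} (named by residue number), \code{total_sasa}
#'   (all in square angstroms), the atom table used, and \code{coarse}.
#' @export
shrake_rupley <- function(structure, probe_radius = 1.4, n_points = 960) {
  stopifnot(inherits(structure, "structure_model"),
            probe_radius >= 0, n_points >= 12)
  coarse <- is_ca_only(structure)
  if (coarse) {
    at <- data.frame(resno = structure$residues$resno,
                     x = structure$residues$x,
                     y = structure$residues$y,
                     z = structure$residues$z)
    radii <- rep(CA_COARSE_RADIUS, nrow(at))
  } else {
    at <- structure$atoms
    radii <- atom_radii(at$element)
  }
  n_atoms <- nrow(at)
  if (n_atoms == 0L) stop("empty structure", call. = FALSE)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  exp_r <- radii + probe_radius
  sphere <- golden_spiral_points(n_points)

  # spatial binning: cells of the maximum possible interaction distance
  cell <- 2 * max(exp_r)
  key <- function(m) paste(floor(m[, 1] / cell), floor(m[, 2] / cell),
                           floor(m[, 3] / cell))
  bins <- split(seq_len(n_atoms), key(xyz))
  cell_of <- floor(xyz / cell)

  neighbours <- function(i) {
    ci <- cell_of[i, ]
    cand <- unlist(lapply(-1:1, function(dx) lapply(-1:1, function(dy) {
      lapply(-1:1, function(dz) {
        bins[[paste(ci[1] + dx, ci[2] + dy, ci[3] + dz)]]
      })
    })), use.names = FALSE)
    cand <- setdiff(cand, i)
    if (length(cand) == 0L) return(integer(0))
    d2 <- rowSums(sweep(xyz[cand, , drop = FALSE], 2, xyz[i, ])^2)
    cand[d2 < (exp_r[i] + exp_r[cand])^2]
  }

  per_atom <- numeric(n_atoms)
  for (i in seq_len(n_atoms)) {
    pts <- sphere * exp_r[i]
    pts <- sweep(pts, 2, xyz[i, ], `+`)
    nb <- neighbours(i)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
      acc <- acc & d2 >= exp_r[j]^2
    }
    per_atom[i] <- 4 * pi * exp_r[i]^2 * sum(acc) / n_points
  }

  per_res <- vapply(split(per_atom, at$resno), sum, 0)
  # restore residue order (split sorts by character key)
  ord <- as.character(structure$residues$resno)
  per_res <- per_res[ord]
  structure(
    list(per_atom_sasa = per_atom,
         per_residue_sasa = per_res,
         total_sasa = sum(per_atom),
         probe_radius = probe_radius,
         n_points = n_points,
         coarse = coarse),
    class = "sasa_result"
  )
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> total %.1f A^2 over %d atoms (%d points%s)\n",
              x$total_sasa, length(x$per_atom_sasa), x$n_points,
              if (x$coarse) ", coarse CA spheres" else ""))
  invisible(x)
}

#' Hydrophobic surface fraction
#'
#' Share of the total solvent-accessible surface contributed by residues in
#' the hydrophobic set. The default set is exactly L, I, V, F — the residues
#' the QTY code replaces — so the fraction measures the surface patch that
#' QTY substitution is designed to remove; the broader class (adding A, M, W,
#' C) is available for sensitivity checks.
#'
#' @param structure the \code{structure_model} the SASA was computed for.
#' @param sasa matching \code{sasa_result}.
#' @param hydrophobic_set residue one-letter codes counted as hydrophobic.
#' @return fraction in [0, 1].
#' @export
hydrophobic_surface_fraction <- function(structure, sasa,
                                         hydrophobic_set = QTY_TARGET_SET) {
  stopifnot(inherits(structure, "structure_model"), inherits(sasa, "sasa_result"))
  if (length(sasa$per_residue_sasa) != nrow(structure$residues)) {
    stop("sasa does not match structure residue count", call. = FALSE)
  }
  if (sasa$total_sasa <= 0) stop("zero total SASA", call. = FALSE)
  hyd <- sum(sasa$per_residue_sasa[structure$residues$aa %in% hydrophobic_set])
  hyd / sasa$total_sasa
}

#' Per-residue SASA report
#'
#' @param structure a \code{structure_model}.
#' @param sasa matching \code{sasa_result}.
#' @return data frame: resno, aa, sasa.
#' @export
sasa_report <- function(structure, sasa) {
  data.frame(resno = structure$residues$resno,
             aa = structure$residues$aa,
             sasa = unname(sasa$per_residue_sasa))
}
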