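#' Optimal rigid superposition of paired coordinates (Kabsch)
#'
#' Closed-form least-squares solution for the proper rotation and translation
#' minimizing the RMSD between paired point sets: the transform maps
#' \code{coords_b} onto \code{coords_a}. Reflections are excluded by the
#' determinant sign correction, as physical superposition requires a proper
#' rotation. Collinear (rank-deficient) inputs are flagged via the
#' \code{degenerate} field but a solution is still returned.
#'
#' @param coords_a,coords_b n x 3 matrices of paired coordinates (angstroms),
#'   n >= 3.
#' @return object of class \code{superposition_result} with fields
#'   \code{rotation} (3 x 3, det +1), \code{translation} (length-3 vector;
#'   rotating b and adding the translation superposes it onto a),
#'   \code{rmsd_all}, \code{rmsd_refined} (equal to \code{rmsd_all} here),
#'   \code{n_paired}, \code{n_kept}, \code{per_residue_deviation} and
#'   \code{degenerate}.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!identical(dim(coords_a), dim(coords_b)) || ncol(coords_a) != 3L) {
    stop("coordinate sets must be equal-size n x 3 matrices", call. = FALSE)
  }
  n <- nrow(coords_a)
  if (n < 3L) stop("need at least 3 paired points", call. = FALSE)
  cen_a <- colMeans(coords_a)
  cen_b <- colMeans(coords_b)
  A <- sweep(coords_a, 2, cen_a)
  B <- sweep(coords_b, 2, cen_b)
  C <- crossprod(B, A)                    # 3x3 covariance
  sv <- svd(C)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-300)
  translation <- as.numeric(cen_a - R %*% cen_b)
  fitted <- coords_b %*% t(R) + matrix(translation, n, 3, byrow = TRUE)
  dev <- sqrt(rowSums((coords_a - fitted)^2))
  rmsd <- sqrt(mean(dev^2))
  structure(
    list(rotation = R, translation = translation,
         rmsd_all = rmsd, rmsd_refined = rmsd,
         n_paired = n, n_kept = n,
         per_residue_deviation = dev,
         kept = seq_len(n),
         degenerate = degenerate),
    class = "superposition_result"
  )
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf(
    "<superposition_result> RMSD %.3f A over %d pairs (refined %.3f A over %d kept)%s\n",
    x$rmsd_all, x$n_paired, x$rmsd_refined, x$n_kept,
    if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Apply a superposition transform to a structure model
#'
#' @param model a \code{structure_model}.
#' @param sp a \code{superposition_result} (maps this model onto the
#'   reference it was superposed against).
#' @return transformed \code{structure_model}.
#' @export
transform_structure <- function(model, sp) {
  stopifnot(inherits(model, "structure_model"),
            inherits(sp, "superposition_result"))
  tf <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(sp$rotation)
    xyz <- sweep(xyz, 2, sp$translation, `+`)
    df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
    df
  }
  model$residues <- tf(model$residues)
  if (!is.null(model$atoms)) model$atoms <- tf(model$atoms)
  model
}

#' Superpose two structures with iterative outlier rejection
#'
#' Emulates the refinement behaviour of interactive viewers' \code{align}:
#' superpose the paired alpha-carbons, discard pairs whose deviation lies
#' more than \code{sigma_cutoff} standard deviations above the mean deviation
#' of the current kept set, and repeat until no pair is dropped or
#' \code{cycles} is exhausted. Both the
#' all-pair RMSD (first superposition) and the refined RMSD (final kept set)
#' are reported so either convention can be compared against published
#' values.
#'
#' @param a,b \code{structure_model} objects (reference and mobile).
#' @param cycles maximum rejection cycles (default 5).
#' @param sigma_cutoff rejection threshold in standard deviations (default 2).
#' @param mode residue pairing mode, see \code{\link{pair_residues}}.
#' @return a \code{superposition_result}; \code{per_residue_deviation} covers
#'   all initially paired residues under the final transform, \code{kept}
#'   indexes the retained pairs.
#' @export
refine_superpose <- function(a, b, cycles = 5, sigma_cutoff = 2.0,
                             mode = c("by_sequence", "by_resnum")) {
  pairs <- pair_residues(a, b, match.arg(mode))
  if (nrow(pairs) < 10L) {
    stop("need at least 10 paired residues for refinement", call. = FALSE)
  }
  xa <- ca_coords(a)[pairs[, 1], , drop = FALSE]
  xb <- ca_coords(b)[pairs[, 2], , drop = FALSE]

  sp <- kabsch_superpose(xa, xb)
  rmsd_all <- sp$rmsd_all
  kept <- seq_len(nrow(pairs))
  dev_kept <- sp$per_residue_deviation

  for (cycle in seq_len(cycles)) {
    # floor guards against rejecting on numerical noise for identical inputs
    cut <- max(mean(dev_kept) + sigma_cutoff * stats::sd(dev_kept), 1e-8)
    if (is.na(cut)) break
    drop <- dev_kept > cut
    if (!any(drop)) break
    if (sum(!drop) < 3L) {
      stop("all residue pairs rejected; sigma_cutoff too aggressive",
           call. = FALSE)
    }
    kept <- kept[!drop]
    sp <- kabsch_superpose(xa[kept, , drop = FALSE], xb[kept, , drop = FALSE])
    dev_kept <- sp$per_residue_deviation
  }

  # deviations of every initial pair under the final transform
  fitted_all <- xb %*% t(sp$rotation) +
    matrix(sp$translation, nrow(xb), 3, byrow = TRUE)
  dev_all <- sqrt(rowSums((xa - fitted_all)^2))

  structure(
    list(rotation = sp$rotation, translation = sp$translation,
         rmsd_all = rmsd_all, rmsd_refined = sp$rmsd_all,
         n_paired = nrow(pairs), n_kept = length(kept),
         per_residue_deviation = dev_all,
         kept = kept,
         degenerate = sp$degenerate),
    class = "superposition_result"
  )
}

#' Superposition report as a one-row data frame
#'
#' @param sp a \code{superposition_result}.
#' @return data frame with rmsd_all, rmsd_refined, n_paired, n_kept.
#' @export
superposition_report <- function(sp) {
  stopifnot(inherits(sp, "superposition_result"))
  data.frame(rmsd_all = sp$rmsd_all, rmsd_refined = sp$rmsd_refined,
             n_paired = sp$n_paired, n_kept = sp$n_kept)
}
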