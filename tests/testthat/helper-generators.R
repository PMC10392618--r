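# Test-data generators shared across test files.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
POLAR_AA <- c("S", "T", "N", "Q", "D", "E", "K", "R", "G", "H")

random_sequence <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# random protein + random non-overlapping topology over it
random_protein_with_topology <- function(min_len = 60, max_len = 200) {
  L <- sample(min_len:max_len, 1)
  seq <- random_sequence(L)
  n_seg <- sample(1:4, 1)
  bounds <- sort(sample(seq_len(L), 2 * n_seg))
  segs <- data.frame(start = bounds[seq(1, by = 2, length.out = n_seg)],
                     end = bounds[seq(2, by = 2, length.out = n_seg)])
  # enforce strict separation (no touching segments)
  keep <- c(TRUE, diff(segs$start) > 1 & segs$start[-1] > segs$end[-n_seg] + 1)
  segs <- segs[keep, , drop = FALSE]
  list(record = protein_record("rand", seq),
       topology = tm_topology(segs, source = "annotation", seq_length = L))
}

# random rigid motion: proper rotation from QR + random translation
random_rigid_transform <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = rnorm(3, sd = 10))
}

apply_rigid <- function(coords, tf) {
  sweep(coords %*% t(tf$R), 2, tf$t, `+`)
}

# CA-only structure model from a bare coordinate matrix
model_from_coords <- function(coords, aa = NULL, id = "m") {
  n <- nrow(coords)
  if (is.null(aa)) aa <- rep("A", n)
  structure_model(id, "A",
                  data.frame(resno = seq_len(n), aa = aa,
                             x = coords[, 1], y = coords[, 2], z = coords[, 3],
                             stringsAsFactors = FALSE),
                  atoms = NULL)
}
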