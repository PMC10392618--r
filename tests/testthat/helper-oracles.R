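# Independent oracles. Each reimplements the checked quantity from first
# principles (or from independently transcribed reference constants) without
# touching the code path under test.

# --- residue-mass summation oracle (ExPASy average masses, transcribed
#     independently of the package's table) -------------------------------
oracle_mw <- function(seq) {
  masses <- c(
    G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
    T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
    D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
    H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
  sum(masses[strsplit(seq, "")[[1]]]) + 18.01524
}

# --- dense grid-scan pI oracle ------------------------------------------
# The Henderson-Hasselbalch net charge is strictly monotone decreasing in
# pH, so a coarse 1e-3 scan followed by a 1e-5 rescan of the bracketing
# window returns the same argmin as a full 1e-5 scan over 0..14.
oracle_pi_gridscan <- function(seq, pka_set = "Bjellqvist") {
  coarse <- seq(0, 14, by = 1e-3)
  q <- abs(net_charge(seq, coarse, pka_set))
  centre <- coarse[which.min(q)]
  fine <- seq(max(0, centre - 0.01), min(14, centre + 0.01), by = 1e-5)
  fine[which.min(abs(net_charge(seq, fine, pka_set)))]
}

# --- brute-force rotation-grid Kabsch oracle ----------------------------
# Hierarchical Euler-angle grid search, independent of the SVD solution:
# global 10-degree scan, then repeated local refinement of the best basins
# down to < 0.01 degree. Returns the minimal RMSD after centring.
oracle_grid_rmsd <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  rot <- function(al, be, ga) {
    ca <- cos(al); sa <- sin(al); cb <- cos(be); sb <- sin(be)
    cg <- cos(ga); sg <- sin(ga)
    Rz1 <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
    Rz2 <- matrix(c(cg, sg, 0, -sg, cg, 0, 0, 0, 1), 3, 3)
    Rz1 %*% Ry %*% Rz2
  }
  rmsd_at <- function(ang) {
    R <- rot(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((ac - bc %*% t(R))^2)))
  }
  step <- 10 * pi / 180
  grid <- expand.grid(al = seq(0, 2 * pi - step, by = step),
                      be = seq(0, pi, by = step),
                      ga = seq(0, 2 * pi - step, by = step))
  vals <- apply(grid, 1, rmsd_at)
  # refine the few best coarse basins independently
  best <- Inf
  for (k in order(vals)[1:5]) {
    ang <- as.numeric(grid[k, ])
    s <- step
    v <- vals[k]
    while (s > 0.01 * pi / 180) {
      offsets <- expand.grid(d1 = c(-s, 0, s) / 2, d2 = c(-s, 0, s) / 2,
                             d3 = c(-s, 0, s) / 2)
      cand_vals <- apply(offsets, 1, function(d) rmsd_at(ang + as.numeric(d)))
      j <- which.min(cand_vals)
      if (cand_vals[j] < v) {
        v <- cand_vals[j]
        ang <- ang + as.numeric(offsets[j, ])
      } else {
        s <- s / 2
      }
    }
    best <- min(best, v)
  }
  best
}

# --- brute-force hydropathy window scan ---------------------------------
oracle_window_means <- function(seq, window) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  h <- kd[strsplit(seq, "")[[1]]]
  n <- length(h) - window + 1L
  vapply(seq_len(n), function(i) mean(h[i:(i + window - 1L)]), 0)
}
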