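# Independent oracles used by the tests. These deliberately re-derive the
# physics by different numerical routes than the package implementation.

.R_GAS <- 8.31446

# --- ITC: numerical equilibrium solver ------------------------------------
# Per-injection heats from bisection on the 1:1 binding mass balance,
# with the same multiplicative displacement-dilution bookkeeping. The
# bound concentration is found numerically instead of via the closed-form
# quadratic, so agreement is a genuine cross-check of the isotherm.
oracle_itc_heats <- function(protocol, Ka, dHb, n_sites = 1) {
  dV <- protocol$injections_ul * 1e-6 / (protocol$V0_ml * 1e-3)
  M <- protocol$M0_mM * 1e-3
  X <- 0
  V0 <- protocol$V0_ml * 1e-3
  Qprev <- 0
  q <- numeric(length(dV))
  for (i in seq_along(dV)) {
    M <- M * (1 - dV[i])
    X <- X * (1 - dV[i]) + protocol$X0_mM * 1e-3 * dV[i]
    # solve free ligand: xf + n*M*Ka*xf/(1+Ka*xf) = X
    f <- function(xf) xf + n_sites * M * Ka * xf / (1 + Ka * xf) - X
    lo <- 0; hi <- X
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    bound <- n_sites * M * Ka * hi / (1 + Ka * hi)
    Q <- bound * dHb * 1000 * V0 * 1e6            # uJ
    q[i] <- Q - Qprev + dV[i] * (Q + Qprev) / 2
    Qprev <- Q
  }
  q
}

# --- Kabsch: brute-force rotation-grid search ------------------------------
# Minimal RMSD over proper rotations by hierarchical grid search on z-y-z
# Euler angles, using |A R - B|^2 = |A|^2 + |B|^2 - 2 tr(R'H), H = A'B.
oracle_grid_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  H <- crossprod(A, B)
  ss <- sum(A^2) + sum(B^2)
  n <- nrow(A)

  trace_for <- function(a, b, g) {
    ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
    cg <- cos(g); sg <- sin(g)
    # R = Rz(a) %*% Ry(b) %*% Rz(g), entries vectorised over the grid
    (ca * cb * cg - sa * sg) * H[1, 1] +
      (-ca * cb * sg - sa * cg) * H[1, 2] + (ca * sb) * H[1, 3] +
      (sa * cb * cg + ca * sg) * H[2, 1] +
      (-sa * cb * sg + ca * cg) * H[2, 2] + (sa * sb) * H[2, 3] +
      (-sb * cg) * H[3, 1] + (sb * sg) * H[3, 2] + cb * H[3, 3]
  }

  # level 1: full Euler ranges; then shrink around the incumbent
  step <- 6 * pi / 180
  gr <- expand.grid(a = seq(-pi, pi, by = step),
                    b = seq(0, pi, by = step),
                    g = seq(-pi, pi, by = step))
  tr <- trace_for(gr$a, gr$b, gr$g)
  best <- unlist(gr[which.max(tr), ], use.names = FALSE)
  for (level in 2:4) {
    span <- 2 * step
    step <- step / 8
    gr <- expand.grid(a = seq(best[1] - span, best[1] + span, by = step),
                      b = seq(best[2] - span, best[2] + span, by = step),
                      g = seq(best[3] - span, best[3] + span, by = step))
    tr <- trace_for(gr$a, gr$b, gr$g)
    best <- unlist(gr[which.max(tr), ], use.names = FALSE)
  }
  tr_best <- trace_for(best[1], best[2], best[3])
  sqrt(max(ss - 2 * tr_best, 0) / n)
}

# --- Markov chains: stationary distribution by eigen-decomposition ---------
oracle_stationary <- function(P) {
  ev <- eigen(t(P))
  v <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  v / sum(v)
}

# random proper rotation matrix
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# assay grid shared by the Michaelis-Menten recovery tests
mm_test_points <- function(kcat = 228, Km = 0.10, E0_nM = 1,
                           replicates = 3) {
  S <- rep(c(0.05, 0.1, 0.2, 0.4, 0.7, 1.0, 1.5, 2.0), each = replicates)
  data.frame(S = S, v = kcat * (E0_nM * 1e-6) * S / (Km + S), E0 = E0_nM)
}
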