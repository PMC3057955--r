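#' Reported kinetic parameters for the five acylphosphatase variants
#'
#' Measured turnover numbers at 298 K and Arrhenius activation energies
#' for the thermophilic acylphosphatase (PhWT and its salt-bridge-free
#' variant PhG91A) and the mesophilic homologue (salt-bridge-bearing
#' HuG99, pseudo-wild-type HuA99 and HuWT), together with the published
#' derived activation thermodynamics used by [reproduce_tables()] as the
#' comparison truth.
#'
#' @return Data frame with one row per variant: measured columns
#'   (`kcat`, `kcat_se` in s^-1; `Ea`, `Ea_se` in kJ mol^-1), the
#'   `salt_bridge` flag, and published derived columns (`dG`, `ddG`,
#'   `dH`, `ddH`, `dS`, `TdS`, `TddS`; kJ mol^-1 except `dS` in
#'   J mol^-1 K^-1; `NA` where no value was reported). Attribute
#'   `pairs` lists the without/with-bridge comparisons.
#' @export
kinetics_presets <- function() {
  df <- data.frame(
    variant = c("PhWT", "PhG91A", "HuG99", "HuA99", "HuWT"),
    salt_bridge = c(TRUE, FALSE, TRUE, FALSE, FALSE),
    kcat = c(228, 211, 1405, 1268, 1214),
    kcat_se = c(15, 25, 225, 100, 196),
    Ea = c(49.1, 32.1, 52.5, 29.5, 37.6),
    Ea_se = c(1.4, 1.7, 2.5, 1.9, 3.1),
    dG = c(59.5, 59.7, 55.0, 55.3, 55.4),
    dG_se = c(0.02, 0.03, 0.04, 0.02, 0.04),
    ddG = c(NA, 0.2, NA, 0.3, 0.4),
    dH = c(46.6, 29.6, 50.0, 27.0, 35.1),
    ddH = c(NA, -17.0, NA, -23.0, -14.9),
    dS = c(-43, -101, -17, -95, -68),
    TdS = c(-12.9, -30.1, -5.0, -28.3, -20.2),
    TddS = c(NA, -17.2, NA, -23.3, -15.2)
  )
  attr(df, "pairs") <- list(Ph = c("PhG91A", "PhWT"),
                            Hu = c("HuA99", "HuG99"),
                            HuWT = c("HuWT", "HuG99"))
  attr(df, "T_ref") <- 298
  df
}

#' Reported binding parameters for the five acylphosphatase variants
#'
#' Association constants and binding enthalpies for the substrate
#' analogue measured by isothermal titration calorimetry at 298 K, plus
#' the published derived binding thermodynamics used as comparison truth.
#'
#' @return Data frame per variant: measured `Ka`, `Ka_se` (M^-1) and
#'   `dHb`, `dHb_se` (kJ mol^-1); the `salt_bridge` flag; and published
#'   derived columns `dGb`, `ddGb`, `ddHb`, `dSb`, `TdSb`, `TddSb`.
#'   Attribute `pairs` as in [kinetics_presets()].
#' @export
binding_presets <- function() {
  df <- data.frame(
    variant = c("PhWT", "PhG91A", "HuG99", "HuA99", "HuWT"),
    salt_bridge = c(TRUE, FALSE, TRUE, FALSE, FALSE),
    Ka = c(6.6e3, 7.5e3, 5.4e3, 5.0e3, 5.1e3),
    Ka_se = c(0.4e3, 0.4e3, 0.2e3, 0.6e3, 0.1e3),
    dHb = c(-6.7, -13.1, -7.0, -10.6, -12.1),
    dHb_se = c(0.4, 1.0, 0.4, 0.8, 3.4),
    dGb = c(-21.8, -22.1, -21.3, -21.1, -21.1),
    ddGb = c(NA, -0.3, NA, 0.2, 0.2),
    ddHb = c(NA, -6.4, NA, -3.6, -5.1),
    dSb = c(50, 30, 48, 35, 30),
    TdSb = c(15.1, 9.0, 14.3, 10.5, 9.0),
    TddSb = c(NA, -6.1, NA, -3.8, -5.3)
  )
  attr(df, "pairs") <- list(Ph = c("PhG91A", "PhWT"),
                            Hu = c("HuA99", "HuG99"),
                            HuWT = c("HuWT", "HuG99"))
  attr(df, "T") <- 298
  df
}

#' Reported equilibrium stability parameters
#'
#' Guanidine-denaturation parameters of the thermophilic variants at
#' 298 K, plus the apparent thermal midpoints (irreversible unfolding,
#' carried as metadata only).
#'
#' @return Data frame with `dGu` (kJ mol^-1), `m_value` (kJ mol^-1 M^-1),
#'   `Cm` (M) with standard errors, and `Tm_app_C`.
#' @export
stability_presets <- function() {
  data.frame(
    variant = c("PhWT", "PhG91A"),
    dGu = c(58, 51), dGu_se = c(7, 6),
    m_value = c(10.9, 9.7), m_value_se = c(1.2, 1.1),
    Cm = c(5.30, 5.23), Cm_se = c(0.04, 0.05),
    Tm_app_C = c(107, 106)
  )
}

# default assay temperature grids: mesophilic 283-303 K, thermophilic
# extended to 318 K (substrate too labile above that)
.default_temperatures <- function(variant) {
  if (grepl("^Ph", variant)) seq(283, 318, by = 5) else seq(283, 303, by = 5)
}

#' Generate synthetic enzyme assay data
#'
#' Emulates initial-rate assays: at every temperature the true turnover
#' number follows the Arrhenius law anchored at 298 K,
#' \eqn{k_{cat}(T) = k_{cat,ref}\exp(-(E_a/R)(1/T - 1/298))}, rates obey
#' Michaelis-Menten kinetics over an 8-level substrate series measured in
#' triplicate, and multiplicative Gaussian noise of coefficient of
#' variation `noise_cv` is applied to each rate. With a preset `variant`
#' the parameters and temperature grid default to that variant's reported
#' values.
#'
#' @param variant Optional preset name (see [kinetics_presets()]).
#' @param kcat_ref Turnover number at 298 K, s^-1.
#' @param Ea Activation energy, kJ mol^-1.
#' @param Km Michaelis constant, mM.
#' @param temperatures Assay temperatures, K.
#' @param S_levels Substrate series, mM.
#' @param replicates Replicates per substrate level.
#' @param E0_nM Enzyme concentration, nM.
#' @param noise_cv Fractional (multiplicative) rate noise; 0 for exact.
#' @param seed Integer seed; the output is a pure function of parameters
#'   and seed.
#' @return Data frame of assay points: `variant`, `T` (K), `S` (mM),
#'   `E0` (nM), `replicate`, `v` (mM s^-1).
#' @examples
#' head(generate_assay_data("PhWT", noise_cv = 0))
#' @export
generate_assay_data <- function(variant = NULL, kcat_ref = 228, Ea = 49.1,
                                Km = 0.10, temperatures = NULL,
                                S_levels = c(0.05, 0.1, 0.2, 0.4, 0.7,
                                             1.0, 1.5, 2.0),
                                replicates = 3, E0_nM = 1.0,
                                noise_cv = 0.03, seed = 1) {
  if (!is.null(variant)) {
    kp <- kinetics_presets()
    row <- kp[kp$variant == variant, ]
    if (nrow(row) != 1L) stop("unknown variant preset: ", variant,
                              call. = FALSE)
    kcat_ref <- row$kcat; Ea <- row$Ea
    if (is.null(temperatures)) temperatures <- .default_temperatures(variant)
  } else if (is.null(temperatures)) temperatures <- seq(283, 318, by = 5)
  stopifnot(kcat_ref > 0, Ea > 0, Km > 0, E0_nM > 0, noise_cv >= 0)

  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(replicates), S = S_levels,
                      T = temperatures)
  kT <- kcat_ref * exp(-(Ea * 1000 / .const$R) * (1 / grid$T - 1 / 298))
  v <- kT * (E0_nM * 1e-6) * grid$S / (Km + grid$S)
  if (noise_cv > 0) v <- v * (1 + stats::rnorm(length(v), 0, noise_cv))
  data.frame(variant = if (is.null(variant)) "synthetic" else variant,
             T = grid$T, S = grid$S, E0 = E0_nM,
             replicate = grid$replicate, v = v)
}

#' Generate synthetic ITC injection heats
#'
#' Seeded wrapper around [simulate_injection_heats()]. With a preset
#' `variant`, Ka and dHb default to that variant's reported values.
#'
#' @param variant Optional preset name (see [binding_presets()]).
#' @param protocol A [titration_protocol()].
#' @param Ka Association constant, M^-1.
#' @param dHb Binding enthalpy, kJ mol^-1.
#' @param n_sites Stoichiometry.
#' @param noise_sd Additive heat noise, uJ.
#' @param seed Integer seed.
#' @return Injection heats in uJ (see [simulate_injection_heats()]).
#' @export
generate_itc_data <- function(variant = NULL, protocol = titration_protocol(),
                              Ka = 6.6e3, dHb = -6.7, n_sites = 1,
                              noise_sd = 0, seed = 1) {
  if (!is.null(variant)) {
    bp <- binding_presets()
    row <- bp[bp$variant == variant, ]
    if (nrow(row) != 1L) stop("unknown variant preset: ", variant,
                              call. = FALSE)
    Ka <- row$Ka; dHb <- row$dHb
  }
  set.seed(seed)
  simulate_injection_heats(protocol, Ka = Ka, dHb = dHb, n_sites = n_sites,
                           noise_sd = noise_sd)
}

#' Generate a synthetic chemical-denaturation curve
#'
#' Evaluates the two-state [lem_model()] on a denaturant grid and adds
#' seeded Gaussian signal noise.
#'
#' @param dGu Free energy of unfolding, kJ mol^-1.
#' @param m_value m-value, kJ mol^-1 M^-1.
#' @param yN,slope_N,yU,slope_U Baseline parameters.
#' @param D Denaturant grid, M.
#' @param noise_sd Additive signal noise (same units as the signal).
#' @param T Temperature, K.
#' @param seed Integer seed.
#' @return Data frame with columns `D` and `y`.
#' @examples
#' generate_denaturation_curve(noise_sd = 0)[1:3, ]
#' @export
generate_denaturation_curve <- function(dGu = 58, m_value = 10.9,
                                        yN = 1, slope_N = 0,
                                        yU = 0, slope_U = 0,
                                        D = seq(0, 7, by = 0.25),
                                        noise_sd = 0.01, T = 298, seed = 1) {
  set.seed(seed)
  y <- lem_model(D, dGu, m_value, yN, slope_N, yU, slope_U, T = T)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  data.frame(D = D, y = y)
}

# canonical chi angles (degrees) of the rotamer states seen in the
# arginine side-chain analysis
.rotamer_canon <- rbind(
  mtm180 = c(300, 180, 300, 180),
  ptt180 = c(60, 180, 180, 180),
  ttp180 = c(180, 180, 60, 180),
  mtt180 = c(300, 180, 180, 180)
)

# von Mises sampler, Best & Fisher (1979) rejection method
.rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    theta <- sign(u3[ok] - 0.5) * acos(f[ok])
    take <- sum(ok)
    out[got + seq_len(take)] <- theta
    got <- got + take
  }
  (mu + out) %% (2 * pi)
}

#' Trajectory scenario for the dihedral/distance generators
#'
#' Describes a hidden-Markov rotamer process: a row-stochastic transition
#' matrix over named rotamer states, a von Mises angular concentration,
#' and whether the salt-bridge is present (which sets the distance-trace
#' regime). The two presets emulate the with-bridge regime (the native
#' mtm180 rotamer dominates, distance ~3.2 A) and the without-bridge
#' regime (excursions to ptt180/ttp180/mtt180 are common, distance
#' ~6 A).
#'
#' @param bridge_present Logical; selects the preset transition matrix
#'   and the distance regime.
#' @param n_frames Number of frames.
#' @param kappa von Mises concentration of each angle about its state's
#'   canonical value (dimensionless; ~50 gives an angular sd of ~8 deg).
#' @param transition_matrix Optional row-stochastic matrix overriding the
#'   preset; rows/columns named by rotamer states present in the
#'   canonical table (mtm180, ptt180, ttp180, mtt180).
#' @param dt_ps Frame spacing, ps.
#' @param seed Integer seed.
#' @return A list of class `"trajectory_scenario"`.
#' @export
trajectory_scenario <- function(bridge_present = TRUE, n_frames = 10000,
                                kappa = 50, transition_matrix = NULL,
                                dt_ps = 1, seed = 1) {
  states <- rownames(.rotamer_canon)
  if (is.null(transition_matrix)) {
    # P = (1-eps) I + eps 1 pi' has stationary distribution pi exactly
    pi_s <- if (bridge_present) c(0.985, 0.005, 0.005, 0.005) else
      c(0.40, 0.25, 0.20, 0.15)
    eps <- if (bridge_present) 0.05 else 0.02
    P <- (1 - eps) * diag(4) + eps * matrix(pi_s, 4, 4, byrow = TRUE)
    dimnames(P) <- list(states, states)
  } else {
    P <- as.matrix(transition_matrix)
    if (is.null(rownames(P))) dimnames(P) <- list(states[seq_len(nrow(P))],
                                                  states[seq_len(nrow(P))])
    if (any(abs(rowSums(P) - 1) > 1e-8))
      stop("transition matrix rows must sum to 1", call. = FALSE)
    if (any(P < 0)) stop("transition probabilities must be nonnegative",
                         call. = FALSE)
  }
  stopifnot(kappa > 0, n_frames >= 2L)
  structure(list(bridge_present = bridge_present, n_frames = n_frames,
                 kappa = kappa, P = P, dt_ps = dt_ps, seed = seed),
            class = "trajectory_scenario")
}

#' Generate a synthetic dihedral trajectory with an aligned distance trace
#'
#' Simulates the rotamer dynamics of the active-site arginine: a Markov
#' state path over named rotamer wells, per-frame chi angles drawn from a
#' von Mises distribution about each state's canonical values, and a
#' donor-acceptor distance trace correlated with occupancy of the native
#' mtm180 state. With the bridge present the distance sits near 3.2 A in
#' the native state (6.0 A during excursions); with the bridge absent it
#' stays near 6.0 A throughout.
#'
#' @param scenario A [trajectory_scenario()].
#' @return A list with `time` (ps), `chi` (n x 4 matrix, degrees, in
#'   \[0, 360)), `state` (true hidden labels), `distance` (Angstrom) and
#'   the `scenario`.
#' @examples
#' tr <- generate_dihedral_trajectory(trajectory_scenario(n_frames = 500))
#' rotamer_statistics(tr$chi)$occupancy[1]
#' @export
generate_dihedral_trajectory <- function(scenario = trajectory_scenario()) {
  stopifnot(inherits(scenario, "trajectory_scenario"))
  set.seed(scenario$seed)
  P <- scenario$P
  states <- rownames(P)
  n <- scenario$n_frames

  # state path, started from the stationary distribution of P
  ev <- eigen(t(P))
  pi_s <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi_s <- pmax(pi_s / sum(pi_s), 0)
  path <- integer(n)
  path[1L] <- sample.int(length(states), 1L, prob = pi_s)
  u <- stats::runif(n - 1L)
  cumP <- t(apply(P, 1L, cumsum))
  for (i in 2:n)
    path[i] <- findInterval(u[i - 1L], cumP[path[i - 1L], ]) + 1L

  canon <- .rotamer_canon[states, , drop = FALSE]
  chi <- matrix(0, n, 4L)
  for (j in 1:4) {
    mu <- canon[path, j] * pi / 180
    # sample per state for speed: same kappa, state-specific mean
    chi[, j] <- (.rvonmises(n, 0, scenario$kappa) + mu) %% (2 * pi) * 180 / pi
  }

  native <- path == match("mtm180", states)
  d_mean <- if (scenario$bridge_present) ifelse(native, 3.2, 6.0) else
    ifelse(native, 5.8, 6.0)
  d_sd <- if (scenario$bridge_present) 0.15 else 0.3
  distance <- pmax(stats::rnorm(n, d_mean, d_sd), 0.5)

  list(time = seq_len(n) * scenario$dt_ps - scenario$dt_ps,
       chi = chi, state = states[path], distance = distance,
       scenario = scenario)
}
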