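#' Analytic 1-D free-energy landscape
#'
#' Sum of Gaussian features, U(s) = -sum_j A_j exp(-(s-c_j)^2 /
#' (2 w_j^2)): positive A_j are wells, negative A_j are barrier humps.
#' Evaluable everywhere and bounded below.  With no features the
#' landscape is flat (U = 0).  Serves as the exact oracle for umbrella
#' sampling / WHAM recovery tests.
#'
#' @param centers feature centers (nm).
#' @param depths feature amplitudes A_j (kJ/mol; positive = well,
#'   negative = barrier).
#' @param widths Gaussian widths w_j (nm).
#' @param domain support interval used for normalization and sampling.
#' @return object of class `gd_landscape` with elements `U` (vectorized
#'   potential) and `density(temperature)` returning the exact normalized
#'   Boltzmann density on `domain`.
#' @export
analytic_landscape <- function(centers, depths, widths,
                               domain = c(-1.5, 12.5)) {
  stopifnot(length(centers) == length(depths),
            length(centers) == length(widths),
            all(widths > 0) || length(widths) == 0)
  U <- function(s) {
    if (!length(centers)) return(rep(0, length(s)))
    out <- rep(0, length(s))
    for (j in seq_along(centers))
      out <- out - depths[j] * exp(-(s - centers[j])^2 / (2 * widths[j]^2))
    out
  }
  density <- function(temperature = 310) {
    beta <- 1 / kT(temperature)
    Z <- stats::integrate(function(s) exp(-beta * U(s)),
                          domain[1], domain[2],
                          subdivisions = 2000L, rel.tol = 1e-10)$value
    function(s) ifelse(s >= domain[1] & s <= domain[2],
                       exp(-beta * U(s)) / Z, 0)
  }
  structure(list(centers = centers, depths = depths, widths = widths,
                 domain = domain, U = U, density = density),
            class = "gd_landscape")
}

#' Default triple-well gating landscape
#'
#' Three wells separated by two barriers along the opening coordinate,
#' laid out like the activation-gating profile: closed well (deepest)
#' near 1.2 nm, a broad intermediate well near 5.4 nm behind a small
#' barrier near 4 nm, and a shallower open well near 10.1 nm behind a
#' larger barrier near 9 nm.  Well depths and barrier heights are
#' package defaults (the layout, not the absolute heights, is the
#' modelled feature).
#'
#' @param depths well depths in kJ/mol, closed/intermediate/open.
#' @param barrier_heights hump amplitudes at 4 and 9 nm, kJ/mol.
#' @export
triple_well_landscape <- function(depths = c(20, 13, 11),
                                  barrier_heights = c(3, 5)) {
  analytic_landscape(
    centers = c(1.2, 4.0, 5.4, 9.0, 10.1),
    depths = c(depths[1], -barrier_heights[1], depths[2],
               -barrier_heights[2], depths[3]),
    widths = c(1.05, 0.45, 1.25, 0.45, 0.75),
    domain = c(-1.5, 12.5))
}

#' Rejection-sample a biased 1-D landscape
#'
#' Draws i.i.d. samples from density proportional to
#' exp(-(U(s) + k/2 (s-s0)^2)/kT) via rejection sampling under a
#' piecewise-constant grid envelope over the landscape domain.
#'
#' @param landscape a [analytic_landscape()].
#' @param s0 bias center (nm).
#' @param k bias force constant (kJ mol^-1 nm^-2), >= 0.
#' @param n number of samples.
#' @param temperature Kelvin.
#' @param seed integer seed (NULL: leave RNG state alone).
#' @param grid_n envelope grid resolution.
#' @return numeric vector of `n` samples (nm).
#' @export
sample_biased_1d <- function(landscape, s0, k, n, temperature = 310,
                             seed = NULL, grid_n = 4000L) {
  stopifnot(inherits(landscape, "gd_landscape"), k >= 0, n >= 0)
  if (n == 0) return(numeric(0))
  if (!is.null(seed)) set.seed(seed)
  beta <- 1 / kT(temperature)
  dom <- landscape$domain
  logf <- function(s) -beta * (landscape$U(s) + 0.5 * k * (s - s0)^2)
  edges <- seq(dom[1], dom[2], length.out = grid_n + 1L)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  h <- diff(edges)[1]
  # per-cell envelope: max of log-density at edges/midpoint plus a
  # curvature-based slack (second difference bounds the in-cell overshoot
  # of a smooth log-density); the acceptance test below still verifies it
  llo <- logf(edges[-length(edges)]); lhi <- logf(edges[-1])
  lmid <- logf(mids)
  lf <- pmax(llo, lhi, lmid) + 0.5 * abs(llo + lhi - 2 * lmid) + 1e-9
  M <- max(lf)
  wcell <- exp(lf - M)
  probs <- wcell / sum(wcell)
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 1000L)
    cell <- sample.int(grid_n, m, replace = TRUE, prob = probs)
    s <- edges[cell] + stats::runif(m) * h
    acc_log <- logf(s) - (lf[cell] - M) - M
    if (any(acc_log > 1e-9))
      stop("envelope failure: widen the landscape grid (grid_n)")
    keep <- log(stats::runif(m)) < acc_log
    out <- c(out, s[keep])
    tries <- tries + 1L
    if (tries > 1000L) stop("rejection sampling failed to accept; ",
                            "check landscape/bias parameters")
  }
  out[seq_len(n)]
}

#' Toy channel specification
#'
#' Parameters of the coarse-grained two-state tetramer: bead geometry of
#' the closed/open endpoints, the tether spring constant of the two
#' elastic networks, the stability offset of the open network
#' (`double_well_bias` > 0 makes the closed basin deeper) and the
#' mixing scale of the smooth two-state switch that couples the subunits
#' (small `mixing_eps` = sharp, strongly cooperative switching).
#'
#' @param n_subunits number of chains (4; the C4 architecture is assumed
#'   by the gate metrics).
#' @param beads_per_helix beads per helix (default 6).
#' @param k_spring tether spring constant, kJ mol^-1 nm^-2.  The default
#'   (800) keeps the thermal RMSD amplitude at 310 K, sqrt(3 kT / k)
#'   ~ 0.1 nm, well below the 0.2 nm opening-success threshold, as
#'   tight packing does in a real protein.
#' @param double_well_bias energy offset of the open network, kJ/mol.
#'   `NULL` (default) sets it to the per-subunit reorganization energy
#'   c = k_spring/2 * |open - closed|^2 / 4, which places the tipping
#'   point of the shared two-state switch exactly between two and three
#'   driven subunits -- the cooperative architecture in which at least
#'   three subunits must move to open the gate.
#' @param mixing_eps softmin mixing scale, kJ/mol.
#' @param temperature Kelvin.
#' @param friction Brownian friction coefficient (kJ mol^-1 nm^-2 ps).
#' @param seed default seed for runs built from this spec.
#' @export
toy_channel_spec <- function(n_subunits = 4L, beads_per_helix = 6L,
                             k_spring = 800, double_well_bias = NULL,
                             mixing_eps = 4, temperature = 310,
                             friction = 1, seed = 1L) {
  stopifnot(n_subunits == 4L, beads_per_helix >= 3L, k_spring > 0,
            mixing_eps > 0)
  structure(list(n_subunits = 4L, beads_per_helix = as.integer(beads_per_helix),
                 k_spring = k_spring, double_well_bias = double_well_bias,
                 mixing_eps = mixing_eps, temperature = temperature,
                 friction = friction, seed = as.integer(seed)),
            class = "gd_toyspec")
}

toy_bead_layout <- function(nb) {
  # residue numbers spread across the TM1 / TM2 segment presets so that
  # selection specs resolve on the toy model; bead 5 of TM2 is the gate
  # (residue 112 analogue)
  list(tm1_res = as.integer(round(seq(30, 50, length.out = nb))),
       tm2_res = as.integer(round(seq(88, 118, length.out = nb))))
}

toy_chain_coords <- function(nb, phi0, open) {
  lay <- toy_bead_layout(nb)
  z1 <- seq(-1.5, 1.5, length.out = nb)
  z2 <- seq(1.5, -1.5, length.out = nb)
  r1 <- rep(1.2, nb)
  # TM2 radius: closed stays tight at the bundle crossing, open splays the
  # C-terminal half outward
  t <- seq(0, 1, length.out = nb)
  r2c <- 0.9 - 0.4 * t + 0.05 * (t > 0.9)
  r2c[nb] <- 0.55
  # C-terminal splay, scaled so the closed/open CA RMSD is 0.40 nm (the
  # 4 Angstrom end-state difference of the modelled transition); radial
  # C4-symmetric displacements leave the optimal superposition at the
  # identity, so the scale follows in closed form
  base <- c(0, 0.05, 0.10, 0.30, 0.50, 0.65,
            rep(0.65, max(0, nb - 6)))[seq_len(nb)]
  scale <- 0.4 * sqrt(2 * nb) / sqrt(sum(base^2))
  r2o <- r2c + scale * base
  r2 <- if (open) r2o else r2c
  twist <- 0.15 * seq_len(nb)       # mild helical twist, avoids collinearity
  ang1 <- phi0 + twist
  ang2 <- phi0 + pi / 4 + twist
  rbind(cbind(r1 * cos(ang1), r1 * sin(ang1), z1),
        cbind(r2 * cos(ang2), r2 * sin(ang2), z2))
}

#' Build the coarse-grained two-state toy channel
#'
#' Four C4-symmetric subunits of two helix rods each (CA pseudo-atoms,
#' chain ids A-D, residue numbering compatible with [kcsa_segments()]),
#' in closed and open endpoint geometries, plus the blended two-state
#' energy.  The energy is a smooth minimum of two harmonic tether networks
#' (one per endpoint), U = -eps log(e^{-Uc/eps} + e^{-(Uo+b)/eps}); the
#' switch is a single global degree of freedom shared by all subunits, so
#' driving fewer than the full complement of subunits toward the open
#' geometry is resisted by the remainder -- the toy analogue of gating
#' cooperativity.
#'
#' @param spec a [toy_channel_spec()].
#' @return list with `closed`, `open` (gd_structure), `energy` (list of
#'   `fn(x)` scalar kJ/mol and `gr(x)` gradient, `x` an n x 3 matrix),
#'   `selection` (a two-helix [selection_spec()] preset matching the toy
#'   bead numbering) and `spec`.
#' @export
make_toy_channel <- function(spec = toy_channel_spec()) {
  nb <- spec$beads_per_helix
  lay <- toy_bead_layout(nb)
  chains <- c("A", "B", "C", "D")
  atoms <- do.call(rbind, lapply(seq_along(chains), function(i) {
    data.frame(serial = 0L,
               atom_name = "CA",
               residue_name = "GLY",
               residue_seq = c(lay$tm1_res, lay$tm2_res),
               chain_id = chains[i],
               element = "C",
               stringsAsFactors = FALSE)
  }))
  atoms$serial <- seq_len(nrow(atoms))
  xyz_state <- function(open)
    do.call(rbind, lapply(0:3, function(k)
      toy_chain_coords(nb, phi0 = k * pi / 2, open = open)))
  closed <- gd_structure(atoms, xyz_state(FALSE))
  open <- gd_structure(atoms, xyz_state(TRUE))
  xc <- closed$xyz; xo <- open$xyz
  kspr <- spec$k_spring; eps <- spec$mixing_eps
  # per-subunit reorganization energy; the default bias b = c makes the
  # closed basin deeper by c and tips the global switch between 2 and 3
  # driven subunits
  c_su <- 0.5 * kspr * sum((xo - xc)^2) / 4
  b <- spec$double_well_bias %||% c_su
  branch_energies <- function(x) {
    c(Uc = 0.5 * kspr * sum((x - xc)^2),
      Uo = 0.5 * kspr * sum((x - xo)^2) + b)
  }
  fn <- function(x) {
    u <- branch_energies(as.matrix(x))
    m <- min(u)
    m - eps * log(sum(exp(-(u - m) / eps)))
  }
  gr <- function(x) {
    x <- as.matrix(x)
    u <- branch_energies(x)
    m <- min(u)
    w <- exp(-(u - m) / eps); w <- w / sum(w)
    w[1] * kspr * (x - xc) + w[2] * kspr * (x - xo)
  }
  list(closed = closed, open = open,
       energy = list(fn = fn, gr = gr),
       selection = selection_spec(
         segments = list(TM1 = c(29L, 51L), TM2 = c(86L, 118L)),
         backbone_atoms = "CA"),
       spec = spec)
}

#' Overdamped Brownian dynamics propagator
#'
#' Euler-Maruyama integration of dx = -grad U / gamma dt +
#' sqrt(2 kT dt / gamma) dW.  At temperature 0 this is plain gradient
#' descent; in the long-time limit it samples exp(-U/kT).
#'
#' @param energy list with `fn(x)` and `gr(x)` as from
#'   [make_toy_channel()]; `x` an n x 3 matrix.
#' @param start starting coordinates (n x 3 matrix or `gd_structure`).
#' @param n_steps number of integration steps.
#' @param dt time step, ps.
#' @param temperature Kelvin.
#' @param friction gamma, kJ mol^-1 nm^-2 ps.
#' @param seed integer seed; identical seeds give identical trajectories.
#' @param save_every store every k-th frame (default 1).
#' @return a [gd_traj()] (first stored frame is after the first step).
#' @export
run_bd <- function(energy, start, n_steps, dt = 5e-4, temperature = 310,
                   friction = 1, seed = NULL, save_every = 1L) {
  if (inherits(start, "gd_structure")) start <- start$xyz
  x <- as.matrix(start)
  if (!all(is.finite(energy$gr(x))))
    stop("non-finite gradient at start coordinates")
  if (!is.null(seed)) set.seed(seed)
  noise_sd <- sqrt(2 * kT(temperature) * dt / friction)
  nout <- n_steps %/% save_every
  out <- matrix(NA_real_, nout, length(x))
  tout <- numeric(nout)
  j <- 0L
  for (step in seq_len(n_steps)) {
    x <- x - energy$gr(x) * (dt / friction)
    if (noise_sd > 0)
      x <- x + matrix(stats::rnorm(length(x), sd = noise_sd), nrow(x), 3)
    if (any(abs(x) > 1e4))
      stop("trajectory diverged (|coords| huge); reduce dt")
    if (step %% save_every == 0L) {
      j <- j + 1L
      out[j, ] <- as_frame_row(x)
      tout[j] <- step * dt
    }
  }
  gd_traj(out[seq_len(j), , drop = FALSE], tout[seq_len(j)])
}

#' Two-state chi1 rotamer trace generator
#'
#' Discrete-time two-state Markov chain (up/down) with wrapped-Gaussian
#' angle emission about the basin centers of the aromatic gate residues
#' (up near -63.5 deg, down near -175.5 deg).  The true state path is
#' returned alongside for classifier validation.
#'
#' @param p_up_to_down,p_down_to_up per-step transition probabilities.
#' @param up_center,down_center emission centers, degrees.
#' @param noise_sd circular emission sd, degrees.
#' @param n_steps chain length.
#' @param seed integer seed.
#' @param start starting state, "up" or "down".
#' @return list with `angles` (degrees in (-180, 180]), `states`
#'   (character), `times` (step index).
#' @export
gen_dihedral_trace <- function(p_up_to_down, p_down_to_up,
                               up_center = -63.5, down_center = -175.5,
                               noise_sd = 8, n_steps = 1000L, seed = NULL,
                               start = "up") {
  stopifnot(p_up_to_down >= 0, p_up_to_down <= 1,
            p_down_to_up >= 0, p_down_to_up <= 1)
  if (!is.null(seed)) set.seed(seed)
  states <- character(n_steps)
  s <- match.arg(start, c("up", "down"))
  for (i in seq_len(n_steps)) {
    states[i] <- s
    p <- if (s == "up") p_up_to_down else p_down_to_up
    if (stats::runif(1) < p) s <- if (s == "up") "down" else "up"
  }
  centers <- ifelse(states == "up", up_center, down_center)
  ang <- centers + stats::rnorm(n_steps, sd = noise_sd)
  list(angles = wrap_angle(ang), states = states,
       times = seq_len(n_steps) - 1)
}

#' Wrap angles to the (-180, 180] convention
#' @param a angles in degrees.
#' @export
wrap_angle <- function(a) {
  w <- a %% 360
  ifelse(w > 180, w - 360, w)
}
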