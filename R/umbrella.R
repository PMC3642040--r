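#' Umbrella window container
#'
#' Biased samples of the reaction coordinate from one umbrella window.
#'
#' @param center bias center s0 (nm).
#' @param k harmonic force constant (kJ mol^-1 nm^-2), >= 0.
#' @param samples projection samples (nm) after equilibration discard.
#' @param discarded_fraction fraction of the raw run discarded.
#' @param source free-text tag (e.g. "toy-bd", "landscape").
#' @export
umbrella_window <- function(center, k, samples, discarded_fraction = 0,
                            source = "") {
  stopifnot(k >= 0)
  samples <- as.numeric(samples)
  if (!length(samples)) stop("umbrella window has no samples after discard")
  structure(list(center = center, k = k, samples = samples,
                 discarded_fraction = discarded_fraction, source = source),
            class = "gd_window")
}

#' Select umbrella window seeds along a path trajectory
#'
#' Picks `n_windows` frames of a (monotone) transition path at
#' approximately equal spacing of the projection, and assigns each its
#' force constant.  The classic atomistic protocol for this transition uses 39 windows,
#' most at 1 kJ mol^-1 nm^-2 with six barrier windows boosted to 100;
#' those are the defaults, with the boosted set empty unless given.
#'
#' @param path_traj a [gd_traj()] spanning the transition.
#' @param cv a [collective_vector()].
#' @param n_windows number of windows (default 39).
#' @param default_k,boosted_k force constants (kJ mol^-1 nm^-2).
#' @param boosted_set window indices (1-based) to boost.
#' @param projections optional precomputed per-frame projections.
#' @return data.frame with `window`, `frame`, `center` (nm, strictly
#'   increasing for a monotone path), `k`; frames usable as seed
#'   structures.
#' @export
make_windows <- function(path_traj, cv, n_windows = 39L, default_k = 1,
                         boosted_k = 100, boosted_set = integer(0),
                         projections = NULL) {
  stopifnot(inherits(path_traj, "gd_traj"), n_windows >= 1)
  if (n_frames(path_traj) < n_windows)
    stop("path trajectory has fewer frames (", n_frames(path_traj),
         ") than requested windows (", n_windows, ")")
  s <- projections %||% project_traj(path_traj, cv)
  if (n_windows == 1L) {
    want <- (min(s) + max(s)) / 2
  } else {
    want <- seq(min(s), max(s), length.out = n_windows)
  }
  frame <- vapply(want, function(w) which.min(abs(s - w)), integer(1))
  k <- rep(default_k, n_windows)
  k[boosted_set[boosted_set >= 1 & boosted_set <= n_windows]] <- boosted_k
  data.frame(window = seq_len(n_windows), frame = frame,
             center = s[frame], k = k)
}

#' Sample one umbrella window
#'
#' Draws biased samples of the coordinate with the harmonic umbrella
#' potential k/2 (s - s0)^2 added, discards the first fraction for
#' equilibration (default one half, mirroring a 50-of-100 ns discard) and
#' returns an [umbrella_window()].  Two backends:
#'
#' * an [analytic_landscape()]: exact rejection sampling of the biased
#'   density (equilibration discard is a no-op on i.i.d. draws but is
#'   applied for protocol fidelity);
#' * a toy-channel energy plus [collective_vector()]: Brownian dynamics
#'   with the bias force mapped onto the cv atoms by the chain rule.
#'   An optional `fit = FALSE` element in the system list skips the
#'   per-step rigid-body fit inside the projection -- exact for
#'   position-tethered systems, which cannot drift, and much faster.
#'
#' @param system an `gd_landscape`, or a list with `energy` and `cv` (and
#'   optionally `start` coordinates).
#' @param center bias center s0 (nm).
#' @param k force constant (kJ mol^-1 nm^-2).
#' @param n_samples raw draws (landscape) or BD steps (toy system); the
#'   first `discard_first_fraction` of them is dropped.
#' @param discard_first_fraction fraction discarded (default 0.5).
#' @param temperature Kelvin.
#' @param seed integer seed.
#' @param dt,friction,save_every BD engine parameters (toy backend).
#' @return an [umbrella_window()].
#' @export
sample_window <- function(system, center, k, n_samples,
                          discard_first_fraction = 0.5,
                          temperature = 310, seed = NULL,
                          dt = 5e-4, friction = 1, save_every = 1L) {
  stopifnot(k >= 0, discard_first_fraction >= 0,
            discard_first_fraction < 1)
  if (inherits(system, "gd_landscape")) {
    s <- sample_biased_1d(system, center, k, n_samples,
                          temperature = temperature, seed = seed)
    drop_n <- ceiling(length(s) * discard_first_fraction)
    if (drop_n >= length(s))
      stop("discard fraction leaves no samples for this run length")
    keep <- if (drop_n > 0) s[-seq_len(drop_n)] else s
    return(umbrella_window(center, k, keep,
                           discarded_fraction = discard_first_fraction,
                           source = "landscape"))
  }
  energy <- system$energy; cv <- system$cv
  start <- system$start %||% ref_as_start(cv)
  fit <- system$fit %||% TRUE
  biased <- list(
    fn = function(x) {
      s <- project_cv(x, cv, fit = fit)
      energy$fn(x) + 0.5 * k * (s - center)^2
    },
    gr = function(x) {
      s <- project_cv(x, cv, fit = fit)
      g <- energy$gr(x)
      # chain rule through the projection: d s / d x = direction on the
      # cv atoms (fit rotation derivative neglected, standard practice)
      g[cv$atom_indices, ] <- g[cv$atom_indices, ] +
        k * (s - center) * matrix(cv$direction, ncol = 3, byrow = TRUE)
      g
    })
  traj <- run_bd(biased, start, n_steps = n_samples, dt = dt,
                 temperature = temperature, friction = friction,
                 seed = seed, save_every = save_every)
  s <- project_traj(traj, cv, fit = fit)
  drop_n <- ceiling(length(s) * discard_first_fraction)
  if (drop_n >= length(s))
    stop("discard fraction leaves no samples for this run length")
  keep <- if (drop_n > 0) s[-seq_len(drop_n)] else s
  umbrella_window(center, k, keep,
                  discarded_fraction = discard_first_fraction,
                  source = "toy-bd")
}

ref_as_start <- function(cv) {
  out <- matrix(0, max(cv$atom_indices), 3)
  out[cv$atom_indices, ] <- cv$reference_coords
  out
}

#' Histogram-overlap diagnostic for umbrella windows
#'
#' @param windows list of [umbrella_window()].
#' @return data.frame of adjacent-window (by center) sample-range overlap
#'   widths (nm); negative width = gap.
#' @export
window_overlap <- function(windows) {
  o <- order(vapply(windows, `[[`, numeric(1), "center"))
  w <- windows[o]
  n <- length(w)
  if (n < 2) return(data.frame(pair = integer(0), overlap = numeric(0)))
  ov <- vapply(seq_len(n - 1), function(i) {
    min(max(w[[i]]$samples), max(w[[i + 1]]$samples)) -
      max(min(w[[i]]$samples), min(w[[i + 1]]$samples))
  }, numeric(1))
  data.frame(pair = seq_len(n - 1), overlap = ov)
}

#' Weighted-histogram analysis (WHAM)
#'
#' Self-consistent unbiasing of umbrella windows into a potential of mean
#' force.  Pooled histograms over `n_bins` bins; iterate
#' p_b = sum_i n_ib / sum_i N_i f_i c_ib and f_i = 1 / sum_b p_b c_ib
#' (c_ib the Boltzmann factor of window i's bias at bin b) until the
#' window free-energy constants -kT log f_i change by less than `tol`.
#' The profile is F_b = -kT log p_b, shifted so its minimum is 0.
#'
#' @param windows list of [umbrella_window()].
#' @param n_bins histogram bins over the pooled sample range (default
#'   200).
#' @param range optional length-2 coordinate interval pinning the
#'   histogram grid (default: the pooled sample range).
#' @param temperature Kelvin.
#' @param tol convergence tolerance on the f constants, kJ/mol.
#' @param max_iter iteration cap.
#' @return object of class `gd_pmf`: `bin_centers`, `free_energy`
#'   (kJ/mol, min 0; NaN for empty bins), `counts`, `temperature`,
#'   `iterations`, `residual`, `window_f` and the overlap diagnostic.
#' @export
wham <- function(windows, n_bins = 200L, range = NULL,
                 temperature = 310, tol = 1e-7, max_iter = 100000L) {
  stopifnot(length(windows) >= 1)
  for (w in windows) stopifnot(inherits(w, "gd_window"))
  beta <- 1 / kT(temperature)
  all_s <- unlist(lapply(windows, `[[`, "samples"))
  rng <- if (is.null(range)) base::range(all_s) else sort(range)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  W <- length(windows)
  counts <- matrix(0, W, n_bins)
  for (i in seq_len(W)) {
    b <- findInterval(windows[[i]]$samples, edges,
                      rightmost.closed = TRUE, all.inside = TRUE)
    counts[i, ] <- tabulate(b, n_bins)
  }
  ov <- window_overlap(windows)
  if (any(ov$overlap < 0))
    warning("non-overlapping adjacent windows (gap in sampling); ",
            "bins inside gaps will be NaN")
  Ni <- rowSums(counts)
  ntot_b <- colSums(counts)
  cmat <- exp(-beta * 0.5 *
              vapply(windows, `[[`, numeric(1), "k") *
              outer(vapply(windows, `[[`, numeric(1), "center"),
                    centers, function(s0, s) (s - s0)^2))
  # cmat is W x n_bins
  f <- rep(1, W)
  gprev <- rep(0, W)
  it <- 0L; resid <- Inf
  repeat {
    it <- it + 1L
    denom <- colSums((Ni * f) * cmat)
    p <- ifelse(denom > 0, ntot_b / denom, 0)
    p <- p / sum(p)
    f <- 1 / as.vector(cmat %*% p)
    g <- -log(f) / beta
    g <- g - g[1]
    resid <- max(abs(g - gprev))
    gprev <- g
    if (resid < tol) break
    if (it >= max_iter)
      stop("WHAM failed to converge: residual ", format(resid),
           " kJ/mol after ", it, " iterations")
  }
  Fb <- ifelse(ntot_b > 0, -log(p) / beta, NaN)
  Fb <- Fb - min(Fb, na.rm = TRUE)
  structure(list(bin_centers = centers, free_energy = Fb,
                 counts = ntot_b, n_bins = n_bins,
                 temperature = temperature, iterations = it,
                 residual = resid, window_f = g, overlap = ov,
                 bootstrap_se = NULL),
            class = "gd_pmf")
}

#' @export
print.gd_pmf <- function(x, ...) {
  cat(sprintf("gd_pmf: %d bins over [%.3g, %.3g] nm, %d WHAM iterations\n",
              x$n_bins, min(x$bin_centers), max(x$bin_centers),
              x$iterations))
  invisible(x)
}

#' @export
plot.gd_pmf <- function(x, ...) {
  graphics::plot(x$bin_centers, x$free_energy, type = "l",
                 xlab = "reaction coordinate (nm)",
                 ylab = "free energy (kJ/mol)", ...)
  if (!is.null(x$bootstrap_se)) {
    graphics::arrows(x$bin_centers, x$free_energy - x$bootstrap_se,
                     x$bin_centers, x$free_energy + x$bootstrap_se,
                     length = 0.01, angle = 90, code = 3,
                     col = "grey60")
  }
  invisible(x)
}

#' Bootstrap standard errors of a PMF
#'
#' Whole-window bootstrap: each window's samples are resampled with
#' replacement, WHAM is re-solved, each replicate profile is aligned at
#' its minimum (WHAM fixes only relative free energies) and the per-bin
#' standard deviation across replicates is the error estimate.  The
#' customary protocol uses 50 bootstraps.
#'
#' @param windows list of [umbrella_window()].
#' @param n_boot bootstrap replicates (default 50).
#' @param seed integer seed.
#' @param ... passed to [wham()].
#' @return list with `se` (per-bin SE, kJ/mol, on the full-set bin grid),
#'   `n_failed` replicates, and `pmf` (the full-set `gd_pmf` with
#'   `bootstrap_se` filled in).
#' @export
bootstrap_pmf <- function(windows, n_boot = 50L, seed = NULL, ...) {
  full <- wham(windows, ...)
  if (n_boot == 0L) {
    warning("n_boot = 0: returning zero-length SE")
    return(list(se = numeric(0), n_failed = 0L, pmf = full))
  }
  if (!is.null(seed)) set.seed(seed)
  reps <- matrix(NA_real_, n_boot, full$n_bins)
  nfail <- 0L
  for (b in seq_len(n_boot)) {
    wb <- lapply(windows, function(w) {
      umbrella_window(w$center, w$k,
                      sample(w$samples, length(w$samples), replace = TRUE),
                      w$discarded_fraction, w$source)
    })
    pb <- tryCatch(wham(wb, ...), error = function(e) NULL)
    if (is.null(pb)) { nfail <- nfail + 1L; next }
    # replicate bins can differ slightly (sample range shifts); put the
    # replicate on the full-set grid
    Fb <- stats::approx(pb$bin_centers, pb$free_energy,
                        xout = full$bin_centers, rule = 1)$y
    reps[b, ] <- Fb - min(Fb, na.rm = TRUE)
  }
  if (nfail > 0) warning(nfail, " bootstrap replicate(s) failed")
  se <- apply(reps, 2, stats::sd, na.rm = TRUE)
  full$bootstrap_se <- se
  list(se = se, n_failed = nfail, pmf = full)
}

#' Projection ranges of state ensembles along the coordinate
#'
#' Projects named state trajectories (e.g. unbiased runs of the closed,
#' intermediate and open conformations) onto the collective vector and
#' reports the sampling interval of each -- the shaded ranges that locate
#' each state's well on the free-energy profile -- plus, per state, the
#' profile minimum inside its interval.
#'
#' @param pmf a `gd_pmf` (or NULL to skip well lookup).
#' @param state_trajs named list of [gd_traj()].
#' @param cv a [collective_vector()].
#' @param probs quantile pair for the robust interval (default 5-95%).
#' @return data.frame: state, min, max, q_lo, q_hi (nm), and
#'   `well_center` (bin of minimal free energy inside [min, max], NA
#'   without a pmf).
#' @export
shade_states <- function(pmf, state_trajs, cv, probs = c(0.05, 0.95)) {
  stopifnot(length(state_trajs) >= 1, !is.null(names(state_trajs)))
  rows <- lapply(names(state_trajs), function(nm) {
    tr <- state_trajs[[nm]]
    if (is.numeric(tr) && length(tr)) {
      s <- tr        # pre-projected samples
    } else {
      if (!inherits(tr, "gd_traj") || n_frames(tr) == 0)
        stop("empty or invalid trajectory for state ", nm)
      s <- project_traj(tr, cv)
    }
    q <- stats::quantile(s, probs, names = FALSE)
    wc <- NA_real_
    if (!is.null(pmf)) {
      # the robust (quantile) interval avoids mis-attributing a well to
      # rare cross-barrier excursions in the state ensemble
      inside <- pmf$bin_centers >= q[1] & pmf$bin_centers <= q[2]
      if (any(inside & is.finite(pmf$free_energy))) {
        sub <- which(inside)
        wc <- pmf$bin_centers[sub[which.min(pmf$free_energy[sub])]]
      }
    }
    data.frame(state = nm, min = min(s), max = max(s),
               q_lo = q[1], q_hi = q[2], well_center = wc)
  })
  do.call(rbind, rows)
}

#' Umbrella/WHAM free-energy profile of the toy channel
#'
#' Convenience wrapper reproducing the umbrella protocol on the
#' coarse-grained channel: soft windows spread over the whole opening
#' coordinate plus a dense set of stiff ("boosted") windows bridging the
#' two-state switch region, where the profile is steepest -- the same
#' trick as boosting a few barrier windows to a 100-fold force constant
#' in the original protocol.  Window seeds are constrained copies of the
#' closed structure; sampling runs with `fit = FALSE` (the tethered toy
#' cannot drift).
#'
#' @param toy a [make_toy_channel()] result.
#' @param cv optional precomputed [build_difference_ev()] coordinate.
#' @param n_soft,n_hard numbers of soft / boosted windows.
#' @param soft_k,hard_k force constants (kJ mol^-1 nm^-2).
#' @param n_samples BD steps per window.
#' @param discard_first_fraction equilibration discard.
#' @param dt BD time step (ps); must resolve `hard_k`.
#' @param n_bins,tol,max_iter passed to [wham()].
#' @param seed integer seed.
#' @return list with `windows`, `pmf` (a `gd_pmf`), `cv` and the
#'   switch-point estimate `s_star` (nm).
#' @export
toy_umbrella_pmf <- function(toy, cv = NULL, n_soft = 29L, n_hard = 19L,
                             soft_k = 4000, hard_k = 40000,
                             n_samples = 1500L,
                             discard_first_fraction = 0.4, dt = 4e-5,
                             n_bins = 120L, tol = 1e-4,
                             max_iter = 500000L, seed = 1L) {
  if (is.null(cv))
    cv <- build_difference_ev(toy$closed, toy$open, toy$selection)
  L <- attr(cv, "path_length")
  # switch point of the two-state blend along the path: where the two
  # tether networks have equal energy, k/2 s^2 = b + k/2 (s - L)^2
  b <- toy$energy$fn(toy$open$xyz) - toy$energy$fn(toy$closed$xyz)
  kspr <- toy$spec$k_spring
  s_star <- (b / (kspr / 2) + L^2) / (2 * L)
  cf <- data.frame(center = c(seq(-0.05, L + 0.05, length.out = n_soft),
                              seq(s_star - 0.45, s_star + 0.45,
                                  length.out = n_hard)),
                   k = c(rep(soft_k, n_soft), rep(hard_k, n_hard)))
  cf <- cf[order(cf$center), ]
  if (!is.null(seed)) set.seed(seed)
  jitter_sd <- 0.01
  windows <- lapply(seq_len(nrow(cf)), function(i) {
    st <- ed_constrain(toy$closed$xyz +
                         matrix(stats::rnorm(3 * n_atoms(toy$closed),
                                             sd = jitter_sd), ncol = 3),
                       cv, cf$center[i])
    sample_window(list(energy = toy$energy, cv = cv, start = st,
                       fit = FALSE),
                  cf$center[i], k = cf$k[i], n_samples = n_samples,
                  discard_first_fraction = discard_first_fraction,
                  temperature = toy$spec$temperature,
                  friction = toy$spec$friction,
                  seed = seed * 1000L + i, dt = dt, save_every = 3L)
  })
  pmf <- suppressWarnings(wham(windows, n_bins = n_bins,
                               temperature = toy$spec$temperature,
                               tol = tol, max_iter = max_iter))
  list(windows = windows, pmf = pmf, cv = cv, s_star = s_star)
}
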