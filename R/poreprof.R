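#' Default hard-sphere radii for pore profiling
#'
#' Simple element-based radii in nm (configurable; the resulting gate
#' diameters are radii-table dependent at the +-0.3 Angstrom level).
#'
#' @return named numeric vector of radii (nm).
#' @export
default_radii <- function() {
  c(C = 0.185, N = 0.175, O = 0.165, S = 0.200, H = 0.100, P = 0.210)
}

#' HOLE-style pore radius profile
#'
#' Largest-sphere search along the channel axis: at each z slab the
#' in-plane sphere center c maximizing r(c) = min_atoms(|c - x_atom| -
#' R_atom) is found by simulated-annealing Monte Carlo seeded from the
#' previous slab's center, backed by a coarse deterministic grid scan
#' (the surface can hold several off-axis pockets) and polished by a
#' multiscale compass search.  The axis defaults to z through the selection
#' centroid (the C4 symmetry axis of a tetramer aligned as built); supply
#' `axis_point` for other orientations after rotating the model.
#'
#' @param model a `gd_structure`.
#' @param selection a [selection_spec()] or an atom index vector
#'   (default: backbone selection including loops).
#' @param radii named element-radius table (nm), see [default_radii()].
#' @param z_range length-2 z interval (nm); default covers the selection.
#' @param z_step slab spacing (nm, default 0.025).
#' @param axis_point in-plane starting center `c(x, y)` for the first
#'   slab; default the selection centroid.
#' @param lateral_bound maximal distance of the sphere center from the
#'   start center before the pore is declared lost (default 1.5 nm).
#' @param mc_steps,mc_step_size,mc_cool annealing schedule: number of MC
#'   moves per slab, initial Gaussian move size (nm), geometric cooling
#'   factor per move.
#' @param z_neighborhood only atoms within this z distance of a slab are
#'   considered (default 1.2 nm; safe while pore radii stay below it).
#' @param seed integer seed for the annealing moves.
#' @return object of class `gd_poreprofile`: `z`, `radius`, `center_x`,
#'   `center_y` (nm), `constriction` (list `z`, `radius`) and the radii
#'   table used.
#' @export
pore_profile <- function(model, selection = NULL, radii = default_radii(),
                         z_range = NULL, z_step = 0.025,
                         axis_point = NULL, lateral_bound = 1.5,
                         mc_steps = 200L, mc_step_size = 0.05,
                         mc_cool = 0.985, z_neighborhood = 1.2,
                         seed = 1L) {
  stopifnot(inherits(model, "gd_structure"))
  if (is.null(selection))
    selection <- selection_spec(include_loops = TRUE)
  idx <- if (inherits(selection, "gd_selection"))
    resolve_selection(model, selection) else as.integer(selection)
  if (!length(idx)) stop("empty selection for pore profiling")
  xyz <- model$xyz[idx, , drop = FALSE]
  el <- model$atoms$element[idx]
  R <- unname(radii[el])
  if (anyNA(R)) {
    miss <- unique(el[is.na(R)])
    warning("elements without radii treated as C: ",
            paste(miss, collapse = ","))
    R[is.na(R)] <- radii[["C"]]
  }
  if (is.null(z_range)) z_range <- range(xyz[, 3])
  zs <- seq(z_range[1], z_range[2], by = z_step)
  c0 <- axis_point %||% colMeans(xyz[, 1:2, drop = FALSE])
  if (!is.null(seed)) set.seed(seed)
  pr <- function(cx, cy, sub) {
    d <- sqrt((sub$x - cx)^2 + (sub$y - cy)^2 + sub$dz2) - sub$R
    min(d)
  }
  # polar candidate grid (relative to the axis) for the global scan;
  # 0.05 nm resolution suffices to land in the right basin, the compass
  # polish does the rest
  grid_rmax <- min(lateral_bound, 0.6)
  grid_pts <- do.call(rbind, lapply(seq(0, grid_rmax, by = 0.05),
                                    function(r) {
    na <- max(1L, ceiling(2 * pi * r / 0.05))
    th <- 2 * pi * seq_len(na) / na
    cbind(r * cos(th), r * sin(th))
  }))
  out_r <- numeric(length(zs)); out_c <- matrix(NA_real_, length(zs), 2)
  cc <- c0
  for (iz in seq_along(zs)) {
    z <- zs[iz]
    near <- abs(xyz[, 3] - z) <= z_neighborhood
    if (!any(near)) { out_r[iz] <- NA_real_; next }
    sub <- list(x = xyz[near, 1], y = xyz[near, 2],
                dz2 = (xyz[near, 3] - z)^2, R = R[near])
    best <- cc
    best_r <- pr(best[1], best[2], sub)
    cur <- best; cur_r <- best_r
    step <- mc_step_size
    Tmc <- 0.05   # acceptance temperature in nm of radius
    for (m in seq_len(mc_steps)) {
      cand <- cur + stats::rnorm(2, sd = step)
      if (sqrt(sum((cand - c0)^2)) > lateral_bound) next
      r <- pr(cand[1], cand[2], sub)
      if (r > cur_r || stats::runif(1) < exp((r - cur_r) / Tmc)) {
        cur <- cand; cur_r <- r
        if (r > best_r) { best <- cand; best_r <- r }
      }
      step <- step * mc_cool
      Tmc <- Tmc * mc_cool
    }
    # deterministic coarse grid scan: the per-slab surface can hold
    # several local maxima (off-axis pockets between tight rings), and
    # the global one is wanted; a 0.02 nm grid bounds the miss distance
    # before polishing
    gx <- grid_pts[, 1] + c0[1]
    gy <- grid_pts[, 2] + c0[2]
    gvals <- rep(Inf, length(gx))
    for (a in seq_along(sub$x))
      gvals <- pmin(gvals, sqrt((gx - sub$x[a])^2 + (gy - sub$y[a])^2 +
                                sub$dz2[a]) - sub$R[a])
    jg <- which.max(gvals)
    g_start <- c(gx[jg], gy[jg])
    # multiscale compass polish (16 directions, halving steps), which is
    # reliable on the ridged surface where simplex methods stall; seeded
    # from the annealed optimum, the axis start and the grid optimum
    dirs <- cbind(cos(2 * pi * (0:15) / 16), sin(2 * pi * (0:15) / 16))
    for (start in list(best, c0, g_start)) {
      cur <- start; cur_r <- pr(start[1], start[2], sub)
      step <- mc_step_size
      while (step > 1e-6) {
        cand <- sweep(dirs * step, 2, cur, `+`)
        vals <- vapply(seq_len(nrow(cand)), function(j)
          pr(cand[j, 1], cand[j, 2], sub), numeric(1))
        jb <- which.max(vals)
        if (vals[jb] > cur_r &&
            sqrt(sum((cand[jb, ] - c0)^2)) <= lateral_bound) {
          cur <- cand[jb, ]; cur_r <- vals[jb]
        } else {
          step <- step / 2
        }
      }
      if (cur_r > best_r) { best <- cur; best_r <- cur_r }
    }
    if (sqrt(sum((best - c0)^2)) > lateral_bound)
      stop("pore lost at z = ", signif(z, 4),
           " nm (center escaped the lateral bound)")
    out_r[iz] <- best_r
    out_c[iz, ] <- best
    cc <- best
  }
  ok <- is.finite(out_r)
  imin <- which(ok)[which.min(out_r[ok])]
  structure(list(z = zs, radius = out_r,
                 center_x = out_c[, 1], center_y = out_c[, 2],
                 constriction = list(z = zs[imin], radius = out_r[imin]),
                 radii = radii, n_atoms = length(idx)),
            class = "gd_poreprofile")
}

#' @export
print.gd_poreprofile <- function(x, ...) {
  cat(sprintf(
    "gd_poreprofile: %d slabs, constriction r = %.3f nm at z = %.3f nm\n",
    length(x$z), x$constriction$radius, x$constriction$z))
  invisible(x)
}

#' @export
plot.gd_poreprofile <- function(x, ...) {
  graphics::plot(x$z, x$radius, type = "l", xlab = "z (nm)",
                 ylab = "pore radius (nm)", ...)
  invisible(x)
}

#' Gate diameter from a pore profile
#'
#' Twice the minimal profile radius inside a z window, reported in
#' Angstrom (the convention of gating figures).  The default window is
#' the intracellular half of the profile, below the selectivity filter.
#'
#' @param profile a `gd_poreprofile`.
#' @param z_window length-2 z interval (nm); default `c(-Inf, 0)`, the
#'   intracellular half for a channel built/aligned with the
#'   extracellular face at positive z.
#' @return diameter in Angstrom.
#' @export
gate_diameter <- function(profile, z_window = c(-Inf, 0)) {
  stopifnot(inherits(profile, "gd_poreprofile"))
  inw <- profile$z >= z_window[1] & profile$z <= z_window[2] &
         is.finite(profile$radius)
  if (!any(inw)) stop("no profile slabs inside the z window")
  2 * min(profile$radius[inw]) * ANG_PER_NM
}
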