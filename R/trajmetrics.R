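#' Signed dihedral angle of four points
#'
#' Praxeolitic formula; degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 3-vectors (nm).
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

#' chi1 side-chain dihedral of a residue
#'
#' N-CA-CB-gamma dihedral (gamma atom CG for Phe and most residues;
#' override for Ile/Val/Thr/Cys).
#'
#' @param coords n x 3 coordinate matrix of the frame (nm), or a
#'   `gd_structure`.
#' @param atoms atom table (as in `gd_structure$atoms`); taken from
#'   `coords` when that is a structure.
#' @param chain_id,residue_seq residue address.
#' @param gamma_atom name of the gamma atom (default "CG").
#' @return chi1 in degrees, or NaN (with a warning) if an atom is
#'   missing.
#' @export
chi1 <- function(coords, atoms = NULL, chain_id, residue_seq,
                 gamma_atom = "CG") {
  if (inherits(coords, "gd_structure")) {
    atoms <- coords$atoms; coords <- coords$xyz
  }
  need <- c("N", "CA", "CB", gamma_atom)
  idx <- vapply(need, function(nm) {
    i <- which(atoms$chain_id == chain_id &
               atoms$residue_seq == residue_seq &
               atoms$atom_name == nm)
    if (length(i) != 1L) NA_integer_ else i
  }, integer(1))
  if (anyNA(idx)) {
    warning("residue ", chain_id, residue_seq, " lacks atom(s): ",
            paste(need[is.na(idx)], collapse = ","))
    return(NaN)
  }
  dihedral(coords[idx[1], ], coords[idx[2], ], coords[idx[3], ],
           coords[idx[4], ])
}

#' Classify a chi1 angle into the up/down rotamer states
#'
#' The aromatic gate residues occupy an "up" basin (chi1 -55 to -72 deg)
#' and a "down" basin (chi1 -166 to -185 deg; circularly this is
#' [-180, -166] plus [175, 180]).  `strict` mode returns "unassigned"
#' outside both printed ranges; `nearest` mode assigns by circular
#' distance to the basin centers (-63.5 and -175.5 deg).
#'
#' @param angle chi1 in degrees (any wrap; vectorized).
#' @param up_range,down_range inclusive ranges in degrees; `down_range`
#'   may extend past -180 and is interpreted circularly.
#' @param mode "strict" or "nearest".
#' @return character vector: "up", "down" or "unassigned".
#' @export
classify_rotamer <- function(angle, up_range = c(-72, -55),
                             down_range = c(-185, -166),
                             mode = c("strict", "nearest")) {
  mode <- match.arg(mode)
  a <- wrap_angle(angle)
  circ_dist <- function(x, y) abs(wrap_angle(x - y))
  in_circular <- function(a, rng) {
    lo <- rng[1]; hi <- rng[2]
    width <- hi - lo
    d <- (a - lo) %% 360
    d >= 0 & d <= width
  }
  up <- in_circular(a, up_range)
  down <- in_circular(a, down_range)
  if (mode == "strict") {
    out <- ifelse(up, "up", ifelse(down, "down", "unassigned"))
  } else {
    cu <- mean(up_range)
    cd <- wrap_angle(mean(down_range))
    out <- ifelse(circ_dist(a, cu) <= circ_dist(a, cd), "up", "down")
  }
  out
}

#' Per-frame up/down state fractions over a set of rotamer traces
#'
#' @param traces list of per-residue state vectors (character, equal
#'   lengths) or of chi1 angle vectors (classified with `...`).
#' @param mode classifier mode when angles are supplied.
#' @param ... passed to [classify_rotamer()].
#' @return data.frame per frame: `frame`, `pct_up`, `pct_down`,
#'   `pct_unassigned`.  In strict mode the up/down percentages use only
#'   assigned residues as denominator; the unassigned share is reported
#'   separately.
#' @export
state_fractions <- function(traces, mode = c("strict", "nearest"), ...) {
  mode <- match.arg(mode)
  if (!length(traces)) stop("no rotamer traces supplied")
  mats <- lapply(traces, function(tr) {
    if (is.numeric(tr)) classify_rotamer(tr, mode = mode, ...) else tr
  })
  len <- unique(vapply(mats, length, integer(1)))
  if (length(len) != 1) stop("traces do not share a time grid")
  S <- do.call(cbind, mats)
  nup <- rowSums(S == "up")
  ndown <- rowSums(S == "down")
  nun <- rowSums(S == "unassigned")
  denom <- pmax(nup + ndown, 1L)
  data.frame(frame = seq_len(len),
             pct_up = 100 * nup / denom,
             pct_down = 100 * ndown / denom,
             pct_unassigned = 100 * nun / ncol(S))
}

#' Opposite-subunit distances at a marker residue
#'
#' CA-CA (or other atom) distances across the two diagonal subunit pairs
#' of a C4 tetramer -- the classic gate-opening metric at the inner-helix
#' bundle crossing (residue 112).  Reported in Angstrom.
#'
#' @param coords n x 3 frame coordinates (nm) or a `gd_structure`.
#' @param atoms atom table (ignored when `coords` is a structure).
#' @param residue_seq marker residue number (default 112).
#' @param atom_name atom to measure (default "CA").
#' @param chain_pairing list of the two diagonal chain pairs.
#' @return list with `d_ac`, `d_bd` and `mean_ang` (all Angstrom).
#' @export
opposite_distance <- function(coords, atoms = NULL, residue_seq = 112L,
                              atom_name = "CA",
                              chain_pairing = list(c("A", "C"),
                                                   c("B", "D"))) {
  if (inherits(coords, "gd_structure")) {
    atoms <- coords$atoms; coords <- coords$xyz
  }
  get1 <- function(ch) {
    i <- which(atoms$chain_id == ch & atoms$residue_seq == residue_seq &
               atoms$atom_name == atom_name)
    if (length(i) != 1L)
      stop("atom ", atom_name, " of residue ", residue_seq,
           " missing in chain ", ch)
    coords[i, ]
  }
  d <- vapply(chain_pairing, function(p)
    sqrt(sum((get1(p[1]) - get1(p[2]))^2)), numeric(1))
  list(d_ac = d[1] * ANG_PER_NM, d_bd = d[2] * ANG_PER_NM,
       mean_ang = mean(d) * ANG_PER_NM)
}

#' Geometric hydrogen-bond count
#'
#' Counts donor/acceptor pairs satisfying the common geometric rule:
#' donor-acceptor distance <= `d_cut` and hydrogen-donor-acceptor angle
#' <= `angle_cut`.
#'
#' @param coords n x 3 frame coordinates (nm).
#' @param donors two-column integer matrix of (donor heavy atom,
#'   attached hydrogen) index pairs.
#' @param acceptors integer vector of acceptor atom indices.
#' @param d_cut donor-acceptor cutoff (nm, default 0.35).
#' @param angle_cut H-D-A angle cutoff (degrees, default 30).
#' @return integer count of bonded (D, H, A) triplets.
#' @export
hbond_count <- function(coords, donors, acceptors, d_cut = 0.35,
                        angle_cut = 30) {
  coords <- as.matrix(coords)
  donors <- matrix(as.integer(donors), ncol = 2)
  if (!nrow(donors) || !length(acceptors)) {
    warning("empty donor or acceptor set")
    return(0L)
  }
  count <- 0L
  for (i in seq_len(nrow(donors))) {
    D <- coords[donors[i, 1], ]; H <- coords[donors[i, 2], ]
    for (a in acceptors) {
      A <- coords[a, ]
      if (a == donors[i, 1]) next
      da <- sqrt(sum((A - D)^2))
      if (da > d_cut) next
      v1 <- H - D; v2 <- A - D
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                  (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
      if (ang <= angle_cut) count <- count + 1L
    }
  }
  count
}

#' Per-frame RMSD against a fixed reference
#'
#' @param traj a [gd_traj()].
#' @param reference `gd_structure` or n x 3 coordinates.
#' @param indices atom indices entering fit and RMSD.
#' @return numeric vector of RMSD values in Angstrom (figure
#'   convention), one per frame.
#' @export
rmsd_timeseries <- function(traj, reference, indices = NULL) {
  ref <- if (inherits(reference, "gd_structure")) reference$xyz
         else as.matrix(reference)
  vapply(seq_len(n_frames(traj)), function(i)
    rmsd(traj_frame(traj, i), ref, indices, fit = TRUE) * ANG_PER_NM,
    numeric(1))
}

#' Replica-averaged RMSD time series
#'
#' @param series_list list of equal-length RMSD series (Angstrom).
#' @return data.frame `frame`, `mean`, `sd`.
#' @export
rmsd_replica_average <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  M <- do.call(cbind, series_list)
  data.frame(frame = seq_len(nrow(M)), mean = rowMeans(M),
             sd = if (ncol(M) > 1) apply(M, 1, stats::sd) else
                  rep(NA_real_, nrow(M)))
}
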