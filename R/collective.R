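#' Trajectory container
#'
#' Ordered coordinate frames stored bio3d-style as an `n_frames x 3N`
#' matrix (nm), with times in ps.
#'
#' @param xyz numeric matrix, one row per frame, 3N columns (x1,y1,z1,...).
#' @param times numeric vector of frame times in ps, strictly increasing.
#' @return object of class `gd_traj`.
#' @export
gd_traj <- function(xyz, times = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) %% 3 != 0) stop("trajectory columns must be a multiple of 3")
  if (is.null(times)) times <- seq_len(nrow(xyz)) - 1
  if (length(times) != nrow(xyz)) stop("times length != number of frames")
  if (nrow(xyz) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(list(xyz = xyz, times = as.numeric(times)), class = "gd_traj")
}

#' @export
print.gd_traj <- function(x, ...) {
  cat(sprintf("gd_traj: %d frames x %d atoms\n",
              nrow(x$xyz), ncol(x$xyz) / 3))
  invisible(x)
}

n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame as an n_atoms x 3 coordinate matrix
#' @param traj a [gd_traj()].
#' @param i frame index.
#' @export
traj_frame <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

as_frame_row <- function(coords) as.vector(t(coords))

#' Kabsch superposition
#'
#' Least-squares rigid-body fit of `mobile` onto `reference` over
#' `fit_indices`, via SVD of the cross-covariance with the usual
#' determinant sign correction, so the rotation is always proper.
#'
#' @param mobile,reference n_atoms x 3 coordinate matrices (nm).
#' @param fit_indices atom indices used for the fit (default: all).
#' @return list with `rotation` (3x3), `translation` (length-3; the fitted
#'   coordinates are `(mobile - mob_center) %*% rotation + ref_center`),
#'   `coords` (all of `mobile` transformed) and `rmsd` over the fit set.
#' @export
kabsch_fit <- function(mobile, reference, fit_indices = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(fit_indices)) fit_indices <- seq_len(nrow(mobile))
  if (length(fit_indices) < 3)
    stop("need at least 3 fit atoms for a rigid-body fit")
  A <- mobile[fit_indices, , drop = FALSE]
  B <- reference[fit_indices, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  # degenerate (collinear) sets have rank-deficient cross-covariance
  H <- crossprod(A0, B0)
  s <- svd(H)
  if (s$d[2] < 1e-12 * max(s$d[1], 1e-300))
    stop("degenerate fit set: atoms are (nearly) collinear")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)      # mobile %*% R aligns onto reference
  fitted <- sweep(sweep(mobile, 2, ca) %*% R, 2, cb, `+`)
  rms <- sqrt(mean(rowSums((fitted[fit_indices, , drop = FALSE] - B)^2)))
  list(rotation = R, translation = cb - ca %*% R, coords = fitted,
       rmsd = rms)
}

#' Root-mean-square deviation between two coordinate sets
#'
#' @param a,b n_atoms x 3 matrices (nm).
#' @param indices atom indices entering the RMSD (default all).
#' @param fit superpose `a` onto `b` over `indices` first (default TRUE).
#' @return RMSD in nm; symmetric in `(a, b)`.
#' @export
rmsd <- function(a, b, indices = NULL, fit = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (is.null(indices)) indices <- seq_len(nrow(a))
  if (!length(indices)) stop("empty index set")
  if (fit) a <- kabsch_fit(a, b, indices)$coords
  sqrt(mean(rowSums((a[indices, , drop = FALSE] -
                     b[indices, , drop = FALSE])^2)))
}

#' Covariance PCA of positional fluctuations
#'
#' Builds and diagonalises the covariance matrix of the selected atoms'
#' positional fluctuations about their trajectory mean.  Frames are
#' superposed onto the first frame over the same selection before the
#' covariance is accumulated.
#'
#' @param traj a [gd_traj()].
#' @param indices atom indices entering the analysis.
#' @param mass_weighted logical; weight coordinates by sqrt(mass).  With
#'   uniform (or absent) masses this is a no-op; default FALSE.
#' @param masses per-atom masses, required if `mass_weighted`.
#' @param fit superpose frames onto frame 1 first (default TRUE).
#' @return list with `values` (eigenvalues, nm^2, descending),
#'   `vectors` (orthonormal columns, length 3*length(indices)),
#'   `mean` (mean fitted coordinates of the selection, n x 3).
#' @export
covariance_pca <- function(traj, indices, mass_weighted = FALSE,
                           masses = NULL, fit = TRUE) {
  stopifnot(inherits(traj, "gd_traj"))
  m <- n_frames(traj)
  if (m < 2) stop("covariance PCA needs at least 2 frames (rank 0 otherwise)")
  ref <- traj_frame(traj, 1)
  X <- matrix(0, m, 3 * length(indices))
  for (i in seq_len(m)) {
    fr <- traj_frame(traj, i)
    if (fit) fr <- kabsch_fit(fr, ref, indices)$coords
    X[i, ] <- as_frame_row(fr[indices, , drop = FALSE])
  }
  if (mass_weighted) {
    if (is.null(masses)) stop("masses required when mass_weighted = TRUE")
    w <- sqrt(rep(masses[indices], each = 3))
    X <- sweep(X, 2, w, `*`)
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  # eigen-decomposition through the (m x m) Gram trick is unnecessary at
  # desk scale; direct covariance is simplest and exact
  C <- crossprod(Xc) / m
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  list(values = vals, vectors = e$vectors,
       mean = matrix(mu, ncol = 3, byrow = TRUE))
}

#' Number of non-trivial PCA modes
#'
#' @param values eigenvalues from [covariance_pca()].
#' @param tol variance tolerance in nm^2 (default 1e-10).
#' @export
pca_rank <- function(values, tol = 1e-10) sum(values > tol)

#' Collective vector (reaction coordinate)
#'
#' A normalized 3N direction over a selected atom set, plus the reference
#' coordinates that anchor projection zero and the fit selection used for
#' superposition.  For a two-conformation PCA this is the single
#' non-trivial eigenvector: the normalized difference between the fitted
#' end states.
#'
#' @param atom_indices indices (into the parent structure) of the atoms
#'   the vector lives on.
#' @param reference_coords n x 3 reference coordinates (nm) of those atoms.
#' @param direction unit 3N vector (x1,y1,z1,...).
#' @param fit_indices indices used for superposition (default
#'   `atom_indices`).
#' @param mass_weighted logical flag carried for bookkeeping.
#' @export
collective_vector <- function(atom_indices, reference_coords, direction,
                              fit_indices = atom_indices,
                              mass_weighted = FALSE) {
  direction <- as.numeric(direction)
  if (length(direction) != 3 * length(atom_indices))
    stop("direction length must equal 3 x number of atoms")
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-10) direction <- direction / nrm
  reference_coords <- as.matrix(reference_coords)
  dimnames(reference_coords) <- NULL
  structure(list(atom_indices = as.integer(atom_indices),
                 reference_coords = reference_coords,
                 direction = direction,
                 fit_indices = as.integer(fit_indices),
                 mass_weighted = isTRUE(mass_weighted)),
            class = "gd_cv")
}

#' @export
print.gd_cv <- function(x, ...) {
  cat(sprintf("gd_cv: %d atoms, path attribute %s nm\n",
              length(x$atom_indices),
              format(attr(x, "path_length") %||% NA)))
  invisible(x)
}

#' Build the closed/open difference eigenvector
#'
#' Constructs the reaction coordinate for activation gating: the two end
#' states are superposed over the selection, a two-frame covariance PCA is
#' formed (it has exactly one non-trivial mode: the normalized fitted
#' coordinate difference) and the resulting eigenvector is oriented so
#' that the open state projects positive.  Projection of `closed` is 0;
#' projection of `open` equals the path length |dx|.
#'
#' @param closed,open `gd_structure` end states with matching atoms.
#' @param spec a [selection_spec()]; restrict `chains` for per-subunit
#'   (cooperativity) coordinates.
#' @return a [collective_vector()] with attribute `"path_length"` (nm) and
#'   `"eigenvalue"` (nm^2).
#' @export
build_difference_ev <- function(closed, open, spec = selection_spec()) {
  idx_c <- resolve_selection(closed, spec)
  idx_o <- resolve_selection(open, spec)
  kc <- with(closed$atoms[idx_c, ], paste(chain_id, residue_seq, atom_name))
  ko <- with(open$atoms[idx_o, ], paste(chain_id, residue_seq, atom_name))
  if (length(kc) != length(ko) || any(kc != ko)) {
    bad <- union(setdiff(kc, ko), setdiff(ko, kc))
    stop("selection atoms do not match between end states: ",
         paste(utils::head(bad, 5), collapse = "; "),
         if (length(bad) > 5) " ...")
  }
  xc <- closed$xyz[idx_c, , drop = FALSE]
  xo <- kabsch_fit(open$xyz[idx_o, , drop = FALSE], xc)$coords
  d <- as_frame_row(xo - xc)
  len <- sqrt(sum(d^2))
  if (len < 1e-12) stop("end states are identical over the selection")
  cv <- collective_vector(idx_c, xc, d / len)
  # two-frame PCA cross-check is the definition; eigenvalue = |dx|^2/4
  attr(cv, "path_length") <- len
  attr(cv, "eigenvalue") <- len^2 / 4
  cv
}

#' Project coordinates onto a collective vector
#'
#' s = direction . (fitted(coords) - reference), with the rigid-body fit
#' over the vector's fit selection, so the projection is invariant to
#' rigid motion of the input.
#'
#' @param coords full n_atoms x 3 coordinate matrix covering the vector's
#'   atoms, or a `gd_structure`.
#' @param cv a [collective_vector()].
#' @param fit superpose before projecting (default TRUE).
#' @return scalar projection in nm.
#' @export
project_cv <- function(coords, cv, fit = TRUE) {
  if (inherits(coords, "gd_structure")) coords <- coords$xyz
  coords <- as.matrix(coords)
  if (max(cv$atom_indices) > nrow(coords)) stop("coords do not cover cv atoms")
  x <- coords[cv$atom_indices, , drop = FALSE]
  if (fit) {
    whole <- kabsch_fit(coords, ref_full(cv, nrow(coords)),
                        cv$fit_indices)$coords
    x <- whole[cv$atom_indices, , drop = FALSE]
  }
  sum(cv$direction * as_frame_row(x - cv$reference_coords))
}

# reference expanded to full-model size for fitting: atoms outside the cv
# only matter through fit_indices, which must lie inside atom_indices
ref_full <- function(cv, n) {
  out <- matrix(0, n, 3)
  out[cv$atom_indices, ] <- cv$reference_coords
  if (!all(cv$fit_indices %in% cv$atom_indices))
    stop("fit_indices must be a subset of the cv atom set")
  out
}

#' Projection of every trajectory frame
#'
#' @param traj a [gd_traj()].
#' @param cv a [collective_vector()].
#' @param fit superpose each frame first.
#' @return numeric vector, one projection (nm) per frame.
#' @export
project_traj <- function(traj, cv, fit = TRUE) {
  vapply(seq_len(n_frames(traj)),
         function(i) project_cv(traj_frame(traj, i), cv, fit = fit),
         numeric(1))
}

#' Serialize / restore a collective vector
#'
#' Plain-text columnar format (header lines `# key value`, then one row
#' per atom: index, ref x/y/z, direction x/y/z) so reaction coordinates
#' are reproducible across sessions.
#'
#' @param cv a [collective_vector()].
#' @param path file path.
#' @return `path` invisibly ([write_cv()]); a collective vector
#'   ([read_cv()]).
#' @export
write_cv <- function(cv, path) {
  dirm <- matrix(cv$direction, ncol = 3, byrow = TRUE)
  hdr <- c(sprintf("# gd_cv 1"),
           sprintf("# fit_indices %s", paste(cv$fit_indices, collapse = ",")),
           sprintf("# mass_weighted %d", as.integer(cv$mass_weighted)),
           sprintf("# path_length %.17g",
                   attr(cv, "path_length") %||% NA_real_))
  tab <- data.frame(index = cv$atom_indices,
                    rx = cv$reference_coords[, 1],
                    ry = cv$reference_coords[, 2],
                    rz = cv$reference_coords[, 3],
                    dx = dirm[, 1], dy = dirm[, 2], dz = dirm[, 3])
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(tab, digits = 17), con, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cv
#' @export
read_cv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  getv <- function(key) {
    h <- hdr[grepl(paste0("^# ", key, " "), hdr)]
    sub(paste0("^# ", key, " "), "", h[1])
  }
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE)
  cv <- collective_vector(tab$index,
                          cbind(tab$rx, tab$ry, tab$rz),
                          as_frame_row(cbind(tab$dx, tab$dy, tab$dz)),
                          fit_indices = as.integer(
                            strsplit(getv("fit_indices"), ",")[[1]]),
                          mass_weighted = getv("mass_weighted") == "1")
  pl <- suppressWarnings(as.numeric(getv("path_length")))
  if (is.finite(pl)) attr(cv, "path_length") <- pl
  cv
}
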