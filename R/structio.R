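#' Structure container
#'
#' A `gd_structure` holds an ordered atom table and coordinates in nm.
#' It is the unit of structural I/O for every downstream operation.
#'
#' @param atoms data.frame with columns `serial`, `atom_name`,
#'   `residue_name`, `residue_seq`, `chain_id`, `element`.
#' @param xyz numeric matrix, one row per atom, columns x/y/z in nm.
#' @return object of class `gd_structure`.
#' @export
gd_structure <- function(atoms, xyz) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("serial", "atom_name", "residue_name", "residue_seq",
           "chain_id", "element")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (nrow(xyz) != nrow(atoms) || ncol(xyz) != 3)
    stop("xyz must be an n_atoms x 3 matrix")
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates in structure")
  key <- paste(atoms$chain_id, atoms$residue_seq, atoms$atom_name)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (chain, residue, atom) record: ", d)
  }
  rownames(xyz) <- NULL
  structure(list(atoms = atoms, xyz = xyz), class = "gd_structure")
}

#' @export
print.gd_structure <- function(x, ...) {
  ch <- unique(x$atoms$chain_id)
  cat(sprintf("gd_structure: %d atoms, %d chain(s) [%s], %d residues\n",
              nrow(x$atoms), length(ch), paste(ch, collapse = ","),
              nrow(unique(x$atoms[, c("chain_id", "residue_seq")]))))
  invisible(x)
}

#' Number of atoms in a structure
#' @param model a `gd_structure`.
#' @export
n_atoms <- function(model) nrow(model$atoms)

infer_element <- function(atom_name) {
  # PDB columns 77-78 when present; fall back to first alphabetic character
  # of the atom name (covers N/CA/C/O/CB/CG... for proteins)
  el <- sub("^[0-9]*", "", trimws(atom_name))
  substr(el, 1, 1)
}

#' Read a PDB file into a structure model
#'
#' Parses ATOM/HETATM records via [bio3d::read.pdb()]; keeps altloc ' ' or
#' 'A'; converts coordinates from Angstrom to nm.  Insertion-coded residues
#' are dropped with a warning (the activation-gate analyses address
#' contiguous transmembrane numbering only).
#'
#' @param path PDB file path.
#' @return a [gd_structure()].
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("PDB parse failure for ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("no ATOM/HETATM records in ", path)
  keep <- is.na(a$alt) | a$alt %in% c("", " ", "A")
  if (!all(keep)) a <- a[keep, , drop = FALSE]
  ins <- !(is.na(a$insert) | a$insert %in% c("", " "))
  if (any(ins)) {
    warning(sum(ins), " insertion-coded atoms dropped")
    a <- a[!ins, , drop = FALSE]
  }
  el <- a$elesy
  bad <- is.na(el) | trimws(el) == ""
  el[bad] <- infer_element(a$elety[bad])
  atoms <- data.frame(serial = a$eleno,
                      atom_name = trimws(a$elety),
                      residue_name = trimws(a$resid),
                      residue_seq = a$resno,
                      chain_id = ifelse(is.na(a$chain) | a$chain == "",
                                        "A", a$chain),
                      element = trimws(el),
                      stringsAsFactors = FALSE)
  xyz <- cbind(a$x, a$y, a$z) * NM_PER_ANG
  gd_structure(atoms, xyz)
}

#' Write a structure model as a PDB file
#'
#' Fixed-column ATOM records, coordinates converted back to Angstrom at
#' %8.3f precision, one TER per chain.  Round-trips through [read_pdb()]
#' to better than 1e-3 nm.
#'
#' @param model a `gd_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "gd_structure"))
  xyz <- model$xyz * ANG_PER_NM
  if (any(abs(xyz) > 9999.999))
    stop("coordinates exceed PDB fixed-column range (|x| > 9999 Angstrom)")
  a <- model$atoms
  fmt_name <- function(nm) {
    # column 13-16: names of <4 chars start in column 14
    ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
  }
  lines <- sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   a$serial %% 100000, fmt_name(a$atom_name),
                   substr(a$residue_name, 1, 3), substr(a$chain_id, 1, 1),
                   a$residue_seq, xyz[, 1], xyz[, 2], xyz[, 3],
                   1.00, 0.00, a$element)
  # insert TER at chain boundaries
  brk <- which(a$chain_id[-1] != a$chain_id[-nrow(a)])
  out <- character(0)
  start <- 1
  for (b in c(brk, nrow(a))) {
    out <- c(out, lines[start:b], "TER")
    start <- b + 1
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path))
  on.exit(close(con))
  writeLines(c(out, "END"), con)
  invisible(path)
}

#' Trim a channel model to a common residue range
#'
#' End-state driving requires starting and target structures of identical
#' length, so all chains are cut to the same inclusive residue interval
#' (transmembrane region 29-118 for the KcsA pore domain).  Chains that do
#' not cover the full range are kept with a coverage warning, never
#' silently truncated.
#'
#' @param model a `gd_structure`.
#' @param first_res,last_res inclusive residue bounds (defaults 29 and 118).
#' @return trimmed `gd_structure` with attribute `"coverage"`: per-chain
#'   residue counts (the inclusive interval 29-118 holds 90 residues).
#' @export
prepare_channel <- function(model, first_res = 29, last_res = 118) {
  stopifnot(inherits(model, "gd_structure"))
  if (first_res > last_res)
    stop("first_res must be <= last_res")
  keep <- model$atoms$residue_seq >= first_res &
          model$atoms$residue_seq <= last_res
  if (!any(keep)) stop("no residues inside [", first_res, ", ", last_res, "]")
  atoms <- model$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  expected <- last_res - first_res + 1
  cov <- tapply(atoms$residue_seq, atoms$chain_id,
                function(r) length(unique(r)))
  short <- names(cov)[cov < expected]
  if (length(short))
    warning("chain(s) ", paste(short, collapse = ","),
            " cover only ", paste(cov[short], collapse = ","),
            " of ", expected, " residues in [", first_res, ",", last_res, "]")
  out <- gd_structure(atoms, model$xyz[keep, , drop = FALSE])
  attr(out, "coverage") <- cov
  out
}

#' Rename a residue across all chains
#'
#' Relabels `residue_name` only (e.g. restoring the wild-type arginine at
#' position 117 in engineered constructs); no side-chain atoms are built,
#' since crystal-input computations here are backbone-based.
#'
#' @param model a `gd_structure`.
#' @param residue_seq residue number to relabel.
#' @param new_name three-letter residue name.
#' @export
relabel_residue <- function(model, residue_seq, new_name) {
  stopifnot(inherits(model, "gd_structure"))
  hit <- model$atoms$residue_seq == residue_seq
  if (!any(hit)) warning("residue ", residue_seq, " not present")
  model$atoms$residue_name[hit] <- new_name
  model
}

#' Segment ranges of the KcsA pore domain
#'
#' Inclusive residue intervals for the two transmembrane helices, the
#' pore helix and the selectivity filter, with the connecting loops.
#' These are the package's shipped preset; override per structure.
#'
#' @return named list of `c(first, last)` integer pairs.
#' @export
kcsa_segments <- function() {
  list(TM1 = c(29L, 51L), loop1 = c(52L, 61L), Phelix = c(62L, 74L),
       SF = c(75L, 79L), loop2 = c(80L, 85L), TM2 = c(86L, 118L))
}

#' Atom selection specification
#'
#' Defines which atoms enter superposition, PCA and RMSD: named segment
#' intervals, a backbone atom-name set, whether loops are included, and an
#' optional chain restriction.  The canonical gating selection is the
#' backbone of TM1, the pore helix and TM2 with loops excluded.
#'
#' @param segments named list of inclusive residue intervals; names
#'   starting with "loop" are treated as loops.  Default [kcsa_segments()].
#' @param backbone_atoms atom names regarded as backbone
#'   (default `c("N","CA","C","O")`; the convention is configurable).
#' @param include_loops logical; include loop segments (default FALSE).
#' @param chains chain ids to keep, or NULL for all.
#' @return object of class `gd_selection`.
#' @export
selection_spec <- function(segments = kcsa_segments(),
                           backbone_atoms = c("N", "CA", "C", "O"),
                           include_loops = FALSE,
                           chains = NULL) {
  stopifnot(is.list(segments), length(segments) > 0)
  iv <- do.call(rbind, lapply(segments, function(s) sort(as.integer(s))))
  o <- order(iv[, 1])
  if (any(iv[o, 1][-1] <= iv[o, 2][-nrow(iv)]))
    stop("segment intervals overlap")
  structure(list(segments = segments, backbone_atoms = backbone_atoms,
                 include_loops = isTRUE(include_loops), chains = chains),
            class = "gd_selection")
}

is_loop_segment <- function(nms) grepl("^loop", nms, ignore.case = TRUE)

#' Resolve a selection against a structure
#'
#' @param model a `gd_structure`.
#' @param spec a [selection_spec()].
#' @return sorted integer atom indices into `model`; deterministic for a
#'   given (model, spec) and invariant to atom-record order permutations
#'   within residues (indices follow the model's atom order).
#' @export
resolve_selection <- function(model, spec) {
  stopifnot(inherits(model, "gd_structure"), inherits(spec, "gd_selection"))
  segs <- spec$segments
  if (!spec$include_loops) segs <- segs[!is_loop_segment(names(segs))]
  a <- model$atoms
  in_seg <- rep(FALSE, nrow(a))
  for (s in segs)
    in_seg <- in_seg | (a$residue_seq >= s[1] & a$residue_seq <= s[2])
  present <- vapply(segs, function(s)
    any(a$residue_seq >= s[1] & a$residue_seq <= s[2]), logical(1))
  if (any(!present))
    warning("segment(s) with no residues in model: ",
            paste(names(segs)[!present], collapse = ","))
  ok <- in_seg & a$atom_name %in% spec$backbone_atoms
  if (!is.null(spec$chains)) ok <- ok & a$chain_id %in% spec$chains
  idx <- sort(which(ok))
  if (!length(idx)) stop("selection resolves to zero atoms")
  idx
}
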