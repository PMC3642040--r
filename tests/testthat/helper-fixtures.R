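# programmatic fixtures shared across test files

# ring-of-beads cylinder: n_beads of radius bead_r on a circle of radius
# ring_R, rings at the given z positions
make_cylinder <- function(ring_R = 0.8, bead_r = 0.185, n_beads = 12L,
                          zs = seq(-1, 1, 0.25)) {
  ang <- seq(0, 2 * pi, length.out = n_beads + 1L)[-(n_beads + 1L)]
  xyz <- do.call(rbind, lapply(zs, function(z)
    cbind(ring_R * cos(ang), ring_R * sin(ang), z)))
  atoms <- data.frame(serial = seq_len(nrow(xyz)), atom_name = "CA",
                      residue_name = "GLY", residue_seq = seq_len(nrow(xyz)),
                      chain_id = "A", element = "C",
                      stringsAsFactors = FALSE)
  gd_structure(atoms, xyz)
}

# small random rotation matrix from an axis-angle pair
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# toy channel + difference eigenvector, built once per test run
toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      toy <- make_toy_channel()
      cv <- build_difference_ev(toy$closed, toy$open, toy$selection)
      cache <<- list(toy = toy, cv = cv)
    }
    cache
  }
})

synth_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_kcsa_models()
    cache
  }
})
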