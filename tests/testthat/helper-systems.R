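# shared fixtures built in code

# small random bonded chain with charges: exercises every potential term
random_chain_system <- function(n = 12, seed = 1, box = c(25, 25, 25)) {
  set.seed(seed)
  atoms <- data.frame(
    name = paste0("X", seq_len(n)),
    element = sample(c("C", "N", "O", "H", "S"), n, replace = TRUE),
    resname = "TST", resid = 1L,
    x = cumsum(runif(n, 1.0, 1.6)),
    y = runif(n, 0, 3), z = runif(n, 0, 3),
    charge = round(runif(n, -0.5, 0.5), 2),
    stringsAsFactors = FALSE)
  mol <- molecule(atoms, cbind(seq_len(n - 1), seq(2, n)))
  mol_system(list(mol), "other", box = box)
}

# finite-difference force check; returns worst |analytic - numeric|
gradient_deviation <- function(top, h = 1e-5, atoms = NULL) {
  pos <- top$xyz
  f_an <- md_forces(top)
  if (is.null(atoms)) atoms <- seq_len(nrow(pos))
  worst <- 0
  for (i in atoms) {
    for (ax in 1:3) {
      pp <- pos; pp[i, ax] <- pp[i, ax] + h
      pm <- pos; pm[i, ax] <- pm[i, ax] - h
      num <- -(total_energy(top, pp)$potential -
                 total_energy(top, pm)$potential) / (2 * h)
      worst <- max(worst, abs(num - f_an[i, ax]))
    }
  }
  worst
}

# isolated-term topology: a 4-atom bent chain with all other terms off
bare_quad_topology <- function() {
  atoms <- data.frame(name = c("A", "B", "C", "D"), element = "C",
                      resname = "TST", resid = 1L,
                      x = c(0, 1.5, 2.2, 3.4), y = c(0, 0, 1.2, 1.3),
                      z = c(0, 0, 0.3, 1.1), charge = 0,
                      stringsAsFactors = FALSE)
  mol <- molecule(atoms, cbind(1:3, 2:4))
  top <- assign_topology(mol_system(list(mol), "other", c(30, 30, 30)))
  top$eps <- rep(0, 4)
  top$charge <- rep(0, 4)
  top$bond_k <- rep(0, length(top$bond_k))
  top$angle_kf <- rep(0, length(top$angle_kf))
  top$tor_v <- rep(0, length(top$tor_v))
  top
}

mini_build_config <- function(...) build_config(n_y = 2, n_z = 2, ...)
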