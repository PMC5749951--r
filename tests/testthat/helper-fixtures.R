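# Programmatic fixtures shared across test files.

coords_of_model <- function(m) as.matrix(m$atoms[, c("x", "y", "z")])

random_cloud_model <- function(n, seed = 1, spread = 20) {
  set.seed(seed)
  structure_model(data.frame(
    name = "CA", resno = seq_len(n), chain = "A",
    x = runif(n, -spread, spread), y = runif(n, -spread, spread),
    z = runif(n, -spread, spread)))
}

# a model carrying N/C/O atoms at random positions for contact tests;
# four uniquely named backbone atoms per residue
random_hetero_model <- function(n, seed = 1, spread = 15) {
  set.seed(seed)
  nm <- rep(c("N", "CA", "C", "O"), length.out = n)
  structure_model(data.frame(
    name = nm, resno = rep(seq_len(ceiling(n / 4)), each = 4)[seq_len(n)],
    chain = "A",
    x = runif(n, -spread, spread), y = runif(n, -spread, spread),
    z = runif(n, -spread, spread)))
}

# spherical shell of atoms at a fixed radius around the origin, plus a
# central marker atom used as the pocket-center selection
shell_model <- function(radius, n = 64, seed = 3) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * radius
  atoms <- data.frame(
    name = c("ZN", rep("CA", n)),
    resno = c(0L, seq_len(n)),
    chain = "A",
    x = c(0, u[, 1]), y = c(0, u[, 2]), z = c(0, u[, 3]))
  structure_model(atoms)
}

nm2c_full_times <- function(tmax = 300, n = 400) seq(0, tmax, length.out = n)
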