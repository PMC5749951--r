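# Independent oracles kept deliberately separate from the package
# implementations they check.

# Horn's closed-form quaternion method for the minimal RMSD of two point
# clouds: no rotation matrix is constructed, only the largest eigenvalue of
# the 4x4 key matrix.
horn_rmsd <- function(P, Q) {
  n <- nrow(P)
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  S <- crossprod(Pc, Qc)
  N <- matrix(c(
    S[1,1] + S[2,2] + S[3,3], S[2,3] - S[3,2], S[3,1] - S[1,3], S[1,2] - S[2,1],
    S[2,3] - S[3,2], S[1,1] - S[2,2] - S[3,3], S[1,2] + S[2,1], S[3,1] + S[1,3],
    S[3,1] - S[1,3], S[1,2] + S[2,1], -S[1,1] + S[2,2] - S[3,3], S[2,3] + S[3,2],
    S[1,2] - S[2,1], S[3,1] + S[1,3], S[2,3] + S[3,2], -S[1,1] - S[2,2] + S[3,3]
  ), 4, 4, byrow = TRUE)
  lmax <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Pc^2) + sum(Qc^2) - 2 * lmax) / n
  sqrt(max(msd, 0))
}

# brute-force all-pairs contact scan between a query atom set and the rest
brute_contacts <- function(model, query_idx, cutoff) {
  a <- model$atoms
  qres <- unique(paste(a$chain[query_idx], a$resno[query_idx]))
  other <- which(!(paste(a$chain, a$resno) %in% qres))
  hits <- list()
  for (i in query_idx) {
    for (j in other) {
      d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                  (a$z[i] - a$z[j])^2)
      if (d <= cutoff) hits[[length(hits) + 1L]] <- c(i = i, j = j, d = d)
    }
  }
  if (!length(hits)) return(data.frame(i = integer(0), j = integer(0),
                                       d = numeric(0)))
  out <- as.data.frame(do.call(rbind, hits))
  out[order(out$d), ]
}

# per-frame boolean H-bond detection, averaged: the population oracle
brute_hbond_population <- function(traj, donor_idx, acceptor_idx, cutoff) {
  nf <- nrow(traj$xyz)
  hit <- logical(nf)
  for (f in seq_len(nf)) {
    m <- matrix(traj$xyz[f, ], ncol = 3, byrow = TRUE)
    found <- FALSE
    for (i in donor_idx) for (j in acceptor_idx) {
      if (sqrt(sum((m[i, ] - m[j, ])^2)) <= cutoff) found <- TRUE
    }
    hit[f] <- found
  }
  mean(hit)
}

# random rigid transform applied to a whole structure model
apply_rigid <- function(model, seed = 1) {
  set.seed(seed)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  tr <- rnorm(3, sd = 20)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% R
  xyz <- sweep(xyz, 2, tr, "+")
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}
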