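# random proper rotation from QR decomposition
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# brute-force minimal RMSD: Euler-angle grid followed by simplex refinement;
# independent oracle for the Kabsch superposition
brute_force_rmsd <- function(ref, mov) {
  refc <- sweep(ref, 2, colMeans(ref))
  movc <- sweep(mov, 2, colMeans(mov))
  rot <- function(ang) {
    a <- ang[1]; b <- ang[2]; cc <- ang[3]
    rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
                 byrow = TRUE)
    rz2 <- matrix(c(cos(cc), -sin(cc), 0, sin(cc), cos(cc), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    rz1 %*% ry %*% rz2
  }
  f <- function(ang) {
    sqrt(mean(rowSums((movc %*% t(rot(ang)) - refc)^2)))
  }
  best <- c(Inf, 0, 0, 0)
  grid_ab <- seq(0, 2 * pi, length.out = 13)[-13]
  grid_b <- seq(0, pi, length.out = 7)
  for (a in grid_ab) for (b in grid_b) for (cc in grid_ab) {
    v <- f(c(a, b, cc))
    if (v < best[1]) best <- c(v, a, b, cc)
  }
  stats::optim(best[2:4], f, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 10000))$value
}
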