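# Independent oracles used by the tests. These deliberately do not share
# code with the package implementation.

# Exposed area of each of two equal spheres of extended radius R whose
# centres are d apart (d < 2R): full sphere minus the buried spherical cap.
two_sphere_exposed_area <- function(R, d) {
  4 * pi * R^2 - 2 * pi * R * (R - d / 2)
}

# Buried (interface) area of the same two-sphere system: both caps.
two_sphere_buried_area <- function(R, d) {
  2 * 2 * pi * R * (R - d / 2)
}

# Quaternion (Theobald key-matrix) RMSD oracle, independent of the SVD
# route used by the package.
quaternion_rmsd <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  xc <- scale(X, scale = FALSE)
  yc <- scale(Y, scale = FALSE)
  R <- crossprod(xc, yc)
  K <- matrix(c(
    R[1,1]+R[2,2]+R[3,3], R[2,3]-R[3,2],        R[3,1]-R[1,3],        R[1,2]-R[2,1],
    R[2,3]-R[3,2],        R[1,1]-R[2,2]-R[3,3], R[1,2]+R[2,1],        R[1,3]+R[3,1],
    R[3,1]-R[1,3],        R[1,2]+R[2,1],       -R[1,1]+R[2,2]-R[3,3], R[2,3]+R[3,2],
    R[1,2]-R[2,1],        R[1,3]+R[3,1],        R[2,3]+R[3,2],       -R[1,1]-R[2,2]+R[3,3]
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE)$values)
  G <- sum(xc^2) + sum(yc^2)
  sqrt(max(0, G - 2 * lambda) / nrow(X))
}

# random proper rotation matrix
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1-2*(y^2+z^2), 2*(x*y - w*z), 2*(x*z + w*y),
    2*(x*y + w*z), 1-2*(x^2+z^2), 2*(y*z - w*x),
    2*(x*z - w*y), 2*(y*z + w*x), 1-2*(x^2+y^2)
  ), 3, 3, byrow = TRUE)
}

# apply a rigid motion to a structure tibble
rigid_move <- function(structure, rotation, translation) {
  xyz <- cbind(structure$x, structure$y, structure$z) %*% t(rotation)
  structure$x <- xyz[, 1] + translation[1]
  structure$y <- xyz[, 2] + translation[2]
  structure$z <- xyz[, 3] + translation[3]
  structure
}

# naive all-pairs inter-chain cysteine SG distance enumeration
naive_cys_pairs <- function(structure, chain_a = "A", chain_b = "B") {
  sg <- structure[structure$residue_name == "CYS" & structure$name == "SG", ]
  a <- sg[sg$chain == chain_a, ]
  b <- sg[sg$chain == chain_b, ]
  out <- data.frame()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt((a$x[i]-b$x[j])^2 + (a$y[i]-b$y[j])^2 + (a$z[i]-b$z[j])^2)
    out <- rbind(out, data.frame(seq_a = a$residue_seq[i],
                                 seq_b = b$residue_seq[j], distance = d))
  }
  out[order(out$distance), ]
}

# a tiny two-atom "dimer": one extended-radius sphere per chain
two_atom_dimer <- function(d, element = "C") {
  as_structure(data.frame(
    name = "X", element = element, residue_name = "TOY",
    chain = c("A", "B"), residue_seq = 1L,
    x = c(0, d), y = 0, z = 0))
}
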