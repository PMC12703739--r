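# Independent oracles used across the suite. Each deliberately takes a
# different computational route than the package implementation.

# Horn's quaternion-eigenvalue method for optimal superposition RMSD:
# the maximum eigenvalue of the 4x4 key matrix gives the residual in
# closed form, with no SVD and no explicit rotation.
quaternion_rmsd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  s <- t(b) %*% a
  k <- matrix(c(
    s[1,1]+s[2,2]+s[3,3], s[2,3]-s[3,2],        s[3,1]-s[1,3],        s[1,2]-s[2,1],
    s[2,3]-s[3,2],        s[1,1]-s[2,2]-s[3,3], s[1,2]+s[2,1],        s[1,3]+s[3,1],
    s[3,1]-s[1,3],        s[1,2]+s[2,1],       -s[1,1]+s[2,2]-s[3,3], s[2,3]+s[3,2],
    s[1,2]-s[2,1],        s[1,3]+s[3,1],        s[2,3]+s[3,2],       -s[1,1]-s[2,2]+s[3,3]
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  n <- nrow(a)
  sqrt(max(0, (sum(a^2) + sum(b^2) - 2 * lambda) / n))
}

# Plain O(N^2) all-pairs contact oracle: nested loops over residues and
# atoms, no vectorised distance matrix. Returns the residue indices of
# chain_a in contact with chain_b and the contacting residue pairs.
brute_force_contacts <- function(s, chain_a, chain_b, cutoff = 5, atom_mode = "heavy") {
  at <- as.data.frame(s)
  if (atom_mode == "heavy") at <- at[at$element != "H", ]
  if (atom_mode == "ca") at <- at[at$atom == "CA", ]
  a <- at[at$chain == chain_a, ]
  b <- at[at$chain == chain_b, ]
  res_a <- sort(unique(a$resno))
  res_b <- sort(unique(b$resno))
  hits_a <- integer(0); hits_b <- integer(0); pairs <- 0L
  for (ra in res_a) {
    aa <- a[a$resno == ra, c("x", "y", "z")]
    for (rb in res_b) {
      bb <- b[b$resno == rb, c("x", "y", "z")]
      dmin <- Inf
      for (i in seq_len(nrow(aa))) {
        for (j in seq_len(nrow(bb))) {
          d <- sqrt(sum((aa[i, ] - bb[j, ])^2))
          if (d < dmin) dmin <- d
        }
      }
      if (dmin <= cutoff) {
        hits_a <- union(hits_a, ra)
        hits_b <- union(hits_b, rb)
        pairs <- pairs + 1L
      }
    }
  }
  list(residues_a = sort(hits_a), residues_b = sort(hits_b), n_pairs = pairs)
}

# Monoisotopic peptide mass from elemental composition: counts atoms per
# residue and sums exact isotope masses — independent of any residue
# mass table.
elemental_mono_mass <- function(seq) {
  comp <- list(  #        C  H  N  O  S
    G = c(2, 3, 1, 1, 0), A = c(3, 5, 1, 1, 0), S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0), V = c(5, 9, 1, 1, 0), T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1), L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0), D = c(4, 5, 1, 3, 0), Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0), M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0), F = c(9, 9, 1, 1, 0), R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0), W = c(11, 10, 2, 1, 0)
  )
  iso <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
           O = 15.9949146221, S = 31.97207069)
  total <- Reduce(`+`, lapply(strsplit(seq, "")[[1]], function(ch) comp[[ch]]))
  sum(total * iso[c("C", "H", "N", "O", "S")]) + 2 * iso[["H"]] + iso[["O"]]
}

# Exhaustive max-min diversity oracle: enumerate every k-subset, score by
# the minimum pairwise distance within the subset, return the best
# subsets (there may be ties).
exhaustive_maxmin <- function(dmat, k) {
  n <- nrow(dmat)
  subsets <- utils::combn(n, k, simplify = FALSE)
  score <- vapply(subsets, function(idx) min(dmat[idx, idx][upper.tri(diag(k))]),
                  numeric(1))
  subsets[score >= max(score) - 1e-12]
}

random_aa_seq <- function(n) {
  paste0(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                  "R","S","T","V","W","Y"), n, replace = TRUE), collapse = "")
}

# Random rigid transform applied to an N x 3 matrix.
random_rigid <- function(m) {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  r <- matrix(c(
    1-2*(q[3]^2+q[4]^2), 2*(q[2]*q[3]-q[1]*q[4]), 2*(q[2]*q[4]+q[1]*q[3]),
    2*(q[2]*q[3]+q[1]*q[4]), 1-2*(q[2]^2+q[4]^2), 2*(q[3]*q[4]-q[1]*q[2]),
    2*(q[2]*q[4]-q[1]*q[3]), 2*(q[3]*q[4]+q[1]*q[2]), 1-2*(q[2]^2+q[3]^2)
  ), 3, 3, byrow = TRUE)
  sweep(m %*% t(r), 2, rnorm(3, sd = 20), "+")
}
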