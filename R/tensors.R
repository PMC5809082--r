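# Symmetric tensor packing conventions used throughout.
#
# Rank 2 (diffusion tensor D, um^2/ms): 6-vector in the order
#   (xx, yy, zz, xy, xz, yz), multiplicities (1, 1, 1, 2, 2, 2).
# Rank 4 (kurtosis tensor W, dimensionless): 15 unique components, ordered by
# the sorted index quadruples produced by `w_index_table()`; multiplicity of a
# quadruple is the number of distinct permutations (1, 4, 6 or 12).

d6_names <- c("xx", "yy", "zz", "xy", "xz", "yz")

d6_to_mat <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)
}

mat_to_d6 <- function(m) c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])

# Design rows for D_app(n) = n' D n given packed d6: row %*% d6.
d_design <- function(dirs) {
  dirs <- matrix(dirs, ncol = 3)
  cbind(dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
        2 * dirs[, 1] * dirs[, 2], 2 * dirs[, 1] * dirs[, 3],
        2 * dirs[, 2] * dirs[, 3])
}

# Unique index quadruples (i <= j <= k <= l) of a fully symmetric rank-4
# tensor with their permutation multiplicities.
w_index_table <- function() {
  idx <- NULL
  for (i in 1:3) for (j in i:3) for (k in j:3) for (l in k:3) {
    idx <- rbind(idx, c(i, j, k, l))
  }
  mult <- apply(idx, 1, function(q) {
    counts <- tabulate(q, 3)
    factorial(4) / prod(factorial(counts))
  })
  list(idx = idx, mult = mult,
       names = apply(idx, 1, paste0, collapse = ""))
}

.w_tab <- w_index_table()

# Design rows for What(n) = sum_ijkl n_i n_j n_k n_l W_ijkl: row %*% w15.
w_design <- function(dirs) {
  dirs <- matrix(dirs, ncol = 3)
  out <- matrix(0, nrow(dirs), 15)
  for (p in 1:15) {
    q <- .w_tab$idx[p, ]
    out[, p] <- .w_tab$mult[p] *
      dirs[, q[1]] * dirs[, q[2]] * dirs[, q[3]] * dirs[, q[4]]
  }
  out
}

w15_to_array <- function(w15) {
  W <- array(0, c(3, 3, 3, 3))
  for (p in 1:15) {
    q <- .w_tab$idx[p, ]
    for (perm in asplit(perms4(), 1)) {
      W[q[perm[1]], q[perm[2]], q[perm[3]], q[perm[4]]] <- w15[p]
    }
  }
  W
}

array_to_w15 <- function(W) {
  vapply(1:15, function(p) {
    q <- .w_tab$idx[p, ]
    W[q[1], q[2], q[3], q[4]]
  }, numeric(1))
}

perms4 <- local({
  p <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  p <- p[apply(p, 1, function(r) length(unique(r)) == 4L), , drop = FALSE]
  function() p
})

# Rotate packed tensors: D' = R D R', W'_ijkl = R_ia R_jb R_kc R_ld W_abcd.
rotate_d6 <- function(d6, R) mat_to_d6(R %*% d6_to_mat(d6) %*% t(R))

mode_mult4 <- function(W, R, mode) {
  perm <- c(mode, setdiff(1:4, mode))
  Wp <- aperm(W, perm)
  dim(Wp) <- c(3L, 27L)
  out <- R %*% Wp
  dim(out) <- c(3L, 3L, 3L, 3L)
  aperm(out, order(perm))
}

rotate_w15 <- function(w15, R) {
  W <- w15_to_array(w15)
  for (mode in 1:4) W <- mode_mult4(W, R, mode)
  array_to_w15(W)
}

# Deterministic eigendecomposition of a symmetric 3x3 tensor: eigenvalues
# sorted descending; near-degenerate leading pair (lambda1 - lambda2 < tol)
# broken by largest |z| component; sign fixed so the max-magnitude entry of
# each eigenvector is positive.
tensor_eigen <- function(d6, tol = 1e-9) {
  e <- eigen(d6_to_mat(d6), symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  if (vals[1] - vals[2] < tol) {
    deg <- which(vals[1] - vals < tol)
    zi <- deg[which.max(abs(vecs[3, deg]))]
    if (zi != 1L) {
      perm <- c(zi, setdiff(seq_len(3), zi))
      vals <- vals[perm]
      vecs <- vecs[, perm, drop = FALSE]
    }
  }
  for (j in 1:3) {
    mx <- which.max(abs(vecs[, j]))
    if (vecs[mx, j] < 0) vecs[, j] <- -vecs[, j]
  }
  # re-establish a right-handed frame after sign fixing
  if (det(vecs) < 0) vecs[, 3] <- -vecs[, 3]
  list(values = vals, vectors = vecs)
}

# Isotropic rank-4 tensor with constant directional contraction What(n) = k.
w15_isotropic <- function(k) {
  delta <- diag(3)
  W <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k2 in 1:3) for (l in 1:3) {
    W[i, j, k2, l] <- (k / 3) * (delta[i, j] * delta[k2, l] +
                                   delta[i, k2] * delta[j, l] +
                                   delta[i, l] * delta[j, k2])
  }
  array_to_w15(W)
}
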