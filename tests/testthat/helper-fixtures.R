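# Shared fixtures, built once per test run. Everything is generated in code;
# nothing is read from disk.

# small head models at two mesh resolutions
fix_mesh1 <- make_cortical_mesh(1, 80)    # D = 42
fix_mesh2 <- make_cortical_mesh(2, 80)    # D = 162
fix_head <- make_head_model()             # D = 642, C = 32, sigma = 0.6

# 3-vertex single-triangle "mesh" (complete graph K3)
fix_triangle <- list(
  vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
  faces = matrix(c(1L, 2L, 3L), nrow = 1)
)

# undirected path graph on n vertices, unit edge weights
path_graph <- function(n) {
  igraph::graph_from_edgelist(cbind(1:(n - 1), 2:n), directed = FALSE)
}

# vertex adjacency sets of a mesh, enumerated independently of the package's
# internal helpers
enumerate_adjacency <- function(mesh) {
  f <- mesh$faces
  D <- max(f)
  adj <- vector("list", D)
  for (i in seq_len(nrow(f))) {
    tri <- f[i, ]
    for (a in tri) adj[[a]] <- union(adj[[a]], setdiff(tri, a))
  }
  adj
}

# brute-force minimizer of the penalized source functional via the
# source-space normal equations (the D x D form)
normal_equations_solution <- function(X, M, Q_J, Q_eps, lam) {
  A <- t(M) %*% solve(Q_eps) %*% M + lam * solve(Q_J)
  solve(A, t(M) %*% solve(Q_eps) %*% X)
}

# random symmetric positive-definite matrix with moderate conditioning
random_spd <- function(n) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + diag(n)
}
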