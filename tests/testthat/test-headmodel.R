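test_that("icosphere meshes have the expected vertex/face counts and radius", {
  expect_equal(nrow(fix_mesh1$vertices), 42)
  expect_equal(nrow(make_cortical_mesh(3, 80)$vertices), 642)
  expect_equal(nrow(make_cortical_mesh(3, 80)$faces), 1280)
  r <- sqrt(rowSums(fix_mesh1$vertices^2))
  expect_true(all(abs(r - 80) < 1e-6))
  nrm <- sqrt(rowSums(fix_mesh1$normals^2))
  expect_true(all(abs(nrm - 1) < 1e-9))
  expect_error(make_cortical_mesh(0, 80), "n_subdivisions")
  expect_error(make_cortical_mesh(6, 80), "n_subdivisions")
})

test_that("mesh adjacency is connected with degree >= 5 everywhere", {
  for (mesh in list(fix_mesh1, fix_mesh2)) {
    adj <- enumerate_adjacency(mesh)
    deg <- lengths(adj)
    expect_true(all(deg >= 5))
    # single connected component by breadth-first search
    seen <- logical(length(adj)); seen[1] <- TRUE; frontier <- 1L
    while (length(frontier) > 0) {
      nxt <- unique(unlist(adj[frontier]))
      frontier <- nxt[!seen[nxt]]
      seen[frontier] <- TRUE
    }
    expect_true(all(seen))
  }
})

test_that("lead-field columns are common-average referenced and peak at the
           sensor over the dipole", {
  sens <- make_sensor_array(32, 96)
  M <- make_lead_field(fix_mesh2, sens)
  expect_true(all(abs(colSums(M)) < 1e-9))
  expect_true(all(is.finite(M)))
  expect_true(all(colSums(abs(M)) > 0))

  # put one sensor exactly above a chosen vertex (same radial direction)
  v <- 7
  dir <- fix_mesh2$vertices[v, ] / sqrt(sum(fix_mesh2$vertices[v, ]^2))
  pos <- rbind(dir * 96, sens$positions[1:11, ])
  custom <- structure(list(positions = pos,
                           labels = sprintf("E%02d", 1:12),
                           radius_mm = 96),
                      class = "sensor_array")
  M2 <- make_lead_field(fix_mesh2, custom)
  expect_equal(which.max(abs(M2[, v])), 1)
})

test_that("lead-field magnitudes decay when sensors are moved outward", {
  near <- make_sensor_array(16, 96)
  far <- structure(list(positions = near$positions * 2,
                        labels = near$labels, radius_mm = 192),
                   class = "sensor_array")
  M_near <- make_lead_field(fix_mesh1, near)
  M_far <- make_lead_field(fix_mesh1, far)
  expect_true(all(apply(abs(M_far), 2, max) < apply(abs(M_near), 2, max)))
})

test_that("graph Laplacian matches the K3 oracle and has zero row sums", {
  G3 <- graph_laplacian(fix_triangle)
  expect_equal(unclass(G3),
               matrix(c(-2, 1, 1, 1, -2, 1, 1, 1, -2), 3), ignore_attr = TRUE)
  G <- graph_laplacian(fix_mesh1)
  expect_true(all(abs(rowSums(G)) < 1e-9))
  expect_true(all(diag(G) %in% c(-5, -6)))
  expect_identical(unclass(G), t(unclass(G)))
})

test_that("Green's function equals the eigendecomposition and series oracles", {
  G3 <- graph_laplacian(fix_triangle)
  Q <- greens_function(G3, 0.6)
  # independent oracle: scaling-and-squaring matrix exponential
  skip_if_not_installed("Matrix")
  Q_oracle <- as.matrix(Matrix::expm(0.6 * Matrix::Matrix(unclass(G3))))
  expect_lt(max(abs(unclass(Q) - Q_oracle)), 1e-8)

  G <- graph_laplacian(fix_mesh2)
  Q2 <- greens_function(G, 0.6)
  Q2_oracle <- as.matrix(Matrix::expm(0.6 * Matrix::Matrix(unclass(G))))
  expect_lt(max(abs(unclass(Q2) - Q2_oracle)), 1e-8)
})

test_that("Green's function is a symmetric stochastic smoothing kernel", {
  G <- graph_laplacian(fix_mesh2)
  for (sigma in c(0.2, 0.6, 1.0)) {
    Q <- greens_function(G, sigma)
    expect_true(all(abs(rowSums(Q) - 1) < 1e-6))
    expect_lt(max(abs(unclass(Q) - t(unclass(Q)))), 1e-12)
    expect_true(min(Q) > -1e-9)
    ev <- eigen(unclass(Q), symmetric = TRUE, only.values = TRUE)$values
    expect_true(min(ev) > 0)
  }
  # sigma -> 0 limit is the identity
  Q0 <- greens_function(G, 1e-8)
  expect_lt(max(abs(unclass(Q0) - diag(nrow(Q0)))), 1e-6)
  expect_error(greens_function(matrix(c(0, 1, 0, 0), 2), 0.5), "symmetric")
})

test_that("Green's columns decay with graph distance from their center", {
  Q <- greens_function(graph_laplacian(fix_mesh2), 0.6)
  adj <- enumerate_adjacency(fix_mesh2)
  center <- 1L
  d <- rep(Inf, length(adj)); d[center] <- 0; frontier <- center; lev <- 0
  while (any(is.infinite(d))) {
    lev <- lev + 1
    nxt <- unique(unlist(adj[frontier]))
    frontier <- nxt[is.infinite(d[nxt])]
    d[frontier] <- lev
  }
  col <- Q[, center]
  expect_gt(min(col[d == 1]), max(col[d == 3]))
})

test_that("simulated patch sources are centered, seeded and zero at zero
           amplitude", {
  Q <- greens_function(graph_laplacian(fix_mesh2), 0.6)
  z <- simulate_sources(fix_mesh2, Q, 1, fs = 128, duration_s = 1,
                        amplitude = 0, seed = 4)
  expect_true(all(z$J_true == 0))

  s1 <- simulate_sources(fix_mesh2, Q, 1, fs = 128, duration_s = 1, seed = 4)
  expect_equal(which.max(rowMeans(s1$J_true^2)), s1$active_centers[1])
  s2 <- simulate_sources(fix_mesh2, Q, 1, fs = 128, duration_s = 1, seed = 4)
  expect_identical(s1$J_true, s2$J_true)

  # two patches must respect the separation constraint
  s3 <- simulate_sources(fix_mesh2, Q, 2, fs = 128, duration_s = 1, seed = 9)
  adj <- enumerate_adjacency(fix_mesh2)
  d <- rep(Inf, length(adj)); d[s3$active_centers[1]] <- 0
  frontier <- s3$active_centers[1]; lev <- 0
  while (length(frontier) > 0) {
    lev <- lev + 1
    nxt <- unique(unlist(adj[frontier]))
    frontier <- nxt[is.infinite(d[nxt])]
    d[frontier] <- lev
  }
  expect_gte(d[s3$active_centers[2]], 4)
  expect_error(
    simulate_sources(fix_mesh1, greens_function(graph_laplacian(fix_mesh1),
                                                0.6),
                     50, fs = 128, duration_s = 1, seed = 1),
    "graph distance"
  )
})

test_that("sensor projection is linear and the noise matches the requested
           SNR", {
  sens <- make_sensor_array(32, 96)
  M <- make_lead_field(fix_mesh1, sens)
  Q <- greens_function(graph_laplacian(fix_mesh1), 0.6)
  src <- simulate_sources(fix_mesh1, Q, 1, fs = 128, duration_s = 2, seed = 2)

  noiseless <- simulate_eeg(M, src$J_true, Inf, seed = 1)
  expect_identical(noiseless$X, unclass(M) %*% src$J_true)
  scaled <- simulate_eeg(M, 3 * src$J_true, Inf, seed = 1)
  expect_equal(scaled$X, 3 * noiseless$X, tolerance = 1e-12)

  # zero sources, unit noise
  null <- simulate_eeg(M, matrix(0, 42, 4000), 0, seed = 7)
  expect_equal(stats::var(as.numeric(null$X)), 1, tolerance = 0.05)

  # empirical SNR from the stored addends
  src2 <- simulate_sources(fix_mesh1, Q, 1, fs = 128, duration_s = 32,
                           seed = 3)
  rec <- simulate_eeg(M, src2$J_true, 0, seed = 11)
  snr_emp <- 10 * log10(mean(rec$signal^2) / mean(rec$noise^2))
  expect_lt(abs(snr_emp - 0), 0.5)
  expect_identical(rec$X, simulate_eeg(M, src2$J_true, 0, seed = 11)$X)

  expect_error(simulate_eeg(M, matrix(NaN, 42, 2), 10, 1), "non-finite")
})
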