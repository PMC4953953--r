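#' Synthetic spherical cortical mesh
#'
#' Builds a recursively subdivided icosahedral sphere used as a stand-in
#' cortical surface. Each vertex hosts one current dipole oriented along the
#' outward surface normal (radially, for a sphere). With `n_subdivisions = n`
#' the mesh has `10 * 4^n + 2` vertices and `20 * 4^n` triangular faces.
#'
#' @param n_subdivisions Number of recursive subdivision passes, an integer in
#'   1..5. The default 3 gives D = 642 dipoles, a desk-scale source space.
#' @param radius_mm Sphere radius in millimetres.
#' @return An object of class `cortical_mesh` with components `vertices`
#'   (D x 3, mm), `faces` (F x 3 integer, 1-based), `normals` (D x 3 unit
#'   vectors) and `radius_mm`.
#' @examples
#' mesh <- make_cortical_mesh(1, 80)
#' nrow(mesh$vertices) # 42
#' @export
make_cortical_mesh <- function(n_subdivisions = 3, radius_mm = 80) {
  if (!is.numeric(n_subdivisions) || length(n_subdivisions) != 1 ||
      n_subdivisions != round(n_subdivisions) ||
      n_subdivisions < 1 || n_subdivisions > 5) {
    stop("n_subdivisions must be an integer in 1..5")
  }
  if (!is.numeric(radius_mm) || length(radius_mm) != 1 || radius_mm <= 0) {
    stop("radius_mm must be a positive scalar")
  }

  ## regular icosahedron
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  v <- v / sqrt(rowSums(v^2))

  for (s in seq_len(n_subdivisions)) {
    midpoint_key <- new.env(hash = TRUE, parent = emptyenv())
    verts <- lapply(seq_len(nrow(v)), function(i) v[i, ])
    get_mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- midpoint_key[[key]]
      if (is.null(idx)) {
        m <- (verts[[a]] + verts[[b]]) / 2
        m <- m / sqrt(sum(m^2))
        verts[[length(verts) + 1]] <<- m
        idx <- length(verts)
        midpoint_key[[key]] <- idx
      }
      idx
    }
    newf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, c); ca <- get_mid(c, a)
      newf[(i - 1) * 4 + 1, ] <- c(a, ab, ca)
      newf[(i - 1) * 4 + 2, ] <- c(b, bc, ab)
      newf[(i - 1) * 4 + 3, ] <- c(c, ca, bc)
      newf[(i - 1) * 4 + 4, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, verts)
    f <- newf
  }

  normals <- v  # unit sphere vertices are their own outward normals
  structure(
    list(vertices = v * radius_mm, faces = f, normals = normals,
         radius_mm = radius_mm),
    class = "cortical_mesh"
  )
}

#' Sensor montage on an outer sphere
#'
#' Places `n_channels` electrode positions on a sphere concentric with the
#' cortical mesh, using a Fibonacci lattice so that sensors are approximately
#' uniformly spread. The default `"full"` montage covers the whole sphere:
#' because the synthetic source space is a full sphere (unlike a real cortex
#' sitting beneath a scalp cap), full coverage is required for every source
#' to be observable. `"cap"` restricts sensors to the upper hemisphere,
#' mimicking the geometry of a conventional EEG cap; with it, lower-hemisphere
#' sources are essentially invisible.
#'
#' @param n_channels Number of electrodes (>= 2); default 32.
#' @param radius_mm Montage radius; must exceed the mesh radius so that all
#'   sensors lie strictly outside the source sphere. Default 96 (1.2 x 80 mm).
#' @param montage `"full"` (whole sphere, default) or `"cap"` (upper
#'   hemisphere).
#' @return Object of class `sensor_array`: `positions` (C x 3, mm), `labels`.
#' @export
make_sensor_array <- function(n_channels = 32, radius_mm = 96,
                              montage = c("full", "cap")) {
  montage <- match.arg(montage)
  if (n_channels < 2) stop("need at least 2 channels")
  i <- seq_len(n_channels)
  golden <- pi * (3 - sqrt(5))
  z <- if (montage == "full") {
    seq(-1 + 1 / n_channels, 1 - 1 / n_channels, length.out = n_channels)
  } else {
    seq(0.15, 0.95, length.out = n_channels)
  }
  r <- sqrt(1 - z^2)
  theta <- golden * (i - 1)
  pos <- cbind(r * cos(theta), r * sin(theta), z) * radius_mm
  structure(
    list(positions = pos,
         labels = sprintf("E%02d", i),
         radius_mm = radius_mm,
         montage = montage),
    class = "sensor_array"
  )
}

#' Lead field for radial dipoles in a homogeneous sphere
#'
#' Computes the quasi-static electric potential of a unit current dipole at
#' each mesh vertex, oriented along the vertex normal, at every sensor, using
#' the infinite homogeneous medium formula
#' \eqn{V = (p . (r - r_0)) / (4 pi |r - r_0|^3)} (unit conductivity).
#' The sensor dimension is then common-average referenced: each column of the
#' gain matrix has its mean across sensors removed, so columns sum to zero.
#'
#' @param mesh A `cortical_mesh`.
#' @param sensors A `sensor_array`; all sensors must lie strictly outside the
#'   mesh bounding sphere and not coincide with any vertex.
#' @return C x D gain matrix `M` (class `lead_field` with attribute
#'   `referenced = TRUE`).
#' @export
make_lead_field <- function(mesh, sensors) {
  stopifnot(inherits(mesh, "cortical_mesh"), inherits(sensors, "sensor_array"))
  V <- mesh$vertices
  P <- sensors$positions
  vert_r <- sqrt(max(rowSums(V^2)))
  sens_r <- sqrt(rowSums(P^2))
  if (any(sens_r <= vert_r + 1e-9)) {
    stop("all sensors must lie strictly outside the mesh bounding sphere")
  }
  C <- nrow(P); D <- nrow(V)
  M <- matrix(0, C, D)
  for (c in seq_len(C)) {
    dr <- sweep(V, 2, P[c, ], function(v, p) p - v)  # r_sensor - r_dipole
    dist3 <- (sqrt(rowSums(dr^2)))^3
    if (any(dist3 < 1e-12)) stop("sensor coincides with a mesh vertex")
    M[c, ] <- rowSums(dr * mesh$normals) / (4 * pi * dist3)
  }
  M <- sweep(M, 2, colMeans(M))  # common-average reference across sensors
  structure(M, class = c("lead_field", "matrix"), referenced = TRUE)
}

#' Mesh graph Laplacian
#'
#' Vertex-adjacency Laplacian `G = A - diag(degree)` with `A[i,j] = 1` when
#' vertices i and j share a triangle edge. Rows sum to zero; the matrix acts
#' as the generator of a diffusion over the cortical surface.
#'
#' @param mesh A `cortical_mesh`, or any list with a `faces` matrix.
#' @return D x D symmetric matrix of class `graph_laplacian`.
#' @export
graph_laplacian <- function(mesh) {
  f <- mesh$faces
  D <- max(f)
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  A <- matrix(0, D, D)
  A[edges] <- 1
  A <- pmax(A, t(A))   # undirected
  G <- A - diag(rowSums(A))
  structure(G, class = c("graph_laplacian", "matrix"))
}

#' Green's function of the cortical surface
#'
#' Matrix exponential `Q_G = expm(sigma * G)` of the scaled graph Laplacian.
#' Because `G` is a generator (zero row sums, non-negative off-diagonal),
#' `Q_G` is a symmetric stochastic smoothing kernel: rows sum to one and
#' entries are non-negative. Its columns are locally smooth cortical patches;
#' `sigma` rules their spatial extent (the default 0.6 spreads appreciable
#' weight over vertices three to four edges away).
#'
#' Computed by symmetric eigendecomposition `V exp(sigma L) V'`, which keeps
#' the result exactly symmetric.
#'
#' @param G A `graph_laplacian` (symmetric, zero row sums).
#' @param sigma Positive smoothness constant (dimensionless).
#' @return D x D matrix of class `greens_function` with attribute `sigma`.
#' @export
greens_function <- function(G, sigma = 0.6) {
  if (sigma <= 0) stop("sigma must be positive")
  G <- unclass(G)
  if (max(abs(G - t(G))) > 1e-9) stop("graph Laplacian must be symmetric")
  eg <- eigen(G, symmetric = TRUE)
  Q <- eg$vectors %*% (exp(sigma * eg$values) * t(eg$vectors))
  Q <- (Q + t(Q)) / 2
  structure(Q, class = c("greens_function", "matrix"), sigma = sigma)
}

## unweighted graph distances from a set of source vertices (BFS)
graph_distance_from <- function(adj_list, from, n) {
  d <- rep(Inf, n)
  d[from] <- 0
  frontier <- from
  level <- 0
  while (length(frontier) > 0) {
    level <- level + 1
    nxt <- unique(unlist(adj_list[frontier]))
    nxt <- nxt[d[nxt] == Inf]
    d[nxt] <- level
    frontier <- nxt
  }
  d
}

adjacency_list <- function(mesh) {
  f <- mesh$faces
  D <- max(f)
  edges <- unique(rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)],
                        f[, c(2, 1)], f[, c(3, 2)], f[, c(1, 3)]))
  split(edges[, 2], factor(edges[, 1], levels = seq_len(D)))
}

#' Simulate patch sources on the cortical mesh
#'
#' Seeds `n_patches` active cortical patches: center vertices are drawn
#' uniformly without replacement subject to a pairwise graph distance of at
#' least 4 edges; each patch's spatial profile is the corresponding column of
#' the Green's function scaled to unit maximum, and its time course is a
#' sinusoid at a frequency drawn uniformly from `band_hz` with random phase,
#' scaled by `amplitude`. The source matrix is the sum of profile-by-time
#' outer products.
#'
#' @param mesh A `cortical_mesh`.
#' @param Q_G Matching `greens_function`.
#' @param n_patches Number of active patches (>= 1).
#' @param fs Sampling rate in Hz.
#' @param duration_s Duration in seconds; `fs * duration_s >= 2`.
#' @param band_hz Length-2 numeric, frequency band for the patch oscillations.
#' @param amplitude Peak current amplitude (source units).
#' @param seed Integer RNG seed; the same seed reproduces the output exactly.
#' @return List with `J_true` (D x T), `active_centers` (vertex indices),
#'   `fs`, `seed`.
#' @export
simulate_sources <- function(mesh, Q_G, n_patches = 1, fs = 128,
                             duration_s = 4, band_hz = c(8, 13),
                             amplitude = 1, seed = 1) {
  T_len <- round(fs * duration_s)
  if (n_patches < 1) stop("n_patches must be >= 1")
  if (T_len < 2) stop("duration too short: need at least 2 samples")
  D <- nrow(mesh$vertices)
  adj <- adjacency_list(mesh)

  set.seed(seed)
  order_v <- sample.int(D)
  centers <- integer(0)
  for (cand in order_v) {
    if (length(centers) == n_patches) break
    if (length(centers) == 0 ||
        min(graph_distance_from(adj, centers, D)[cand]) >= 4) {
      centers <- c(centers, cand)
    }
  }
  if (length(centers) < n_patches) {
    stop("cannot place ", n_patches,
         " patch centers with pairwise graph distance >= 4 on this mesh")
  }

  t_s <- (seq_len(T_len) - 1) / fs
  J <- matrix(0, D, T_len)
  for (k in seq_along(centers)) {
    profile <- Q_G[, centers[k]]
    profile <- profile / max(profile)
    freq <- stats::runif(1, band_hz[1], band_hz[2])
    phase <- stats::runif(1, 0, 2 * pi)
    J <- J + outer(profile, amplitude * sin(2 * pi * freq * t_s + phase))
  }
  list(J_true = J, active_centers = centers, fs = fs, seed = seed)
}

#' Project sources to the sensors and add Gaussian noise
#'
#' Forms `X = M J + E` where `E` has i.i.d. zero-mean Gaussian entries whose
#' variance is set so that the expected ratio of total signal power to total
#' noise power, over all channels and samples, equals `snr_db` decibels.
#' `snr_db = Inf` disables the noise.
#'
#' @param M Lead field (C x D).
#' @param J_true Source currents (D x T).
#' @param snr_db Requested signal-to-noise ratio in dB, or `Inf`.
#' @param seed Integer RNG seed.
#' @return List of class `simulated_recording`: `X` (C x T), `J_true`,
#'   `snr_db`, `seed`, plus `signal` and `noise` addends for diagnostics.
#' @export
simulate_eeg <- function(M, J_true, snr_db = 10, seed = 1) {
  if (!all(is.finite(M)) || !all(is.finite(J_true))) {
    stop("non-finite inputs")
  }
  S <- unclass(M) %*% J_true
  if (is.infinite(snr_db)) {
    E <- matrix(0, nrow(S), ncol(S))
  } else {
    sig_pow <- mean(S^2)
    noise_var <- if (sig_pow == 0) 1 else sig_pow / 10^(snr_db / 10)
    set.seed(seed)
    E <- matrix(stats::rnorm(length(S), sd = sqrt(noise_var)),
                nrow(S), ncol(S))
  }
  structure(
    list(X = S + E, J_true = J_true, signal = S, noise = E,
         snr_db = snr_db, seed = seed),
    class = "simulated_recording"
  )
}
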