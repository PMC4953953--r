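#' Source energy map
#'
#' Per-dipole mean squared reconstructed current over time,
#' `e_bar[d] = mean_t J_hat[d, t]^2`.
#'
#' @param J_hat D x T matrix of (estimated) source currents.
#' @return Non-negative D-vector of class `energy_map`.
#' @export
source_energy <- function(J_hat) {
  if (is.null(dim(J_hat)) || ncol(J_hat) < 1) stop("J_hat must be D x T")
  structure(rowMeans(J_hat^2), class = "energy_map")
}

#' Weighted mesh graph for geodesic distances
#'
#' Converts a cortical mesh into an undirected `igraph` whose edge weights are
#' Euclidean edge lengths in mm, so that shortest paths approximate geodesic
#' distance along the surface.
#'
#' @param mesh A `cortical_mesh`.
#' @return An `igraph` object with a `weight` edge attribute (mm).
#' @export
mesh_graph <- function(mesh) {
  f <- mesh$faces
  e <- unique(t(apply(rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)]),
                      1, sort)))
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- w
  g
}

#' Greedy selection of spatially compact regions of interest
#'
#' Implements data-driven peak picking on the source energy map. Dipoles whose
#' energy is below `threshold_frac` of the maximum are ineligible: they can
#' never seed an ROI. Then, repeatedly, the unlabeled eligible dipole with the
#' highest energy becomes the next ROI center (ties go to the lowest index)
#' and every unlabeled dipole within geodesic distance `rho` of it receives
#' the new label; the loop stops when no eligible dipole remains unlabeled.
#' The number of ROIs is thus fixed automatically by the energy landscape.
#'
#' By default sub-threshold dipoles falling inside a selected radius are
#' absorbed into the ROI, which keeps regions spatially solid;
#' `strict_threshold = TRUE` leaves them unlabeled instead (they still never
#' seed an ROI under either reading).
#'
#' @param e_bar Energy map (non-negative D-vector).
#' @param graph An `igraph` over the dipoles with edge `weight`s in the same
#'   units as `rho` (see [mesh_graph()]), or a `cortical_mesh` (converted
#'   internally, distances in mm).
#' @param rho ROI radius, geodesic, in edge-weight units (mm for meshes).
#'   Default 20.
#' @param threshold_frac Peak exclusion threshold as a fraction of the
#'   maximum energy; default 0.10.
#' @param strict_threshold If `TRUE`, sub-threshold dipoles are never labeled.
#' @return Object of class `roi_labeling`: `iota` (integer labels, 0 =
#'   unassigned), `centers` (in selection order, decreasing center energy),
#'   `rho`, `threshold_frac`, `n_roi`.
#' @export
select_rois <- function(e_bar, graph, rho = 20, threshold_frac = 0.10,
                        strict_threshold = FALSE) {
  e_bar <- as.numeric(e_bar)
  if (inherits(graph, "cortical_mesh")) graph <- mesh_graph(graph)
  D <- length(e_bar)
  if (igraph::vcount(graph) != D) stop("graph size does not match energy map")
  if (any(!is.finite(e_bar)) || any(e_bar < 0)) {
    stop("energy map must be finite and non-negative")
  }
  if (max(e_bar) == 0) stop("no activity above threshold: all energies zero")
  eligible <- e_bar >= threshold_frac * max(e_bar)

  iota <- integer(D)
  centers <- integer(0)
  repeat {
    open <- which(eligible & iota == 0L)
    if (length(open) == 0) break
    center <- open[which.max(e_bar[open])]  # which.max: ties -> lowest index
    centers <- c(centers, center)
    d <- as.numeric(igraph::distances(graph, v = center))
    members <- which(d <= rho & iota == 0L)
    if (strict_threshold) members <- members[eligible[members]]
    iota[members] <- length(centers)
  }
  structure(
    list(iota = iota, centers = centers, rho = rho,
         threshold_frac = threshold_frac, n_roi = length(centers)),
    class = "roi_labeling"
  )
}

#' ROI time courses
#'
#' Row `r` is the arithmetic mean of the time courses of all dipoles labeled
#' `r`, giving the `N_ROI x T` matrix of representative ROI signals.
#'
#' @param J_hat D x T source currents.
#' @param labeling An `roi_labeling` whose labels match `nrow(J_hat)`.
#' @return N_ROI x T numeric matrix; row names `ROI1`, `ROI2`, ...
#' @export
roi_timecourses <- function(J_hat, labeling) {
  if (length(labeling$iota) != nrow(J_hat)) {
    stop("labeling does not match J_hat row count")
  }
  Y <- t(vapply(seq_len(labeling$n_roi), function(r) {
    rows <- which(labeling$iota == r)
    if (length(rows) == 0) stop("internal error: empty ROI ", r)
    colMeans(J_hat[rows, , drop = FALSE])
  }, numeric(ncol(J_hat))))
  rownames(Y) <- paste0("ROI", seq_len(labeling$n_roi))
  Y
}
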