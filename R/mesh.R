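#' Build a sphere-like triangulated surface template
#'
#' Constructs a closed, connected triangulated sphere with exactly
#' `n_vertices` vertices and approximately uniform vertex spacing, standing
#' in for a common cortical surface template. Vertices are laid out on
#' latitude rings (two poles plus interior rings with counts proportional to
#' ring circumference) and rings are stitched with a deterministic zig-zag
#' triangulation, so the mesh is fully reproducible.
#'
#' @param n_vertices Number of vertices, at least 12.
#' @param radius Sphere radius in mm; default 70 (hemisphere-like scale so
#'   that millimetre smoothing kernels are meaningful).
#' @param seed Unused (the construction is deterministic); accepted so all
#'   generators share a signature.
#' @return An object of class `surface_mesh`: list with `coords`
#'   (`n_vertices` x 3, mm), `triangles` (T x 3, 1-based vertex indices) and
#'   `radius`.
#' @export
make_mesh <- function(n_vertices, radius = 70, seed = NULL) {
  if (n_vertices < 12) stop("value error: n_vertices must be >= 12")
  n_int <- n_vertices - 2L
  n_rings <- max(2L, as.integer(round(sqrt(pi * n_int) / 2 - 1)))
  theta <- pi * seq_len(n_rings) / (n_rings + 1)
  raw <- sin(theta)
  m <- pmax(3L, as.integer(round(n_int * raw / sum(raw))))
  # adjust ring counts so they sum exactly to n_int
  while (sum(m) != n_int) {
    if (sum(m) < n_int) {
      k <- which.max(raw / m)        # most under-filled ring
      m[k] <- m[k] + 1L
    } else {
      ok <- m > 3L
      k <- which(ok)[which.min((raw / m)[ok])]
      m[k] <- m[k] - 1L
    }
  }
  coords <- matrix(0, n_vertices, 3)
  coords[1L, ] <- c(0, 0, radius)
  coords[n_vertices, ] <- c(0, 0, -radius)
  ring_idx <- vector("list", n_rings)
  ring_phi <- vector("list", n_rings)
  nxt <- 2L
  for (k in seq_len(n_rings)) {
    phi <- 2 * pi * (seq_len(m[k]) - 1L) / m[k] + (k %% 2L) * pi / m[k]
    idx <- nxt:(nxt + m[k] - 1L)
    coords[idx, ] <- radius * cbind(sin(theta[k]) * cos(phi),
                                    sin(theta[k]) * sin(phi),
                                    cos(theta[k]))
    ring_idx[[k]] <- idx
    ring_phi[[k]] <- phi
    nxt <- nxt + m[k]
  }
  tris <- list()
  # polar fans
  i1 <- ring_idx[[1L]]
  tris[[1L]] <- cbind(1L, i1, c(i1[-1L], i1[1L]))
  ir <- ring_idx[[n_rings]]
  tris[[2L]] <- cbind(n_vertices, c(ir[-1L], ir[1L]), ir)
  for (k in seq_len(n_rings - 1L)) {
    tris[[k + 2L]] <- stitch_rings(ring_idx[[k]], ring_phi[[k]],
                                   ring_idx[[k + 1L]], ring_phi[[k + 1L]])
  }
  mesh <- structure(list(coords = coords,
                         triangles = do.call(rbind, tris),
                         radius = radius),
                    class = "surface_mesh")
  mesh
}

# Stitch two closed latitude rings into a triangle strip. `ia`/`ib` are the
# vertex indices of the two rings, `aa`/`ab` their azimuths in ascending
# order. Advancing the ring whose next azimuth is smaller keeps triangles
# well-shaped for arbitrary ring sizes.
stitch_rings <- function(ia, aa, ib, ab) {
  ma <- length(ia); mb <- length(ib)
  # rotate ring b so it starts just after aa[1]
  rel <- (ab - aa[1L]) %% (2 * pi)
  rot <- order(rel)
  ib <- ib[rot]
  ab <- aa[1L] + rel[rot]
  tri <- matrix(0L, ma + mb, 3L)
  i <- 0L; j <- 0L; t <- 0L
  ang_a <- function(p) aa[((p - 1L) %% ma) + 1L] + 2 * pi * ((p - 1L) %/% ma)
  ang_b <- function(p) ab[((p - 1L) %% mb) + 1L] + 2 * pi * ((p - 1L) %/% mb)
  at <- function(v, p, mm) v[((p - 1L) %% mm) + 1L]
  while (i < ma || j < mb) {
    adv_a <- if (i >= ma) FALSE
             else if (j >= mb) TRUE
             else ang_a(i + 2L) <= ang_b(j + 2L)
    t <- t + 1L
    if (adv_a) {
      tri[t, ] <- c(at(ia, i + 1L, ma), at(ib, j + 1L, mb), at(ia, i + 2L, ma))
      i <- i + 1L
    } else {
      tri[t, ] <- c(at(ia, i + 1L, ma), at(ib, j + 1L, mb), at(ib, j + 2L, mb))
      j <- j + 1L
    }
  }
  tri[seq_len(t), , drop = FALSE]
}

#' Edge list of a surface mesh
#'
#' @param mesh A `surface_mesh`.
#' @return A two-column integer matrix of unique undirected edges with an
#'   attribute `length` holding Euclidean edge lengths (mm).
#' @export
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  d <- sqrt(rowSums((mesh$coords[e[, 1], , drop = FALSE] -
                     mesh$coords[e[, 2], , drop = FALSE])^2))
  attr(e, "length") <- d
  e
}

#' Validate the structural invariants of a surface mesh
#'
#' Checks index bounds, that every vertex belongs to at least one triangle,
#' and that the edge graph is connected.
#'
#' @param mesh A `surface_mesh`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_mesh <- function(mesh) {
  v <- nrow(mesh$coords)
  tr <- mesh$triangles
  if (any(tr < 1L) || any(tr > v)) stop("mesh error: triangle index out of range")
  if (!all(seq_len(v) %in% tr)) stop("mesh error: isolated vertex")
  g <- mesh_graph(mesh)
  if (igraph::components(g)$no != 1L) stop("mesh error: mesh not connected")
  invisible(TRUE)
}

# igraph representation (edge weights = Euclidean lengths)
mesh_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- attr(e, "length")
  g
}

#' Geodesic disc of vertices around a seed vertex
#'
#' Grows a connected patch by shortest-path (edge-length) distance on the
#' mesh graph until the geodesic radius is reached.
#'
#' @param mesh A `surface_mesh`.
#' @param seed_vertex 1-based seed vertex index.
#' @param radius_mm Geodesic radius in mm.
#' @return Integer vector of vertex indices (always includes the seed).
#' @export
mesh_patch <- function(mesh, seed_vertex, radius_mm) {
  g <- mesh_graph(mesh)
  d <- as.numeric(igraph::distances(g, v = seed_vertex))
  which(d <= radius_mm)
}
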