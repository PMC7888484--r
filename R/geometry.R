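#' Construct the spatial substrate of a two-scale brain model
#'
#' A `model_geometry` bundles the two open cortical surface meshes (left and
#' right hemisphere), the vertex-to-area parcellation, the lumped
#' subcortical centroids and the homolog pairing between left and right
#' areas.  Cortical areas are numbered `1..m` (left) and `m+1..2m` (right);
#' subcortical areas continue from `2m+1`, left hemisphere first.  Network
#' nodes are the cortical vertices (in storage order) followed by one node
#' per subcortical area.
#'
#' @param vertices numeric matrix (n x 3), vertex positions in mm.
#' @param triangles integer matrix (t x 3), 1-based vertex indices with
#'   consistent outward winding.
#' @param hemisphere character vector per vertex, `"left"` or `"right"`.
#' @param region_map integer vector per vertex, cortical area id.
#' @param n_cortical_per_hemisphere number of cortical areas per hemisphere.
#' @param subcortical_centroids numeric matrix (s x 3) in mm, ordered by
#'   subcortical area id; may have zero rows.
#' @param area_homolog integer vector over all areas: `area_homolog[i]` is
#'   the contralateral homolog of area `i` (an involution).
#' @return An object of class `model_geometry`.
#' @export
model_geometry <- function(vertices, triangles, hemisphere, region_map,
                           n_cortical_per_hemisphere, subcortical_centroids,
                           area_homolog) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3L)
  abort_if(ncol(vertices) != 3L, "vertices must be an n x 3 matrix")
  n <- nrow(vertices)
  abort_if(length(hemisphere) != n, "hemisphere must have one entry per vertex")
  abort_if(!all(hemisphere %in% c("left", "right")),
           "hemisphere entries must be 'left' or 'right'")
  abort_if(length(region_map) != n, "region_map must have one entry per vertex")
  abort_if(any(triangles < 1L) || any(triangles > n),
           "triangle indices out of range")
  abort_if(any(triangles[, 1] == triangles[, 2] |
               triangles[, 1] == triangles[, 3] |
               triangles[, 2] == triangles[, 3]),
           "degenerate triangles present")
  m <- as.integer(n_cortical_per_hemisphere)
  abort_if(!is_count(m), "n_cortical_per_hemisphere must be a positive count")
  region_map <- as.integer(region_map)
  abort_if(any(region_map < 1L) || any(region_map > 2L * m),
           "region_map entries must lie in 1..2m")
  abort_if(!all(seq_len(2L * m) %in% region_map),
           "every cortical area must contain at least one vertex")
  if (is.null(subcortical_centroids)) {
    subcortical_centroids <- matrix(numeric(0), ncol = 3L)
  }
  subcortical_centroids <- as.matrix(subcortical_centroids)
  if (ncol(subcortical_centroids) == 0L) {
    subcortical_centroids <- matrix(numeric(0), ncol = 3L)
  }
  n_sub <- nrow(subcortical_centroids)
  n_areas <- 2L * m + n_sub
  area_homolog <- as.integer(area_homolog)
  abort_if(length(area_homolog) != n_areas,
           "area_homolog must cover every area")
  abort_if(!identical(area_homolog[area_homolog], seq_len(n_areas)),
           "area_homolog must be an involution")
  geom <- structure(list(
    vertices = vertices,
    triangles = triangles,
    hemisphere = hemisphere,
    region_map = region_map,
    n_cortical_per_hemisphere = m,
    subcortical_centroids = subcortical_centroids,
    area_homolog = area_homolog
  ), class = "model_geometry")
  geom
}

#' @export
print.model_geometry <- function(x, ...) {
  cat("model_geometry:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles,",
      2L * x$n_cortical_per_hemisphere, "cortical areas,",
      nrow(x$subcortical_centroids), "subcortical areas\n")
  invisible(x)
}

n_areas <- function(geometry) {
  2L * geometry$n_cortical_per_hemisphere + nrow(geometry$subcortical_centroids)
}

n_nodes <- function(geometry) {
  nrow(geometry$vertices) + nrow(geometry$subcortical_centroids)
}

# Area id of every network node (vertices then subcortical nodes).
node_areas <- function(geometry) {
  m2 <- 2L * geometry$n_cortical_per_hemisphere
  c(geometry$region_map,
    m2 + seq_len(nrow(geometry$subcortical_centroids)))
}

# Number of network nodes per area (subcortical areas count 1).
area_sizes <- function(geometry) {
  tabulate(node_areas(geometry), nbins = n_areas(geometry))
}

#' Area centroids (cortical: mean vertex position; subcortical: the point)
#' @param geometry a [model_geometry()].
#' @return numeric matrix (areas x 3), mm.
#' @export
area_centroids <- function(geometry) {
  m2 <- 2L * geometry$n_cortical_per_hemisphere
  cort <- t(vapply(seq_len(m2), function(a) {
    colMeans(geometry$vertices[geometry$region_map == a, , drop = FALSE])
  }, numeric(3)))
  rbind(cort, geometry$subcortical_centroids)
}

# Hemisphere of each area, following the id convention.
area_hemispheres <- function(geometry) {
  m <- geometry$n_cortical_per_hemisphere
  n_sub <- nrow(geometry$subcortical_centroids)
  c(rep(c("left", "right"), each = m),
    rep(c("left", "right"), length.out = n_sub,
        each = max(1L, n_sub %/% 2L))[seq_len(n_sub)])
}

#' Outward vertex normals of the cortical mesh
#'
#' Angle-agnostic area-weighted accumulation of incident triangle normals,
#' normalized per vertex.  Orientation follows the triangle winding.
#'
#' @param geometry a [model_geometry()].
#' @return numeric matrix (vertices x 3) of unit normals.
#' @export
vertex_normals <- function(geometry) {
  v <- geometry$vertices
  tr <- geometry$triangles
  e1 <- v[tr[, 2], ] - v[tr[, 1], ]
  e2 <- v[tr[, 3], ] - v[tr[, 1], ]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- matrix(0, nrow(v), 3L)
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- tapply(fn[, d], tr[, k], sum)
      idx <- as.integer(names(acc))
      nrm[idx, d] <- nrm[idx, d] + as.numeric(acc)
    }
  }
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm / len
}

# Undirected unique mesh edges with Euclidean lengths.
mesh_edges <- function(geometry) {
  tr <- geometry$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  d <- sqrt(rowSums((geometry$vertices[e[, 1], , drop = FALSE] -
                     geometry$vertices[e[, 2], , drop = FALSE])^2))
  list(edges = e, lengths = d)
}

# Adjacency list over mesh vertices (indices of neighbours).
mesh_adjacency <- function(geometry) {
  ed <- mesh_edges(geometry)$edges
  adj <- vector("list", nrow(geometry$vertices))
  for (i in seq_len(nrow(ed))) {
    a <- ed[i, 1]; b <- ed[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Write / read a triangle mesh in OFF format
#'
#' @param geometry a [model_geometry()] (only mesh fields are written).
#' @param path file path.
#' @return `read_off` returns a list with `vertices` and `triangles`.
#' @export
write_off <- function(geometry, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(geometry$vertices),
                     nrow(geometry$triangles)), con)
  utils::write.table(format(geometry$vertices, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, geometry$triangles - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_off
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  abort_if(trimws(lines[1]) != "OFF", "not an OFF file")
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nt <- counts[2]
  verts <- matrix(scan(text = paste(lines[3:(2 + nv)], collapse = "\n"),
                       quiet = TRUE), ncol = 3L, byrow = TRUE)
  tri <- matrix(scan(text = paste(lines[(3 + nv):(2 + nv + nt)],
                                  collapse = "\n"),
                     quiet = TRUE), ncol = 4L, byrow = TRUE)
  list(vertices = verts, triangles = matrix(as.integer(tri[, 2:4]) + 1L,
                                            ncol = 3L))
}

#' Write / read a vertex-to-area region mapping as two-column TSV
#'
#' Vertex ids are written 0-based, as in TVB region-mapping files.
#'
#' @param region_map integer vector of area ids per vertex.
#' @param path file path.
#' @export
write_region_map <- function(region_map, path) {
  utils::write.table(
    data.frame(vertex_id = seq_along(region_map) - 1L, area_id = region_map),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_region_map
#' @export
read_region_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  as.integer(df$area_id[order(df$vertex_id)])
}
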