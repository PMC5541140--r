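#' Construct a SurfaceMesh
#'
#' @param vertices n x 3 matrix of world-mm points.
#' @param faces m x 3 integer matrix of 1-based vertex indices, wound
#'   counter-clockwise seen from outside.
#' @param vertexNormals optional n x 3 unit normals; computed from
#'   area-weighted face normals when missing.
#' @param checkWatertight warn if the mesh is not closed (every edge shared
#'   by exactly two faces); inside/outside reasoning needs a closed surface.
#' @return A \linkS4class{SurfaceMesh}.
#' @export
surfaceMesh <- function(vertices, faces, vertexNormals = NULL,
                        checkWatertight = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (is.null(vertexNormals))
    vertexNormals <- computeVertexNormals(vertices, faces)
  m <- new("SurfaceMesh", vertices = vertices, faces = faces,
           vertexNormals = as.matrix(vertexNormals))
  if (checkWatertight && !meshIsWatertight(m))
    warning("mesh is not watertight; inside/outside tests may be unreliable")
  m
}

#' Area-weighted vertex normals from face winding
#' @param vertices n x 3 matrix.
#' @param faces m x 3 integer matrix (1-based, CCW from outside).
#' @return n x 3 matrix of unit normals.
#' @export
computeVertexNormals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  cc <- vertices[faces[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  vn <- matrix(0, nrow(vertices), 3)
  for (k in 1:3) {
    for (ax in 1:3) {
      acc <- rowsum(fn[, ax], faces[, k])
      idx <- as.integer(rownames(acc))
      vn[idx, ax] <- vn[idx, ax] + acc
    }
  }
  nrm <- sqrt(rowSums(vn^2))
  nrm[nrm == 0] <- 1
  vn / nrm
}

#' Is a mesh watertight?
#'
#' Every undirected edge must be used by exactly two faces.
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return logical.
#' @export
meshIsWatertight <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Rasterize a surface mesh onto a voxel grid
#'
#' Marks every voxel whose centre lies within half a voxel of the surface,
#' by dense barycentric sampling of each triangle at half-voxel pitch.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param grid ScalarField or LabelVolume supplying geometry.
#' @return logical array of the grid's dimensions.
#' @export
rasterizeMesh <- function(mesh, grid) {
  dims <- gridDim(grid)
  affine <- fieldAffine(grid)
  h <- min(voxelSpacing(affine)) / 2
  mask <- array(FALSE, dims)
  v <- mesh@vertices
  f <- mesh@faces
  for (t in seq_len(nrow(f))) {
    a <- v[f[t, 1], ]; b <- v[f[t, 2], ]; cc <- v[f[t, 3], ]
    n <- max(2L, ceiling(max(sqrt(sum((b - a)^2)), sqrt(sum((cc - a)^2)),
                             sqrt(sum((cc - b)^2))) / h) + 1L)
    u <- rep(seq(0, 1, length.out = n), times = n)
    w <- rep(seq(0, 1, length.out = n), each = n)
    keep <- u + w <= 1
    u <- u[keep]; w <- w[keep]
    pts <- outer(1 - u - w, a) + outer(u, b) + outer(w, cc)
    ijk <- round(worldToVoxel(affine, pts))
    ok <- ijk[, 1] >= 0 & ijk[, 1] < dims[1] &
          ijk[, 2] >= 0 & ijk[, 2] < dims[2] &
          ijk[, 3] >= 0 & ijk[, 3] < dims[3]
    ijk <- ijk[ok, , drop = FALSE]
    if (nrow(ijk))
      mask[ijk + matrix(1, nrow(ijk), 3)] <- TRUE
  }
  mask
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto an ellipsoid; the standard
#' closed, near-uniform triangulation of a head-sized surface. Subdivision
#' level s gives 10*4^s + 2 vertices (642 at s = 3).
#'
#' @param radius scalar or length-3 semi-axes (mm).
#' @param subdivisions non-negative integer.
#' @param centre world-mm centre.
#' @return A watertight \linkS4class{SurfaceMesh} with outward normals.
#' @export
icosphere <- function(radius = 1, subdivisions = 3, centre = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid <- new.env()
    nf <- matrix(0L, 0, 3)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(mid[[key]])) return(mid[[key]])
      p <- v[i, ] + v[j, ]
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      mid[[key]] <- nrow(v)
      nrow(v)
    }
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  radius <- rep(as.numeric(radius), length.out = 3)
  verts <- sweep(sweep(v, 2, radius, "*"), 2, centre, "+")
  # ellipsoid outward normal: gradient of the implicit surface
  nrm <- sweep(v, 2, radius, "/")
  nrm <- nrm / sqrt(rowSums(nrm^2))
  surfaceMesh(verts, f, vertexNormals = nrm, checkWatertight = FALSE)
}
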