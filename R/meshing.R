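## Isosurface extraction by marching tetrahedra.
##
## Each grid cell is split into six tetrahedra sharing the cell's main
## diagonal (Kuhn subdivision).  The subdivision is face-consistent across
## neighbouring cells, and a tetrahedron has no ambiguous sign
## configurations, so the extracted surface is closed and orientable by
## construction.  Triangle vertices lie on tetrahedron edges at the linear
## zero crossing of (field - level).

cubeCorners <- matrix(c(
  0, 0, 0,
  1, 0, 0,
  1, 1, 0,
  0, 1, 0,
  0, 0, 1,
  1, 0, 1,
  1, 1, 1,
  0, 1, 1), ncol = 3, byrow = TRUE)

kuhnTets <- matrix(c(
  0, 1, 2, 6,
  0, 2, 3, 6,
  0, 3, 7, 6,
  0, 7, 4, 6,
  0, 4, 5, 6,
  0, 5, 1, 6) + 1, ncol = 4, byrow = TRUE)

#' Extract a closed surface mesh from a label volume
#'
#' Triangulated isosurface of the binarized structure (level 0.5 by default)
#' with vertices in world mm.  The volume is padded by one background voxel
#' layer so the surface is always closed, also for structures touching the
#' grid boundary.
#'
#' @param volume a \linkS4class{LabelVolume}.
#' @param structure integer label to binarize on.
#' @param level iso-level on the binarized field (default 0.5).
#' @return A \linkS4class{SurfaceMesh} with outward-oriented faces.
#' @export
extractMesh <- function(volume, structure, level = 0.5) {
  stopifnot(is(volume, "LabelVolume"))
  if (!any(volume@labels == structure))
    stop("structure label ", structure, " absent from volume")
  field <- (volume@labels == structure) * 1
  marchingTetrahedra(field, volume@affine, level = level,
                     structure = as.character(structure),
                     spaceId = volume@spaceId)
}

## field: 3D numeric array; affine maps 0-based voxel indices to world mm
marchingTetrahedra <- function(field, affine, level = 0.5,
                               structure = "structure", spaceId = "subject") {
  D <- dim(field) + 2L
  F <- array(0, D)
  F[2:(D[1] - 1), 2:(D[2] - 1), 2:(D[3] - 1)] <- field
  Fv <- as.vector(F)
  inside <- Fv > level

  ## active cells: mixed inside/outside corners
  I <- array(inside, D) * 1L
  i1 <- 1:(D[1] - 1); j1 <- 1:(D[2] - 1); k1 <- 1:(D[3] - 1)
  csum <- I[i1, j1, k1] + I[i1 + 1, j1, k1] + I[i1 + 1, j1 + 1, k1] +
    I[i1, j1 + 1, k1] + I[i1, j1, k1 + 1] + I[i1 + 1, j1, k1 + 1] +
    I[i1 + 1, j1 + 1, k1 + 1] + I[i1, j1 + 1, k1 + 1]
  act <- which(csum > 0L & csum < 8L, arr.ind = TRUE)
  if (nrow(act) == 0L)
    stop("no isosurface crossings at the requested level")
  org <- act - 1L                              # 0-based cell origins
  nAct <- nrow(org)

  ## global (0-based) grid-vertex ids of the 8 corners of each active cell
  cornerId <- matrix(0, nAct, 8)
  for (cc in 1:8) {
    cornerId[, cc] <- (org[, 1] + cubeCorners[cc, 1]) +
      D[1] * (org[, 2] + cubeCorners[cc, 2]) +
      D[1] * D[2] * (org[, 3] + cubeCorners[cc, 3])
  }

  triEdgeA <- triEdgeB <- vector("list", 0L)   # edge endpoints per triangle
  triRef <- list(); triSign <- list()
  for (tt in seq_len(nrow(kuhnTets))) {
    a <- cornerId[, kuhnTets[tt, 1]]
    b <- cornerId[, kuhnTets[tt, 2]]
    cc <- cornerId[, kuhnTets[tt, 3]]
    d <- cornerId[, kuhnTets[tt, 4]]
    verts <- cbind(a, b, cc, d)
    code <- inside[a + 1] + 2L * inside[b + 1] + 4L * inside[cc + 1] +
      8L * inside[d + 1]
    for (cd in 1:14) {
      sel <- which(code == cd)
      if (!length(sel)) next
      bits <- which(bitwAnd(cd, c(1L, 2L, 4L, 8L)) != 0L)
      vs <- verts[sel, , drop = FALSE]
      if (length(bits) == 1L) {
        p <- vs[, bits]; qs <- vs[, -bits, drop = FALSE]
        triEdgeA <- c(triEdgeA, list(cbind(p, p, p)))
        triEdgeB <- c(triEdgeB, list(qs))
        triRef <- c(triRef, list(cbind(p)))
        triSign <- c(triSign, list(rep(1, length(sel))))   # away from inside
      } else if (length(bits) == 3L) {
        out <- (1:4)[-bits]
        p <- vs[, out]; qs <- vs[, bits, drop = FALSE]
        triEdgeA <- c(triEdgeA, list(qs))
        triEdgeB <- c(triEdgeB, list(cbind(p, p, p)))
        triRef <- c(triRef, list(cbind(p)))
        triSign <- c(triSign, list(rep(-1, length(sel))))  # toward outside
      } else {
        pin <- vs[, bits, drop = FALSE]; qout <- vs[, -bits, drop = FALSE]
        p1 <- pin[, 1]; p2 <- pin[, 2]; q1 <- qout[, 1]; q2 <- qout[, 2]
        ## quad (p1q1, p1q2, p2q2, p2q1) split into two triangles
        triEdgeA <- c(triEdgeA, list(cbind(p1, p1, p2), cbind(p1, p2, p2)))
        triEdgeB <- c(triEdgeB, list(cbind(q1, q2, q2), cbind(q1, q2, q1)))
        triRef <- c(triRef, list(cbind(p1, p2), cbind(p1, p2)))
        triSign <- c(triSign, list(rep(1, length(sel)), rep(1, length(sel))))
      }
    }
  }
  eA <- do.call(rbind, triEdgeA)               # m x 3 inside-side endpoints
  eB <- do.call(rbind, triEdgeB)               # m x 3 outside-side endpoints

  ## weld shared edge vertices via canonical edge keys
  lo <- pmin(eA, eB); hi <- pmax(eA, eB)
  key <- lo * (D[1] * D[2] * D[3]) + hi        # < 2^53 for practical grids
  ukey <- sort(unique(as.vector(key)))
  faceIdx <- matrix(match(as.vector(key), ukey), ncol = 3)

  idToWorld <- function(id) {
    i <- id %% D[1]
    j <- (id %/% D[1]) %% D[2]
    k <- id %/% (D[1] * D[2])
    voxelToWorld(affine, cbind(i, j, k) - 1)   # padded index -> source index
  }
  N3 <- D[1] * D[2] * D[3]
  u <- ukey %/% N3; v <- ukey %% N3
  fu <- Fv[u + 1]; fv <- Fv[v + 1]
  t <- (level - fu) / (fv - fu)
  V <- idToWorld(u) + t * (idToWorld(v) - idToWorld(u))

  ## orient every face: normal away from the inside reference point
  refList <- lapply(seq_along(triRef), function(ii) {
    r <- triRef[[ii]]
    if (ncol(r) == 1L) idToWorld(r[, 1])
    else (idToWorld(r[, 1]) + idToWorld(r[, 2])) / 2
  })
  refPts <- do.call(rbind, refList)
  sgn <- unlist(triSign)
  v1 <- V[faceIdx[, 1], , drop = FALSE]
  v2 <- V[faceIdx[, 2], , drop = FALSE]
  v3 <- V[faceIdx[, 3], , drop = FALSE]
  n <- crossRows(v2 - v1, v3 - v1)
  centroid <- (v1 + v2 + v3) / 3
  flip <- rowSums(n * (centroid - refPts)) * sgn < 0
  faceIdx[flip, 2:3] <- faceIdx[flip, 3:2]

  new("SurfaceMesh", vertices = V, faces = faceIdx,
      structure = structure, spaceId = spaceId)
}

crossRows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

## every undirected edge must be shared by exactly two faces
meshIsClosed <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (nrow(mesh@vertices) + 1) +
    pmax(e[, 1], e[, 2])
  all(tabulate(match(key, unique(key))) == 2L)
}

#' Euler characteristic of a mesh
#'
#' V - E + F; equals 2 for a closed genus-0 surface.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return Integer Euler characteristic.
#' @export
eulerCharacteristic <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (nrow(mesh@vertices) + 1) +
    pmax(e[, 1], e[, 2])
  nrow(mesh@vertices) - length(unique(key)) + nrow(f)
}

#' Volume enclosed by a closed mesh
#'
#' Signed volume via the divergence theorem (sum of signed tetrahedra
#' spanned by each face and the origin); the orientation is normalized first
#' and the absolute value returned.
#'
#' @param mesh a closed \linkS4class{SurfaceMesh}.
#' @return Volume in mm^3.
#' @export
meshVolume <- function(mesh) {
  stopifnot(is(mesh, "SurfaceMesh"))
  if (!meshIsClosed(mesh))
    stop("mesh is not closed: enclosed volume undefined")
  v1 <- mesh@vertices[mesh@faces[, 1], , drop = FALSE]
  v2 <- mesh@vertices[mesh@faces[, 2], , drop = FALSE]
  v3 <- mesh@vertices[mesh@faces[, 3], , drop = FALSE]
  signed <- sum(rowSums(v1 * crossRows(v2, v3))) / 6
  abs(signed)
}

## area-weighted vertex normals (unit length)
vertexNormals <- function(mesh) {
  V <- mesh@vertices; f <- mesh@faces
  fn <- crossRows(V[f[, 2], ] - V[f[, 1], ], V[f[, 3], ] - V[f[, 1], ])
  n <- matrix(0, nrow(V), 3)
  for (cc in 1:3) {
    acc <- rowsum(fn, f[, cc])
    n[as.integer(rownames(acc)), ] <- n[as.integer(rownames(acc)), ] + acc
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Smooth a mesh along vertex normals
#'
#' Each iteration moves every vertex along its (area-weighted) normal by
#' `step` times the normal component of the uniform-Laplacian displacement
#' (the vector from the vertex to the centroid of its neighbours).  The
#' displacement magnitude is proportional to the local mean curvature, so
#' flat regions do not move and the overall shape is preserved; tangential
#' drift is suppressed by projecting onto the normal.  Vertex count and
#' connectivity are unchanged.  If an iteration would create a degenerate
#' (zero-area) face, smoothing stops there with a warning reporting the
#' number of completed iterations.
#'
#' @param mesh a closed \linkS4class{SurfaceMesh}.
#' @param nIter number of iterations (default 10).
#' @param step step size in (0, 1] (default 0.1).
#' @return The smoothed \linkS4class{SurfaceMesh}.
#' @export
smoothMesh <- function(mesh, nIter = 10L, step = 0.1) {
  stopifnot(is(mesh, "SurfaceMesh"))
  if (step <= 0 || step > 1) stop("step must be in (0, 1]")
  if (nIter == 0L) return(mesh)
  f <- mesh@faces
  ## undirected neighbour pairs (each edge twice, once per direction)
  eFrom <- c(f[, 1], f[, 2], f[, 3], f[, 2], f[, 3], f[, 1])
  eTo <- c(f[, 2], f[, 3], f[, 1], f[, 1], f[, 2], f[, 3])
  deg <- tabulate(eFrom, nbins = nrow(mesh@vertices)) / 2
  V <- mesh@vertices
  cur <- mesh
  for (it in seq_len(nIter)) {
    nb <- rowsum(V[eTo, , drop = FALSE], eFrom) / 2
    nb <- nb[order(as.integer(rownames(nb))), , drop = FALSE] / deg
    delta <- nb - V
    nrm <- vertexNormals(cur)
    disp <- step * rowSums(delta * nrm)
    Vnew <- V + disp * nrm
    ## reject the iteration if a face degenerates
    a1 <- crossRows(Vnew[f[, 2], ] - Vnew[f[, 1], ],
                    Vnew[f[, 3], ] - Vnew[f[, 1], ])
    if (any(rowSums(a1^2) < 1e-24)) {
      warning("degenerate face would appear; stopped after ", it - 1L,
              " iterations")
      return(cur)
    }
    V <- Vnew
    cur <- new("SurfaceMesh", vertices = V, faces = f,
               structure = mesh@structure, spaceId = mesh@spaceId)
  }
  cur
}

#' Write or read a mesh as Wavefront OBJ (ASCII)
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param path file path.
#' @param structure,spaceId metadata attached on read.
#' @return `writeOBJ` returns `path` invisibly; `readOBJ` returns a
#'   \linkS4class{SurfaceMesh}.
#' @export
writeOBJ <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f", mesh@vertices[, 1],
                     mesh@vertices[, 2], mesh@vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh@faces[, 1], mesh@faces[, 2],
                     mesh@faces[, 3]), con)
  invisible(path)
}

#' @rdname writeOBJ
#' @export
readOBJ <- function(path, structure = "structure", spaceId = "subject") {
  ln <- readLines(path)
  vs <- ln[startsWith(ln, "v ")]
  fs <- ln[startsWith(ln, "f ")]
  V <- do.call(rbind, lapply(strsplit(vs, " +"), function(x)
    as.numeric(x[2:4])))
  f <- do.call(rbind, lapply(strsplit(fs, " +"), function(x)
    as.integer(sub("/.*", "", x[2:4]))))
  mesh <- new("SurfaceMesh", vertices = V, faces = f,
              structure = structure, spaceId = spaceId)
  if (!meshIsClosed(mesh))
    warning("imported mesh is not closed")
  mesh
}
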