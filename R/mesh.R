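# ---- container -------------------------------------------------------------

#' Triangle mesh container
#'
#' @param vertices V x 3 numeric matrix of positions (µm; columns x, y, z).
#' @param faces F x 3 integer matrix of 1-based vertex indices.
#' @param axon_id Optional name carried through export.
#' @return An object of class `"trimesh"`.
#' @export
trimesh <- function(vertices, faces, axon_id = NULL) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 3,
            is.matrix(faces), ncol(faces) == 3)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (nrow(faces) && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces, axon_id = axon_id),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh%s: %d vertices, %d faces\n",
              if (is.null(x$axon_id)) "" else paste0(" ", x$axon_id),
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# unique undirected edges of a face matrix
mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# number of connected components of the vertex graph
mesh_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  e <- mesh_edges(mesh$faces)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (k in seq_len(nrow(e))) {
    a <- find(e[k, 1]); b <- find(e[k, 2])
    if (a != b) comp[a] <- b
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Mesh statistics
#'
#' Exact vertex/edge/face counts, Euler characteristic `V - E + F`, enclosed
#' volume by signed tetrahedra, and total surface area. A closed (watertight)
#' genus-0 component has Euler characteristic 2.
#'
#' @param mesh A `"trimesh"`.
#' @return List with `vertex_count`, `edge_count`, `face_count`, `euler`,
#'   `volume`, `area`, `watertight` (every edge shared by exactly two
#'   faces), `components`.
#' @export
mesh_stats <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  tab <- table(key)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  crossp <- function(u, w) cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                                 u[, 3] * w[, 1] - u[, 1] * w[, 3],
                                 u[, 1] * w[, 2] - u[, 2] * w[, 1])
  cr <- crossp(b - a, cc - a)
  area <- sum(sqrt(rowSums(cr^2))) / 2
  vol <- sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
             a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
             a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
  nE <- length(tab)
  list(vertex_count = nrow(v), edge_count = nE, face_count = nrow(f),
       euler = nrow(v) - nE + nrow(f), volume = abs(vol), area = area,
       watertight = all(tab == 2), components = mesh_components(mesh))
}

# ---- lofting ---------------------------------------------------------------

# resample a closed contour to m points at uniform angles about its centroid
resample_contour <- function(xy, m) {
  cen <- polygon_centroid(xy)
  th <- atan2(xy[, 2] - cen[2], xy[, 1] - cen[1]) %% (2 * pi)
  r <- sqrt((xy[, 1] - cen[1])^2 + (xy[, 2] - cen[2])^2)
  ord <- order(th)
  th <- th[ord]; r <- r[ord]
  # wrap for periodic interpolation
  th2 <- c(th[length(th)] - 2 * pi, th, th[1] + 2 * pi)
  r2 <- c(r[length(r)], r, r[1])
  tgt <- 2 * pi * (seq_len(m) - 1) / m
  ri <- approx(th2, r2, xout = tgt, ties = mean)$y
  cbind(cen[1] + ri * cos(tgt), cen[2] + ri * sin(tgt))
}

#' Loft a trace into a closed triangle mesh
#'
#' Resamples every contour of the trace to a common vertex count by angular
#' parameterization about its centroid (a consistent angular origin across
#' rings keeps the stitching twist-free), stitches consecutive rings with
#' `2 * n_ring` triangles per slab, and closes both ends with centroid fans.
#' Mesh coordinates are `(x, y, z) = (row_um, col_um, slice * z_step)`.
#'
#' @param trace An `"axon_trace"` with contours on >= 2 contiguous slices.
#' @param z_step Section spacing, µm.
#' @param n_ring Vertices per contour ring (default 64).
#' @return A watertight `"trimesh"` (outward-oriented).
#' @export
loft_trace <- function(trace, z_step, n_ring = 64L) {
  cts <- trace$contours
  if (length(cts) < 2) stop("trace needs at least 2 contours")
  sl <- vapply(cts, `[[`, integer(1), "slice")
  o <- order(sl)
  cts <- cts[o]; sl <- sl[o]
  if (any(diff(sl) != 1))
    stop("trace is not contiguous: missing slice in range")
  m <- as.integer(n_ring)
  k <- length(cts)
  rings <- lapply(cts, function(ct) resample_contour(ct$vertices, m))
  verts <- matrix(NA_real_, k * m + 2, 3)
  for (i in seq_len(k))
    verts[(i - 1) * m + seq_len(m), ] <- cbind(rings[[i]], (sl[i] - 1) * z_step)
  cen1 <- polygon_centroid(cts[[1]]$vertices)
  cenk <- polygon_centroid(cts[[k]]$vertices)
  i_c1 <- k * m + 1L; i_ck <- k * m + 2L
  verts[i_c1, ] <- c(cen1, (sl[1] - 1) * z_step)
  verts[i_ck, ] <- c(cenk, (sl[k] - 1) * z_step)
  faces <- vector("list", k + 1)
  jn <- c(seq_len(m)[-1], 1L)  # j + 1 cyclic
  for (i in seq_len(k - 1)) {
    a <- (i - 1) * m + seq_len(m)
    b <- i * m + seq_len(m)
    an <- (i - 1) * m + jn
    bn <- i * m + jn
    faces[[i]] <- rbind(cbind(a, an, b), cbind(an, bn, b))
  }
  # end caps (fans)
  a1 <- seq_len(m); a1n <- jn
  faces[[k]] <- cbind(a1n, a1, i_c1)
  ak <- (k - 1) * m + seq_len(m); akn <- (k - 1) * m + jn
  faces[[k + 1]] <- cbind(ak, akn, i_ck)
  f <- do.call(rbind, faces)
  mesh <- trimesh(verts, f, axon_id = trace$axon_id)
  # orient outward
  if (signed_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# ---- smoothing -------------------------------------------------------------

# neighbor-structure helper: directed edge list and vertex degrees
neighbor_struct <- function(mesh) {
  e <- mesh_edges(mesh$faces)
  ed <- rbind(e, e[, c(2, 1)])
  deg <- tabulate(ed[, 1], nbins = nrow(mesh$vertices))
  if (any(deg == 0)) stop("mesh has isolated vertices")
  list(ed = ed, deg = deg)
}

neighbor_average <- function(p, ns) {
  s <- rowsum(p[ns$ed[, 2], , drop = FALSE], ns$ed[, 1],
              reorder = TRUE)
  s / ns$deg
}

#' HC Laplacian smoothing (volume-preserving)
#'
#' Laplacian smoothing with the "HC" pushback correction: after moving each
#' vertex to the average of its neighbors, the difference to a blend of the
#' original and previous position is computed and a weighted average of
#' these correction vectors (the vertex's own and its neighbors') is pushed
#' back, largely cancelling the shrinkage of plain Laplacian smoothing.
#' Connectivity is unchanged.
#'
#' @param mesh A `"trimesh"` (manifold; no isolated vertices).
#' @param iterations Number of smoothing passes (0 = identity).
#' @param alpha Weight of the original position in the pushback reference
#'   (default 0).
#' @param beta Weight of the vertex's own correction versus its neighbors'
#'   (default 0.5).
#' @return The smoothed `"trimesh"`.
#' @export
hc_laplacian_smooth <- function(mesh, iterations = 10, alpha = 0, beta = 0.5) {
  stopifnot(iterations >= 0, alpha >= 0, alpha <= 1, beta >= 0, beta <= 1)
  if (iterations == 0) return(mesh)
  ns <- neighbor_struct(mesh)
  o <- mesh$vertices
  p <- o
  for (it in seq_len(iterations)) {
    q <- p
    p <- neighbor_average(q, ns)
    b <- p - (alpha * o + (1 - alpha) * q)
    bavg <- neighbor_average(b, ns)
    p <- p - (beta * b + (1 - beta) * bavg)
  }
  mesh$vertices <- p
  mesh
}

#' Plain Laplacian smoothing
#'
#' Each vertex moves to the average of its neighbors; shrinks closed
#' surfaces noticeably (provided for comparison with
#' [hc_laplacian_smooth()]).
#'
#' @inheritParams hc_laplacian_smooth
#' @return The smoothed `"trimesh"`.
#' @export
laplacian_smooth <- function(mesh, iterations = 10) {
  stopifnot(iterations >= 0)
  if (iterations == 0) return(mesh)
  ns <- neighbor_struct(mesh)
  p <- mesh$vertices
  for (it in seq_len(iterations)) p <- neighbor_average(p, ns)
  mesh$vertices <- p
  mesh
}

# ---- quadric decimation ----------------------------------------------------

# fundamental error quadrics (Garland-Heckbert), one 4x4 per vertex
vertex_quadrics <- function(pos, faces) {
  n <- nrow(pos)
  Q <- array(0, c(4, 4, n))
  for (k in seq_len(nrow(faces))) {
    i <- faces[k, ]
    a <- pos[i[1], ]; b <- pos[i[2], ]; cc <- pos[i[3], ]
    nrm <- c((b[2] - a[2]) * (cc[3] - a[3]) - (b[3] - a[3]) * (cc[2] - a[2]),
             (b[3] - a[3]) * (cc[1] - a[1]) - (b[1] - a[1]) * (cc[3] - a[3]),
             (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
    l <- sqrt(sum(nrm^2))
    if (l < 1e-15) next
    nrm <- nrm / l
    pl <- c(nrm, -sum(nrm * a))
    K <- outer(pl, pl)
    for (j in i) Q[, , j] <- Q[, , j] + K
  }
  Q
}

# optimal collapse position and cost for quadric Q
quadric_optimum <- function(Q, pa, pb) {
  A <- Q[1:3, 1:3]
  rhs <- -Q[1:3, 4]
  v <- NULL
  ok <- FALSE
  if (abs(det(A)) > 1e-10 * (sum(abs(A)) / 9 + 1e-30)^3) {
    v <- tryCatch(solve(A, rhs), error = function(e) NULL)
    ok <- !is.null(v) && all(is.finite(v))
  }
  cost_of <- function(x) { h <- c(x, 1); as.numeric(h %*% Q %*% h) }
  if (!ok) {
    cand <- list(pa, pb, (pa + pb) / 2)
    costs <- vapply(cand, cost_of, numeric(1))
    j <- which.min(costs)
    return(list(pos = cand[[j]], cost = costs[j]))
  }
  list(pos = as.numeric(v), cost = cost_of(as.numeric(v)))
}

#' Quadric edge-collapse decimation
#'
#' Iteratively collapses the edge with the least quadric (squared
#' plane-distance) error, merging its endpoints at the quadric-optimal
#' position, until the vertex count falls to `target_vertex_fraction` of the
#' original. Collapses that would break the manifold link condition or flip
#' face normals are rejected; if no admissible collapse remains before the
#' target is reached, decimation stops early and the achieved fraction is
#' reported in the `"achieved_fraction"` attribute. Euler characteristic and
#' component count are preserved.
#'
#' @param mesh A manifold `"trimesh"`.
#' @param target_vertex_fraction Fraction of vertices to keep, in (0, 1).
#' @return The decimated `"trimesh"` with attribute `"achieved_fraction"`.
#' @export
quadric_decimate <- function(mesh, target_vertex_fraction) {
  stopifnot(target_vertex_fraction > 0, target_vertex_fraction < 1)
  pos <- mesh$vertices
  faces <- mesh$faces
  v0 <- nrow(pos)
  target <- max(4L, as.integer(ceiling(target_vertex_fraction * v0)))
  Q <- vertex_quadrics(pos, faces)
  vact <- rep(TRUE, v0)
  fact <- rep(TRUE, nrow(faces))
  ed <- mesh_edges(faces)
  ecost <- numeric(nrow(ed))
  epos <- matrix(0, nrow(ed), 3)
  eskip <- rep(FALSE, nrow(ed))
  recompute <- function(idx) {
    for (k in idx) {
      a <- ed[k, 1]; b <- ed[k, 2]
      qo <- quadric_optimum(Q[, , a] + Q[, , b], pos[a, ], pos[b, ])
      ecost[k] <<- qo$cost
      epos[k, ] <<- qo$pos
      eskip[k] <<- FALSE
    }
  }
  recompute(seq_len(nrow(ed)))
  ealive <- rep(TRUE, nrow(ed))
  nv <- v0
  face_has <- function(vv) fact & (faces[, 1] == vv | faces[, 2] == vv |
                                     faces[, 3] == vv)
  while (nv > target) {
    cand <- which(ealive & !eskip)
    if (!length(cand)) break
    k <- cand[which.min(ecost[cand])]
    a <- ed[k, 1]; b <- ed[k, 2]
    # link condition: exactly two common neighbors, both the wing vertices
    ea <- ealive & (ed[, 1] == a | ed[, 2] == a)
    eb <- ealive & (ed[, 1] == b | ed[, 2] == b)
    nb_a <- setdiff(unique(as.vector(ed[ea, ])), a)
    nb_b <- setdiff(unique(as.vector(ed[eb, ])), b)
    common <- intersect(nb_a, nb_b)
    dying <- which(face_has(a) & (faces[, 1] == b | faces[, 2] == b |
                                    faces[, 3] == b))
    wings <- unique(setdiff(as.vector(faces[dying, , drop = FALSE]), c(a, b)))
    if (length(common) != 2 || length(dying) != 2 ||
        !setequal(common, wings)) { eskip[k] <- TRUE; next }
    # normal-flip check on surviving faces around a and b
    newp <- epos[k, ]
    surv <- which((face_has(a) | face_has(b)))
    surv <- setdiff(surv, dying)
    flip <- FALSE
    for (fi in surv) {
      tri <- faces[fi, ]
      pts_old <- pos[tri, , drop = FALSE]
      tri2 <- ifelse(tri == b, a, tri)
      pts_new <- pos[tri2, , drop = FALSE]
      pts_new[tri2 == a, ] <- matrix(newp, sum(tri2 == a), 3, byrow = TRUE)
      n1 <- crossv(pts_old[2, ] - pts_old[1, ], pts_old[3, ] - pts_old[1, ])
      n2 <- crossv(pts_new[2, ] - pts_new[1, ], pts_new[3, ] - pts_new[1, ])
      if (sum(n2^2) < 1e-24 || sum(n1 * n2) <= 0) { flip <- TRUE; break }
    }
    if (flip) { eskip[k] <- TRUE; next }
    # collapse b into a
    pos[a, ] <- newp
    Q[, , a] <- Q[, , a] + Q[, , b]
    vact[b] <- FALSE
    fact[dying] <- FALSE
    fb <- which(face_has(b))
    for (fi in fb) faces[fi, ] <- ifelse(faces[fi, ] == b, a, faces[fi, ])
    # remap edges touching b, drop the collapsed edge, dedupe
    touch_b <- ealive & (ed[, 1] == b | ed[, 2] == b)
    ed[touch_b, ] <- t(apply(ed[touch_b, , drop = FALSE], 1, function(r) {
      r[r == b] <- a
      sort(r)
    }))
    ealive[k] <- FALSE
    self <- ealive & ed[, 1] == ed[, 2]
    ealive[self] <- FALSE
    touch_a <- which(ealive & (ed[, 1] == a | ed[, 2] == a))
    if (length(touch_a) > 1) {
      keys <- paste(ed[touch_a, 1], ed[touch_a, 2])
      dup <- duplicated(keys)
      ealive[touch_a[dup]] <- FALSE
      touch_a <- touch_a[!dup]
    }
    recompute(touch_a)
    nv <- nv - 1L
  }
  # compact
  keep <- which(vact)
  remap <- integer(v0)
  remap[keep] <- seq_along(keep)
  f2 <- faces[fact, , drop = FALSE]
  f2[] <- remap[f2]
  out <- trimesh(pos[keep, , drop = FALSE], f2, axon_id = mesh$axon_id)
  attr(out, "achieved_fraction") <- nv / v0
  out
}

crossv <- function(u, w) c(u[2] * w[3] - u[3] * w[2],
                           u[3] * w[1] - u[1] * w[3],
                           u[1] * w[2] - u[2] * w[1])

# ---- overlap audit ---------------------------------------------------------

#' Count inter-axon mesh overlap errors
#'
#' For every ordered pair of meshes with intersecting bounding boxes, counts
#' the vertices of mesh A lying strictly inside mesh B (ray-parity
#' containment). Such incorporated vertices short-circuit downstream field
#' simulations, so their count is the model-quality metric of interest.
#'
#' @param meshes Named list of watertight `"trimesh"` objects.
#' @return List with `pairs` (data frame `mesh_a, mesh_b, n_inside`) and
#'   `total`.
#' @export
overlap_errors <- function(meshes) {
  nm <- names(meshes)
  if (is.null(nm)) nm <- paste0("mesh", seq_along(meshes))
  for (i in seq_along(meshes)) {
    st <- mesh_stats(meshes[[i]])
    if (!st$watertight)
      stop(sprintf("mesh '%s' is not watertight", nm[i]))
  }
  bb <- lapply(meshes, function(m) rbind(apply(m$vertices, 2, min),
                                         apply(m$vertices, 2, max)))
  rows <- list()
  for (i in seq_along(meshes)) for (j in seq_along(meshes)) {
    if (i == j) next
    if (any(bb[[i]][1, ] > bb[[j]][2, ] | bb[[i]][2, ] < bb[[j]][1, ])) {
      n_in <- 0L
    } else {
      ins <- .points_in_mesh_cpp(meshes[[i]]$vertices,
                                 meshes[[j]]$vertices, meshes[[j]]$faces)
      n_in <- sum(ins)
    }
    rows[[length(rows) + 1]] <- data.frame(mesh_a = nm[i], mesh_b = nm[j],
                                           n_inside = n_in)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mesh_a = character(), mesh_b = character(),
               n_inside = integer())
  list(pairs = pairs, total = sum(pairs$n_inside))
}

# ---- file formats ----------------------------------------------------------

#' Export meshes as ASCII PLY or VRML 2.0
#'
#' PLY holds a single mesh (a list is merged into one); VRML 2.0 writes one
#' `DEF <axon_id> Shape` with an `IndexedFaceSet` per mesh, preserving axon
#' names.
#'
#' @param mesh A `"trimesh"` or a (named) list of them.
#' @param path Output file path.
#' @param format `"ply"` or `"vrml"`; inferred from the file extension when
#'   missing.
#' @return Invisibly, `path`.
#' @export
export_mesh <- function(mesh, path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", wrl = , vrml = "vrml",
                     stop("cannot infer mesh format from extension: ", ext))
  }
  format <- match.arg(format, c("ply", "vrml"))
  meshes <- if (inherits(mesh, "trimesh")) list(mesh) else mesh
  nm <- names(meshes)
  if (is.null(nm))
    nm <- vapply(seq_along(meshes), function(i)
      if (!is.null(meshes[[i]]$axon_id)) meshes[[i]]$axon_id
      else paste0("mesh", i), character(1))
  if (format == "ply") {
    if (length(meshes) > 1) {
      off <- 0L
      vs <- list(); fs <- list()
      for (m in meshes) {
        vs[[length(vs) + 1]] <- m$vertices
        fs[[length(fs) + 1]] <- m$faces + off
        off <- off + nrow(m$vertices)
      }
      meshes <- list(trimesh(do.call(rbind, vs), do.call(rbind, fs)))
    }
    m <- meshes[[1]]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(m$vertices)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(m$faces)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(apply(m$vertices, 1, function(r)
      paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
            collapse = " ")), con)
    writeLines(paste(3, m$faces[, 1] - 1, m$faces[, 2] - 1, m$faces[, 3] - 1),
               con)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#VRML V2.0 utf8", con)
  for (i in seq_along(meshes)) {
    m <- meshes[[i]]
    writeLines(sprintf("DEF %s Shape {", nm[i]), con)
    writeLines("  geometry IndexedFaceSet {", con)
    writeLines("    coord Coordinate { point [", con)
    writeLines(paste0("      ",
                      apply(m$vertices, 1, function(r)
                        paste(format(r, digits = 17, scientific = FALSE,
                                     trim = TRUE), collapse = " ")), ","), con)
    writeLines("    ] }", con)
    writeLines("    coordIndex [", con)
    writeLines(paste0("      ", m$faces[, 1] - 1, ", ", m$faces[, 2] - 1,
                      ", ", m$faces[, 3] - 1, ", -1,"), con)
    writeLines("    ]", con)
    writeLines("  }", con)
    writeLines("}", con)
  }
  invisible(path)
}

#' Import meshes written by [export_mesh()]
#'
#' Reads ASCII PLY (one mesh) or the VRML 2.0 subset written by this
#' package (named `IndexedFaceSet` nodes).
#'
#' @param path PLY or VRML/WRL file path.
#' @return A `"trimesh"` (PLY) or a named list of them (VRML).
#' @export
import_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    lines <- readLines(path)
    if (lines[1] != "ply" || !grepl("ascii", lines[2]))
      stop("only ASCII PLY is supported")
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)[1]))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", lines, value = TRUE)[1]))
    h <- which(lines == "end_header")
    vl <- lines[(h + 1):(h + nv)]
    fl <- lines[(h + nv + 1):(h + nv + nf)]
    verts <- do.call(rbind, lapply(strsplit(vl, " +"), function(x)
      as.numeric(x[1:3])))
    faces <- do.call(rbind, lapply(strsplit(fl, " +"), function(x)
      as.integer(x[2:4]) + 1L))
    return(trimesh(verts, faces))
  }
  if (!ext %in% c("wrl", "vrml")) stop("unknown format: ", ext)
  txt <- paste(readLines(path), collapse = "\n")
  if (!grepl("^#VRML V2.0 utf8", txt)) stop("not a VRML 2.0 file")
  out <- list()
  starts <- gregexpr("DEF +([A-Za-z_][A-Za-z0-9_]*) +Shape", txt)[[1]]
  if (starts[1] == -1) stop("no named Shape nodes found")
  nmatch <- length(starts)
  bounds <- c(starts, nchar(txt) + 1)
  for (i in seq_len(nmatch)) {
    blk <- substr(txt, bounds[i], bounds[i + 1] - 1)
    name <- sub(".*?DEF +([A-Za-z_][A-Za-z0-9_]*) +Shape.*", "\\1",
                substr(blk, 1, 200))
    pts <- sub(".*point \\[", "", blk)
    pts <- sub("\\].*", "", pts)
    xyz <- as.numeric(strsplit(gsub(",", " ", pts), "[ \n\t]+")[[1]])
    xyz <- xyz[!is.na(xyz)]
    verts <- matrix(xyz, ncol = 3, byrow = TRUE)
    idx <- sub(".*coordIndex \\[", "", blk)
    idx <- sub("\\].*", "", idx)
    iv <- as.integer(strsplit(gsub(",", " ", idx), "[ \n\t]+")[[1]])
    iv <- iv[!is.na(iv)]
    iv <- matrix(iv, ncol = 4, byrow = TRUE)
    stopifnot(all(iv[, 4] == -1))
    out[[name]] <- trimesh(verts, iv[, 1:3] + 1L, axon_id = name)
  }
  if (length(out) == 1 && ext == "ply") out[[1]] else out
}

# ---- utility solids --------------------------------------------------------

#' Unit icosphere
#'
#' Icosahedron subdivided `subdiv` times with vertices projected to the
#' sphere of the given radius; a standard well-conditioned closed test
#' surface.
#'
#' @param subdiv Number of 4-to-1 subdivisions (0 = icosahedron).
#' @param radius Sphere radius.
#' @return A `"trimesh"`.
#' @export
make_icosphere <- function(subdiv = 2, radius = 1) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdiv)) {
    midkey <- new.env()
    nv <- nrow(v)
    vl <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(midkey[[key]])) return(midkey[[key]])
      p <- (vl[[a]] + vl[[b]]) / 2
      p <- p / sqrt(sum(p^2))
      vl[[length(vl) + 1]] <<- p
      midkey[[key]] <- length(vl)
      length(vl)
    }
    f2 <- matrix(0L, 0, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      f2 <- rbind(f2, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vl)
    f <- f2
  }
  m <- trimesh(v * radius, f)
  if (signed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Lofted circular cylinder (analytic test solid)
#'
#' Builds a cylinder by lofting identical circular contours, exercising the
#' same stitching as [loft_trace()].
#'
#' @param radius,height Cylinder radius and height (µm).
#' @param n_ring Vertices per ring.
#' @param n_slabs Number of axial slabs (rings = `n_slabs + 1`).
#' @param jitter_sd Optional radial vertex jitter SD (fraction of radius),
#'   for smoothing experiments.
#' @return A watertight `"trimesh"`.
#' @export
make_cylinder <- function(radius, height, n_ring = 64, n_slabs = 10,
                          jitter_sd = 0) {
  z_step <- height / n_slabs
  cts <- lapply(seq_len(n_slabs + 1), function(s)
    manual_circle(c(0, 0), radius, s, n_vertices = max(32, n_ring)))
  tr <- structure(list(axon_id = "cylinder", contours = cts,
                       status = "complete", start_slice = 1L),
                  class = "axon_trace")
  m <- loft_trace(tr, z_step, n_ring = n_ring)
  if (jitter_sd > 0) {
    v <- m$vertices
    r <- sqrt(v[, 1]^2 + v[, 2]^2)
    body <- r > 1e-9
    scale <- 1 + rnorm(sum(body), 0, jitter_sd)
    v[body, 1:2] <- v[body, 1:2] * scale
    m$vertices <- v
  }
  m
}
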