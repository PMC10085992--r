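# Minimal triangle-mesh support: STL read/write (binary and ASCII),
# watertightness checks, signed volume, parametric test meshes, and
# vertical ray casting used by the voxelizer and the lens re-sampler.
#
# A mesh is a list with `triangles`: numeric array [n_tri, 3 (vertex), 3
# (x,y,z)], plus a `units` string ("mm" by convention for STL files).

new_mesh <- function(triangles, units = "mm") {
  structure(list(triangles = triangles, units = units), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d triangles (%s), volume %.4g %s^3\n",
              dim(x$triangles)[1L], x$units, mesh_volume(x), x$units))
  invisible(x)
}

#' Read an STL file
#'
#' Handles both binary and ASCII STL. Coordinates are kept in the file's
#' units (STL files are conventionally millimeters; [voxelize_mesh()]
#' converts to meters).
#'
#' @param path file path.
#' @param units unit label to attach, default "mm".
#' @return a `tri_mesh`.
#' @export
read_stl <- function(path, units = "mm") {
  con <- file(path, "rb")
  header <- readBin(con, "raw", 80L)
  n_claimed <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  rest <- readBin(con, "raw", file.size(path))
  close(con)
  is_binary <- length(n_claimed) == 1L && !is.na(n_claimed) &&
    n_claimed >= 0 && n_claimed < 2^24 &&
    length(rest) == n_claimed * 50L
  if (is_binary) {
    tri <- array(NA_real_, dim = c(n_claimed, 3L, 3L))
    m <- matrix(rest[seq_len(n_claimed * 50L)], nrow = 50L)
    for (t in seq_len(n_claimed)) {
      vals <- readBin(m[1:48, t], "double", 12L, size = 4L, endian = "little")
      tri[t, , ] <- matrix(vals[4:12], nrow = 3L, byrow = TRUE)
    }
    return(new_mesh(tri, units))
  }
  # ASCII
  txt <- readLines(path, warn = FALSE)
  vx <- grep("^\\s*vertex", txt, value = TRUE)
  if (!length(vx) || length(vx) %% 3L != 0L) {
    abort("'%s' is neither valid binary nor ASCII STL", path)
  }
  vals <- t(vapply(strsplit(trimws(vx), "\\s+"),
                   function(p) as.numeric(p[2:4]), numeric(3L)))
  nt <- nrow(vals) / 3L
  tri <- array(NA_real_, dim = c(nt, 3L, 3L))
  for (v in 1:3) tri[, v, ] <- vals[seq(v, by = 3L, length.out = nt), ]
  new_mesh(tri, units)
}

#' Write a mesh to STL
#'
#' @param mesh a `tri_mesh`.
#' @param path output path.
#' @param format "binary" (compact) or "ascii".
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  tri <- mesh$triangles
  nt <- dim(tri)[1L]
  # facet normals from vertex winding
  e1 <- tri[, 2L, ] - tri[, 1L, ]
  e2 <- tri[, 3L, ] - tri[, 1L, ]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / ifelse(len > 0, len, 1)
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(c(charToRaw(sprintf("%-79s", "holofocus lens")), as.raw(0L)), con)
    writeBin(as.integer(nt), con, size = 4L, endian = "little")
    block <- matrix(0, nrow = 12L, ncol = nt)
    block[1:3, ] <- t(nrm)
    for (v in 1:3) block[3L * v + (1:3), ] <- t(tri[, v, ])
    for (t in seq_len(nt)) {
      writeBin(block[, t], con, size = 4L, endian = "little")
      writeBin(as.integer(0L), con, size = 2L, endian = "little")
    }
  } else {
    lines <- character(7L * nt + 2L)
    lines[1L] <- "solid holofocus"
    for (t in seq_len(nt)) {
      b <- 7L * (t - 1L) + 1L
      lines[b + 1L] <- sprintf("  facet normal %.9g %.9g %.9g",
                               nrm[t, 1], nrm[t, 2], nrm[t, 3])
      lines[b + 2L] <- "    outer loop"
      for (v in 1:3) {
        lines[b + 2L + v] <- sprintf("      vertex %.9g %.9g %.9g",
                                     tri[t, v, 1], tri[t, v, 2], tri[t, v, 3])
      }
      lines[b + 6L] <- "    endloop"
      lines[b + 7L] <- "  endfacet"
    }
    lines[7L * nt + 2L] <- "endsolid holofocus"
    writeLines(lines, path)
  }
  invisible(path)
}

# canonical vertex keys (exact double equality is guaranteed for meshes we
# build ourselves; imported meshes get a tolerance via rounding)
vertex_keys <- function(tri, digits = 9L) {
  nt <- dim(tri)[1L]
  flat <- matrix(aperm(tri, c(2L, 1L, 3L)), ncol = 3L)  # (tri,vertex) rows
  apply(round(flat, digits), 1L, paste, collapse = ",")
}

#' Check mesh watertightness
#'
#' Tests the closed-surface (cycle) condition: with consistent orientation,
#' every directed edge must be traversed exactly as many times as its
#' reverse, so the surface has zero boundary. This admits the "kissing
#' column" corners of quantized heightfield lenses (four walls meeting on
#' one vertical line, pairwise matched) while rejecting any hole, crack or
#' orientation flip.
#'
#' @param mesh a `tri_mesh`.
#' @return TRUE/FALSE.
#' @export
mesh_is_watertight <- function(mesh) {
  keys <- vertex_keys(mesh$triangles)
  ids <- match(keys, unique(keys))
  v <- matrix(ids, nrow = 3L)  # vertex ids per triangle
  edges <- cbind(c(v[1L, ], v[2L, ], v[3L, ]), c(v[2L, ], v[3L, ], v[1L, ]))
  if (any(edges[, 1L] == edges[, 2L])) return(FALSE)  # degenerate edge
  dir_key <- paste(edges[, 1L], edges[, 2L])
  rev_key <- paste(edges[, 2L], edges[, 1L])
  td <- table(dir_key)
  tr <- table(rev_key)
  setequal(names(td), names(tr)) && all(td == tr[names(td)])
}

#' Signed mesh volume
#'
#' Divergence-theorem volume (positive for outward-oriented closed meshes),
#' in the cube of the mesh units.
#'
#' @param mesh a `tri_mesh`.
#' @return volume.
#' @export
mesh_volume <- function(mesh) {
  tri <- mesh$triangles
  v1 <- tri[, 1L, , drop = FALSE]; dim(v1) <- dim(tri)[c(1L, 3L)]
  v2 <- tri[, 2L, , drop = FALSE]; dim(v2) <- dim(tri)[c(1L, 3L)]
  v3 <- tri[, 3L, , drop = FALSE]; dim(v3) <- dim(tri)[c(1L, 3L)]
  det3 <- v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
    v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
    v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  sum(det3) / 6
}

#' Parametric test meshes
#'
#' Axis-aligned box and UV-sphere/ellipsoid meshes with outward
#' orientation, in arbitrary (caller-chosen) units.
#'
#' @param lo,hi box corners (length 3).
#' @return a `tri_mesh`.
#' @export
make_box_mesh <- function(lo, hi, units = "mm") {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # vertex order: 1:(---) 2:(+--) 3:(-+-) 4:(++-) 5:(--+) 6:(+-+) 7:(-++) 8:(+++)
  quads <- rbind(c(1, 3, 4, 2),   # z = lo (outward -z)
                 c(5, 6, 8, 7),   # z = hi (+z)
                 c(1, 2, 6, 5),   # y = lo (-y)
                 c(3, 7, 8, 4),   # y = hi (+y)
                 c(1, 5, 7, 3),   # x = lo (-x)
                 c(2, 4, 8, 6))   # x = hi (+x)
  tris <- matrix(0, nrow = 12L, ncol = 3L)
  for (q in seq_len(6L)) {
    tris[2L * q - 1L, ] <- quads[q, c(1, 2, 3)]
    tris[2L * q, ] <- quads[q, c(1, 3, 4)]
  }
  tri <- array(NA_real_, dim = c(12L, 3L, 3L))
  for (k in 1:3) tri[, k, ] <- v[tris[, k], ]
  new_mesh(tri, units)
}

#' @rdname make_box_mesh
#' @param center,radii ellipsoid center and semi-axes (radii may be scalar
#'   for a sphere).
#' @param n_theta,n_phi latitudinal / longitudinal resolution.
#' @param units unit label.
#' @export
make_ellipsoid_mesh <- function(center, radii, n_theta = 24L, n_phi = 48L,
                                units = "mm") {
  radii <- rep_len(radii, 3L)
  th <- seq(0, pi, length.out = n_theta + 1L)
  ph <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  pt <- function(it, ip) {
    cbind(center[1] + radii[1] * sin(th[it]) * cos(ph[ip]),
          center[2] + radii[2] * sin(th[it]) * sin(ph[ip]),
          center[3] + radii[3] * cos(th[it]))
  }
  tris <- list()
  for (it in seq_len(n_theta)) {
    ipn <- c(seq_len(n_phi)[-1L], 1L)
    a <- pt(it, seq_len(n_phi));     b <- pt(it + 1L, seq_len(n_phi))
    c_ <- pt(it + 1L, ipn);          d <- pt(it, ipn)
    if (it > 1L) tris[[length(tris) + 1L]] <- list(a, b, d)  # upper tri
    if (it < n_theta) tris[[length(tris) + 1L]] <- list(b, c_, d)
  }
  nt <- sum(vapply(tris, function(t) nrow(t[[1L]]), 1L))
  tri <- array(NA_real_, dim = c(nt, 3L, 3L))
  row <- 1L
  for (t in tris) {
    nr <- nrow(t[[1L]])
    for (k in 1:3) tri[row:(row + nr - 1L), k, ] <- t[[k]]
    row <- row + nr
  }
  # orient outward (poles collapse keeps winding consistent; fix by volume)
  if (mesh_volume(new_mesh(tri, units)) < 0) tri <- tri[, c(1L, 3L, 2L), ]
  new_mesh(tri, units)
}

# z-values where vertical rays through the (x, y) points pierce the mesh.
# Returns a list of numeric vectors, one per point. Rays are offset by a
# tiny irrational fraction of `jitter_scale` to dodge edge/vertex grazing;
# the offset is deterministic.
ray_z_hits <- function(mesh, xy, jitter_scale = 0) {
  tri <- mesh$triangles
  nt <- dim(tri)[1L]
  np <- nrow(xy)
  eps <- jitter_scale * 1e-6 * (sqrt(2) - 1)
  px <- xy[, 1L] + eps
  py <- xy[, 2L] + 2 * eps
  hits <- vector("list", np)
  ax <- tri[, 1L, 1L]; ay <- tri[, 1L, 2L]; az <- tri[, 1L, 3L]
  bx <- tri[, 2L, 1L]; by <- tri[, 2L, 2L]; bz <- tri[, 2L, 3L]
  cx <- tri[, 3L, 1L]; cy <- tri[, 3L, 2L]; cz <- tri[, 3L, 3L]
  den <- (by - cy) * (ax - cx) + (cx - bx) * (ay - cy)
  for (t in seq_len(nt)) {
    if (den[t] == 0) next  # triangle parallel to the ray
    inb <- which(px >= min(ax[t], bx[t], cx[t]) - abs(eps) &
                   px <= max(ax[t], bx[t], cx[t]) + abs(eps) &
                   py >= min(ay[t], by[t], cy[t]) - abs(eps) &
                   py <= max(ay[t], by[t], cy[t]) + abs(eps))
    if (!length(inb)) next
    l1 <- ((by[t] - cy[t]) * (px[inb] - cx[t]) +
             (cx[t] - bx[t]) * (py[inb] - cy[t])) / den[t]
    l2 <- ((cy[t] - ay[t]) * (px[inb] - cx[t]) +
             (ax[t] - cx[t]) * (py[inb] - cy[t])) / den[t]
    l3 <- 1 - l1 - l2
    ok <- l1 >= 0 & l2 >= 0 & l3 >= 0
    if (!any(ok)) next
    zin <- l1[ok] * az[t] + l2[ok] * bz[t] + l3[ok] * cz[t]
    for (j in seq_along(zin)) {
      i <- inb[ok][j]
      hits[[i]] <- c(hits[[i]], zin[j])
    }
  }
  hits
}
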