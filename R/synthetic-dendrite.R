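# Dendritic membrane stand-in: a triangulated cylinder (shaft) decorated
# with mushroom spines, each spine a closed surface of revolution (neck +
# head) sitting on the shaft.  A 2D parameterization of the shaft surface
# (axial coordinate x unrolled circumference, periodic) with spines as
# equal-area disk patches is attached for the surface-reaction simulator.

revolve_profile <- function(prof_r, prof_z, n_seg, cap_bottom = TRUE) {
  np <- length(prof_r)
  ang <- 2 * pi * (0:(n_seg - 1)) / n_seg
  verts <- do.call(rbind, lapply(seq_len(np), function(i) {
    if (prof_r[i] == 0) {
      matrix(c(0, 0, prof_z[i]), ncol = 3)
    } else {
      cbind(prof_r[i] * cos(ang), prof_r[i] * sin(ang), prof_z[i])
    }
  }))
  idx <- vector("list", np)
  off <- 0
  for (i in seq_len(np)) {
    if (prof_r[i] == 0) { idx[[i]] <- off + 1; off <- off + 1 }
    else { idx[[i]] <- off + seq_len(n_seg); off <- off + n_seg }
  }
  faces <- list()
  for (i in seq_len(np - 1)) {
    a <- idx[[i]]; b <- idx[[i + 1]]
    if (length(a) == 1 && length(b) == n_seg) {
      faces[[length(faces) + 1]] <-
        cbind(a, b, b[c(2:n_seg, 1)])
    } else if (length(a) == n_seg && length(b) == 1) {
      faces[[length(faces) + 1]] <-
        cbind(a, a[c(2:n_seg, 1)], b)
    } else {
      a2 <- a[c(2:n_seg, 1)]; b2 <- b[c(2:n_seg, 1)]
      faces[[length(faces) + 1]] <- rbind(cbind(a, b, b2), cbind(a, b2, a2))
    }
  }
  if (cap_bottom && prof_r[1] > 0) {
    center <- nrow(verts) + 1
    verts <- rbind(verts, c(0, 0, prof_z[1]))
    a <- idx[[1]]
    faces[[length(faces) + 1]] <- cbind(a[c(2:n_seg, 1)], a, center)
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

triangle_areas <- function(v, f) {
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  u <- p2 - p1; w <- p3 - p1
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Synthetic dendritic membrane with labeled spines
#'
#' Builds a closed triangulated cylinder of the given length and radius
#' (shaft compartment) carrying `n_spines` mushroom spines.  Each spine is a
#' closed surface of revolution (cylindrical neck merged smoothly into a
#' spherical head) placed on the shaft at a seeded random position; its faces
#' are labeled `spine` and grouped by `spine_id`.  Default dimensions are
#' typical for a cortical pyramidal-cell dendrite.
#'
#' @param length shaft length, um.
#' @param radius shaft radius, um.
#' @param n_spines number of spines (>= 0).
#' @param seed integer seed for spine placement.
#' @param head_diameter,neck_diameter,neck_length spine dimensions, um.
#' @param n_seg azimuthal resolution of the triangulation.
#' @return An object of class `membrane_geometry`: list with tibbles
#'   `vertices` (`id, x, y, z`), `faces` (`v1, v2, v3, label, spine_id,
#'   area`), and `param` (the 2D surface parameterization used by the
#'   signaling simulator).
#' @export
#' @examples
#' geom <- synth_dendrite(10, 0.5, n_spines = 4, seed = 1)
#' mesh_area(geom)
synth_dendrite <- function(length = 10, radius = 0.5, n_spines = 10, seed = 1,
                           head_diameter = 0.5, neck_diameter = 0.2,
                           neck_length = 0.5, n_seg = 32) {
  if (length <= 0 || radius <= 0)
    abort("`length` and `radius` must be > 0.", class = "ngf_error_geometry")
  if (n_spines < 0)
    abort("`n_spines` must be >= 0.", class = "ngf_error_geometry")
  head_r <- head_diameter / 2; neck_r <- neck_diameter / 2
  if (n_spines > 0 && neck_r >= head_r)
    abort("spine neck must be narrower than the head.",
          class = "ngf_error_geometry")
  # shaft: cylinder along z in [0, length], closed by end caps
  n_rings <- max(2L, ceiling(length / 0.5) + 1L)
  prof_z <- seq(0, length, length.out = n_rings)
  shaft <- revolve_profile(c(0, rep(radius, n_rings), 0),
                           c(0, prof_z, length), n_seg, cap_bottom = FALSE)
  verts <- shaft$vertices
  faces <- tibble(v1 = shaft$faces[, 1], v2 = shaft$faces[, 2],
                  v3 = shaft$faces[, 3], label = "shaft",
                  spine_id = NA_integer_)
  patches <- tibble(spine_id = integer(), u = double(), v = double(),
                    patch_radius = double(), area = double())
  if (n_spines > 0) {
    # spine profile in local coordinates (z = radial offset from shaft surface)
    z_c <- neck_length + sqrt(head_r^2 - neck_r^2)
    psi_j <- pi - asin(neck_r / head_r)
    psi <- seq(psi_j, 0, length.out = 12)
    prof_r_sp <- c(neck_r, neck_r, head_r * sin(psi))
    prof_z_sp <- c(0, neck_length, z_c + head_r * cos(psi))
    sp_mesh <- revolve_profile(prof_r_sp, prof_z_sp, n_seg = 16,
                               cap_bottom = TRUE)
    pos <- with_seed(seed, {
      u <- (seq_len(n_spines) - 0.5) / n_spines * length +
        runif(n_spines, -0.25, 0.25) * length / n_spines
      u <- pmin(pmax(u, 0.02 * length), 0.98 * length)
      list(u = u, az = runif(n_spines, 0, 2 * pi))
    })
    for (i in seq_len(n_spines)) {
      az <- pos$az[i]
      er <- c(cos(az), sin(az), 0); et <- c(-sin(az), cos(az), 0)
      ez <- c(0, 0, 1)
      local <- sp_mesh$vertices
      world <- cbind(
        radius * er[1] + local[, 1] * et[1] + local[, 3] * er[1],
        radius * er[2] + local[, 1] * et[2] + local[, 3] * er[2],
        pos$u[i] + local[, 2]
      )
      off <- nrow(verts)
      verts <- rbind(verts, world)
      faces <- bind_rows(faces, tibble(
        v1 = sp_mesh$faces[, 1] + off, v2 = sp_mesh$faces[, 2] + off,
        v3 = sp_mesh$faces[, 3] + off, label = "spine", spine_id = i))
      sp_area <- sum(triangle_areas(world - 0,
                                    sp_mesh$faces))
      patches <- bind_rows(patches, tibble(
        spine_id = i, u = pos$u[i], v = radius * az,
        patch_radius = sqrt(sp_area / pi), area = sp_area))
    }
  }
  area <- triangle_areas(as.matrix(verts), as.matrix(faces[, 1:3]))
  faces$area <- area
  out <- list(
    vertices = tibble(id = seq_len(nrow(verts)), x = verts[, 1],
                      y = verts[, 2], z = verts[, 3]),
    faces = faces,
    param = list(length = length, radius = radius,
                 circumference = 2 * pi * radius, spines = patches)
  )
  class(out) <- "membrane_geometry"
  out
}

#' Surface area of a membrane geometry
#'
#' @param geometry a `membrane_geometry`.
#' @param by_label if `TRUE`, return per-compartment areas.
#' @return Total area (um^2), or a tibble `label`, `area` when
#'   `by_label = TRUE`.
#' @export
mesh_area <- function(geometry, by_label = FALSE) {
  stopifnot(inherits(geometry, "membrane_geometry"))
  if (!by_label) return(sum(geometry$faces$area))
  geometry$faces |>
    group_by(.data$label) |>
    summarise(area = sum(.data$area), .groups = "drop")
}

#' Number of connected spine-face components of a membrane geometry
#' @param geometry a `membrane_geometry`.
#' @return Integer count of connected components among spine faces.
#' @export
spine_components <- function(geometry) {
  sp <- geometry$faces[geometry$faces$label == "spine", ]
  if (nrow(sp) == 0) return(0L)
  # union-find over shared vertices
  parent <- seq_len(nrow(geometry$vertices))
  find <- function(i) {
    i <- as.integer(i)
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  for (r in seq_len(nrow(sp))) {
    a <- find(sp$v1[r]); b <- find(sp$v2[r]); cc <- find(sp$v3[r])
    parent[a] <- b; parent[find(b)] <- cc
  }
  roots <- vapply(unique(c(sp$v1, sp$v2, sp$v3)), find, integer(1))
  length(unique(roots))
}

#' Write a membrane geometry as a Wavefront OBJ file
#'
#' Faces are grouped (`g shaft`, `g spine_1`, ...) so compartment labels
#' survive the round trip.
#'
#' @param geometry a `membrane_geometry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(geometry, path) {
  stopifnot(inherits(geometry, "membrane_geometry"))
  con <- file(path, "w")
  on.exit(close(con))
  v <- geometry$vertices
  writeLines(sprintf("v %.6f %.6f %.6f", v$x, v$y, v$z), con)
  f <- geometry$faces
  grp <- ifelse(f$label == "shaft", "shaft", paste0("spine_", f$spine_id))
  for (g in unique(grp)) {
    writeLines(paste0("g ", g), con)
    sel <- f[grp == g, ]
    writeLines(sprintf("f %d %d %d", sel$v1, sel$v2, sel$v3), con)
  }
  invisible(path)
}
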