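# Beam / phantom / panel geometry: divergent-beam footprints on the tilted
# phantom surfaces and their orthographic projections along the magnetic
# field onto the film panels.

deg2rad <- function(deg) deg * pi / 180

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) abort("cannot normalize a zero vector")
  v / n
}

#' Describe the treatment beam
#'
#' A square Co-60 beam delivered at a given gantry angle. The gantry rotates
#' about the magnetic-field axis (`y`); at gantry 0 the beam points straight
#' down (`-z`). The field size is the side of the square field at the
#' isocenter plane and the source sits at `sad` centimetres upstream of the
#' isocenter along the central axis.
#'
#' @param gantry_angle Gantry angle in degrees; any value is accepted and is
#'   normalized to `[0, 360)`.
#' @param field_size Side of the square field at the isocenter, cm.
#' @param sad Source-to-axis distance, cm.
#' @return An object of class `beam_setup`.
#' @examples
#' beam_setup(330, 12.6)
#' @export
beam_setup <- function(gantry_angle, field_size, sad = 105) {
  if (!is.numeric(field_size) || length(field_size) != 1 || field_size < 0)
    abort("`field_size` must be a single non-negative number (cm)")
  if (!is.numeric(sad) || length(sad) != 1 || sad <= 0)
    abort("`sad` must be a single positive number (cm)")
  structure(
    list(gantry_angle = gantry_angle %% 360, field_size = field_size, sad = sad),
    class = "beam_setup"
  )
}

#' Describe the tilted acrylic phantom
#'
#' A rectangular acrylic block whose centre of mass sits at the isocenter.
#' The support tilts the block about the `x` axis so that the entrance
#' surface normal acquires a `+y` (field-direction) component; the tilt angle
#' equals the angle between the beam central axis at gantry 0 and the surface
#' normal.
#'
#' @param tilt_angle Phantom angle in degrees, `0 <= tilt < 90`.
#' @param dimensions Length-3 numeric, cm: extents along the (tilted) box
#'   axes; the third entry is the thickness separating entrance and exit
#'   surfaces.
#' @param density Mass density, g/cm^3.
#' @return An object of class `phantom_setup`.
#' @export
phantom_setup <- function(tilt_angle, dimensions = c(15, 15, 10), density = 1.18) {
  if (!is.numeric(tilt_angle) || length(tilt_angle) != 1 ||
      tilt_angle < 0 || tilt_angle >= 90)
    abort("`tilt_angle` must be a single angle in [0, 90) degrees")
  if (length(dimensions) != 3 || any(dimensions <= 0))
    abort("`dimensions` must be three positive lengths (cm)")
  if (density <= 0) abort("`density` must be positive (g/cm^3)")
  structure(
    list(tilt_angle = tilt_angle, dimensions = as.numeric(dimensions),
         density = density, isocenter_at_center_of_mass = TRUE),
    class = "phantom_setup"
  )
}

#' Describe a scoring panel
#'
#' Film panels stand parallel to the beam central axis and orthogonal to the
#' magnetic field, one on each side of the phantom. The front panel faces the
#' beam-entrance surface (at `y = +distance`), the end panel the beam-exit
#' surface (`y = -distance`).
#'
#' @param side `"front"` or `"end"`.
#' @param distance Distance from the central axis, cm.
#' @param extent Physical panel size, cm pair (u, v).
#' @param pixel_size Scoring pixel size, mm.
#' @return An object of class `panel_setup`.
#' @export
panel_setup <- function(side = c("front", "end"), distance,
                        extent = c(30, 30), pixel_size = 1.36) {
  side <- match.arg(side)
  if (!is.numeric(distance) || length(distance) != 1 || distance <= 0)
    abort("`distance` must be a single positive number (cm)")
  if (length(extent) != 2 || any(extent <= 0))
    abort("`extent` must be two positive lengths (cm)")
  if (pixel_size <= 0) abort("`pixel_size` must be positive (mm)")
  structure(
    list(side = side, distance = distance, extent = as.numeric(extent),
         pixel_size = pixel_size),
    class = "panel_setup"
  )
}

#' Bundle one experimental condition
#'
#' @param beam A [beam_setup()].
#' @param phantom A [phantom_setup()].
#' @param panel A [panel_setup()].
#' @param prescription_dose Dose delivered to the isocenter, cGy.
#' @return An object of class `experiment_condition`.
#' @export
experiment_condition <- function(beam, phantom, panel, prescription_dose = 300) {
  stopifnot(inherits(beam, "beam_setup"), inherits(phantom, "phantom_setup"),
            inherits(panel, "panel_setup"))
  if (prescription_dose <= 0) abort("`prescription_dose` must be positive (cGy)")
  structure(
    list(beam = beam, phantom = phantom, panel = panel,
         prescription_dose = prescription_dose),
    class = "experiment_condition"
  )
}

#' A ray in 3-space
#'
#' @param origin Length-3 numeric, cm.
#' @param direction Length-3 numeric; normalized internally.
#' @return An object of class `ray3`.
#' @export
ray3 <- function(origin, direction) {
  if (length(origin) != 3 || length(direction) != 3)
    abort("`origin` and `direction` must be length-3 numerics")
  structure(list(origin = as.numeric(origin), direction = unitize(direction)),
            class = "ray3")
}

#' A plane in 3-space
#'
#' @param point Any point on the plane, cm.
#' @param normal Plane normal; normalized internally.
#' @return An object of class `plane3`.
#' @export
plane3 <- function(point, normal) {
  if (length(point) != 3 || length(normal) != 3)
    abort("`point` and `normal` must be length-3 numerics")
  structure(list(point = as.numeric(point), normal = unitize(normal)),
            class = "plane3")
}

#' Beam direction and source position
#'
#' @param beam A [beam_setup()].
#' @return `beam_direction()` gives the unit central-axis direction;
#'   `source_position()` the source coordinates (cm).
#' @export
beam_direction <- function(beam) {
  g <- deg2rad(beam$gantry_angle)
  c(sin(g), 0, -cos(g))
}

#' @rdname beam_direction
#' @export
source_position <- function(beam) {
  -beam$sad * beam_direction(beam)
}

#' Corner positions of the field square at the isocenter plane
#'
#' Two conventions are supported. `"isocenter"` (the default, used throughout
#' the published-area reconstruction) places the square flat in the horizontal
#' isocenter plane, corners at `(+-fs/2, +-fs/2, 0)` regardless of gantry
#' angle. `"bev"` is the conventional beam's-eye-view definition: the square
#' lies in the plane through the isocenter perpendicular to the central axis
#' and rotates with the gantry. The two agree at gantry 0.
#'
#' @param beam A [beam_setup()].
#' @param field_plane `"isocenter"` or `"bev"`.
#' @return A 4 x 3 matrix of corner coordinates (cm), in cyclic order.
#' @export
field_corners <- function(beam, field_plane = c("isocenter", "bev")) {
  field_plane <- match.arg(field_plane)
  h <- beam$field_size / 2
  if (field_plane == "isocenter") {
    e1 <- c(1, 0, 0)
    e2 <- c(0, 1, 0)
  } else {
    g <- deg2rad(beam$gantry_angle)
    e1 <- c(cos(g), 0, sin(g))
    e2 <- c(0, 1, 0)
  }
  rbind(h * e1 + h * e2,
        h * e1 - h * e2,
        -h * e1 - h * e2,
        -h * e1 + h * e2)
}

#' Rays from the source through the four field corners
#'
#' @inheritParams field_corners
#' @return A list of four [ray3()] objects in cyclic corner order.
#' @examples
#' rays <- beam_corner_rays(beam_setup(0, 6.3))
#' rays[[1]]$origin   # the source, (0, 0, 105)
#' @export
beam_corner_rays <- function(beam, field_plane = c("isocenter", "bev")) {
  s <- source_position(beam)
  corners <- field_corners(beam, field_plane)
  lapply(seq_len(4), function(i) ray3(s, corners[i, ] - s))
}

#' Entrance or exit surface plane of the tilted phantom
#'
#' The entrance plane passes through `isocenter + (h/2) n`, the exit plane
#' through `isocenter - (h/2) n`, with `h` the phantom thickness and
#' `n = (0, sin tilt, cos tilt)` the tilted surface normal.
#'
#' @param phantom A [phantom_setup()].
#' @param which `"entrance"` or `"exit"`.
#' @return A [plane3()].
#' @export
surface_plane <- function(phantom, which = c("entrance", "exit")) {
  which <- match.arg(which)
  th <- deg2rad(phantom$tilt_angle)
  n <- c(0, sin(th), cos(th))
  h2 <- phantom$dimensions[3] / 2
  p0 <- if (which == "entrance") h2 * n else -h2 * n
  plane3(p0, n)
}

#' Intersect a ray with a plane
#'
#' @param ray A [ray3()].
#' @param plane A [plane3()].
#' @return The intersection point (length-3 numeric, cm), or `NULL` when the
#'   ray is parallel to the plane (within 1e-12) or the intersection lies
#'   behind the ray origin. A miss is a distinct return value, not an error.
#' @export
ray_plane_intersection <- function(ray, plane) {
  den <- sum(plane$normal * ray$direction)
  if (abs(den) < 1e-12) return(NULL)
  t <- sum(plane$normal * (plane$point - ray$origin)) / den
  if (t <= 0) return(NULL)
  ray$origin + t * ray$direction
}

# in-plane orthonormal axes of a tilted surface: a1 along x, a2 down-slope
surface_axes <- function(tilt_angle) {
  th <- deg2rad(tilt_angle)
  list(a1 = c(1, 0, 0), a2 = c(0, cos(th), -sin(th)))
}

# Sutherland-Hodgman clip of a 2D polygon against half-plane a.x <= b
clip_halfplane <- function(pts, a, b) {
  n <- nrow(pts)
  if (n == 0) return(pts)
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    p <- pts[i, ]
    q <- pts[if (i == n) 1L else i + 1L, ]
    dp <- sum(a * p) - b
    dq <- sum(a * q) - b
    if (dp <= 0) out <- rbind(out, p)
    if ((dp < 0) != (dq < 0) && dp != dq) {
      t <- dp / (dp - dq)
      out <- rbind(out, p + t * (q - p))
    }
  }
  out
}

# shoelace area of a simple 2D polygon (absolute value)
shoelace_area <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  xs <- x[c(2:n, 1L)]; ys <- y[c(2:n, 1L)]
  abs(sum(x * ys - xs * y)) / 2
}

#' Beam footprint on a phantom surface
#'
#' Intersects the four field-corner rays with the requested (tilted) surface
#' plane and returns the resulting quadrilateral, optionally clipped to the
#' physical 15 x 15 cm phantom face. The exit surface coincides with the
#' support-plate plane, which extends beyond the phantom face; footprints
#' there are conventionally left unclipped (`clip_to_phantom = FALSE`, the
#' default), matching the published projected-area computation.
#'
#' @param condition An [experiment_condition()], or a list with elements
#'   `beam` and `phantom`.
#' @param which `"entrance"` or `"exit"` surface.
#' @param clip_to_phantom Clip the footprint to the phantom face rectangle?
#' @param field_plane Field-square convention, see [field_corners()].
#' @return An object of class `footprint_polygon` with elements `vertices`
#'   (n x 3 matrix, cm), `plane` ([plane3()]), `local` (n x 2 in-plane
#'   coordinates), and `clipped` (logical).
#' @export
footprint_polygon <- function(condition, which = c("entrance", "exit"),
                              clip_to_phantom = FALSE,
                              field_plane = c("isocenter", "bev")) {
  which <- match.arg(which)
  beam <- condition$beam
  phantom <- condition$phantom
  if (beam$field_size <= 0)
    abort("degenerate footprint: field size is zero")
  pl <- surface_plane(phantom, which)
  rays <- beam_corner_rays(beam, field_plane)
  pts <- vector("list", 4)
  for (i in seq_len(4)) {
    p <- ray_plane_intersection(rays[[i]], pl)
    if (is.null(p))
      abort(sprintf("corner ray %d does not intersect the %s plane", i, which))
    pts[[i]] <- p
  }
  V <- do.call(rbind, pts)
  ax <- surface_axes(phantom$tilt_angle)
  rel <- sweep(V, 2, pl$point)
  P2 <- cbind(rel %*% ax$a1, rel %*% ax$a2)
  if (clip_to_phantom) {
    half <- phantom$dimensions[1:2] / 2
    P2 <- clip_halfplane(P2, c(1, 0), half[1])
    P2 <- clip_halfplane(P2, c(-1, 0), half[1])
    P2 <- clip_halfplane(P2, c(0, 1), half[2])
    P2 <- clip_halfplane(P2, c(0, -1), half[2])
  }
  V <- matrix(pl$point, nrow(P2), 3, byrow = TRUE) +
    P2[, 1] %o% ax$a1 + P2[, 2] %o% ax$a2
  structure(
    list(vertices = V, plane = pl, local = P2, clipped = clip_to_phantom),
    class = "footprint_polygon"
  )
}

#' Projected area of a footprint on the panels
#'
#' Orthographic projection of the footprint polygon along the magnetic-field
#' axis `y` onto a panel plane. Two equivalent computations are carried out
#' and checked against each other: the shoelace area of the vertices'
#' `(x, z)` coordinates, and the in-plane polygon area multiplied by
#' `|n . y|`. The result is independent of the panel distance.
#'
#' @param poly A [footprint_polygon()].
#' @return Projected area in cm^2. An attribute `planar_area` holds the
#'   polygon area in its own plane.
#' @export
projected_area <- function(poly) {
  stopifnot(inherits(poly, "footprint_polygon"))
  a_planar <- shoelace_area(poly$local)
  cosy <- abs(poly$plane$normal[2])
  via_cos <- a_planar * cosy
  via_proj <- shoelace_area(poly$vertices[, c(1, 3), drop = FALSE])
  if (abs(via_cos - via_proj) > 1e-9 * max(1, via_cos))
    abort("internal inconsistency: projection routes disagree")
  structure(via_proj, planar_area = a_planar)
}

#' Default study configuration
#'
#' The factor levels of the panel-dose study: three phantom angles, two field
#' sizes, three gantry angles, two panel distances, both panel sides, 3 Gy
#' prescription.
#'
#' @param tilt_angles,field_sizes,gantry_angles,distances,sides Factor levels.
#' @param prescription_dose cGy per delivery.
#' @param sad Source-to-axis distance, cm.
#' @return A list of class `study_config`.
#' @export
study_config <- function(tilt_angles = c(10, 20, 30),
                         field_sizes = c(6.3, 12.6),
                         gantry_angles = c(0, 30, 330),
                         distances = c(10, 17),
                         sides = c("front", "end"),
                         prescription_dose = 300,
                         sad = 105) {
  structure(
    list(tilt_angles = tilt_angles, field_sizes = field_sizes,
         gantry_angles = gantry_angles, distances = distances, sides = sides,
         prescription_dose = prescription_dose, sad = sad),
    class = "study_config"
  )
}

#' Enumerate the study conditions
#'
#' Expands the study configuration into one row per panel dose distribution,
#' ordered by tilt, then field size, then gantry, then distance, then panel
#' side. The default study yields 36 beam deliveries and 72 panel dose
#' distributions.
#'
#' @param config A [study_config()].
#' @return A tibble with one row per condition and a stable `condition_id`.
#' @examples
#' nrow(enumerate_conditions())  # 72
#' @export
enumerate_conditions <- function(config = study_config()) {
  grid <- tidyr::expand_grid(
    tilt_deg = config$tilt_angles,
    field_size = config$field_sizes,
    gantry_deg = config$gantry_angles,
    distance_cm = config$distances,
    panel = config$sides
  )
  grid %>%
    mutate(
      condition_id = sprintf("t%02d_fs%04.1f_g%03d_d%02d_%s",
                             .data$tilt_deg, .data$field_size,
                             .data$gantry_deg, .data$distance_cm, .data$panel),
      prescription_cGy = config$prescription_dose
    )
}

# build an experiment_condition from one enumerate_conditions() row
condition_from_row <- function(row, config = study_config()) {
  experiment_condition(
    beam = beam_setup(row$gantry_deg, row$field_size, config$sad),
    phantom = phantom_setup(row$tilt_deg),
    panel = panel_setup(row$panel, row$distance_cm),
    prescription_dose = config$prescription_dose
  )
}

#' Projected areas for every study geometry
#'
#' Computes the footprint of each beam on the surface facing each panel
#' (entrance surface for the front panel, exit/support surface for the end
#' panel) and its projected area along the field axis, together with the
#' clipped-footprint area for sensitivity reporting. Projected areas do not
#' depend on the panel distance, so there is one row per
#' (tilt, field size, gantry, panel side).
#'
#' @param config A [study_config()].
#' @param field_plane Field-square convention, see [field_corners()].
#' @return A tibble with columns `tilt_deg`, `field_size`, `gantry_deg`,
#'   `panel`, `plane` (entrance/exit), `planar_area_cm2`, `n_dot_y`,
#'   `area_cm2` (unclipped projected area) and `area_clipped_cm2`.
#' @export
projected_area_table <- function(config = study_config(),
                                 field_plane = c("isocenter", "bev")) {
  field_plane <- match.arg(field_plane)
  grid <- tidyr::expand_grid(
    tilt_deg = config$tilt_angles,
    field_size = config$field_sizes,
    gantry_deg = config$gantry_angles,
    panel = config$sides
  )
  rows <- purrr::pmap(grid, function(tilt_deg, field_size, gantry_deg, panel) {
    which <- if (panel == "front") "entrance" else "exit"
    cond <- list(beam = beam_setup(gantry_deg, field_size, config$sad),
                 phantom = phantom_setup(tilt_deg))
    fp <- footprint_polygon(cond, which, clip_to_phantom = FALSE,
                            field_plane = field_plane)
    fpc <- footprint_polygon(cond, which, clip_to_phantom = TRUE,
                             field_plane = field_plane)
    a <- projected_area(fp)
    tibble(
      tilt_deg = tilt_deg, field_size = field_size, gantry_deg = gantry_deg,
      panel = panel, plane = which,
      planar_area_cm2 = attr(a, "planar_area"),
      n_dot_y = abs(fp$plane$normal[2]),
      area_cm2 = as.numeric(a),
      area_clipped_cm2 = as.numeric(projected_area(fpc))
    )
  })
  bind_rows(rows)
}
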