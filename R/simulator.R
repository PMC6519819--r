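# Desk-scale Monte Carlo of the air-electron stream: Co-60 photons from a
# point source, exponential attenuation in the tilted acrylic geometry
# (phantom block plus the support plate it rests on), one Klein-Nishina
# Compton scatter per interacting photon, straight-line CSDA electron escape,
# then analytic helical transport along the 0.35 T field to the scoring
# panels. Air is treated as vacuum for the electron flight (CSDA ranges of
# sub-MeV electrons in air are metres, far beyond the 10-17 cm panel
# distances).
#
# The support plate matters for the directional balance: electrons forming
# the end-panel stream enter the air from the underside of the plate at the
# exit beam cross-section, while the plate also intercepts electrons that
# gyrate back towards the assembly. Without it the simulated front/end
# balance inverts.

# rotation rows taking world coordinates to the tilted assembly frame
# (axes: a1 = x, a2 = down-slope, a3 = surface normal)
phantom_basis <- function(tilt_angle) {
  th <- deg2rad(tilt_angle)
  rbind(c(1, 0, 0),
        c(0, cos(th), -sin(th)),
        c(0, sin(th), cos(th)))
}

# world (n x 3) -> assembly-local coordinates
to_local <- function(xyz, basis) xyz %*% t(basis)

#' Describe the support plate under the phantom
#'
#' The acrylic plate the phantom rests on, coplanar with the phantom's exit
#' surface and tilted with it. Electrons reaching the end panel enter the air
#' from the plate's underside at the exit-beam cross-section; the plate also
#' absorbs electrons whose helices curl back onto the assembly. Dimensions
#' are not critical and default to a 20 x 20 cm, 1 cm thick plate.
#'
#' @param thickness Plate thickness, cm.
#' @param extent In-plane extent (a1, a2 axes), cm pair.
#' @return An object of class `support_setup`, or `NULL` to simulate the
#'   bare phantom.
#' @export
support_setup <- function(thickness = 1, extent = c(20, 20)) {
  if (thickness <= 0 || any(extent <= 0))
    abort("support plate dimensions must be positive (cm)")
  structure(list(thickness = thickness, extent = as.numeric(extent)),
            class = "support_setup")
}

# axis-aligned boxes (local-frame lo/hi corners) of the assembly
assembly_boxes <- function(phantom, support = NULL) {
  half <- phantom$dimensions / 2
  boxes <- list(list(lo = -half, hi = half))
  if (!is.null(support)) {
    eh <- support$extent / 2
    boxes <- c(boxes, list(list(
      lo = c(-eh[1], -eh[2], -half[3] - support$thickness),
      hi = c(eh[1], eh[2], -half[3])
    )))
  }
  boxes
}

# slab-method ray/box intersection, vectorized over rays.
# Returns entry and exit parameters; miss encoded as t_in > t_out.
ray_box_span <- function(o_local, d_local, lo, hi) {
  n <- nrow(o_local)
  t_in <- rep(-Inf, n)
  t_out <- rep(Inf, n)
  for (ax in 1:3) {
    o <- o_local[, ax]; d <- d_local[, ax]
    par <- abs(d) < 1e-12
    t1 <- (lo[ax] - o) / d
    t2 <- (hi[ax] - o) / d
    a <- pmin(t1, t2); b <- pmax(t1, t2)
    if (any(par)) {
      in_slab <- o[par] >= lo[ax] & o[par] <= hi[ax]
      a[par] <- ifelse(in_slab, -Inf, Inf)
      b[par] <- ifelse(in_slab, Inf, -Inf)
    }
    t_in <- pmax(t_in, a)
    t_out <- pmin(t_out, b)
  }
  list(t_in = t_in, t_out = t_out)
}

# material intervals (ahead of t = 0) of the assembly along each ray:
# up to two boxes sharing a face, merged when contiguous. Returns the first
# contiguous material block [a1, b1] (a1 = Inf when no material ahead) plus
# a possible later block [a2, b2].
material_blocks <- function(o_local, d_local, boxes) {
  n <- nrow(o_local)
  spans <- lapply(boxes, function(bx) {
    s <- ray_box_span(o_local, d_local, bx$lo, bx$hi)
    a <- pmax(s$t_in, 0)
    b <- s$t_out
    miss <- !(b > a)
    a[miss] <- Inf
    b[miss] <- Inf
    list(a = a, b = b)
  })
  if (length(spans) == 1) {
    return(list(a1 = spans[[1]]$a, b1 = spans[[1]]$b,
                a2 = rep(Inf, n), b2 = rep(Inf, n)))
  }
  first_is_1 <- spans[[1]]$a <= spans[[2]]$a
  a1 <- ifelse(first_is_1, spans[[1]]$a, spans[[2]]$a)
  b1 <- ifelse(first_is_1, spans[[1]]$b, spans[[2]]$b)
  a2 <- ifelse(first_is_1, spans[[2]]$a, spans[[1]]$a)
  b2 <- ifelse(first_is_1, spans[[2]]$b, spans[[1]]$b)
  # merge contiguous/overlapping blocks (shared face)
  touch <- is.finite(a2) & a2 <= b1 + 1e-9
  b1[touch] <- pmax(b1[touch], b2[touch])
  a2[touch] <- Inf
  b2[touch] <- Inf
  list(a1 = a1, b1 = b1, a2 = a2, b2 = b2)
}

#' Sample primary photons from the beam
#'
#' Rays run from the point source through positions drawn uniformly over the
#' field square at the isocenter plane; energies are drawn from the
#' configured line spectrum.
#'
#' @param beam A [beam_setup()].
#' @param physics A [physics_config()].
#' @param n Number of photons.
#' @param field_plane Field-square convention, see [field_corners()].
#' @return A list with `origin` (source, length 3), `direction` (n x 3 unit
#'   rows), `energy_mev` (length n) and `target` (n x 2 sampled in-plane
#'   offsets).
#' @export
sample_photon <- function(beam, physics = physics_config(), n,
                          field_plane = c("isocenter", "bev")) {
  field_plane <- match.arg(field_plane)
  s <- source_position(beam)
  h <- beam$field_size / 2
  u1 <- runif(n, -h, h)
  u2 <- runif(n, -h, h)
  if (field_plane == "isocenter") {
    pts <- cbind(u1, u2, 0)
  } else {
    g <- deg2rad(beam$gantry_angle)
    e1 <- c(cos(g), 0, sin(g))
    pts <- cbind(u1 * e1[1], u2, u1 * e1[3])
  }
  d <- sweep(pts, 2, s)
  d <- d / sqrt(rowSums(d^2))
  line <- sample.int(nrow(physics$photon_lines), n, replace = TRUE,
                     prob = physics$photon_lines[, 2])
  list(origin = s, direction = d,
       energy_mev = physics$photon_lines[line, 1], target = cbind(u1, u2))
}

#' Sample photon interaction points in the phantom assembly
#'
#' Draws an exponential free path in material length along each ray's chords
#' through the phantom (and support plate, when given); photons whose path
#' exceeds the total material length pass through. Air gaps between the
#' blocks do not consume free path.
#'
#' @param origin Source position (shared), length 3.
#' @param direction n x 3 unit directions.
#' @param energy_mev Photon energies (selects the attenuation coefficient).
#' @param phantom A [phantom_setup()].
#' @param physics A [physics_config()].
#' @param support A [support_setup()] or `NULL`.
#' @return A list with logical `interacts`, `point` (n x 3, NA rows for
#'   pass-throughs) and the `mu` used per photon.
#' @export
sample_interaction <- function(origin, direction, energy_mev, phantom,
                               physics = physics_config(), support = NULL) {
  n <- nrow(direction)
  basis <- phantom_basis(phantom$tilt_angle)
  boxes <- assembly_boxes(phantom, support)
  o_l <- to_local(matrix(origin, n, 3, byrow = TRUE), basis)
  d_l <- to_local(direction, basis)
  blk <- material_blocks(o_l, d_l, boxes)
  len1 <- pmax(blk$b1 - blk$a1, 0)
  len1[!is.finite(len1)] <- 0
  len2 <- pmax(blk$b2 - blk$a2, 0)
  len2[!is.finite(len2)] <- 0
  mu_key <- format(energy_mev, trim = TRUE)
  mu <- unname(physics$phantom_attenuation[mu_key])
  if (anyNA(mu))
    abort("no attenuation coefficient configured for a sampled photon line")
  path <- rexp(n) / mu
  interacts <- path <= len1 + len2
  tt <- ifelse(path <= len1, blk$a1 + path, blk$a2 + (path - len1))
  point <- matrix(NA_real_, n, 3)
  if (any(interacts)) {
    point[interacts, ] <- matrix(origin, sum(interacts), 3, byrow = TRUE) +
      direction[interacts, , drop = FALSE] * tt[interacts]
  }
  list(interacts = interacts, point = point, mu = mu)
}

# orthonormal transverse basis for each row-direction d (n x 3)
transverse_basis <- function(d) {
  n <- nrow(d)
  helper <- matrix(rep(c(1, 0, 0), n), n, 3, byrow = TRUE)
  swap <- abs(d[, 1]) > 0.9
  if (any(swap))
    helper[swap, ] <- matrix(c(0, 1, 0), sum(swap), 3, byrow = TRUE)
  u1 <- cbind(d[, 2] * helper[, 3] - d[, 3] * helper[, 2],
              d[, 3] * helper[, 1] - d[, 1] * helper[, 3],
              d[, 1] * helper[, 2] - d[, 2] * helper[, 1])
  u1 <- u1 / sqrt(rowSums(u1^2))
  u2 <- cbind(d[, 2] * u1[, 3] - d[, 3] * u1[, 2],
              d[, 3] * u1[, 1] - d[, 1] * u1[, 3],
              d[, 1] * u1[, 2] - d[, 2] * u1[, 1])
  list(u1 = u1, u2 = u2)
}

# electron directions from photon directions and scatter angles
electron_directions <- function(photon_dir, polar, azimuth) {
  tb <- transverse_basis(photon_dir)
  cp <- cos(polar); sp <- sin(polar)
  photon_dir * cp + (tb$u1 * cos(azimuth) + tb$u2 * sin(azimuth)) * sp
}

# outward world-frame surface normal of the assembly face nearest each point
exit_face_normals <- function(points, phantom, support = NULL) {
  basis <- phantom_basis(phantom$tilt_angle)
  boxes <- assembly_boxes(phantom, support)
  L <- to_local(points, basis)
  n <- nrow(L)
  best_dist <- rep(Inf, n)
  face_axis <- rep(1L, n)
  face_sign <- rep(1, n)
  for (bx in boxes) {
    # only points on/near this box's closure can exit through its faces
    margin <- 1e-6
    inb <- L[, 1] >= bx$lo[1] - margin & L[, 1] <= bx$hi[1] + margin &
      L[, 2] >= bx$lo[2] - margin & L[, 2] <= bx$hi[2] + margin &
      L[, 3] >= bx$lo[3] - margin & L[, 3] <= bx$hi[3] + margin
    for (ax in 1:3) {
      dlo <- abs(L[, ax] - bx$lo[ax])
      dhi <- abs(L[, ax] - bx$hi[ax])
      cand <- pmin(dlo, dhi)
      upd <- inb & cand < best_dist
      best_dist[upd] <- cand[upd]
      face_axis[upd] <- ax
      face_sign[upd] <- ifelse(dlo[upd] <= dhi[upd], -1, 1)
    }
  }
  local_normal <- matrix(0, n, 3)
  local_normal[cbind(seq_len(n), face_axis)] <- face_sign
  local_normal %*% basis
}

# uniform directions on the sphere
isotropic_directions <- function(n) {
  cz <- runif(n, -1, 1)
  sz <- sqrt(1 - cz^2)
  phi <- runif(n, 0, 2 * pi)
  cbind(sz * cos(phi), sz * sin(phi), cz)
}

# cosine-weighted (Lambertian) directions about per-row outward normals:
# the surrogate for multiple-scattering angular diffusion inside the acrylic
cosine_lobe_directions <- function(normals) {
  n <- nrow(normals)
  tb <- transverse_basis(normals)
  uu <- runif(n)
  phi <- runif(n, 0, 2 * pi)
  rho <- sqrt(uu)
  normals * sqrt(1 - uu) + (tb$u1 * cos(phi) + tb$u2 * sin(phi)) * rho
}

#' Transport electrons to the assembly surface
#'
#' Straight-line continuous-slowing-down transport: an electron escapes when
#' the material thickness ahead of it (through the phantom and, when present,
#' the contiguous support plate) is shorter than its CSDA range, and exits
#' with the energy whose residual range equals the range left at the surface.
#' An electron whose first air crossing is followed by more material further
#' along its straight line is still considered escaped at the first surface
#' (its subsequent flight is helical and handled by the re-entry cull).
#'
#' @param point n x 3 starting positions inside the assembly (cm).
#' @param direction n x 3 unit directions.
#' @param kinetic_mev Starting kinetic energies.
#' @param phantom A [phantom_setup()].
#' @param physics A [physics_config()].
#' @param support A [support_setup()] or `NULL`.
#' @return A list with logical `escapes`, `exit_point` (n x 3), and
#'   `exit_energy_mev`.
#' @export
propagate_electron_to_surface <- function(point, direction, kinetic_mev,
                                          phantom,
                                          physics = physics_config(),
                                          support = NULL) {
  n <- nrow(point)
  basis <- phantom_basis(phantom$tilt_angle)
  boxes <- assembly_boxes(phantom, support)
  o_l <- to_local(point, basis)
  d_l <- to_local(direction, basis)
  blk <- material_blocks(o_l, d_l, boxes)
  # starting inside material: the first block begins at 0
  depth <- blk$b1
  range_cm <- csda_range_cm(kinetic_mev, physics)
  escapes <- is.finite(depth) & depth >= 0 & depth < range_cm
  exit_point <- matrix(NA_real_, n, 3)
  exit_energy <- rep(NA_real_, n)
  if (any(escapes)) {
    exit_point[escapes, ] <- point[escapes, , drop = FALSE] +
      direction[escapes, , drop = FALSE] * depth[escapes]
    residual <- range_cm[escapes] - depth[escapes]
    exit_energy[escapes] <- csda_energy_mev(residual, physics)
  }
  list(escapes = escapes, exit_point = exit_point,
       exit_energy_mev = exit_energy)
}

#' Helical electron transport to a panel plane
#'
#' Analytic helix in a uniform field along `+y`: the `y` velocity component
#' is constant and the transverse motion is circular with gyroradius
#' `p_perp / (e B)`. An electron reaches the panel at `y = signed_distance`
#' only when its `y` velocity points towards it; the first crossing point is
#' returned. With `reentry_check`, helices are sampled at 36 points per turn
#' (up to 30 turns) and electrons whose path re-enters the phantom assembly
#' are culled. With `b_field = 0` the flight is a straight line and no
#' culling is needed (a straight path leaving the convex blocks cannot
#' re-enter them).
#'
#' @param position n x 3 starting positions in air (cm).
#' @param direction n x 3 unit directions.
#' @param kinetic_mev Kinetic energies, MeV.
#' @param b_field Tesla.
#' @param signed_distance Panel plane `y` coordinate (`+d` front, `-d` end).
#' @param phantom A [phantom_setup()] for the re-entry check, or `NULL` to
#'   skip it.
#' @param reentry_check Cull electrons that would re-enter the assembly?
#' @param support A [support_setup()] or `NULL`.
#' @param floor_z Height (cm) of the horizontal base/couch surface under the
#'   assembly; flight paths dipping below it are absorbed. `NULL` disables.
#' @return A list with logical `hits`, and `u`, `v` crossing coordinates
#'   (`x`, `z` at the panel plane) for the hitting electrons (NA otherwise).
#' @export
helix_to_panel <- function(position, direction, kinetic_mev, b_field,
                           signed_distance, phantom = NULL,
                           reentry_check = TRUE, support = NULL,
                           floor_z = -11) {
  n <- nrow(position)
  dy <- direction[, 2]
  dely <- signed_distance - position[, 2]
  towards <- abs(dy) >= 1e-9 & sign(dy) == sign(dely)
  u <- rep(NA_real_, n)
  v <- rep(NA_real_, n)
  if (!any(towards)) return(list(hits = towards, u = u, v = v))

  if (b_field <= 0) {
    tpar <- dely / dy
    u[towards] <- position[towards, 1] + direction[towards, 1] * tpar[towards]
    v[towards] <- position[towards, 3] + direction[towards, 3] * tpar[towards]
    hits <- towards & !is.na(u)
    if (!is.null(floor_z)) {
      # straight path: z is monotone, so it dips below the couch iff either
      # endpoint does
      low <- hits & (position[, 3] < floor_z | v < floor_z)
      hits[low] <- FALSE
      u[low] <- NA_real_
      v[low] <- NA_real_
    }
    return(list(hits = hits, u = u, v = v))
  }

  pc <- electron_momentum_mev(kinetic_mev)
  dperp <- sqrt(direction[, 1]^2 + direction[, 3]^2)
  r <- gyroradius_cm(pc * dperp, b_field)
  straight <- dperp < 1e-12
  # gyration phase swept while advancing dely in y
  phase <- ifelse(straight, 0, (dperp / dy) * (dely / r))
  ux <- ifelse(straight, 0, direction[, 1] / dperp)
  uz <- ifelse(straight, 0, direction[, 3] / dperp)
  sel <- which(towards)
  u[sel] <- position[sel, 1] +
    r[sel] * (ux[sel] * sin(phase[sel]) + uz[sel] * (1 - cos(phase[sel])))
  v[sel] <- position[sel, 3] +
    r[sel] * (uz[sel] * sin(phase[sel]) - ux[sel] * (1 - cos(phase[sel])))
  hits <- towards & !is.na(u)
  if (!is.null(floor_z)) {
    # gyration keeps z within 2r of launch; a cheap conservative bound first,
    # exact oscillation handled with the sampled points below
    low <- hits & straight & position[, 3] < floor_z
    hits[low] <- FALSE
    u[low] <- NA_real_
    v[low] <- NA_real_
  }

  if ((reentry_check || !is.null(floor_z)) && !is.null(phantom) && any(hits)) {
    basis <- phantom_basis(phantom$tilt_angle)
    boxes <- assembly_boxes(phantom, support)
    # straight (+-y) flights leave the convex blocks for good; only gyrating
    # electrons can curl back in
    sel <- which(hits & !straight)
    chunk <- 20000L
    for (start in if (length(sel)) seq(1, length(sel), by = chunk) else integer(0)) {
      ii <- sel[start:min(start + chunk - 1L, length(sel))]
      # sample the flight at 36 points per turn, capped at 30 turns
      ph_cap <- pmin(abs(phase[ii]), 30 * 2 * pi) * sign(phase[ii])
      maxpts <- max(pmax(ceiling(abs(ph_cap) / (2 * pi)) * 36L, 8L))
      frac <- (seq_len(maxpts) - 0.5) / maxpts
      # rows electrons, cols samples along flight
      PH <- outer(ph_cap, frac)
      X <- position[ii, 1] + r[ii] * (ux[ii] * sin(PH) + uz[ii] * (1 - cos(PH)))
      Z <- position[ii, 3] + r[ii] * (uz[ii] * sin(PH) - ux[ii] * (1 - cos(PH)))
      Y <- position[ii, 2] + (dy[ii] * r[ii] / dperp[ii]) * PH
      # local frame inside-assembly test at every sample
      L1 <- X  # basis[1, ] = (1, 0, 0)
      L2 <- Y * basis[2, 2] + Z * basis[2, 3]
      L3 <- Y * basis[3, 2] + Z * basis[3, 3]
      bad <- rep(FALSE, length(ii))
      if (reentry_check) {
        for (bx in boxes) {
          inside <- L1 > bx$lo[1] + 1e-9 & L1 < bx$hi[1] - 1e-9 &
            L2 > bx$lo[2] + 1e-9 & L2 < bx$hi[2] - 1e-9 &
            L3 > bx$lo[3] + 1e-9 & L3 < bx$hi[3] - 1e-9
          bad <- bad | rowSums(inside) > 0
        }
      }
      if (!is.null(floor_z))
        bad <- bad | rowSums(Z < floor_z) > 0
      hits[ii[bad]] <- FALSE
      u[ii[bad]] <- NA_real_
      v[ii[bad]] <- NA_real_
    }
  }
  list(hits = hits, u = u, v = v)
}

# bin energies onto a panel raster
score_panel <- function(u, v, weight, panel) {
  px <- panel$pixel_size / 10
  nu <- floor(panel$extent[1] / px)
  nv <- floor(panel$extent[2] / px)
  width_u <- nu * px
  width_v <- nv * px
  iu <- floor((u + width_u / 2) / px) + 1L
  iv <- floor((v + width_v / 2) / px) + 1L
  ok <- !is.na(iu) & iu >= 1L & iu <= nu & iv >= 1L & iv <= nv
  m <- matrix(0, nv, nu)
  if (any(ok)) {
    lin <- (iu[ok] - 1L) * nv + iv[ok]
    agg <- rowsum(weight[ok], lin)
    m[as.integer(rownames(agg))] <- agg[, 1]
  }
  list(values = m, hit_count = sum(ok),
       origin = c(-width_u / 2 + px / 2, -width_v / 2 + px / 2))
}

#' Simulate one experimental condition
#'
#' Runs the full chain photon -> interaction in the phantom assembly ->
#' Compton electron -> surface escape -> helical flight -> panel scoring,
#' for both panels of one beam delivery. Panel rasters accumulate
#' escaped-electron kinetic energy (or counts with `score = "fluence"`);
#' maps are normalized so that the Compton-electron energy density released
#' in a 1 cm^3 voxel at the isocenter corresponds to the prescription dose.
#'
#' @param condition An [experiment_condition()]; the panel element sets the
#'   distance and raster while both sides are always scored.
#' @param physics A [physics_config()].
#' @param n_photons Number of primary photons.
#' @param seed RNG seed (the simulation is deterministic given the seed).
#' @param score `"energy"` or `"fluence"`.
#' @param reentry_check Cull electrons whose helix re-enters the assembly.
#' @param support A [support_setup()] (default) or `NULL` for the bare
#'   phantom.
#' @param split Surface-splitting factor: each escaping electron is
#'   replicated this many times with independent emission draws, each
#'   carrying `1/split` of the weight. Pure variance reduction for the panel
#'   maps; expectations are unchanged.
#' @param compton_split Interaction-splitting factor: each interacting photon
#'   spawns this many independent Compton electrons at `1/compton_split`
#'   weight. Also pure variance reduction; it multiplies the number of
#'   distinct escaping electrons without extra photon histories.
#' @param floor_z Height (cm) of the horizontal base/couch plane absorbing
#'   electrons that fly below it; `NULL` removes it.
#' @param emission Exit-direction model. `"diffuse"` (default) redraws each
#'   escaping electron's direction from a cosine-weighted lobe about the
#'   outward normal of its exit face, a surrogate for the angular diffusion
#'   that multiple scattering produces inside the acrylic; `"ballistic"`
#'   keeps the straight-line Compton direction (no angular diffusion, which
#'   starves the field-axis escape cone: single-scatter kinematics only give
#'   large field-axis velocity components to electrons whose energy vanishes).
#' @param chunk_size Photons per internal batch (memory control only; does
#'   not change results for a fixed seed).
#' @return An object of class `sim_result` with `front_map` and `end_map`
#'   ([dose_map()]s in cGy), `isocenter_score` (MeV), `escaped_count`,
#'   `panel_hit_counts`, `normalization`, and the inputs. Use [glance()] for
#'   a one-row summary.
#' @export
simulate_condition <- function(condition, physics = physics_config(),
                               n_photons = 1e5, seed = 1,
                               score = c("energy", "fluence"),
                               reentry_check = TRUE,
                               support = support_setup(),
                               emission = c("diffuse", "ballistic"),
                               floor_z = -11,
                               split = 16L,
                               compton_split = 1L,
                               chunk_size = 250000L) {
  score <- match.arg(score)
  emission <- match.arg(emission)
  split <- max(1L, as.integer(split))
  compton_split <- max(1L, as.integer(compton_split))
  stopifnot(inherits(condition, "experiment_condition"))
  if (n_photons < 1) abort("`n_photons` must be at least 1")
  set.seed(seed)
  beam <- condition$beam
  phantom <- condition$phantom
  dist <- condition$panel$distance
  panel_front <- panel_setup("front", dist, condition$panel$extent,
                             condition$panel$pixel_size)
  panel_end <- panel_setup("end", dist, condition$panel$extent,
                           condition$panel$pixel_size)

  acc_front <- NULL
  acc_end <- NULL
  iso_score <- 0
  escaped <- 0L
  hits_front <- 0L
  hits_end <- 0L
  origin_front <- NULL
  origin_end <- NULL

  remaining <- n_photons
  while (remaining > 0) {
    n <- as.integer(min(remaining, chunk_size))
    remaining <- remaining - n

    ph <- sample_photon(beam, physics, n)
    ia <- sample_interaction(ph$origin, ph$direction, ph$energy_mev,
                             phantom, physics, support = support)
    if (!any(ia$interacts)) next
    pt <- ia$point[ia$interacts, , drop = FALSE]
    pdir <- ph$direction[ia$interacts, , drop = FALSE]
    pE <- ph$energy_mev[ia$interacts]
    if (compton_split > 1) {
      ridx <- rep(seq_len(nrow(pt)), each = compton_split)
      pt <- pt[ridx, , drop = FALSE]
      pdir <- pdir[ridx, , drop = FALSE]
      pE <- pE[ridx]
    }

    cs <- sample_compton(pE, physics)
    eT <- cs$electron_kinetic_mev
    # isocenter kerma proxy: electron energy released in the central voxel
    in_vox <- abs(pt[, 1]) <= 0.5 & abs(pt[, 2]) <= 0.5 & abs(pt[, 3]) <= 0.5
    iso_score <- iso_score + sum(eT[in_vox]) / compton_split

    live <- eT > 1e-4  # drop sub-0.1 keV electrons
    pt <- pt[live, , drop = FALSE]
    pdir <- pdir[live, , drop = FALSE]
    eT <- eT[live]
    if (length(eT) == 0) next
    edir <- electron_directions(pdir, cs$electron_polar[live],
                                cs$electron_azimuth[live])
    # multiple-scattering surrogate: a fraction of electrons random-walk far
    # enough that their net transport direction is effectively isotropic
    if (physics$transport_isotropic_fraction > 0) {
      iso <- runif(length(eT)) < physics$transport_isotropic_fraction
      if (any(iso)) edir[iso, ] <- isotropic_directions(sum(iso))
    }

    esc <- propagate_electron_to_surface(pt, edir, eT, phantom, physics,
                                         support = support)
    if (!any(esc$escapes)) next
    escaped <- escaped + sum(esc$escapes) / compton_split
    xp <- esc$exit_point[esc$escapes, , drop = FALSE]
    xdir <- edir[esc$escapes, , drop = FALSE]
    xE <- esc$exit_energy_mev[esc$escapes]
    # surface splitting: replicate each escaping electron with independent
    # emission draws at 1/split weight (variance reduction; expectations
    # unchanged)
    if (split > 1) {
      rep_idx <- rep(seq_len(nrow(xp)), each = split)
      xp <- xp[rep_idx, , drop = FALSE]
      xdir <- xdir[rep_idx, , drop = FALSE]
      xE <- xE[rep_idx]
    }
    if (emission == "diffuse") {
      normals <- exit_face_normals(xp, phantom, support)
      xdir <- cosine_lobe_directions(normals)
    }

    for (side in c("front", "end")) {
      sd_panel <- if (side == "front") dist else -dist
      hx <- helix_to_panel(xp, xdir, xE, physics$b_field, sd_panel,
                           phantom = phantom, reentry_check = reentry_check,
                           support = support, floor_z = floor_z)
      keep <- hx$hits
      w_energy <- xE
      uu <- hx$u
      vv <- hx$v
      if (physics$air_interactions == "csda") {
        # helical path length to the panel: |delta y| / |dy-hat|
        path <- abs((sd_panel - xp[, 2]) / xdir[, 2])
        rng_air <- csda_range_cm(xE, physics, physics$air_density)
        keep <- keep & rng_air > path
        w_energy <- rep(0, length(xE))
        if (any(keep)) {
          w_energy[keep] <- csda_energy_mev(
            pmax(rng_air[keep] - path[keep], 1e-9), physics,
            physics$air_density)
          # multiple scattering in air (Highland): without the field the
          # lateral spread grows with the whole flight path; with it the
          # magnetic confinement bounds the guiding-centre wander to the
          # gyroradius scale
          e_mid <- (xE[keep] + w_energy[keep]) / 2
          pc_mid <- electron_momentum_mev(e_mid)
          beta_cp <- pc_mid^2 / (e_mid + ELECTRON_REST_MEV)
          xfrac <- pmax(path[keep], 1e-6) / AIR_RADIATION_LENGTH_CM
          theta0 <- pmax(13.6 / beta_cp * sqrt(xfrac) *
                           (1 + 0.038 * log(xfrac)), 0)
          sig <- if (physics$b_field > 0) {
            theta0 * gyroradius_cm(pc_mid, physics$b_field)
          } else {
            theta0 * path[keep] / sqrt(3)
          }
          uu[keep] <- uu[keep] + rnorm(sum(keep), 0, sig)
          vv[keep] <- vv[keep] + rnorm(sum(keep), 0, sig)
        }
      }
      if (!any(keep)) next
      w <- if (score == "energy") w_energy[keep] else rep(1, sum(keep))
      sc <- score_panel(uu[keep], vv[keep], w / (split * compton_split),
                        if (side == "front") panel_front else panel_end)
      if (side == "front") {
        acc_front <- if (is.null(acc_front)) sc$values else acc_front + sc$values
        hits_front <- hits_front + sc$hit_count
        origin_front <- sc$origin
      } else {
        acc_end <- if (is.null(acc_end)) sc$values else acc_end + sc$values
        hits_end <- hits_end + sc$hit_count
        origin_end <- sc$origin
      }
    }
  }

  if (iso_score <= 0)
    abort("normalization error: no Compton energy released in the isocenter voxel")

  px <- condition$panel$pixel_size / 10
  nu <- floor(condition$panel$extent[1] / px)
  nv <- floor(condition$panel$extent[2] / px)
  default_origin <- c(-nu * px / 2 + px / 2, -nv * px / 2 + px / 2)
  if (is.null(acc_front)) {
    acc_front <- matrix(0, nv, nu)
    origin_front <- default_origin
  }
  if (is.null(acc_end)) {
    acc_end <- matrix(0, nv, nu)
    origin_end <- default_origin
  }
  # cGy per (MeV per pixel): prescription anchored to the isocenter energy
  # density, with a 1 cm effective scoring depth on the panel
  norm <- condition$prescription_dose / iso_score / ((px^2) * 1.0)
  mk_map <- function(vals, origin, side) {
    dose_map(vals * norm, condition$panel$pixel_size, origin,
             label = sprintf("simulated %s panel (d=%g cm, tilt %g, FS %g, g %g)",
                             side, dist, phantom$tilt_angle, beam$field_size,
                             beam$gantry_angle))
  }
  structure(
    list(front_map = mk_map(acc_front, origin_front, "front"),
         end_map = mk_map(acc_end, origin_end, "end"),
         isocenter_score = iso_score,
         escaped_count = escaped,
         panel_hit_counts = c(front = hits_front, end = hits_end),
         normalization = norm, n_photons = n_photons, seed = seed,
         score = score, condition = condition),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %g photons, %g escaped electrons, hits front/end %d/%d\n",
              x$n_photons, x$escaped_count, x$panel_hit_counts[1],
              x$panel_hit_counts[2]))
  invisible(x)
}

#' @rdname simulate_condition
#' @param x,object A `sim_result`.
#' @param ... Unused.
#' @method glance sim_result
#' @export
glance.sim_result <- function(x, ...) {
  tibble(
    n_photons = x$n_photons, seed = x$seed,
    escaped = x$escaped_count,
    hits_front = unname(x$panel_hit_counts["front"]),
    hits_end = unname(x$panel_hit_counts["end"]),
    isocenter_score_mev = x$isocenter_score,
    front_dr1_cGy = mean_dose_in_circle(x$front_map, radius = 1),
    end_dr1_cGy = mean_dose_in_circle(x$end_map, radius = 1)
  )
}
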