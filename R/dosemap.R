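# Planar absolute-dose distributions: construction, text-grid and image I/O,
# rebinning, and the panel summary metrics (circle averages and isodose areas).

#' Create a planar dose map
#'
#' A 2D grid of absolute dose in cGy on a square-pixel raster. Rows index the
#' panel-local `v` axis and columns the `u` axis; `origin` gives the physical
#' `(u, v)` coordinates (cm) of the centre of pixel `[1, 1]`.
#'
#' @param values Numeric matrix of doses, cGy; all finite and non-negative,
#'   at least 2 x 2.
#' @param pixel_size Pixel pitch, mm (isotropic).
#' @param origin Physical coordinates (cm) of the first pixel centre.
#' @param label Free-text description.
#' @return An object of class `dose_map`.
#' @examples
#' m <- dose_map(matrix(runif(64, 0, 10), 8, 8), pixel_size = 1.36)
#' max_point(m)
#' @export
dose_map <- function(values, pixel_size, origin = c(0, 0), label = "") {
  values <- as.matrix(values)
  if (nrow(values) < 2 || ncol(values) < 2)
    abort("a dose map needs at least 2 x 2 pixels")
  if (!all(is.finite(values)))
    abort("dose values must all be finite")
  if (any(values < 0))
    abort("dose values must be non-negative (cGy)")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    abort("`pixel_size` must be a single positive number (mm)")
  if (length(origin) != 2) abort("`origin` must be a (u, v) pair in cm")
  structure(
    list(values = unname(values), pixel_size = pixel_size,
         origin = as.numeric(origin), label = as.character(label)),
    class = "dose_map"
  )
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("<dose_map> %d x %d px @ %.4g mm%s\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              if (nzchar(x$label)) paste0("  [", x$label, "]") else ""))
  cat(sprintf("  dose range %.3g - %.3g cGy\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.dose_map <- function(x) dim(x$values)

# pixel-centre coordinate vectors (cm)
pixel_axes <- function(map) {
  px <- map$pixel_size / 10
  list(u = map$origin[1] + (seq_len(ncol(map$values)) - 1) * px,
       v = map$origin[2] + (seq_len(nrow(map$values)) - 1) * px,
       px = px)
}

#' Read and write dose maps
#'
#' The text-grid format carries a three-line header (`pixel_size_mm=`,
#' `origin_cm=u,v`, `units=cGy`) followed by whitespace-separated dose rows.
#' Grayscale image import (`format = "image"`, PNG or TIFF by extension)
#' requires a YAML sidecar `<path>.yml` giving either `pixel_size_mm` or
#' `dpi`, plus `cgy_per_value`, the dose per unit gray level.
#'
#' @param path File to read or write.
#' @param format `"text_grid"` or `"image"`.
#' @return `read_dose_map()` returns a [dose_map()]; `write_dose_map()`
#'   returns `path` invisibly.
#' @export
read_dose_map <- function(path, format = c("text_grid", "image")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (format == "text_grid") read_dose_map_text(path) else read_dose_map_image(path)
}

read_dose_map_text <- function(path) {
  lines <- readLines(path)
  hdr <- lines[seq_len(min(10, length(lines)))]
  get_field <- function(name) {
    hit <- grep(paste0("^", name, "="), hdr, value = TRUE)
    if (length(hit) != 1)
      abort(sprintf("malformed dose-map header: missing field `%s`", name))
    sub(paste0("^", name, "="), "", hit)
  }
  px <- as.numeric(get_field("pixel_size_mm"))
  origin <- as.numeric(strsplit(get_field("origin_cm"), ",")[[1]])
  units <- get_field("units")
  if (!identical(units, "cGy"))
    abort(sprintf("malformed dose-map header: units must be cGy, got `%s`", units))
  body <- lines[!grepl("=", lines) & nzchar(trimws(lines))]
  rows <- lapply(strsplit(trimws(body), "[[:space:]]+"), as.numeric)
  if (length(unique(lengths(rows))) != 1)
    abort("malformed dose-map body: ragged rows")
  values <- do.call(rbind, rows)
  if (anyNA(values)) abort("malformed dose-map body: non-numeric entries")
  if (any(values < 0)) abort("dose map contains negative doses")
  dose_map(values, px, origin, label = basename(path))
}

read_dose_map_image <- function(path) {
  sidecar <- paste0(path, ".yml")
  if (!file.exists(sidecar))
    abort(sprintf("image import needs a metadata sidecar: %s", sidecar))
  meta <- yaml::read_yaml(sidecar)
  px <- if (!is.null(meta$pixel_size_mm)) {
    as.numeric(meta$pixel_size_mm)
  } else if (!is.null(meta$dpi)) {
    25.4 / as.numeric(meta$dpi)
  } else {
    abort("sidecar must give `pixel_size_mm` or `dpi`")
  }
  if (is.null(meta$cgy_per_value))
    abort("sidecar must give `cgy_per_value` (dose per unit gray level)")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("unsupported image extension `%s`", ext))
  )
  if (length(dim(img)) == 3) img <- img[, , 1]  # first channel of RGB scans
  origin <- if (!is.null(meta$origin_cm)) as.numeric(meta$origin_cm) else c(0, 0)
  dose_map(img * as.numeric(meta$cgy_per_value), px, origin,
           label = basename(path))
}

#' @rdname read_dose_map
#' @param map A [dose_map()] to write (text-grid format only).
#' @export
write_dose_map <- function(map, path) {
  stopifnot(inherits(map, "dose_map"))
  hdr <- c(sprintf("pixel_size_mm=%.17g", map$pixel_size),
           sprintf("origin_cm=%.17g,%.17g", map$origin[1], map$origin[2]),
           "units=cGy")
  body <- apply(map$values, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# 1D block-average weight matrix: n_out output cells of width `ratio` input
# pixels; fractional overlaps weighted by covered length.
rebin_weights <- function(n_in, ratio) {
  n_out <- floor(n_in / ratio + 1e-9)
  if (n_out < 1) abort("rebin factor larger than the map")
  W <- matrix(0, n_out, n_in)
  for (k in seq_len(n_out)) {
    lo <- (k - 1) * ratio
    hi <- k * ratio
    j0 <- floor(lo) + 1L
    j1 <- ceiling(hi - 1e-12)
    for (j in j0:min(j1, n_in)) {
      W[k, j] <- min(hi, j) - max(lo, j - 1)
    }
  }
  W
}

#' Rebin a dose map to a coarser pixel size
#'
#' Block-average (area-weighted) rebinning; the mean dose over the covered
#' region is preserved to numerical precision. Upsampling is not supported.
#' Trailing rows/columns that do not fill a whole output pixel are dropped.
#'
#' @param map A [dose_map()].
#' @param new_pixel_size Target pixel pitch, mm; must be `>=` the current one.
#' @return A [dose_map()] at the new resolution.
#' @export
rebin <- function(map, new_pixel_size) {
  stopifnot(inherits(map, "dose_map"))
  if (new_pixel_size < map$pixel_size)
    abort("upsampling is out of scope: `new_pixel_size` must be >= pixel_size")
  if (isTRUE(all.equal(new_pixel_size, map$pixel_size))) return(map)
  ratio <- new_pixel_size / map$pixel_size
  Wr <- rebin_weights(nrow(map$values), ratio)
  Wc <- rebin_weights(ncol(map$values), ratio)
  vals <- (Wr %*% map$values %*% t(Wc)) / ratio^2
  vals[vals < 0] <- 0  # guard tiny negative fp residue
  shift <- (ratio - 1) / 2 * map$pixel_size / 10
  dose_map(vals, new_pixel_size, map$origin + shift, map$label)
}

#' Locate the dose maximum
#'
#' Index of the global maximum; ties are broken by the smallest row-major
#' index (first along the row, then down).
#'
#' @param map A [dose_map()].
#' @return Integer pair `(row, col)`.
#' @export
max_point <- function(map) {
  stopifnot(inherits(map, "dose_map"))
  v <- map$values
  hits <- which(v == max(v), arr.ind = TRUE)
  rowmajor <- (hits[, 1] - 1L) * ncol(v) + hits[, 2]
  as.integer(hits[which.min(rowmajor), ])
}

#' Average dose inside a circle
#'
#' Unweighted mean over all pixels whose centres lie within `radius` (cm) of
#' the centre pixel's centre. Pixels outside the map are simply absent from
#' the average; the circle need not fit inside the map.
#'
#' @param map A [dose_map()].
#' @param center Pixel index pair `(row, col)`; defaults to [max_point()].
#' @param radius Circle radius, cm.
#' @return Mean dose, cGy.
#' @export
mean_dose_in_circle <- function(map, center = max_point(map), radius) {
  stopifnot(inherits(map, "dose_map"))
  if (radius <= 0) abort("`radius` must be positive (cm)")
  px <- map$pixel_size / 10
  dv <- (seq_len(nrow(map$values)) - center[1]) * px
  du <- (seq_len(ncol(map$values)) - center[2]) * px
  inside <- outer(dv^2, du^2, `+`) <= radius^2 + 1e-12
  if (!any(inside)) abort("no pixel centres inside the circle")
  mean(map$values[inside])
}

#' Circle-average dose profile (D_Rx)
#'
#' Computes the mean dose in concentric circles around the dose maximum; the
#' value at radius x cm is the field's D_Rx statistic.
#'
#' @param map A [dose_map()].
#' @param radii Strictly increasing radii, cm.
#' @param center Pixel index pair; defaults to the dose maximum.
#' @return An object of class `drx_profile`: a list with `center`, `radii`
#'   and `values`. Use [tidy()] for a tibble.
#' @export
drx_profile <- function(map, radii = 1:4, center = max_point(map)) {
  if (any(diff(radii) <= 0)) abort("`radii` must be strictly increasing")
  vals <- vapply(radii, function(r) mean_dose_in_circle(map, center, r),
                 numeric(1))
  structure(
    list(center = center, radii = as.numeric(radii), values = vals,
         label = map$label),
    class = "drx_profile"
  )
}

#' @export
print.drx_profile <- function(x, ...) {
  cat("<drx_profile> centre px (", x$center[1], ",", x$center[2], ")\n")
  print(setNames(round(x$values, 2), paste0("D_R", x$radii)))
  invisible(x)
}

#' @rdname drx_profile
#' @param x A `drx_profile`.
#' @param ... Unused.
#' @method tidy drx_profile
#' @export
tidy.drx_profile <- function(x, ...) {
  tibble(radius_cm = x$radii, mean_dose_cGy = x$values)
}

#' Area above a dose threshold
#'
#' The area enclosed by an isodose line, computed as the count of pixels with
#' dose `>=` the threshold times the pixel area. Zero is a valid result.
#'
#' @param map A [dose_map()].
#' @param threshold Dose threshold, cGy (positive).
#' @return Area, cm^2.
#' @export
isodose_area <- function(map, threshold) {
  stopifnot(inherits(map, "dose_map"))
  if (threshold <= 0) abort("`threshold` must be positive (cGy)")
  px_area <- (map$pixel_size / 10)^2
  sum(map$values >= threshold) * px_area
}

#' Isodose-line areas at fractions of the prescription (A_y%)
#'
#' @param map A [dose_map()].
#' @param prescription Prescription dose, cGy.
#' @param levels Fractions of the prescription, in `(0, 1.5]`.
#' @return A tibble with `level`, `threshold_cGy` and `area_cm2`, of class
#'   `isodose_areas`.
#' @export
isodose_areas <- function(map, prescription = 300,
                          levels = c(0.30, 0.50, 0.70, 0.90, 1.00)) {
  if (any(levels <= 0) || any(levels > 1.5))
    abort("`levels` must lie in (0, 1.5]")
  out <- tibble(
    level = levels,
    threshold_cGy = levels * prescription,
    area_cm2 = vapply(levels * prescription,
                      function(thr) isodose_area(map, thr), numeric(1))
  )
  class(out) <- c("isodose_areas", class(out))
  out
}

#' Plot a dose map
#'
#' @param object A [dose_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dose_map
#' @export
autoplot.dose_map <- function(object, ...) {
  ax <- pixel_axes(object)
  df <- tidyr::expand_grid(v_cm = ax$v, u_cm = ax$u)
  df$dose_cGy <- as.vector(t(object$values))
  ggplot(df, aes(.data$u_cm, .data$v_cm, fill = .data$dose_cGy)) +
    geom_raster() +
    scale_fill_viridis_c(name = "dose (cGy)") +
    coord_equal() +
    labs(x = "u (cm)", y = "v (cm)", title = object$label) +
    theme_minimal()
}

#' @rdname drx_profile
#' @param object A `drx_profile`.
#' @method autoplot drx_profile
#' @export
autoplot.drx_profile <- function(object, ...) {
  ggplot(tidy(object), aes(.data$radius_cm, .data$mean_dose_cGy)) +
    geom_line() +
    geom_point() +
    labs(x = "circle radius (cm)", y = expression(D[Rx] ~ "(cGy)")) +
    theme_minimal()
}
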