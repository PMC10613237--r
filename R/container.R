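# Hierarchical result container and image export.
#
# The container is an R-native hierarchical structure mirroring the dataset
# tree of the pipeline (/grid, /matrices, /plates, /object, /mst, /meta).
# Complex arrays are stored as paired real/imag double arrays for maximal
# portability of the on-disk form; phases are stored wrapped to (-pi, pi].
# Reading then writing reproduces bit-identical datasets.

CONTAINER_SCHEMA_VERSION <- "1.0"

split_complex <- function(x) list(re = Re(x), im = Im(x))
join_complex <- function(x) {
  out <- complex(real = as.vector(x$re), imaginary = as.vector(x$im))
  dim(out) <- dim(x$re)
  out
}

wrap_phase <- function(p) {
  w <- atan2(sin(p), cos(p))
  # represent the branch point as +pi, keeping the (-pi, pi] convention
  w[w == -pi] <- pi
  w
}

#' Build a result container
#'
#' Collects grid metadata, matrices, plates, the object map and
#' reconstruction results into the package's hierarchical container
#' structure, ready for [write_container()].
#'
#' @param grid a [make_grid()] grid.
#' @param matrices named list of `reflection_matrix`/`transmission_matrix`
#'   objects (conventional names: `R`, `R_c`, `T_c`).
#' @param plates optional list of `phase_plate`s (ground truth).
#' @param object optional `object_map`.
#' @param mst optional [mst_iterate()] result.
#' @param meta named list merged into `/meta` (seed, config echo, log).
#' @return object of class `mst_container`.
#' @export
mst_container <- function(grid, matrices = list(), plates = list(),
                          object = NULL, mst = NULL, meta = list()) {
  stopifnot(is_field_grid(grid))
  cn <- list(
    grid = list(n = grid$n, pitch_um = grid$pitch,
                wavelength_um = grid$wavelength, na = grid$na),
    matrices = lapply(matrices, function(m) {
      list(values = split_complex(m$values), basis = m$basis,
           input_plane_um = m$input_plane, output_plane_um = m$output_plane,
           kind = class(m)[1])
    }),
    plates = lapply(plates, function(p)
      list(phase_rad = wrap_phase(p$phase), depth_um = p$depth,
           pitch_um = p$pitch,
           correlation_length_um = p$correlation_length,
           phase_std_rad = p$phase_std, seed = p$seed)),
    object = if (!is.null(object))
      list(reflectance = split_complex(object$reflectance),
           extent_um = object$extent),
    mst = if (!is.null(mst)) list(
      phase_c_rad = lapply(mst$estimates, function(e) wrap_phase(e$phase_c)),
      phase_c_unwrapped_rad = lapply(mst$estimates, function(e) e$phase_c),
      depths_um = vapply(mst$estimates, function(e) e$depth, numeric(1)),
      image = mst$image,
      object_estimate = split_complex(mst$object_estimate),
      traces = mst$traces,
      converged = mst$converged, cycles_run = mst$cycles_run),
    meta = utils::modifyList(
      list(schema_version = CONTAINER_SCHEMA_VERSION,
           created = format(Sys.time(), tz = "UTC")), meta)
  )
  structure(cn, class = "mst_container")
}

#' Write a container to disk
#' @param container an [mst_container()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_container <- function(container, path) {
  stopifnot(inherits(container, "mst_container"))
  saveRDS(unclass(container), path, version = 3)
  invisible(path)
}

#' Read a container from disk
#' @param path file written by [write_container()].
#' @return an `mst_container`.
#' @export
read_container <- function(path) {
  x <- readRDS(path)
  if (is.null(x$meta$schema_version))
    stop("read_container: not an mstrace container (no schema version)")
  structure(x, class = "mst_container")
}

#' @export
print.mst_container <- function(x, ...) {
  cat(sprintf("<mst_container> schema %s: %d matrices, %d plates%s%s\n",
              x$meta$schema_version, length(x$matrices), length(x$plates),
              if (!is.null(x$object)) ", object" else "",
              if (!is.null(x$mst)) ", mst results" else ""))
  invisible(x)
}

# rebuild live objects from a container
container_grid <- function(cn)
  make_grid(cn$grid$n, cn$grid$pitch_um, cn$grid$wavelength_um, cn$grid$na)

container_matrix <- function(cn, name) {
  m <- cn$matrices[[name]]
  if (is.null(m)) stop("container is missing matrix '", name, "'")
  g <- container_grid(cn)
  vals <- matrix(join_complex(m$values), g$n^2, g$n^2)
  if (m$kind == "transmission_matrix")
    transmission_matrix(vals, g, m$input_plane_um, m$output_plane_um,
                        basis = m$basis)
  else
    reflection_matrix(vals, g, m$input_plane_um, m$output_plane_um,
                      basis = m$basis)
}

container_object <- function(cn) {
  if (is.null(cn$object)) return(NULL)
  g <- container_grid(cn)
  structure(list(reflectance = matrix(join_complex(cn$object$reflectance),
                                      g$n, g$n),
                 grid = g, extent = cn$object$extent_um),
            class = "object_map")
}

container_medium <- function(cn) {
  g <- container_grid(cn)
  plates <- lapply(cn$plates, function(p)
    structure(list(phase = p$phase_rad, depth = p$depth_um,
                   pitch = p$pitch_um, extent = g$extent,
                   correlation_length = p$correlation_length_um,
                   phase_std = p$phase_std_rad, seed = p$seed),
              class = "phase_plate"))
  medium_model(g, plates)
}

#' Export a real-valued map as TIFF and/or PNG
#'
#' TIFF stores the raw values as 32-bit float (after scaling to `[0, 1]` if
#' `normalize`); PNG stores a display-normalised 8-bit image.
#'
#' @param map numeric matrix.
#' @param path output path without extension.
#' @param formats subset of `c("tiff", "png")`.
#' @param normalize rescale to `[0, 1]` before writing?
#' @return character vector of files written, invisibly.
#' @export
export_image <- function(map, path, formats = c("tiff", "png"),
                         normalize = TRUE) {
  rng <- range(map)
  norm <- if (normalize && diff(rng) > 0) (map - rng[1]) / diff(rng)
          else pmin(pmax(map, 0), 1)
  written <- character(0)
  if ("tiff" %in% formats) {
    f <- paste0(path, ".tiff")
    tiff::writeTIFF(norm, f, bits.per.sample = 32L)
    written <- c(written, f)
  }
  if ("png" %in% formats) {
    f <- paste0(path, ".png")
    png::writePNG(norm, f)
    written <- c(written, f)
  }
  invisible(written)
}
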