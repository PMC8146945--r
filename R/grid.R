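# 3D neuron grids in template (Talairach-like) space.

#' Construct a neuron grid
#'
#' @param coords N x 3 numeric matrix of positions (mm).
#' @param source provenance tag.
#' @return `snn_neuron_grid` object.
#' @export
neuron_grid <- function(coords, source = "custom") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coordinates must have 3 columns")
  if (anyDuplicated(round(coords, 9))) stop("duplicate neuron coordinates")
  colnames(coords) <- c("x", "y", "z")
  structure(list(coords = coords, n = nrow(coords), source = source),
            class = "snn_neuron_grid")
}

#' @export
print.snn_neuron_grid <- function(x, ...) {
  cat(sprintf("<snn_neuron_grid> %d neurons (%s)\n", x$n, x$source))
  invisible(x)
}

#' Load a neuron grid from an xyz text file
#'
#' Reads a whitespace- or comma-delimited list of xyz coordinates, one neuron
#' per row. The packaged 1-cm template stand-in
#' (`system.file("extdata", "talairach_grid_1cm_synthetic.txt",
#' package = "snnmorph")`) has 1471 points, matching the neuron count of the
#' published brain-template grid; it is a synthetic reconstruction (a 10-mm
#' lattice inside a brain-shaped ellipsoid), not the original atlas file.
#'
#' @param path file path.
#' @return `snn_neuron_grid`.
#' @export
#' @examples
#' g <- load_grid(system.file("extdata", "talairach_grid_1cm_synthetic.txt",
#'                            package = "snnmorph"))
#' g$n
load_grid <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  rows <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(trimws(lines[[i]]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 3L || anyNA(vals))
      stop(sprintf("malformed coordinate row at line %d: '%s'", i, lines[[i]]))
    vals
  })
  neuron_grid(do.call(rbind, rows), source = "talairach_template")
}

#' Synthetic lattice grid inside a brain-shaped ellipsoid
#'
#' Deterministic regular lattice of `n_per_axis` points per axis, clipped to
#' an ellipsoid with semi-axes 70 x 85 x 65 mm. A download-free stand-in for
#' the anatomical template; `n_per_axis = 11` yields 503 neurons, the
#' "500-neuron" desk-scale grid used by the pipeline defaults.
#'
#' @param n_per_axis lattice points per axis (>= 2).
#' @return `snn_neuron_grid`.
#' @export
#' @examples
#' synthetic_grid(5)$n
synthetic_grid <- function(n_per_axis) {
  if (n_per_axis < 2) stop("n_per_axis must be >= 2")
  axes <- c(70, 85, 65)
  u <- seq(-1, 1, length.out = n_per_axis)
  g <- as.matrix(expand.grid(x = u, y = u, z = u))
  g <- g[rowSums(g^2) <= 1, , drop = FALSE]
  neuron_grid(sweep(g, 2, axes, `*`), source = "synthetic_grid")
}
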