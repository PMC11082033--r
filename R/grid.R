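#' Masked structured grid
#'
#' A uniform Cartesian grid of cell centers with an in-domain mask and wall
#' faces extracted on the mask boundary — the discrete stand-in for an
#' unstructured CFD mesh that keeps every kernel testable against analytic
#' fixtures. Wall faces are the axis-aligned faces separating an in-domain
#' cell from the outside (or the grid boundary); each borders exactly one
#' in-domain cell and carries an outward unit normal and its face area.
#'
#' @param dims Integer vector, cells per axis, each >= 1.
#' @param spacing Cell spacing per axis, m.
#' @param mask Logical array of dimension `dims`; `TRUE` marks in-domain
#'   cells. Default: all cells in-domain.
#' @param origin Coordinates of the center of cell (1,1,1), m.
#' @return An object of class `field_grid`: list with `dims`, `spacing`,
#'   `origin`, `mask`, `cell_volume` (m^3), `n_cells` (in-domain count) and
#'   `wall_faces` (data frame with columns `cell` — linear index of the
#'   bordering in-domain cell —, `axis`, `side` (+1/-1, outward), `area`).
#' @export
field_grid <- function(dims, spacing, mask = NULL, origin = spacing / 2) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1),
            length(spacing) == 3, all(spacing > 0))
  if (is.null(mask)) mask <- array(TRUE, dims)
  stopifnot(is.logical(mask), all(dim(mask) == dims))
  areas <- c(spacing[2] * spacing[3],
             spacing[1] * spacing[3],
             spacing[1] * spacing[2])
  faces <- list()
  for (a in 1:3) {
    for (s in c(1L, -1L)) {
      # wall where an in-domain cell's neighbor in direction s*e_a is
      # outside (.shift_array with by = s reads the value at i + s)
      nb <- .shift_array(mask, a, s, fill = FALSE)
      hit <- which(mask & !nb)
      if (length(hit)) {
        faces[[length(faces) + 1L]] <-
          data.frame(cell = hit, axis = a, side = s, area = areas[a])
      }
    }
  }
  wall_faces <- if (length(faces)) do.call(rbind, faces) else
    data.frame(cell = integer(), axis = integer(), side = integer(),
               area = numeric())
  structure(list(dims = dims, spacing = spacing, origin = origin,
                 mask = mask, cell_volume = prod(spacing),
                 n_cells = sum(mask), wall_faces = wall_faces),
            class = "field_grid")
}

# Shift an array along one axis by one cell; vacated entries get `fill`.
# by = +1 brings the value from the next cell along the axis (i+1 -> i).
.shift_array <- function(A, axis, by, fill = NA) {
  d <- dim(A)
  n <- d[axis]
  out <- array(fill, d)
  idx_src <- idx_dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  if (by > 0) {
    idx_dst[[axis]] <- seq_len(n - 1L)
    idx_src[[axis]] <- 2L:n
  } else if (by < 0) {
    idx_dst[[axis]] <- 2L:n
    idx_src[[axis]] <- seq_len(n - 1L)
  } else {
    return(A)
  }
  if (n == 1L) return(out)
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    A[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Cell-center coordinates
#'
#' @param grid A `field_grid`.
#' @return List of three arrays `x`, `y`, `z` of dimension `grid$dims`, m.
#' @export
grid_coords <- function(grid) {
  d <- grid$dims; h <- grid$spacing; o <- grid$origin
  ax <- lapply(1:3, function(a) o[a] + (seq_len(d[a]) - 1) * h[a])
  list(x = array(rep(ax[[1]], times = d[2] * d[3]), d),
       y = array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d),
       z = array(rep(ax[[3]], each = d[1] * d[2]), d))
}

#' Total wall area of a grid
#'
#' @param grid A `field_grid`.
#' @return Area, m^2.
#' @export
wall_area <- function(grid) sum(grid$wall_faces$area)

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf(
    "field_grid: %d x %d x %d cells (%d in domain), spacing %s m\n",
    x$dims[1], x$dims[2], x$dims[3], x$n_cells,
    paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  domain volume %.2f ml, wall area %.2f cm^2 (%d faces)\n",
              x$n_cells * x$cell_volume * 1e6, wall_area(x) * 1e4,
              nrow(x$wall_faces)))
  invisible(x)
}
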