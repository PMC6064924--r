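#' Idealized 2-D branched channel geometry
#'
#' Builds a rectangular channel of length `length_L` (x) and height
#' `height_h` (y) on a uniform `grid_nx` by `grid_ny` staggered grid, with
#' small side-branch openings (ostia) on the top and bottom walls. The
#' channel is an idealized stand-in for a descending aorta with intercostal
#' ostia: flow enters at `x = 0`, the main outlet is at `x = length_L`, and
#' each ostium is a short opening in a wall through which a prescribed
#' fraction of the inflow leaves. Ostia are snapped to whole grid cells;
#' their effective (snapped) width is stored alongside the requested one.
#'
#' Each ostium must be narrow relative to the channel (`width < height_h/4`),
#' must lie strictly inside the wall, and ostia on the same wall must not
#' overlap. The default layout, built by [default_ostia()], places 12 ostia
#' as 6 axial pairs on opposite walls, mirroring paired intercostal
#' branches; pairs in the proximal half are labelled `upper`, distal half
#' `lower`, and the top/bottom walls map to the `left`/`right` sides of the
#' vessel, giving the four quadrants `left_upper`, `right_upper`,
#' `left_lower`, `right_lower`.
#'
#' @param length_L Channel length in m.
#' @param height_h Channel height in m.
#' @param grid_nx,grid_ny Number of grid cells along x and y.
#' @param ostia Data frame with columns `side` (`"top"` or `"bottom"`),
#'   `position` (axial center, m) and `width` (m); or `NULL` for a plain
#'   straight channel. See [default_ostia()].
#' @param branch_length Length of the (unmeshed) branch stubs in m; kept as
#'   metadata only — ostia are modelled as wall openings with prescribed
#'   outflow, not as meshed side channels.
#' @return An object of class `channel_geometry`.
#' @examples
#' geo <- build_channel(0.019, 0.00158, 60, 40, default_ostia(0.019))
#' @export
build_channel <- function(length_L, height_h, grid_nx, grid_ny,
                          ostia = NULL, branch_length = 0) {
  check_positive(length_L, "length_L")
  check_positive(height_h, "height_h")
  grid_nx <- as.integer(grid_nx); grid_ny <- as.integer(grid_ny)
  if (is.na(grid_nx) || grid_nx < 4L || is.na(grid_ny) || grid_ny < 4L)
    stop("invalid geometry: need at least a 4 x 4 grid", call. = FALSE)
  dx <- length_L / grid_nx
  dy <- height_h / grid_ny

  ost <- NULL
  if (!is.null(ostia) && nrow(ostia) > 0L) {
    stopifnot(all(c("side", "position", "width") %in% names(ostia)))
    if (!all(ostia$side %in% c("top", "bottom")))
      stop("invalid geometry: ostium side must be 'top' or 'bottom'", call. = FALSE)
    if (any(ostia$width <= 0) || any(ostia$position <= 0))
      stop("invalid geometry: ostium positions and widths must be positive",
           call. = FALSE)
    if (any(ostia$width >= height_h / 4))
      stop("invalid geometry: each ostium width must be < height_h / 4",
           call. = FALSE)
    lo <- ostia$position - ostia$width / 2
    hi <- ostia$position + ostia$width / 2
    if (any(lo <= dx) || any(hi >= length_L - dx))
      stop("invalid geometry: ostia must lie strictly inside the wall",
           call. = FALSE)
    for (s in c("top", "bottom")) {
      k <- which(ostia$side == s)
      if (length(k) > 1L) {
        o <- k[order(ostia$position[k])]
        if (any(lo[o][-1L] < hi[o][-length(o)]))
          stop("invalid geometry: overlapping ostia on the same wall", call. = FALSE)
      }
    }
    xc <- (seq_len(grid_nx) - 0.5) * dx
    cells <- lapply(seq_len(nrow(ostia)), function(k) {
      cc <- which(xc >= lo[k] & xc < hi[k])
      if (length(cc) == 0L) cc <- which.min(abs(xc - ostia$position[k]))
      cc
    })
    # Snapping must not merge neighbours
    for (s in c("top", "bottom")) {
      k <- which(ostia$side == s)
      if (length(unlist(cells[k])) != length(unique(unlist(cells[k]))))
        stop("invalid geometry: grid too coarse, snapped ostia overlap", call. = FALSE)
    }
    ost <- data.frame(ostium = sprintf("ostium_%02d", seq_len(nrow(ostia))),
                      side = ostia$side, position = ostia$position,
                      width = ostia$width,
                      width_eff = vapply(cells, length, 0L) * dx,
                      stringsAsFactors = FALSE)
    ost$quadrant <- paste(ifelse(ost$side == "top", "left", "right"),
                          ifelse(ost$position < length_L / 2, "upper", "lower"),
                          sep = "_")
    ost$cells <- cells
  }

  structure(list(length_L = length_L, height_h = height_h,
                 grid_nx = grid_nx, grid_ny = grid_ny, dx = dx, dy = dy,
                 ostia = ost, branch_length = branch_length),
            class = "channel_geometry")
}

#' Default paired-ostia layout
#'
#' Twelve ostia as six axial pairs on opposite walls, centered at
#' `length_L * k / 7` for `k = 1..6`.
#'
#' @param length_L Channel length in m.
#' @param width Ostium width in m.
#' @return Data frame suitable for the `ostia` argument of [build_channel()].
#' @export
default_ostia <- function(length_L, width = length_L / 60) {
  pos <- length_L * (1:6) / 7
  data.frame(side = rep(c("top", "bottom"), times = 6L),
             position = rep(pos, each = 2L),
             width = width, stringsAsFactors = FALSE)
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("<channel_geometry> L = %g m, h = %g m, grid %d x %d, %d ostia\n",
              x$length_L, x$height_h, x$grid_nx, x$grid_ny,
              if (is.null(x$ostia)) 0L else nrow(x$ostia)))
  invisible(x)
}

#' Classify grid cells and boundary openings
#'
#' Every cell is assigned exactly one class: `inlet` (adjacent to the inlet
#' plane), `outlet` (adjacent to the main outlet plane), `ostium` (adjacent
#' to an ostium opening in a wall), `wall` (other wall-adjacent cells) or
#' `fluid` (interior). The counts of distinct boundary openings are
#' attached as attribute `"openings"` (`inlet`, `main_outlet`,
#' `ostium_outlets`).
#'
#' @param geometry A [build_channel()] geometry.
#' @return Character matrix (`grid_nx` by `grid_ny`) of cell classes.
#' @export
classify_cells <- function(geometry) {
  stopifnot(inherits(geometry, "channel_geometry"))
  nx <- geometry$grid_nx; ny <- geometry$grid_ny
  cls <- matrix("fluid", nx, ny)
  cls[, c(1L, ny)] <- "wall"
  if (!is.null(geometry$ostia)) {
    for (k in seq_len(nrow(geometry$ostia))) {
      j <- if (geometry$ostia$side[k] == "bottom") 1L else ny
      cls[geometry$ostia$cells[[k]], j] <- "ostium"
    }
  }
  cls[nx, ] <- "outlet"
  cls[1L, ] <- "inlet"
  attr(cls, "openings") <- c(
    inlet = 1L, main_outlet = 1L,
    ostium_outlets = if (is.null(geometry$ostia)) 0L else nrow(geometry$ostia))
  cls
}

#' Outlet flow split fractions
#'
#' Named positive fractions assigning each outlet its share of the
#' instantaneous inflow. Raw fractions are renormalized to sum exactly to 1
#' (mass conservation is non-negotiable); the raw values are kept as
#' attribute `"raw"`.
#'
#' @param fractions Named numeric vector of raw fractions; must include
#'   `main` and one entry per ostium (`ostium_01`, ...), all > 0.
#' @return An object of class `outlet_split` (named numeric summing to 1).
#' @export
outlet_split <- function(fractions) {
  if (is.null(names(fractions)) || any(names(fractions) == "") ||
      !"main" %in% names(fractions))
    stop("`fractions` must be a named vector including 'main'", call. = FALSE)
  if (any(!is.finite(fractions)) || any(fractions <= 0))
    stop("all split fractions must be positive", call. = FALSE)
  structure(fractions / sum(fractions), raw = fractions, class = "outlet_split")
}

#' @export
print.outlet_split <- function(x, ...) {
  cat("<outlet_split> normalized fractions:\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' Default outlet split for a channel geometry
#'
#' The single-channel reduction of the aortic split: the descending-aorta
#' outlet keeps its raw 69.8% and each ostium its raw 0.14%; with the arch
#' branches absent these are renormalized among themselves (see
#' [aortic_outlet_split()] for the full set).
#'
#' @param geometry A [build_channel()] geometry.
#' @param main_raw Raw main-outlet fraction (default 0.698).
#' @param ostium_raw Raw per-ostium fraction (default 0.0014).
#' @return An [outlet_split()].
#' @export
default_outlet_split <- function(geometry, main_raw = 0.698, ostium_raw = 0.0014) {
  stopifnot(inherits(geometry, "channel_geometry"))
  n_ost <- if (is.null(geometry$ostia)) 0L else nrow(geometry$ostia)
  f <- c(main = main_raw, stats::setNames(rep(ostium_raw, n_ost),
                                          sprintf("ostium_%02d", seq_len(n_ost))))
  outlet_split(f)
}

#' Full aortic outlet split
#'
#' The four arterial outlets (descending aorta 69.8%, innominate 16%,
#' common carotid 8%, subclavian 6%) plus 0.14% for each of 12 ostia. The
#' raw percentages sum to 101.48%; the returned fractions are renormalized
#' to 1.
#'
#' @return An [outlet_split()] with 16 entries.
#' @export
aortic_outlet_split <- function() {
  f <- c(main = 0.698, innominate = 0.16, carotid = 0.08, subclavian = 0.06,
         stats::setNames(rep(0.0014, 12L), sprintf("ostium_%02d", 1:12)))
  outlet_split(f)
}
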