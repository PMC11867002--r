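#' Sensor layout
#'
#' A 2-D sensor array description: channel positions (x increases from left
#' to right, y from posterior to anterior, arbitrary units), hemisphere
#' labels, a symmetric channel adjacency relation used by the cluster
#' permutation test, and a left-to-right mirror pairing used by the
#' lateralization index. Midline channels (|x| below `midline_tol`) are
#' excluded from mirroring.
#'
#' @param channel_ids character vector of unique channel names.
#' @param positions numeric matrix (n x 2) of sensor coordinates.
#' @param adjacency logical n x n matrix, or NULL to derive it from
#'   positions via [build_adjacency()].
#' @param mirror_map named character vector pairing left channels to right
#'   channels, or NULL to leave unset (see [build_mirror_map()]).
#' @param groups optional named list of channel-id subsets (e.g. the
#'   simulated evoked-field channels, the artifact wire path).
#' @param midline_tol channels with |x| < midline_tol are labeled midline.
#' @return an object of class `sensor_layout`.
#' @export
sensor_layout <- function(channel_ids, positions, adjacency = NULL,
                          mirror_map = NULL, groups = list(),
                          midline_tol = 1e-9) {
  positions <- as.matrix(positions)
  stopifnot(length(channel_ids) == nrow(positions), ncol(positions) == 2,
            !anyDuplicated(channel_ids))
  rownames(positions) <- channel_ids
  colnames(positions) <- c("x", "y")
  hemisphere <- ifelse(positions[, "x"] > midline_tol, "right",
                       ifelse(positions[, "x"] < -midline_tol, "left",
                              "midline"))
  names(hemisphere) <- channel_ids
  if (is.null(adjacency)) adjacency <- build_adjacency(positions)
  adjacency <- as.matrix(adjacency)
  dimnames(adjacency) <- list(channel_ids, channel_ids)
  layout <- structure(list(channel_ids = channel_ids,
                           positions = positions,
                           hemisphere = hemisphere,
                           adjacency = adjacency,
                           mirror_map = mirror_map,
                           groups = groups),
                      class = "sensor_layout")
  validate_layout(layout)
  layout
}

#' Validate a sensor layout's structural invariants
#'
#' Checks that adjacency is symmetric and irreflexive, and (when present)
#' that the mirror map is a bijection between left- and right-labeled
#' channels whose paired positions satisfy x_right = -x_left and
#' y_right = y_left within `tol`.
#'
#' @param layout a `sensor_layout`.
#' @param tol positional tolerance for mirrored coordinates.
#' @return the layout, invisibly; errors on violation.
#' @export
validate_layout <- function(layout, tol = 1e-6) {
  adj <- layout$adjacency
  if (!isTRUE(all(adj == t(adj))))
    stop("adjacency must be symmetric")
  if (any(diag(adj)))
    stop("adjacency must be irreflexive (no self-neighbors)")
  mm <- layout$mirror_map
  if (!is.null(mm)) {
    left <- names(mm)
    right <- unname(mm)
    lch <- layout$channel_ids[layout$hemisphere == "left"]
    rch <- layout$channel_ids[layout$hemisphere == "right"]
    if (!setequal(left, lch) || !setequal(right, rch) ||
        anyDuplicated(right) > 0)
      stop("mirror_map must be a bijection between left and right channels")
    dx <- layout$positions[right, "x"] + layout$positions[left, "x"]
    dy <- layout$positions[right, "y"] - layout$positions[left, "y"]
    if (any(abs(dx) > tol) || any(abs(dy) > tol))
      stop("mirrored positions violate x_right = -x_left, y_right = y_left")
  }
  invisible(layout)
}

#' Derive a channel adjacency graph from sensor positions
#'
#' Two channels are neighbors when their Euclidean distance does not exceed
#' `max_dist`. The default threshold (1.5 times the smallest non-zero
#' inter-channel distance) connects rook and diagonal neighbors on a
#' regular grid.
#'
#' @param positions n x 2 coordinate matrix.
#' @param max_dist neighbor distance threshold; NULL for the default.
#' @return logical n x n symmetric, irreflexive matrix.
#' @export
build_adjacency <- function(positions, max_dist = NULL) {
  d <- as.matrix(stats::dist(positions))
  if (is.null(max_dist)) {
    nz <- d[d > 0]
    if (length(nz) == 0) stop("need at least two distinct positions")
    max_dist <- 1.5 * min(nz)
  }
  adj <- d > 0 & d <= max_dist
  diag(adj) <- FALSE
  adj
}

#' Pair each left channel with its mirror across the posteroanterior midline
#'
#' For every left-hemisphere channel the right-hemisphere channel nearest to
#' its x-negated position is selected. With equal left/right channel counts
#' and an (approximately) symmetric array this is the bijective mirror
#' pairing used to build the right-hemisphere ROI from the left one.
#'
#' @param layout a `sensor_layout`.
#' @param tol positional tolerance passed to [validate_layout()]; use a
#'   larger value for jittered arrays.
#' @return the layout with `mirror_map` populated.
#' @export
build_mirror_map <- function(layout, tol = 1e-6) {
  lch <- layout$channel_ids[layout$hemisphere == "left"]
  rch <- layout$channel_ids[layout$hemisphere == "right"]
  if (length(lch) != length(rch))
    stop("unequal hemisphere channel counts; unmatched channels: ",
         paste(c(lch, rch)[seq_len(abs(length(lch) - length(rch)))],
               collapse = ", "))
  if (length(lch) == 0) stop("no lateralized channels to mirror")
  rpos <- layout$positions[rch, , drop = FALSE]
  mm <- vapply(lch, function(ch) {
    target <- layout$positions[ch, ] * c(-1, 1)
    d2 <- (rpos[, 1] - target[1])^2 + (rpos[, 2] - target[2])^2
    rch[which.min(d2)]
  }, character(1))
  if (anyDuplicated(mm) > 0)
    stop("mirror pairing is not one-to-one; unmatched channels: ",
         paste(setdiff(rch, mm), collapse = ", "))
  layout$mirror_map <- mm
  validate_layout(layout, tol = tol)
  layout
}

#' Regular bilateral grid layout
#'
#' Builds a mirror-symmetric sensor array with `n_per_hemisphere` channels
#' per hemisphere arranged on a rectangular grid (columns run medial to
#' lateral, rows posterior to anterior). Left channels are named
#' `L01, L02, ...` and right channels `R01, R02, ...`. Two channel groups
#' are predefined for simulation: `roi_left`, the anterior-row left
#' channels standing in for the frontal/sensorimotor sensors that show a
#' pulse-evoked field, and `wire_right`, the most posterior right channels
#' standing in for the sensors over the subcutaneous stimulator wires that
#' carry the pulse artifact.
#'
#' @param n_per_hemisphere channels per hemisphere (>= 2).
#' @param spacing grid spacing in arbitrary units.
#' @param jitter optional positional jitter SD (applied to both coordinates,
#'   breaking exact symmetry; pairing is still recovered by
#'   [build_mirror_map()] for jitter << spacing).
#' @param seed RNG seed used only when `jitter > 0`.
#' @return a `sensor_layout` with `mirror_map` populated (exact layouts) or
#'   unset (jittered layouts).
#' @export
make_grid_layout <- function(n_per_hemisphere, spacing = 1, jitter = 0,
                             seed = 1L) {
  n <- n_per_hemisphere
  stopifnot(n >= 2)
  ncols <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  col <- idx %% ncols          # 0 = medial
  row <- idx %/% ncols         # 0 = posterior
  xl <- -(col + 1) * spacing
  y <- row * spacing
  ids <- c(sprintf("L%02d", seq_len(n)), sprintf("R%02d", seq_len(n)))
  pos <- rbind(cbind(xl, y), cbind(-xl, y))
  if (jitter > 0) {
    pos <- pos + with_seed(seed, matrix(stats::rnorm(4 * n, sd = jitter),
                                        ncol = 2))
  }
  anterior <- which(row == max(row))
  posterior <- which(row == 0)
  groups <- list(
    roi_left = ids[anterior],
    wire_right = ids[n + posterior[seq_len(min(2, length(posterior)))]])
  layout <- sensor_layout(ids, pos, groups = groups)
  if (jitter == 0) layout <- build_mirror_map(layout)
  layout
}
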