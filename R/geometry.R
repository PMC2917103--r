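# Spherical cell geometry and random cluster layouts.
#
# IP3R channel clusters are treated as points scattered through the cell
# volume (the ER pervades the cell in the bi-domain picture). Layouts are
# rejection-sampled: positions uniform in the ball, a minimum pairwise
# separation, and a cap on every cluster's nearest-neighbour distance
# matching the experimentally observed 1-7 µm range of inter-cluster
# distances.

#' Spherical cell shape
#'
#' @param radius cell radius in µm (default 10).
#' @return An object of class `cell_shape`.
#' @export
cell_shape <- function(radius = 10) {
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
    stop("cell radius must be a positive number (um)", call. = FALSE)
  }
  structure(list(radius = radius), class = "cell_shape")
}

#' Generate a random cluster layout
#'
#' Cluster positions are sampled uniformly in the cell volume and accepted
#' when all pairwise distances are at least `min_sep`; whole layouts are
#' resampled until additionally every cluster's nearest neighbour lies
#' within `max_nn`. Channel counts are drawn uniformly from `channel_range`.
#'
#' @param n_clusters number of clusters.
#' @param channel_range integer interval `c(lo, hi)` of channels per cluster.
#' @param min_sep minimum pairwise cluster distance (µm).
#' @param max_nn maximum nearest-neighbour distance per cluster (µm);
#'   `Inf` disables the constraint.
#' @param cell a [cell_shape()].
#' @param seed integer seed; the layout is reproducible for a fixed seed.
#' @param max_attempts bound on whole-layout resampling before a packing
#'   error is raised.
#' @return An object of class `cluster_layout` with fields `positions`
#'   (n x 3 matrix, µm, origin at the cell centre), `channels` (integer
#'   vector), `cell`, and `seed`.
#' @export
generate_layout <- function(n_clusters, channel_range = c(4L, 16L),
                            min_sep = 1, max_nn = 7, cell = cell_shape(),
                            seed = 1L, max_attempts = 200L) {
  stopifnot(n_clusters >= 1, min_sep > 0, length(channel_range) == 2,
            channel_range[1] >= 1, channel_range[2] >= channel_range[1])
  # crude feasibility: n spheres of radius min_sep/2 must fit in the cell
  if (n_clusters * (min_sep / 2)^3 > cell$radius^3) {
    stop("packing infeasible: ", n_clusters, " clusters with min_sep ",
         min_sep, " um cannot fit in a ", cell$radius, " um cell",
         call. = FALSE)
  }
  set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    pos <- sample_packed_positions(n_clusters, min_sep, cell$radius)
    if (is.null(pos)) next
    if (n_clusters > 1 && is.finite(max_nn)) {
      nn <- nn_dist_from_positions(pos)
      if (any(nn > max_nn)) next
    }
    channels <- sample(seq.int(channel_range[1], channel_range[2]),
                       n_clusters, replace = TRUE)
    layout <- structure(
      list(positions = pos, channels = as.integer(channels), cell = cell,
           seed = as.integer(seed), min_sep = min_sep, max_nn = max_nn),
      class = "cluster_layout")
    validate_layout(layout)
    return(layout)
  }
  stop("failed to place ", n_clusters, " clusters with min_sep ", min_sep,
       " um and max_nn ", max_nn, " um after ", max_attempts, " attempts",
       call. = FALSE)
}

# sequential rejection sampling of positions uniform in the ball
sample_packed_positions <- function(n, min_sep, R, tries_per_point = 500L) {
  pos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (tr in seq_len(tries_per_point)) {
      u <- stats::rnorm(3)
      r <- R * stats::runif(1)^(1 / 3)
      p <- u / sqrt(sum(u^2)) * r
      if (i == 1 ||
          min(sqrt(colSums((t(pos[seq_len(i - 1), , drop = FALSE]) - p)^2))) >=
            min_sep) {
        pos[i, ] <- p
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  colnames(pos) <- c("x", "y", "z")
  pos
}

validate_layout <- function(layout) {
  pos <- layout$positions
  stopifnot(is.matrix(pos), ncol(pos) == 3,
            nrow(pos) == length(layout$channels),
            all(layout$channels >= 0))
  r <- sqrt(rowSums(pos^2))
  if (any(r >= layout$cell$radius)) {
    stop("cluster positions must lie strictly inside the cell", call. = FALSE)
  }
  if (nrow(pos) > 1) {
    d <- stats::dist(pos)
    if (min(d) < layout$min_sep * (1 - 1e-12)) {
      stop("pairwise cluster distance below min_sep", call. = FALSE)
    }
  }
  invisible(layout)
}

nn_dist_from_positions <- function(pos) {
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  unname(apply(d, 1, min))
}

#' Nearest-neighbour distances of a layout
#'
#' @param layout a `cluster_layout`.
#' @return Numeric vector, one value per cluster (µm); empty for a
#'   single-cluster layout.
#' @export
nearest_neighbor_distances <- function(layout) {
  if (nrow(layout$positions) < 2) return(numeric(0))
  nn_dist_from_positions(layout$positions)
}

#' Construct a layout from explicit positions
#'
#' @param positions n x 3 numeric matrix (µm).
#' @param channels integer vector of channels per cluster.
#' @param cell a [cell_shape()].
#' @param min_sep,max_nn constraints recorded with the layout (validated
#'   against `min_sep`).
#' @return A `cluster_layout`.
#' @export
cluster_layout <- function(positions, channels, cell = cell_shape(),
                           min_sep = 0, max_nn = Inf) {
  positions <- matrix(as.numeric(positions), ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z")))
  layout <- structure(
    list(positions = positions, channels = as.integer(channels), cell = cell,
         seed = NA_integer_, min_sep = min_sep, max_nn = max_nn),
    class = "cluster_layout")
  validate_layout(layout)
  layout
}

#' @export
print.cluster_layout <- function(x, ...) {
  cat("cluster_layout:", nrow(x$positions), "clusters,",
      sum(x$channels), "channels, cell radius", x$cell$radius, "um\n")
  invisible(x)
}

#' Write / read a layout as plain tabular text
#'
#' One row per cluster: x, y, z (µm) and channel count, tab separated with
#' a header line.
#'
#' @param layout a `cluster_layout`.
#' @param path file path.
#' @rdname layout_io
#' @export
write_layout <- function(layout, path) {
  df <- data.frame(layout$positions, n_channels = layout$channels)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param cell a [cell_shape()] for the read layout.
#' @rdname layout_io
#' @export
read_layout <- function(path, cell = cell_shape()) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  cluster_layout(as.matrix(df[, c("x", "y", "z")]), df$n_channels, cell)
}
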