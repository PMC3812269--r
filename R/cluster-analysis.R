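#' Distance-cutoff clustering of fullerene balls in one frame
#'
#' Builds a proximity graph with an edge whenever the inter-fullerene
#' distance falls below `cutoff` (default 0.6 nm) and returns its connected
#' components. The distance is the minimal atom-atom distance
#' ([min_interball_distance()]) for atomistic balls; for single-site
#' trajectories the surface gap `d_COM - 2 * radius` is used, which matches
#' the facing-atom gap of rigid cages to within a few hundredths of a nm.
#' A COM-based measure can be selected explicitly.
#'
#' @param x an `md_frame` containing fullerene atoms, a list of
#'   `fullerene_ball`s, or an n x 3 matrix of ball centres.
#' @param cutoff nm.
#' @param box optional [simulation_box()] (taken from the frame when `x` is
#'   a frame).
#' @param method `"atom"` (minimal atom-atom / surface gap, default) or
#'   `"com"` (raw centre distance).
#' @param radius cage radius used for the surface-gap reduction of centre
#'   coordinates, nm.
#' @param time time stamp attached to the assignment, ps.
#' @return object of class `cluster_assignment`: list with `time` and
#'   `partition` (list of integer vectors of ball ids, a disjoint cover).
#' @export
cluster_frame <- function(x, cutoff = 0.6, box = NULL,
                          method = c("atom", "com"), radius = 0.35,
                          time = NULL) {
  method <- match.arg(method)
  if (inherits(x, "md_frame")) {
    if (is.null(box)) box <- x$box
    if (is.null(time)) time <- x$time
    x <- frame_balls(x)
  }
  if (is.null(time)) time <- 0
  if (is.list(x) && length(x) && inherits(x[[1]], "fullerene_ball")) {
    ids <- vapply(x, function(b) b$ball_id, integer(1))
    n <- length(x)
    if (n == 0L) stop("invalid-input: no balls in frame")
    D <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
      D[i, j] <- D[j, i] <- if (method == "atom") {
        min_interball_distance(x[[i]], x[[j]], box)
      } else {
        min_image_distance(x[[i]]$center, x[[j]]$center, box)
      }
    }
  } else {
    X <- as.matrix(x)
    n <- nrow(X)
    if (!n) stop("invalid-input: no balls in frame")
    ids <- seq_len(n)
    D <- .min_image_dmat(X, X, box)
    if (method == "atom") D <- D - 2 * radius  # surface gap for point sites
    diag(D) <- Inf
  }
  adj <- (D < cutoff) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  structure(list(
    time = time,
    partition = unname(lapply(split(ids, comp), as.integer))
  ), class = "cluster_assignment")
}

#' Largest-cluster size over a trajectory, block-averaged
#'
#' Per frame, the size of the largest connected component of the proximity
#' graph; per block (default 1 ns), the arithmetic mean of those integer
#' sizes (the published growth curves are 1-ns block averages, so the block
#' mean may be fractional).
#'
#' @param traj a `ball_trajectory` or a list of `md_frame`s.
#' @param cutoff clustering cutoff, nm.
#' @param block block length, ps.
#' @param ... passed to [cluster_frame()].
#' @return object of class `cluster_size_series`: data.frame with
#'   `block_time` (block midpoint, ps) and `largest_size`; attributes
#'   `block` and `n_balls`.
#' @export
largest_cluster_series <- function(traj, cutoff = 0.6, block = 1000, ...) {
  if (inherits(traj, "ball_trajectory")) {
    times <- traj$times
    per_frame <- vapply(traj$positions, function(X) {
      ca <- cluster_frame(X, cutoff = cutoff, box = traj$box,
                          radius = traj$radius, ...)
      max(lengths(ca$partition))
    }, numeric(1))
    n_balls <- nrow(traj$positions[[1]])
  } else if (is.list(traj) && length(traj) && inherits(traj[[1]], "md_frame")) {
    times <- vapply(traj, function(f) f$time, numeric(1))
    per_frame <- vapply(traj, function(f) {
      ca <- cluster_frame(f, cutoff = cutoff, ...)
      max(lengths(ca$partition))
    }, numeric(1))
    n_balls <- length(frame_balls(traj[[1]]))
  } else {
    stop("invalid-input: empty trajectory")
  }
  if (!length(times)) stop("invalid-input: empty trajectory")
  if (is.unsorted(times)) stop("invalid-input: frames must be time-ordered")
  idx <- floor((times - min(times)) / block)
  agg <- tapply(per_frame, idx, mean)
  mids <- (as.numeric(names(agg)) + 0.5) * block + min(times)
  structure(data.frame(block_time = mids, largest_size = as.numeric(agg)),
            class = c("cluster_size_series", "data.frame"),
            block = block, n_balls = n_balls)
}

#' Classify the stacking motif of a small cluster
#'
#' Geometric classification of 2-6 centre-of-mass coordinates by contact
#' topology. With `d0` the minimum pairwise distance, contacts are pairs
#' closer than `(1 + contact_tol) * d0`. Labels follow the motif taxonomy of
#' small fullerene aggregates:
#' * N=2: `pair`
#' * N=3, 3 contacts: `equilateral_triangle`
#' * N=4, 6 contacts: `tetrahedron`
#' * N=5, 9 contacts (+ apex-apex near sqrt(8/3) d0): `trigonal_bipyramid_regular`
#' * N=5, 8 contacts with a 6-contact 4-subset: `trigonal_bipyramid_deformed`
#'   (a regular tetrahedron plus a fifth particle riding on one edge)
#' * N=6, 12 contacts, 3 equal diagonals near sqrt(2) d0: `octahedron_regular`
#' * N=6, 12 contacts, a 9-contact 5-subset plus a 3-contact sixth vertex:
#'   `octahedron_deformed` (trigonal bipyramid + face-capping tetrahedron)
#' * anything else: `irregular`
#'
#' @param com_coords N x 3 matrix, nm.
#' @param contact_tol fractional tolerance on the contact distance
#'   (default 0.1).
#' @return a single character label.
#' @export
motif_classify <- function(com_coords, contact_tol = 0.1) {
  X <- as.matrix(com_coords)
  n <- nrow(X)
  if (n < 2L || n > 6L) stop("unsupported-size: motif classification needs 2..6 balls")
  D <- as.matrix(dist(X))
  ut <- D[upper.tri(D)]
  d0 <- min(ut)
  contact <- D < (1 + contact_tol) * d0 & upper.tri(D)
  n_contact <- sum(contact)
  cmat <- contact | t(contact)
  long <- ut[ut >= (1 + contact_tol) * d0]

  if (n == 2L) return("pair")
  if (n == 3L) return(if (n_contact == 3L) "equilateral_triangle" else "irregular")
  if (n == 4L) return(if (n_contact == 6L) "tetrahedron" else "irregular")

  subset_contacts <- function(idx) sum(cmat[idx, idx]) / 2
  if (n == 5L) {
    if (n_contact == 9L) {
      # the single long distance is the apex-apex diagonal of the bipyramid
      if (length(long) == 1L && abs(long / d0 - sqrt(8 / 3)) < contact_tol * sqrt(8 / 3)) {
        return("trigonal_bipyramid_regular")
      }
      return("irregular")
    }
    if (n_contact == 8L) {
      has_tetra <- any(vapply(seq_len(5), function(drop)
        subset_contacts(setdiff(1:5, drop)) == 6L, logical(1)))
      if (has_tetra) return("trigonal_bipyramid_deformed")
    }
    return("irregular")
  }
  # n == 6
  if (n_contact == 12L) {
    if (length(long) == 3L &&
        all(abs(long / d0 - sqrt(2)) < contact_tol * sqrt(2))) {
      return("octahedron_regular")
    }
    for (drop in seq_len(6)) {
      rest <- setdiff(1:6, drop)
      if (subset_contacts(rest) == 9L && sum(cmat[drop, rest]) == 3L) {
        return("octahedron_deformed")
      }
    }
  }
  "irregular"
}

#' Lifetimes of small nucleus clusters in a size series
#'
#' Durations of the maximal runs during which the largest cluster size stays
#' within the nucleus range (default 2-3 particles) before first growing
#' beyond it -- the transient 2-3 particle nuclei that template subsequent
#' aggregate growth. A run still open at the end of the series is reported
#' with `censored = TRUE`.
#'
#' @param series a [largest_cluster_series()] result (or any data.frame with
#'   `block_time` and `largest_size`).
#' @param nucleus_sizes sizes counting as a nucleus (an inclusive range is
#'   taken from their min and max so fractional block means are handled).
#' @return data.frame with `start_time`, `duration` (ps) and `censored`;
#'   zero rows when no nucleus ever forms.
#' @export
nucleus_lifetimes <- function(series, nucleus_sizes = c(2, 3)) {
  stopifnot(nrow(series) >= 1L)
  block <- attr(series, "block")
  if (is.null(block)) {
    block <- if (nrow(series) > 1L) diff(series$block_time[1:2]) else 1000
  }
  lo <- min(nucleus_sizes); hi <- max(nucleus_sizes)
  s <- series$largest_size
  out <- data.frame(start_time = numeric(0), duration = numeric(0),
                    censored = logical(0))
  i <- 1L
  n <- length(s)
  while (i <= n) {
    if (s[i] >= lo && s[i] <= hi) {
      j <- i
      while (j < n && s[j + 1L] >= lo && s[j + 1L] <= hi) j <- j + 1L
      grew <- j < n && s[j + 1L] > hi
      ended <- j == n
      if (grew || ended) {
        out <- rbind(out, data.frame(
          start_time = series$block_time[i],
          duration = (j - i + 1L) * block,
          censored = ended && !grew))
      }
      # runs that end by shrinking below the range are not nucleus->growth
      # events and are dropped
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}
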