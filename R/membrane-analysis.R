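#' Locate the membrane midplane and half thickness
#'
#' Head beads are split into leaflets at the median head z; the centre is
#' the midpoint of the two leaflet mean head heights, and the half thickness
#' is half their separation. Head beads rather than whole-lipid centres keep
#' the estimate robust to tail disorder.
#'
#' @param frame an `md_frame` with `lipid_head` atoms in two leaflets.
#' @return list with `center_z` and `half_thickness`, nm.
#' @export
membrane_center <- function(frame) {
  stopifnot(inherits(frame, "md_frame"))
  hz <- frame$atoms$z[frame$atoms$label == "lipid_head"]
  if (length(hz) < 2L) stop("not-a-bilayer: need head atoms in two leaflets")
  med <- stats::median(hz)
  top <- hz[hz > med]
  bot <- hz[hz <= med]
  if (!length(top) || !length(bot) ||
      abs(mean(top) - mean(bot)) < 1e-9) {
    stop("not-a-bilayer: all head atoms on one side")
  }
  list(center_z = (mean(top) + mean(bot)) / 2,
       half_thickness = (mean(top) - mean(bot)) / 2)
}

#' Insertion depth of fullerene balls over a trajectory
#'
#' Signed distance of each ball centre from the membrane midplane,
#' `z_COM - center_z` (positive = upper-leaflet side), with the
#' fullerene-free half thickness attached as the leaflet-border reference:
#' a ball with |depth| below the reference line is inside the membrane.
#'
#' @param traj a `ball_trajectory`, or a list of `md_frame`s containing
#'   fullerene atoms.
#' @param reference_half_thickness nm; the pure-membrane half thickness used
#'   as the reference border.
#' @param center_z membrane centre, nm. Required for `ball_trajectory`
#'   input; for frame lists it defaults to the per-frame
#'   [membrane_center()].
#' @return object of class `depth_series`: data.frame with `time`,
#'   `ball_id`, `depth` (signed nm); attribute `reference_half_thickness`.
#' @export
insertion_depth <- function(traj, reference_half_thickness, center_z = NULL) {
  stopifnot(reference_half_thickness > 0)
  if (inherits(traj, "ball_trajectory")) {
    if (is.null(center_z)) {
      stop("center_z is required for single-site ball trajectories")
    }
    rows <- lapply(seq_along(traj$times), function(f) {
      X <- traj$positions[[f]]
      data.frame(time = traj$times[f], ball_id = seq_len(nrow(X)),
                 depth = X[, 3] - center_z)
    })
  } else {
    stopifnot(is.list(traj), length(traj) >= 1L,
              inherits(traj[[1]], "md_frame"))
    rows <- lapply(traj, function(fr) {
      cz <- if (is.null(center_z)) membrane_center(fr)$center_z else center_z
      balls <- frame_balls(fr)
      data.frame(time = fr$time,
                 ball_id = vapply(balls, function(b) b$ball_id, integer(1)),
                 depth = vapply(balls, function(b) b$center[3], numeric(1)) - cz)
    })
  }
  structure(do.call(rbind, rows),
            class = c("depth_series", "data.frame"),
            reference_half_thickness = reference_half_thickness)
}

#' Number-density profile along the membrane normal
#'
#' Per-component atom counts in z bins referenced to the membrane centre,
#' divided by bin volume and frame count. Bins cover the full z range of the
#' data, so for every component the profile integrates back to its atom
#' count: `sum(density) * bin_width * box_area = count`.
#'
#' Profiles are computed against the per-frame instantaneous membrane centre
#' (removing bilayer drift) unless a fixed `center_z` is given; no leaflet
#' symmetrisation is applied.
#'
#' @param frames list of `md_frame`s (or a single frame).
#' @param components labels to profile (default all four).
#' @param bin_width nm.
#' @param center_z fixed membrane centre; `NULL` = per-frame
#'   [membrane_center()].
#' @return object of class `density_profile`: data.frame with `bin_center`
#'   (nm, relative to the membrane centre) and one density column
#'   (nm^-3) per component; attributes `bin_width` and `box_area`.
#' @export
density_profile <- function(frames, components = .component_labels,
                            bin_width = 0.1, center_z = NULL) {
  stopifnot(bin_width > 0)
  if (inherits(frames, "md_frame")) frames <- list(frames)
  stopifnot(length(frames) >= 1L)
  area <- prod(frames[[1]]$box$lengths[1:2])
  rel <- lapply(frames, function(fr) {
    cz <- if (is.null(center_z)) membrane_center(fr)$center_z else center_z
    data.frame(dz = fr$atoms$z - cz, label = fr$atoms$label)
  })
  rel <- do.call(rbind, rel)
  lo <- floor(min(rel$dz) / bin_width) * bin_width
  hi <- ceiling(max(rel$dz) / bin_width) * bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  mids <- head(breaks, -1L) + bin_width / 2
  out <- data.frame(bin_center = mids)
  for (comp in components) {
    cnt <- hist(rel$dz[rel$label == comp], breaks = breaks,
                plot = FALSE, right = FALSE)$counts
    out[[comp]] <- cnt / (area * bin_width * length(frames))
  }
  structure(out, class = c("density_profile", "data.frame"),
            bin_width = bin_width, box_area = area)
}

#' Lipid orientational order parameter
#'
#' For each lipid the molecular long axis is the minimal-moment principal
#' axis of its unit-mass inertia tensor, signed toward the lipid's own
#' leaflet outward normal; the two remaining principal axes (maximal moment
#' = molecular x, middle = molecular y) complete the molecular frame. With
#' `theta_a` the angle between molecular axis a and the bilayer normal,
#'
#'   `S_aa = < (3 cos^2 theta_a - 1) / 2 >`  over lipids,
#'
#' and the deuterium-order-style combination
#' `S_cd = -(2/3) S_xx - (1/3) S_yy`. Perfectly aligned long axes give
#' `S_zz = 1`, `S_xx = S_yy = -1/2`, `S_cd = 1/2`; isotropic axes give 0.
#'
#' @param frame an `md_frame` with lipid molecules of >= 3 atoms.
#' @param normal bilayer normal (default +z).
#' @return object of class `order_parameter`: list with `S_xx`, `S_yy`,
#'   `S_zz`, `S_cd`, `n_lipids`.
#' @export
order_parameter <- function(frame, normal = c(0, 0, 1)) {
  stopifnot(inherits(frame, "md_frame"))
  normal <- normal / sqrt(sum(normal^2))
  a <- frame$atoms[frame$atoms$label %in% c("lipid_head", "lipid_tail"), ]
  if (!nrow(a)) stop("not-a-bilayer: no lipid atoms")
  cz <- membrane_center(frame)$center_z
  xyz <- as.matrix(a[, c("x", "y", "z")])
  groups <- split(seq_len(nrow(a)), a$molecule_id)
  ids <- names(groups)
  n_degenerate <- 0L
  cos2 <- matrix(NA_real_, length(groups), 3L)  # columns: mol x, y, z axes
  for (q in seq_along(groups)) {
    m <- xyz[groups[[q]], , drop = FALSE]
    if (nrow(m) < 3L) next
    zmean <- mean(m[, 3])
    m <- sweep(m, 2L, colMeans(m))
    # unit-mass inertia tensor
    I3 <- diag(3) * sum(m^2) - t(m) %*% m
    ev <- eigen(I3, symmetric = TRUE)   # eigenvalues descending
    vals <- ev$values
    # collinear atoms give two equal moments: the axes in the degenerate
    # plane are then only defined up to LAPACK's basis choice
    if (min(diff(rev(vals))) / max(vals[1], 1e-12) < 1e-8) {
      n_degenerate <- n_degenerate + 1L
    }
    molz <- ev$vectors[, 3]  # minimal moment: the molecular long axis
    molx <- ev$vectors[, 1]  # maximal moment
    # sign the long axis toward the leaflet outward normal
    outward <- if (zmean > cz) 1 else -1
    if (sum(molz * normal) * outward < 0) molz <- -molz
    moly <- c(molz[2] * molx[3] - molz[3] * molx[2],
              molz[3] * molx[1] - molz[1] * molx[3],
              molz[1] * molx[2] - molz[2] * molx[1])
    cos2[q, ] <- c(sum(molx * normal), sum(moly * normal),
                   sum(molz * normal))^2
  }
  if (n_degenerate > 0L) {
    warning("degenerate inertia tensor for ", n_degenerate,
            " molecule(s); axes resolved by lowest-index eigenvector")
  }
  ok <- stats::complete.cases(cos2)
  cos2 <- cos2[ok, , drop = FALSE]
  S <- colMeans((3 * cos2 - 1) / 2)
  structure(list(S_xx = S[1], S_yy = S[2], S_zz = S[3],
                 S_cd = -2 / 3 * S[1] - 1 / 3 * S[2],
                 n_lipids = sum(ok)),
            class = "order_parameter")
}

#' @export
print.order_parameter <- function(x, ...) {
  cat(sprintf(
    "<order_parameter> n=%d  S_xx=%.4f S_yy=%.4f S_zz=%.4f  S_cd=%.4f\n",
    x$n_lipids, x$S_xx, x$S_yy, x$S_zz, x$S_cd))
  invisible(x)
}

#' Grid-based bilayer thickness and area per lipid
#'
#' GridMAT-style maps: the box xy plane is tiled with `grid_n x grid_n`
#' cells; per cell the thickness is the z separation of the closest
#' (periodic xy) head bead in the top and bottom leaflets, and each cell is
#' assigned to the lipid owning its nearest same-leaflet head, so a lipid's
#' area is its cell count times the cell area. Per leaflet the per-lipid
#' areas tile the box exactly.
#'
#' @param frame bilayer `md_frame`.
#' @param grid_n cells per box edge (>= 4).
#' @return object of class `bilayer_grid_maps`: `thickness_map`
#'   (`grid_n x grid_n`, nm), `apl_top` / `apl_bottom` (named per-lipid
#'   areas, nm^2), `mean_thickness`, `mean_apl_top`, `mean_apl_bottom`,
#'   `cell_area`.
#' @export
grid_thickness_apl <- function(frame, grid_n = 20L) {
  stopifnot(inherits(frame, "md_frame"), grid_n >= 4L)
  L <- frame$box$lengths
  heads <- frame$atoms[frame$atoms$label == "lipid_head", ]
  if (!nrow(heads)) stop("not-a-bilayer: no head atoms")
  cz <- membrane_center(frame)$center_z
  top <- heads[heads$z > cz, ]
  bot <- heads[heads$z <= cz, ]
  if (!nrow(top) || !nrow(bot)) stop("not-a-bilayer: a leaflet has no heads")

  gx <- (seq_len(grid_n) - 0.5) * L[1] / grid_n
  gy <- (seq_len(grid_n) - 0.5) * L[2] / grid_n
  cells <- as.matrix(expand.grid(x = gx, y = gy))
  nearest <- function(leaf) {
    dx <- outer(cells[, 1], leaf$x, "-")
    dy <- outer(cells[, 2], leaf$y, "-")
    dx <- dx - L[1] * round(dx / L[1])
    dy <- dy - L[2] * round(dy / L[2])
    max.col(-(dx^2 + dy^2), ties.method = "first")
  }
  it <- nearest(top)
  ib <- nearest(bot)
  thick <- top$z[it] - bot$z[ib]
  cell_area <- (L[1] / grid_n) * (L[2] / grid_n)
  apl <- function(leaf, idx) {
    cnt <- table(factor(leaf$molecule_id[idx],
                        levels = unique(leaf$molecule_id)))
    as.numeric(cnt) * cell_area
  }
  apl_top <- setNames(apl(top, it), unique(top$molecule_id))
  apl_bot <- setNames(apl(bot, ib), unique(bot$molecule_id))
  structure(list(
    thickness_map = matrix(thick, grid_n, grid_n),
    apl_top = apl_top, apl_bottom = apl_bot,
    mean_thickness = mean(thick),
    mean_apl_top = mean(apl_top), mean_apl_bottom = mean(apl_bot),
    cell_area = cell_area, grid_n = as.integer(grid_n)
  ), class = "bilayer_grid_maps")
}

#' @export
print.bilayer_grid_maps <- function(x, ...) {
  cat(sprintf(
    "<bilayer_grid_maps %dx%d> thickness %.3f nm, APL top %.4f / bottom %.4f nm^2\n",
    x$grid_n, x$grid_n, x$mean_thickness, x$mean_apl_top, x$mean_apl_bottom))
  invisible(x)
}
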