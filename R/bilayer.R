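#' Specification of a synthetic pseudo-lipid bilayer
#'
#' Parametric bilayer used as a ground-truth fixture for the membrane
#' analysis operators: two leaflets of single-head, multi-bead-tail
#' pseudo-lipids on a jittered square lattice, with exact head-plane
#' separation and area per lipid, tail directors drawn from a von
#' Mises-Fisher distribution around the (inward) bilayer normal, and water
#' bead slabs on both sides. Default thickness and area per lipid are the
#' fluid-phase DOPC reference values (4.26 nm, 0.599 nm^2).
#'
#' @param n_lipids_per_leaflet lipids per leaflet (default 64, i.e. a
#'   128-lipid patch).
#' @param target_area_per_lipid nm^2 per lipid.
#' @param target_thickness head-plane separation, nm.
#' @param tail_beads_per_lipid tail beads after the head bead.
#' @param tilt_concentration von Mises-Fisher concentration of the tail
#'   director about the normal; 0 = isotropic, `Inf` = perfectly aligned.
#' @param n_water_layers water bead layers per side.
#' @param tail_bond_length spacing between consecutive tail beads, nm.
#' @param xy_jitter lateral head jitter (sd, nm) so grid maps are exercised
#'   off-lattice; 0 gives a perfect lattice.
#' @param seed RNG seed.
#' @return object of class `bilayer_spec`.
#' @export
bilayer_spec <- function(n_lipids_per_leaflet = 64L,
                         target_area_per_lipid = 0.599,
                         target_thickness = 4.26,
                         tail_beads_per_lipid = 8L,
                         tilt_concentration = 20,
                         n_water_layers = 3L,
                         tail_bond_length = 0.15,
                         xy_jitter = 0,
                         seed = 1L) {
  stopifnot(target_area_per_lipid > 0, target_thickness > 0,
            tilt_concentration >= 0, n_lipids_per_leaflet >= 4L,
            tail_beads_per_lipid >= 2L)
  structure(as.list(environment()), class = "bilayer_spec")
}

# von Mises-Fisher unit vectors about +z with concentration kappa
.sample_vmf_z <- function(n, kappa) {
  if (is.infinite(kappa)) {
    return(matrix(rep(c(0, 0, 1), each = n), n, 3L))
  }
  u <- runif(n)
  w <- if (kappa == 0) 2 * u - 1 else
    1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  cbind(s * cos(phi), s * sin(phi), w)
}

#' Build a synthetic pseudo-lipid bilayer frame
#'
#' See [bilayer_spec()] for the generative model. The head planes sit at
#' `center_z +- target_thickness / 2` exactly; the box xy area is
#' `n_lipids_per_leaflet * target_area_per_lipid` exactly.
#'
#' @param spec a [bilayer_spec()].
#' @return an `md_frame` (xy-periodic, z non-periodic).
#' @export
build_synthetic_bilayer <- function(spec) {
  stopifnot(inherits(spec, "bilayer_spec"))
  set.seed(spec$seed)
  n_side <- ceiling(sqrt(spec$n_lipids_per_leaflet))
  if (n_side^2 != spec$n_lipids_per_leaflet) {
    stop("placement-failure: n_lipids_per_leaflet must be a perfect square")
  }
  a <- sqrt(spec$target_area_per_lipid)   # lattice spacing
  Lxy <- n_side * a
  tail_len <- spec$tail_beads_per_lipid * spec$tail_bond_length
  water_gap <- 0.3
  slab <- spec$n_water_layers * water_gap + 0.4
  Lz <- spec$target_thickness + 2 * slab + 1.0
  cz <- Lz / 2
  z_top <- cz + spec$target_thickness / 2
  z_bot <- cz - spec$target_thickness / 2

  lat <- as.matrix(expand.grid(x = (seq_len(n_side) - 0.5) * a,
                               y = (seq_len(n_side) - 0.5) * a))
  mk_leaflet <- function(zhead, inward_sign, id0) {
    nl <- nrow(lat)
    heads <- lat
    if (spec$xy_jitter > 0) {
      heads <- heads + matrix(rnorm(2 * nl, sd = spec$xy_jitter), nl, 2L)
      heads <- heads %% Lxy
    }
    dirs <- .sample_vmf_z(nl, spec$tilt_concentration)
    dirs[, 3] <- dirs[, 3] * inward_sign   # tails point into the bilayer
    # random azimuth for the chain zig-zag (see below)
    azim <- runif(nl, 0, 2 * pi)
    atoms <- vector("list", nl)
    for (i in seq_len(nl)) {
      k <- seq_len(spec$tail_beads_per_lipid) * spec$tail_bond_length
      # alternate beads off-axis so the chain zig-zags like a real tail;
      # this keeps the inertia tensor non-degenerate (a straight rod has
      # no defined short axes)
      u <- dirs[i, ]
      ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      p1 <- ref - sum(ref * u) * u
      p1 <- p1 / sqrt(sum(p1^2))
      p2 <- c(u[2] * p1[3] - u[3] * p1[2], u[3] * p1[1] - u[1] * p1[3],
              u[1] * p1[2] - u[2] * p1[1])
      perp <- cos(azim[i]) * p1 + sin(azim[i]) * p2
      wig <- 0.05 * (-1)^(seq_along(k))
      tail <- cbind(heads[i, 1] + u[1] * k + perp[1] * wig,
                    heads[i, 2] + u[2] * k + perp[2] * wig,
                    zhead + u[3] * k + perp[3] * wig)
      atoms[[i]] <- data.frame(
        x = c(heads[i, 1], tail[, 1]) %% Lxy,
        y = c(heads[i, 2], tail[, 2]) %% Lxy,
        z = c(zhead, tail[, 3]),
        label = c("lipid_head", rep("lipid_tail", spec$tail_beads_per_lipid)),
        molecule_id = id0 + i)
    }
    do.call(rbind, atoms)
  }
  top <- mk_leaflet(z_top, -1, 0L)
  bot <- mk_leaflet(z_bot, +1, spec$n_lipids_per_leaflet)

  # water slabs on a simple cubic lattice outside the head planes
  mk_water <- function(z0, sign, id0) {
    zs <- z0 + sign * (water_gap * seq_len(spec$n_water_layers))
    g <- expand.grid(x = seq(water_gap / 2, Lxy - 1e-9, by = water_gap),
                     y = seq(water_gap / 2, Lxy - 1e-9, by = water_gap),
                     z = zs)
    data.frame(x = g$x, y = g$y, z = g$z, label = "water",
               molecule_id = id0 + seq_len(nrow(g)))
  }
  id0 <- 2L * spec$n_lipids_per_leaflet
  w1 <- mk_water(z_top + 0.2, +1, id0)
  w2 <- mk_water(z_bot - 0.2, -1, id0 + nrow(w1))
  atoms <- rbind(top, bot, w1, w2)
  new_frame(atoms, simulation_box(c(Lxy, Lxy, Lz),
                                  periodic = c(TRUE, TRUE, FALSE)),
            time = 0)
}

#' Insert a fullerene ball into a bilayer frame
#'
#' Places the ball centre at `membrane_center + depth` on the bilayer normal
#' (box xy centre laterally) and carves a simple cavity: lipids whose head
#' xy position falls within `exclusion` of the ball axis are displaced
#' radially in plane to the exclusion radius (whole molecule, min-image
#' aware). Total lipid count is preserved.
#'
#' @param frame bilayer `md_frame`.
#' @param ball a [build_c60()] ball; its current centre is ignored.
#' @param depth signed nm from the membrane centre (0 = midplane).
#' @param exclusion cavity radius, nm (default ball radius + 0.35).
#' @return a new `md_frame` containing the bilayer plus the ball.
#' @export
inject_ball_into_bilayer <- function(frame, ball, depth, exclusion = NULL) {
  stopifnot(inherits(frame, "md_frame"), inherits(ball, "fullerene_ball"))
  mc <- membrane_center(frame)
  L <- frame$box$lengths
  if (abs(depth) >= L[3]) stop("invalid-argument: |depth| exceeds the box")
  r_ball <- mean(sqrt(rowSums(sweep(ball$atom_coords, 2, ball$center)^2)))
  if (is.null(exclusion)) exclusion <- r_ball + 0.35
  target <- c(L[1] / 2, L[2] / 2, mc$center_z + depth)
  shift <- target - ball$center
  atom_coords <- sweep(ball$atom_coords, 2L, shift, "+")

  atoms <- frame$atoms
  new_id <- max(atoms$molecule_id) + 1L
  # displace lipids whose head is inside the exclusion cylinder
  heads <- atoms[atoms$label == "lipid_head", ]
  for (i in seq_len(nrow(heads))) {
    dxy <- c(heads$x[i], heads$y[i]) - target[1:2]
    dxy <- dxy - L[1:2] * round(dxy / L[1:2])
    d <- sqrt(sum(dxy^2))
    if (d < exclusion) {
      u <- if (d < 1e-9) c(1, 0) else dxy / d
      push <- (exclusion - d) * u
      sel <- atoms$molecule_id == heads$molecule_id[i]
      atoms$x[sel] <- (atoms$x[sel] + push[1]) %% L[1]
      atoms$y[sel] <- (atoms$y[sel] + push[2]) %% L[2]
    }
  }
  ball_df <- data.frame(x = atom_coords[, 1], y = atom_coords[, 2],
                        z = atom_coords[, 3], label = "fullerene",
                        molecule_id = new_id)
  new_frame(rbind(atoms, ball_df), frame$box, time = frame$time)
}
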