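#' Coordinate frame with component labels
#'
#' A frame bundles atom coordinates with a periodic box, a time stamp and a
#' component label per atom (`fullerene`, `lipid_head`, `lipid_tail`,
#' `water`). `molecule_id` groups atoms belonging to one molecule and must be
#' contiguous within a molecule.
#'
#' @param atoms data.frame with columns `x`, `y`, `z` (nm), `label`
#'   (character, one of the four component labels) and `molecule_id`
#'   (integer).
#' @param box a [simulation_box()].
#' @param time time stamp, ps.
#' @return An object of class `md_frame`.
#' @export
new_frame <- function(atoms, box, time = 0) {
  stopifnot(is.data.frame(atoms),
            all(c("x", "y", "z", "label", "molecule_id") %in% names(atoms)),
            inherits(box, "simulation_box"))
  bad <- setdiff(unique(atoms$label), .component_labels)
  if (length(bad)) {
    stop("invalid-argument: unknown component label(s): ",
         paste(bad, collapse = ", "))
  }
  # molecule ids must be contiguous runs
  runs <- rle(atoms$molecule_id)$values
  if (anyDuplicated(runs)) {
    stop("invalid-argument: molecule_id groups must be contiguous")
  }
  structure(list(atoms = atoms, box = box, time = as.numeric(time)),
            class = "md_frame")
}

.component_labels <- c("fullerene", "lipid_head", "lipid_tail", "water")

#' @export
print.md_frame <- function(x, ...) {
  tab <- table(factor(x$atoms$label, levels = .component_labels))
  cat(sprintf("<md_frame t=%g ps> %d atoms in %.2f x %.2f x %.2f nm box\n",
              x$time, nrow(x$atoms),
              x$box$lengths[1], x$box$lengths[2], x$box$lengths[3]))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Extract fullerene balls from a frame
#'
#' Groups atoms labelled `fullerene` by `molecule_id` and rebuilds
#' [build_c60()]-style ball objects (centres are atom centroids).
#'
#' @param frame an `md_frame`.
#' @return list of `fullerene_ball` objects (possibly empty).
#' @export
frame_balls <- function(frame) {
  stopifnot(inherits(frame, "md_frame"))
  a <- frame$atoms[frame$atoms$label == "fullerene", , drop = FALSE]
  if (!nrow(a)) return(list())
  lapply(unique(a$molecule_id), function(id) {
    m <- as.matrix(a[a$molecule_id == id, c("x", "y", "z")])
    structure(list(ball_id = as.integer(id), center = colMeans(m),
                   atom_coords = m),
              class = "fullerene_ball")
  })
}

#' System composition bookkeeping
#'
#' Per-component molecule and atom counts for a fullerene + membrane + water
#' system. Fullerenes carry 60 atoms each and waters 3 (rigid 3-site water);
#' atoms per lipid is configurable (138 for all-atom DOPC, fewer for
#' pseudo-lipids).
#'
#' @param n_fullerenes,n_lipids,n_waters molecule counts.
#' @param atoms_per_lipid sites per lipid molecule (default 138, all-atom DOPC).
#' @return An object of class `system_composition` with an `atom_counts`
#'   vector.
#' @examples
#' system_composition(6, 128, 5547)$atom_counts
#' @export
system_composition <- function(n_fullerenes, n_lipids = 0L, n_waters = 0L,
                               atoms_per_lipid = 138L) {
  structure(list(
    n_fullerenes = as.integer(n_fullerenes),
    n_lipids = as.integer(n_lipids),
    n_waters = as.integer(n_waters),
    atom_counts = c(fullerene = 60L * as.integer(n_fullerenes),
                    lipid = as.integer(atoms_per_lipid) * as.integer(n_lipids),
                    water = 3L * as.integer(n_waters))
  ), class = "system_composition")
}

#' Assemble an initial fullerene (+ membrane) system
#'
#' Places `n_balls` C60 cages in the box with at least `offset` nm mutual
#' centre separation, and -- when a membrane frame is supplied -- at least
#' `offset` nm between each cage centre and the nearer membrane surface,
#' split as evenly as possible between the two leaflet sides (3 above /
#' 3 below for 6 balls, mirroring the standard setup). Without a membrane a
#' single ball is placed at the box centre and further balls at random
#' positions honouring the separation.
#'
#' @param n_balls number of C60 cages (>= 1).
#' @param box a [simulation_box()].
#' @param membrane optional `md_frame` of a bilayer to merge with; its box is
#'   ignored in favour of `box`.
#' @param offset minimum separation, nm (default 2.0).
#' @param radius cage radius, nm.
#' @param seed RNG seed for placement and orientations.
#' @param max_tries placement attempts before giving up.
#' @return list with `frame` (`md_frame`), `balls` (list of `fullerene_ball`)
#'   and `composition` (`system_composition`).
#' @export
assemble_initial_system <- function(n_balls, box, membrane = NULL,
                                    offset = 2.0, radius = 0.35, seed = 1L,
                                    max_tries = 2000L) {
  stopifnot(n_balls >= 1L, offset > 0, inherits(box, "simulation_box"))
  set.seed(seed)
  L <- box$lengths

  if (is.null(membrane)) {
    centers <- matrix(L / 2, 1L, 3L, byrow = TRUE)
    while (nrow(centers) < n_balls) {
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        cand <- runif(3) * L
        d <- apply(centers, 1L, function(p)
          min_image_distance(cand, p, box))
        if (all(d >= offset)) { ok <- TRUE; break }
      }
      if (!ok) stop("placement-failure: box too small for requested separations")
      centers <- rbind(centers, cand)
    }
    mem_atoms <- NULL
    n_lip <- 0L
    n_wat <- 0L
    apl_atoms <- 138L
  } else {
    stopifnot(inherits(membrane, "md_frame"))
    mc <- membrane_center(membrane)
    surf_top <- mc$center_z + mc$half_thickness
    surf_bot <- mc$center_z - mc$half_thickness
    n_up <- ceiling(n_balls / 2)
    sides <- c(rep(1, n_up), rep(-1, n_balls - n_up))
    centers <- matrix(NA_real_, 0L, 3L)
    for (i in seq_len(n_balls)) {
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        xy <- runif(2) * L[1:2]
        if (sides[i] > 0) {
          zmin <- surf_top + offset
          zmax <- L[3] - radius
        } else {
          zmin <- radius
          zmax <- surf_bot - offset
        }
        if (zmax <= zmin) stop("placement-failure: no room outside the membrane")
        z <- runif(1, zmin, zmax)
        cand <- c(xy, z)
        d <- if (nrow(centers)) {
          apply(centers, 1L, function(p) min_image_distance(cand, p, box))
        } else Inf
        if (all(d >= offset)) { ok <- TRUE; break }
      }
      if (!ok) stop("placement-failure: box too small for requested separations")
      centers <- rbind(centers, cand)
    }
    mem_atoms <- membrane$atoms
    n_lip <- length(unique(mem_atoms$molecule_id[
      mem_atoms$label %in% c("lipid_head", "lipid_tail")]))
    n_wat <- length(unique(mem_atoms$molecule_id[mem_atoms$label == "water"]))
    lip_atoms <- sum(mem_atoms$label %in% c("lipid_head", "lipid_tail"))
    apl_atoms <- if (n_lip) as.integer(lip_atoms / n_lip) else 138L
  }

  id0 <- if (is.null(mem_atoms)) 0L else max(mem_atoms$molecule_id)
  balls <- lapply(seq_len(n_balls), function(i) {
    build_c60(radius = radius, center = centers[i, ],
              rotation = random_rotation(), ball_id = id0 + i)
  })
  ball_atoms <- do.call(rbind, lapply(balls, function(b) {
    data.frame(x = b$atom_coords[, 1], y = b$atom_coords[, 2],
               z = b$atom_coords[, 3], label = "fullerene",
               molecule_id = b$ball_id)
  }))
  atoms <- rbind(mem_atoms, ball_atoms)
  list(
    frame = new_frame(atoms, box, time = 0),
    balls = balls,
    composition = system_composition(n_balls, n_lip, n_wat,
                                     atoms_per_lipid = apl_atoms)
  )
}
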