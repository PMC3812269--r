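#' Read a GRO single-frame coordinate file
#'
#' Fixed-column GROMACS GRO format, nm units. Component labels are inferred
#' from residue and atom names (see [infer_labels()]) unless a sidecar label
#' map is supplied.
#'
#' @param path file path.
#' @param label_map optional named character vector `molecule_id -> label`
#'   (as written by [write_label_map()]); overrides name-based inference.
#' @return an `md_frame`. The GRO title line's `t= <ps>` field, if present,
#'   sets the frame time.
#' @export
read_gro <- function(path, label_map = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("invalid GRO file: fewer than 3 lines")
  title <- lines[1]
  n <- as.integer(trimws(lines[2]))
  if (is.na(n) || length(lines) < n + 3L) stop("invalid GRO file: bad atom count")
  body <- lines[3:(n + 2L)]
  resid   <- as.integer(substr(body, 1L, 5L))
  resname <- trimws(substr(body, 6L, 10L))
  atname  <- trimws(substr(body, 11L, 15L))
  x <- as.numeric(substr(body, 21L, 28L))
  y <- as.numeric(substr(body, 29L, 36L))
  z <- as.numeric(substr(body, 37L, 44L))
  boxv <- as.numeric(strsplit(trimws(lines[n + 3L]), "\\s+")[[1]])[1:3]
  time <- 0
  tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
  if (length(tm)) time <- as.numeric(sub("t=\\s*", "", tm))
  label <- if (!is.null(label_map)) {
    unname(label_map[as.character(resid)])
  } else {
    infer_labels(resname, atname)
  }
  atoms <- data.frame(x = x, y = y, z = z, label = label, molecule_id = resid)
  new_frame(atoms, simulation_box(boxv), time = time)
}

#' Infer component labels from residue / atom names
#'
#' `C60`/`FUL` residues are fullerene; `SOL`/`WAT`/`TIP3`/`HOH` are water;
#' anything else is a lipid, with atom names starting `H` (head bead) mapped
#' to `lipid_head` and the rest to `lipid_tail`. Matches the naming this
#' package writes; real topologies should use an explicit label map.
#'
#' @param resname,atname character vectors of equal length.
#' @return character vector of component labels.
#' @export
infer_labels <- function(resname, atname) {
  out <- rep("lipid_tail", length(resname))
  out[toupper(resname) %in% c("C60", "FUL")] <- "fullerene"
  out[toupper(resname) %in% c("SOL", "WAT", "TIP3", "HOH")] <- "water"
  lip <- out == "lipid_tail"
  out[lip & startsWith(toupper(atname), "H")] <- "lipid_head"
  out
}

#' Write a frame to GRO
#'
#' Residue names encode the component (`C60`, `LIP`, `SOL`); lipid atom names
#' are `HD`/`TL` for head/tail beads so that [infer_labels()] round-trips.
#'
#' @param frame an `md_frame`.
#' @param path output path.
#' @export
write_gro <- function(frame, path) {
  stopifnot(inherits(frame, "md_frame"))
  a <- frame$atoms
  resname <- c(fullerene = "C60", lipid_head = "LIP", lipid_tail = "LIP",
               water = "SOL")[a$label]
  atname <- c(fullerene = "C", lipid_head = "HD", lipid_tail = "TL",
              water = "OW")[a$label]
  lines <- c(
    sprintf("fullermem frame t= %g", frame$time),
    sprintf("%5d", nrow(a)),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            a$molecule_id %% 100000L, resname, atname,
            seq_len(nrow(a)) %% 100000L, a$x, a$y, a$z),
    sprintf("%10.5f%10.5f%10.5f", frame$box$lengths[1], frame$box$lengths[2],
            frame$box$lengths[3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a molecule-id to component-label sidecar map (JSON)
#'
#' @param frame an `md_frame` (for writing).
#' @param path JSON file path.
#' @return `read_label_map` returns a named character vector.
#' @export
write_label_map <- function(frame, path) {
  a <- frame$atoms
  m <- tapply(a$label, a$molecule_id, function(l) l[1])
  jsonlite::write_json(as.list(m), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  unlist(jsonlite::read_json(path))
}

#' Read / write multi-frame XYZ trajectories
#'
#' Plain XYZ with the time stamp stored in each comment line as `t= <ps>`.
#' Coordinates are nm. The element column carries a one-letter component code
#' (`F` fullerene, `H` lipid head, `T` lipid tail, `W` water).
#'
#' @param path file path.
#' @param box a [simulation_box()] attached to every frame on reading (XYZ
#'   itself stores no box).
#' @param molecule_ids optional integer vector recycled across frames; when
#'   `NULL`, each atom gets its own molecule id.
#' @return `read_xyz` returns a list of `md_frame`s.
#' @export
read_xyz <- function(path, box, molecule_ids = NULL) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  code2label <- c(F = "fullerene", H = "lipid_head", T = "lipid_tail",
                  W = "water")
  while (i <= length(lines)) {
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) break
    comment <- lines[i + 1L]
    time <- 0
    tm <- regmatches(comment, regexpr("t=\\s*[-0-9.eE+]+", comment))
    if (length(tm)) time <- as.numeric(sub("t=\\s*", "", tm))
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    el <- vapply(parts, `[[`, "", 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    mid <- if (is.null(molecule_ids)) seq_len(n) else molecule_ids
    atoms <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        label = unname(code2label[el]), molecule_id = mid)
    frames[[length(frames) + 1L]] <- new_frame(atoms, box, time = time)
    i <- i + 2L + n
  }
  frames
}

#' @rdname read_xyz
#' @param frames list of `md_frame`s (for writing).
#' @export
write_xyz <- function(frames, path) {
  if (inherits(frames, "md_frame")) frames <- list(frames)
  label2code <- c(fullerene = "F", lipid_head = "H", lipid_tail = "T",
                  water = "W")
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    a <- fr$atoms
    writeLines(c(sprintf("%d", nrow(a)), sprintf("t= %g", fr$time),
                 sprintf("%s %12.6f %12.6f %12.6f",
                         label2code[a$label], a$x, a$y, a$z)), con)
  }
  invisible(path)
}
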