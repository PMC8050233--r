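# Accessible-volume dye simulation: sterically allowed dye positions around
# an attachment site, and expected inter-dye distances.

#' Read heavy atoms from a PDB file
#'
#' Parses standard `ATOM` records (hydrogens ignored) into a flat atom table
#' carrying a uniform heavy-atom radius.
#'
#' @param path Path to a PDB file.
#' @param atom_radius Radius assigned to every heavy atom in Å.
#' @return A tibble of class `structure_model`:
#'   `chain, resno, resid, atom, x, y, z, radius`.
#' @export
read_pdb <- function(path, atom_radius = 1.7) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) abort(sprintf("failed to parse %s: %s",
                                                    path, conditionMessage(e))))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  # drop hydrogens by element symbol, falling back to the atom-name convention
  elesy <- at$elesy
  is_h <- if (!is.null(elesy) && !all(is.na(elesy))) {
    toupper(trimws(elesy)) == "H"
  } else {
    grepl("^[0-9]*H", trimws(at$elety))
  }
  at <- at[!is_h, , drop = FALSE]
  if (nrow(at) == 0) abort(sprintf("%s: no heavy ATOM records", path))
  out <- tibble(chain = at$chain, resno = at$resno, resid = at$resid,
                atom = trimws(at$elety),
                x = at$x, y = at$y, z = at$z, radius = atom_radius)
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))) {
    abort(sprintf("%s: non-finite coordinates", path))
  }
  class(out) <- c("structure_model", class(out))
  out
}

#' Accessible-volume simulation parameters
#'
#' Geometry of the dye-linker construct: the dye centre can reach anywhere
#' within `linker_length` of the attachment atom provided a corridor of
#' diameter `linker_width` connects it back to the attachment point and the
#' dye sphere of radius `dye_radius` clashes with no atom. Defaults are the
#' Cy3/Cy5 maleimide values 14.0 / 4.5 / 3.5 Å.
#'
#' @param linker_length Maximum dye-attachment distance in Å.
#' @param linker_width Corridor diameter in Å.
#' @param dye_radius Dye sphere radius in Å.
#' @param grid_spacing Grid resolution in Å (must not exceed `linker_width`).
#' @return An object of class `av_parameters`.
#' @export
av_parameters <- function(linker_length = 14.0, linker_width = 4.5,
                          dye_radius = 3.5, grid_spacing = 1.0) {
  assert_pos(linker_length, "linker_length")
  assert_pos(linker_width, "linker_width")
  assert_pos(dye_radius, "dye_radius")
  assert_pos(grid_spacing, "grid_spacing")
  if (grid_spacing > linker_width) abort("`grid_spacing` must be <= `linker_width`")
  structure(list(linker_length = linker_length, linker_width = linker_width,
                 dye_radius = dye_radius, grid_spacing = grid_spacing),
            class = "av_parameters")
}

# resolve "chain:resno:atom" (e.g. "A:181:CB") to one atom row
resolve_site <- function(structure, site) {
  if (is.character(site) && length(site) == 1) {
    parts <- strsplit(site, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3) abort("`site` must be \"chain:resno:atomName\"")
    hit <- structure$chain == parts[1] &
      structure$resno == as.integer(parts[2]) &
      structure$atom == parts[3]
  } else if (is.numeric(site) && length(site) == 1) {
    hit <- seq_len(nrow(structure)) == site
  } else {
    abort("`site` must be a \"chain:resno:atomName\" string or a row index")
  }
  idx <- which(hit)
  if (length(idx) != 1) {
    abort(sprintf("site does not resolve to exactly one atom (%d matches)",
                  length(idx)))
  }
  idx
}

#' Compute the accessible volume of a tethered dye
#'
#' Grid-based geometric accessible-volume (AV) simulation: a cubic grid of
#' spacing `grid_spacing` is laid over the ball of radius `linker_length`
#' around the attachment atom. A node is an allowed dye position when its
#' distance to every structure atom is at least `dye_radius + atom_radius`;
#' it is reachable when a 26-neighbourhood path of corridor nodes (clearance
#' at least `linker_width/2 + atom_radius`) connects it to the attachment
#' node. The cloud is the set of allowed, reachable nodes with uniform
#' weights. The attachment atom itself is excluded from clash tests.
#'
#' @param structure A [read_pdb()] table (or any tibble with
#'   `x, y, z, radius`).
#' @param site Attachment site, `"chain:resno:atomName"` or a row index.
#' @param params [av_parameters()].
#' @return An object of class `av_cloud`: `points` (tibble of node
#'   coordinates), `attachment`, `n_points`, `volume` (n x spacing^3),
#'   `params`.
#' @export
compute_av <- function(structure, site, params = av_parameters()) {
  if (!all(c("x", "y", "z", "radius") %in% names(structure))) {
    abort("`structure` needs columns x, y, z, radius")
  }
  if (nrow(structure) < 1) abort("empty structure")
  idx <- resolve_site(structure, site)
  att <- c(structure$x[idx], structure$y[idx], structure$z[idx])
  g <- params$grid_spacing
  L <- params$linker_length
  m <- as.integer(ceiling(L / g))
  ax <- seq(-m, m) * g

  # node coordinates relative to the attachment point
  grid_dim <- length(ax)
  coords <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  within <- sqrt(rowSums(coords^2)) <= L

  # clearance: distance to the nearest atom surface (attachment atom excluded)
  atoms <- structure[-idx, , drop = FALSE]
  reach <- L + params$dye_radius + max(c(atoms$radius, 0)) + g
  if (nrow(atoms) > 0) {
    d_att <- sqrt((atoms$x - att[1])^2 + (atoms$y - att[2])^2 + (atoms$z - att[3])^2)
    atoms <- atoms[d_att <= reach, , drop = FALSE]
  }
  clearance <- rep(Inf, nrow(coords))
  if (nrow(atoms) > 0) {
    for (a in seq_len(nrow(atoms))) {
      dx <- coords[, 1] + att[1] - atoms$x[a]
      dy <- coords[, 2] + att[2] - atoms$y[a]
      dz <- coords[, 3] + att[3] - atoms$z[a]
      clearance <- pmin(clearance, sqrt(dx * dx + dy * dy + dz * dz) - atoms$radius[a])
    }
  }
  allowed <- within & clearance >= params$dye_radius
  traversable <- within & clearance >= params$linker_width / 2

  # flood fill over traversable nodes from the attachment node
  trav <- array(traversable, dim = rep(grid_dim, 3))
  visited <- array(FALSE, dim = rep(grid_dim, 3))
  origin <- matrix(rep(m + 1L, 3), nrow = 1)
  if (!trav[origin]) {
    abort("no accessible volume: the attachment site is buried")
  }
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  visited[origin] <- TRUE
  frontier <- origin
  while (nrow(frontier) > 0) {
    nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(o) {
      sweep(frontier, 2, offs[o, ], "+")
    }))
    ok <- nb[, 1] >= 1 & nb[, 1] <= grid_dim &
      nb[, 2] >= 1 & nb[, 2] <= grid_dim &
      nb[, 3] >= 1 & nb[, 3] <= grid_dim
    nb <- nb[ok, , drop = FALSE]
    nb <- nb[!duplicated(nb), , drop = FALSE]
    keep <- trav[nb] & !visited[nb]
    nb <- nb[keep, , drop = FALSE]
    if (nrow(nb) == 0) break
    visited[nb] <- TRUE
    frontier <- nb
  }
  cloud_mask <- as.vector(visited) & allowed
  if (!any(cloud_mask)) {
    abort("no accessible volume: every reachable node clashes with the structure")
  }
  pts <- coords[cloud_mask, , drop = FALSE]
  pts <- sweep(pts, 2, att, "+")
  out <- list(points = tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3]),
              attachment = att, n_points = nrow(pts),
              volume = nrow(pts) * g^3, params = params)
  class(out) <- "av_cloud"
  out
}

#' @export
print.av_cloud <- function(x, ...) {
  cat(sprintf("Accessible volume: %d grid nodes, %.0f Å³ (spacing %.2f Å)\n",
              x$n_points, x$volume, x$params$grid_spacing))
  invisible(x)
}

#' Write an AV cloud as an XYZ point list
#'
#' @param cloud An [compute_av()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_av_cloud <- function(cloud, path) {
  stopifnot(inherits(cloud, "av_cloud"))
  readr::write_tsv(cloud$points, path)
  invisible(path)
}

#' Expected inter-dye distances between two AV clouds
#'
#' Monte Carlo average over random dye position pairs:
#' the mean distance `<R>` and the FRET-averaged distance
#' `R_<E> = R0 (1/<E> - 1)^(1/6)` with `<E>` the mean efficiency over the
#' same pairs. `R_<E>` is always at most `<R>` for non-degenerate clouds
#' because E is a convex-decreasing function of distance over the sampled
#' range.
#'
#' @param cloud1,cloud2 [compute_av()] results.
#' @param cal A [forster_calibration()].
#' @param n_pairs Number of random pairs.
#' @param seed Integer seed.
#' @return A one-row tibble `mean_R, R_mean_E, attachment_distance, delta`
#'   (`delta = mean_R - attachment_distance`).
#' @export
dye_pair_distances <- function(cloud1, cloud2, cal = forster_calibration(),
                               n_pairs = 10000, seed = 1) {
  stopifnot(inherits(cloud1, "av_cloud"), inherits(cloud2, "av_cloud"))
  n_pairs <- assert_count(n_pairs, "n_pairs")
  p1 <- as.matrix(cloud1$points)
  p2 <- as.matrix(cloud2$points)
  with_seed(seed, {
    i <- sample.int(nrow(p1), n_pairs, replace = TRUE)
    j <- sample.int(nrow(p2), n_pairs, replace = TRUE)
    r <- sqrt(rowSums((p1[i, , drop = FALSE] - p2[j, , drop = FALSE])^2))
    e <- 1 / (1 + (r / cal$r0)^6)
    att_d <- sqrt(sum((cloud1$attachment - cloud2$attachment)^2))
    tibble(mean_R = mean(r),
           R_mean_E = cal$r0 * (1 / mean(e) - 1)^(1 / 6),
           attachment_distance = att_d,
           delta = mean(r) - att_d)
  })
}
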