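# Accessible-volume simulation: PDB parsing, cloud geometry, pair distances.

test_that("toy PDB files parse with exact coordinates", {
  atoms <- tibble::tibble(
    type = "ATOM", atom = c("N", "CA", "CB"), resid = "CYS", chain = "A",
    resno = 1L, x = c(0, 1.5, 2.25), y = c(0, 0, 1.1), z = c(0, 0, -0.5),
    element = c("N", "C", "C"))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(path, atoms)
  s <- read_pdb(path)
  expect_equal(nrow(s), 3)
  expect_equal(s$x, c(0, 1.5, 2.25))
  expect_equal(s$atom, c("N", "CA", "CB"))
  expect_equal(s$radius, rep(1.7, 3))
})

test_that("structures with only HETATM waters are rejected", {
  atoms <- tibble::tibble(
    type = "HETATM", atom = "O", resid = "HOH", chain = "A",
    resno = 1:3, x = c(0, 5, 10), y = 0, z = 0, element = "O")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(path, atoms)
  expect_error(read_pdb(path), "no heavy ATOM records")
})

test_that("a synthetic 100-residue helix yields 100 CA atoms", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(path, helix_atoms(100))
  s <- read_pdb(path)
  expect_equal(sum(s$atom == "CA"), 100)
  expect_equal(nrow(s), 300)
})

test_that("an unobstructed attachment yields the free-space linker ball", {
  cloud <- compute_av(lone_atom_structure(), "A:1:CB",
                      av_parameters(grid_spacing = 0.5))
  ball <- 4 / 3 * pi * 14^3
  expect_lt(abs(cloud$volume - ball) / ball, 0.05)
  d <- sqrt(rowSums(sweep(as.matrix(cloud$points), 2, cloud$attachment)^2))
  expect_lte(max(d), 14)
})

test_that("a buried attachment raises a no-accessible-volume error", {
  # dense shell of atoms at 5 Å around the attachment point
  set.seed(1)
  n_shell <- 600
  i <- seq_len(n_shell)
  phi <- acos(1 - 2 * (i - 0.5) / n_shell)
  theta <- pi * (1 + sqrt(5)) * i
  shell <- tibble::tibble(chain = "A", resno = 2L, resid = "XXX", atom = "X",
                          x = 5 * sin(phi) * cos(theta),
                          y = 5 * sin(phi) * sin(theta),
                          z = 5 * cos(phi), radius = 1.7)
  s <- dplyr::bind_rows(lone_atom_structure(), shell)
  expect_error(compute_av(s, "A:1:CB", av_parameters()), "no accessible volume")
})

test_that("a wall of atoms halves the cloud, matching a rejection oracle", {
  wall_xy <- tidyr::expand_grid(x = seq(-18, 18, by = 1.4),
                                y = seq(-18, 18, by = 1.4))
  wall <- tibble::tibble(chain = "B", resno = 2L, resid = "XXX", atom = "X",
                         x = wall_xy$x, y = wall_xy$y, z = -5.3, radius = 1.7)
  s <- dplyr::bind_rows(lone_atom_structure(), wall)
  params <- av_parameters(grid_spacing = 1.0)
  cloud <- compute_av(s, "A:1:CB", params)
  free <- compute_av(lone_atom_structure(), "A:1:CB", params)
  expect_lt(abs(cloud$volume / free$volume - 0.5), 0.10)

  # brute-force oracle: allowed nodes by direct rejection, restricted to the
  # attachment side of the wall (nodes behind it pass the clash test but are
  # unreachable by any linker path)
  g <- 1.0
  ax <- seq(-14, 14, by = g)
  nodes <- as.matrix(expand.grid(ax, ax, ax))
  nodes <- nodes[sqrt(rowSums(nodes^2)) <= 14, ]
  keep <- nodes[, 3] > -5.3
  for (r in seq_len(nrow(wall))) {
    d <- sqrt((nodes[, 1] - wall$x[r])^2 + (nodes[, 2] - wall$y[r])^2 +
                (nodes[, 3] - wall$z[r])^2)
    keep <- keep & (d - 1.7 >= 3.5)
  }
  expect_equal(cloud$n_points, sum(keep))
})

test_that("cloud volume never grows as atoms are added", {
  params <- av_parameters(grid_spacing = 1.0)
  base <- compute_av(lone_atom_structure(), "A:1:CB", params)
  blocker <- tibble::tibble(chain = "A", resno = 3L, resid = "XXX", atom = "X",
                            x = 6, y = 0, z = 0, radius = 1.7)
  s1 <- dplyr::bind_rows(lone_atom_structure(), blocker)
  v1 <- compute_av(s1, "A:1:CB", params)$volume
  blocker2 <- dplyr::mutate(blocker, x = -6)
  s2 <- dplyr::bind_rows(s1, blocker2)
  v2 <- compute_av(s2, "A:1:CB", params)$volume
  expect_lte(v1, base$volume)
  expect_lte(v2, v1)
})

test_that("pair distances hit analytic cases and the Jensen direction", {
  point_cloud <- function(p) {
    out <- list(points = tibble::tibble(x = p[1], y = p[2], z = p[3]),
                attachment = p, n_points = 1L, volume = 1,
                params = av_parameters())
    class(out) <- "av_cloud"
    out
  }
  a <- point_cloud(c(0, 0, 0))
  b <- point_cloud(c(50, 0, 0))
  d <- dye_pair_distances(a, b, n_pairs = 100, seed = 1)
  expect_equal(d$mean_R, 50)
  expect_equal(dye_pair_distances(a, a, n_pairs = 10, seed = 1)$mean_R, 0)

  params <- av_parameters(grid_spacing = 1.0)
  c1 <- compute_av(lone_atom_structure(), "A:1:CB", params)
  s2 <- lone_atom_structure()
  s2$x <- 50
  c2 <- compute_av(s2, "A:1:CB", params)
  dd <- dye_pair_distances(c1, c2, n_pairs = 2e4, seed = 2)
  # E|d + u1 - u2| exceeds d by ~(sigma_y^2 + sigma_z^2)/(2d) for symmetric
  # clouds: two 14 Å linker balls give +1.57 Å first order at d = 50
  expect_gt(dd$mean_R, 50)
  expect_lt(abs(dd$mean_R - 50 - 156.8 / 100), 0.6)
  expect_equal(dd$attachment_distance, 50)

  # the convexity bias falls off as 1/d: within 1 Å at 100 Å separation,
  # where the transfer efficiency is also convex over the sampled range so
  # the FRET-averaged distance undershoots the mean distance
  s3 <- lone_atom_structure()
  s3$x <- 100
  c3 <- compute_av(s3, "A:1:CB", params)
  d100 <- dye_pair_distances(c1, c3, n_pairs = 2e4, seed = 6)
  expect_lt(abs(d100$mean_R - 100), 1)
  expect_lt(d100$R_mean_E, d100$mean_R)

  # exhaustive pair-average oracle on a coarse grid
  coarse <- av_parameters(linker_length = 6, linker_width = 4.5,
                          dye_radius = 3.5, grid_spacing = 3)
  k1 <- compute_av(lone_atom_structure(), "A:1:CB", coarse)
  k2 <- compute_av(s2, "A:1:CB", coarse)
  p1 <- as.matrix(k1$points); p2 <- as.matrix(k2$points)
  all_d <- sqrt(outer(rowSums(p1^2), rep(1, nrow(p2))) +
                  outer(rep(1, nrow(p1)), rowSums(p2^2)) -
                  2 * p1 %*% t(p2))
  mc <- dye_pair_distances(k1, k2, n_pairs = 4e4, seed = 3)
  expect_lt(abs(mc$mean_R - mean(all_d)), 3 * sd(all_d) / sqrt(4e4) + 0.05)
})

test_that("pair-distance estimates are seed-reproducible and converge", {
  params <- av_parameters(grid_spacing = 1.0)
  c1 <- compute_av(lone_atom_structure(), "A:1:CB", params)
  s2 <- lone_atom_structure(); s2$x <- 40
  c2 <- compute_av(s2, "A:1:CB", params)
  d1 <- dye_pair_distances(c1, c2, n_pairs = 5000, seed = 4)
  d2 <- dye_pair_distances(c1, c2, n_pairs = 5000, seed = 4)
  expect_identical(d1, d2)
  big <- dye_pair_distances(c1, c2, n_pairs = 4e4, seed = 5)
  expect_lt(abs(big$mean_R - d1$mean_R), 0.5)
})
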