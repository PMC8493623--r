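tiny_cube_text <- function() {
  # hand-written 2x2x2 cube in Bohr with values 1..8, one H nucleus
  paste(c(
    "test cube", "comment",
    "    1  0.0 0.0 0.0",
    "    2  1.0 0.0 0.0",
    "    2  0.0 1.0 0.0",
    "    2  0.0 0.0 1.0",
    "    1  1.0  0.0 0.0 0.0",
    " 1 2 3 4", " 5 6 7 8", ""), collapse = "\n")
}

test_that("cube reading follows the format's z-fastest value ordering", {
  cube <- read_cube(tiny_cube_text())
  b3 <- pixkit:::.BOHR_A^3
  # file order: (i,j,k) with k fastest
  expect_equal(cube$values[1, 1, 1] * b3, 1)
  expect_equal(cube$values[1, 1, 2] * b3, 2)
  expect_equal(cube$values[1, 2, 1] * b3, 3)
  expect_equal(cube$values[2, 1, 1] * b3, 5)
  expect_equal(cube$values[2, 2, 2] * b3, 8)
  expect_equal(cube$counts, c(2L, 2L, 2L))
  expect_equal(cube$axes, diag(3) * pixkit:::.BOHR_A, tolerance = 1e-12)
  expect_equal(cube$nuclei$q, 1)
})

test_that("cube write/read round-trips values, grid and nuclei", {
  set.seed(3)
  cube <- structure(list(
    origin = c(-1.5, 0.2, 0.7),
    axes = diag(3) * 0.21,
    counts = c(5L, 4L, 3L),
    values = array(stats::rexp(60), dim = c(5, 4, 3)),
    nuclei = data.frame(znum = c(6L, 8L), q = c(4, 6),
                        x = c(0, 1.1), y = c(0.3, 0), z = c(0.5, -0.2)),
    comments = c("a", "b")), class = "density_cube")
  c2 <- read_cube(write_cube(cube))
  expect_equal(c2$values, cube$values, tolerance = 1e-10)
  expect_equal(c2$origin, cube$origin, tolerance = 1e-10)
  expect_equal(c2$axes, cube$axes, tolerance = 1e-10)
  expect_equal(c2$nuclei$q, cube$nuclei$q, tolerance = 1e-10)
  expect_equal(c2$nuclei$x, cube$nuclei$x, tolerance = 1e-10)
})

test_that("truncated value blocks are a structured error", {
  txt <- sub(" 5 6 7 8\n", "", tiny_cube_text(), fixed = TRUE)
  expect_error(read_cube(txt), "expected 8 grid values, found 4")
})

test_that("a generated Gaussian cube matches its analytic field", {
  g <- make_gaussian_cube(rbind(c(1, 1, 1)), 0.6, 2,
                          origin = c(-1, -1, -1), spacing = 0.1,
                          counts = c(41, 41, 41))
  cube <- read_cube(write_cube(g$cube))
  # direct analytic evaluation at a few grid points
  for (idx in list(c(1, 1, 1), c(21, 21, 21), c(30, 15, 8))) {
    p <- cube$origin + (idx - 1) * 0.1
    rho <- 2 * prod(exp(-(p - 1)^2 / (2 * 0.6^2)) / (sqrt(2 * pi) * 0.6))
    expect_equal(cube$values[idx[1], idx[2], idx[3]], rho, tolerance = 1e-9)
  }
})

test_that("condensation at n = 1 puts one pixel per voxel at the voxel center", {
  g <- make_gaussian_cube(rbind(c(0.5, 0.5, 0.5)), 0.3, 1,
                          origin = c(0, 0, 0), spacing = 0.05, counts = c(4, 4, 4))
  cl <- condense(g$cube, 1)
  expect_equal(nrow(cl$pixels), 64)
  expect_equal(cl$pixels$x[1], 0)
  expect_equal(cl$pixels$q, -as.vector(aperm(g$cube$values, 3:1)) * 0.05^3,
               tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("a uniform cube condenses to equal pixels at block centers", {
  cube <- structure(list(origin = c(0, 0, 0), axes = diag(3), counts = c(4L, 4L, 4L),
                         values = array(2, dim = c(4, 4, 4)),
                         nuclei = data.frame(znum = integer(0), q = numeric(0),
                                             x = numeric(0), y = numeric(0),
                                             z = numeric(0)),
                         comments = c("", "")), class = "density_cube")
  cl <- condense(cube, 2)
  expect_equal(nrow(cl$pixels), 8)
  expect_equal(unique(round(cl$pixels$q, 12)), -2 * 8)     # -rho * 8 voxels * dV
  expect_equal(sum(cl$pixels$q), -2 * 64)                  # total = -rho * V
  expect_setequal(round(cl$pixels$x, 9), c(0.5, 2.5))      # block centers
})

test_that("a nonuniform block's pixel sits at the hand-computed weighted mean", {
  vals <- array(0, dim = c(2, 2, 2))
  vals[1, 1, 1] <- 1; vals[2, 1, 1] <- 3  # weight along x only
  cube <- structure(list(origin = c(0, 0, 0), axes = diag(3), counts = c(2L, 2L, 2L),
                         values = vals,
                         nuclei = data.frame(znum = integer(0), q = numeric(0),
                                             x = numeric(0), y = numeric(0),
                                             z = numeric(0)),
                         comments = c("", "")), class = "density_cube")
  cl <- condense(cube, 2)
  expect_equal(nrow(cl$pixels), 1)
  expect_equal(cl$pixels$q, -4)
  expect_equal(cl$pixels$x, (1 * 0 + 3 * 1) / 4)  # weighted mean of voxel x
  expect_equal(cl$pixels$y, 0)
})

test_that("condensation conserves total charge for all levels", {
  set.seed(9)
  cube <- structure(list(origin = c(0, 0, 0), axes = diag(3) * 0.3,
                         counts = c(7L, 9L, 11L),
                         values = array(stats::runif(693), dim = c(7, 9, 11)),
                         nuclei = data.frame(znum = integer(0), q = numeric(0),
                                             x = numeric(0), y = numeric(0),
                                             z = numeric(0)),
                         comments = c("", "")), class = "density_cube")
  total <- -sum(cube$values) * voxel_volume(cube)
  for (n in 1:5) {
    cl <- condense(cube, n)
    expect_lt(abs(cl$total_electron_charge - total), 1e-10)
    expect_lt(abs(sum(cl$pixels$q) - total), 1e-10)
  }
  expect_error(condense(cube, 0), ">= 1")
})

test_that("pruning filters by charge magnitude and reports removals", {
  cl <- condense(structure(list(origin = c(0, 0, 0), axes = diag(3),
                                counts = c(2L, 2L, 2L),
                                values = array(c(1e-12, rep(0.5, 7)), dim = c(2, 2, 2)),
                                nuclei = data.frame(znum = 1L, q = 1, x = 0, y = 0, z = 0),
                                comments = c("", "")), class = "density_cube"), 1)
  expect_identical(prune_pixels(cl, 0)$pixels, cl$pixels)
  p <- prune_pixels(cl, 1e-6)
  expect_equal(nrow(p$pixels), 7)
  expect_equal(nrow(p$nuclei), 1)          # nuclei untouched
  # oracle: plain filter
  expect_equal(p$pixels$q, cl$pixels$q[abs(cl$pixels$q) >= 1e-6])
  expect_warning(prune_pixels(cl, 10), "empty")
})

test_that("point-charge pairs reproduce the Coulomb constant", {
  mk <- function(q, x) structure(list(
    pixels = data.frame(q = q, x = x, y = 0, z = 0),
    nuclei = data.frame(znum = integer(0), q = numeric(0), x = numeric(0),
                        y = numeric(0), z = numeric(0)),
    condensation_level = 1L, total_electron_charge = q), class = "pixel_cloud")
  a <- mk(1, 0); b <- mk(-1, 1)
  e <- coulomb_energy(a, b)
  expect_equal(as.numeric(e), -coulomb_constant(), tolerance = 1e-12)
  expect_equal(coulomb_constant(), 1389.35, tolerance = 1e-5)
  # symmetric in the arguments
  expect_equal(as.numeric(coulomb_energy(b, a)), as.numeric(e))
  # clash skipping
  c_ <- mk(1, 0.2)
  e2 <- coulomb_energy(a, c_, r_min = 0.5)
  expect_equal(as.numeric(e2), 0)
  expect_equal(attr(e2, "clashes"), 1)
})

test_that("overlapping nuclei across clouds are rejected", {
  mk <- function(x) structure(list(
    pixels = data.frame(q = numeric(0), x = numeric(0), y = numeric(0), z = numeric(0)),
    nuclei = data.frame(znum = 1L, q = 1, x = x, y = 0, z = 0),
    condensation_level = 1L, total_electron_charge = 0), class = "pixel_cloud")
  expect_error(coulomb_energy(mk(0), mk(0.05)), "not distinct")
})

test_that("Coulomb energy is stable across condensation levels for separated clouds", {
  # two Gaussian dipole clouds 8 A apart; the pixel model must not depend on
  # the condensation level once the separation far exceeds the voxel size.
  # (Cube built directly at sigma/4 to keep this a fast unit test; the
  # acceptance suite exercises the finer fixture-generator resolution.)
  sg <- 0.5; h <- sg / 4
  gr <- seq(-2, 2, by = h)
  mk <- function(zc) {
    # +- unit Gaussian blobs at zc +- 0.5 along z, in a box centered on zc
    pts <- as.matrix(expand.grid(x = gr, y = gr, z = gr))
    rho <- exp(-(pts[, 1]^2 + pts[, 2]^2 + (pts[, 3] - 0.5)^2) / (2 * sg^2)) -
      exp(-(pts[, 1]^2 + pts[, 2]^2 + (pts[, 3] + 0.5)^2) / (2 * sg^2))
    structure(list(origin = c(-2, -2, zc - 2), axes = diag(3) * h,
                   counts = rep(length(gr), 3L),
                   values = array(rho / ((2 * pi)^1.5 * sg^3),
                                  dim = rep(length(gr), 3)),
                   nuclei = data.frame(znum = integer(0), q = numeric(0),
                                       x = numeric(0), y = numeric(0),
                                       z = numeric(0)),
                   comments = c("", "")), class = "density_cube")
  }
  ga <- mk(0); gb <- mk(8)
  es <- vapply(1:2, function(n)
    as.numeric(coulomb_energy(condense(ga, n), condense(gb, n))), 0)
  expect_equal(es[2], es[1], tolerance = 0.01)

  # higher levels checked at the fixture generator's full 6-voxel/sigma
  # resolution, where a level-4 pixel still spans only ~0.7 sigma
  mk6 <- function(zc) {
    make_gaussian_cube(rbind(c(0, 0, zc + 0.5), c(0, 0, zc - 0.5)),
                       c(sg, sg), c(1, -1),
                       origin = c(-2, -2, zc - 2), spacing = sg / 6,
                       counts = rep(49, 3))
  }
  g6a <- mk6(0); g6b <- mk6(8)
  es6 <- vapply(2:4, function(n)
    as.numeric(coulomb_energy(condense(g6a$cube, n), condense(g6b$cube, n))), 0)
  expect_equal(es6[2], es6[1], tolerance = 0.01)
  expect_equal(es6[3], es6[1], tolerance = 0.01)

  # neutral-neutral decay is faster than 1/R: compare R = 8 and R = 16 at n = 4
  gc_ <- mk(16)
  e16 <- as.numeric(coulomb_energy(condense(ga, 4), condense(gc_, 4)))
  e8 <- as.numeric(coulomb_energy(condense(ga, 4), condense(gb, 4)))
  expect_lt(abs(e16), abs(e8) / 2)
})
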