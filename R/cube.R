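.BOHR_A <- 0.529177210903  # Bohr radius in Angstrom

#' Coulomb constant in kJ mol^-1 Angstrom e^-2
#'
#' e^2 N_A / (4 pi eps0 * 1 Angstrom), from CODATA constants.
#' @return numeric scalar, about 1389.35.
#' @export
coulomb_constant <- function() {
  e <- 1.602176634e-19       # C
  na <- 6.02214076e23        # 1/mol
  eps0 <- 8.8541878128e-12   # F/m
  e^2 * na / (4 * pi * eps0 * 1e-10) / 1000  # kJ/mol per e^2/Angstrom
}

#' Read a Gaussian-format electron-density cube file
#'
#' Standard layout: two comment lines; a line with the atom count and grid
#' origin; three lines with voxel counts and voxel vectors; one line per atom
#' (atomic number, charge, position); then the scalar field in Fortran order
#' (last grid index fastest). Positive voxel counts signal atomic units
#' (Bohr), which are converted to Angstrom; density values are converted to
#' e/Angstrom^3.
#'
#' @param text cube file text (single string or lines), or a file path.
#' @return a `density_cube`: list with `origin` (Angstrom), `axes` (3x3, rows
#'   are voxel vectors), `counts`, `values` (3d array, `values[i,j,k]`),
#'   `nuclei` (data.frame z, q, x, y, z), `comments`.
#' @export
read_cube <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text)
  } else {
    lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  if (length(lines) < 7) stop("cube parse error: fewer than 7 header lines")
  comments <- lines[1:2]
  hd <- scan(text = lines[3], quiet = TRUE)
  natoms <- as.integer(hd[1])
  has_dset <- natoms < 0
  natoms <- abs(natoms)
  origin <- hd[2:4]
  counts <- integer(3)
  axes <- matrix(0, 3, 3)
  for (i in 1:3) {
    v <- scan(text = lines[3 + i], quiet = TRUE)
    counts[i] <- as.integer(v[1])
    axes[i, ] <- v[2:4]
  }
  bohr <- all(counts > 0)  # negative counts signal Angstrom by convention
  counts <- abs(counts)
  nuc <- matrix(0, natoms, 5)
  for (a in seq_len(natoms)) {
    nuc[a, ] <- scan(text = lines[6 + a], quiet = TRUE)
  }
  skip <- 6 + natoms + if (has_dset) 1L else 0L
  vals <- scan(text = paste(lines[(skip + 1):length(lines)], collapse = "\n"),
               quiet = TRUE)
  nexp <- prod(counts)
  if (length(vals) != nexp) {
    stop(sprintf("cube parse error: expected %d grid values, found %d (after line %d)",
                 nexp, length(vals), skip))
  }
  if (bohr) {
    origin <- origin * .BOHR_A
    axes <- axes * .BOHR_A
    nuc[, 3:5] <- nuc[, 3:5] * .BOHR_A
    vals <- vals / .BOHR_A^3
  }
  # file order: first index slowest, third fastest
  values <- aperm(array(vals, dim = rev(counts)), 3:1)
  nuclei <- data.frame(znum = as.integer(nuc[, 1]),
                       q = ifelse(nuc[, 2] != 0, nuc[, 2], nuc[, 1]),
                       x = nuc[, 3], y = nuc[, 4], z = nuc[, 5])
  structure(list(origin = origin, axes = axes, counts = counts,
                 values = values, nuclei = nuclei, comments = comments),
            class = "density_cube")
}

#' @rdname read_cube
#' @param cube a `density_cube`.
#' @param path optional file path; when `NULL` the text is returned.
#' @return for `write_cube`, the cube file text (written in Bohr).
#' @export
write_cube <- function(cube, path = NULL) {
  b <- .BOHR_A
  fmt <- function(x) sprintf("%5d %19.12E %19.12E %19.12E", x[[1]], x[[2]], x[[3]], x[[4]])
  lines <- c(
    if (length(cube$comments) >= 1) cube$comments[1] else "pixkit cube",
    if (length(cube$comments) >= 2) cube$comments[2] else "electron density",
    fmt(list(nrow(cube$nuclei), cube$origin[1] / b, cube$origin[2] / b, cube$origin[3] / b)),
    vapply(1:3, function(i)
      fmt(list(cube$counts[i], cube$axes[i, 1] / b, cube$axes[i, 2] / b, cube$axes[i, 3] / b)), "")
  )
  if (nrow(cube$nuclei) > 0) {
    lines <- c(lines, sprintf("%5d %19.12E %19.12E %19.12E %19.12E",
                              cube$nuclei$znum, cube$nuclei$q,
                              cube$nuclei$x / b, cube$nuclei$y / b, cube$nuclei$z / b))
  }
  vals <- as.vector(aperm(cube$values, 3:1)) * b^3
  n <- length(vals)
  rows <- split(vals, ceiling(seq_len(n) / 6))
  lines <- c(lines, vapply(rows, function(v)
    paste(sprintf("%22.14E", v), collapse = " "), ""))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(sub("\n$", "", txt), path)
  invisible(txt)
}

#' Voxel volume of a cube (Angstrom^3)
#' @param cube a `density_cube`.
#' @export
voxel_volume <- function(cube) abs(det(cube$axes))

#' Condense an electron-density cube into charge pixels
#'
#' Merges `n` x `n` x `n` blocks of grid points into single pixels (edge
#' remainders form smaller blocks so charge is conserved exactly). Each pixel
#' carries charge -sum(rho dV) (electrons are negative) at the charge-weighted
#' mean of its voxel centers; blocks with zero total charge use the geometric
#' center.
#'
#' @param cube a `density_cube`.
#' @param n condensation level (positive integer).
#' @return a `pixel_cloud`: list with `pixels` (data.frame q, x, y, z),
#'   `condensation_level`, `nuclei`, `total_electron_charge`.
#' @export
condense <- function(cube, n = 1L) {
  n <- as.integer(n)
  if (n < 1) stop("condensation level must be >= 1")
  cnt <- cube$counts
  dv <- voxel_volume(cube)
  idx1 <- slice.index(cube$values, 1)
  idx2 <- slice.index(cube$values, 2)
  idx3 <- slice.index(cube$values, 3)
  ax <- cube$axes
  px <- cube$origin[1] + (idx1 - 1) * ax[1, 1] + (idx2 - 1) * ax[2, 1] + (idx3 - 1) * ax[3, 1]
  py <- cube$origin[2] + (idx1 - 1) * ax[1, 2] + (idx2 - 1) * ax[2, 2] + (idx3 - 1) * ax[3, 2]
  pz <- cube$origin[3] + (idx1 - 1) * ax[1, 3] + (idx2 - 1) * ax[2, 3] + (idx3 - 1) * ax[3, 3]
  b1 <- (idx1 - 1L) %/% n
  b2 <- (idx2 - 1L) %/% n
  b3 <- (idx3 - 1L) %/% n
  nb2 <- (cnt[2] + n - 1L) %/% n
  nb3 <- (cnt[3] + n - 1L) %/% n
  id <- (as.vector(b1) * nb2 + as.vector(b2)) * nb3 + as.vector(b3) + 1L
  rho <- as.vector(cube$values)
  w <- rho * dv
  sw <- rowsum(w, id)
  swx <- rowsum(w * as.vector(px), id)
  swy <- rowsum(w * as.vector(py), id)
  swz <- rowsum(w * as.vector(pz), id)
  cnt_blk <- rowsum(rep(1, length(id)), id)
  sx <- rowsum(as.vector(px), id)
  sy <- rowsum(as.vector(py), id)
  sz <- rowsum(as.vector(pz), id)
  zero <- abs(sw) < 1e-300
  x <- ifelse(zero, sx / cnt_blk, swx / sw)
  y <- ifelse(zero, sy / cnt_blk, swy / sw)
  z <- ifelse(zero, sz / cnt_blk, swz / sw)
  pixels <- data.frame(q = -as.numeric(sw), x = as.numeric(x),
                       y = as.numeric(y), z = as.numeric(z))
  structure(list(pixels = pixels, condensation_level = n,
                 nuclei = cube$nuclei,
                 total_electron_charge = sum(pixels$q)),
            class = "pixel_cloud")
}

#' @export
print.pixel_cloud <- function(x, ...) {
  cat(sprintf("<pixel_cloud> %d pixels (n = %d), %d nuclei, electron charge %.6f e\n",
              nrow(x$pixels), x$condensation_level, nrow(x$nuclei),
              x$total_electron_charge))
  invisible(x)
}

#' Remove pixels below a charge magnitude threshold
#'
#' @param cloud a `pixel_cloud`.
#' @param q_min charge magnitude threshold in e (>= 0).
#' @param verbose report the removed charge.
#' @return the pruned cloud; nuclei are never touched.
#' @export
prune_pixels <- function(cloud, q_min = 0, verbose = FALSE) {
  stopifnot(q_min >= 0)
  keep <- abs(cloud$pixels$q) >= q_min
  removed <- sum(cloud$pixels$q[!keep])
  cloud$pixels <- cloud$pixels[keep, , drop = FALSE]
  if (verbose && any(!keep)) {
    message(sprintf("pruned %d pixels carrying %.3e e total", sum(!keep), removed))
  }
  if (nrow(cloud$pixels) == 0) warning("all pixels pruned; cloud is empty")
  attr(cloud, "pruned_charge") <- removed
  cloud
}

#' Rigidly translate a pixel cloud
#'
#' @param cloud a `pixel_cloud`.
#' @param v Cartesian displacement 3-vector (Angstrom).
#' @export
shift_cloud <- function(cloud, v) {
  cloud$pixels$x <- cloud$pixels$x + v[1]
  cloud$pixels$y <- cloud$pixels$y + v[2]
  cloud$pixels$z <- cloud$pixels$z + v[3]
  if (nrow(cloud$nuclei) > 0) {
    cloud$nuclei$x <- cloud$nuclei$x + v[1]
    cloud$nuclei$y <- cloud$nuclei$y + v[2]
    cloud$nuclei$z <- cloud$nuclei$z + v[3]
  }
  cloud
}

.cloud_sites <- function(cloud) {
  px <- cloud$pixels
  if (nrow(cloud$nuclei) > 0) {
    list(q = c(px$q, cloud$nuclei$q),
         xyz = rbind(as.matrix(px[, c("x", "y", "z")]),
                     as.matrix(cloud$nuclei[, c("x", "y", "z")])))
  } else {
    list(q = px$q, xyz = as.matrix(px[, c("x", "y", "z")]))
  }
}

#' Pixel-sum Coulomb energy between two charge clouds
#'
#' Sums K q_i q_j / r_ij over every cross pair of charge sites (pixel-pixel,
#' pixel-nucleus, nucleus-nucleus) of two distinct molecules. Pairs closer
#' than `r_min` are skipped and counted as clashes (unphysical at condensed
#' resolution).
#'
#' @param a,b `pixel_cloud`s of two distinct molecules.
#' @param r_min minimum pair distance in Angstrom (default 0.5).
#' @return energy in kJ/mol, with attribute `clashes` giving the number of
#'   skipped pairs.
#' @export
coulomb_energy <- function(a, b, r_min = 0.5) {
  stopifnot(r_min > 0)
  if (nrow(a$nuclei) > 0 && nrow(b$nuclei) > 0) {
    na_ <- as.matrix(a$nuclei[, c("x", "y", "z")])
    nb_ <- as.matrix(b$nuclei[, c("x", "y", "z")])
    for (i in seq_len(nrow(na_))) {
      d <- sqrt(rowSums(sweep(nb_, 2, na_[i, ])^2))
      if (any(d < 0.1)) {
        stop("overlapping nuclei between the two clouds (r < 0.1 Angstrom); molecules are not distinct")
      }
    }
  }
  sa <- .cloud_sites(a)
  sb <- .cloud_sites(b)
  res <- coulomb_pair_sum(sa$q, sa$xyz[, 1], sa$xyz[, 2], sa$xyz[, 3],
                          sb$q, sb$xyz[, 1], sb$xyz[, 2], sb$xyz[, 3], r_min)
  e <- coulomb_constant() * res$sum
  attr(e, "clashes") <- res$skipped
  e
}
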