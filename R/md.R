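# Bilayer MD post-processing: membrane-centered, symmetrized number-density
# profiles along the membrane normal, ion peak statistics, area per lipid.
# Coordinates are Angstrom throughout; densities are reported in nm^-3.

#' Bilayer trajectory container
#'
#' @param frames list of frames, each a list with `xyz` (N x 3 matrix, Å)
#'   and `box` (`c(Lx, Ly, Lz)`, Å)
#' @param groups named list of atom index vectors (e.g. `PO4`, `Ca`, `H3O`)
#' @param lipids_per_leaflet lipid count per leaflet (for [area_per_lipid()])
#' @return object of class `"bilayer_trajectory"`
#' @export
bilayer_trajectory <- function(frames, groups = list(),
                               lipids_per_leaflet = NA_integer_) {
  if (length(frames) == 0L) stop("empty trajectory (0 frames)")
  natom <- nrow(frames[[1]]$xyz)
  for (f in frames) {
    stopifnot(is.matrix(f$xyz), ncol(f$xyz) == 3L, length(f$box) == 3L)
    if (any(f$box <= 0)) stop("box dimensions must be positive")
  }
  for (g in groups)
    if (any(g < 1L | g > natom)) stop("group index outside atom count")
  structure(list(frames = frames, groups = groups,
                 lipids_per_leaflet = lipids_per_leaflet),
            class = "bilayer_trajectory")
}

#' @export
print.bilayer_trajectory <- function(x, ...) {
  b <- x$frames[[1]]$box
  cat(sprintf("Bilayer trajectory: %d frames, %d atoms, box %.1f x %.1f x %.1f A\n",
              length(x$frames), nrow(x$frames[[1]]$xyz), b[1], b[2], b[3]))
  if (length(x$groups))
    cat("  groups:", paste(sprintf("%s(%d)", names(x$groups),
                                   lengths(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a toy bilayer trajectory with known densities
#'
#' Draws, for every frame, particle z coordinates i.i.d. from per-group
#' distributions — Gaussians mirrored about the membrane center (two
#' leaflet peaks at \eqn{\pm \mu}) or a single Gaussian, or uniform through
#' the box — with x, y uniform in the lateral box.  The generating density
#' of every group is therefore known exactly, which makes the profile
#' machinery testable against closed-form expectations.
#'
#' @param n_frames number of frames (> 0)
#' @param groups named list; each element a list with `count`, and either
#'   `mean_z`/`sd_z` (Gaussian, Å; `mirrored = TRUE` splits the count evenly
#'   between leaflets at `±mean_z`) or `uniform = TRUE`
#' @param box `c(Lx, Ly, Lz)` in Å (constant) or list of per-frame boxes
#' @param lipids_per_leaflet passed through to the container
#' @param seed integer seed; generation is bit-reproducible
#' @return a [bilayer_trajectory()]
#' @examples
#' tj <- generate_toy_trajectory(5,
#'   groups = list(PO4 = list(count = 100, mean_z = 20, sd_z = 2)),
#'   box = c(60, 60, 80), seed = 1)
#' @export
generate_toy_trajectory <- function(n_frames, groups, box,
                                    lipids_per_leaflet = NA_integer_,
                                    seed = 1L) {
  if (n_frames < 1L) stop("empty trajectory (0 frames)")
  stopifnot(length(groups) >= 1L, !is.null(names(groups)))
  boxes <- if (is.list(box)) box else rep(list(box), n_frames)
  stopifnot(length(boxes) == n_frames)
  counts <- vapply(groups, function(g) as.integer(g$count), integer(1))
  idx <- split(seq_len(sum(counts)), rep(seq_along(groups), counts))
  names(idx) <- names(groups)

  set.seed(as.integer(seed))
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    b <- boxes[[f]]
    xyz <- matrix(NA_real_, sum(counts), 3L)
    for (g in seq_along(groups)) {
      sp <- groups[[g]]; m <- counts[g]
      z <- if (isTRUE(sp$uniform)) {
        stats::runif(m, -b[3] / 2, b[3] / 2)
      } else if (isTRUE(sp$mirrored %||% TRUE)) {
        side <- rep(c(-1, 1), length.out = m)
        stats::rnorm(m, mean = side * sp$mean_z, sd = sp$sd_z)
      } else {
        stats::rnorm(m, mean = sp$mean_z, sd = sp$sd_z)
      }
      xyz[idx[[g]], 1] <- stats::runif(m, 0, b[1])
      xyz[idx[[g]], 2] <- stats::runif(m, 0, b[2])
      xyz[idx[[g]], 3] <- z
    }
    frames[[f]] <- list(xyz = xyz, box = b)
  }
  bilayer_trajectory(frames, groups = idx,
                     lipids_per_leaflet = lipids_per_leaflet)
}

# wrap into [-L/2, L/2)
wrap_z <- function(z, L) z - L * round(z / L)

#' Center a frame on the membrane
#'
#' Translates the frame along z so that the center of geometry of the
#' reference group (conventionally the phosphate atoms) sits at z = 0.  The
#' center is computed as a circular mean over the periodic z axis, so a
#' membrane wrapped across the boundary is centered identically to its
#' unwrapped copy; all z coordinates are then wrapped into
#' \eqn{[-L_z/2, L_z/2)}.  x and y are untouched.
#'
#' @param frame list with `xyz` (N x 3, Å) and `box`
#' @param reference_idx atom indices of the reference group
#' @return the recentered frame
#' @export
center_membrane <- function(frame, reference_idx) {
  if (length(reference_idx) == 0L) stop("empty reference group")
  Lz <- frame$box[3]
  z <- frame$xyz[reference_idx, 3]
  theta <- 2 * pi * z / Lz
  center <- Lz / (2 * pi) * atan2(mean(sin(theta)), mean(cos(theta)))
  frame$xyz[, 3] <- wrap_z(frame$xyz[, 3] - center, Lz)
  frame
}

#' Symmetrized number-density profiles along the membrane normal
#'
#' Histograms each group's z coordinates (after optional per-frame
#' centering on a reference group) into bins symmetric about the membrane
#' center, normalizes by the bin volume \eqn{L_x L_y \Delta z} per frame,
#' and averages over frames.  With `symmetrize = TRUE` the profile is
#' averaged with its mirror image, \eqn{\rho(z) \leftarrow
#' (\rho(z)+\rho(-z))/2} — the standard presentation for bilayers, whose
#' two leaflets are statistically equivalent.
#'
#' @param traj a [bilayer_trajectory()]
#' @param groups group names to profile; default all
#' @param bin_width bin width (Å), default 1
#' @param symmetrize mirror-average the profiles?
#' @param center center every frame with [center_membrane()]?
#' @param reference_group group used for centering; default the first group
#' @return object of class `"density_profile"`: list with `z` (bin centers,
#'   Å), `density` (bins x groups matrix, nm^-3), `bin_width`, `n_frames`,
#'   `area` (mean lateral area, Å^2), `counts` (per-group mean atoms/frame)
#' @export
density_profile <- function(traj, groups = NULL, bin_width = 1,
                            symmetrize = TRUE, center = TRUE,
                            reference_group = NULL) {
  stopifnot(inherits(traj, "bilayer_trajectory"))
  if (length(traj$frames) == 0L) stop("zero frames")
  groups <- groups %||% names(traj$groups)
  stopifnot(all(groups %in% names(traj$groups)))
  reference_group <- reference_group %||% groups[1]

  Lz_max <- max(vapply(traj$frames, function(f) f$box[3], numeric(1)))
  half <- bin_width * ceiling(Lz_max / 2 / bin_width)
  edges <- seq(-half, half, by = bin_width)
  nb <- length(edges) - 1L
  acc <- matrix(0, nb, length(groups), dimnames = list(NULL, groups))

  for (f in traj$frames) {
    if (center) f <- center_membrane(f, traj$groups[[reference_group]])
    A <- f$box[1] * f$box[2]
    for (g in groups) {
      z <- wrap_z(f$xyz[traj$groups[[g]], 3], f$box[3])
      h <- graphics::hist(z, breaks = edges, plot = FALSE)$counts
      # counts / (A * dz) in A^-3 -> x1000 to nm^-3
      acc[, g] <- acc[, g] + h / (A * bin_width) * 1000
    }
  }
  dens <- acc / length(traj$frames)
  if (symmetrize) dens <- (dens + dens[nb:1, , drop = FALSE]) / 2
  structure(list(
    z = (edges[-1] + edges[-length(edges)]) / 2,
    density = dens, bin_width = bin_width, n_frames = length(traj$frames),
    area = mean(vapply(traj$frames, function(f) f$box[1] * f$box[2],
                       numeric(1))),
    counts = lengths(traj$groups[groups]), symmetrized = symmetrize
  ), class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("Density profile: %d bins x %g A, %d frames%s\n",
              length(x$z), x$bin_width, x$n_frames,
              if (x$symmetrized) ", symmetrized" else ""))
  for (g in colnames(x$density)) {
    pk <- peak_stats(x, g)
    cat(sprintf("  %-10s peak %6.2f nm^-3 at %+6.2f A%s\n", g, pk$height,
                pk$position, if (pk$flagged) "  [flat]" else ""))
  }
  invisible(x)
}

#' @export
plot.density_profile <- function(x, groups = colnames(x$density), ...) {
  cols <- grDevices::hcl.colors(length(groups), "Dark 3")
  graphics::matplot(x$z, x$density[, groups, drop = FALSE], type = "l",
                    lty = 1, col = cols, xlab = "z (Å)",
                    ylab = expression(rho ~ (nm^-3)), ...)
  graphics::legend("topright", legend = groups, col = cols, lty = 1,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Peak position and height of a density profile
#'
#' Locates the maximum bin of one group's profile and refines the position
#' sub-bin by a parabola through the three bins around the maximum.  For
#' symmetrized profiles the reported position is from the z > 0 half
#' (positions are reported as distance from the membrane center).
#'
#' @param profile a [density_profile()]
#' @param group group name
#' @return list `position` (Å), `height` (nm^-3), `flagged` (TRUE for a
#'   flat profile, where no peak is defined)
#' @export
peak_stats <- function(profile, group) {
  stopifnot(inherits(profile, "density_profile"),
            group %in% colnames(profile$density))
  rho <- profile$density[, group]
  z <- profile$z
  if (max(rho) - min(rho) <= 1e-12 * max(abs(rho), 1))
    return(list(position = NA_real_, height = max(rho), flagged = TRUE))
  if (profile$symmetrized) {
    pos_half <- z >= 0
    i <- which(pos_half)[which.max(rho[pos_half])]
  } else i <- which.max(rho)
  pos <- z[i]; hgt <- rho[i]
  if (i > 1L && i < length(z)) {
    y1 <- rho[i - 1L]; y2 <- rho[i]; y3 <- rho[i + 1L]
    den <- y1 - 2 * y2 + y3
    if (den < 0) {
      d <- 0.5 * (y1 - y3) / den
      pos <- z[i] + d * profile$bin_width
      hgt <- y2 - 0.25 * (y1 - y3) * d
    }
  }
  list(position = pos, height = hgt, flagged = FALSE)
}

#' Area per lipid
#'
#' The per-frame lateral box area divided by the number of lipids per
#' leaflet, \eqn{APL = L_x L_y / n_{leaflet}}, with the mean and a
#' block-averaged standard error (frames are serially correlated in real
#' trajectories, so naive standard errors are optimistic).
#'
#' @param traj a [bilayer_trajectory()] with `lipids_per_leaflet` set, or
#'   set it via the argument
#' @param lipids_per_leaflet override the trajectory's value
#' @param n_blocks number of blocks for the standard error
#' @return object of class `"apl_series"`: list with `apl` (per-frame, Å^2),
#'   `mean`, `se`, `n_blocks`
#' @export
area_per_lipid <- function(traj, lipids_per_leaflet = NULL, n_blocks = 5L) {
  stopifnot(inherits(traj, "bilayer_trajectory"))
  npl <- lipids_per_leaflet %||% traj$lipids_per_leaflet
  if (is.na(npl) || npl <= 0) stop("lipids_per_leaflet must be positive")
  apl <- vapply(traj$frames, function(f) {
    if (length(f$box) != 3L || any(!is.finite(f$box))) stop("missing box")
    f$box[1] * f$box[2] / npl
  }, numeric(1))
  nb <- max(1L, min(n_blocks, length(apl)))
  blocks <- split(apl, cut(seq_along(apl), nb, labels = FALSE))
  bm <- vapply(blocks, mean, numeric(1))
  se <- if (nb > 1L) stats::sd(bm) / sqrt(nb) else 0
  structure(list(apl = apl, mean = mean(apl), se = se, n_blocks = nb),
            class = "apl_series")
}

#' @export
print.apl_series <- function(x, ...) {
  cat(sprintf("Area per lipid: %.3f +/- %.3f A^2 (%.4f nm^2, %d frames, %d blocks)\n",
              x$mean, x$se, x$mean / 100, length(x$apl), x$n_blocks))
  invisible(x)
}
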