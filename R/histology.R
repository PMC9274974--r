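#' Tissue / particle mask pair for one adrenal section
#'
#' @param tissue Binary matrix (nonzero = tissue).
#' @param particles Binary matrix, same shape (nonzero = nanoparticle).
#' @param pixel_size Pixel edge length in micrometers.
#' @return An object of class `section_mask`.
#' @export
section_mask <- function(tissue, particles, pixel_size = NA_real_) {
  tissue <- (as.matrix(tissue) != 0) * 1L
  particles <- (as.matrix(particles) != 0) * 1L
  if (!all(dim(tissue) == dim(particles)))
    stop("tissue and particle masks must have the same shape")
  structure(list(tissue = tissue, particles = particles,
                 pixel_size = pixel_size),
            class = "section_mask")
}

#' Moment-based ellipse fit of a tissue mask
#'
#' Takes the largest connected component of the tissue mask, fills holes,
#' and fits an ellipse from the image moments: center = centroid, axes and
#' orientation from the eigendecomposition of the second-order central
#' moments (for a solid ellipse the semi-axis equals twice the square root
#' of the corresponding eigenvalue).
#'
#' @param mask A `section_mask` (or binary matrix).
#' @return An object of class `ellipse_fit`: `center` (row, col),
#'   `semi_axes` (major, minor, px), `orientation` (radians, major axis
#'   w.r.t. rows), and the cleaned component mask.
#' @export
fit_ellipse_moments <- function(mask) {
  m <- if (inherits(mask, "section_mask")) mask$tissue else (as.matrix(mask) != 0) * 1L
  if (!any(m > 0)) stop("empty tissue mask")
  lab <- EBImage::bwlabel(m)
  tab <- tabulate(lab[lab > 0])
  comp <- (lab == which.max(tab)) * 1
  comp <- EBImage::fillHull(comp)
  idx <- which(comp > 0, arr.ind = TRUE)
  ctr <- colMeans(idx)
  cc <- sweep(idx, 2, ctr)
  S <- crossprod(cc) / nrow(cc)
  eg <- eigen(S, symmetric = TRUE)
  semi <- 2 * sqrt(eg$values)          # solid ellipse: lambda = a^2 / 4
  v <- eg$vectors[, 1]
  structure(list(center = ctr, semi_axes = semi,
                 orientation = atan2(v[2], v[1]),
                 axes_vectors = eg$vectors, component = comp),
            class = "ellipse_fit")
}

#' Label adrenal sub-regions by normalized elliptical radius
#'
#' Every pixel gets a normalized radius r (r = 1 on the fitted boundary)
#' from the ellipse fit; radial bands map pixels to zones inside-out:
#' medulla (r < b1), zona reticularis (b1 <= r < b2), zona fasciculata
#' (b2 <= r < b3), zona glomerulosa (b3 <= r <= 1), outside beyond.
#'
#' @param fit An `ellipse_fit`.
#' @param dim Image dimensions (rows, cols); defaults to the fitted
#'   component's dimensions.
#' @param bands Three increasing radial fractions in (0, 1) (default
#'   `c(0.4, 0.7, 0.9)`).
#' @return An object of class `zone_map`: character matrix of labels in
#'   `{medulla, ZR, ZF, ZG, outside}` plus the radius matrix and bands.
#' @export
assign_zones <- function(fit, dim = base::dim(fit$component),
                         bands = c(0.4, 0.7, 0.9)) {
  if (length(bands) != 3 || any(diff(bands) <= 0) || bands[1] <= 0 ||
      bands[3] >= 1)
    stop("bands must be three strictly increasing fractions in (0, 1)")
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2]) - fit$center[1]
  cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE) - fit$center[2]
  V <- fit$axes_vectors
  u1 <- rows * V[1, 1] + cols * V[2, 1]
  u2 <- rows * V[1, 2] + cols * V[2, 2]
  r <- sqrt((u1 / fit$semi_axes[1])^2 + (u2 / fit$semi_axes[2])^2)
  zone <- matrix("outside", dim[1], dim[2])
  zone[r <= 1] <- "ZG"
  zone[r < bands[3]] <- "ZF"
  zone[r < bands[2]] <- "ZR"
  zone[r < bands[1]] <- "medulla"
  structure(list(zones = zone, radius = r, bands = bands),
            class = "zone_map")
}

#' Per-zone nanoparticle coverage
#'
#' For each zone, the percentage of tissue pixels in that zone covered by
#' the particle mask. Tissue pixels that fall outside the fitted ellipse
#' (boundary jitter of the moments fit) are assigned to the outermost zone
#' (ZG) so zone pixel counts sum exactly to the tissue pixel count. Empty
#' zones report `NA` coverage, not 0.
#'
#' @param zones A `zone_map`.
#' @param mask The `section_mask` the zones were fitted on.
#' @return An object of class `coverage_report`: data frame with
#'   `zone`, `zone_px`, `particle_px`, `coverage_pct`.
#' @export
coverage_by_zone <- function(zones, mask) {
  z <- zones$zones
  if (!all(dim(z) == dim(mask$tissue))) stop("shape mismatch")
  z[mask$tissue > 0 & z == "outside"] <- "ZG"
  zl <- c("medulla", "ZR", "ZF", "ZG")
  tis <- mask$tissue > 0
  par <- mask$particles > 0
  out <- do.call(rbind, lapply(zl, function(lvl) {
    in_zone <- tis & z == lvl
    np <- sum(in_zone)
    data.frame(zone = lvl, zone_px = np,
               particle_px = sum(par & in_zone),
               coverage_pct = if (np > 0) 100 * sum(par & in_zone) / np
                              else NA_real_)
  }))
  attr(out, "tissue_px") <- sum(tis)
  class(out) <- c("coverage_report", class(out))
  out
}

#' Full zone-coverage analysis of one section
#'
#' Convenience wrapper: ellipse fit, zone assignment, coverage report.
#'
#' @param mask A `section_mask`.
#' @param bands Radial band fractions (see [assign_zones()]).
#' @return List with `fit`, `zones`, `coverage`.
#' @export
map_section <- function(mask, bands = c(0.4, 0.7, 0.9)) {
  fit <- fit_ellipse_moments(mask)
  zones <- assign_zones(fit, dim = dim(mask$tissue), bands = bands)
  list(fit = fit, zones = zones, coverage = coverage_by_zone(zones, mask))
}
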