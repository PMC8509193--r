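# Track sampling and critical-lesion placement.
#
# Randomness uses the global R RNG: call set.seed() (or use the seed arguments
# of the higher-level drivers) for reproducibility.

# Gy per (keV/um) per (um^-2) at unit density: D = 0.1602 * LET * Phi.
FLUENCE_DOSE_CONST <- 0.1602

#' Sample straight ion tracks through a nucleus
#'
#' Track count is Poisson with mean \eqn{\mu = \Phi \pi R^2} where the fluence
#' \eqn{\Phi = D / (0.1602\,L)} (particles per square micrometre) follows from
#' the absorbed dose `dose` (Gy) and LET `let` (keV/um) at unit density.
#' Tracks are parallel to the beam (z) axis with impact points uniform over
#' the projected disc.
#'
#' @param dose Absorbed dose in Gy (>= 0).
#' @param let LET in keV/um (> 0).
#' @param nucleus A [build_nucleus()] object.
#' @return Data frame of class `tracks`: `x`, `y` (impact point, um),
#'   `b` (impact parameter), `chord_um`, `z_entry`, `z_exit`, `let`.
#' @examples
#' set.seed(1)
#' tr <- sample_tracks(1.602, 100, build_nucleus(3))
#' @export
sample_tracks <- function(dose, let, nucleus) {
  stopifnot(inherits(nucleus, "nucleus"))
  if (!is.numeric(dose) || dose < 0) stop("dose must be >= 0", call. = FALSE)
  if (!is.numeric(let) || let <= 0) stop("let must be > 0", call. = FALSE)
  R <- nucleus$radius_um
  phi <- dose / (FLUENCE_DOSE_CONST * let)
  n <- if (dose == 0) 0L else rpois(1L, phi * nucleus$area_um2)
  b <- R * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  half <- sqrt(pmax(0, R^2 - b^2))
  out <- data.frame(x = b * cos(th), y = b * sin(th), b = b,
                    chord_um = 2 * half, z_entry = -half, z_exit = half,
                    let = rep(let, n))
  class(out) <- c("tracks", "data.frame")
  out
}

# content-weighted chromosome draw for n lesions
.draw_chrom <- function(n, karyotype) {
  if (n == 0L) return(integer(0))
  p <- karyotype$length_mbp / sum(karyotype$length_mbp)
  sample.int(nrow(karyotype), n, replace = TRUE, prob = p)
}

.assign_chrom <- function(pos, nucleus) {
  if (nucleus$assignment_mode == "voronoi_territories" && nrow(pos) > 0L) {
    seeds <- nucleus$territory_seeds
    apply(pos, 1L, function(p) {
      which.min((seeds[, 1] - p[1])^2 + (seeds[, 2] - p[2])^2 +
                  (seeds[, 3] - p[3])^2)
    })
  } else {
    .draw_chrom(nrow(pos), nucleus$karyotype)
  }
}

.lesion_frame <- function(pos, chrom, karyotype) {
  coord <- runif(length(chrom)) * karyotype$length_mbp[chrom]
  out <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    chrom = chrom, coord_mbp = coord)
  class(out) <- c("critical_lesions", "data.frame")
  out
}

#' Place critical lesions along an ion track
#'
#' Lesion count is Poisson with mean `cl_per_um` times the chord length;
#' positions are uniform along the chord.  Chromosome identity follows the
#' nucleus assignment mode; the genomic coordinate is uniform on the
#' chromosome.
#'
#' @param track One row of a [sample_tracks()] frame (or a list with `x`,
#'   `y`, `z_entry`, `chord_um`).
#' @param cl_per_um Mean critical lesions per micrometre of path (>= 0).
#' @param nucleus A [build_nucleus()] object.
#' @return Data frame of class `critical_lesions`: `x`, `y`, `z`, `chrom`,
#'   `coord_mbp`.
#' @export
place_ion_cls <- function(track, cl_per_um, nucleus) {
  stopifnot(inherits(nucleus, "nucleus"))
  if (!is.numeric(cl_per_um) || cl_per_um < 0)
    stop("cl_per_um must be >= 0", call. = FALSE)
  n <- if (cl_per_um == 0) 0L else rpois(1L, cl_per_um * track$chord_um)
  z <- track$z_entry + runif(n) * track$chord_um
  pos <- cbind(rep(track$x, n), rep(track$y, n), z)
  .lesion_frame(pos, .assign_chrom(pos, nucleus), nucleus$karyotype)
}

#' Place critical lesions for a photon exposure
#'
#' Lesion count is Poisson with mean `dose * cl_per_gy_cell`; positions are
#' uniform in the nuclear volume and chromosome identity is always
#' content-weighted (sparse photon lesions carry no track correlation).
#'
#' @param dose Absorbed dose in Gy (>= 0).
#' @param cl_per_gy_cell Mean critical lesions per Gy per cell (>= 0),
#'   referring the per-unit-DNA-mass yield to the full diploid genome.
#' @param nucleus A [build_nucleus()] object.
#' @return Data frame of class `critical_lesions`.
#' @export
place_photon_cls <- function(dose, cl_per_gy_cell, nucleus) {
  stopifnot(inherits(nucleus, "nucleus"))
  if (!is.numeric(dose) || dose < 0) stop("dose must be >= 0", call. = FALSE)
  if (!is.numeric(cl_per_gy_cell) || cl_per_gy_cell < 0)
    stop("cl_per_gy_cell must be >= 0", call. = FALSE)
  n <- if (dose == 0 || cl_per_gy_cell == 0) 0L else
    rpois(1L, dose * cl_per_gy_cell)
  pos <- runif_sphere(n, nucleus$radius_um)
  .lesion_frame(pos, .draw_chrom(n, nucleus$karyotype), nucleus$karyotype)
}
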