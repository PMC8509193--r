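# Lymphocyte nucleus geometry and chromosome assignment scheme.

#' Build a spherical lymphocyte nucleus
#'
#' The nucleus is a sphere of radius `radius_um` containing the 46 chromosomes
#' of [human_karyotype()].  Chromosome identity of a lesion is assigned either
#' by DNA content (`"content_weighted"`: chromosome drawn with probability
#' proportional to its Mbp, independent of position) or by nearest-seed
#' Voronoi territories (`"voronoi_territories"`: 46 seed points sampled
#' uniformly in the sphere; a lesion belongs to the territory containing it).
#' Both modes are declared approximations of interphase chromosome-territory
#' architecture.
#'
#' @param radius_um Nuclear radius in micrometres (> 0); default 3.0, a
#'   typical human lymphocyte nucleus.
#' @param assignment_mode `"content_weighted"` (default) or
#'   `"voronoi_territories"`.
#' @param seed Integer seed used to sample territory seed points (voronoi
#'   mode); the build is deterministic given `seed`.
#' @param karyotype A [human_karyotype()]-style data frame.
#' @return An object of class `nucleus`: list with `radius_um`, `area_um2`
#'   (projected cross-section \eqn{\pi R^2}), `assignment_mode`, `karyotype`,
#'   and `territory_seeds` (46 x 3 matrix, voronoi mode only).
#' @examples
#' nuc <- build_nucleus(3.0, seed = 1)
#' nuc$area_um2  # 28.274
#' @export
build_nucleus <- function(radius_um = 3.0,
                          assignment_mode = c("content_weighted",
                                              "voronoi_territories"),
                          seed = 1L,
                          karyotype = human_karyotype()) {
  if (!is.numeric(radius_um) || length(radius_um) != 1L || radius_um <= 0)
    stop("radius_um must be a single positive number", call. = FALSE)
  assignment_mode <- match.arg(assignment_mode)
  seeds <- matrix(numeric(0), 0L, 3L)
  if (assignment_mode == "voronoi_territories") {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
    seeds <- runif_sphere(nrow(karyotype), radius_um)
  }
  structure(list(radius_um = radius_um,
                 area_um2 = pi * radius_um^2,
                 assignment_mode = assignment_mode,
                 karyotype = karyotype,
                 territory_seeds = seeds,
                 seed = as.integer(seed)),
            class = "nucleus")
}

#' @export
print.nucleus <- function(x, ...) {
  cat(sprintf("<nucleus> R = %.2f um (area %.3f um^2), %s, %d chromosomes\n",
              x$radius_um, x$area_um2, x$assignment_mode,
              nrow(x$karyotype)))
  invisible(x)
}

# n points uniform in a sphere of radius R, as an n x 3 matrix
runif_sphere <- function(n, R) {
  r <- R * runif(n)^(1 / 3)
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * s * cos(phi), y = r * s * sin(phi), z = r * z)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
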