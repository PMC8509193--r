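# Synthetic-data generators replacing external dependencies: a parametric
# spread-out-Bragg-peak (SOBP) scoring generator standing in for transport
# code output, and a pseudo-experiment generator standing in for literature
# dose-response curves.  The component shapes (LET ramps, fragment fractions,
# tail decay) are openly invented; the RBE engine's correctness does not
# depend on them.

#' Specification of a synthetic SOBP carbon field
#'
#' @param depth_max_mm Depth range of the scoring grid (1 mm voxels).
#' @param proximal_mm,distal_mm SOBP edges (default 60-110 mm: a 5 cm SOBP).
#' @param dose_gy Prescribed uniform SOBP absorbed dose (typically 1, 2, 4).
#' @param opposed Two opposing beams?  In opposed mode the window is
#'   recentred on the midplane (the two mirrored SOBPs must coincide for the
#'   prescription to hold) and each beam delivers half the prescription.
#' @param entrance_frac Entrance-channel dose as a fraction of the SOBP dose.
#' @param tail_frac,tail_tau_mm Fragmentation-tail amplitude (fraction of the
#'   SOBP dose just past the distal edge) and exponential decay length.
#' @param let_entry,let_distal Primary-carbon LET ramp endpoints, keV/um.
#' @param photon_frac Photon/electron dose fraction in every voxel.
#' @return Object of class `sobp_spec`.
#' @export
sobp_spec <- function(depth_max_mm = 200, proximal_mm = 60, distal_mm = 110,
                      dose_gy = 2, opposed = FALSE,
                      entrance_frac = 0.55, tail_frac = 0.15,
                      tail_tau_mm = 25, let_entry = 13, let_distal = 80,
                      photon_frac = 0.03) {
  if (distal_mm <= proximal_mm)
    stop("distal edge must exceed proximal edge", call. = FALSE)
  if (distal_mm >= depth_max_mm)
    stop("distal edge beyond depth range", call. = FALSE)
  if (dose_gy <= 0) stop("dose must be > 0", call. = FALSE)
  structure(as.list(environment()), class = "sobp_spec")
}

# analytic on-axis total-dose profile of one mono-directional beam (per unit
# prescription), at depth d (mm)
.sobp_total <- function(spec, d) {
  ifelse(d < spec$proximal_mm,
         spec$entrance_frac +
           (1 - spec$entrance_frac) * 0.45 * d / spec$proximal_mm,
         ifelse(d <= spec$distal_mm, 1,
                spec$tail_frac * exp(-(d - spec$distal_mm) / spec$tail_tau_mm)))
}

# species table for one beam at depth d: Z, LET (keV/um), dose fraction
.sobp_components <- function(spec, d) {
  frag_w <- c(H = 0.40, He = 0.30, Li = 0.12, Be = 0.09, B = 0.09)
  frag_Z <- c(H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L)
  frag_let <- c(H = 1.0 + 1.5 * d / spec$depth_max_mm,
                He = 4.0 + 2.0 * d / spec$depth_max_mm,
                Li = 10 + 2.0 * d / spec$depth_max_mm,
                Be = 14 + 2.0 * d / spec$depth_max_mm,
                B = 18 + 3.0 * d / spec$depth_max_mm)
  in_beam <- d <= spec$distal_mm
  fC <- if (in_beam) 0.85 - 0.25 * d / spec$distal_mm else 0
  rest <- 1 - fC - spec$photon_frac
  Z <- c(0L, frag_Z)
  let <- c(0.5, frag_let)
  frac <- c(spec$photon_frac, rest * frag_w / sum(frag_w))
  if (in_beam) {
    letC <- spec$let_entry +
      (spec$let_distal - spec$let_entry) * (d / spec$distal_mm)^2
    Z <- c(Z, 6L)
    let <- c(let, letC)
    frac <- c(frac, fC)
  }
  data.frame(Z = Z, LET_keV_um = let, frac = frac)
}

#' Generate a synthetic SOBP scoring table
#'
#' Builds per-voxel particle contributions on a 1 mm depth grid: an entrance
#' channel below the SOBP dose with a rising primary-carbon LET ramp, a
#' uniform-dose SOBP, and a fragment-only exponential tail beyond the distal
#' edge (primaries stop there; only Z < 6 and photons remain).  The per-voxel
#' total dose follows the analytic profile exactly; the seeded jitter only
#' reshuffles the species fractions (which always sum to 1).  In opposed
#' mode the mirrored half-dose beam is added, so healthy tissue receives
#' entrance + tail mixtures and the depth-dose profile is symmetric about
#' the midplane.
#'
#' @param spec An [sobp_spec()].
#' @param seed Integer seed (jitter of species fractions).
#' @param path Optional output TSV path (scoring dialect of
#'   [read_scoring()]).
#' @param jitter_sd Lognormal sd of the fraction jitter (0 disables).
#' @return A `scoring` data frame (invisibly if `path` is given).
#' @export
make_sobp_scoring <- function(spec = sobp_spec(), seed = 1L, path = NULL,
                              jitter_sd = 0.005) {
  stopifnot(inherits(spec, "sobp_spec"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  depths <- seq(0.5, spec$depth_max_mm - 0.5, by = 1)
  if (spec$opposed) {
    ext <- spec$distal_mm - spec$proximal_mm
    mid <- spec$depth_max_mm / 2
    s1 <- spec
    s1$proximal_mm <- mid - ext / 2
    s1$distal_mm <- mid + ext / 2
    s1$dose_gy <- spec$dose_gy / 2
    s1$opposed <- FALSE
    beams <- list(list(spec = s1, flip = FALSE),
                  list(spec = s1, flip = TRUE))
  } else {
    beams <- list(list(spec = spec, flip = FALSE))
  }
  rows <- list()
  for (bm in beams) {
    sp <- bm$spec
    for (d in depths) {
      db <- if (bm$flip) sp$depth_max_mm - d else d
      tot <- sp$dose_gy * .sobp_total(sp, db)
      comp <- .sobp_components(sp, db)
      f <- comp$frac * exp(rnorm(nrow(comp), 0, jitter_sd))
      f <- f / sum(f)
      rows[[length(rows) + 1L]] <-
        data.frame(depth_mm = d, radial_mm = 0, Z = comp$Z,
                   LET_keV_um = comp$LET_keV_um, dose_Gy = tot * f)
    }
  }
  out <- do.call(rbind, rows)
  # merge the two beams' rows per voxel/species is deferred to read/profile;
  # keep one contribution per (beam, species, voxel) row
  class(out) <- c("scoring", "data.frame")
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines(c("# format: scoring/1",
                 sprintf("# seed: %d", as.integer(seed)),
                 sprintf("# dose_gy: %g", spec$dose_gy),
                 sprintf("# opposed: %s", spec$opposed)), con)
    writeLines("voxel_depth_mm\tvoxel_radial_mm\tZ\tLET_keV_um\tdose_Gy", con)
    writeLines(sprintf("%g\t%g\t%d\t%.17g\t%.17g", out$depth_mm,
                       out$radial_mm, out$Z, out$LET_keV_um, out$dose_Gy),
               con)
    return(invisible(out))
  }
  out
}

#' Generate a pseudo-experimental dicentric dose-response curve
#'
#' Runs the Monte Carlo simulator at a known ground-truth critical-lesion
#' yield and emits per-dose means and standard errors, emulating a literature
#' calibration curve; the truth is recorded in the file metadata for
#' parameter-recovery tests.
#'
#' @param field An ion [radiation_field()].
#' @param truth_cl_per_um Ground-truth CL yield, CL/um.
#' @param doses Dose points in (0, 3] Gy.
#' @param n_cells Cells per dose (>= 1; with 1 cell the standard error is
#'   reported as NA).
#' @param seed Integer seed.
#' @param path Optional output TSV path.
#' @param ... Passed to [simulate_dose_response()] (nucleus, kernel, ...).
#' @return A `dose_response` frame with attribute `truth`.
#' @export
make_pseudo_experiment <- function(field, truth_cl_per_um,
                                   doses = c(0.5, 1, 1.5, 2, 2.5, 3),
                                   n_cells = 2000L, seed = 1L, path = NULL,
                                   ...) {
  if (any(doses <= 0) || any(doses > 3))
    stop("pseudo-experiment doses must lie in (0, 3] Gy", call. = FALSE)
  curve <- simulate_dose_response(field, truth_cl_per_um, doses, n_cells,
                                  seed = seed, ...)
  attr(curve, "truth") <- truth_cl_per_um
  if (!is.null(path)) {
    write_dose_response(curve, path)
    return(invisible(curve))
  }
  curve
}

#' Packaged default critical-lesion yield models
#'
#' Synthetic stand-ins for the fitted LET dependences of the lesion yield
#' (the source fits are not tabulated anywhere): linear-quadratic through the
#' origin for protons and heavy ions, linear for helium, with coefficients
#' chosen once to give realistic dicentric yields (order 0.1-0.5 per cell
#' per Gy at therapeutic LETs).  See the methods vignette.
#'
#' @return Named list of `cl_yield_model` objects (`proton`, `helium`,
#'   `heavy`).
#' @export
default_cl_models <- function() {
  mk <- function(category, c1, c2) {
    structure(list(category = category, form = .cat_form[[category]],
                   c1 = c1, c2 = c2,
                   let_range = .cat_bounds[[category]],
                   exclusion_let = .cat_exclusion[[category]],
                   points = NULL),
              class = "cl_yield_model")
  }
  # frozen from a one-off magnitude-matching run: lesion yields solved so the
  # simulated dicentric yield at 1 Gy matches typical published magnitudes
  # (protons 0.03-0.12, He 0.10-0.35, heavy 0.15-0.40 per cell across each
  # category's LET range), then fitted with fit_cl_vs_let()
  list(proton = mk("proton", 9.065e-4, 5.374e-5),
       helium = mk("helium", 2.988e-3, 0),
       heavy = mk("heavy", 2.870e-3, 2.480e-6))
}

#' Synthetic cell-survival endpoint table
#'
#' A synthetic second-endpoint database emulating a chordoma cell-survival
#' table for RBE comparisons: photon reference alpha_X = 0.159 Gy^-1 (the
#' published chordoma photon value) with alpha_X/beta_X = `alpha_beta_gy`
#' (default 2 Gy), and ion alpha rising linearly with LET
#' (`alpha = alpha_X (1 + slope LET)`) to chordoma-like SOBP RBEs, with
#' constant beta.  Purely synthetic: a stand-in, not a fit to survival data.
#'
#' @param grids Per-category LET grids (defaults as in
#'   [default_let_grids()]).
#' @param alpha_X Photon linear coefficient, Gy^-1.
#' @param alpha_beta_gy Photon alpha/beta ratio, Gy.
#' @param slope LET slope of the ion alpha, per keV/um.
#' @return A `dicentric_db`-shaped endpoint table.
#' @export
synthetic_survival_db <- function(grids = default_let_grids(),
                                  alpha_X = 0.159, alpha_beta_gy = 2,
                                  slope = 0.055) {
  beta_X <- alpha_X / alpha_beta_gy
  rows <- list()
  for (cat in names(grids)) {
    g <- sort(grids[[cat]])
    rows[[cat]] <- data.frame(category = cat, LET_keV_um = g,
                              alpha_Gy1 = alpha_X * (1 + slope * g),
                              beta_Gy2 = beta_X)
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 photon = photon_reference(alpha_X, beta_X),
                 meta = list(endpoint = "survival_synthetic",
                             slope = slope)),
            class = "dicentric_db")
}
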