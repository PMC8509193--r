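# Calibration of the critical-lesion yield and its LET dependence.

#' Map atomic number to ion category
#'
#' Z = 1 is proton; Z = 2 is helium and, lacking dedicated lithium data,
#' Z = 3 borrows the helium coefficients; Z >= 4 is "heavy" (beryllium and
#' boron borrow the heavy-ion coefficients; carbon and above are heavy by
#' definition).  Z = 0 denotes photons/electrons.
#'
#' @param Z Atomic number(s), >= 0.
#' @return Character vector: `"photon"`, `"proton"`, `"helium"` or `"heavy"`.
#' @examples
#' ion_category(c(0, 1, 2, 3, 4, 6, 26))
#' @export
ion_category <- function(Z) {
  if (any(Z < 0) || any(Z != floor(Z)))
    stop("Z must be non-negative integers", call. = FALSE)
  out <- character(length(Z))
  out[Z == 0] <- "photon"
  out[Z == 1] <- "proton"
  out[Z %in% c(2, 3)] <- "helium"
  out[Z >= 4] <- "heavy"
  out
}

# category constants: LET exclusion threshold for CL-yield fits (keV/um) and
# functional form of the LET dependence
.cat_exclusion <- c(proton = Inf, helium = 113, heavy = 155)
.cat_form <- c(proton = "linear_quadratic", helium = "linear",
               heavy = "linear_quadratic")

#' Calibrate the critical-lesion yield against an observed curve
#'
#' Finds the CL/um value whose simulated dicentric dose-response best matches
#' the observed curve in error-weighted least squares, by golden-section
#' search (relative tolerance 1e-2) inside a bracket located by a log-spaced
#' grid scan.  Every objective evaluation re-simulates the same doses with
#' the same fixed seed, so the objective is deterministic during the search.
#' The bracketing scan runs at a reduced cell count (`grid_cells`) since it
#' only needs to localize the minimum; the golden-section refinement uses the
#' full `n_cells`.
#'
#' @param curve Observed `dose_response` frame (`dose_Gy`,
#'   `mean_dicentrics`, optional `stderr`); needs >= 2 nonzero-dose points.
#' @param field An ion [radiation_field()].
#' @param bounds Length-2 positive search interval for the yield (CL/um).
#' @param n_cells Cells per dose per objective evaluation.
#' @param seed Integer seed for the per-evaluation simulations.
#' @param nucleus,kernel,visibility_mbp Simulator configuration.
#' @param rel_tol Relative golden-section tolerance (default 1e-2).
#' @param grid_n Points in the initial bracketing grid scan.
#' @param grid_cells Cells per dose during the bracketing scan.
#' @return List of class `cl_calibration`: `cl_per_um` (the optimum),
#'   `objective` (weighted SSE at the optimum), `bounds`, `n_cells`, `seed`.
#'   A warning is raised when the optimum sits on a search bound.
#' @export
calibrate_cl_yield <- function(curve, field, bounds = c(0.05, 2.5),
                               n_cells = 2000L, seed = 1L,
                               nucleus = build_nucleus(),
                               kernel = rejoining_kernel(),
                               visibility_mbp = 3,
                               rel_tol = 1e-2, grid_n = 21L,
                               grid_cells = max(100L, n_cells %/% 10L)) {
  stopifnot(inherits(field, "radiation_field"), field$category != "photon")
  if (length(bounds) != 2L || any(bounds <= 0) || bounds[1] >= bounds[2])
    stop("bounds must be an increasing positive interval", call. = FALSE)
  obs <- curve[curve$dose_Gy > 0, , drop = FALSE]
  if (nrow(obs) < 2L)
    stop("need >= 2 nonzero-dose points to calibrate", call. = FALSE)
  w <- if ("stderr" %in% names(obs) && all(is.finite(obs$stderr)) &&
           all(obs$stderr > 0)) {
    1 / obs$stderr^2
  } else {
    # Poisson-based weights: var(mean) ~ Y / n
    n <- if ("n_cells" %in% names(obs)) obs$n_cells else n_cells
    n / pmax(obs$mean_dicentrics, 0.05)
  }
  objective <- function(y, cells = n_cells) {
    sim <- simulate_dose_response(field, y, obs$dose_Gy, cells, seed = seed,
                                  nucleus = nucleus, kernel = kernel,
                                  visibility_mbp = visibility_mbp,
                                  dose_ceiling_gy = max(obs$dose_Gy))
    sum(w * (sim$mean_dicentrics - obs$mean_dicentrics)^2)
  }
  # log-spaced grid scan (reduced cell count) to bracket the minimum
  grid <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = grid_n))
  fg <- vapply(grid, objective, numeric(1), cells = grid_cells)
  i <- which.min(fg)
  if (i == 1L || i == grid_n) {
    warning("calibration optimum at a search bound; check bounds",
            call. = FALSE)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(grid_n, i + 1L)]
  } else {
    lo <- grid[i - 1L]
    hi <- grid[i + 1L]
  }
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- objective(x1); f2 <- objective(x2)
  while ((b - a) > rel_tol * (abs(a) + abs(b)) / 2) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- objective(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- objective(x2)
    }
  }
  xopt <- (a + b) / 2
  structure(list(cl_per_um = xopt, objective = objective(xopt),
                 bounds = bounds, n_cells = as.integer(n_cells),
                 seed = as.integer(seed), field = field),
            class = "cl_calibration")
}

#' Fit the LET dependence of the critical-lesion yield
#'
#' Marks excluded points (helium: LET > 113 keV/um; heavy ions: LET > 155
#' keV/um; protons: none — yields above those thresholds fall below the
#' threshold yield and would make the model underestimate high-LET damage),
#' then least-squares fits the category's functional form through the origin
#' on the remainder: linear for helium, linear-quadratic for protons and
#' heavy ions.
#'
#' @param points Data frame with columns `LET_keV_um` and `cl_per_um`.
#' @param category `"proton"`, `"helium"` or `"heavy"`.
#' @param exclusion_let Override of the category exclusion threshold.
#' @return Object of class `cl_yield_model`: `category`, `form`, `c1`, `c2`,
#'   `let_range` (the category's LET interval; predictions plateau above its
#'   maximum), `exclusion_let`, `points` (with an `excluded` flag).
#' @examples
#' fit_cl_vs_let(data.frame(LET_keV_um = c(10, 20), cl_per_um = c(0.5, 1)),
#'               "helium")
#' @export
fit_cl_vs_let <- function(points, category = c("proton", "helium", "heavy"),
                          exclusion_let = NULL) {
  category <- match.arg(category)
  stopifnot(all(c("LET_keV_um", "cl_per_um") %in% names(points)))
  if (any(points$LET_keV_um <= 0) || any(points$cl_per_um < 0))
    stop("need LET > 0 and cl_per_um >= 0", call. = FALSE)
  thr <- if (is.null(exclusion_let)) .cat_exclusion[[category]]
         else exclusion_let
  points$excluded <- points$LET_keV_um > thr
  inc <- points[!points$excluded, , drop = FALSE]
  form <- .cat_form[[category]]
  need <- if (form == "linear") 1L else 2L
  if (nrow(inc) < need)
    stop("too few points after exclusion to fit ", category, call. = FALSE)
  L <- inc$LET_keV_um
  y <- inc$cl_per_um
  if (form == "linear") {
    c1 <- sum(L * y) / sum(L^2)
    c2 <- 0
  } else {
    X <- cbind(L, L^2)
    beta <- solve(crossprod(X), crossprod(X, y))
    c1 <- beta[1]
    c2 <- beta[2]
  }
  m <- structure(list(category = category, form = form,
                      c1 = unname(c1), c2 = unname(c2),
                      let_range = .cat_bounds[[category]],
                      exclusion_let = thr, points = points),
                 class = "cl_yield_model")
  chk <- predict_cl_yield(m, seq(m$let_range[1], m$let_range[2],
                                 length.out = 50L), .clip = FALSE)
  if (any(chk < 0))
    warning("fitted CL-yield model predicts negative yields on its range",
            call. = FALSE)
  m
}

#' Predict the critical-lesion yield at a given LET
#'
#' Evaluates the fitted through-origin form; above the model's valid range
#' the yield plateaus at the range maximum, mirroring the database's
#' conservative high-LET rule.
#'
#' @param model A [fit_cl_vs_let()] model.
#' @param let LET value(s) in keV/um, > 0.
#' @param .clip Internal; clip negative predictions to zero.
#' @return Predicted yield(s), CL/um.
#' @export
predict_cl_yield <- function(model, let, .clip = TRUE) {
  stopifnot(inherits(model, "cl_yield_model"))
  if (any(let <= 0)) stop("let must be > 0", call. = FALSE)
  l <- pmin(let, model$let_range[2])
  y <- model$c1 * l + model$c2 * l^2
  if (.clip) y <- pmax(y, 0)
  y
}

#' Write / read a CL-yield point table as TSV
#'
#' Columns `category  LET_keV_um  cl_per_um  excluded`, `#` metadata lines.
#'
#' @param points Data frame with those columns (excluded optional on write).
#' @param path File path.
#' @export
write_cl_table <- function(points, path) {
  if (!"excluded" %in% names(points)) points$excluded <- FALSE
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# format: cl_yield_table/1", con)
  cols <- c("category", "LET_keV_um", "cl_per_um", "excluded")
  writeLines(paste(cols, collapse = "\t"), con)
  write.table(format(points[cols], digits = 17, trim = TRUE, scientific = NA),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_cl_table
#' @export
read_cl_table <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines)]
  df <- read.table(text = body, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("category", "LET_keV_um", "cl_per_um")
  if (!all(need %in% names(df)))
    stop("CL table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}
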