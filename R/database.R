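# Radiobiological database: linear-quadratic dicentric coefficients per ion
# category and LET, with photon reference and high-LET plateau rules.

# category LET bounds for database grids, keV/um
.cat_bounds <- list(proton = c(2.5, 30), helium = c(5, 110),
                    heavy = c(5, 150))

#' Photon reference coefficients
#'
#' Linear-quadratic coefficients describing dicentric induction by the
#' reference photons (Cs-137 gamma rays): alpha_X = 0.020 Gy^-1 and
#' beta_X = 0.047 Gy^-2 by default.
#'
#' @param alpha_X Linear coefficient, Gy^-1 (>= 0).
#' @param beta_X Quadratic coefficient, Gy^-2 (>= 0); not both zero.
#' @return Object of class `photon_reference`.
#' @export
photon_reference <- function(alpha_X = 0.020, beta_X = 0.047) {
  if (alpha_X < 0 || beta_X < 0 || (alpha_X == 0 && beta_X == 0))
    stop("need alpha_X > 0 or beta_X > 0", call. = FALSE)
  structure(list(alpha_X = alpha_X, beta_X = beta_X),
            class = "photon_reference")
}

#' Fit the linear-quadratic model Y(D) = alpha D + beta D^2
#'
#' Weighted least squares of the mean yield on (D, D^2) with zero intercept;
#' weights 1/stderr^2 (unit weights when standard errors are absent).
#' Negative fitted coefficients are clipped at zero with a warning.
#'
#' @param curve `dose_response` frame (`dose_Gy`, `mean_dicentrics`, optional
#'   `stderr`); >= 2 distinct nonzero doses required.
#' @return Named numeric vector `c(alpha = , beta = )` (Gy^-1, Gy^-2).
#' @examples
#' d <- seq(0, 3, by = 0.25)
#' fit_lq(data.frame(dose_Gy = d, mean_dicentrics = 0.02 * d + 0.047 * d^2))
#' @export
fit_lq <- function(curve) {
  obs <- curve[curve$dose_Gy > 0, , drop = FALSE]
  if (nrow(obs) < 2L || length(unique(obs$dose_Gy)) < 2L)
    stop("fit_lq needs >= 2 distinct nonzero-dose points", call. = FALSE)
  w <- if ("stderr" %in% names(obs) && all(is.finite(obs$stderr)) &&
           all(obs$stderr > 0)) 1 / obs$stderr^2 else rep(1, nrow(obs))
  D <- obs$dose_Gy
  X <- cbind(D, D^2)
  XtW <- t(X * w)
  beta <- solve(XtW %*% X, XtW %*% obs$mean_dicentrics)
  ab <- c(alpha = beta[1], beta = beta[2])
  if (any(ab < 0)) {
    warning("negative LQ coefficient clipped to zero", call. = FALSE)
    ab <- pmax(ab, 0)
  }
  ab
}

#' Build the dicentric radiobiological database
#'
#' For each ion category and LET grid point: predict the critical-lesion
#' yield from the category's [fit_cl_vs_let()] model, simulate a dicentric
#' dose-response curve, fit the linear-quadratic model, and store alpha and
#' beta.  The photon reference is stored alongside.  Deterministic given
#' `seed`.
#'
#' @param cl_models Named list of `cl_yield_model`s (`proton`, `helium`,
#'   `heavy`); categories may be omitted.
#' @param grids Named list of LET grids (keV/um), one per category, each
#'   within the category bounds: protons 2.5-30, helium 5-110, heavy 5-150.
#'   Defaults to 2.5 keV/um steps across each category interval.
#' @param photon_ref A [photon_reference()].
#' @param doses Dose grid for the simulated curves, Gy.
#' @param n_cells Cells per dose point.
#' @param seed Integer seed.
#' @param nucleus,kernel,visibility_mbp Simulator configuration.
#' @return Object of class `dicentric_db`: list with `table` (data frame
#'   `category`, `LET_keV_um`, `alpha_Gy1`, `beta_Gy2`), `photon`
#'   (`photon_reference`), `meta` (seed, n_cells, parameters).
#' @export
build_database <- function(cl_models,
                           grids = default_let_grids(names(cl_models)),
                           photon_ref = photon_reference(),
                           doses = seq(0.5, 3, by = 0.5),
                           n_cells = 1000L, seed = 1L,
                           nucleus = build_nucleus(),
                           kernel = rejoining_kernel(),
                           visibility_mbp = 3) {
  stopifnot(is.list(cl_models), length(cl_models) > 0,
            inherits(photon_ref, "photon_reference"))
  cats <- names(cl_models)
  if (!all(cats %in% names(.cat_bounds)))
    stop("unknown ion category in cl_models", call. = FALSE)
  rows <- list()
  for (cat in cats) {
    g <- sort(grids[[cat]])
    b <- .cat_bounds[[cat]]
    if (any(g < b[1]) || any(g > b[2]))
      stop(sprintf("%s grid outside [%g, %g] keV/um", cat, b[1], b[2]),
           call. = FALSE)
    for (i in seq_along(g)) {
      let <- g[i]
      y <- predict_cl_yield(cl_models[[cat]], let)
      # derive a stable per-entry seed so entries are order-independent
      sub_seed <- (seed * 1000L + match(cat, names(.cat_bounds)) * 100L +
                     i) %% .Machine$integer.max
      curve <- simulate_dose_response(radiation_field(cat, let), y, doses,
                                      n_cells, seed = sub_seed,
                                      nucleus = nucleus, kernel = kernel,
                                      visibility_mbp = visibility_mbp,
                                      dose_ceiling_gy = max(doses))
      ab <- suppressWarnings(fit_lq(curve))
      rows[[length(rows) + 1L]] <-
        data.frame(category = cat, LET_keV_um = let,
                   alpha_Gy1 = ab[["alpha"]], beta_Gy2 = ab[["beta"]])
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, photon = photon_ref,
                 meta = list(seed = as.integer(seed),
                             n_cells = as.integer(n_cells),
                             doses = doses,
                             r0_um = kernel$r0_um, c_free = kernel$c_free,
                             radius_um = nucleus$radius_um,
                             assignment_mode = nucleus$assignment_mode)),
            class = "dicentric_db")
}

#' @rdname build_database
#' @param categories Character vector of categories to produce grids for.
#' @param step Grid spacing in keV/um (default 2.5).
#' @export
default_let_grids <- function(categories = c("proton", "helium", "heavy"),
                              step = 2.5) {
  out <- lapply(.cat_bounds[categories], function(b)
    seq(b[1], b[2], by = step))
  out
}

#' Look up linear-quadratic coefficients for a particle
#'
#' Z = 0 returns the photon reference.  Ions map to a category (Z = 1
#' proton; Z = 2, 3 helium; Z >= 4 heavy) and the coefficients are linearly
#' interpolated in LET on the category grid; LET below the grid clamps to the
#' first entry and LET above the grid clamps to the last entry (the
#' conservative high-LET plateau).
#'
#' @param db A `dicentric_db`.
#' @param Z Atomic number (scalar, >= 0).
#' @param let LET in keV/um (> 0 for ions; ignored for Z = 0).
#' @return Named numeric vector `c(alpha = , beta = )`.
#' @examples
#' \donttest{
#' lookup_lq(db, Z = 3, let = 50)  # lithium borrows helium coefficients
#' }
#' @export
lookup_lq <- function(db, Z, let = NA_real_) {
  stopifnot(inherits(db, "dicentric_db"), length(Z) == 1L, Z >= 0)
  if (Z == 0)
    return(c(alpha = db$photon$alpha_X, beta = db$photon$beta_X))
  if (!is.finite(let) || let <= 0)
    stop("ion lookup needs LET > 0", call. = FALSE)
  cat <- ion_category(Z)
  tab <- db$table[db$table$category == cat, , drop = FALSE]
  if (nrow(tab) == 0L)
    stop("database has no entries for category ", cat, call. = FALSE)
  if (nrow(tab) == 1L)
    return(c(alpha = tab$alpha_Gy1, beta = tab$beta_Gy2))
  a <- stats::approx(tab$LET_keV_um, tab$alpha_Gy1, xout = let, rule = 2)$y
  b <- stats::approx(tab$LET_keV_um, tab$beta_Gy2, xout = let, rule = 2)$y
  c(alpha = a, beta = b)
}

#' Serialize / parse the database as TSV
#'
#' Header `category  LET_keV_um  alpha_Gy-1  beta_Gy-2`; one `photon` row with
#' LET `-` carrying the reference coefficients; `#` metadata lines.  The
#' round trip is lossless at full double precision.
#'
#' @param db A `dicentric_db`.
#' @param path File path.
#' @return `read_db` returns a `dicentric_db`.
#' @export
write_db <- function(db, path) {
  stopifnot(inherits(db, "dicentric_db"))
  con <- file(path, "w")
  on.exit(close(con))
  m <- db$meta
  writeLines(c("# format: dicentric_db/1",
               sprintf("# seed: %s", m$seed %||% "NA"),
               sprintf("# n_cells: %s", m$n_cells %||% "NA"),
               sprintf("# r0_um: %s", m$r0_um %||% "NA"),
               sprintf("# c_free: %s", m$c_free %||% "NA"),
               sprintf("# radius_um: %s", m$radius_um %||% "NA"),
               sprintf("# assignment_mode: %s", m$assignment_mode %||% "NA")),
             con)
  writeLines("category\tLET_keV_um\talpha_Gy-1\tbeta_Gy-2", con)
  writeLines(sprintf("photon\t-\t%.17g\t%.17g",
                     db$photon$alpha_X, db$photon$beta_X), con)
  tab <- db$table
  writeLines(sprintf("%s\t%.17g\t%.17g\t%.17g", tab$category,
                     tab$LET_keV_um, tab$alpha_Gy1, tab$beta_Gy2), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_db
#' @export
read_db <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 1L) stop("empty database file", call. = FALSE)
  hdr <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, c("category", "LET_keV_um", "alpha_Gy-1", "beta_Gy-2")))
    stop("malformed database header: ", body[1], call. = FALSE)
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  bad <- which(vapply(rows, length, integer(1)) != 4L)
  if (length(bad))
    stop("malformed database row at line ",
         bad[1] + length(meta_lines) + 1L, call. = FALSE)
  cat <- vapply(rows, `[`, character(1), 1L)
  letc <- vapply(rows, `[`, character(1), 2L)
  alpha <- as.numeric(vapply(rows, `[`, character(1), 3L))
  beta <- as.numeric(vapply(rows, `[`, character(1), 4L))
  is_ph <- cat == "photon"
  if (!any(is_ph))
    stop("photon reference required in database file", call. = FALSE)
  if (any(is.na(alpha)) || any(is.na(beta)) || any(alpha < 0) || any(beta < 0))
    stop("invalid coefficient in database file", call. = FALSE)
  ph <- photon_reference(alpha[is_ph][1], beta[is_ph][1])
  tab <- data.frame(category = cat[!is_ph],
                    LET_keV_um = as.numeric(letc[!is_ph]),
                    alpha_Gy1 = alpha[!is_ph], beta_Gy2 = beta[!is_ph])
  if (any(is.na(tab$LET_keV_um)))
    stop("non-numeric LET in database file", call. = FALSE)
  for (cc in unique(tab$category)) {
    l <- tab$LET_keV_um[tab$category == cc]
    if (any(diff(l) <= 0))
      stop("non-increasing LET grid for category ", cc, call. = FALSE)
  }
  meta <- list()
  kv <- regmatches(meta_lines, regexec("^#\\s*([^:]+):\\s*(.*)$", meta_lines))
  for (m in kv) if (length(m) == 3L) meta[[trimws(m[2])]] <- m[3]
  structure(list(table = tab, photon = ph, meta = meta),
            class = "dicentric_db")
}
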