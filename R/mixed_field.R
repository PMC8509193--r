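# Per-voxel mixed-field coefficients, photon-equivalent dose, and RBE.

#' Read a per-voxel particle scoring file
#'
#' Scoring TSV dialect: header
#' `voxel_depth_mm  voxel_radial_mm  Z  LET_keV_um  dose_Gy`, one particle
#' contribution per row, `#` comment lines.  By default the radial dimension
#' is collapsed onto the beam axis (contributions summed over radial bins);
#' pass `radial = TRUE` to keep radial bins distinct.
#'
#' @param path File path.
#' @param radial Keep radial bins separate (default `FALSE`).
#' @return Data frame of class `scoring`: `depth_mm`, `radial_mm`, `Z`,
#'   `LET_keV_um`, `dose_Gy`.
#' @export
read_scoring <- function(path, radial = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  lineno <- which(keep)
  if (length(body) == 0L) return(.empty_scoring())
  hdr <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  need <- c("voxel_depth_mm", "voxel_radial_mm", "Z", "LET_keV_um", "dose_Gy")
  if (!all(need %in% hdr))
    stop("scoring file missing columns: ",
         paste(setdiff(need, hdr), collapse = ", "), call. = FALSE)
  if (length(body) == 1L) return(.empty_scoring())
  df <- read.table(text = body, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  for (col in need) {
    v <- df[[col]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric %s at line %d", col, lineno[bad + 1L]),
           call. = FALSE)
    }
  }
  if (any(df$dose_Gy < 0))
    stop(sprintf("negative dose at line %d",
                 lineno[which(df$dose_Gy < 0)[1] + 1L]), call. = FALSE)
  if (any(df$Z < 0 | df$Z != floor(df$Z)))
    stop(sprintf("invalid atomic number at line %d",
                 lineno[which(df$Z < 0 | df$Z != floor(df$Z))[1] + 1L]),
         call. = FALSE)
  if (any(df$Z >= 1 & df$LET_keV_um <= 0))
    stop("ion contribution with non-positive LET", call. = FALSE)
  out <- data.frame(depth_mm = df$voxel_depth_mm,
                    radial_mm = if (radial) df$voxel_radial_mm else 0,
                    Z = as.integer(df$Z), LET_keV_um = df$LET_keV_um,
                    dose_Gy = df$dose_Gy)
  # merge identical (voxel, species, LET) rows
  key <- paste(out$depth_mm, out$radial_mm, out$Z, out$LET_keV_um)
  if (anyDuplicated(key)) {
    agg <- stats::aggregate(dose_Gy ~ depth_mm + radial_mm + Z + LET_keV_um,
                            data = out, FUN = sum)
    out <- agg[order(agg$depth_mm, agg$radial_mm, agg$Z), ]
    rownames(out) <- NULL
  }
  class(out) <- c("scoring", "data.frame")
  out
}

.empty_scoring <- function() {
  out <- data.frame(depth_mm = numeric(0), radial_mm = numeric(0),
                    Z = integer(0), LET_keV_um = numeric(0),
                    dose_Gy = numeric(0))
  class(out) <- c("scoring", "data.frame")
  out
}

#' Dose-weighted mixed-field coefficients
#'
#' Theory-of-dual-radiation-action averaging over the particle contributions
#' in one voxel: \eqn{\bar\alpha = \sum_i \alpha_i D_i / \sum_i D_i} and
#' \eqn{\bar\beta = \sum_i \beta_i D_i / \sum_i D_i}, with \eqn{(\alpha_i,
#' \beta_i)} looked up in the database by species and LET.
#'
#' @param voxel Data frame of contributions (`Z`, `LET_keV_um`, `dose_Gy`)
#'   with positive total dose.
#' @param db A `dicentric_db`.
#' @return Named numeric vector `c(alpha_bar = , beta_bar = , dose_Gy = )`.
#' @export
average_coefficients <- function(voxel, db) {
  D <- voxel$dose_Gy
  total <- sum(D)
  if (total <= 0) stop("undefined average: zero total dose", call. = FALSE)
  ab <- vapply(seq_len(nrow(voxel)), function(i)
    lookup_lq(db, voxel$Z[i], voxel$LET_keV_um[i]), numeric(2))
  c(alpha_bar = sum(ab[1, ] * D) / total,
    beta_bar = sum(ab[2, ] * D) / total,
    dose_Gy = total)
}

#' Photon-equivalent dose from a dicentric yield
#'
#' Inverts the photon linear-quadratic response: the photon dose producing
#' yield Y is \eqn{D_X = (-\alpha_X + \sqrt{\alpha_X^2 + 4 \beta_X Y}) /
#' (2 \beta_X)}, with the analytic limit \eqn{Y/\alpha_X} when
#' \eqn{\beta_X = 0}.
#'
#' @param Y Dicentric yield(s) per cell, >= 0.
#' @param ref A [photon_reference()].
#' @return Photon-equivalent dose(s) in Gy.
#' @examples
#' photon_equivalent_dose(0.067, photon_reference(0.020, 0.047))  # 1 Gy
#' @export
photon_equivalent_dose <- function(Y, ref = photon_reference()) {
  stopifnot(inherits(ref, "photon_reference"))
  if (any(Y < 0)) stop("Y must be >= 0", call. = FALSE)
  if (ref$beta_X == 0) return(Y / ref$alpha_X)
  (-ref$alpha_X + sqrt(ref$alpha_X^2 + 4 * ref$beta_X * Y)) / (2 * ref$beta_X)
}

#' Per-voxel RBE for dicentric induction
#'
#' Computes the mixed-field yield \eqn{Y = \bar\alpha D + \bar\beta D^2},
#' the photon-equivalent dose \eqn{D_X}, and \eqn{RBE = D_X / D}.  A
#' zero-dose voxel is returned with `RBE = NA` (undefined, not zero).
#'
#' @param voxel Contributions data frame (`Z`, `LET_keV_um`, `dose_Gy`).
#' @param db A `dicentric_db`.
#' @return One-row data frame: `dose_Gy`, `alpha_bar`, `beta_bar`, `yield`,
#'   `D_X_Gy`, `RBE`, `RBE_weighted_dose_Gy`.
#' @export
voxel_rbe <- function(voxel, db) {
  D <- sum(voxel$dose_Gy)
  if (D <= 0) {
    return(data.frame(dose_Gy = D, alpha_bar = NA_real_, beta_bar = NA_real_,
                      yield = 0, D_X_Gy = 0, RBE = NA_real_,
                      RBE_weighted_dose_Gy = NA_real_))
  }
  m <- average_coefficients(voxel, db)
  Y <- m[["alpha_bar"]] * D + m[["beta_bar"]] * D^2
  DX <- photon_equivalent_dose(Y, db$photon)
  data.frame(dose_Gy = D, alpha_bar = m[["alpha_bar"]],
             beta_bar = m[["beta_bar"]], yield = Y, D_X_Gy = DX,
             RBE = DX / D, RBE_weighted_dose_Gy = DX)
}

#' Depth profile of RBE and RBE-weighted dose
#'
#' Evaluates [voxel_rbe()] for every voxel of a scoring table, per endpoint.
#' The primary endpoint is the dicentric database `db`; `endpoint2` may carry
#' a second endpoint table (e.g., a synthetic cell-survival database) with
#' its own photon reference, evaluated on the same voxels for comparison.
#'
#' @param scoring A [read_scoring()] frame (or path to a scoring TSV).
#' @param db A `dicentric_db` (dicentric endpoint).
#' @param endpoint2 Optional second `dicentric_db`-shaped endpoint table.
#' @param endpoint_names Labels for the endpoint column.
#' @return Data frame of class `rbe_profile`, depth-ordered, one row per
#'   voxel per endpoint: `depth_mm`, `dose_Gy`, `alpha_bar`, `beta_bar`,
#'   `yield`, `D_X_Gy`, `RBE`, `RBE_weighted_dose_Gy`, `endpoint`.
#' @export
rbe_profile <- function(scoring, db, endpoint2 = NULL,
                        endpoint_names = c("dicentrics", "endpoint2")) {
  if (is.character(scoring)) scoring <- read_scoring(scoring)
  stopifnot(inherits(db, "dicentric_db"))
  key <- paste(scoring$depth_mm, scoring$radial_mm)
  vox <- split(scoring, factor(key, levels = unique(key)))
  ids <- vapply(vox, function(v)
    paste(v$depth_mm[1], v$radial_mm[1]), character(1))
  if (anyDuplicated(ids)) stop("duplicate voxel ids", call. = FALSE)
  run <- function(dbx, label) {
    rows <- lapply(vox, function(v) {
      r <- voxel_rbe(v, dbx)
      cbind(data.frame(depth_mm = v$depth_mm[1], radial_mm = v$radial_mm[1]),
            r)
    })
    out <- do.call(rbind, rows)
    out$endpoint <- label
    out
  }
  prof <- run(db, endpoint_names[1])
  if (!is.null(endpoint2)) prof <- rbind(prof, run(endpoint2,
                                                   endpoint_names[2]))
  prof <- prof[order(prof$endpoint, prof$radial_mm, prof$depth_mm), ]
  rownames(prof) <- NULL
  class(prof) <- c("rbe_profile", "data.frame")
  prof
}

#' Write an RBE profile as TSV
#'
#' Columns `depth_mm  dose_Gy  alpha_bar  beta_bar  yield  D_X_Gy  RBE
#' RBE_weighted_dose_Gy  endpoint`, `#` metadata lines.
#'
#' @param profile An [rbe_profile()] frame.
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# format: rbe_profile/1", con)
  cols <- c("depth_mm", "dose_Gy", "alpha_bar", "beta_bar", "yield",
            "D_X_Gy", "RBE", "RBE_weighted_dose_Gy", "endpoint")
  writeLines(paste(cols, collapse = "\t"), con)
  write.table(format(as.data.frame(profile)[cols], digits = 17, trim = TRUE,
                     scientific = NA),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
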