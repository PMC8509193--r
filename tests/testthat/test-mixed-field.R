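# Mixed-field averaging, photon-equivalent dose, per-voxel RBE.

make_test_db <- function() {
  structure(list(
    table = data.frame(
      category = c("proton", "proton", "helium", "helium", "heavy", "heavy"),
      LET_keV_um = c(2.5, 30, 5, 110, 5, 150),
      alpha_Gy1 = c(0.03, 0.1, 0.08, 0.4, 0.1, 0.5),
      beta_Gy2 = c(0.05, 0.06, 0.05, 0.01, 0.05, 0.02)),
    photon = photon_reference(0.020, 0.047), meta = list()),
    class = "dicentric_db")
}

test_that("read_scoring parses, groups and validates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# demo scoring",
               "voxel_depth_mm\tvoxel_radial_mm\tZ\tLET_keV_um\tdose_Gy",
               "10.5\t0\t6\t30\t0.5",
               "10.5\t0\t1\t2\t0.1"), f)
  s <- read_scoring(f)
  expect_equal(nrow(s), 2L)
  expect_equal(sum(s$dose_Gy), 0.6, tolerance = 1e-12)

  # empty file
  writeLines(character(0), f)
  expect_equal(nrow(read_scoring(f)), 0L)

  # negative dose names the offending line
  writeLines(c("voxel_depth_mm\tvoxel_radial_mm\tZ\tLET_keV_um\tdose_Gy",
               "10.5\t0\t6\t30\t0.5",
               "11.5\t0\t6\t30\t-0.1"), f)
  expect_error(read_scoring(f), "negative dose at line 3")

  # missing column
  writeLines(c("voxel_depth_mm\tZ\tLET_keV_um\tdose_Gy",
               "10.5\t6\t30\t0.5"), f)
  expect_error(read_scoring(f), "missing columns")

  # fractional Z rejected
  writeLines(c("voxel_depth_mm\tvoxel_radial_mm\tZ\tLET_keV_um\tdose_Gy",
               "10.5\t0\t1.5\t30\t0.5"), f)
  expect_error(read_scoring(f), "atomic number")
})

test_that("average_coefficients is the dose-weighted mean", {
  db <- make_test_db()
  # single component: identity
  v1 <- data.frame(Z = 2L, LET_keV_um = 110, dose_Gy = 1)
  m1 <- average_coefficients(v1, db)
  expect_equal(m1[["alpha_bar"]], 0.4, tolerance = 1e-12)
  expect_equal(m1[["beta_bar"]], 0.01, tolerance = 1e-12)

  # equal doses: midpoint
  v2 <- data.frame(Z = c(2L, 2L), LET_keV_um = c(5, 110),
                   dose_Gy = c(1, 1))
  expect_equal(average_coefficients(v2, db)[["alpha_bar"]],
               (0.08 + 0.4) / 2, tolerance = 1e-12)

  # doses (1, 3) with alphas (0.1, 0.2) -> 0.175
  dbx <- make_test_db()
  dbx$table$alpha_Gy1[dbx$table$category == "helium"] <- c(0.1, 0.2)
  v3 <- data.frame(Z = c(2L, 2L), LET_keV_um = c(5, 110),
                   dose_Gy = c(1, 3))
  expect_equal(average_coefficients(v3, dbx)[["alpha_bar"]], 0.175,
               tolerance = 1e-12)

  expect_error(average_coefficients(
    data.frame(Z = 2L, LET_keV_um = 5, dose_Gy = 0), db), "zero total dose")
})

test_that("mixing stays inside the component envelope with unit weights", {
  db <- make_test_db()
  set.seed(88)
  for (rep in 1:200) {
    n <- sample(1:6, 1)
    v <- data.frame(Z = sample(0:8, n, replace = TRUE),
                    LET_keV_um = runif(n, 1, 200),
                    dose_Gy = runif(n, 0.01, 2))
    ab <- vapply(seq_len(n), function(i)
      lookup_lq(db, v$Z[i], v$LET_keV_um[i]), numeric(2))
    m <- average_coefficients(v, db)
    ww <- v$dose_Gy / sum(v$dose_Gy)
    expect_equal(sum(ww), 1, tolerance = 1e-12)
    expect_gte(m[["alpha_bar"]], min(ab[1, ]) - 1e-12)
    expect_lte(m[["alpha_bar"]], max(ab[1, ]) + 1e-12)
    expect_gte(m[["beta_bar"]], min(ab[2, ]) - 1e-12)
    expect_lte(m[["beta_bar"]], max(ab[2, ]) + 1e-12)
  }
})

test_that("photon_equivalent_dose inverts the photon LQ", {
  ref <- photon_reference(0.020, 0.047)
  expect_equal(photon_equivalent_dose(0, ref), 0)
  expect_equal(photon_equivalent_dose(0.020 * 1 + 0.047 * 1, ref), 1,
               tolerance = 1e-12)
  expect_equal(photon_equivalent_dose(0.020 * 2 + 0.047 * 4, ref), 2,
               tolerance = 1e-12)
  # printed-value examples: Y(1) = 0.067, Y(2) = 0.228
  expect_equal(photon_equivalent_dose(0.067, ref), 1.000, tolerance = 1e-9)
  expect_equal(photon_equivalent_dose(0.228, ref), 2.000, tolerance = 1e-9)
  # linear limit
  lin <- photon_reference(0.05, 0)
  expect_equal(photon_equivalent_dose(0.25, lin), 5)
  expect_error(photon_equivalent_dose(-0.1, ref), "Y")
  expect_error(photon_reference(0, 0), "alpha_X")
})

test_that("voxel_rbe computes Y, D_X and RBE; photon voxels give RBE = 1", {
  db <- make_test_db()
  # pure photon contributions -> RBE exactly 1 at any dose
  for (d in c(0.1, 1, 4)) {
    v <- data.frame(Z = 0L, LET_keV_um = 0.5, dose_Gy = d)
    r <- voxel_rbe(v, db)
    expect_equal(r$RBE, 1, tolerance = 1e-12)
    expect_equal(r$RBE_weighted_dose_Gy, d, tolerance = 1e-12)
  }

  # hand-computed: D = 1, alpha_bar = 0.06, beta_bar = 0.047
  dbx <- make_test_db()
  dbx$table$alpha_Gy1[dbx$table$category == "proton"] <- c(0.06, 0.06)
  dbx$table$beta_Gy2[dbx$table$category == "proton"] <- c(0.047, 0.047)
  v <- data.frame(Z = 1L, LET_keV_um = 10, dose_Gy = 1)
  r <- voxel_rbe(v, dbx)
  expect_equal(r$yield, 0.107, tolerance = 1e-9)
  expect_equal(r$D_X_Gy, 1.311, tolerance = 1e-3)
  expect_equal(r$RBE, r$D_X_Gy)
  expect_equal(r$RBE_weighted_dose_Gy, r$RBE * r$dose_Gy)

  # zero-dose voxel flagged with absent RBE
  r0 <- voxel_rbe(data.frame(Z = 1L, LET_keV_um = 10, dose_Gy = 0), db)
  expect_true(is.na(r0$RBE))
})

test_that("RBE limits and monotonicity follow the LQ algebra", {
  ref <- photon_reference(0.020, 0.047)
  # low-dose limit: RBE -> alpha_bar / alpha_X
  ab <- 0.26
  D <- 1e-6
  Y <- ab * D + 0.03 * D^2
  expect_equal(photon_equivalent_dose(Y, ref) / D, ab / 0.020,
               tolerance = 1e-4)
  # strictly increasing in alpha_bar at fixed beta_bar, D
  D <- 2
  rbes <- vapply(c(0.05, 0.1, 0.2, 0.4), function(a)
    photon_equivalent_dose(a * D + 0.03 * D^2, ref) / D, numeric(1))
  expect_true(all(diff(rbes) > 0))
})

test_that("rbe_profile shapes, determinism and endpoint RBE-vs-dose flip", {
  db <- make_test_db()
  scor <- make_sobp_scoring(sobp_spec(dose_gy = 1), seed = 2)
  prof <- rbe_profile(scor, db)
  expect_equal(nrow(prof), 200L)
  expect_true(all(diff(prof$depth_mm) > 0))
  prof2 <- rbe_profile(make_sobp_scoring(sobp_spec(dose_gy = 1), seed = 2),
                       db)
  expect_identical(prof, prof2)

  # two endpoints share the absorbed-dose column
  surv <- synthetic_survival_db()
  both <- rbe_profile(scor, db, endpoint2 = surv,
                      endpoint_names = c("dic", "surv"))
  expect_equal(nrow(both), 400L)
  d1 <- both$dose_Gy[both$endpoint == "dic"]
  d2 <- both$dose_Gy[both$endpoint == "surv"]
  expect_equal(d1, d2, tolerance = 1e-12)

  # with fixed mixed coefficients between the dicentric-like reference
  # (alpha/beta 0.43 Gy) and a survival-like reference (alpha/beta 2 Gy),
  # the low-dose vs high-dose RBE ordering flips between endpoints
  ref_dic <- photon_reference(0.020, 0.047)
  ref_srv <- photon_reference(0.159, 0.0795)
  abar <- 0.06
  bbar <- 0.047
  rbe_at <- function(ref, D)
    photon_equivalent_dose(abar * D + bbar * D^2, ref) / D
  expect_gt(rbe_at(ref_dic, 0.1), rbe_at(ref_dic, 4))  # decreasing
  expect_lt(rbe_at(ref_srv, 0.1), rbe_at(ref_srv, 4))  # increasing
})

test_that("profile TSV writer emits the documented columns", {
  db <- make_test_db()
  scor <- make_sobp_scoring(sobp_spec(depth_max_mm = 40, proximal_mm = 10,
                                      distal_mm = 25, dose_gy = 1),
                            seed = 1)
  prof <- rbe_profile(scor, db)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, f)
  lines <- readLines(f)
  hdr <- strsplit(lines[!grepl("^#", lines)][1], "\t")[[1]]
  expect_equal(hdr, c("depth_mm", "dose_Gy", "alpha_bar", "beta_bar",
                      "yield", "D_X_Gy", "RBE", "RBE_weighted_dose_Gy",
                      "endpoint"))
  expect_equal(length(lines[!grepl("^#", lines)]) - 1L, nrow(prof))
})
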