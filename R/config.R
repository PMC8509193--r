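# Run configuration: structured key-value text (base-R DCF format).

#' Default run configuration
#'
#' @return Named list: `radius_um` (3), `r0_um` (0.8), `c_free` (0.1),
#'   `assignment_mode`, `visibility_mbp` (3), `dose_ceiling_gy` (3),
#'   `seed` (1), `alpha_X` (0.020), `beta_X` (0.047), `photon_cl_per_gy`
#'   (6, illustrative), `n_cells` (1000), `doses` (0.5..3 Gy).
#' @export
default_run_config <- function() {
  list(radius_um = 3.0, r0_um = 0.8, c_free = 0.1,
       assignment_mode = "content_weighted", visibility_mbp = 3,
       dose_ceiling_gy = 3.0, seed = 1L, alpha_X = 0.020, beta_X = 0.047,
       photon_cl_per_gy = 6, n_cells = 1000L,
       doses = seq(0.5, 3, by = 0.5))
}

#' Read / write a run configuration file
#'
#' Plain-text DCF (`Field: value` lines); unknown fields are kept, missing
#' fields fall back to [default_run_config()].  `doses` is a comma-separated
#' list.
#'
#' @param path File path.
#' @param config Named list (for `write_run_config`).
#' @return `read_run_config` returns the merged configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- read.dcf(path)
  vals <- as.list(raw[1, ])
  num_fields <- c("radius_um", "r0_um", "c_free", "visibility_mbp",
                  "dose_ceiling_gy", "alpha_X", "beta_X", "photon_cl_per_gy")
  int_fields <- c("seed", "n_cells")
  for (f in names(vals)) {
    v <- trimws(vals[[f]])
    cfg[[f]] <- if (f %in% num_fields) as.numeric(v)
    else if (f %in% int_fields) as.integer(v)
    else if (f == "doses") as.numeric(strsplit(v, ",")[[1]])
    else v
  }
  if (cfg$radius_um <= 0) stop("radius_um must be > 0", call. = FALSE)
  if (cfg$r0_um <= 0) stop("r0_um must be > 0", call. = FALSE)
  if (cfg$c_free < 0) stop("c_free must be >= 0", call. = FALSE)
  if (!cfg$assignment_mode %in% c("content_weighted", "voronoi_territories"))
    stop("invalid assignment_mode", call. = FALSE)
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  cfg <- utils::modifyList(default_run_config(), config)
  cfg$doses <- paste(cfg$doses, collapse = ",")
  m <- matrix(vapply(cfg, function(x) paste(format(x, digits = 17),
                                            collapse = ","), character(1)),
              nrow = 1, dimnames = list(NULL, names(cfg)))
  write.dcf(m, path)
  invisible(path)
}

# nucleus/kernel pair from a config list
.sim_objects <- function(cfg) {
  list(nucleus = build_nucleus(cfg$radius_um, cfg$assignment_mode,
                               seed = cfg$seed),
       kernel = rejoining_kernel(cfg$r0_um, cfg$c_free))
}
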