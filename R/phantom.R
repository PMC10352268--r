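#' Phantom layout
#'
#' Geometry of a multi-tube imaging phantom: cylindrical sample tubes
#' (circles on an axial slice, replicated across slices) embedded in an
#' agarose background. Each tube holds one agent at one metal concentration.
#'
#' @param grid integer `(rows, cols, slices)` voxel dimensions.
#' @param centers numeric matrix with one `(row, col)` center per tube
#'   (1-based voxel coordinates).
#' @param radius tube radius in voxels.
#' @param tubes data.frame with columns `agent` (label) and `conc` (mmol/L),
#'   one row per tube.
#' @param background_rates named numeric `c(R1, R2)` of the agent-free
#'   agarose matrix, 1/s.
#' @return object of class `phantom_layout`.
#' @export
phantom_layout <- function(grid, centers, radius, tubes,
                           background_rates = c(R1 = 0.35, R2 = 1.5)) {
  centers <- as.matrix(centers)
  stopifnot(length(grid) == 3L, all(grid >= 1), ncol(centers) == 2L,
            nrow(centers) == nrow(tubes), radius > 0,
            all(c("agent", "conc") %in% names(tubes)),
            all(tubes$conc >= 0), length(background_rates) == 2L)
  if (nrow(centers) > 1) {
    dd <- as.matrix(stats::dist(centers))
    diag(dd) <- Inf
    if (min(dd) <= 2 * radius) stop("tubes overlap")
  }
  if (any(centers[, 1] - radius < 1 | centers[, 1] + radius > grid[1] |
          centers[, 2] - radius < 1 | centers[, 2] + radius > grid[2]))
    stop("tube extends outside the grid")
  structure(list(grid = as.integer(grid), centers = centers, radius = radius,
                 tubes = tubes, background_rates = background_rates),
            class = "phantom_layout")
}

#' Default single-agent dilution-series layout
#'
#' Places one tube per concentration of the standard dilution series
#' (0, 0.03, 0.06, 0.12, 0.25, 0.5 and 1 mmol/L metal by default) on a
#' square lattice inside the grid.
#'
#' @param agent agent label.
#' @param concs concentration series, mmol/L.
#' @param grid voxel grid dimensions.
#' @param radius tube radius, voxels.
#' @param background_rates background `c(R1, R2)`, 1/s.
#' @return a [phantom_layout()].
#' @export
default_phantom_layout <- function(agent,
                                   concs = c(0, 0.03, 0.06, 0.12, 0.25, 0.5, 1),
                                   grid = c(32, 32, 1), radius = 4,
                                   background_rates = c(R1 = 0.35, R2 = 1.5)) {
  n <- length(concs)
  per_row <- ceiling(sqrt(n))
  spacing <- 2 * radius + 3
  offs <- radius + 2
  centers <- t(vapply(seq_len(n) - 1L, function(i) {
    c(offs + (i %/% per_row) * spacing, offs + (i %% per_row) * spacing)
  }, numeric(2)))
  phantom_layout(grid, centers, radius,
                 data.frame(agent = agent, conc = concs,
                            stringsAsFactors = FALSE),
                 background_rates)
}

#' Logical voxel masks for each tube
#'
#' @param layout a [phantom_layout()].
#' @return list of logical arrays (one per tube) over the layout grid.
#' @export
tube_masks <- function(layout) {
  g <- layout$grid
  rr <- matrix(seq_len(g[1]), g[1], g[2])
  cc <- matrix(seq_len(g[2]), g[1], g[2], byrow = TRUE)
  lapply(seq_len(nrow(layout$centers)), function(i) {
    ctr <- layout$centers[i, ]
    disk <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= layout$radius^2
    array(rep(disk, g[3]), dim = g)
  })
}

#' Acquisition protocol
#'
#' Timing and noise parameters of one imaging experiment: an
#' inversion-recovery series (TI list) for T1 or a multi-echo series (TE
#' list) for T2.
#'
#' @param field field strength, tesla.
#' @param mode `"inversion_recovery"` or `"echo_decay"`.
#' @param times TI or TE list, ms; strictly increasing and positive.
#' @param TR repetition time, ms; must exceed the largest TI/TE.
#' @param d inversion scale factor used in simulation (1 = perfect inversion).
#' @param noise_sigma magnitude-noise SD as a fraction of S0 (e.g. 0.02 for
#'   SNR 50).
#' @param seed RNG seed attached to the protocol for reproducible simulation.
#' @return object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(field,
                                 mode = c("inversion_recovery", "echo_decay"),
                                 times, TR, d = 1, noise_sigma = 0,
                                 seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(field > 0, all(times > 0), !is.unsorted(times, strictly = TRUE),
            TR > max(times), d >= 0, noise_sigma >= 0)
  structure(list(field = field, mode = mode, times = times, TR = TR, d = d,
                 noise_sigma = noise_sigma, seed = seed),
            class = "acquisition_protocol")
}

#' Published acquisition timings for the two scanners
#'
#' The 64 mT protocols use 15 inversion times from 100 to 2500 ms with
#' TR = 3000 ms, and ten echo times from 37 to 702 ms; the 3 T protocols use
#' 11 inversion times from 50 to 6000 ms with TR = 10000 ms and five echo
#' times from 14 to 224 ms.
#'
#' @param field 0.064 or 3 (tesla).
#' @param mode `"inversion_recovery"` or `"echo_decay"`.
#' @param noise_sigma,seed,d passed to [acquisition_protocol()].
#' @return an [acquisition_protocol()].
#' @export
default_protocol <- function(field = 0.064,
                             mode = c("inversion_recovery", "echo_decay"),
                             noise_sigma = 0, seed = NULL, d = 1) {
  mode <- match.arg(mode)
  if (abs(field - 0.064) < 1e-9) {
    if (mode == "inversion_recovery")
      acquisition_protocol(field, mode,
        times = c(100, 200, 300, 400, 500, 600, 700, 800, 900,
                  1100, 1300, 1500, 1800, 2100, 2500),
        TR = 3000, d = d, noise_sigma = noise_sigma, seed = seed)
    else
      acquisition_protocol(field, mode,
        times = c(37, 111, 184, 259, 333, 407, 480, 554, 628, 702),
        TR = 3000, d = d, noise_sigma = noise_sigma, seed = seed)
  } else if (abs(field - 3) < 1e-9) {
    if (mode == "inversion_recovery")
      acquisition_protocol(field, mode,
        times = c(50, 75, 100, 125, 250, 500, 1000, 1500, 2000, 3000, 6000),
        TR = 10000, d = d, noise_sigma = noise_sigma, seed = seed)
    else
      acquisition_protocol(field, mode,
        times = c(14, 28, 56, 112, 224),
        TR = 10000, d = d, noise_sigma = noise_sigma, seed = seed)
  } else stop(sprintf("no default protocol at %g T", field))
}

#' Image series container
#'
#' A stack of magnitude volumes indexed by TI or TE with the acquisition
#' metadata needed for parametric mapping.
#'
#' @param data 4-D non-negative array `(rows, cols, slices, index)`.
#' @param times TI or TE values, ms, matching the 4th dimension.
#' @param mode `"inversion_recovery"` or `"echo_decay"`.
#' @param field tesla.
#' @param TR ms.
#' @param noise_sigma noise SD as a fraction of `S0`.
#' @param S0 simulated equilibrium amplitude (signal units).
#' @param layout optional [phantom_layout()] the series was generated from.
#' @return object of class `image_series`.
#' @export
image_series <- function(data, times, mode, field, TR, noise_sigma = 0,
                         S0 = 1, layout = NULL) {
  stopifnot(length(dim(data)) == 4L, dim(data)[4] == length(times),
            !is.unsorted(times, strictly = TRUE), all(data >= 0))
  structure(list(data = data, times = times, mode = mode, field = field,
                 TR = TR, noise_sigma = noise_sigma, S0 = S0,
                 layout = layout),
            class = "image_series")
}

#' Simulate a phantom image series
#'
#' Builds per-voxel T1 (or T2) from the tube assignments via [true_rates()]
#' (background voxels get the agarose rates), evaluates the
#' inversion-recovery or echo-decay signal model at every TI/TE, and applies
#' magnitude (Rician) noise. With the same seed the output is reproduced
#' bit for bit; with `noise_sigma = 0` every voxel equals the analytic model
#' value exactly.
#'
#' @param layout a [phantom_layout()].
#' @param protocol an [acquisition_protocol()].
#' @param agents named list of [agent_spec()]s covering every agent label in
#'   the layout.
#' @param S0 equilibrium signal amplitude (arbitrary units).
#' @param use_measured_conc rescale the nominal tube concentrations by each
#'   agent's measured/nominal stock ratio before computing rates (the
#'   physical samples are diluted from the assayed stock).
#' @return an [image_series()].
#' @export
simulate_phantom_series <- function(layout, protocol, agents, S0 = 100,
                                    use_measured_conc = TRUE) {
  stopifnot(inherits(layout, "phantom_layout"),
            inherits(protocol, "acquisition_protocol"))
  g <- layout$grid
  ir <- protocol$mode == "inversion_recovery"
  bg <- layout$background_rates
  Rmap <- array(if (ir) unname(bg[1]) else unname(bg[2]), dim = g)
  masks <- tube_masks(layout)
  for (i in seq_len(nrow(layout$tubes))) {
    lab <- layout$tubes$agent[i]
    if (!lab %in% names(agents))
      stop(sprintf("layout references undefined agent '%s'", lab))
    ag <- agents[[lab]]
    conc <- layout$tubes$conc[i]
    if (use_measured_conc)
      conc <- conc * ag$stock_measured_conc / ag$stock_nominal_conc
    rates <- true_rates(ag, conc, protocol$field, bg)
    Rmap[masks[[i]]] <- if (ir) rates[["R1"]] else rates[["R2"]]
  }
  Tmap_ms <- 1000 / Rmap
  nt <- length(protocol$times)
  data <- array(NA_real_, dim = c(g, nt))
  for (k in seq_len(nt)) {
    data[, , , k] <- if (ir)
      ir_signal(protocol$times[k], protocol$TR, Tmap_ms, S0, protocol$d)
    else
      se_signal(protocol$times[k], Tmap_ms, S0)
  }
  if (protocol$noise_sigma > 0)
    data <- with_seed(protocol$seed,
                      add_rician_noise(data, protocol$noise_sigma * S0))
  image_series(data, protocol$times, protocol$mode, protocol$field,
               protocol$TR, protocol$noise_sigma, S0, layout)
}

#' Per-tube relaxation-time table from a parametric map
#'
#' Summarizes a fitted map over each tube ROI of the generating layout:
#' the tube median T (robust against stray non-converged voxels) plus the
#' ROI mean/SD/count from [roi_statistics()].
#'
#' @param map a `parametric_map` from [map_volume()].
#' @param layout the [phantom_layout()] describing the ROIs.
#' @return data.frame with columns `agent`, `conc`, `T_ms` (median),
#'   `mean_ms`, `sd_ms`, `n`.
#' @export
tube_relaxation_table <- function(map, layout) {
  masks <- tube_masks(layout)
  rows <- lapply(seq_along(masks), function(i) {
    conv_mask <- masks[[i]] & map$converged
    if (!any(conv_mask)) {
      # tube entirely failed to fit (e.g. signal fully decayed before the
      # first sampling time): report NA rather than abort; the exclusion
      # rule downstream treats this as unfittable
      return(data.frame(agent = layout$tubes$agent[i],
                        conc = layout$tubes$conc[i],
                        T_ms = NA_real_, mean_ms = NA_real_,
                        sd_ms = NA_real_, n = 0L, stringsAsFactors = FALSE))
    }
    st <- roi_statistics(map$T, conv_mask)
    med <- stats::median(map$T[conv_mask], na.rm = TRUE)
    data.frame(agent = layout$tubes$agent[i], conc = layout$tubes$conc[i],
               T_ms = med, mean_ms = st[["mean"]], sd_ms = st[["sd"]],
               n = st[["n"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write an image series as NIfTI volumes plus a JSON sidecar
#'
#' One 3-D NIfTI volume per TI/TE (`<prefix>_NNN.nii.gz`) and a
#' `<prefix>.json` sidecar holding the acquisition metadata and layout, so
#' the series can be reconstructed by [read_image_series()].
#'
#' @param series an [image_series()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the sidecar path.
#' @export
write_image_series <- function(series, dir, prefix = "series") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(series$times)) {
    vol <- series$data[, , , k, drop = TRUE]
    dim(vol) <- dim(series$data)[1:3]
    RNifti::writeNifti(RNifti::asNifti(vol),
                       file.path(dir, sprintf("%s_%03d.nii.gz", prefix, k)))
  }
  side <- list(times = series$times, mode = series$mode, field = series$field,
               TR = series$TR, noise_sigma = series$noise_sigma, S0 = series$S0)
  if (!is.null(series$layout)) {
    lay <- series$layout
    side$layout <- list(grid = lay$grid, centers = lay$centers,
                        radius = lay$radius, tubes = lay$tubes,
                        background_rates = as.list(lay$background_rates))
  }
  path <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image series written by [write_image_series()]
#'
#' @param dir directory holding the volumes and sidecar.
#' @param prefix file-name prefix used at write time.
#' @return an [image_series()].
#' @export
read_image_series <- function(dir, prefix = "series") {
  side <- jsonlite::read_json(file.path(dir, paste0(prefix, ".json")),
                              simplifyVector = TRUE)
  nt <- length(side$times)
  vols <- lapply(seq_len(nt), function(k)
    as.array(RNifti::readNifti(
      file.path(dir, sprintf("%s_%03d.nii.gz", prefix, k)))))
  g <- dim(vols[[1]])
  if (length(g) == 2L) g <- c(g, 1L)
  data <- array(NA_real_, dim = c(g, nt))
  for (k in seq_len(nt)) data[, , , k] <- vols[[k]]
  layout <- NULL
  if (!is.null(side$layout)) {
    lay <- side$layout
    layout <- phantom_layout(lay$grid, lay$centers, lay$radius,
                             as.data.frame(lay$tubes),
                             unlist(lay$background_rates))
  }
  image_series(data, side$times, side$mode, side$field, side$TR,
               side$noise_sigma, side$S0, layout)
}
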