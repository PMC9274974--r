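#' Tissue thermal properties
#'
#' Bundle of the three material constants the bio-heat solver needs for one
#' tissue compartment.
#'
#' @param density Mass density in kg/m^3.
#' @param heat_capacity Specific heat capacity in J/(kg K).
#' @param conductivity Thermal conductivity in W/(m K).
#' @return An object of class `tissue_properties`.
#' @export
tissue_properties <- function(density, heat_capacity, conductivity) {
  stopifnot(density > 0, heat_capacity > 0, conductivity > 0)
  structure(list(density = density, heat_capacity = heat_capacity,
                 conductivity = conductivity),
            class = "tissue_properties")
}

#' Default adrenal and fat tissue properties
#'
#' Literature values for rat adrenal parenchyma and perirenal fat:
#' adrenal rho = 1020 kg/m^3, C_p = 3540 J/(kg K), K = 0.52 W/(m K);
#' fat rho = 911 kg/m^3, C_p = 2348 J/(kg K), K = 0.21 W/(m K).
#'
#' @return A `tissue_properties` object.
#' @export
adrenal_tissue <- function() tissue_properties(1020, 3540, 0.52)

#' @rdname adrenal_tissue
#' @export
fat_tissue <- function() tissue_properties(911, 2348, 0.21)

#' Blood perfusion parameters for the Pennes sink term
#'
#' The perfusion term removes heat at rate
#' `rho_b * C_b * omega_b * (T - T_b)` per unit volume wherever tissue is
#' perfused. Defaults: blood density 1000 kg/m^3, heat capacity
#' 4180 J/(kg K), perfusion rate 0.0064 1/s, arterial temperature 37 C.
#'
#' @param blood_density kg/m^3.
#' @param blood_heat_capacity J/(kg K).
#' @param perfusion_rate Volumetric perfusion rate omega_b in 1/s.
#' @param arterial_temperature Arterial blood temperature T_b in deg C.
#' @return An object of class `perfusion_properties`.
#' @export
perfusion_properties <- function(blood_density = 1000,
                                 blood_heat_capacity = 4180,
                                 perfusion_rate = 0.0064,
                                 arterial_temperature = 37) {
  stopifnot(blood_density > 0, blood_heat_capacity > 0, perfusion_rate >= 0,
            is.finite(arterial_temperature))
  structure(list(blood_density = blood_density,
                 blood_heat_capacity = blood_heat_capacity,
                 perfusion_rate = perfusion_rate,
                 arterial_temperature = arterial_temperature),
            class = "perfusion_properties")
}

#' Ellipsoidal gland geometry with a fat shell
#'
#' The rat adrenal gland is modeled as an ellipsoid of full axis lengths
#' 5.5 x 2.2 x 2.2 mm (semi-axes 2.75 / 1.1 / 1.1 mm) surrounded by a
#' concentric fat layer of constant thickness.
#'
#' @param axis_lengths Numeric triple, full axis lengths in mm (or semi-axes
#'   if `semi_axes = TRUE`).
#' @param fat_shell_thickness Fat layer thickness in mm (>= 0).
#' @param semi_axes If `TRUE`, `axis_lengths` are interpreted as semi-axes.
#' @return An object of class `gland_geometry` with element `semi` (mm
#'   semi-axes) and `fat_shell_thickness`.
#' @export
gland_geometry <- function(axis_lengths = c(5.5, 2.2, 2.2),
                           fat_shell_thickness = 0.5,
                           semi_axes = FALSE) {
  stopifnot(length(axis_lengths) == 3, all(axis_lengths > 0),
            fat_shell_thickness >= 0)
  semi <- if (semi_axes) axis_lengths else axis_lengths / 2
  structure(list(semi = semi, fat_shell_thickness = fat_shell_thickness),
            class = "gland_geometry")
}

#' Simulation grid for the bio-heat solver
#'
#' Cell-centered, isotropic Cartesian grid. If `bounds` is omitted it is
#' derived from `gland` by adding `margin` mm beyond the fat shell on every
#' side; the box is centered on the gland and snapped so that one voxel
#' center sits exactly at the origin.
#'
#' @param spacing Voxel spacing in mm.
#' @param gland Optional `gland_geometry` used to derive bounds.
#' @param bounds Optional 2 x 3 matrix (rows lo, hi) in mm.
#' @param margin Margin beyond the fat shell in mm (default 1).
#' @param dt Optional explicit time step in s; when `NULL` the solver picks
#'   a stable step.
#' @param duration Simulated time in s (default 60, one stimulation epoch).
#' @param initial_temperature Initial and Dirichlet boundary temperature T_o
#'   in deg C.
#' @return An object of class `sim_grid`.
#' @export
sim_grid <- function(spacing = 0.1, gland = NULL, bounds = NULL, margin = 1,
                     dt = NULL, duration = 60, initial_temperature = 37) {
  stopifnot(spacing > 0, duration > 0)
  if (is.null(bounds)) {
    if (is.null(gland)) stop("supply either `gland` or `bounds`")
    half <- gland$semi + gland$fat_shell_thickness + margin
    bounds <- rbind(lo = -half, hi = half)
  }
  bounds <- as.matrix(bounds)
  stopifnot(nrow(bounds) == 2, ncol(bounds) == 3,
            all(bounds[2, ] > bounds[1, ]))
  # odd voxel counts so a voxel center lies at the box center
  half <- (bounds[2, ] - bounds[1, ]) / 2
  mid <- colMeans(bounds)
  dims <- 2L * as.integer(ceiling(half / spacing - 0.5)) + 1L
  structure(list(spacing = spacing, dims = dims, center = mid,
                 dt = dt, duration = duration,
                 initial_temperature = initial_temperature),
            class = "sim_grid")
}

# voxel-center coordinates (mm) along each axis
grid_axes <- function(grid) {
  lapply(1:3, function(a) {
    n <- grid$dims[a]
    grid$center[a] + (seq_len(n) - (n + 1) / 2) * grid$spacing
  })
}

#' Specification of one MNP injection site
#'
#' @param center Numeric triple, site center in the gland frame (mm).
#' @param volume Injected volume in microliters (default 1).
#' @param iron_concentration Iron concentration in mg/ml (default 40).
#' @param slp Specific loss power in W/g(Fe) (default 600).
#' @return An object of class `injection_spec`. The implied volumetric power
#'   density is `slp * iron_concentration` mW/mm^3 (i.e. 2.4e7 W/m^3 at the
#'   defaults) over a sphere of radius `(3 V / 4 pi)^(1/3)` mm.
#' @export
injection_spec <- function(center, volume = 1, iron_concentration = 40,
                           slp = 600) {
  stopifnot(length(center) == 3, volume > 0, iron_concentration > 0, slp >= 0)
  structure(list(center = as.numeric(center), volume = volume,
                 iron_concentration = iron_concentration, slp = slp),
            class = "injection_spec")
}

#' Two default injection sites on the gland's long axis
#'
#' Mirrors the surgical protocol of two 1-ul boluses per gland: sites at
#' +/- `offset` mm from the gland center along the long axis.
#'
#' @param gland A `gland_geometry`.
#' @param offset Distance from center along the long axis in mm.
#' @param ... Passed to [injection_spec()].
#' @return List of two `injection_spec`s.
#' @export
default_injection_sites <- function(gland = gland_geometry(), offset = 1.0,
                                    ...) {
  list(injection_spec(c(-offset, 0, 0), ...),
       injection_spec(c(offset, 0, 0), ...))
}

#' Label grid voxels as adrenal, fat, or outside
#'
#' A voxel is adrenal iff its center satisfies the inner-ellipsoid
#' inequality, fat iff it lies between the inner ellipsoid and the ellipsoid
#' grown by the fat shell thickness.
#'
#' @param gland A `gland_geometry`.
#' @param grid A `sim_grid`; its bounds must enclose the fat shell with at
#'   least 2 voxels of margin, and the smallest gland axis must span at
#'   least 8 voxels.
#' @return An object of class `domain_labels`: integer 3-D array with codes
#'   0 = outside, 1 = adrenal, 2 = fat, plus the grid and gland.
#' @export
build_geometry <- function(gland, grid) {
  h <- grid$spacing
  if (min(2 * gland$semi) / h < 8)
    stop("grid too coarse: smallest gland axis spans fewer than 8 voxels")
  ax <- grid_axes(grid)
  outer_semi <- gland$semi + gland$fat_shell_thickness
  lo <- sapply(ax, min); hi <- sapply(ax, max)
  if (any(-outer_semi - lo < 2 * h) || any(hi - outer_semi < 2 * h))
    stop("grid bounds must enclose the fat shell with >= 2 voxels margin")
  # squared normalized radius w.r.t. inner and outer ellipsoids
  q <- function(semi) {
    x2 <- (ax[[1]] / semi[1])^2
    y2 <- (ax[[2]] / semi[2])^2
    z2 <- (ax[[3]] / semi[3])^2
    outer(outer(x2, y2, `+`), z2, `+`)
  }
  lab <- array(0L, grid$dims)
  lab[q(outer_semi) <= 1] <- 2L
  lab[q(gland$semi) <= 1] <- 1L
  structure(list(labels = lab, grid = grid, gland = gland),
            class = "domain_labels")
}

#' Render injection sites as a volumetric power-density field
#'
#' Each site becomes a uniform sphere of radius `(3 V / 4 pi)^(1/3)` (the
#' injected bolus) with power density `slp x iron_concentration`
#' (W/m^3 after unit conversion); overlapping spheres add. A Gaussian
#' alternative (`shape = "gaussian"`, sigma = half the bolus radius,
#' same total power) is available.
#'
#' @param sites List of `injection_spec`s; each center must fall in the
#'   adrenal region.
#' @param grid A `sim_grid`.
#' @param labels A `domain_labels` from [build_geometry()].
#' @param shape `"sphere"` (default) or `"gaussian"`.
#' @return Numeric 3-D array of power density in W/m^3, with attributes
#'   `total_power` (W, analytic `sum(slp * iron mass)`) and
#'   `integrated_power` (W, discretized).
#' @export
build_source <- function(sites, grid, labels, shape = c("sphere", "gaussian")) {
  shape <- match.arg(shape)
  if (inherits(sites, "injection_spec")) sites <- list(sites)
  ax <- grid_axes(grid)
  h <- grid$spacing
  src <- array(0, grid$dims)
  gland <- labels$gland
  total_power <- 0
  for (s in sites) {
    if (!is.null(gland) && sum((s$center / gland$semi)^2) > 1)
      stop("injection site outside the gland ellipsoid")
    a <- (3 * s$volume / (4 * pi))^(1 / 3)          # bolus radius, mm
    p0 <- s$slp * s$iron_concentration * 1000       # W/m^3
    # iron mass (g) = conc (mg/ml) * volume (ul) * 1e-6; power = slp * mass
    site_power <- s$slp * s$iron_concentration * s$volume * 1e-6  # W
    total_power <- total_power + site_power
    d2 <- outer(outer((ax[[1]] - s$center[1])^2, (ax[[2]] - s$center[2])^2,
                      `+`), (ax[[3]] - s$center[3])^2, `+`)
    if (shape == "sphere") {
      # partial-volume weight on boundary voxels keeps the integral honest
      w <- pmin(1, pmax(0, (a - sqrt(d2)) / h + 0.5))
      contrib <- p0 * w
    } else {
      sig <- a / 2
      contrib <- exp(-d2 / (2 * sig^2))
      contrib <- contrib * site_power / (sum(contrib) * (h * 1e-3)^3)
    }
    # bolus truncated by the simulation box -> renormalize to site power
    lo <- sapply(ax, min); hi <- sapply(ax, max)
    if (any(s$center + a > hi + h / 2) || any(s$center - a < lo - h / 2)) {
      got <- sum(contrib) * (h * 1e-3)^3
      if (got < site_power * 0.999) {
        warning("source sphere truncated by domain boundary; renormalizing")
        contrib <- contrib * site_power / got
      }
    }
    src <- src + contrib
  }
  attr(src, "total_power") <- total_power
  attr(src, "integrated_power") <- sum(src) * (h * 1e-3)^3
  src
}

#' Single-tissue domain covering the whole grid
#'
#' Labels every voxel as one compartment. Used for analytic verification
#' configurations (energy-balance and uniform-sphere conduction oracles)
#' where the heterogeneous gland/fat geometry is not wanted.
#'
#' @param grid A `sim_grid`.
#' @param label `"adrenal"` or `"fat"`.
#' @return A `domain_labels` object.
#' @export
uniform_labels <- function(grid, label = c("adrenal", "fat")) {
  label <- match.arg(label)
  lab <- array(if (label == "adrenal") 1L else 2L, grid$dims)
  structure(list(labels = lab, grid = grid, gland = NULL),
            class = "domain_labels")
}

# stability limit of the explicit scheme, s
ftcs_dt_limit <- function(tissue, spacing_mm) {
  alpha <- max(sapply(tissue, function(p)
    p$conductivity / (p$density * p$heat_capacity)))
  (spacing_mm * 1e-3)^2 / (6 * alpha)
}

#' Solve the Pennes bio-heat equation
#'
#' Explicit forward-time central-space integration of
#' `rho C dT/dt = div(K grad T) - rho_b C_b omega_b (T - T_b) + P`
#' with per-compartment tissue properties, harmonic-mean face
#' conductivities, and a Dirichlet (default) or insulated outer box.
#' The perfusion term is the standard Pennes heat sink: it cools tissue
#' above arterial temperature.
#'
#' @param labels A `domain_labels`.
#' @param source Power-density array from [build_source()] (W/m^3), or
#'   `NULL` for no heating.
#' @param tissue Named list of `tissue_properties` for `adrenal`, `fat` and
#'   `outside` (the perfused medium between the fat shell and the box;
#'   defaults to fat).
#' @param perfusion A `perfusion_properties`.
#' @param probe_points Optional matrix of probe coordinates (mm, one row per
#'   probe); temperature at the nearest voxel center is recorded every step.
#' @param snapshot_times Times (s) at which to store full 3-D fields.
#' @param boundary `"dirichlet"` (outer box held at T_o) or `"insulated"`.
#' @param courant Fraction of the explicit stability limit used when the
#'   grid does not fix `dt` (default 0.8).
#' @return An object of class `temperature_field` with probe traces, stored
#'   snapshots, the final field, and the running peak tissue temperature.
#' @export
simulate_bioheat <- function(labels, source = NULL,
                             tissue = list(adrenal = adrenal_tissue(),
                                           fat = fat_tissue(),
                                           outside = fat_tissue()),
                             perfusion = perfusion_properties(),
                             probe_points = NULL, snapshot_times = NULL,
                             boundary = c("dirichlet", "insulated"),
                             courant = 0.8) {
  boundary <- match.arg(boundary)
  grid <- labels$grid
  lab <- labels$labels
  dims <- dim(lab)
  n <- prod(dims)
  if (is.null(source)) source <- array(0, dims)
  stopifnot(all(dim(source) == dims), all(source >= 0))

  stopifnot(all(c("adrenal", "fat", "outside") %in% names(tissue)))
  code <- c(outside = 1L, adrenal = 2L, fat = 3L)
  pick <- lab + 1L  # 0,1,2 -> 1,2,3
  ord <- c("outside", "adrenal", "fat")
  Kv <- sapply(ord, function(t) tissue[[t]]$conductivity)[pick]
  rhoCv <- sapply(ord, function(t)
    tissue[[t]]$density * tissue[[t]]$heat_capacity)[pick]
  perf_coef <- perfusion$blood_density * perfusion$blood_heat_capacity *
    perfusion$perfusion_rate
  perfv <- rep(perf_coef, n)

  h <- grid$spacing * 1e-3
  dt_max <- ftcs_dt_limit(tissue, grid$spacing)
  dt <- grid$dt
  if (is.null(dt)) dt <- courant * dt_max
  if (dt > dt_max * (1 + 1e-12))
    stop(sprintf("dt = %.4g s violates the explicit stability limit %.4g s",
                 dt, dt_max))
  nsteps <- as.integer(ceiling(grid$duration / dt - 1e-9))
  dt <- grid$duration / nsteps

  probe_idx <- integer(0)
  if (!is.null(probe_points)) {
    probe_points <- matrix(probe_points, ncol = 3)
    ax <- grid_axes(grid)
    probe_idx <- apply(probe_points, 1, function(p) {
      ijk <- sapply(1:3, function(a) which.min(abs(ax[[a]] - p[a])))
      (ijk[1] - 1L) + dims[1] * ((ijk[2] - 1L) + dims[2] * (ijk[3] - 1L))
    })
  }
  snap_steps <- integer(0)
  if (!is.null(snapshot_times)) {
    snap_steps <- sort(unique(pmin(nsteps, pmax(1L,
      as.integer(round(snapshot_times / dt))))))
  }

  res <- pennes_ftcs(as.numeric(Kv), as.numeric(rhoCv), perfv,
                     as.numeric(source), lab > 0L, as.integer(dims),
                     h, dt, nsteps,
                     grid$initial_temperature,
                     perfusion$arterial_temperature,
                     if (boundary == "dirichlet") 0L else 1L,
                     snap_steps, as.integer(probe_idx))

  snaps <- lapply(res$snapshots, function(s) array(s, dims))
  probes <- NULL
  if (length(probe_idx)) {
    probes <- data.frame(time_s = seq(0, by = dt, length.out = nsteps + 1))
    for (p in seq_along(probe_idx))
      probes[[paste0("probe", p)]] <- res$probes[, p]
  }
  structure(list(times = snap_steps * dt, snapshots = snaps,
                 final = array(res$final, dims), probe_traces = probes,
                 peak = res$peak, peak_time = res$peak_time,
                 dt = dt, nsteps = nsteps, grid = grid, boundary = boundary),
            class = "temperature_field")
}

#' Threshold crossing report for a simulated temperature field
#'
#' Summarizes whether and when the field reaches an activation threshold
#' (default 42 C, the TRPV1 threshold). Per-probe first-crossing times use
#' linear interpolation between solver steps; the comparison is `>=`.
#'
#' @param field A `temperature_field`.
#' @param threshold Threshold temperature in deg C.
#' @param labels The `domain_labels` used for the simulation (defines the
#'   tissue voxels counted in the volume-above curve).
#' @return An object of class `threshold_report`: `peak_temperature`,
#'   `time_to_threshold` per probe (NA when never crossed), and a data frame
#'   `volume_above` (time_s, volume_mm3) over the stored snapshots.
#' @export
threshold_report <- function(field, threshold = 42, labels) {
  if (threshold < field$grid$initial_temperature)
    warning("threshold below the initial temperature: everything is 'above' at t = 0")
  ttt <- NULL
  if (!is.null(field$probe_traces)) {
    tm <- field$probe_traces$time_s
    ttt <- sapply(grep("^probe", names(field$probe_traces)), function(j) {
      v <- field$probe_traces[[j]]
      k <- which(v >= threshold)[1]
      if (is.na(k)) return(NA_real_)
      if (k == 1) return(0)
      tm[k - 1] + (threshold - v[k - 1]) / (v[k] - v[k - 1]) * (tm[k] - tm[k - 1])
    })
  }
  h3 <- field$grid$spacing^3  # mm^3 per voxel
  tis <- labels$labels > 0L
  vol <- data.frame(time_s = field$times,
                    volume_mm3 = vapply(field$snapshots, function(s)
                      sum(s[tis] >= threshold) * h3, numeric(1)))
  structure(list(threshold = threshold, peak_temperature = field$peak,
                 peak_time = field$peak_time, time_to_threshold = ttt,
                 volume_above = vol,
                 tissue_volume_mm3 = sum(tis) * h3),
            class = "threshold_report")
}

#' One-call thermal design check for an MNP-injected gland
#'
#' Builds the gland geometry and injection sources, runs the bio-heat
#' solver for one stimulation epoch, and reports threshold attainment.
#'
#' @param gland A `gland_geometry`.
#' @param sites List of `injection_spec`s (default: two 1-ul, 40 mg/ml,
#'   600 W/g sites at +/- 1 mm on the long axis).
#' @param spacing Grid spacing in mm.
#' @param duration Stimulation time in s.
#' @param threshold Activation threshold in deg C.
#' @param snapshot_times Snapshot times in s (default 20/40/60 s).
#' @param ... Passed to [simulate_bioheat()].
#' @return List with `labels`, `source`, `field`, `report`.
#' @export
simulate_adrenal_heating <- function(gland = gland_geometry(),
                                     sites = default_injection_sites(gland),
                                     spacing = 0.1, duration = 60,
                                     threshold = 42,
                                     snapshot_times = c(20, 40, 60), ...) {
  grid <- sim_grid(spacing = spacing, gland = gland, duration = duration)
  labels <- build_geometry(gland, grid)
  source <- build_source(sites, grid, labels)
  centers <- do.call(rbind, lapply(sites, `[[`, "center"))
  field <- simulate_bioheat(labels, source, probe_points = centers,
                            snapshot_times = snapshot_times, ...)
  list(labels = labels, source = source, field = field,
       report = threshold_report(field, threshold, labels))
}

#' Steady-state temperature rise of a uniformly heated sphere
#'
#' Closed-form conduction solution for a sphere of radius `a` with uniform
#' volumetric power `P` in an infinite medium of conductivity `K` (no
#' perfusion): `P (3 a^2 - r^2) / (6 K)` inside, `P a^3 / (3 K r)` outside.
#' Used as the independent oracle for the numerical solver.
#'
#' @param P Volumetric power density, W/m^3.
#' @param a_mm Sphere radius, mm.
#' @param K Conductivity, W/(m K).
#' @param r_mm Radius at which to evaluate (default 0 = center), mm.
#' @return Temperature rise in K.
#' @export
sphere_steady_rise <- function(P, a_mm, K, r_mm = 0) {
  a <- a_mm * 1e-3; r <- r_mm * 1e-3
  ifelse(r <= a, P * (3 * a^2 - r^2) / (6 * K), P * a^3 / (3 * K * r))
}

#' @rdname sphere_steady_rise
#' @param rho_c Volumetric heat capacity rho*C in J/(m^3 K) (transient only).
#' @param t_s Elapsed heating time in s (transient only).
#' @details `sphere_transient_rise()` gives the center temperature at finite
#'   time by superposing continuous point sources
#'   (`dT = q erfc(r / (2 sqrt(alpha t))) / (4 pi K r)` integrated over the
#'   sphere), approaching the steady value as `t -> Inf`.
#' @export
sphere_transient_rise <- function(P, a_mm, K, rho_c, t_s) {
  a <- a_mm * 1e-3
  alpha <- K / rho_c
  f <- function(r) r * erfc(r / (2 * sqrt(alpha * t_s)))
  (P / K) * integrate(f, 0, a, rel.tol = 1e-10)$value
}

erfc <- function(x) 2 * pnorm(-sqrt(2) * x)
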