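#' Construct a layered one-dimensional soil nitrate profile
#'
#' The soil is a stack of horizontal layers holding nitrate stocks (umol
#' per layer over one plant's ground area). Texture enters through the
#' leaching velocity -- the downward displacement of nitrate (cm per cm of
#' drainage water) -- which is several-fold larger in loamy sand than in
#' silt loam, and through nothing else: the simulator treats texture purely
#' as a nitrate-mobility contrast.
#'
#' @param texture `"silt_loam"` or `"loamy_sand"`.
#' @param depth Profile depth (cm, default 150).
#' @param dz Layer thickness (cm, default 3).
#' @param total_nitrate Profile nitrate at nitrogen-supply scalar 1 (umol
#'   per plant ground area; default 90000, about 0.8 kg N per plant area,
#'   ample for unstressed 40-day growth).
#' @param topsoil_fraction Fraction of initial nitrate placed in an
#'   exponential topsoil pool (the rest is uniform over the profile).
#' @param topsoil_decay e-folding depth (cm) of the topsoil pool.
#' @param leaching_velocity Displacement per cm drainage; defaults by
#'   texture (silt loam 1.2, loamy sand 3.4).
#' @param theta Volumetric water content used to convert stocks to
#'   concentrations for Michaelis-Menten uptake.
#' @param base_drainage Daily background drainage (cm d^-1).
#' @param event_drainage Extra drainage on rain-event days (cm).
#' @param event_every Rain-event period (days).
#' @return An object of class `soil_profile`.
#' @export
soil_profile <- function(texture = c("silt_loam", "loamy_sand"),
                         depth = 150, dz = 3,
                         total_nitrate = 90000,
                         topsoil_fraction = 0.5, topsoil_decay = 30,
                         leaching_velocity = NULL, theta = 0.3,
                         base_drainage = 0.35, event_drainage = 1.5,
                         event_every = 5) {
  texture <- match.arg(texture)
  if (depth <= 0 || dz <= 0 || depth %% dz != 0) {
    stop("depth must be a positive multiple of dz", call. = FALSE)
  }
  if (total_nitrate < 0) stop("total_nitrate must be >= 0", call. = FALSE)
  if (is.null(leaching_velocity)) {
    leaching_velocity <- switch(texture, silt_loam = 1.2, loamy_sand = 3.4)
  }
  n_layers <- as.integer(depth / dz)
  mid <- (seq_len(n_layers) - 0.5) * dz

  # initial nitrate: exponential topsoil pool plus uniform background
  w_top <- exp(-mid / topsoil_decay)
  w <- topsoil_fraction * w_top / sum(w_top) +
    (1 - topsoil_fraction) / n_layers

  structure(
    list(texture = texture, depth = depth, dz = dz, n_layers = n_layers,
         layer_mid = mid, total_nitrate = total_nitrate,
         init_weights = w / sum(w),
         leaching_velocity = leaching_velocity, theta = theta,
         base_drainage = base_drainage, event_drainage = event_drainage,
         event_every = event_every),
    class = "soil_profile"
  )
}

#' @export
print.soil_profile <- function(x, ...) {
  cat(sprintf(
    "Soil profile: %s, %g cm in %d layers of %g cm, %g umol nitrate at supply 1\n",
    x$texture, x$depth, x$n_layers, x$dz, x$total_nitrate))
  cat(sprintf("  leaching velocity %g cm per cm drainage, theta %g\n",
              x$leaching_velocity, x$theta))
  invisible(x)
}

#' Simulate nitrate leaching without a plant
#'
#' Runs only the downward advection of the soil profile for `duration`
#' days: each day a fraction `leaching_velocity * drainage / dz` (capped at
#' 1) of every layer's nitrate moves one layer down, and nitrate leaving
#' the bottom layer is lost. Useful for contrasting textures: the same
#' drainage schedule loses severalfold more nitrate from loamy sand than
#' from silt loam.
#'
#' @param soil A [soil_profile()].
#' @param duration Days (default 40).
#' @param n_supply Nitrogen supply scalar.
#' @return A list with `initial_n`, `final_n`, `leached_n` (umol) and
#'   `loss_fraction`.
#' @export
simulate_leaching <- function(soil, duration = 40, n_supply = 1) {
  stopifnot(inherits(soil, "soil_profile"), duration >= 1)
  stocks <- soil$init_weights * soil$total_nitrate * n_supply
  initial <- sum(stocks)
  drain <- drainage_schedule(soil, duration)
  leached <- 0
  nl <- soil$n_layers
  for (d in seq_len(duration)) {
    frac <- min(1, soil$leaching_velocity * drain[d] / soil$dz)
    if (frac <= 0) next
    moving <- stocks * frac
    stocks <- stocks - moving
    if (nl > 1) stocks[2:nl] <- stocks[2:nl] + moving[1:(nl - 1)]
    leached <- leached + moving[nl]
  }
  list(initial_n = initial, final_n = sum(stocks), leached_n = leached,
       loss_fraction = if (initial > 0) leached / initial else 0)
}

# Daily drainage schedule (cm water per day) over a simulation.
drainage_schedule <- function(soil, duration) {
  drain <- rep(soil$base_drainage, duration)
  if (soil$event_every > 0 && soil$event_drainage > 0 &&
      soil$event_every <= duration) {
    events <- seq(soil$event_every, duration, by = soil$event_every)
    drain[events] <- drain[events] + soil$event_drainage
  }
  drain
}
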