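#' Default fed-batch kinetics configuration
#'
#' Simple biomass-driven consumption/production kinetics for a CHO-style
#' fed-batch: logistic biomass growth; glucose consumed in proportion to
#' biomass and restored toward a per-batch setpoint by daily bolus feeds;
#' lactate produced during the growth phase and consumed after a metabolic
#' shift; glutamine fed daily and consumed; glutamate slowly exchanged at low
#' concentration. `jitter_sd` is the SD of the per-batch log-normal jitter
#' applied to rates and setpoints, which is what makes batches differ.
#'
#' @param glucose0 Initial glucose (g/L).
#' @param glucose_setpoint Post-feed glucose target (g/L).
#' @param glutamine0,glutamine_setpoint Initial / target glutamine (g/L).
#' @param lactate0,glutamate0 Initial lactate / glutamate (g/L).
#' @param mu Biomass specific growth rate (1/h).
#' @param biomass0,biomass_max Initial and plateau biomass (arbitrary units).
#' @param q_glucose Glucose consumption rate per biomass unit (g/L/h).
#' @param y_lactate Lactate yield on consumed glucose (g/g).
#' @param q_lactate_consumption Lactate consumption rate after the shift
#'   (g/L/h per biomass unit).
#' @param q_glutamine Glutamine consumption rate per biomass unit (g/L/h).
#' @param y_glutamate Glutamate yield on consumed glutamine (g/g).
#' @param q_glutamate_consumption Glutamate consumption rate (g/L/h per
#'   biomass unit).
#' @param shift_time_h Time of the lactate metabolic shift (h).
#' @param feed_interval_h Interval between bolus feeds (h, default daily).
#' @param feed_efficiency Fraction of the setpoint deficit replaced per feed.
#' @param jitter_sd Per-batch log-normal jitter SD (0 = identical batches).
#' @return A named list of kinetic parameters.
#' @export
default_kinetics <- function(glucose0 = 10, glucose_setpoint = 8,
                             glutamine0 = 0.55, glutamine_setpoint = 0.45,
                             lactate0 = 0.1, glutamate0 = 0.15,
                             mu = 0.035, biomass0 = 0.3, biomass_max = 12,
                             q_glucose = 0.010, y_lactate = 0.35,
                             q_lactate_consumption = 0.004,
                             q_glutamine = 0.0009, y_glutamate = 0.12,
                             q_glutamate_consumption = 0.0002,
                             shift_time_h = 132, feed_interval_h = 24,
                             feed_efficiency = 0.9, jitter_sd = 0.25) {
  k <- list(glucose0 = glucose0, glucose_setpoint = glucose_setpoint,
            glutamine0 = glutamine0, glutamine_setpoint = glutamine_setpoint,
            lactate0 = lactate0, glutamate0 = glutamate0,
            mu = mu, biomass0 = biomass0, biomass_max = biomass_max,
            q_glucose = q_glucose, y_lactate = y_lactate,
            q_lactate_consumption = q_lactate_consumption,
            q_glutamine = q_glutamine, y_glutamate = y_glutamate,
            q_glutamate_consumption = q_glutamate_consumption,
            shift_time_h = shift_time_h, feed_interval_h = feed_interval_h,
            feed_efficiency = feed_efficiency, jitter_sd = jitter_sd)
  bad <- names(k)[!vapply(k, function(v) is.numeric(v) && length(v) == 1 &&
                            is.finite(v) && v >= 0, logical(1))]
  if (length(bad)) {
    stop(sprintf("kinetic parameters must be finite and >= 0: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  k
}

#' Simulate a fed-batch metabolite trajectory
#'
#' Forward-Euler integration of the kinetics in [default_kinetics()] on a
#' fine time grid. Glucose and glutamine increase only at feed events and are
#' non-increasing between them; all concentrations stay >= 0; lactate rises
#' during the production phase and declines after the metabolic shift;
#' glutamine and glutamate stay in the sub-g/L range typical of culture
#' supernatant.
#'
#' @param duration_h Total simulated time (h, >= 0).
#' @param interval_h Integration/reporting time step (h, > 0).
#' @param kinetics Parameter list from [default_kinetics()].
#' @param seed Integer seed controlling the per-batch parameter jitter.
#' @param batch_id,site_id Identifiers stored with the trajectory.
#' @return An object of class `culture_trajectory`: `time_h`, a
#'   `concentrations` data frame (`glucose_g_L`, `lactate_g_L`,
#'   `glutamine_g_L`, `glutamate_g_L`), `feed_times_h`, and the ids.
#' @export
simulate_culture_trajectory <- function(duration_h, interval_h = 1,
                                        kinetics = default_kinetics(), seed = 1,
                                        batch_id = "batch1", site_id = "site1") {
  assert_scalar_number(duration_h, "duration_h", min = 0)
  assert_scalar_number(interval_h, "interval_h", min = 0, allow_zero = FALSE)
  k <- do.call(default_kinetics, kinetics[intersect(names(kinetics),
                                                    names(formals(default_kinetics)))])
  set.seed(seed)
  j <- function(x) x * exp(stats::rnorm(1, 0, k$jitter_sd))
  glucose <- j(k$glucose0); g_set <- j(k$glucose_setpoint)
  glutamine <- j(k$glutamine0); q_set <- j(k$glutamine_setpoint)
  lactate <- j(k$lactate0); glutamate <- j(k$glutamate0)
  q_glc <- j(k$q_glucose); q_gln <- j(k$q_glutamine)
  q_lac <- j(k$q_lactate_consumption); q_glu <- j(k$q_glutamate_consumption)
  shift <- j(k$shift_time_h)

  times <- seq(0, duration_h, by = interval_h)
  if (times[length(times)] < duration_h) times <- c(times, duration_h)
  n <- length(times)
  G <- L <- Q <- E <- numeric(n)
  G[1] <- glucose; L[1] <- lactate; Q[1] <- glutamine; E[1] <- glutamate
  feed_times <- if (duration_h > 0 && k$feed_interval_h > 0) {
    seq(k$feed_interval_h, duration_h, by = k$feed_interval_h)
  } else numeric(0)
  fed <- logical(length(feed_times))

  biomass <- function(t) {
    k$biomass_max / (1 + (k$biomass_max - k$biomass0) / k$biomass0 * exp(-k$mu * t))
  }
  for (i in seq_len(n - 1)) {
    dt <- times[i + 1] - times[i]
    X <- biomass(times[i])
    dG_cons <- min(G[i], q_glc * X * dt)
    G[i + 1] <- G[i] - dG_cons
    if (times[i] < shift) {
      L[i + 1] <- L[i] + k$y_lactate * dG_cons
    } else {
      L[i + 1] <- max(0, L[i] - q_lac * X * dt)
    }
    dQ_cons <- min(Q[i], q_gln * X * dt)
    Q[i + 1] <- Q[i] - dQ_cons
    E[i + 1] <- max(0, E[i] + k$y_glutamate * dQ_cons - q_glu * X * dt)
    # bolus feeds occur at the step boundary; sampled values at a feed time are
    # post-feed, consumption resumes immediately after
    due <- !fed & feed_times <= times[i + 1]
    if (any(due)) {
      G[i + 1] <- G[i + 1] + max(0, g_set - G[i + 1]) * k$feed_efficiency
      Q[i + 1] <- Q[i + 1] + max(0, q_set - Q[i + 1]) * k$feed_efficiency
      fed[due] <- TRUE
    }
  }
  structure(list(
    time_h = times,
    concentrations = data.frame(glucose_g_L = G, lactate_g_L = L,
                                glutamine_g_L = Q, glutamate_g_L = E),
    feed_times_h = feed_times, batch_id = batch_id, site_id = site_id),
    class = "culture_trajectory")
}

#' @export
print.culture_trajectory <- function(x, ...) {
  cat(sprintf("<culture_trajectory> %s/%s: %d points over %.0f h, %d feeds\n",
              x$site_id, x$batch_id, length(x$time_h), max(x$time_h),
              length(x$feed_times_h)))
  invisible(x)
}
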