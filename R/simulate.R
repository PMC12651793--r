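# Seeded generator of first-order digestion curves and food panels. The
# simulator is the package's surrogate for wet-lab digestion runs: every
# downstream stage (metrics, eGI, validation) can be exercised against data
# whose generating parameters are known exactly.

INTESTINAL_GRID <- c(0, 15, 30, 45, 60, 90, 120)

#' Configuration of a simulated digestion run
#'
#' Describes one first-order hydrolysis process
#' \code{C(t) = c0 + (c_inf - c0)(1 - exp(-k t))} sampled on a grid with
#' additive Gaussian noise, clamped to [0, 100]. All randomness is driven by
#' the explicit seed; there is no ambient RNG use.
#'
#' @param seed integer seed; required.
#' @param c0 hydrolysis at t = 0 (%).
#' @param c_inf asymptotic hydrolysis (%); \code{c0 <= c_inf <= 100}.
#' @param k rate constant in min^-1; non-negative.
#' @param times sampling grid in minutes (default: the 0-120 min intestinal
#'   grid at 0, 15, 30, 45, 60, 90, 120).
#' @param noise_sd standard deviation of the additive measurement noise, in
#'   percentage points (default 2, a typical replicate spread for
#'   reducing-sugar assays).
#' @param n_replicates number of replicate curves to generate (default 3,
#'   matching triplicate assay practice).
#' @return Object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(seed, c0, c_inf, k,
                              times = INTESTINAL_GRID,
                              noise_sd = 2, n_replicates = 3L) {
  if (missing(seed)) stop("simulation_config: seed is required", call. = FALSE)
  stopifnot(length(seed) == 1L, is.finite(seed))
  times <- as.numeric(times)
  if (any(diff(times) <= 0) || times[1] < 0) {
    stop("simulation_config: times must be strictly increasing, starting >= 0",
         call. = FALSE)
  }
  if (!(c0 >= 0 && c0 <= c_inf && c_inf <= 100)) {
    stop("simulation_config: need 0 <= c0 <= c_inf <= 100", call. = FALSE)
  }
  if (k < 0) stop("simulation_config: k must be non-negative", call. = FALSE)
  if (noise_sd < 0) stop("simulation_config: noise_sd must be non-negative",
                         call. = FALSE)
  structure(
    list(seed = as.integer(seed), c0 = as.numeric(c0),
         c_inf = as.numeric(c_inf), k = as.numeric(k), times = times,
         noise_sd = as.numeric(noise_sd),
         n_replicates = as.integer(n_replicates)),
    class = "simulation_config"
  )
}

#' Simulate replicate hydrolysis curves
#'
#' Evaluates the configured first-order model on the sampling grid and adds
#' independent Gaussian measurement noise per replicate, clamping to
#' [0, 100]. Identical (config, food_id, digestion_model) input yields
#' byte-identical output.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param food_id identifier stamped on the curves.
#' @param digestion_model \code{"dynamic"} or \code{"static"}.
#' @return List of \code{config$n_replicates}
#'   \code{\link{hydrolysis_curve}} objects.
#' @examples
#' cfg <- simulation_config(seed = 1, c0 = 10, c_inf = 95, k = 0.03,
#'                          noise_sd = 0, n_replicates = 1)
#' simulate_curve(cfg, "rice")[[1]]
#' @export
simulate_curve <- function(config, food_id = "sim",
                           digestion_model = c("dynamic", "static")) {
  stopifnot(inherits(config, "simulation_config"))
  digestion_model <- match.arg(digestion_model)
  truth <- first_order_value(config$times, config$c0, config$c_inf, config$k)
  rng <- local_rng(config$seed)
  on.exit(rng())
  lapply(seq_len(config$n_replicates), function(rep) {
    eps <- if (config$noise_sd > 0) {
      stats::rnorm(length(truth), 0, config$noise_sd)
    } else {
      numeric(length(truth))
    }
    hydrolysis_curve(food_id, config$times, pmin(pmax(truth + eps, 0), 100),
                     digestion_model, replicate = rep)
  })
}

# Seed the session RNG for the duration of a call, restoring prior state on
# exit so simulation never perturbs the caller's RNG stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# Preset endpoint targets: percent hydrolysed at 0 and 120 min of the
# intestinal phase for each cereal x grain-size x digestion-model condition.
# Where a 0-min value was not reported, c0 defaults to 5% (flagged).
PRESET_TABLE <- data.frame(
  name = c("rice_small_dynamic", "rice_small_static",
           "rice_large_dynamic", "rice_large_static",
           "corn_small_dynamic", "corn_small_static",
           "corn_large_dynamic", "corn_large_static",
           "millet_small_dynamic", "millet_small_static",
           "millet_large_dynamic", "millet_large_static"),
  c0 = c(10.2, 8.3, 5, 5, 5, 5, 5, 5, 5, 5, 5, 5),
  c0_assumed = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                 TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
  target120 = c(95.6, 60.0, 51.9, 21.3, 62.4, 53.7,
                37.4, 34.9, 95.7, 65.6, 28.1, 17.9),
  stringsAsFactors = FALSE
)

#' Names of the built-in digestion scenario presets
#' @return Character vector of preset names.
#' @export
preset_names <- function() PRESET_TABLE$name

#' Build a named digestion scenario preset
#'
#' Each preset encodes one cereal / grain-size / digestion-model condition
#' by its measured hydrolysis endpoints: the noiseless simulated curve starts
#' at the reported 0-min value and passes through the reported 120-min value
#' to within 0.1 percentage point. The rate constant is fixed at
#' 0.03 min^-1 (a mid-range digestion rate on this grid) and the plateau
#' c_inf is solved from the 120-min target:
#' \code{c_inf = c0 + (target - c0) / (1 - exp(-120 k))}.
#' Conditions whose 0-min value was not reported start at 5% and carry
#' \code{c0_assumed = TRUE}.
#'
#' @param name one of \code{\link{preset_names}}.
#' @param seed integer seed for the generated curves; required.
#' @param noise_sd measurement noise SD in percentage points (default 2; use
#'   0 for the noiseless kinetic backbone).
#' @param n_replicates replicate curves per run (default 3).
#' @return Object of class \code{"scenario_preset"}: \code{name},
#'   \code{digestion_model}, \code{c0_assumed}, \code{target120},
#'   \code{config} (a \code{\link{simulation_config}}).
#' @examples
#' pr <- make_preset("rice_small_dynamic", seed = 1, noise_sd = 0)
#' cv <- simulate_curve(pr$config, "rice_small", pr$digestion_model)[[1]]
#' value_at(cv, 120)  # 95.6
#' @export
make_preset <- function(name, seed, noise_sd = 2, n_replicates = 3L) {
  row <- PRESET_TABLE[PRESET_TABLE$name == name, ]
  if (nrow(row) != 1L) {
    stop("make_preset: unknown preset '", name, "'; available: ",
         paste(preset_names(), collapse = ", "), call. = FALSE)
  }
  if (missing(seed)) stop("make_preset: seed is required", call. = FALSE)
  k <- 0.03
  c_inf <- row$c0 + (row$target120 - row$c0) / (1 - exp(-120 * k))
  cfg <- simulation_config(seed = seed, c0 = row$c0, c_inf = c_inf, k = k,
                           noise_sd = noise_sd, n_replicates = n_replicates)
  structure(
    list(name = name,
         digestion_model = if (grepl("dynamic$", name)) "dynamic" else "static",
         c0_assumed = row$c0_assumed,
         target120 = row$target120,
         config = cfg),
    class = "scenario_preset"
  )
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat(sprintf("Preset %s (%s model): c0 = %g%%%s, 120-min target = %g%%, k = %g /min\n",
              x$name, x$digestion_model, x$config$c0,
              if (x$c0_assumed) " (assumed)" else "", x$target120, x$config$k))
  invisible(x)
}

#' Simulate a food panel with known true eGI
#'
#' Generates \code{n_foods} foods whose compositions span the realistic
#' ranges of a mixed panel (carbohydrate 3-95, protein 0-36, fat 0-22,
#' fiber 0-10 g/100 g) and whose digestion kinetics (c0 in 2-15%, c_inf in
#' 20-98%, k in 0.01-0.06 min^-1) spread the hydrolysis index over roughly
#' 10-90. Each food's "true" eGI is computed from its noiseless curve by the
#' kinetic formula, and the human GI is that truth plus Gaussian noise
#' (floored at 1 so GI stays positive). A validation of the recomputed eGI
#' against these human GI values should therefore recover slope ~ 1 and
#' intercept ~ 0 — exactly 1 and 0 when \code{gi_noise_sd = 0}.
#'
#' @param n_foods number of foods (>= 3).
#' @param seed integer seed; required.
#' @param gi_noise_sd SD of the noise separating human GI from true eGI, in
#'   GI units (default 5, the order of inter-study GI variability).
#' @param coefs an \code{\link{egi_coefficients}} set.
#' @return List with \code{foods} (composition table with \code{human_gi}),
#'   \code{curves} (noiseless \code{\link{hydrolysis_curve}} list, dynamic
#'   model, one per food), and \code{truth} (data.frame \code{food_id},
#'   \code{c0}, \code{c_inf}, \code{k}, \code{egi_true}).
#' @examples
#' pan <- simulate_food_panel(14, seed = 42, gi_noise_sd = 0)
#' head(pan$truth)
#' @export
simulate_food_panel <- function(n_foods, seed, gi_noise_sd = 5,
                                coefs = egi_coefficients()) {
  if (missing(seed)) stop("simulate_food_panel: seed is required", call. = FALSE)
  if (n_foods < 3L) {
    stop("simulate_food_panel: need at least 3 foods", call. = FALSE)
  }
  coefs <- as_egi_coefficients(coefs)
  rng <- local_rng(seed)
  on.exit(rng())

  ids <- sprintf("food%03d", seq_len(n_foods))
  foods <- data.frame(
    food_id = ids,
    name = sprintf("Synthetic food %d", seq_len(n_foods)),
    carbohydrate = stats::runif(n_foods, 3, 95),
    protein = stats::runif(n_foods, 0, 36),
    fat = stats::runif(n_foods, 0, 22),
    fiber = stats::runif(n_foods, 0, 10)
  )
  kin <- data.frame(
    food_id = ids,
    c0 = stats::runif(n_foods, 2, 15),
    c_inf = stats::runif(n_foods, 20, 98),
    k = stats::runif(n_foods, 0.01, 0.06)
  )
  kin$c_inf <- pmax(kin$c_inf, kin$c0 + 5)  # keep the curve rising

  curves <- vector("list", n_foods)
  egi_true <- numeric(n_foods)
  for (i in seq_len(n_foods)) {
    vals <- first_order_value(INTESTINAL_GRID, kin$c0[i], kin$c_inf[i], kin$k[i])
    curves[[i]] <- hydrolysis_curve(ids[i], INTESTINAL_GRID, vals, "dynamic")
    m <- hydrolysis_metrics(curves[[i]])
    egi_true[i] <- egi_new(m, foods[i, ], coefs)
  }
  noise <- if (gi_noise_sd > 0) stats::rnorm(n_foods, 0, gi_noise_sd) else 0
  foods$human_gi <- pmax(egi_true + noise, 1)

  list(foods = foods,
       curves = curves,
       truth = cbind(kin, egi_true = egi_true))
}
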