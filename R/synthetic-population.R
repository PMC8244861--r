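## Ground-truth generator standing in for real network activations: unit
## populations whose color/form tuning mixes an additive (orthogonal)
## component with an interactive component at a controllable strength lambda.

#' Synthetic population specification
#'
#' Generative recipe for a unit population responding to a color x form
#' stimulus grid. Unit u's response to color c (hue angle theta_c) on object
#' f is
#'
#'   r_u(c, f) = (1 - lambda) * (alpha_u cos(theta_c - phi_u) + beta_u xi_uf)
#'               + lambda * gamma_ucf + eps
#'
#' with alpha, beta, xi, gamma ~ N(0, tuning_sd), phi ~ U(0, 360), and
#' eps ~ N(0, noise_sd). At lambda = 0 coding is purely additive (orthogonal:
#' every object shares the cosine-induced color geometry); at lambda = 1 the
#' color tuning is drawn independently per object (fully interactive).
#'
#' @param n_units number of units (>= 2).
#' @param n_objects number of object forms.
#' @param lambda interaction strength in \[0, 1\].
#' @param n_colors number of hues (default 12).
#' @param tuning_sd sd of all tuning draws (default 1).
#' @param noise_sd sd of the additive response noise (default 0.25).
#' @param seed integer seed.
#' @return a `population_spec` object.
#' @export
population_spec <- function(n_units, n_objects, lambda, n_colors = 12,
                            tuning_sd = 1, noise_sd = 0.25, seed = 1) {
  if (n_units < 2) stop("need at least 2 units", call. = FALSE)
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]", call. = FALSE)
  if (tuning_sd <= 0 || noise_sd < 0) stop("invalid sd", call. = FALSE)
  structure(list(n_units = n_units, n_objects = n_objects, lambda = lambda,
                 n_colors = n_colors, tuning_sd = tuning_sd,
                 noise_sd = noise_sd, seed = seed),
            class = "population_spec")
}

# draw the additive tuning base: cosine hue tuning plus per-object offsets
.population_base <- function(n_units, n_objects, n_colors, tuning_sd, seed) {
  set.seed(seed)
  theta <- hue_angles(n_colors) * pi / 180
  alpha <- stats::rnorm(n_units, sd = tuning_sd)
  phi <- stats::runif(n_units, 0, 2 * pi)
  beta <- stats::rnorm(n_units, sd = tuning_sd)
  xi <- matrix(stats::rnorm(n_units * n_objects, sd = tuning_sd), n_units, n_objects)
  list(col_tuning = alpha * cos(outer(phi, theta, function(p, t) t - p)),
       beta = beta, xi = xi)
}

#' Generate a synthetic unit population
#'
#' @param spec a [population_spec()].
#' @param base optional shared additive tuning base from an enclosing
#'   trajectory; drawn fresh from `spec$seed` when NULL.
#' @return activation matrix of dim (n_objects * n_colors) x n_units, rows
#'   object-major then hue-ordered, with attributes `keys` (stimulus key data
#'   frame) and `ground_truth` (the spec).
#' @export
generate_population <- function(spec, base = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  nu <- spec$n_units; nf <- spec$n_objects; nc <- spec$n_colors
  if (is.null(base)) {
    base <- .population_base(nu, nf, nc, spec$tuning_sd, spec$seed)
  }
  # interactive component and noise draw from a distinct sub-stream
  set.seed((spec$seed + 15485863L) %% .Machine$integer.max)
  col_tuning <- base$col_tuning
  beta <- base$beta
  xi <- base$xi
  out <- matrix(0, nf * nc, nu)
  for (f in seq_len(nf)) {
    gamma <- matrix(stats::rnorm(nu * nc, sd = spec$tuning_sd), nc, nu)
    additive <- t(col_tuning) + matrix(beta * xi[, f], nc, nu, byrow = TRUE)
    resp <- (1 - spec$lambda) * additive + spec$lambda * gamma
    if (spec$noise_sd > 0) {
      resp <- resp + matrix(stats::rnorm(nu * nc, sd = spec$noise_sd), nc, nu)
    }
    out[(f - 1) * nc + seq_len(nc), ] <- resp
  }
  keys <- data.frame(
    object_id = rep(sprintf("obj%02d", seq_len(nf)), each = nc),
    hue_index = rep(seq_len(nc) - 1L, nf),
    variant = "synthetic",
    stringsAsFactors = FALSE)
  attr(out, "keys") <- keys
  attr(out, "ground_truth") <- spec
  out
}

#' Trajectory specification: a synthetic layer hierarchy
#'
#' One population per layer with shared object/color identities and a
#' recorded lambda schedule — the synthetic twin of a processing hierarchy
#' whose color/form coding grows more interactive with depth. Layers share
#' the additive tuning base (drawn once from the master seed), standing in
#' for the common upstream signal all layers of one network process, while
#' the interactive component and response noise are redrawn per layer under
#' per-layer sub-seeds.
#'
#' @param lambdas lambda value per layer.
#' @param n_units,n_objects,n_colors,tuning_sd,noise_sd shared population
#'   parameters (see [population_spec()]).
#' @param seed master seed; layer k draws under a distinct sub-seed.
#' @return a `trajectory_spec` object.
#' @export
trajectory_spec <- function(lambdas, n_units, n_objects, n_colors = 12,
                            tuning_sd = 1, noise_sd = 0.25, seed = 1) {
  structure(list(lambdas = lambdas, n_units = n_units, n_objects = n_objects,
                 n_colors = n_colors, tuning_sd = tuning_sd,
                 noise_sd = noise_sd, seed = seed),
            class = "trajectory_spec")
}

#' Generate a synthetic layer trajectory
#'
#' @param spec a [trajectory_spec()].
#' @return named list of activation matrices ("layer1", ...), each as in
#'   [generate_population()]; attribute `lambdas` records the ground truth,
#'   attribute `fractions` the layer_fraction values 1/L .. 1.
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  L <- length(spec$lambdas)
  base <- .population_base(spec$n_units, spec$n_objects, spec$n_colors,
                           spec$tuning_sd, spec$seed)
  layers <- lapply(seq_len(L), function(k) {
    generate_population(population_spec(
      n_units = spec$n_units, n_objects = spec$n_objects,
      lambda = spec$lambdas[k], n_colors = spec$n_colors,
      tuning_sd = spec$tuning_sd, noise_sd = spec$noise_sd,
      seed = (spec$seed + 104729L * k) %% .Machine$integer.max),
      base = base)
  })
  names(layers) <- paste0("layer", seq_len(L))
  attr(layers, "lambdas") <- spec$lambdas
  attr(layers, "fractions") <- compute_layer_fraction(seq_len(L), L)
  layers
}
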