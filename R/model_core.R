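#' Define a microbial species by its demographic traits
#'
#' A species in the environmental pool is characterised by the per-capita
#' rate at which its members divide inside a community (`division_rate`,
#' conventionally written r), the rate at which new individuals disperse
#' from the pool and establish in a community (`dispersal_rate`, written c),
#' and an optional per-capita death rate d (0 in the core model).
#'
#' @param label Short unique species label, e.g. `"A"`.
#' @param division_rate Per-capita division rate r; must be positive.
#' @param dispersal_rate Establishment rate c from the pool; non-negative.
#' @param death_rate Per-capita death rate d; non-negative, and must be
#'   strictly below `division_rate` when positive (the supported regime is
#'   r >> d; a death rate at or above the division rate drives the community
#'   extinct and is rejected).
#'
#' @return An object of class `species_traits`.
#' @examples
#' species_traits("A", division_rate = 1, dispersal_rate = 0.5)
#' @export
species_traits <- function(label, division_rate, dispersal_rate, death_rate = 0) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (!is.numeric(division_rate) || length(division_rate) != 1L || division_rate <= 0)
    stop("`division_rate` must be a single positive number", call. = FALSE)
  if (!is.numeric(dispersal_rate) || length(dispersal_rate) != 1L || dispersal_rate < 0)
    stop("`dispersal_rate` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(death_rate) || length(death_rate) != 1L || death_rate < 0)
    stop("`death_rate` must be a single non-negative number", call. = FALSE)
  if (death_rate > 0 && death_rate >= division_rate)
    stop("unsupported regime: `death_rate` must be smaller than `division_rate` ",
         "(a community with d >= r declines to extinction)", call. = FALSE)
  structure(
    list(label = label, division_rate = division_rate,
         dispersal_rate = dispersal_rate, death_rate = death_rate),
    class = "species_traits"
  )
}

#' @export
print.species_traits <- function(x, ...) {
  cat(sprintf("<species_traits> %s: r = %g, c = %g, d = %g\n",
              x$label, x$division_rate, x$dispersal_rate, x$death_rate))
  invisible(x)
}

#' Assemble a community model from a species pool
#'
#' Bundles an ordered pool of species with the carrying capacity K that
#' bounds community size. Division is always logistically saturated: the
#' per-capita division rate of species i is r_i (1 - N/K). By default the
#' same saturation applies to dispersal (establishment gets harder as the
#' community fills up); setting `saturated_dispersal = FALSE` removes that
#' factor from the dispersal propensity in simulations, while still
#' disallowing dispersal at N = K so that assembly terminates.
#'
#' @param species A list of [species_traits()] objects (length S >= 1) with
#'   unique labels, or a single `species_traits` object.
#' @param carrying_capacity Positive integer K.
#' @param saturated_dispersal Logical; multiply dispersal propensities by
#'   (1 - N/K)? Default `TRUE`.
#'
#' @return An object of class `assembly_model`.
#' @examples
#' pool <- list(species_traits("A", 1, 0.5), species_traits("B", 1, 0.5))
#' assembly_model(pool, carrying_capacity = 1000)
#' @export
assembly_model <- function(species, carrying_capacity, saturated_dispersal = TRUE) {
  if (inherits(species, "species_traits")) species <- list(species)
  if (!is.list(species) || length(species) < 1L ||
      !all(vapply(species, inherits, logical(1), "species_traits")))
    stop("`species` must be a non-empty list of species_traits objects", call. = FALSE)
  labels <- vapply(species, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("species labels must be unique", call. = FALSE)
  if (!is.numeric(carrying_capacity) || length(carrying_capacity) != 1L ||
      carrying_capacity < 1 || carrying_capacity != round(carrying_capacity))
    stop("`carrying_capacity` must be a positive integer", call. = FALSE)
  stopifnot(is.logical(saturated_dispersal), length(saturated_dispersal) == 1L)
  structure(
    list(species = species,
         carrying_capacity = as.integer(carrying_capacity),
         saturated_dispersal = saturated_dispersal),
    class = "assembly_model"
  )
}

#' @export
print.assembly_model <- function(x, ...) {
  cat(sprintf("<assembly_model> S = %d species, K = %d, %s dispersal\n",
              length(x$species), x$carrying_capacity,
              if (x$saturated_dispersal) "saturated" else "unsaturated"))
  for (sp in x$species) print(sp)
  invisible(x)
}

# rate vectors of an assembly_model, in species order
model_rates <- function(model) {
  list(
    labels = vapply(model$species, `[[`, character(1), "label"),
    r = vapply(model$species, `[[`, numeric(1), "division_rate"),
    c = vapply(model$species, `[[`, numeric(1), "dispersal_rate"),
    d = vapply(model$species, `[[`, numeric(1), "death_rate")
  )
}

#' Snapshot of a community during assembly
#'
#' @param counts Vector of non-negative integer abundances, one per species.
#' @param time Elapsed time since the start of assembly (default 0).
#'
#' @return An object of class `community_state` with fields `counts`, `time`
#'   and `total`.
#' @export
community_state <- function(counts, time = 0) {
  if (!is.numeric(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must be non-negative integers", call. = FALSE)
  if (!is.numeric(time) || length(time) != 1L || time < 0)
    stop("`time` must be a single non-negative number", call. = FALSE)
  structure(list(counts = as.integer(counts), time = time,
                 total = as.integer(sum(counts))),
            class = "community_state")
}

#' Selection coefficient and dispersal ratio of a species pair
#'
#' Contrasts two species: the selection coefficient s = r_A - r_B measures
#' the within-community division advantage of the first species (s > 0 means
#' it is favoured), and the dispersal ratio c_A / c_B measures its advantage
#' in colonising from the pool. When the second species never disperses
#' (c_B = 0) the ratio is reported as `NA` and flagged undefined rather than
#' infinite, so downstream metrics stay finite.
#'
#' @param a,b [species_traits()] objects (species A and B).
#'
#' @return An object of class `trait_contrast` with fields
#'   `selection_coefficient`, `dispersal_ratio` and `ratio_defined`.
#' @examples
#' trait_contrast(species_traits("A", 1.05, 1), species_traits("B", 1, 1))
#' @export
trait_contrast <- function(a, b) {
  stopifnot(inherits(a, "species_traits"), inherits(b, "species_traits"))
  defined <- b$dispersal_rate > 0
  structure(
    list(selection_coefficient = a$division_rate - b$division_rate,
         dispersal_ratio = if (defined) a$dispersal_rate / b$dispersal_rate else NA_real_,
         ratio_defined = defined),
    class = "trait_contrast"
  )
}

#' @export
print.trait_contrast <- function(x, ...) {
  cat(sprintf("<trait_contrast> s = %g, cA/cB = %s\n",
              x$selection_coefficient,
              if (x$ratio_defined) format(x$dispersal_ratio) else "undefined (cB = 0)"))
  invisible(x)
}

#' Event propensities at a community state
#'
#' Returns the instantaneous rates of every event type the assembly process
#' can perform at the given state. With N individuals in a community of
#' capacity K, species i (abundance n_i) divides at total rate
#' r_i (1 - N/K) n_i, receives a disperser at rate c_i (1 - N/K)
#' (or plain c_i when the model turns dispersal saturation off; either way
#' dispersal is 0 at N = K so assembly terminates), and loses an individual
#' at rate d_i n_i.
#'
#' @param state A [community_state()] whose `counts` length matches the
#'   model's species pool.
#' @param model An [assembly_model()].
#'
#' @return A list with numeric per-species vectors `division`, `dispersal`,
#'   `death`, and scalar `total`.
#' @examples
#' m <- assembly_model(list(species_traits("A", 1, 0.5),
#'                          species_traits("B", 1, 0.5)), 10)
#' event_propensities(community_state(c(2, 3)), m)
#' @export
event_propensities <- function(state, model) {
  stopifnot(inherits(state, "community_state"), inherits(model, "assembly_model"))
  rates <- model_rates(model)
  S <- length(rates$r)
  if (length(state$counts) != S)
    stop("`state` has ", length(state$counts), " species but the model has ", S,
         call. = FALSE)
  K <- model$carrying_capacity
  N <- state$total
  if (N > K)
    stop("invalid state: total abundance ", N, " exceeds carrying capacity ", K,
         call. = FALSE)
  sat <- 1 - N / K
  division <- rates$r * sat * state$counts
  dispersal <- if (model$saturated_dispersal) rates$c * sat else rates$c
  if (N == K) dispersal <- rep(0, S)  # terminate even when unsaturated
  death <- rates$d * state$counts
  list(division = division, dispersal = dispersal, death = death,
       total = sum(division) + sum(dispersal) + sum(death))
}

#' Dispersal and growth timescales, and the limiting dispersal rate
#'
#' Community assembly is governed by two timescales: the mean waiting time
#' between establishing dispersal events, T_c = 1/c, and the time T_r for a
#' community seeded by one individual to grow logistically to the carrying
#' capacity K. The exact growth time is the sum of mean division times,
#' T_r = sum over N of 1 / (r (1 - N/K) N) for N = 1 .. K-1, which behaves as
#' 2 ln(K) / r for large K. Equating the two timescales defines the limiting
#' dispersal rate `c_lim = r / (2 ln K)`: assembly is division-driven for
#' c well below `c_lim` and dispersal-driven well above it.
#'
#' @param r Division rate (> 0).
#' @param c Dispersal rate (> 0).
#' @param K Carrying capacity, an integer >= 2.
#'
#' @return An object of class `timescales`: a list with `dispersal_time`,
#'   `growth_time_exact`, `growth_time_asymptotic` and `c_lim`.
#' @examples
#' timescales(r = 1, c = 0.5, K = 1e5)
#' @export
timescales <- function(r, c, K) {
  stopifnot(is.numeric(r), r > 0, is.numeric(c), c > 0, is.numeric(K))
  if (K < 2 || K != round(K))
    stop("`K` must be an integer >= 2 (growth sum is empty otherwise)", call. = FALSE)
  N <- seq_len(K - 1)
  structure(
    list(dispersal_time = 1 / c,
         growth_time_exact = sum(1 / (r * (1 - N / K) * N)),
         growth_time_asymptotic = 2 * log(K) / r,
         c_lim = r / (2 * log(K))),
    class = "timescales"
  )
}

#' @export
print.timescales <- function(x, ...) {
  cat(sprintf(paste0("<timescales> T_c = %g, T_r = %g (exact) ~ %g (large-K), ",
                     "c_lim = %g\n"),
              x$dispersal_time, x$growth_time_exact,
              x$growth_time_asymptotic, x$c_lim))
  invisible(x)
}

#' Limiting dispersal rate separating assembly regimes
#'
#' Convenience wrapper returning only c_lim = r / (2 ln K).
#'
#' @inheritParams timescales
#' @return The limiting dispersal rate, a single number.
#' @examples
#' c_lim(r = 1, K = 1e5)
#' @export
c_lim <- function(r, K) {
  stopifnot(is.numeric(r), r > 0, is.numeric(K), K >= 2)
  r / (2 * log(K))
}
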