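# Exact and closed-form analytics for the two-species assembly process:
# distribution of the focal species' abundance across replicate communities
# (the abundance fluctuation distribution, AFD), boundary probabilities in
# Pochhammer closed form, co-occurrence, limit distributions, neutral moment
# recursion and analytic bimodality coefficients.

# Accept a pair of species_traits, a list of two, or a two-species
# assembly_model; return the four rates.
pair_rates <- function(traits) {
  if (inherits(traits, "assembly_model")) traits <- traits$species
  if (inherits(traits, "species_traits")) stop("two species are required", call. = FALSE)
  if (!is.list(traits) || length(traits) != 2L ||
      !all(vapply(traits, inherits, logical(1), "species_traits")))
    stop("`traits` must be a pair of species_traits (or a 2-species assembly_model)",
         call. = FALSE)
  list(rA = traits[[1]]$division_rate, cA = traits[[1]]$dispersal_rate,
       rB = traits[[2]]$division_rate, cB = traits[[2]]$dispersal_rate)
}

new_afd <- function(probabilities, community_size) {
  structure(list(community_size = as.integer(community_size),
                 probabilities = probabilities),
            class = "afd")
}

#' @export
print.afd <- function(x, ...) {
  cat(sprintf("<afd> abundance fluctuation distribution over 0..%d\n",
              x$community_size))
  utils::str(x$probabilities)
  invisible(x)
}

#' @export
plot.afd <- function(x, ...) {
  graphics::barplot(x$probabilities, names.arg = 0:x$community_size,
                    xlab = "abundance of focal species",
                    ylab = "probability", ...)
  invisible(x)
}

#' Probability that the next recruit belongs to the focal species
#'
#' During assembly every event increases community size by one (death-free
#' model). Given N_A focal-species individuals in a community of size N, the
#' recruit is of the focal species with probability
#' alpha = (r_A N_A + c_A) / (r_A N_A + c_A + r_B (N - N_A) + c_B).
#' The logistic saturation factor cancels, so alpha is independent of the
#' form of density dependence.
#'
#' @param N_A Focal-species abundance(s), 0 <= N_A <= N (vectorised).
#' @param N Community size(s).
#' @param traits Pair of [species_traits()] (focal species first), or a
#'   two-species [assembly_model()].
#'
#' @return Recruit probability in \[0, 1\], same length as `N_A`.
#' @examples
#' tr <- list(species_traits("A", 1, 1), species_traits("B", 1, 1))
#' recruit_prob(3, 8, tr)  # (3 + 1) / (8 + 2) = 0.4
#' @export
recruit_prob <- function(N_A, N, traits) {
  p <- pair_rates(traits)
  if (any(N_A < 0) || any(N_A > N))
    stop("`N_A` must satisfy 0 <= N_A <= N", call. = FALSE)
  num <- p$rA * N_A + p$cA
  den <- num + p$rB * (N - N_A) + p$cB
  if (any(den == 0))
    stop("all rates are zero: recruit probability undefined", call. = FALSE)
  num / den
}

#' Exact abundance fluctuation distribution by forward recursion
#'
#' Solves the master equation of the assembly process by dynamic
#' programming: starting from an empty community (probability 1 at
#' N_A = 0, N = 0), the distribution at size N + 1 is obtained from the
#' distribution at size N through the recruit probability alpha,
#' `P(N_A, N+1) = alpha(N_A - 1, N) P(N_A - 1, N) + (1 - alpha(N_A, N)) P(N_A, N)`.
#' Cost is O(N^2) time and O(N) memory; for community sizes above `cap` use
#' the closed forms ([prob_all_A()], [prob_all_B()]), the binomial limit
#' ([afd_binomial_limit()]) or the neutral moment recursion
#' ([neutral_moments()]), which are O(N) or O(1).
#'
#' @param N Final community size (>= 0).
#' @inheritParams recruit_prob
#' @param cap Guard on `N` (default 5000); raise explicitly for larger exact
#'   solves.
#'
#' @return An `afd` object: probabilities over N_A = 0..N, exactly
#'   normalised.
#' @examples
#' tr <- list(species_traits("A", 1, 1), species_traits("B", 1, 1))
#' afd_exact(2, tr)$probabilities  # uniform: 1/3, 1/3, 1/3
#' @export
afd_exact <- function(N, traits, cap = 5000L) {
  p <- pair_rates(traits)
  stopifnot(is.numeric(N), length(N) == 1L, N >= 0, N == round(N))
  if (N > cap)
    stop("N = ", N, " exceeds the exact-recursion cap (", cap, "); ",
         "use the closed forms / limit distributions, or raise `cap`",
         call. = FALSE)
  prob <- 1  # P(0, 0) = 1
  if (N > 0) {
    for (n in 0:(N - 1)) {
      NA_ <- 0:n
      num <- p$rA * NA_ + p$cA
      alpha <- num / (num + p$rB * (n - NA_) + p$cB)
      prob <- c((1 - alpha) * prob, 0) + c(0, alpha * prob)
    }
  }
  new_afd(prob / sum(prob), N)
}

# log of Pochhammer (rising factorial) (x)_n via log-gamma; stable at n = 1e5
log_poch <- function(x, n) {
  if (n == 0) return(0)
  lgamma(x + n) - lgamma(x)
}

#' Probability that assembly ends with a single species
#'
#' At the boundaries the master equation collapses to a one-term recurrence
#' with a Pochhammer closed form. The probability that a community of size N
#' contains no focal-species (A) individuals is
#' `P(0, N) = cB/(cA+cB) * (1 + cB/rB)_{N-1} / (1 + (cA+cB)/rB)_{N-1}`,
#' and symmetrically for all-A. Evaluated as differences of log-gamma values
#' so it is stable up to community sizes of 1e5 and beyond.
#'
#' @param N Community size (>= 1).
#' @inheritParams recruit_prob
#'
#' @return A probability.
#' @examples
#' tr <- list(species_traits("A", 1, 1), species_traits("B", 1, 1))
#' prob_all_B(1, tr)  # first recruit is B with probability 1/2
#' @export
prob_all_B <- function(N, traits) {
  p <- pair_rates(traits)
  stopifnot(N >= 1, N == round(N))
  if (p$cA + p$cB == 0)
    stop("cA + cB = 0: no assembly possible", call. = FALSE)
  if (p$cB == 0) return(0)
  exp(log(p$cB / (p$cA + p$cB)) +
        log_poch(1 + p$cB / p$rB, N - 1) -
        log_poch(1 + (p$cA + p$cB) / p$rB, N - 1))
}

#' @rdname prob_all_B
#' @export
prob_all_A <- function(N, traits) {
  p <- pair_rates(traits)
  stopifnot(N >= 1, N == round(N))
  if (p$cA + p$cB == 0)
    stop("cA + cB = 0: no assembly possible", call. = FALSE)
  if (p$cA == 0) return(0)
  exp(log(p$cA / (p$cA + p$cB)) +
        log_poch(1 + p$cA / p$rA, N - 1) -
        log_poch(1 + (p$cA + p$cB) / p$rA, N - 1))
}

#' Probability that both species co-occur at carrying capacity
#'
#' P_cooc = 1 - P(0, K) - P(K, K): the chance that an assembled community
#' contains both species, the model's first indicator of within-community
#' diversity. Increases from 0 (division-dominated assembly, monodominant
#' communities) to ~1 (dispersal-dominated assembly) as the dispersal rate
#' grows, passing 1/2 near the limiting dispersal rate [c_lim()].
#'
#' @param K Carrying capacity (>= 1).
#' @inheritParams recruit_prob
#'
#' @return A probability, clipped into \[0, 1\] against floating-point
#'   residue.
#' @examples
#' tr <- list(species_traits("A", 1, 1), species_traits("B", 1, 1))
#' prob_cooccurrence(1000, tr)
#' @export
prob_cooccurrence <- function(K, traits) {
  min(1, max(0, 1 - prob_all_B(K, traits) - prob_all_A(K, traits)))
}

#' Binomial abundance fluctuation distribution (very high dispersal)
#'
#' When dispersal is much faster than division the community fills with
#' dispersers before any division occurs, and the focal-species abundance is
#' Binomial(N, cA / (cA + cB)).
#'
#' @param N Community size.
#' @param c_A,c_B Dispersal rates, with c_A + c_B > 0.
#'
#' @return An `afd` object.
#' @examples
#' afd_binomial_limit(2, 1, 1)$probabilities  # 1/4, 1/2, 1/4
#' @export
afd_binomial_limit <- function(N, c_A, c_B) {
  stopifnot(N >= 0, N == round(N), c_A >= 0, c_B >= 0)
  if (c_A + c_B <= 0) stop("c_A + c_B must be positive", call. = FALSE)
  pr <- stats::dbinom(0:N, N, c_A / (c_A + c_B))
  new_afd(pr / sum(pr), N)
}

#' Uniform abundance fluctuation distribution (intermediate dispersal)
#'
#' When all four rates coincide (c_A = c_B = r_A = r_B) the recruit
#' probability becomes (N_A + 1)/(N + 2) and the master equation is solved
#' by the flat distribution: every composition N_A = 0..N has probability
#' 1/(N + 1).
#'
#' @param N Community size.
#' @return An `afd` object with N + 1 equal entries.
#' @examples
#' afd_uniform_solution(5)$probabilities
#' @export
afd_uniform_solution <- function(N) {
  stopifnot(N >= 0, N == round(N))
  new_afd(rep(1 / (N + 1), N + 1), N)
}

#' First four moments of the neutral abundance fluctuation distribution
#'
#' In the neutral case (equal division rates r_A = r_B = r) the recruit
#' probability is linear in N_A, which closes the moment hierarchy: the
#' raw moments of order 1..4 obey an O(N) recursion in community size,
#' `m_n(N+1) = m_n(N) + E[alpha ((N_A+1)^n - N_A^n)]`, with the expectation
#' expanded exactly over lower-order moments. The mean is exactly
#' N cA / (cA + cB) in every regime.
#'
#' @param N Community size (>= 1).
#' @param r Shared division rate (> 0).
#' @param c_A,c_B Dispersal rates (c_A + c_B > 0).
#'
#' @return An object of class `moment_summary`: list with `mean`,
#'   `variance`, `skewness`, `kurtosis` (non-excess) and `raw_moments`
#'   (orders 1..4).
#' @examples
#' neutral_moments(100, r = 1, c_A = 1, c_B = 1)
#' @export
neutral_moments <- function(N, r, c_A, c_B) {
  stopifnot(N >= 1, N == round(N), r > 0, c_A >= 0, c_B >= 0)
  if (c_A + c_B <= 0) stop("c_A + c_B must be positive", call. = FALSE)
  # m[k+1] holds the raw moment of order k, m[1] = m_0 = 1
  m <- c(1, 0, 0, 0, 0)
  ctot <- c_A + c_B
  for (n in 0:(N - 1)) {
    den <- r * n + ctot
    new_m <- m
    for (ord in 1:4) {
      k <- 0:(ord - 1)
      # E[alpha ((NA+1)^ord - NA^ord)]
      #   = sum_k C(ord,k) (r m_{k+1} + c_A m_k) / (r n + c_A + c_B)
      inc <- sum(choose(ord, k) * (r * m[k + 2] + c_A * m[k + 1])) / den
      new_m[ord + 1] <- m[ord + 1] + inc
    }
    m <- new_m
  }
  raw <- m[2:5]
  moment_summary_from_raw(raw)
}

# central moments, skewness, non-excess kurtosis from raw moments 1..4
moment_summary_from_raw <- function(raw) {
  m1 <- raw[1]; m2 <- raw[2]; m3 <- raw[3]; m4 <- raw[4]
  v <- m2 - m1^2
  mu3 <- m3 - 3 * m1 * m2 + 2 * m1^3
  mu4 <- m4 - 4 * m1 * m3 + 6 * m1^2 * m2 - 3 * m1^4
  structure(
    list(mean = m1, variance = v,
         skewness = if (v > 0) mu3 / v^1.5 else NA_real_,
         kurtosis = if (v > 0) mu4 / v^2 else NA_real_,
         raw_moments = raw),
    class = "moment_summary"
  )
}

#' @export
print.moment_summary <- function(x, ...) {
  cat(sprintf("<moment_summary> mean = %g, var = %g, skewness = %g, kurtosis = %g\n",
              x$mean, x$variance, x$skewness, x$kurtosis))
  invisible(x)
}

# moments of a discrete distribution on 0..N given its probability vector
afd_moments <- function(x) {
  stopifnot(inherits(x, "afd"))
  support <- 0:x$community_size
  raw <- vapply(1:4, function(n) sum(support^n * x$probabilities), numeric(1))
  moment_summary_from_raw(raw)
}

#' Sarle's bimodality coefficient of the neutral symmetric distribution
#'
#' The bimodality coefficient BC = (skewness^2 + 1) / kurtosis (non-excess
#' kurtosis) summarises the shape of the abundance fluctuation distribution:
#' BC = 1 for a two-point (Bernoulli) distribution, 5/9 for a uniform and
#' 1/3 in the large binomial limit, so BC > 5/9 flags a bimodal AFD
#' (division-dominated assembly) and BC < 5/9 a unimodal one
#' (dispersal-dominated). For equal dispersal rates c_A = c_B = c the
#' neutral model gives the closed form
#' `BC = N (2c + 3r)(2c + rN) / ((2c + r)(3 r N^2 + 2c(3N - 2)))`,
#' which tends to `(2c + 3r) / (3 (2c + r))` for large N.
#'
#' @param N Community size (>= 2, so that kurtosis is defined). `Inf` gives
#'   the large-N limit.
#' @param r Shared division rate (> 0).
#' @param c Shared dispersal rate (> 0).
#'
#' @return The bimodality coefficient, in \[1/3, 1\].
#' @examples
#' bc_symmetric(Inf, r = 1, c = 1)  # 5/9: uniform AFD
#' @export
bc_symmetric <- function(N, r, c) {
  stopifnot(r > 0, c > 0)
  if (is.infinite(N)) return((2 * c + 3 * r) / (3 * (2 * c + r)))
  if (N < 2) stop("N must be >= 2 for the kurtosis to be defined", call. = FALSE)
  N * (2 * c + 3 * r) * (2 * c + r * N) /
    ((2 * c + r) * (3 * r * N^2 + 2 * c * (3 * N - 2)))
}

#' Large-N bimodality coefficient of the neutral model, unequal dispersal
#'
#' Closed form for the N >> 1 bimodality coefficient when the two species
#' share the division rate r but disperse at different rates c_A and c_B.
#' Reduces to the symmetric large-N limit when c_A = c_B, to 1 as r
#' dominates, and to 1/3 as dispersal dominates.
#'
#' @param r Shared division rate (> 0).
#' @param c_A,c_B Dispersal rates (c_A + c_B > 0).
#'
#' @return The bimodality coefficient.
#' @examples
#' bc_asymmetric(r = 1, c_A = 1, c_B = 1)  # 5/9
#' @export
bc_asymmetric <- function(r, c_A, c_B) {
  stopifnot(r > 0, c_A >= 0, c_B >= 0)
  if (c_A + c_B <= 0) stop("c_A + c_B must be positive", call. = FALSE)
  cs <- c_A + c_B
  q <- c_A^2 - c_A * c_B + c_B^2
  num <- (cs + 3 * r) *
    (4 * r * (c_A^3 + c_B^3) + 4 * r^2 * q + c_A * c_B * cs^2)
  den <- 3 * (cs + r) * (cs + 2 * r) * (2 * r * q + c_A * c_B * cs)
  num / den
}

#' Monodominance probabilities in the very low-dispersal limit (S species)
#'
#' When dispersal is far slower than division the first disperser populates
#' the whole community before a second establishes, so every community ends
#' monodominant and species i wins with probability c_i / sum(c).
#'
#' @param c Vector of dispersal rates, all >= 0 with a positive sum.
#'
#' @return Probability vector over species.
#' @examples
#' monodominance_probs(c(2, 1))  # 2/3, 1/3
#' @export
monodominance_probs <- function(c) {
  stopifnot(is.numeric(c), all(c >= 0))
  if (sum(c) <= 0) stop("at least one dispersal rate must be positive", call. = FALSE)
  c / sum(c)
}

#' Multinomial composition in the very high-dispersal limit (S species)
#'
#' When dispersal is far faster than division the K slots fill with
#' independent dispersers, so the composition is
#' Multinomial(K, p) with p_i = c_i / sum(c).
#'
#' @param c Vector of dispersal rates (>= 0, positive sum).
#' @param K Carrying capacity.
#'
#' @return A list with `size` (K), `prob` (p) and `mean` (K p).
#' @examples
#' multinomial_limit(c(1, 1, 2), 100)$mean
#' @export
multinomial_limit <- function(c, K) {
  stopifnot(K >= 1, K == round(K))
  p <- monodominance_probs(c)
  list(size = as.integer(K), prob = p, mean = K * p)
}
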