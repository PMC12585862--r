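# Empirical diagnostics on replicate-by-species abundance tables, simulated
# or user-supplied: moments and bimodality coefficient of the abundance
# fluctuation distribution, mean relative abundance, richness and
# co-occurrence, and between-community dissimilarity.

# coerce an ensemble_result or a replicate x species matrix/data.frame
as_abundance_matrix <- function(x) {
  if (inherits(x, "ensemble_result")) return(x$abundances)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("expected an ensemble_result or a numeric replicate-by-species matrix",
         call. = FALSE)
  x
}

#' Population moments of a sample of relative abundances
#'
#' Computes mean, variance, skewness and non-excess kurtosis with
#' population (divide-by-n) estimators, so that values are directly
#' comparable with the analytic moments of the abundance fluctuation
#' distribution ([neutral_moments()]).
#'
#' @param values Numeric vector with at least two distinct values (the
#'   standardised moments are undefined at zero variance).
#'
#' @return A `moment_summary` (see [neutral_moments()]).
#' @examples
#' empirical_moments(c(0, 0, 1, 1))  # skewness 0, kurtosis 1
#' @export
empirical_moments <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2)
  if (stats::var(values) == 0)
    stop("undefined moments: all values are equal (zero variance)", call. = FALSE)
  raw <- vapply(1:4, function(n) mean(values^n), numeric(1))
  moment_summary_from_raw(raw)
}

#' Bimodality coefficient of an empirical abundance fluctuation distribution
#'
#' Sarle's bimodality coefficient BC = (skewness^2 + 1) / kurtosis
#' (non-excess), computed by default from population moments so that it
#' converges to the analytic coefficients ([bc_symmetric()],
#' [bc_asymmetric()]). BC = 1 flags a two-point (Bernoulli-like) sample,
#' 5/9 a uniform one and 1/3 a large binomial one. The finite-sample
#' corrected variant (`bias_corrected = TRUE`) uses the g1/b2-based formula
#' `BC = (g1^2 + 1) / (b2 + 3 (n-1)^2 / ((n-2)(n-3)))` with sample skewness
#' g1 and sample excess kurtosis b2.
#'
#' @param values Numeric vector of abundances or relative abundances.
#' @param bias_corrected Apply the finite-sample Sarle correction
#'   (default `FALSE`).
#'
#' @return The bimodality coefficient.
#' @examples
#' bimodality_coefficient(c(rep(0, 50), rep(1, 50)))  # 1: Bernoulli-like
#' @export
bimodality_coefficient <- function(values, bias_corrected = FALSE) {
  mom <- empirical_moments(values)
  if (!bias_corrected) return((mom$skewness^2 + 1) / mom$kurtosis)
  n <- length(values)
  if (n < 4)
    stop("bias-corrected BC needs at least 4 observations", call. = FALSE)
  g1 <- mom$skewness * sqrt(n * (n - 1)) / (n - 2)
  b2 <- (n - 1) / ((n - 2) * (n - 3)) * ((n + 1) * (mom$kurtosis - 3) + 6)
  (g1^2 + 1) / (b2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Mean relative abundance per species across replicates
#'
#' Averages n_i / N over replicate communities. Replicates with zero total
#' abundance (possible extinctions under an explicit death rate) are
#' excluded with a warning that reports how many were dropped.
#'
#' @param ensemble An `ensemble_result` or replicate-by-species matrix.
#'
#' @return Named numeric vector summing to 1 across species.
#' @examples
#' mean_relative_abundance(rbind(c(90, 10), c(50, 50)))
#' @export
mean_relative_abundance <- function(ensemble) {
  ab <- as_abundance_matrix(ensemble)
  tot <- rowSums(ab)
  drop <- tot == 0
  if (any(drop)) {
    warning(sum(drop), " replicate(s) with zero total abundance excluded",
            call. = FALSE)
    ab <- ab[!drop, , drop = FALSE]
    tot <- tot[!drop]
  }
  if (nrow(ab) == 0) stop("no replicates with positive abundance", call. = FALSE)
  colMeans(ab / tot)
}

#' Species richness of one community
#'
#' Number of species present (count >= 1).
#'
#' @param counts Abundance vector of one replicate.
#' @return Integer richness.
#' @examples
#' richness(c(10, 0, 3))
#' @export
richness <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  sum(counts >= 1)
}

#' Fraction of replicate communities where species co-occur
#'
#' Share of replicates with richness >= 2; in the two-species case this is
#' the empirical estimate of the co-occurrence probability
#' [prob_cooccurrence()].
#'
#' @inheritParams mean_relative_abundance
#' @return A fraction in \[0, 1\].
#' @export
cooccurrence_fraction <- function(ensemble) {
  ab <- as_abundance_matrix(ensemble)
  mean(apply(ab, 1, richness) >= 2)
}

#' Mean pairwise between-community dissimilarity
#'
#' Bray-Curtis dissimilarity between the relative-abundance profiles of all
#' replicate pairs (via [vegan::vegdist()]), averaged. For ensembles larger
#' than `max_exact` replicates the O(n^2) pair set is replaced by a uniform
#' random subsample of `n_pairs` pairs.
#'
#' @inheritParams mean_relative_abundance
#' @param max_exact Largest ensemble for which all pairs are used
#'   (default 2000).
#' @param n_pairs Number of sampled pairs above `max_exact` (default 1e5).
#'
#' @return Mean pairwise Bray-Curtis dissimilarity in \[0, 1\].
#' @examples
#' dissimilarity(rbind(c(100, 0), c(0, 100)))  # disjoint: 1
#' @export
dissimilarity <- function(ensemble, max_exact = 2000L, n_pairs = 1e5L) {
  ab <- as_abundance_matrix(ensemble)
  if (nrow(ab) < 2) stop("at least 2 replicates are required", call. = FALSE)
  tot <- rowSums(ab)
  keep <- tot > 0
  ab <- ab[keep, , drop = FALSE]
  rel <- ab / rowSums(ab)
  n <- nrow(rel)
  if (n <= max_exact) return(mean(vegan::vegdist(rel, method = "bray")))
  i <- sample.int(n, n_pairs, replace = TRUE)
  j <- sample.int(n - 1L, n_pairs, replace = TRUE)
  j <- ifelse(j >= i, j + 1L, j)  # uniform over ordered distinct pairs
  # Bray-Curtis on relative abundances: 1 - sum(pmin) row-wise
  mean(1 - rowSums(pmin(rel[i, , drop = FALSE], rel[j, , drop = FALSE])))
}

#' Histogram of a focal species' relative abundance across replicates
#'
#' Bins the relative abundance of one species over \[0, 1\] with half-open
#' bins (last bin closed), the standard visualisation of the abundance
#' fluctuation distribution across replicate communities.
#'
#' @inheritParams mean_relative_abundance
#' @param species Column index or name of the focal species (default 1).
#' @param n_bins Number of bins (>= 2, default 20).
#'
#' @return A data frame with columns `lower`, `upper`, `count`; counts sum
#'   to the number of replicates.
#' @export
afd_histogram <- function(ensemble, species = 1L, n_bins = 20L) {
  stopifnot(n_bins >= 2, n_bins == round(n_bins))
  ab <- as_abundance_matrix(ensemble)
  tot <- rowSums(ab)
  if (any(tot == 0)) stop("replicates with zero total abundance", call. = FALSE)
  rel <- ab[, species] / tot
  breaks <- seq(0, 1, length.out = n_bins + 1)
  idx <- pmin(findInterval(rel, breaks, rightmost.closed = TRUE), n_bins)
  data.frame(lower = breaks[-length(breaks)],
             upper = breaks[-1],
             count = tabulate(idx, nbins = n_bins))
}

#' Regime diagnostics of a replicate ensemble
#'
#' Bundles the metrics that characterise the assembly regime of an ensemble
#' of replicate communities: bimodality coefficient of the focal species'
#' relative abundance, per-species mean relative abundance, the fractions
#' of replicates monodominant for each species, the co-occurrence fraction
#' and the mean pairwise Bray-Curtis dissimilarity. BC above 5/9 indicates
#' a bimodal abundance fluctuation distribution (low-dispersal,
#' division-driven assembly), near 5/9 a uniform one (intermediate), and
#' below 5/9 a unimodal one (high-dispersal).
#'
#' @inheritParams mean_relative_abundance
#' @param focal_species Column used for the bimodality coefficient
#'   (default 1).
#' @param bc_band Half-width of the BC band around 5/9 used by the regime
#'   label (default 0.05).
#'
#' @return An object of class `regime_metrics`: list with
#'   `bimodality_coefficient`, `mean_relative_abundance`, `p_only` (named
#'   per-species monodominance fractions; for two species these are the
#'   empirical P_K and P_0), `cooccurrence_fraction`,
#'   `mean_pairwise_dissimilarity`, `regime`
#'   (`"low-dispersal"` / `"intermediate"` / `"high-dispersal"`),
#'   `n_replicates` and `n_excluded` (zero-total replicates dropped).
#' @examples
#' m <- two_species_pool(1, 1, 1, 1, K = 200)
#' regime_metrics(assemble_ensemble(m, 200, master_seed = 7))
#' @export
regime_metrics <- function(ensemble, focal_species = 1L, bc_band = 0.05) {
  ab <- as_abundance_matrix(ensemble)
  tot <- rowSums(ab)
  n_excluded <- sum(tot == 0)
  ab <- ab[tot > 0, , drop = FALSE]
  if (nrow(ab) < 2) stop("at least 2 surviving replicates are required", call. = FALSE)
  rel <- ab / rowSums(ab)
  bc <- bimodality_coefficient(rel[, focal_species])
  rich <- apply(ab, 1, richness)
  p_only <- vapply(seq_len(ncol(ab)),
                   function(i) mean(rich == 1 & ab[, i] > 0), numeric(1))
  names(p_only) <- colnames(ab)
  regime <- if (bc > 5 / 9 + bc_band) "low-dispersal"
            else if (bc < 5 / 9 - bc_band) "high-dispersal"
            else "intermediate"
  structure(
    list(bimodality_coefficient = bc,
         mean_relative_abundance = colMeans(rel),
         p_only = p_only,
         cooccurrence_fraction = mean(rich >= 2),
         mean_pairwise_dissimilarity = dissimilarity(ab),
         regime = regime,
         n_replicates = nrow(ab),
         n_excluded = n_excluded),
    class = "regime_metrics"
  )
}

#' @export
print.regime_metrics <- function(x, ...) {
  cat(sprintf("<regime_metrics> %d replicates (%d excluded)\n",
              x$n_replicates, x$n_excluded))
  cat(sprintf("  BC = %.4f  ->  %s regime (5/9 = uniform threshold)\n",
              x$bimodality_coefficient, x$regime))
  cat("  mean relative abundance:",
      paste(names(x$mean_relative_abundance),
            sprintf("%.3f", x$mean_relative_abundance),
            sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  co-occurrence fraction = %.3f, mean Bray-Curtis = %.3f\n",
              x$cooccurrence_fraction, x$mean_pairwise_dissimilarity))
  invisible(x)
}

#' Estimate the dispersal-rate ratio from a high-dispersal ensemble
#'
#' In the neutral model the mean relative abundance of the focal species is
#' m = c_A / (c_A + c_B) in both the very low- and very high-dispersal
#' regimes, so the dispersal ratio can be inferred as
#' `rho_hat = m / (1 - m)`. This is the estimator behind reading trait
#' asymmetries off replicate community data.
#'
#' @inheritParams mean_relative_abundance
#' @param focal_species Column of the focal species (default 1).
#'
#' @return Point estimate of c_focal / c_other (two-species ensembles).
#' @export
dispersal_ratio_estimate <- function(ensemble, focal_species = 1L) {
  ab <- as_abundance_matrix(ensemble)
  if (ncol(ab) != 2)
    stop("dispersal ratio estimation is defined for two-species ensembles",
         call. = FALSE)
  m <- mean_relative_abundance(ab)[focal_species]
  unname(m / (1 - m))
}

#' Read a replicate-by-species abundance table
#'
#' Reads a delimited text file with a header row of species labels and one
#' replicate community per row.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#'
#' @return Integer-valued replicate-by-species matrix with species labels
#'   as column names.
#' @export
read_abundance_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m) || any(m < 0))
    stop("abundance table must be numeric and non-negative", call. = FALSE)
  m
}

#' Write a replicate-by-species abundance table
#'
#' @param ensemble An `ensemble_result` or abundance matrix.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(ensemble, path, sep = "\t") {
  ab <- as_abundance_matrix(ensemble)
  utils::write.table(ab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
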