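#' Mutation frequency from colony counts
#'
#' Frequency = resistant colonies / (total colonies x dilution factor),
#' i.e. drug-resistant mutants per viable cell, where `total` is the colony
#' count on the non-selective plate and `dilution` is the factor by which the
#' culture was diluted before non-selective plating.
#'
#' @param resistant Resistant colony count (>= 0).
#' @param total Non-selective colony count (> 0).
#' @param dilution Dilution factor applied to the non-selective plating
#'   (default 1).
#' @return Mutant frequency (mutants per cell).
#' @examples
#' mutation_frequency(5, 50, dilution = 100)  # 1e-3
#' @export
mutation_frequency <- function(resistant, total, dilution = 1) {
  if (any(total <= 0)) stop_mutspectra("total colony count must be > 0")
  if (any(resistant < 0)) stop_mutspectra("resistant count must be >= 0")
  resistant / (total * dilution)
}

#' Fold elevation of a mutation frequency over a control
#'
#' @param freq Treated-condition frequency.
#' @param control_freq Control frequency (> 0).
#' @param report If `TRUE`, round half-up to an integer (the convention used
#'   for reported fold elevations).
#' @return Fold elevation (ratio, or rounded integer when `report = TRUE`).
#' @examples
#' fold_elevation(35e-7, 2e-7)                 # 17.5
#' fold_elevation(35e-7, 2e-7, report = TRUE)  # 18
#' @export
fold_elevation <- function(freq, control_freq, report = FALSE) {
  if (any(control_freq <= 0))
    stop_mutspectra("control frequency must be > 0")
  r <- freq / control_freq
  if (report) round_half_up(r) else r
}

#' Per-site base-substitution rate across strains
#'
#' Per-strain rate r_i = n_i / (s_i x generations), where n_i is the number
#' of accepted SNVs and s_i the number of callable sites (sites meeting the
#' depth criterion) in strain i.  The estimate is the mean of the per-strain
#' rates, with SE = sd(r_i)/sqrt(n).  Use `generations = 1` for a
#' per-site-per-treatment rate (one-shot mutagen exposure) and the number of
#' cell divisions for a per-site-per-division rate (continuously mutating
#' strains, e.g. 30 generations of growth).
#'
#' @param snv_counts Integer vector of accepted SNV counts per strain.
#' @param callable_sites Numeric vector of callable site counts per strain.
#' @param generations Cell divisions over which the mutations accumulated
#'   (default 1).
#' @return An object of class `rate_estimate`.
#' @export
per_site_rate <- function(snv_counts, callable_sites, generations = 1) {
  if (length(snv_counts) != length(callable_sites))
    stop_mutspectra("snv_counts and callable_sites must have equal length")
  if (any(callable_sites <= 0)) stop_mutspectra("callable_sites must be > 0")
  r <- snv_counts / (callable_sites * generations)
  n <- length(r)
  structure(list(per_strain_rates = r, rate = mean(r),
                 se = if (n > 1) stats::sd(r) / sqrt(n) else NA_real_,
                 n_strains = n, generations = generations),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Per-site rate: %.3g (SE %.3g) per site%s; %d strain(s)\n",
              x$rate, x$se,
              if (x$generations != 1) " per cell division" else "",
              x$n_strains))
  invisible(x)
}

#' Luria-Delbruck mutant-count probabilities (Ma-Sandri-Sarkar recursion)
#'
#' Probability of observing k mutant colonies in a culture with expected
#' mutation count m, for k = 0..kmax, computed with the recursion
#' p0 = exp(-m), p_k = (m/k) * sum_{i=0}^{k-1} p_i / (k - i + 1).
#'
#' @param m Expected mutations per culture (>= 0).
#' @param kmax Largest count to evaluate.
#' @return Numeric vector of length `kmax + 1` (probabilities of 0..kmax).
#' @export
luria_delbruck_pmf <- function(m, kmax) {
  stopifnot(m >= 0, kmax >= 0)
  p <- numeric(kmax + 1)
  p[1] <- exp(-m)
  for (k in seq_len(kmax)) {
    i <- 0:(k - 1)
    p[k + 1] <- (m / k) * sum(p[i + 1] / (k - i + 1))
  }
  p
}

ld_loglik <- function(m, counts, max_k = 1000L) {
  if (m <= 0) return(if (all(counts == 0)) 0 else -Inf)
  kcap <- min(max(counts), max_k)
  p <- luria_delbruck_pmf(m, kcap)
  tail_p <- max(1 - sum(p), 1e-300)
  obs <- pmin(counts, kcap + 1L)
  ll <- sum(ifelse(obs <= kcap, log(pmax(p[obs + 1L], 1e-300)),
                   log(tail_p)))
  ll
}

#' Luria-Delbruck fluctuation analysis
#'
#' Estimates the expected number of mutations per culture (m) from the
#' distribution of mutant colony counts over parallel cultures, and the
#' mutation rate per cell division as mu = m / N_final.
#'
#' Methods:
#' \describe{
#'   \item{`"mss_mle"`}{Maximum likelihood under the Luria-Delbruck
#'     distribution computed by the Ma-Sandri-Sarkar recursion (default;
#'     recommended for the usual 5-100 culture experiments).  The 95\%
#'     confidence interval is a profile-likelihood interval.  Counts larger
#'     than `max_k` are lumped into the distribution's upper tail.}
#'   \item{`"p0"`}{The zero-fraction method, m = -ln(fraction of cultures
#'     with zero mutants); requires at least one zero-mutant culture.  The
#'     confidence interval is the transformed exact binomial interval for
#'     the zero fraction.}
#' }
#'
#' @param mutant_counts Integer vector of mutant colony counts, one per
#'   culture (>= 2 cultures).
#' @param final_population Final cells per culture (> 0).
#' @param method `"mss_mle"` or `"p0"`.
#' @param conf_level Confidence level for the interval on m (default 0.95).
#' @param max_k Truncation point for the MSS recursion (default 1000).
#' @return An object of class `fluctuation_result` with elements `m`, `mu`,
#'   `method`, `conf_int` (on m), `n_cultures`, `final_population`,
#'   `loglik`.
#' @examples
#' fluctuation_rate(c(0, 0, 1, 3, 0), final_population = 2e6, method = "p0")
#' @export
fluctuation_rate <- function(mutant_counts, final_population,
                             method = c("mss_mle", "p0"),
                             conf_level = 0.95, max_k = 1000L) {
  method <- match.arg(method)
  counts <- as.integer(mutant_counts)
  if (length(counts) < 2L)
    stop_mutspectra("fluctuation analysis needs at least 2 cultures")
  if (any(counts < 0)) stop_mutspectra("mutant counts must be >= 0")
  if (final_population <= 0)
    stop_mutspectra("final_population must be > 0")
  n <- length(counts)
  ci <- c(NA_real_, NA_real_)
  ll <- NA_real_
  if (method == "p0") {
    nz <- sum(counts == 0L)
    if (nz == 0L)
      stop_mutspectra(
        "p0 method requires at least one zero-mutant culture; use method = 'mss_mle'")
    p0 <- nz / n
    m <- -log(p0)
    bt <- stats::binom.test(nz, n, conf.level = conf_level)
    ci <- sort(-log(bt$conf.int))
  } else {
    if (all(counts == 0L)) {
      warning("all cultures have zero mutants; m = 0 (degenerate data)",
              call. = FALSE)
      m <- 0
      ci <- c(0, -log(stats::binom.test(n, n,
                                        conf.level = conf_level)$conf.int[1]))
    } else {
      upper <- max(counts) + 5
      ## the log-likelihood is flat and very low for m far above the truth
      ## (heavy-tailed jackpot counts inflate `upper` enormously), so bracket
      ## the optimum on a log-spaced grid before the scalar search
      grid <- exp(seq(log(1e-4), log(upper), length.out = 80))
      ll_grid <- vapply(grid, ld_loglik, numeric(1), counts = counts,
                        max_k = max_k)
      j <- which.max(ll_grid)
      bracket <- c(grid[max(j - 1L, 1L)], grid[min(j + 1L, length(grid))])
      opt <- stats::optimize(ld_loglik, interval = bracket, counts = counts,
                             max_k = max_k, maximum = TRUE, tol = 1e-6)
      m <- opt$maximum
      ll <- opt$objective
      drop <- stats::qchisq(conf_level, df = 1) / 2
      target <- ll - drop
      f <- function(x) ld_loglik(x, counts, max_k) - target
      lo <- tryCatch({
        if (f(1e-8) < 0) stats::uniroot(f, c(1e-8, m), tol = 1e-8)$root
        else 0
      }, error = function(e) 0)
      hi_bound <- upper
      while (f(hi_bound) > 0 && hi_bound < 1e6) hi_bound <- hi_bound * 2
      hi <- tryCatch(stats::uniroot(f, c(m, hi_bound), tol = 1e-8)$root,
                     error = function(e) NA_real_)
      ci <- c(lo, hi)
    }
  }
  structure(list(m = m, mu = m / final_population, method = method,
                 conf_int = ci, conf_level = conf_level,
                 n_cultures = n, final_population = final_population,
                 loglik = ll),
            class = "fluctuation_result")
}

#' @export
print.fluctuation_result <- function(x, ...) {
  cat(sprintf("Fluctuation analysis (%s), %d cultures\n", x$method,
              x$n_cultures))
  cat(sprintf("  m  = %.4g mutations/culture (%g%% CI %.4g - %.4g)\n",
              x$m, 100 * x$conf_level, x$conf_int[1], x$conf_int[2]))
  cat(sprintf("  mu = %.4g per cell division (N_final = %.3g)\n",
              x$mu, x$final_population))
  invisible(x)
}

#' Simulate Luria-Delbruck mutant counts
#'
#' Independent forward simulation of the fluctuation experiment under
#' deterministic binary growth: the number of mutational events per culture
#' is Poisson(m); an event striking when the culture has k cells (k uniform
#' over the divisions) founds a mutant clone of final size N/k, so clone
#' sizes are drawn as `floor(1/U)` capped at `final_population`.  This
#' reproduces the classic heavy-tailed ("jackpot") mutant-count
#' distribution without using the MSS recursion, so it can serve as an
#' independent check of the likelihood machinery.
#'
#' @param n_cultures Number of cultures.
#' @param m Expected mutations per culture.
#' @param final_population Final cells per culture (caps clone size).
#' @param seed Integer seed.
#' @return Integer vector of mutant counts.
#' @export
rluria <- function(n_cultures, m, final_population = 1e8, seed = 1L) {
  with_seed(seed, {
    vapply(seq_len(n_cultures), function(i) {
      k <- stats::rpois(1, m)
      if (k == 0L) return(0L)
      sizes <- pmin(floor(1 / stats::runif(k)), final_population)
      as.integer(sum(sizes))
    }, integer(1))
  })
}
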