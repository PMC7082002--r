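## Mother-to-offspring transmission through a single-generation binomial
## germline bottleneck, and a moment estimator of its effective size.

#' Draw offspring heteroplasmy fractions through a bottleneck
#'
#' Each offspring fraction is `Binomial(N, p) / N`: N segregating units
#' sampled from the maternal pool at fraction p.
#'
#' @param p maternal minor-variant fraction in \[0,1\].
#' @param N positive integer bottleneck size.
#' @param n number of offspring.
#' @param seed integer seed.
#' @return numeric vector of n fractions in \[0,1\].
#' @export
sample_offspring_fractions <- function(p, N, n, seed = 1L) {
  if (p < 0 || p > 1) stop("p must be in [0,1]")
  if (N < 1) stop("bottleneck size N must be a positive integer")
  if (n < 1) stop("n must be >= 1")
  with_stream(seed, rbinom(n, as.integer(N), p) / as.integer(N))
}

#' Moment estimator of the effective bottleneck size
#'
#' Under the binomial model Var(f) = p(1-p)/N, so
#' `N_hat = mean(f) * (1 - mean(f)) / (var(f) - measurement_sd^2)`.
#' Measurement noise is handled by variance subtraction; when the
#' corrected variance is not positive the bottleneck is reported
#' unresolved (no drift observed at this sample size).  A bootstrap over
#' offspring gives the standard error and a percentile interval.
#'
#' @param offspring numeric vector of offspring fractions (>= 3).
#' @param measurement_sd sd of the fraction measurement (default 0; can
#'   be estimated from replicate calls).
#' @param n_boot bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @return list of class `bottleneck_estimate`: `N_hat`, `se`, `ci`
#'   (2.5/97.5 percentiles), `resolved`, `p_bar`, `n`.
#' @export
estimate_bottleneck_N <- function(offspring, measurement_sd = 0,
                                  n_boot = 200L, seed = 1L) {
  offspring <- as.numeric(offspring)
  if (length(offspring) < 3L) stop("need >= 3 offspring fractions")
  if (any(offspring < 0 | offspring > 1)) stop("fractions must be in [0,1]")
  p_bar <- mean(offspring)
  if (p_bar <= 0 || p_bar >= 1)
    stop("degenerate input: mean offspring fraction is 0 or 1")
  point <- function(f) {
    v <- var(f) - measurement_sd^2
    if (!is.finite(v) || v <= 0) return(Inf)
    m <- mean(f)
    if (m <= 0 || m >= 1) return(NA_real_)
    m * (1 - m) / v
  }
  N_hat <- point(offspring)
  if (!is.finite(N_hat)) {
    return(structure(list(N_hat = Inf, se = NA_real_, ci = c(NA, NA),
                          resolved = FALSE, p_bar = p_bar,
                          n = length(offspring)),
                     class = "bottleneck_estimate"))
  }
  boots <- with_stream(seed, vapply(seq_len(n_boot), function(i)
    point(sample(offspring, replace = TRUE)), numeric(1)))
  finite <- boots[is.finite(boots)]
  structure(list(N_hat = N_hat,
                 se = if (length(finite) > 1) stats::sd(finite) else NA_real_,
                 ci = if (length(finite) > 1)
                   unname(quantile(finite, c(0.025, 0.975))) else c(NA, NA),
                 resolved = TRUE, p_bar = p_bar, n = length(offspring)),
            class = "bottleneck_estimate")
}

#' @export
print.bottleneck_estimate <- function(x, ...) {
  if (!x$resolved)
    cat(sprintf("bottleneck unresolved (no excess variance; n = %d)\n", x$n))
  else
    cat(sprintf("N_hat = %.1f (se %.1f, 95%% CI [%.1f, %.1f]), mean fraction %.3f, n = %d\n",
                x$N_hat, x$se, x$ci[1], x$ci[2], x$p_bar, x$n))
  invisible(x)
}

#' Estimate bottleneck size from a mother/egg fraction CSV
#'
#' Input columns: `mother_id`, `mother_fraction`, `egg_id`, `egg_fraction`.
#' One estimate per mother with >= 3 eggs.
#'
#' @param path CSV path.
#' @param measurement_sd,n_boot,seed passed to [estimate_bottleneck_N()].
#' @return named list of `bottleneck_estimate` per mother.
#' @export
estimate_bottleneck_from_csv <- function(path, measurement_sd = 0,
                                         n_boot = 200L, seed = 1L) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("mother_id", "mother_fraction", "egg_id", "egg_fraction")
  if (!all(need %in% names(df)))
    stop("bottleneck CSV must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (mom in unique(df$mother_id)) {
    f <- df$egg_fraction[df$mother_id == mom]
    if (length(f) < 3L) next
    out[[mom]] <- estimate_bottleneck_N(f, measurement_sd, n_boot,
                                        substream_seed(seed, match(mom, unique(df$mother_id))))
  }
  out
}
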