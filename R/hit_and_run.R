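#' Settings for the hit-and-run sampler
#'
#' The defaults follow the benchmark's generation procedure: a chain of
#' `1000 * n^3` iterations thinned every `n^3` iterations, where `n` is the
#' number of constrained populations.
#'
#' @param N chain length (`NULL` = `1000 * n^3`).
#' @param thin thinning interval (`NULL` = `n^3`).
#' @param seed optional integer seed.
#' @return A list of class `sampler_settings`.
#' @export
sampler_settings <- function(N = NULL, thin = NULL, seed = NULL) {
  if (!is.null(N) && !is.null(thin)) stopifnot(N >= thin, thin >= 1)
  structure(list(N = N, thin = thin, seed = seed), class = "sampler_settings")
}

.resolve_settings <- function(settings, n) {
  thin <- if (is.null(settings$thin)) n^3 else settings$thin
  N <- if (is.null(settings$N)) 1000 * n^3 else settings$N
  stopifnot(N >= thin, thin >= 1)
  list(N = N, thin = thin, seed = settings$seed)
}

# absolute per-population bounds from either a flattened hierarchical model
# or a proportion_constraint
.absolute_bounds <- function(model, populations) {
  if (inherits(model, "constraint_model")) {
    b <- flatten_model(model, populations)
    list(lower = b$min, upper = b$max, populations = b$population)
  } else if (inherits(model, "proportion_constraint")) {
    n <- length(populations)
    list(lower = rep_len(model$min_c, n), upper = rep_len(model$max_c, n),
         populations = populations)
  } else if (is.data.frame(model) && all(c("population", "min", "max") %in% names(model))) {
    b <- model[match(populations, model$population), ]
    if (anyNA(b$population)) stop("populations missing from bounds table")
    list(lower = b$min, upper = b$max, populations = populations)
  } else {
    stop("model must be a constraint_model, proportion_constraint or bounds table")
  }
}

#' Sample proportion vectors uniformly from a constraint polytope
#'
#' Hit-and-run Markov chain Monte Carlo over the polytope
#' `{x >= 0, sum(x) = p, min_c <= x_c <= max_c}`, with the per-population
#' bounds taken from a flattened hierarchical constraint model (or a
#' [proportion_constraint()]). The chain starts at an interior seed point
#' (the convex combination of the lower- and upper-bound vertices that meets
#' the sum constraint) and is asymptotically uniform on the polytope.
#'
#' @param model a `constraint_model`, [proportion_constraint()] or a
#'   data.frame with columns `population`, `min`, `max` (absolute bounds).
#' @param populations character vector of populations to sample (defines the
#'   dimension `n` and column order).
#' @param p total proportion the populations must sum to.
#' @param n_samples number of (thinned) samples to return; defaults to the
#'   full chain yield `N / thin`.
#' @param settings a [sampler_settings()].
#' @return `n_samples` x `n` matrix of proportions; attribute `run_log`
#'   records `n`, `N` and `thin`.
#' @export
hit_and_run_sample <- function(model, populations, p = 1, n_samples = NULL,
                               settings = sampler_settings()) {
  n <- length(populations)
  stopifnot(n >= 1, p > 0, p <= 1)
  cfg <- .resolve_settings(settings, n)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  b <- .absolute_bounds(model, populations)
  lower <- pmax(b$lower, 0)
  upper <- pmin(b$upper, p)
  if (any(lower > upper + 1e-12)) {
    bad <- b$populations[lower > upper + 1e-12]
    stop("empty polytope: min > max for ", paste(bad, collapse = ", "))
  }
  if (sum(lower) > p + 1e-9 || sum(upper) < p - 1e-9) {
    stop("empty polytope: sum of bounds incompatible with total proportion ",
         p, " (sum min = ", signif(sum(lower), 4),
         ", sum max = ", signif(sum(upper), 4), ")")
  }
  if (is.null(n_samples)) n_samples <- cfg$N %/% cfg$thin
  stopifnot(n_samples >= 1)

  span <- sum(upper) - sum(lower)
  if (span < 1e-12) {  # point polytope
    out <- matrix(rep(lower, each = n_samples), nrow = n_samples)
    colnames(out) <- b$populations
    return(out)
  }
  # populations pinned by min == max contribute nothing to the chain; sample
  # the free coordinates and reassemble
  fixed <- (upper - lower) < 1e-12
  if (any(fixed)) {
    free_pops <- b$populations[!fixed]
    sub <- data.frame(population = free_pops,
                      min = lower[!fixed], max = upper[!fixed])
    inner <- hit_and_run_sample(sub, free_pops, p = p - sum(lower[fixed]),
                                n_samples = n_samples,
                                settings = sampler_settings(cfg$N, cfg$thin))
    out <- matrix(rep(lower, each = n_samples), nrow = n_samples)
    out[, !fixed] <- inner
    colnames(out) <- b$populations
    attr(out, "run_log") <- attr(inner, "run_log")
    return(out)
  }
  if (n == 1L) {  # sum constraint pins the single population at p
    out <- matrix(p, nrow = n_samples, ncol = 1,
                  dimnames = list(NULL, b$populations))
    return(out)
  }
  s <- (p - sum(lower)) / span
  x0 <- lower + s * (upper - lower)

  chain <- .har_chain(x0, lower, upper, cfg$N, as.integer(cfg$thin))
  if (nrow(chain) < n_samples) {
    stop("chain of length ", cfg$N, " thinned every ", cfg$thin,
         " yields only ", nrow(chain), " samples; requested ", n_samples)
  }
  out <- chain[seq(nrow(chain) - n_samples + 1L, nrow(chain)), , drop = FALSE]
  colnames(out) <- b$populations
  attr(out, "run_log") <- list(n = n, N = cfg$N, thin = cfg$thin)
  out
}
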