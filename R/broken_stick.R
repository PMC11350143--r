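#' Per-population proportion constraints for the broken-stick sampler
#'
#' @param min_c,max_c numeric scalars or named vectors of per-type bounds in
#'   `[0, 1]`. Scalars are recycled across populations.
#' @param step grid increment for segment boundaries (default 0.01).
#' @param p total proportion allotted to the constrained populations
#'   (`p < 1` leaves `1 - p` for e.g. a fixed spike-in or cancer slot).
#' @param min_prop minimum proportion every represented population must
#'   reach (default 0.01, i.e. the 1 percent floor).
#' @return A list of class `proportion_constraint`.
#' @export
proportion_constraint <- function(min_c = 0, max_c = 1, step = 0.01, p = 1,
                                  min_prop = 0.01) {
  stopifnot(all(min_c >= 0), all(max_c <= 1), all(min_c <= max_c),
            step > 0, step <= p, p <= 1, min_prop >= 0)
  structure(list(min_c = min_c, max_c = max_c, step = step, p = p,
                 min_prop = min_prop),
            class = "proportion_constraint")
}

#' Broken-stick proportion sampler on a fixed grid
#'
#' Partitions the total proportion `p` across `n` populations. Each
#' population is first allotted its effective minimum
#' `max(min_prop, min_c)` — so every represented population reaches the 1
#' percent floor by construction — and the remaining slack is broken into
#' `n` segments by `n - 1` boundaries drawn uniformly from the step grid.
#' In the continuous limit this equals the uniform stick partition
#' conditioned on every segment reaching its minimum. Candidates violating
#' any `max_c` upper bound are rejected and redrawn.
#'
#' @param n number of populations.
#' @param constraint a [proportion_constraint()].
#' @param n_candidates number of accepted vectors to return.
#' @param seed optional integer seed.
#' @param max_attempts cap on total draws before declaring infeasibility.
#' @return `n_candidates` x `n` matrix of proportions, rows summing to `p`.
#' @export
broken_stick <- function(n, constraint = proportion_constraint(),
                         n_candidates = 1, seed = NULL,
                         max_attempts = 1e7) {
  stopifnot(n >= 1, n_candidates >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- constraint$p
  step <- constraint$step
  min_c <- pmax(rep_len(constraint$min_c, n), constraint$min_prop)
  max_c <- rep_len(constraint$max_c, n)
  if (any(min_c > max_c + 1e-12)) {
    stop("infeasible bounds: min exceeds max for population ",
         which(min_c > max_c + 1e-12)[1])
  }
  slack <- p - sum(min_c)
  if (slack < -1e-12) {
    stop("infeasible bounds: the ", n, " population minima sum to ",
         signif(sum(min_c), 4), ", exceeding the total proportion ", p)
  }
  if (n == 1L) {
    if (p > max_c[1] + 1e-12) {
      stop("infeasible bounds: population 1 is capped at ", max_c[1],
           " but must take the whole proportion ", p)
    }
    return(matrix(p, nrow = n_candidates, ncol = 1))
  }

  grid <- seq(0, slack, by = step)
  if (length(grid) < 1L) grid <- 0
  out <- matrix(NA_real_, nrow = n_candidates, ncol = n)
  got <- 0L
  attempts <- 0L
  chunk <- max(256L, min(131072L, n_candidates * 256L))
  while (got < n_candidates) {
    if (attempts >= max_attempts) {
      stop("infeasibility: no candidate satisfied the [min_c, max_c] bounds ",
           "after ", attempts, " attempts")
    }
    m <- as.integer(min(chunk, max_attempts - attempts))
    attempts <- attempts + m
    b <- matrix(grid[sample.int(length(grid), m * (n - 1L), replace = TRUE)],
                nrow = m)
    # row-wise sort via a single two-key radix order
    b <- matrix(b[order(row(b), b)], nrow = m, byrow = TRUE)
    segs <- cbind(b[, 1L], b[, -1L, drop = FALSE] - b[, -(n - 1L), drop = FALSE],
                  slack - b[, n - 1L])
    segs <- segs + rep(min_c, each = m)
    ok <- rowSums(segs > rep(max_c, each = m) + 1e-12) == 0L
    hits <- which(ok)
    if (length(hits)) {
      take <- hits[seq_len(min(length(hits), n_candidates - got))]
      out[(got + 1L):(got + length(take)), ] <- segs[take, , drop = FALSE]
      got <- got + length(take)
    }
  }
  out
}
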