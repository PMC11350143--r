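#' Select mutually extremal candidate admixtures
#'
#' Orders candidates to prioritize those most different from one another:
#' the first two selected are the pair with maximum sum of squared
#' proportion differences; thereafter each added candidate greedily
#' maximizes its minimal sum of squared differences to the already-selected
#' set. Deterministic given input order (ties broken by lowest index).
#'
#' @param candidates matrix of candidate proportion vectors (rows).
#' @param k number of candidates to select.
#' @return Integer vector of selected row indices, in selection order.
#' @export
select_extremal <- function(candidates, k) {
  candidates <- as.matrix(candidates)
  m <- nrow(candidates)
  if (k < 1) stop("k must be >= 1")
  if (k > m) stop("k exceeds the number of candidates")
  if (m == 1L) return(1L)

  d2 <- as.matrix(stats::dist(candidates))^2
  # first pair: maximum squared distance, lowest indices on ties
  best <- which(d2 == max(d2), arr.ind = TRUE)
  best <- best[best[, 1] < best[, 2], , drop = FALSE]
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  selected <- as.integer(best[1, ])
  if (k == 1L) return(selected[1L])

  min_d2 <- unname(pmin(d2[, selected[1]], d2[, selected[2]]))
  while (length(selected) < k) {
    min_d2[selected] <- -Inf
    nxt <- which.max(min_d2)  # which.max takes the lowest index on ties
    selected <- c(selected, nxt)
    min_d2 <- pmin(min_d2, d2[, nxt])
  }
  as.integer(selected)
}
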