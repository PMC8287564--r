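# Internal helpers shared across modules.

R_GAS <- 8.314462618      # J/(mol K)
AVOGADRO <- 6.02214076e23 # 1/mol

#' Evaluate an expression under a fixed RNG seed without touching global state
#'
#' The calling environment's `.Random.seed` is saved and restored, so
#' generators are bit-reproducible and leave no trace on the session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_if_not_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

stop_if_not_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != round(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Wrap Cartesian displacements into the minimum image of an orthorhombic box.
# `d` is an n x 3 matrix of raw displacements; `box` a length-3 edge vector.
min_image <- function(d, box) {
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# All pairwise minimum-image distances between two position sets (n_i x n_j).
pair_distances <- function(pos_i, pos_j, box) {
  ni <- nrow(pos_i)
  nj <- nrow(pos_j)
  d2 <- matrix(0, ni, nj)
  for (k in 1:3) {
    dk <- outer(pos_i[, k], pos_j[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}
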