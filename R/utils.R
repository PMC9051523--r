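#' Derive a deterministic child seed from a root seed and integer ids
#'
#' A small Lehmer-style fold over the ids. Child streams let field counts or
#' sweep grids change without reshuffling unrelated draws: every (entity, year,
#' policy, fold) combination owns its own stream keyed by stable integer ids.
#'
#' @param root integer root seed.
#' @param ... integer ids (field counter, year index, policy code, ...).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(root, ...) {
  ids <- c(root, ...)
  m <- 2147483647
  s <- 20260928 %% m
  for (id in ids) {
    s <- (s * 48271 + (as.numeric(id) %% m) + 1) %% m
  }
  as.integer(s) + 1L
}

#' Evaluate an expression under a temporary, substream-derived RNG state
#' @keywords internal
with_substream <- function(root, ..., expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(root, ...))
  expr
}

#' Snap continuous N rates to a discrete grid
#'
#' @param x numeric vector of N rates (kg N/ha).
#' @param grid ordered numeric grid of admissible rates.
#' @param mode `"nearest"` (ties broken toward the lower rate) or `"down"`
#'   (largest grid point not exceeding `x`).
#' @return numeric vector of grid points, clipped to the grid range.
#' @export
#' @examples
#' snap_to_grid(c(104.9, 105, 327, -4), seq(0, 320, 10))
snap_to_grid <- function(x, grid = seq(0, 320, by = 10),
                         mode = c("nearest", "down")) {
  mode <- match.arg(mode)
  grid <- sort(grid)
  x <- pmin(pmax(x, grid[1]), grid[length(grid)])
  lo_idx <- findInterval(x, grid)
  lo <- grid[lo_idx]
  hi <- grid[pmin(lo_idx + 1L, length(grid))]
  if (mode == "down") {
    return(lo)
  }
  # nearest, exact midpoints go down
  ifelse((x - lo) > (hi - x), hi, lo)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# two-sided p-value for a slope in a simple linear regression summary
slope_stats <- function(fit) {
  s <- summary(fit)
  co <- s$coefficients
  if (nrow(co) < 2L || is.na(co[2L, 1L])) {
    return(list(slope = NA_real_, p = NA_real_, r2 = NA_real_))
  }
  list(slope = unname(co[2L, 1L]),
       p = unname(co[2L, 4L]),
       r2 = s$r.squared)
}

# significance stars, *p<0.1 **p<0.05 ***p<0.01
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.01 ~ "***",
    p < 0.05 ~ "**",
    p < 0.1 ~ "*",
    TRUE ~ "ns"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

REGIONS <- c("south", "central", "north")
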