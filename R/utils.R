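# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library calls do not disturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Centered moving average; width must be odd. Edges use shrunken windows so
#' the output has the same length and no NA.
#' @noRd
moving_average <- function(x, width) {
  width <- as.integer(width)
  if (width <= 1L) return(as.numeric(x))
  if (width %% 2L == 0L) width <- width + 1L
  n <- length(x)
  half <- width %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Distance (in frames) from each query frame to the nearest frame of a given
#' set; Inf when the set is empty. `frames` must be sorted ascending.
#' @noRd
nearest_frame_distance <- function(query, frames) {
  if (length(frames) == 0L) return(rep(Inf, length(query)))
  idx <- findInterval(query, frames)
  lo <- ifelse(idx >= 1L, frames[pmax(idx, 1L)], -Inf)
  hi <- ifelse(idx < length(frames), frames[pmin(idx + 1L, length(frames))], Inf)
  pmin(abs(query - lo), abs(hi - query))
}

#' Bilinear resize of a numeric matrix to `out_dim = c(rows, cols)`.
#' Cell centers are mapped linearly between the two grids.
#' @noRd
bilinear_resize <- function(m, out_dim) {
  nr <- nrow(m); nc <- ncol(m)
  or <- out_dim[1]; oc <- out_dim[2]
  rx <- if (or == 1L) rep(1, or) else seq(1, nr, length.out = or)
  cx <- if (oc == 1L) rep(1, oc) else seq(1, nc, length.out = oc)
  r0 <- pmin(floor(rx), nr - 1L); r0[nr == 1L] <- 1L
  c0 <- pmin(floor(cx), nc - 1L); c0[nc == 1L] <- 1L
  if (nr == 1L) { r0 <- rep(1L, or); fr <- rep(0, or) } else fr <- rx - r0
  if (nc == 1L) { c0 <- rep(1L, oc); fc <- rep(0, oc) } else fc <- cx - c0
  r1 <- pmin(r0 + 1L, nr); c1 <- pmin(c0 + 1L, nc)
  a <- m[r0, c0, drop = FALSE]; b <- m[r0, c1, drop = FALSE]
  d <- m[r1, c0, drop = FALSE]; e <- m[r1, c1, drop = FALSE]
  top <- a * (1 - fc)[col(a)] + b * fc[col(b)]
  bot <- d * (1 - fc)[col(d)] + e * fc[col(e)]
  top * (1 - fr)[row(top)] + bot * fr[row(bot)]
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

# Condition helpers used by the CLI to map failures to exit codes.
stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("gait_data_error", "error")))
}

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("gait_usage_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
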