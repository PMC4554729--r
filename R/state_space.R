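# The state space: a buffered, habitat-masked regular grid of potential
# activity centres around the trap array.

#' Build a state space around a trap array
#'
#' Lays a regular square grid of pixel centres over the bounding rectangle
#' of the traps expanded by `buffer_m` on every side, then keeps a pixel
#' iff its centre lies within `buffer_m` of the nearest trap.  All retained
#' pixels start as suitable habitat; use [apply_habitat_mask()] to mark
#' unsuitable ones.
#'
#' @param traps a [trap_array].
#' @param buffer_m buffer distance around the trap array, metres.
#' @param pixel_area_km2 area of one (square) pixel in km^2; the grid
#'   spacing is `sqrt(pixel_area_km2)` km.
#' @return object of class `state_space`: list with pixel centres `x`, `y`
#'   (metres), `suitable` (logical), `pixel_area_km2`, `buffer_m`,
#'   `spacing_m`.
#' @export
build_state_space <- function(traps, buffer_m, pixel_area_km2) {
  stopifnot(inherits(traps, "trap_array"))
  if (length(traps$x) == 0) stop("state space requires at least one trap")
  if (buffer_m <= 0) stop("buffer_m must be > 0")
  if (pixel_area_km2 <= 0) stop("pixel_area_km2 must be > 0")
  spacing <- sqrt(pixel_area_km2) * 1000
  # anchor the lattice on the trap-array centre so enlarging the buffer
  # only extends the grid and never shifts existing pixel centres
  ctr_x <- mean(range(traps$x))
  ctr_y <- mean(range(traps$y))
  he_x <- diff(range(traps$x)) / 2 + buffer_m
  he_y <- diff(range(traps$y)) / 2 + buffer_m
  n_x <- max(1, ceiling(he_x / spacing))
  n_y <- max(1, ceiling(he_y / spacing))
  gx <- ctr_x + (seq(-n_x + 0.5, n_x - 0.5, by = 1)) * spacing
  gy <- ctr_y + (seq(-n_y + 0.5, n_y - 0.5, by = 1)) * spacing
  cx <- rep(gx, times = length(gy))
  cy <- rep(gy, each = length(gx))
  d2min <- rep(Inf, length(cx))
  contains <- rep(FALSE, length(cx))
  half <- spacing / 2
  for (j in seq_along(traps$x)) {
    d2 <- (cx - traps$x[j])^2 + (cy - traps$y[j])^2
    d2min <- pmin(d2min, d2)
    # half-open footprint [c - h, c + h) so a trap on a pixel edge
    # belongs to exactly one pixel
    contains <- contains | (cx <= traps$x[j] + half & cx > traps$x[j] - half &
                              cy <= traps$y[j] + half & cy > traps$y[j] - half)
  }
  # centre-in-buffer rule, plus any pixel whose footprint holds a trap so
  # the state space always covers the traps in the vanishing-buffer limit
  keep <- d2min <= buffer_m^2 | contains
  structure(list(x = cx[keep], y = cy[keep],
                 suitable = rep(TRUE, sum(keep)),
                 pixel_area_km2 = pixel_area_km2,
                 buffer_m = buffer_m, spacing_m = spacing),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("state_space: %d pixels (%.2f km^2 each), %d suitable (%.1f km^2), buffer %.1f km\n",
              length(x$x), x$pixel_area_km2, sum(x$suitable),
              suitable_area_km2(x), x$buffer_m / 1000))
  invisible(x)
}

#' Suitable-habitat area of a state space, km^2
#' @param ss a `state_space`.
#' @export
suitable_area_km2 <- function(ss) {
  stopifnot(inherits(ss, "state_space"))
  ss$pixel_area_km2 * sum(ss$suitable)
}

#' Apply a habitat-suitability mask
#'
#' Marks pixels whose mask flag is FALSE/0 as unsuitable.  The flags come
#' from an external habitat delineation (reserve boundary, villages,
#' roads); the mask is combined with, never replaces, the current flags.
#'
#' @param ss a `state_space`.
#' @param mask_flags logical/0-1 vector, one per pixel.
#' @return the masked `state_space`.
#' @export
apply_habitat_mask <- function(ss, mask_flags) {
  stopifnot(inherits(ss, "state_space"))
  if (length(mask_flags) != length(ss$x))
    stop("mask length (", length(mask_flags), ") != number of pixels (",
         length(ss$x), ")")
  ss$suitable <- ss$suitable & as.logical(mask_flags)
  if (!any(ss$suitable))
    stop("habitat mask leaves no suitable pixel: SECR undefined")
  ss
}

#' Read a state-space file (X, Y, HABITAT dialect)
#'
#' @param path CSV with columns X, Y, HABITAT (1 = suitable).
#' @param pixel_area_km2 pixel area; inferred from grid spacing when NULL.
#' @param buffer_m recorded buffer distance (metadata only).
#' @export
read_state_space <- function(path, pixel_area_km2 = NULL, buffer_m = NA) {
  df <- utils::read.csv(path)
  miss <- setdiff(c("X", "Y", "HABITAT"), names(df))
  if (length(miss))
    stop("state-space file missing column(s): ", paste(miss, collapse = ", "))
  ux <- sort(unique(df$X))
  spacing <- if (length(ux) > 1) min(diff(ux)) else NA_real_
  if (is.null(pixel_area_km2)) {
    if (is.na(spacing)) stop("cannot infer pixel area from a single column of pixels")
    pixel_area_km2 <- (spacing / 1000)^2
  } else if (is.na(spacing)) {
    spacing <- sqrt(pixel_area_km2) * 1000
  }
  structure(list(x = df$X, y = df$Y, suitable = df$HABITAT > 0,
                 pixel_area_km2 = pixel_area_km2,
                 buffer_m = buffer_m, spacing_m = spacing),
            class = "state_space")
}

#' Write a state-space file (X, Y, HABITAT dialect)
#' @param ss a `state_space`.
#' @param path output CSV path.
#' @export
write_state_space <- function(ss, path) {
  utils::write.csv(data.frame(X = ss$x, Y = ss$y,
                              HABITAT = as.integer(ss$suitable)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Buffer-sensitivity check
#'
#' Refits the SECR model over a sequence of buffer widths and reports the
#' posterior-mean density trajectory, the standard way of checking that
#' the buffer is wide enough for density to have stabilised.
#'
#' @param history a `capture_history`.
#' @param traps a [trap_array].
#' @param buffers_m increasing vector of buffer distances, metres.
#' @param pixel_area_km2 pixel area for every refit.
#' @param config fit settings passed to [fit_secr()] (a [secr_config()]).
#' @return data.frame with columns `buffer_m`, `density_mean`, `n_mean`,
#'   `suitable_area_km2`.
#' @export
buffer_sensitivity <- function(history, traps, buffers_m, pixel_area_km2,
                               config = secr_config()) {
  out <- lapply(buffers_m, function(b) {
    ss <- build_state_space(traps, b, pixel_area_km2)
    fit <- fit_secr(history, traps, ss, config)
    data.frame(buffer_m = b,
               density_mean = mean(fit$chains$density),
               n_mean = mean(fit$chains$N),
               suitable_area_km2 = suitable_area_km2(ss))
  })
  do.call(rbind, out)
}
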