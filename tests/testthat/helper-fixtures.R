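# shared in-code fixtures; everything is generated, nothing is stored

# small 2x2-cell design: quick state spaces and fits
small_design <- function(seed = 101, n_occasions = 30) {
  traps <- generate_trap_grid(n_cells_x = 2, n_cells_y = 2, cell_km = 4,
                              traps_per_cell = 2, min_spacing_m = 1000,
                              n_occasions = n_occasions, seed = seed)
  ss <- build_state_space(traps, buffer_m = 6000, pixel_area_km2 = 4)
  list(traps = traps, ss = ss)
}

# capture history with prescribed per-individual capture counts, all on
# distinct trap-occasions of a fully active array
history_with_counts <- function(counts, n_traps = 60, n_occasions = 93) {
  n <- length(counts)
  y <- array(0L, dim = c(n, n_traps, n_occasions))
  k <- 1L
  for (i in seq_len(n)) {
    for (c in seq_len(counts[i])) {
      j <- ((k - 1L) %% n_traps) + 1L
      occ <- ((k - 1L) %/% n_traps) + 1L
      y[i, j, occ] <- 1L
      k <- k + 1L
    }
  }
  structure(list(y = y, individual_id = sprintf("A%02d", seq_len(n)),
                 n_individuals = n, n_traps = n_traps,
                 n_occasions = n_occasions),
            class = "capture_history")
}

# timestamped records helper
rec_df <- function(trap, animal, time) {
  out <- data.frame(trap_id = trap, individual_id = animal,
                    timestamp = as.POSIXct(time, tz = "UTC"))
  class(out) <- c("capture_records", "data.frame")
  out
}
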