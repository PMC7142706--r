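# Small herds built in code for the unit tests.

# Two rooms x two pens of 10 animals each (40 animals), one indicator.
toy_herd <- function(count = 8L, clustering = 0, seed = 1L) {
  generate_herd(herd_config(
    room_sizes = c(20L, 20L), pens_per_room = 2L, max_pen_size = 25L,
    indicator_counts = c(lameness = count),
    clustering = clustering, seed = seed))
}

# One room whose pens all have identical size.
equal_pen_herd <- function(n_pens = 8L, pen_size = 10L, count = 12L,
                           seed = 1L, clustering = 0) {
  generate_herd(herd_config(
    room_sizes = n_pens * pen_size, pens_per_room = n_pens,
    max_pen_size = pen_size,
    indicator_counts = c(lameness = count),
    clustering = clustering, seed = seed))
}

# Four rooms x 8 pens of 20 animals (640 animals, every pen > 15), used to
# exercise the S5 lesion cap.
big_even_herd <- function(seed = 1L) {
  generate_herd(herd_config(
    room_sizes = rep(160L, 4L), pens_per_room = 8L, max_pen_size = 20L,
    indicator_counts = c(tail_lesions = 30L, faecal_soiling = 25L,
                         skin_lesions = 40L, ear_lesions = 50L,
                         lameness = 35L, runts = 10L),
    seed = seed))
}

# Reference study conditions: S1/S2 draw 167 animals.
REF_N <- 167L
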