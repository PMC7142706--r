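# Synthetic herd construction: rooms -> pens -> animals with binary
# indicator states. The herd is the finite population being sampled; its
# per-indicator proportion of problematic animals is the "true prevalence".

#' Configuration for a synthetic herd
#'
#' @param room_sizes Integer vector of animals per room.
#' @param pens_per_room Number of pens in each room.
#' @param max_pen_size Pen capacity (animals).
#' @param indicator_counts Named integer vector: number of problematic
#'   animals per indicator in the whole herd.
#' @param clustering Non-negative clustering strength, a single value or one
#'   per indicator. 0 places affected animals uniformly at random across the
#'   herd; larger values concentrate them into fewer pens via a Polya-urn
#'   scheme (see [generate_herd()]).
#' @param seed Integer seed making the herd reproducible.
#' @return An object of class `herd_config`.
#' @examples
#' cfg <- herd_config(room_sizes = c(20, 20), pens_per_room = 2,
#'                    indicator_counts = c(lameness = 4), seed = 1)
#' @export
herd_config <- function(room_sizes, pens_per_room = 8L, max_pen_size = 25L,
                        indicator_counts, clustering = 0, seed = 1L) {
  room_sizes <- as.integer(room_sizes)
  n_total <- sum(room_sizes)
  stopifnot(length(room_sizes) >= 1L, all(room_sizes >= 1L),
            pens_per_room >= 1L, max_pen_size >= 1L)
  if (is.null(names(indicator_counts)) || any(!nzchar(names(indicator_counts))))
    stop("indicator_counts must be a named vector")
  indicator_counts <- vapply(indicator_counts, as.integer, integer(1))
  if (any(indicator_counts < 0L) || any(indicator_counts > n_total))
    stop(sprintf("indicator counts must lie in [0, %d] (herd size)", n_total))
  if (length(clustering) == 1L)
    clustering <- stats::setNames(rep(clustering, length(indicator_counts)),
                                  names(indicator_counts))
  if (!setequal(names(clustering), names(indicator_counts)))
    stop("clustering must be a single value or named like indicator_counts")
  if (any(clustering < 0)) stop("clustering must be non-negative")
  structure(
    list(room_sizes = room_sizes, pens_per_room = as.integer(pens_per_room),
         max_pen_size = as.integer(max_pen_size),
         indicator_counts = indicator_counts,
         clustering = clustering[names(indicator_counts)],
         seed = as.integer(seed)),
    class = "herd_config")
}

#' Split each room's animals across its pens as evenly as possible
#'
#' Within a room, pen sizes differ by at most one animal; when the room size
#' is not divisible by the pen count the extra animals go to the
#' lowest-indexed pens, so the allocation is deterministic.
#'
#' @inheritParams herd_config
#' @return Data frame with columns `pen_id` (unique across the herd),
#'   `room_id` and `size`.
#' @examples
#' allocate_pens(c(88, 174, 174, 200), pens_per_room = 8)
#' @export
allocate_pens <- function(room_sizes, pens_per_room = 8L, max_pen_size = 25L) {
  room_sizes <- as.integer(room_sizes)
  for (r in seq_along(room_sizes)) {
    if (room_sizes[r] > pens_per_room * max_pen_size)
      stop(sprintf(
        "room %d holds %d animals, exceeding %d pens x %d places",
        r, room_sizes[r], pens_per_room, max_pen_size))
    if (room_sizes[r] < pens_per_room)
      stop(sprintf("room %d has %d animals for %d pens; every pen needs >= 1",
                   r, room_sizes[r], pens_per_room))
  }
  sizes <- unlist(lapply(room_sizes, function(n) {
    base <- n %/% pens_per_room
    rem <- n %% pens_per_room
    base + as.integer(seq_len(pens_per_room) <= rem)
  }))
  data.frame(pen_id = seq_along(sizes),
             room_id = rep(seq_along(room_sizes), each = pens_per_room),
             size = as.integer(sizes))
}

#' Generate a synthetic herd
#'
#' Builds the rooms-pens-animals hierarchy via [allocate_pens()] and then
#' assigns each indicator's configured number of problematic animals. With
#' `clustering = 0` the affected animals are a uniformly random subset of the
#' herd (sampling without replacement). With `clustering = c > 0` affected
#' animals are placed one at a time by a Polya-urn scheme over pens: the next
#' affected animal lands in pen *j* with probability proportional to
#' `pen_size_j + c * affected_already_in_j` (pens whose animals are all
#' already affected are excluded), then a still-unaffected animal of that pen
#' is chosen uniformly. Larger `c` concentrates each indicator into fewer
#' pens, emulating within-pen disease aggregation. Indicators are assigned
#' independently of one another.
#'
#' @param config A [herd_config()].
#' @return An object of class `herd`: a list with `animals` (data frame
#'   `animal_id`, `room_id`, `pen_id`, plus one 0/1 column per indicator),
#'   `pens` (as [allocate_pens()]), and the originating `config`.
#' @examples
#' h <- generate_herd(herd_config(c(20, 20), pens_per_room = 2,
#'                                indicator_counts = c(lameness = 4), seed = 1))
#' true_prevalence(h)
#' @export
generate_herd <- function(config) {
  stopifnot(inherits(config, "herd_config"))
  pens <- allocate_pens(config$room_sizes, config$pens_per_room,
                        config$max_pen_size)
  n_total <- sum(pens$size)
  animals <- data.frame(
    animal_id = seq_len(n_total),
    room_id = rep(pens$room_id, pens$size),
    pen_id = rep(pens$pen_id, pens$size))

  pen_members <- split(animals$animal_id, animals$pen_id)

  states <- with_seed(config$seed, {
    out <- matrix(0L, nrow = n_total, ncol = length(config$indicator_counts),
                  dimnames = list(NULL, names(config$indicator_counts)))
    for (ind in names(config$indicator_counts)) {
      k <- config$indicator_counts[[ind]]
      if (k == 0L) next
      cl <- config$clustering[[ind]]
      if (cl == 0) {
        out[sample.int(n_total, k), ind] <- 1L
      } else {
        out[polya_place(pen_members, pens$size, k, cl), ind] <- 1L
      }
    }
    out
  })
  animals <- cbind(animals, as.data.frame(states))
  h <- structure(list(animals = animals, pens = pens, config = config),
                 class = "herd")
  validate_herd(h)
  h
}

# Sequential Polya-urn placement of k affected animals over pens.
# Weight of pen j: size_j + c * affected_j, zeroed once the pen is saturated.
polya_place <- function(pen_members, pen_sizes, k, c) {
  n_pens <- length(pen_members)
  affected <- integer(n_pens)
  taken <- vector("list", n_pens) # affected animal ids per pen
  chosen <- integer(k)
  for (i in seq_len(k)) {
    w <- pen_sizes + c * affected
    w[affected >= pen_sizes] <- 0
    j <- sample.int(n_pens, 1L, prob = w)
    free <- setdiff(pen_members[[j]], taken[[j]])
    a <- free[sample.int(length(free), 1L)]
    taken[[j]] <- c(taken[[j]], a)
    affected[j] <- affected[j] + 1L
    chosen[i] <- a
  }
  chosen
}

#' The packaged 636-pig reference herd
#'
#' Four rooms of 88, 174, 174 and 200 fattening pigs, eight pens per room
#' (32 pens, mean pen size 19.875), and indicator counts back-computed from
#' the census prevalences reported for the source farm: 20 tail lesions
#' (3.1\%), 28 faecal soiling (4.4\%), 35 skin lesions (5.5\%), 54 ear
#' lesions (8.5\%), 37 lameness (5.8\%) and 7 runts (1.1\%). Each count is
#' the unique integer that rounds to the printed one-decimal prevalence at
#' a herd size of 636, so the fixture's census is exact. Affected animals
#' are placed uniformly (`clustering = 0`) by default because the room- and
#' pen-level distribution of the real herd was never published.
#'
#' @param seed Seed for the placement of affected animals.
#' @param clustering Clustering strength passed to [herd_config()].
#' @return A `herd` of 636 animals in 32 pens.
#' @examples
#' h <- reference_herd(seed = 1)
#' round(100 * true_prevalence(h), 1)
#' @export
reference_herd <- function(seed = 1L, clustering = 0) {
  generate_herd(herd_config(
    room_sizes = c(88L, 174L, 174L, 200L),
    pens_per_room = 8L,
    max_pen_size = 25L,
    indicator_counts = c(tail_lesions = 20L, faecal_soiling = 28L,
                         skin_lesions = 35L, ear_lesions = 54L,
                         lameness = 37L, runts = 7L),
    clustering = clustering,
    seed = seed))
}

#' @export
print.herd <- function(x, ...) {
  cat(sprintf("<herd> %d animals, %d rooms, %d pens\n",
              nrow(x$animals), length(unique(x$pens$room_id)), nrow(x$pens)))
  p <- true_prevalence(x)
  cat("true prevalences (%):\n")
  print(round(100 * p, 2))
  invisible(x)
}

#' Herd accessors
#'
#' `herd_size()` is the number of animals; `herd_indicators()` the indicator
#' names; `indicator_states()` the animals-by-indicators 0/1 matrix;
#' `herd_digest()` a short content hash of the animal table used to match
#' estimate matrices to the herd they were drawn from.
#'
#' @param herd A `herd`.
#' @return See each description.
#' @export
herd_size <- function(herd) nrow(herd$animals)

#' @rdname herd_size
#' @export
herd_indicators <- function(herd)
  setdiff(names(herd$animals), c("animal_id", "room_id", "pen_id"))

#' @rdname herd_size
#' @export
indicator_states <- function(herd) {
  as.matrix(herd$animals[, herd_indicators(herd), drop = FALSE])
}

#' @rdname herd_size
#' @export
herd_digest <- function(herd) {
  txt <- paste(
    capture_csv(herd$animals),
    collapse = "\n")
  fnv1a(txt)
}

capture_csv <- function(df) {
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  out
}

#' True (census) prevalence of an indicator
#'
#' The proportion of problematic animals in the whole herd — the quantity a
#' sampling strategy tries to estimate.
#'
#' @param herd A `herd`.
#' @param indicator Indicator name, or `NULL` for all indicators.
#' @return Named numeric vector of proportions in \[0, 1\].
#' @examples
#' true_prevalence(reference_herd(), "ear_lesions") # 54/636
#' @export
true_prevalence <- function(herd, indicator = NULL) {
  inds <- herd_indicators(herd)
  if (!is.null(indicator)) {
    missing <- setdiff(indicator, inds)
    if (length(missing))
      stop(sprintf("unknown indicator(s): %s", paste(missing, collapse = ", ")))
    inds <- indicator
  }
  colSums(herd$animals[, inds, drop = FALSE]) / nrow(herd$animals)
}

#' Validate the structural invariants of a herd
#'
#' Checks unique animal ids, one pen per animal and one room per pen, pen
#' occupancies within capacity, binary indicator states, and (when the herd
#' carries its generating config) agreement between realized indicator
#' totals and the configured counts.
#'
#' @param herd A `herd`.
#' @return The herd, invisibly; errors describe the first violated invariant.
#' @export
validate_herd <- function(herd) {
  a <- herd$animals
  if (anyDuplicated(a$animal_id)) stop("duplicated animal ids")
  occ <- table(factor(a$pen_id, levels = herd$pens$pen_id))
  if (!all(as.integer(occ) == herd$pens$size))
    stop("pen occupancies disagree with the pen table")
  if (any(herd$pens$size < 1L))
    stop("every pen must hold at least one animal")
  pen_room <- unique(a[, c("pen_id", "room_id")])
  if (anyDuplicated(pen_room$pen_id))
    stop("a pen maps to more than one room")
  X <- indicator_states(herd)
  if (!all(X %in% c(0L, 1L))) stop("indicator states must be 0/1")
  if (!is.null(herd$config)) {
    if (any(herd$pens$size > herd$config$max_pen_size))
      stop("pen occupancy exceeds max_pen_size")
    want <- herd$config$indicator_counts
    got <- colSums(X)[names(want)]
    if (!all(got == want))
      stop("realized indicator totals do not match the configured counts")
  }
  invisible(herd)
}

#' Read and write herds as animal-level CSV
#'
#' The on-disk form is one row per animal with columns `animal_id`,
#' `room_id`, `pen_id` and one 0/1 column per indicator. `read_herd()`
#' rebuilds the pen table and validates all structural invariants.
#'
#' @param herd A `herd`.
#' @param path File path.
#' @return `write_herd()` the path invisibly; `read_herd()` a `herd`.
#' @export
write_herd <- function(herd, path) {
  utils::write.csv(herd$animals, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_herd
#' @export
read_herd <- function(path) {
  a <- utils::read.csv(path)
  need <- c("animal_id", "room_id", "pen_id")
  if (!all(need %in% names(a)))
    stop(sprintf("herd file %s lacks columns %s", path,
                 paste(setdiff(need, names(a)), collapse = ", ")))
  pens <- aggregate(list(size = a$animal_id),
                    by = list(pen_id = a$pen_id, room_id = a$room_id),
                    FUN = length)
  pens <- pens[order(pens$pen_id), c("pen_id", "room_id", "size")]
  rownames(pens) <- NULL
  for (ind in setdiff(names(a), need)) a[[ind]] <- as.integer(a[[ind]])
  h <- structure(list(animals = a, pens = pens, config = NULL),
                 class = "herd")
  validate_herd(h)
  h
}

#' Read a herd configuration from a YAML file
#'
#' The file mirrors the fields of [herd_config()]: `room_sizes`,
#' `pens_per_room`, `max_pen_size`, `indicator_counts` (a mapping),
#' `clustering` (scalar or mapping) and `seed`.
#'
#' @param path Path to a YAML file.
#' @return A `herd_config`.
#' @export
read_herd_config <- function(path) {
  y <- yaml::read_yaml(path)
  clustering <- y$clustering %||% 0
  if (is.list(clustering)) clustering <- unlist(clustering)
  herd_config(room_sizes = unlist(y$room_sizes),
              pens_per_room = y$pens_per_room %||% 8L,
              max_pen_size = y$max_pen_size %||% 25L,
              indicator_counts = unlist(y$indicator_counts),
              clustering = clustering,
              seed = y$seed %||% 1L)
}
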