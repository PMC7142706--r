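# The five sampling designs. Each maps a herd and the current RNG state to
# one realized sample: selected animals per indicator plus the estimated
# prevalences. Animals and pens are always drawn without replacement, pens
# before animals, so a fixed seed reproduces a draw exactly.

#' Describe one sampling design
#'
#' @param kind One of `"S1_simple"` (simple random sample of animals),
#'   `"S2_stratified"` (animals allocated to rooms proportionally),
#'   `"S3_clustered"` (whole pens, rooms ignored), `"S4_stratified_clustered"`
#'   (a fixed number of whole pens per room), `"S5_ktbl"` (the pen-based
#'   guide scheme: ten pens — two per room plus two extra — with a per-pen
#'   cap of 15 animals for the three lesion indicators).
#' @param n_animals Sample size for S1/S2 (default 167).
#' @param n_pens Pens to draw for S3 (default 8).
#' @param pens_per_stratum Pens per room for S4 (default 2).
#' @param per_pen_cap Per-pen animal cap for the S5 lesion group (default 15).
#' @param ktbl_pens Total pens for S5 (default 10).
#' @param lesion_total_floor Target lesion-group total for S5 when fewer
#'   than `ktbl_pens` pens exist (default 150).
#' @return An object of class `strategy_spec`.
#' @examples
#' strategy_spec("S1_simple")
#' strategy_spec("S3_clustered", n_pens = 8)
#' @export
strategy_spec <- function(kind = c("S1_simple", "S2_stratified",
                                   "S3_clustered", "S4_stratified_clustered",
                                   "S5_ktbl"),
                          n_animals = 167L, n_pens = 8L,
                          pens_per_stratum = 2L, per_pen_cap = 15L,
                          ktbl_pens = 10L, lesion_total_floor = 150L) {
  kind <- match.arg(kind)
  structure(list(kind = kind,
                 n_animals = as.integer(n_animals),
                 n_pens = as.integer(n_pens),
                 pens_per_stratum = as.integer(pens_per_stratum),
                 per_pen_cap = as.integer(per_pen_cap),
                 ktbl_pens = as.integer(ktbl_pens),
                 lesion_total_floor = as.integer(lesion_total_floor)),
            class = "strategy_spec")
}

#' @export
print.strategy_spec <- function(x, ...) {
  extra <- switch(x$kind,
    S1_simple = sprintf("n = %d animals", x$n_animals),
    S2_stratified = sprintf("n = %d animals, proportional over rooms",
                            x$n_animals),
    S3_clustered = sprintf("%d pens, rooms ignored", x$n_pens),
    S4_stratified_clustered = sprintf("%d pens per room", x$pens_per_stratum),
    S5_ktbl = sprintf("%d pens, lesion cap %d/pen", x$ktbl_pens,
                      x$per_pen_cap))
  cat(sprintf("<strategy_spec> %s (%s)\n", x$kind, extra))
  invisible(x)
}

#' Largest-remainder (Hamilton) proportional allocation
#'
#' Allocates `total_n` sampling units over strata proportionally to stratum
#' size: each stratum first receives the floor of its exact quota
#' `total_n * size / sum(sizes)`, then the remaining units go to strata in
#' decreasing order of fractional remainder (ties broken by stratum index).
#' No stratum ever receives more units than it has members. Plain rounding
#' of the quotas can miss the total (e.g. it yields 168 where 167 was asked
#' of the four reference rooms); largest remainder always hits it.
#'
#' @param total_n Total number of units to allocate.
#' @param stratum_sizes Positive stratum sizes.
#' @return Integer vector of per-stratum counts summing to `total_n`.
#' @examples
#' allocate_proportional(167, c(88, 174, 174, 200)) # 23, 46, 46, 52
#' @export
allocate_proportional <- function(total_n, stratum_sizes) {
  stopifnot(all(stratum_sizes > 0))
  total_n <- as.integer(total_n)
  if (total_n > sum(stratum_sizes))
    stop(sprintf("cannot allocate %d units over a population of %d",
                 total_n, sum(stratum_sizes)))
  quota <- total_n * stratum_sizes / sum(stratum_sizes)
  counts <- as.integer(floor(quota))
  rem <- total_n - sum(counts)
  if (rem > 0L) {
    ord <- order(-(quota - counts), seq_along(quota))
    for (j in ord) {
      if (rem == 0L) break
      if (counts[j] < stratum_sizes[j]) {
        counts[j] <- counts[j] + 1L
        rem <- rem - 1L
      }
    }
  }
  counts
}

# ---- internal fast representation ------------------------------------------

# Precompute what the per-replicate draw loops need from a herd.
herd_index <- function(herd) {
  a <- herd$animals
  list(X = indicator_states(herd),
       n = nrow(a),
       indicators = herd_indicators(herd),
       room_members = split(seq_len(nrow(a)), a$room_id),
       pen_members = split(seq_len(nrow(a)), a$pen_id),
       pen_sizes = herd$pens$size,
       pen_room = herd$pens$room_id,
       room_sizes = as.integer(tapply(herd$pens$size, herd$pens$room_id, sum)))
}

# Draw animal row indices for each design; RNG state is the caller's.
# Returns list(idx = shared index vector) or, for S5,
# list(idx_a =, idx_b =) for the two indicator groups.
draw_indices <- function(ix, spec) {
  switch(spec$kind,
    S1_simple = {
      if (spec$n_animals > ix$n)
        stop("sample size exceeds herd size")
      list(idx = sample.int(ix$n, spec$n_animals))
    },
    S2_stratified = {
      per_room <- allocate_proportional(spec$n_animals, ix$room_sizes)
      idx <- unlist(lapply(seq_along(ix$room_members), function(r) {
        m <- ix$room_members[[r]]
        m[sample.int(length(m), per_room[r])]
      }), use.names = FALSE)
      list(idx = idx)
    },
    S3_clustered = {
      if (spec$n_pens > length(ix$pen_members))
        stop("more pens requested than exist")
      pens <- sample.int(length(ix$pen_members), spec$n_pens)
      list(idx = unlist(ix$pen_members[pens], use.names = FALSE))
    },
    S4_stratified_clustered = {
      rooms <- unique(ix$pen_room)
      idx <- unlist(lapply(rooms, function(r) {
        pens_r <- which(ix$pen_room == r)
        if (spec$pens_per_stratum > length(pens_r))
          stop(sprintf("room %s has fewer than %d pens", r,
                       spec$pens_per_stratum))
        sel <- pens_r[sample.int(length(pens_r), spec$pens_per_stratum)]
        unlist(ix$pen_members[sel], use.names = FALSE)
      }), use.names = FALSE)
      list(idx = idx)
    },
    S5_ktbl = draw_indices_s5(ix, spec))
}

# S5: herds of <= lesion_total_floor animals get a full census. Otherwise
# 2 pens per room plus one extra pen from each of 2 distinct random rooms
# (10 pens for 4 rooms). Group A (runts, faecal soiling, lameness): every
# animal of the chosen pens. Group B (tail/skin/ear lesions): capped at
# per_pen_cap animals per pen, drawn uniformly within the pen. With fewer
# than ktbl_pens pens in total, every pen is used and the group-B per-pen
# quota is raised to ceiling(lesion_total_floor / n_pens) (experimental
# generalization of the guide's small-barn rule).
draw_indices_s5 <- function(ix, spec) {
  if (ix$n <= spec$lesion_total_floor) {
    idx <- seq_len(ix$n)
    return(list(idx_a = idx, idx_b = idx))
  }
  n_pens <- length(ix$pen_members)
  cap <- spec$per_pen_cap
  if (n_pens < spec$ktbl_pens) {
    sel <- seq_len(n_pens)
    cap <- as.integer(ceiling(spec$lesion_total_floor / n_pens))
  } else {
    rooms <- unique(ix$pen_room)
    sel <- integer(0)
    for (r in rooms) {
      pens_r <- which(ix$pen_room == r)
      if (length(pens_r) < 2L)
        stop(sprintf("room %s has fewer than 2 pens", r))
      sel <- c(sel, pens_r[sample.int(length(pens_r), 2L)])
    }
    n_extra <- spec$ktbl_pens - length(sel)
    if (n_extra > 0L) {
      extra_rooms <- rooms[sample.int(length(rooms), n_extra)]
      for (r in extra_rooms) {
        left <- setdiff(which(ix$pen_room == r), sel)
        if (!length(left))
          stop(sprintf("room %s has no unchosen pen left", r))
        sel <- c(sel, left[sample.int(length(left), 1L)])
      }
    }
  }
  idx_a <- unlist(ix$pen_members[sel], use.names = FALSE)
  idx_b <- unlist(lapply(sel, function(j) {
    m <- ix$pen_members[[j]]
    if (length(m) <= cap) m else m[sample.int(length(m), cap)]
  }), use.names = FALSE)
  list(idx_a = idx_a, idx_b = idx_b)
}

# Indicators assessed on all animals of the S5 pens (group A) vs the capped
# lesion group (group B).
S5_GROUP_A <- c("runts", "faecal_soiling", "lameness")

# counts/sizes per indicator for one realized draw.
draw_counts <- function(ix, spec) {
  sel <- draw_indices(ix, spec)
  p <- length(ix$indicators)
  if (!is.null(sel$idx)) {
    counts <- colSums(ix$X[sel$idx, , drop = FALSE])
    sizes <- rep(length(sel$idx), p)
  } else {
    in_a <- ix$indicators %in% S5_GROUP_A
    counts <- numeric(p)
    sizes <- integer(p)
    if (any(in_a)) {
      counts[in_a] <- colSums(ix$X[sel$idx_a, in_a, drop = FALSE])
      sizes[in_a] <- length(sel$idx_a)
    }
    if (any(!in_a)) {
      counts[!in_a] <- colSums(ix$X[sel$idx_b, !in_a, drop = FALSE])
      sizes[!in_a] <- length(sel$idx_b)
    }
  }
  list(counts = as.integer(counts), sizes = as.integer(sizes),
       selection = sel)
}

# ---- public one-draw interface ---------------------------------------------

#' Draw one sample from a herd under a given strategy
#'
#' `draw_sample()` dispatches on the strategy kind; `draw_s1()` ...
#' `draw_s5()` are direct entry points for the individual designs. All
#' consume the current RNG state (use `set.seed()` or [simulate_strategy()]
#' for reproducible streams).
#'
#' @param herd A `herd`.
#' @param spec A [strategy_spec()].
#' @return An object of class `sample_draw`: per-indicator selected animal
#'   ids, sample sizes, affected counts and estimated prevalences.
#' @examples
#' h <- reference_herd(seed = 1)
#' set.seed(42)
#' d <- draw_sample(h, strategy_spec("S1_simple"))
#' d$estimates
#' @export
draw_sample <- function(herd, spec) {
  stopifnot(inherits(herd, "herd"), inherits(spec, "strategy_spec"))
  ix <- herd_index(herd)
  d <- draw_counts(ix, spec)
  ids <- herd$animals$animal_id
  selection <- if (!is.null(d$selection$idx)) {
    shared <- ids[d$selection$idx]
    stats::setNames(rep(list(shared), length(ix$indicators)), ix$indicators)
  } else {
    lapply(stats::setNames(ix$indicators, ix$indicators), function(ind) {
      if (ind %in% S5_GROUP_A) ids[d$selection$idx_a] else ids[d$selection$idx_b]
    })
  }
  structure(list(
    strategy = spec,
    animal_ids = selection,
    counts = stats::setNames(d$counts, ix$indicators),
    sample_size = stats::setNames(d$sizes, ix$indicators),
    estimates = stats::setNames(d$counts / d$sizes, ix$indicators)),
    class = "sample_draw")
}

#' @export
print.sample_draw <- function(x, ...) {
  cat(sprintf("<sample_draw> %s\n", x$strategy$kind))
  print(data.frame(indicator = names(x$estimates),
                   n = as.integer(x$sample_size),
                   affected = as.integer(x$counts),
                   estimate = round(x$estimates, 4), row.names = NULL))
  invisible(x)
}

#' @rdname draw_sample
#' @param n_animals Sample size (S1/S2).
#' @export
draw_s1 <- function(herd, n_animals = 167L)
  draw_sample(herd, strategy_spec("S1_simple", n_animals = n_animals))

#' @rdname draw_sample
#' @export
draw_s2 <- function(herd, n_animals = 167L)
  draw_sample(herd, strategy_spec("S2_stratified", n_animals = n_animals))

#' @rdname draw_sample
#' @param n_pens Number of pens (S3).
#' @export
draw_s3 <- function(herd, n_pens = 8L)
  draw_sample(herd, strategy_spec("S3_clustered", n_pens = n_pens))

#' @rdname draw_sample
#' @param pens_per_stratum Pens per room (S4).
#' @export
draw_s4 <- function(herd, pens_per_stratum = 2L)
  draw_sample(herd, strategy_spec("S4_stratified_clustered",
                                  pens_per_stratum = pens_per_stratum))

#' @rdname draw_sample
#' @export
draw_s5 <- function(herd, spec = strategy_spec("S5_ktbl"))
  draw_sample(herd, spec)

#' Estimate an indicator's prevalence from a selection of animals
#'
#' @param animal_ids Selected animal ids (without replacement; must be
#'   non-empty).
#' @param herd The `herd` the animals belong to.
#' @param indicator Indicator name.
#' @return Proportion of selected animals that are problematic.
#' @examples
#' h <- reference_herd()
#' estimate_prevalence(h$animals$animal_id, h, "runts") # census: 7/636
#' @export
estimate_prevalence <- function(animal_ids, herd, indicator) {
  if (!length(animal_ids)) stop("empty selection: cannot estimate")
  if (anyDuplicated(animal_ids)) stop("selection contains duplicate animals")
  if (!indicator %in% herd_indicators(herd))
    stop(sprintf("unknown indicator '%s'", indicator))
  rows <- match(animal_ids, herd$animals$animal_id)
  if (anyNA(rows)) stop("selection contains unknown animal ids")
  mean(herd$animals[[indicator]][rows])
}
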