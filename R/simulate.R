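# Monte-Carlo engine: many replicate draws of one strategy on one herd,
# assembled into a replicates x indicators estimate matrix.

#' Run replicate draws of one sampling strategy
#'
#' Draws `n_replicates` independent samples from `herd` under `spec` and
#' records, per replicate and indicator, the number of affected animals and
#' the sample size. Randomness uses L'Ecuyer-CMRG substreams derived from
#' `master_seed`: replicate *r* always consumes substream *r*, so a run with
#' more replicates reproduces the earlier replicates exactly, and the
#' caller's RNG state is left untouched.
#'
#' @param herd A `herd`.
#' @param spec A [strategy_spec()].
#' @param n_replicates Number of replicate draws (the reference study size
#'   is 100,000).
#' @param master_seed Integer seed for the whole run.
#' @return An object of class `estimate_matrix`: integer matrices `counts`
#'   and `sizes` (replicates x indicators), the strategy, the herd digest,
#'   `n_replicates` and `master_seed`. Prevalence estimates are formed on
#'   demand by [estimates()] as `counts / sizes`, keeping the stored record
#'   exact.
#' @examples
#' h <- reference_herd(seed = 1)
#' em <- simulate_strategy(h, strategy_spec("S1_simple"), 200, master_seed = 7)
#' colMeans(estimates(em))
#' @export
simulate_strategy <- function(herd, spec, n_replicates = 100000L,
                              master_seed = 1L) {
  stopifnot(inherits(herd, "herd"), inherits(spec, "strategy_spec"),
            n_replicates >= 1L)
  ix <- herd_index(herd)
  p <- length(ix$indicators)
  counts <- matrix(0L, n_replicates, p,
                   dimnames = list(NULL, ix$indicators))
  sizes <- matrix(0L, n_replicates, p,
                  dimnames = list(NULL, ix$indicators))

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  old_kind <- RNGkind()
  on.exit({
    do.call(RNGkind, as.list(old_kind[1:2]))
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)

  suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
  set.seed(master_seed)
  stream <- get(".Random.seed", envir = globalenv())
  for (r in seq_len(n_replicates)) {
    stream <- parallel::nextRNGSubStream(stream)
    assign(".Random.seed", stream, envir = globalenv())
    d <- draw_counts(ix, spec)
    counts[r, ] <- d$counts
    sizes[r, ] <- d$sizes
  }

  structure(list(counts = counts, sizes = sizes, strategy = spec,
                 herd_digest = herd_digest(herd),
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed)),
            class = "estimate_matrix")
}

#' @export
print.estimate_matrix <- function(x, ...) {
  cat(sprintf("<estimate_matrix> %s: %d replicates x %d indicators (seed %d)\n",
              x$strategy$kind, x$n_replicates, ncol(x$counts), x$master_seed))
  cat(sprintf("herd digest %s; mean sample size %.1f\n",
              x$herd_digest, mean(x$sizes)))
  invisible(x)
}

#' Replicate prevalence estimates
#'
#' @param em An `estimate_matrix`.
#' @return Numeric replicates x indicators matrix of `counts / sizes`.
#' @export
estimates <- function(em) {
  stopifnot(inherits(em, "estimate_matrix"))
  em$counts / em$sizes
}

#' Mean realized sample size
#'
#' Fixed-size designs (S1, S2) return their nominal size exactly; pen-based
#' designs vary by replicate. With `indicator = NULL` the per-indicator
#' means are averaged (the "across all indicators" convention used when the
#' reference study equates sample sizes across strategies).
#'
#' @param em An `estimate_matrix`.
#' @param indicator Indicator name, or `NULL` for the all-indicator average.
#' @return A single number of animals.
#' @export
mean_sample_size <- function(em, indicator = NULL) {
  stopifnot(inherits(em, "estimate_matrix"))
  if (is.null(indicator)) return(mean(colMeans(em$sizes)))
  if (!indicator %in% colnames(em$sizes))
    stop(sprintf("unknown indicator '%s'", indicator))
  mean(em$sizes[, indicator])
}

#' Write / read an estimate matrix
#'
#' The on-disk form is a wide CSV (`replicate`, then `<indicator>_count` and
#' `<indicator>_size` columns) plus a JSON sidecar holding the strategy,
#' seed, replicate count and herd digest, so a stored run can be matched to
#' its population. The round trip is lossless.
#'
#' @param em An `estimate_matrix`.
#' @param prefix Path prefix; files `<prefix>.csv` and `<prefix>.json` are
#'   written.
#' @return `write_estimate_matrix()` the prefix invisibly;
#'   `read_estimate_matrix()` the reconstructed `estimate_matrix`.
#' @export
write_estimate_matrix <- function(em, prefix) {
  stopifnot(inherits(em, "estimate_matrix"))
  inds <- colnames(em$counts)
  wide <- data.frame(replicate = seq_len(nrow(em$counts)))
  for (ind in inds) {
    wide[[paste0(ind, "_count")]] <- em$counts[, ind]
    wide[[paste0(ind, "_size")]] <- em$sizes[, ind]
  }
  utils::write.csv(wide, paste0(prefix, ".csv"), row.names = FALSE)
  side <- list(strategy = unclass(em$strategy),
               herd_digest = em$herd_digest,
               n_replicates = em$n_replicates,
               master_seed = em$master_seed)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_estimate_matrix
#' @export
read_estimate_matrix <- function(prefix) {
  wide <- utils::read.csv(paste0(prefix, ".csv"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  inds <- sub("_count$", "", grep("_count$", names(wide), value = TRUE))
  counts <- as.matrix(wide[paste0(inds, "_count")])
  sizes <- as.matrix(wide[paste0(inds, "_size")])
  colnames(counts) <- colnames(sizes) <- inds
  storage.mode(counts) <- storage.mode(sizes) <- "integer"
  spec <- do.call(strategy_spec, side$strategy)
  structure(list(counts = counts, sizes = sizes, strategy = spec,
                 herd_digest = side$herd_digest,
                 n_replicates = as.integer(side$n_replicates),
                 master_seed = as.integer(side$master_seed)),
            class = "estimate_matrix")
}
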