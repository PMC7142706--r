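# End-to-end runner: build or load a herd, simulate a set of strategies,
# write estimate matrices, per-strategy validity reports and a
# cross-strategy summary table.

#' Assemble a study configuration
#'
#' @param herd A `herd`, a [herd_config()], or a path to an animal-level
#'   herd CSV (see [read_herd()]).
#' @param strategies Named list of [strategy_spec()]s; names label output
#'   files and the summary rows.
#' @param n_replicates Replicates per strategy.
#' @param master_seed Seed for the whole study; strategy *k* uses
#'   `master_seed + k - 1` so strategies are independent but individually
#'   reproducible.
#' @param output_dir Directory for result files (created if absent); `NULL`
#'   keeps everything in memory.
#' @param thresholds Deviation thresholds, positive and increasing.
#' @return An object of class `run_config`.
#' @export
run_config <- function(herd,
                       strategies = default_strategies(),
                       n_replicates = 100000L,
                       master_seed = 1L,
                       output_dir = NULL,
                       thresholds = c(0.10, 0.30, 0.50)) {
  if (length(strategies) < 1L) stop("need at least one strategy")
  if (is.null(names(strategies)) || any(!nzchar(names(strategies))))
    stop("strategies must be a named list")
  for (s in strategies) stopifnot(inherits(s, "strategy_spec"))
  if (any(thresholds <= 0) || is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be positive and strictly increasing")
  structure(list(herd = herd, strategies = strategies,
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed),
                 output_dir = output_dir, thresholds = thresholds),
            class = "run_config")
}

#' The five reference designs with their standard parameters
#'
#' Simple random and stratified samples of 167 animals, 8 whole pens,
#' 2 whole pens per room, and the guide's 10-pen scheme with the 15-animal
#' lesion cap.
#'
#' @return Named list of [strategy_spec()]s (names `S1` ... `S5`).
#' @export
default_strategies <- function() {
  list(S1 = strategy_spec("S1_simple", n_animals = 167L),
       S2 = strategy_spec("S2_stratified", n_animals = 167L),
       S3 = strategy_spec("S3_clustered", n_pens = 8L),
       S4 = strategy_spec("S4_stratified_clustered", pens_per_stratum = 2L),
       S5 = strategy_spec("S5_ktbl"))
}

#' Read a study configuration from YAML
#'
#' Top-level keys: `herd` (either a nested herd configuration as in
#' [read_herd_config()] or `{csv: path}`), `strategies` (a mapping of label
#' to `{kind: ..., <overrides>}`), `n_replicates`, `master_seed`,
#' `output_dir`, `thresholds`.
#'
#' @param path YAML file path.
#' @param output_dir Optional override of the file's `output_dir`.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, output_dir = NULL) {
  y <- yaml::read_yaml(path)
  herd <- if (!is.null(y$herd$csv)) {
    read_herd(file.path(dirname(path), y$herd$csv))
  } else {
    clustering <- y$herd$clustering %||% 0
    if (is.list(clustering)) clustering <- unlist(clustering)
    herd_config(room_sizes = unlist(y$herd$room_sizes),
                pens_per_room = y$herd$pens_per_room %||% 8L,
                max_pen_size = y$herd$max_pen_size %||% 25L,
                indicator_counts = unlist(y$herd$indicator_counts),
                clustering = clustering,
                seed = y$herd$seed %||% 1L)
  }
  strategies <- lapply(y$strategies, function(s) do.call(strategy_spec, s))
  run_config(herd = herd, strategies = strategies,
             n_replicates = y$n_replicates %||% 100000L,
             master_seed = y$master_seed %||% 1L,
             output_dir = output_dir %||% y$output_dir,
             thresholds = unlist(y$thresholds %||% c(0.10, 0.30, 0.50)))
}

#' Run a whole sampling-validity study
#'
#' Resolves the herd, simulates every configured strategy, computes each
#' validity report, and (when `output_dir` is set) writes: the herd CSV,
#' per-strategy estimate matrices (CSV + JSON sidecar), per-strategy tidy
#' reports, a cross-strategy `summary.csv` of indicator-averaged measures,
#' and `run_log.txt` recording seeds and digests.
#'
#' @param config A [run_config()] or path to a YAML study file.
#' @param quiet Suppress progress messages.
#' @return List with `herd`, `matrices`, `reports` and `summary` (data
#'   frame strategy x measure), invisibly when writing to disk.
#' @examples
#' h <- reference_herd(seed = 1)
#' res <- run_validity_study(run_config(
#'   herd = h, strategies = default_strategies()[c("S1", "S3")],
#'   n_replicates = 200, master_seed = 9), quiet = TRUE)
#' res$summary
#' @export
run_validity_study <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  herd <- config$herd
  if (is.character(herd)) herd <- read_herd(herd)
  if (inherits(herd, "herd_config")) herd <- generate_herd(herd)
  stopifnot(inherits(herd, "herd"))
  digest <- herd_digest(herd)
  say("herd: %d animals, %d pens, digest %s",
      herd_size(herd), nrow(herd$pens), digest)

  out <- config$output_dir
  log_lines <- c(sprintf("herd_digest %s", digest),
                 sprintf("master_seed %d", config$master_seed),
                 sprintf("n_replicates %d", config$n_replicates))
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_herd(herd, file.path(out, "herd.csv"))
  }

  matrices <- list()
  reports <- list()
  for (k in seq_along(config$strategies)) {
    label <- names(config$strategies)[k]
    spec <- config$strategies[[k]]
    seed_k <- config$master_seed + k - 1L
    say("strategy %s (%s): %d replicates, seed %d",
        label, spec$kind, config$n_replicates, seed_k)
    em <- simulate_strategy(herd, spec, config$n_replicates, seed_k)
    rep_k <- validity_report(em, herd, config$thresholds)
    matrices[[label]] <- em
    reports[[label]] <- rep_k
    log_lines <- c(log_lines, sprintf("strategy %s seed %d", label, seed_k))
    if (!is.null(out)) {
      write_estimate_matrix(em, file.path(out, paste0("estimates_", label)))
      write_validity_report(rep_k,
                            csv_path = file.path(out, paste0("report_", label, ".csv")),
                            json_path = file.path(out, paste0("report_", label, ".json")))
    }
  }

  summary <- do.call(rbind, lapply(names(reports), function(label) {
    agg <- reports[[label]]$aggregate
    row <- as.data.frame(as.list(stats::setNames(agg$mean, agg$measure)))
    cbind(data.frame(strategy = label,
                     mean_sample_size = mean_sample_size(matrices[[label]])),
          row)
  }))

  if (!is.null(out)) {
    utils::write.csv(summary, file.path(out, "summary.csv"), row.names = FALSE)
    writeLines(log_lines, file.path(out, "run_log.txt"))
    say("results written to %s", out)
  }
  res <- list(herd = herd, matrices = matrices, reports = reports,
              summary = summary)
  if (is.null(out)) res else invisible(res)
}
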