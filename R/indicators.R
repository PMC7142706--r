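#' Welfare indicator definitions
#'
#' The six animal-based KTBL welfare indicators that are assessed on a sample
#' rather than the whole herd. Skin lesions and faecal soiling are scored on
#' a three-level scale (0/1/2), the other four on a two-level scale (0/1).
#' An animal is "problematic" for an indicator when it carries the highest
#' score of that indicator's scale.
#'
#' @return A data frame with one row per indicator and columns `name`,
#'   `n_levels` and `problematic_score` (always `n_levels - 1`).
#' @examples
#' indicator_definitions()
#' @export
indicator_definitions <- function() {
  defs <- data.frame(
    name = c("tail_lesions", "faecal_soiling", "skin_lesions",
             "ear_lesions", "lameness", "runts"),
    n_levels = c(2L, 3L, 3L, 2L, 2L, 2L),
    stringsAsFactors = FALSE
  )
  defs$problematic_score <- defs$n_levels - 1L
  defs
}

#' Collapse raw indicator scores to the binary normal/problematic coding
#'
#' Three-level indicators (skin lesions, faecal soiling) map scores 0 and 1
#' to normal (0) and score 2 to problematic (1); two-level indicators pass
#' through unchanged. The result is the 0/1 indicator-state coding used by
#' [generate_herd()] and the estimators.
#'
#' @param scores Data frame of raw per-animal scores. Any columns whose names
#'   match an indicator in `definitions` are recoded; other columns (ids,
#'   room, pen) pass through untouched.
#' @param definitions Indicator definition table, by default
#'   [indicator_definitions()].
#' @return `scores` with each indicator column recoded to integer 0/1.
#' @examples
#' raw <- data.frame(animal_id = 1:3, skin_lesions = c(0, 1, 2),
#'                   tail_lesions = c(0, 1, 0))
#' binarize_scores(raw)
#' @export
binarize_scores <- function(scores, definitions = indicator_definitions()) {
  stopifnot(is.data.frame(scores))
  for (j in seq_len(nrow(definitions))) {
    ind <- definitions$name[j]
    if (!ind %in% names(scores)) next
    x <- scores[[ind]]
    bad <- which(!(x %in% 0:(definitions$n_levels[j] - 1L)))
    if (length(bad)) {
      who <- if ("animal_id" %in% names(scores))
        scores$animal_id[bad[1]] else bad[1]
      stop(sprintf(
        "score %s out of scale for indicator '%s' (animal %s); allowed 0..%d",
        format(x[bad[1]]), ind, format(who), definitions$n_levels[j] - 1L))
    }
    scores[[ind]] <- as.integer(x == definitions$problematic_score[j])
  }
  scores
}
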