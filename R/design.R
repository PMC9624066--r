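#' Canonical design vocabulary
#'
#' The stimulus design crossed 5 object categories with 5 object identities
#' and 5 viewing conditions (size/rotation variations), giving 125 distinct
#' experimental conditions.  These constants fix the canonical ordering used
#' throughout the package: conditions are sorted by category, then identity,
#' then variation, and `condition_id` runs 1..125 in that order.
#'
#' @format Character vectors.
#' @name design_vocabulary
NULL

#' @rdname design_vocabulary
#' @export
nf_categories <- c("animal", "chair", "face", "fruit", "vehicle")

#' @rdname design_vocabulary
#' @export
nf_variations <- c("v1", "v2", "v3", "v4", "v5")

## Human-readable description of each viewing condition (visual angle / depth
## rotation); v1 is the reference condition used for training in the
## invariance schemes.
#' @rdname design_vocabulary
#' @export
nf_variation_labels <- c(
  v1 = "3deg/0deg", v2 = "3deg/45deg", v3 = "3deg/90deg",
  v4 = "1.5deg/0deg", v5 = "6deg/0deg"
)

#' @rdname design_vocabulary
#' @export
nf_rois <- c("O-Inf", "T-LFus", "T-MLing", "T-MTPhip", "T-IT", "T-Pole")

#' Build a condition table for the object-vision design
#'
#' Enumerates every (category, identity, variation, repetition) cell of the
#' factorial design, one row per trial.  Under the default 5 x 5 x 5 design
#' there are 125 distinct conditions; `condition_id` indexes the distinct
#' (category, identity, variation) triples in the canonical order (category,
#' then identity, then variation).
#'
#' @param n_categories Number of object categories (<= 5; named from
#'   [nf_categories]).
#' @param n_identities Number of object identities per category.
#' @param n_variations Number of viewing conditions (<= 5; named from
#'   [nf_variations]).
#' @param n_repetitions Number of repetitions of each condition.
#' @param n_runs Optional number of acquisition runs.  When given,
#'   `n_repetitions` must be a multiple of `n_runs` and repetitions are dealt
#'   to runs in order (with one repetition per run this reproduces the
#'   fMRI-style design in which every condition appears once per run).
#'
#' @return A `data.frame` of class `condition_table` with columns
#'   `condition_id`, `category`, `identity`, `variation`, `repetition` and,
#'   if `n_runs` was given, `run`.  Rows are ordered by category, identity,
#'   variation, repetition.
#'
#' @examples
#' d <- make_design(5, 5, 5, n_repetitions = 2)
#' nrow(d)                      # 250
#' length(unique(d$condition_id))  # 125
#' @export
make_design <- function(n_categories = 5, n_identities = 5, n_variations = 5,
                        n_repetitions = 1, n_runs = NULL) {
  counts <- c(n_categories = n_categories, n_identities = n_identities,
              n_variations = n_variations, n_repetitions = n_repetitions)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("all design counts must be positive integers")
  }
  if (n_categories > length(nf_categories)) {
    stop("at most ", length(nf_categories), " categories are defined")
  }
  if (n_variations > length(nf_variations)) {
    stop("at most ", length(nf_variations), " variations are defined")
  }
  cats <- nf_categories[seq_len(n_categories)]
  vars <- nf_variations[seq_len(n_variations)]

  conds <- expand.grid(
    variation = vars, identity = seq_len(n_identities), category = cats,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("category", "identity", "variation")]
  conds <- conds[order(match(conds$category, cats), conds$identity,
                       match(conds$variation, vars)), , drop = FALSE]
  conds$condition_id <- seq_len(nrow(conds))

  tab <- conds[rep(seq_len(nrow(conds)), each = n_repetitions), , drop = FALSE]
  tab$repetition <- rep(seq_len(n_repetitions), times = nrow(conds))
  if (!is.null(n_runs)) {
    if (n_runs < 1 || n_runs != round(n_runs)) stop("n_runs must be a positive integer")
    if (n_repetitions %% n_runs != 0) {
      stop("n_repetitions must be a multiple of n_runs")
    }
    tab$run <- ((tab$repetition - 1L) %% n_runs) + 1L
  }
  rownames(tab) <- NULL
  tab <- tab[, c("condition_id", "category", "identity", "variation",
                 "repetition", if (!is.null(n_runs)) "run")]
  class(tab) <- c("condition_table", "data.frame")
  tab
}

#' Canonical condition ordering of a condition table
#'
#' @param design A `condition_table`.
#' @return Integer vector of the distinct `condition_id`s in canonical order.
#' @export
condition_order <- function(design) {
  sort(unique(design$condition_id))
}
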