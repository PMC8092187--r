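#' @include stopsignal-package.R
NULL

# Stimulus inventory: 8 low-poly pictograms, 4 per category, colour-balanced
# within category (2 red / 2 brown each).
.STIMULI <- data.frame(
  stimulus_id       = c("french_fries", "pizza", "donut", "cake",
                        "glove", "scissors", "wooden_hammer", "chopping_board"),
  stimulus_category = rep(c("food", "control"), each = 4L),
  color             = c("red", "red", "brown", "brown",
                        "red", "red", "brown", "brown"),
  stringsAsFactors  = FALSE
)

#' Stimulus inventory used by the session designer
#'
#' Eight stimuli, four per category (`food`, `control`), each category
#' colour-balanced between `red` and `brown` targets.
#'
#' @return A data.frame with columns `stimulus_id`, `stimulus_category`,
#'   `color`.
#' @export
sst_stimuli <- function() .STIMULI

#' Generate a randomized stop-signal session design
#'
#' Builds the trial list for one session of the adaptive stop-signal task: a
#' 2-alternative colour classification (go trials) with a minority of stop
#' trials. Stop trials are split equally across stimulus categories so that
#' each category supports its own staircase and SSRT estimate; stimulus
#' identities are balanced exactly; the whole sequence is then uniformly
#' shuffled.
#'
#' @param n_trials Total number of trials (default 256). Must be divisible by
#'   the number of categories and by the stimuli per category.
#' @param p_stop Proportion of stop trials (default 0.25). `n_trials * p_stop`
#'   must be a whole number; stop trials are split across categories as
#'   evenly as possible (exactly at the defaults: 32 per category).
#' @param categories Character vector of stimulus categories to include
#'   (default `c("food", "control")`); must be a subset of the inventory.
#' @param seed Integer seed for the shuffle; identical seeds give identical
#'   designs. `NULL` uses the ambient RNG state.
#' @param color_key_map Named character vector mapping colour to response key;
#'   default `c(red = "left", brown = "right")`. Must be a bijection onto
#'   `c("left", "right")`.
#'
#' @return A data.frame of trial specifications with columns `index` (0-based),
#'   `trial_type` (`"go"`/`"stop"`), `stimulus_id`, `stimulus_category`,
#'   `color`, `correct_key`.
#' @examples
#' d <- generate_design(seed = 1)
#' table(d$trial_type)
#' @export
generate_design <- function(n_trials = 256L, p_stop = 0.25,
                            categories = c("food", "control"),
                            seed = NULL,
                            color_key_map = c(red = "left", brown = "right")) {
  categories <- unique(as.character(categories))
  if (length(categories) == 0L)
    stop("`categories` must contain at least one stimulus category",
         call. = FALSE)
  unknown <- setdiff(categories, unique(.STIMULI$stimulus_category))
  if (length(unknown))
    stop("unknown stimulus categories: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1)
    stop("`n_trials` must be a positive count", call. = FALSE)
  n_trials <- as.integer(n_trials)
  n_stop <- n_trials * p_stop
  if (abs(n_stop - round(n_stop)) > 1e-9)
    stop("n_trials * p_stop must be a whole number of stop trials",
         call. = FALSE)
  n_stop <- as.integer(round(n_stop))
  k <- length(categories)
  if (n_trials %% k != 0L)
    stop("`n_trials` must be divisible by the number of categories",
         call. = FALSE)
  if (!setequal(names(color_key_map), c("red", "brown")) ||
      !setequal(unname(color_key_map), c("left", "right")))
    stop("`color_key_map` must map {red, brown} one-to-one onto {left, right}",
         call. = FALSE)

  per_cat <- n_trials %/% k
  # stop trials split as evenly as possible (exact at defaults: 32/32); a
  # remainder goes to the first categories in the order given
  stop_per_cat <- rep(n_stop %/% k, k) + (seq_len(k) <= n_stop %% k)

  build_category <- function(cat, stop_per_cat) {
    stim <- .STIMULI[.STIMULI$stimulus_category == cat, , drop = FALSE]
    m <- nrow(stim)
    # exact balance of stimulus identity: spread trials (and stop trials)
    # across the m stimuli as evenly as possible, round-robin
    n_each <- rep(per_cat %/% m, m) + (seq_len(m) <= per_cat %% m)
    s_each <- rep(stop_per_cat %/% m, m) + (seq_len(m) <= stop_per_cat %% m)
    rows <- rep(seq_len(m), times = n_each)
    is_stop <- unlist(lapply(seq_len(m), function(i)
      rep(c(TRUE, FALSE), c(s_each[i], n_each[i] - s_each[i]))))
    data.frame(
      trial_type        = ifelse(is_stop, "stop", "go"),
      stimulus_id       = stim$stimulus_id[rows],
      stimulus_category = cat,
      color             = stim$color[rows],
      stringsAsFactors  = FALSE
    )
  }

  design <- do.call(rbind, Map(build_category, categories, stop_per_cat))
  perm <- with_seed(seed, sample.int(nrow(design)))
  design <- design[perm, , drop = FALSE]
  design$correct_key <- unname(color_key_map[design$color])
  design <- cbind(index = seq_len(nrow(design)) - 1L, design)
  rownames(design) <- NULL
  design
}

#' Create a per-category stop-signal delay staircase
#'
#' The SSD staircase implements 1-up/1-down tracking: a successful stop raises
#' the SSD by one step (harder), a failed or premature stop lowers it
#' (easier), clamped to `[floor_ms, ceiling_ms]`. One SSD is tracked per
#' stimulus category.
#'
#' @param categories Character vector of category names.
#' @param start_ms Initial SSD in ms (default 200).
#' @param step_ms Step size in ms (default 50).
#' @param floor_ms Minimum SSD in ms (default 50).
#' @param ceiling_ms Maximum SSD in ms (default 900).
#' @return An object of class `staircase_state`.
#' @examples
#' st <- new_staircase()
#' st <- staircase_update(st, "food", stop_succeeded = TRUE)
#' st$ssd_ms[["food"]]  # 250
#' @export
new_staircase <- function(categories = c("food", "control"),
                          start_ms = 200, step_ms = 50,
                          floor_ms = 50, ceiling_ms = 900) {
  if (floor_ms > ceiling_ms)
    stop("`floor_ms` must not exceed `ceiling_ms`", call. = FALSE)
  if (start_ms < floor_ms || start_ms > ceiling_ms)
    stop("`start_ms` must lie in [floor_ms, ceiling_ms]", call. = FALSE)
  ssd <- stats::setNames(rep(as.numeric(start_ms), length(categories)),
                         categories)
  structure(list(ssd_ms = ssd, step_ms = as.numeric(step_ms),
                 floor_ms = as.numeric(floor_ms),
                 ceiling_ms = as.numeric(ceiling_ms)),
            class = "staircase_state")
}

#' Update a staircase after a stop trial
#'
#' @param state A `staircase_state`.
#' @param category Stimulus category of the stop trial just run.
#' @param stop_succeeded `TRUE` if the response was withheld, `FALSE` if the
#'   participant responded (including premature responses before the signal).
#' @return The updated `staircase_state`; other categories are untouched.
#' @export
staircase_update <- function(state, category, stop_succeeded) {
  stopifnot(inherits(state, "staircase_state"))
  if (!category %in% names(state$ssd_ms))
    stop("unknown category: ", category, call. = FALSE)
  delta <- if (isTRUE(stop_succeeded)) state$step_ms else -state$step_ms
  state$ssd_ms[[category]] <- min(state$ceiling_ms,
                                  max(state$floor_ms,
                                      state$ssd_ms[[category]] + delta))
  state
}

#' @export
print.staircase_state <- function(x, ...) {
  cat("SSD staircase (step", x$step_ms, "ms, range [",
      x$floor_ms, ",", x$ceiling_ms, "] ms)\n")
  print(x$ssd_ms)
  invisible(x)
}

# run `expr` under a temporary seed, restoring the ambient RNG state;
# seed = NULL draws from the ambient stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
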