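#' Trial design configuration
#'
#' Parameters of a single-run episodic recall design: a cued-recall block in
#' which every memory class repeats a fixed number of times with no class
#' shown twice in a row, a rest gap, and a free-recall block whose class
#' labels are chosen by the participant. Defaults reproduce the study design
#' this package simulates: 3 memory classes, 7 cued repetitions each
#' (21 cued trials) and 30 free-recall trials, with onsets spaced
#' `inter_trial_volumes` apart and a `rest_gap_volumes` pause between blocks.
#'
#' @param n_classes Number of memory classes (>= 2).
#' @param cued_reps_per_class Cued repetitions of each class (>= 1).
#' @param free_trials Number of free-recall trials (>= `n_classes`, so every
#'   class can occur at least once).
#' @param inter_trial_volumes Onset-to-onset spacing within a block, in
#'   volumes (default 4, i.e. 14 s at TR = 3.5 s).
#' @param rest_gap_volumes Gap between the cued and free blocks, in volumes
#'   (default 9, i.e. ~30 s at TR = 3.5 s).
#' @param seed Integer seed controlling the pseudorandom trial orders.
#' @return A `design_config` list.
#' @seealso [generate_trial_design()]
#' @export
design_config <- function(n_classes = 3, cued_reps_per_class = 7,
                          free_trials = 30, inter_trial_volumes = 4,
                          rest_gap_volumes = 9, seed = 1L) {
  cfg <- list(
    n_classes = check_count(n_classes, "n_classes", min = 2L),
    cued_reps_per_class = check_count(cued_reps_per_class,
                                      "cued_reps_per_class"),
    free_trials = check_count(free_trials, "free_trials"),
    inter_trial_volumes = check_count(inter_trial_volumes,
                                      "inter_trial_volumes"),
    rest_gap_volumes = check_count(rest_gap_volumes, "rest_gap_volumes"),
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  )
  if (cfg$free_trials < cfg$n_classes) {
    abort("`free_trials` must be >= `n_classes` so every class can occur")
  }
  structure(cfg, class = "design_config")
}

# A no-adjacent-repeat arrangement of counts `rem` (with the first element
# forbidden to equal `prev`) exists iff max(rem) <= ceil(s/2) and not
# (s odd and rem[prev] == ceil(s/2)).
no_repeat_feasible <- function(rem, prev) {
  s <- sum(rem)
  if (s == 0L) return(TRUE)
  cap <- ceiling(s / 2)
  if (max(rem) > cap) return(FALSE)
  !(prev > 0L && s %% 2L == 1L && rem[prev] == cap)
}

# Pseudorandom sequence over classes with given per-class counts and no
# immediate repeats; greedy with a feasibility look-ahead, so it terminates
# for every feasible count vector.
sample_no_repeat_sequence <- function(counts) {
  n <- sum(counts)
  if (!no_repeat_feasible(counts, 0L)) {
    abort("no ordering without immediate repeats exists for these counts")
  }
  out <- integer(n)
  rem <- counts
  prev <- 0L
  for (i in seq_len(n)) {
    cand <- which(rem > 0L & seq_along(rem) != prev)
    cand <- cand[sample.int(length(cand))]
    picked <- FALSE
    for (c in cand) {
      rem2 <- rem
      rem2[c] <- rem2[c] - 1L
      if (no_repeat_feasible(rem2, c)) {
        out[i] <- c
        rem <- rem2
        prev <- c
        picked <- TRUE
        break
      }
    }
    if (!picked) abort("no ordering without immediate repeats exists")
  }
  out
}

#' Generate a single-run trial design
#'
#' Produces the ordered trial list for one functional run: first the cued
#' block (`n_classes * cued_reps_per_class` trials, classes in pseudorandom
#' order with no class repeated on consecutive trials), then a rest gap, then
#' the free-recall block (`free_trials` trials whose labels are drawn so that
#' every class occurs at least once). Onset volumes are 0-based.
#'
#' @param cfg A [design_config()].
#' @return A `trial_design`: a tibble with columns `onset_volume` (0-based),
#'   `condition` (`"cued"` or `"free"`) and `label` (1..`n_classes`), with
#'   attributes `n_volumes` and `n_classes`.
#' @examples
#' d <- generate_trial_design(design_config(seed = 7))
#' table(d$condition)
#' @export
generate_trial_design <- function(cfg = design_config()) {
  stopifnot(inherits(cfg, "design_config"))
  n_cued <- cfg$n_classes * cfg$cued_reps_per_class
  with_seed(cfg$seed, {
    cued_labels <- sample_no_repeat_sequence(
      rep(cfg$cued_reps_per_class, cfg$n_classes))
    # every class at least once, remainder uniform, block order shuffled
    extra <- cfg$free_trials - cfg$n_classes
    free_labels <- c(seq_len(cfg$n_classes),
                     if (extra > 0L) sample.int(cfg$n_classes, extra,
                                                replace = TRUE))
    free_labels <- free_labels[sample.int(cfg$free_trials)]
  })
  iti <- cfg$inter_trial_volumes
  cued_onsets <- (seq_len(n_cued) - 1L) * iti
  free_start <- n_cued * iti + cfg$rest_gap_volumes
  free_onsets <- free_start + (seq_len(cfg$free_trials) - 1L) * iti
  trials <- tibble(
    onset_volume = as.integer(c(cued_onsets, free_onsets)),
    condition = rep(c("cued", "free"), c(n_cued, cfg$free_trials)),
    label = as.integer(c(cued_labels, free_labels))
  )
  # tail pad leaves room for the hemodynamic shift plus the pattern window
  n_volumes <- max(trials$onset_volume) + iti + 6L
  new_trial_design(trials, n_volumes = n_volumes, n_classes = cfg$n_classes)
}

new_trial_design <- function(trials, n_volumes, n_classes) {
  stopifnot(all(diff(trials$onset_volume) > 0L))
  structure(trials,
            n_volumes = as.integer(n_volumes),
            n_classes = as.integer(n_classes),
            class = c("trial_design", class(trials)))
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("<trial_design: %d trials (%d cued, %d free), %d classes, %d volumes>\n",
              nrow(x), sum(x$condition == "cued"), sum(x$condition == "free"),
              attr(x, "n_classes"), attr(x, "n_volumes")))
  NextMethod()
}

#' Shift trial onsets for the hemodynamic delay
#'
#' The BOLD response lags the neural event; the analysis accounts for this by
#' shifting every trial onset forward by a fixed number of volumes before
#' patterns are extracted.
#'
#' @param design A `trial_design`.
#' @param delay_volumes Non-negative shift in volumes (default 2, i.e. 7 s at
#'   TR = 3.5 s).
#' @param window_volumes Pattern window length used downstream; shifting
#'   errors if any shifted onset plus this window would overrun the run.
#' @return The shifted `trial_design` (order and labels unchanged).
#' @export
shift_onsets <- function(design, delay_volumes = 2L, window_volumes = 1L) {
  stopifnot(inherits(design, "trial_design"))
  delay_volumes <- check_count(delay_volumes, "delay_volumes", min = 0L)
  window_volumes <- check_count(window_volumes, "window_volumes")
  n_volumes <- attr(design, "n_volumes")
  shifted <- design
  shifted$onset_volume <- design$onset_volume + delay_volumes
  if (any(shifted$onset_volume + window_volumes > n_volumes)) {
    abort(sprintf(
      "hemodynamic shift of %d pushes a trial window past the run end (%d volumes)",
      delay_volumes, n_volumes))
  }
  shifted
}
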