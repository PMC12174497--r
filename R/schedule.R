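#' Specify a pre/post-switch trial schedule
#'
#' A session is a sequence of runs of trials in which the relevant side (the
#' concealed centre of mass of the object, or the target button) alternates at
#' every switch. `n_sets` runs of each length in `run_lengths` precede a
#' switch ("pre-switch" runs); the trials immediately after each switch are
#' the "post-switch" trials. In the *matched* design the post-switch run has
#' the same length as the pre-switch run it follows; in the *unmatched* design
#' there is always exactly one post-switch trial per switch.
#'
#' With the defaults (`n_sets = 5`, `run_lengths = c(1, 3, 5)`) the matched
#' design has 91 trials (45 pre-switch + 46 post-switch, the extra post-switch
#' trial being the session-initial lift, which follows no run) and the
#' unmatched design has 60 trials (45 pre-switch + 15 post-switch).
#'
#' @param design `"matched"` or `"unmatched"`.
#' @param n_sets Number of pre-switch runs of each length. Default 5.
#' @param run_lengths Integer vector of pre-switch run lengths. Default
#'   `c(1, 3, 5)`.
#' @param start_side `"left"` or `"right"`: side of the session-initial
#'   context.
#' @param seed Integer seed controlling the shuffled order of run lengths
#'   within the session.
#' @return An object of class `schedule_spec`.
#' @export
schedule_spec <- function(design = c("matched", "unmatched"), n_sets = 5L,
                          run_lengths = c(1L, 3L, 5L),
                          start_side = c("left", "right"), seed = 1L) {
  design <- match.arg(design)
  start_side <- match.arg(start_side)
  if (length(n_sets) != 1L || !is.finite(n_sets) || n_sets < 1 ||
      n_sets != round(n_sets)) {
    stop("schedule_spec: `n_sets` must be a single positive integer",
         call. = FALSE)
  }
  if (length(run_lengths) < 1L || any(!is.finite(run_lengths)) ||
      any(run_lengths < 1) || any(run_lengths != round(run_lengths))) {
    stop("schedule_spec: `run_lengths` must be positive integers",
         call. = FALSE)
  }
  structure(
    list(design = design, n_sets = as.integer(n_sets),
         run_lengths = as.integer(run_lengths), start_side = start_side,
         seed = as.integer(seed)),
    class = "schedule_spec"
  )
}

other_side <- function(side) ifelse(side == "left", "right", "left")

#' Build the ordered trial plan for a session
#'
#' Expands a [schedule_spec()] into one row per trial. The session opens with
#' a single novel trial on `start_side`, labelled post-switch (it follows no
#' pre-switch run; `run_length` is `NA`) -- present only in the matched
#' design, whose printed totals (45 pre + 46 post) require it. Each
#' subsequent pre-switch run continues on the side established by the
#' preceding switch; the side then flips for its post-switch trials.
#'
#' @param spec A [schedule_spec()].
#' @return A tibble with columns `trial_index`, `side`, `phase`
#'   (`"pre_switch"`/`"post_switch"`), `run_length` (length of the pre-switch
#'   run the trial belongs to or follows; `NA` for the session-initial
#'   trial), and `position_in_run`.
#' @examples
#' sched <- build_schedule(schedule_spec("matched"))
#' table(sched$phase)  # 45 pre_switch, 46 post_switch
#' @export
build_schedule <- function(spec) {
  stopifnot(inherits(spec, "schedule_spec"))
  lengths_pool <- rep(spec$run_lengths, each = spec$n_sets)
  order_idx <- withr_seed(spec$seed, sample.int(length(lengths_pool)))
  lengths_seq <- lengths_pool[order_idx]

  n_runs <- length(lengths_seq)
  # each switch flips the context side; the pre-switch run after a switch
  # continues on the side the switch established, so pre-run sides alternate
  pre_sides <- rep_len(c(spec$start_side, other_side(spec$start_side)),
                       n_runs)
  post_sides <- other_side(pre_sides)
  post_len <- if (spec$design == "matched") lengths_seq else
    rep(1L, n_runs)

  block_len <- as.vector(rbind(lengths_seq, post_len))
  side <- rep(as.vector(rbind(pre_sides, post_sides)), block_len)
  phase <- rep(rep(c("pre_switch", "post_switch"), n_runs), block_len)
  run_length <- rep(rep(lengths_seq, each = 2L), block_len)
  position_in_run <- sequence(block_len)
  if (spec$design == "matched") {
    # session-initial novel trial: post-switch by label, no preceding run
    side <- c(spec$start_side, side)
    phase <- c("post_switch", phase)
    run_length <- c(NA_integer_, run_length)
    position_in_run <- c(1L, position_in_run)
  }
  tibble::tibble(trial_index = seq_along(side), side = side,
                 phase = phase, run_length = run_length,
                 position_in_run = position_in_run)
}

#' Label the first post-switch trial of every switch with its preceding
#' run length
#'
#' Performance on the trial immediately following a switch carries the
#' repetition-interference signature; this helper extracts those trials and
#' the length of the pre-switch run that preceded them. The session-initial
#' trial (no preceding run) is excluded.
#'
#' @param plans Tibble from [build_schedule()].
#' @return Tibble with columns `trial_index`, `side`, `run_length`.
#' @export
label_post_switch_trials <- function(plans) {
  stopifnot(is.data.frame(plans), all(c("phase", "run_length",
                                        "position_in_run") %in% names(plans)))
  out <- plans[plans$phase == "post_switch" & plans$position_in_run == 1L &
                 !is.na(plans$run_length),
               c("trial_index", "side", "run_length")]
  if (nrow(out) == 0L) {
    warning("label_post_switch_trials: schedule contains no switch",
            call. = FALSE)
  }
  tibble::as_tibble(out)
}

#' Write a schedule as TSV
#' @param plans Tibble from [build_schedule()].
#' @param path Output file.
#' @export
write_schedule_tsv <- function(plans, path) {
  utils::write.table(plans, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# run `expr` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
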