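# Timing constants for the block design (seconds). One TR = 2.7 s; every
# event duration is an integer number of TRs so the whole schedule sits on
# the TR grid.
TR_SECONDS <- 2.7
VIDEO_SECONDS <- 5.4
RESPONSE_SECONDS <- 2.7
INSTRUCTION_SECONDS <- 2.7
FIXATION_SECONDS <- 5.4
BALL_ONSETS <- c(0, 1.2, 2.4, 3.6)

BLOCK_LABELS <- c("1-action", "3-actions", "1-ball", "3-balls")

#' Enumerate the full factorial stimulus space
#'
#' Builds the complete crossing of the six stimulus factors: actor gender,
#' majority action (the act performed three times out of four), majority
#' ball colour, actor position in the visual field, and the order variant
#' (1-3) for actions and for balls. The order variant places the single
#' minority event at serial position 1, 2 or 3 of the four events.
#'
#' @return A data frame with one row per video (144 rows) and columns
#'   `video_id`, `actor_gender`, `action_majority`, `ball_majority`,
#'   `actor_position`, `action_order_variant`, `ball_order_variant`,
#'   `action_labels`, `ball_labels`. The label columns hold the ordered
#'   4-tuples as comma-separated strings.
#' @export
#' @examples
#' v <- enumerate_videos()
#' nrow(v)  # 144
enumerate_videos <- function() {
  grid <- expand.grid(
    ball_order_variant = 1:3,
    action_order_variant = 1:3,
    actor_position = c("right", "left"),
    ball_majority = c("white", "orange"),
    action_majority = c("push", "flick"),
    actor_gender = c("male", "female"),
    stringsAsFactors = FALSE
  )
  grid <- grid[, rev(names(grid))]
  grid$video_id <- seq_len(nrow(grid))
  grid$action_labels <- mapply(order_tuple,
                               grid$action_majority, grid$action_order_variant,
                               MoreArgs = list(levels = c("push", "flick")))
  grid$ball_labels <- mapply(order_tuple,
                             grid$ball_majority, grid$ball_order_variant,
                             MoreArgs = list(levels = c("white", "orange")))
  rownames(grid) <- NULL
  grid[, c("video_id", "actor_gender", "action_majority", "ball_majority",
           "actor_position", "action_order_variant", "ball_order_variant",
           "action_labels", "ball_labels")]
}

# 4-tuple with the minority level at serial position `variant` (1-3) and the
# majority level elsewhere, as a comma-separated string.
order_tuple <- function(majority, variant, levels) {
  minority <- setdiff(levels, majority)
  tup <- rep(majority, 4L)
  tup[variant] <- minority
  paste(tup, collapse = ",")
}

#' Select a balanced half-fraction of the factorial video set
#'
#' Picks `size` videos (default 72) from the full 144-video factorial so
#' that each level of the four binary factors (gender, majority action,
#' majority ball colour, actor position) appears in exactly half of the
#' subset. The subset is chosen constructively: the 144 videos form 16
#' cells of the binary factors (9 videos each, one per order-variant
#' combination); cells whose factor-bit parity matches a seeded bit
#' contribute ceiling(size/16) videos and the rest floor(size/16), which
#' makes every binary marginal exactly size/2 for any seed. Within a cell
#' the videos are sampled under the seed.
#'
#' @param videos Data frame from [enumerate_videos()].
#' @param seed Integer seed; different seeds give different (always
#'   balanced) subsets.
#' @param size Subset size; must satisfy `size %% 8 == 0` and
#'   `size/16 <= 8` so the per-cell quota is feasible.
#' @return Data frame of `size` rows, same columns as the input.
#' @export
select_balanced_subset <- function(videos, seed, size = 72L) {
  if (nrow(videos) != 144L)
    stop("`videos` must be the full 144-video factorial set")
  size <- as.integer(size)
  if (size <= 0L || size %% 8L != 0L || size > 144L)
    stop("balance constraints unsatisfiable for subset size ", size)
  lo <- size %/% 16L
  rem <- size - 16L * lo            # 0 or 8 given size %% 8 == 0
  if (!rem %in% c(0L, 8L) || lo + (rem > 0L) > 9L)
    stop("balance constraints unsatisfiable for subset size ", size)

  rng <- local_rng(seed)
  bits <- cbind(
    as.integer(videos$actor_gender == "male"),
    as.integer(videos$action_majority == "push"),
    as.integer(videos$ball_majority == "white"),
    as.integer(videos$actor_position == "right")
  )
  cell <- bits %*% c(1L, 2L, 4L, 8L)          # 0..15
  parity <- rowSums(bits) %% 2L
  hi_parity <- if (rem > 0L) sample(0:1, 1L) else -1L

  keep <- integer(0)
  for (cl in 0:15) {
    idx <- which(cell == cl)
    n_take <- lo + as.integer(parity[idx[1L]] == hi_parity)
    if (n_take > 0L)
      keep <- c(keep, sample(idx, n_take))
  }
  out <- videos[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All seeded entry points go through here so seed handling is uniform.
local_rng <- function(seed) {
  set.seed(as.integer(seed))
  invisible(NULL)
}

#' Build a counterbalanced nine-run session
#'
#' Partitions 72 balanced videos into 9 runs of 8 and lays out each run as
#' four cycles of one fixation trial (announced by a "random" instruction)
#' plus the four discrimination blocks, two trials per block. Within a run
#' the 8 videos are grouped into 4 pairs and a Latin-square rotation assigns
#' each pair to each block label exactly once across the four cycles, so
#' every video is shown once under every block label and the visual stimuli
#' are identical across attention conditions. Block positions within cycles
#' follow a seeded 4x4 Latin square, cyclically rotated across runs, so each
#' label occupies each within-cycle position exactly 9 times over the
#' session.
#'
#' @param videos72 Data frame of 72 videos from [select_balanced_subset()].
#' @param seed Integer seed controlling the partition, pairing and Latin
#'   squares.
#' @return List of 9 run schedules. Each is a list with `run_index`,
#'   `videos` (the run's 8 video ids) and `events`, a data frame with
#'   columns `onset`, `duration`, `kind`, `block_label`, `video_id`,
#'   `cycle`.
#' @export
build_session <- function(videos72, seed) {
  if (nrow(videos72) != 72L) stop("`videos72` must contain exactly 72 videos")
  rng <- local_rng(seed)

  run_of <- split(sample(videos72$video_id), rep(1:9, each = 8L))
  base_square <- latin_square_4(sample(4L))
  lapply(1:9, function(r) {
    vids <- run_of[[r]]
    pairs <- matrix(sample(vids), nrow = 4L, byrow = TRUE)  # 4 pairs x 2
    # label order per cycle: row = cycle, entries = block label index at
    # positions 1..4; rotate the base square's rows across runs
    square <- base_square[((0:3 + (r - 1L)) %% 4L) + 1L, , drop = FALSE]
    events <- list()
    t <- 0
    for (cy in 1:4) {
      # fixation trial: "random" instruction, fixation, response
      events[[length(events) + 1L]] <- data.frame(
        onset = t + c(0, INSTRUCTION_SECONDS,
                      INSTRUCTION_SECONDS + FIXATION_SECONDS),
        duration = c(INSTRUCTION_SECONDS, FIXATION_SECONDS, RESPONSE_SECONDS),
        kind = c("instruction", "fixation", "response"),
        block_label = "fixation",
        video_id = NA_integer_, cycle = cy,
        stringsAsFactors = FALSE)
      t <- t + INSTRUCTION_SECONDS + FIXATION_SECONDS + RESPONSE_SECONDS
      for (pos in 1:4) {
        lab_idx <- square[cy, pos]
        lab <- BLOCK_LABELS[lab_idx]
        # Latin rotation: pair assigned to this label in this cycle
        pair_idx <- ((lab_idx - 1L + (cy - 1L)) %% 4L) + 1L
        block_vids <- pairs[pair_idx, ]
        events[[length(events) + 1L]] <- data.frame(
          onset = t, duration = INSTRUCTION_SECONDS, kind = "instruction",
          block_label = lab, video_id = NA_integer_, cycle = cy,
          stringsAsFactors = FALSE)
        t <- t + INSTRUCTION_SECONDS
        for (tr in 1:2) {
          events[[length(events) + 1L]] <- data.frame(
            onset = t + c(0, VIDEO_SECONDS),
            duration = c(VIDEO_SECONDS, RESPONSE_SECONDS),
            kind = c("video", "response"),
            block_label = lab, video_id = block_vids[tr], cycle = cy,
            stringsAsFactors = FALSE)
          t <- t + VIDEO_SECONDS + RESPONSE_SECONDS
        }
      }
    }
    # trailing rest so the lag-shifted samples of the final trial are
    # still inside the acquired series
    events[[length(events) + 1L]] <- data.frame(
      onset = t, duration = FIXATION_SECONDS, kind = "fixation",
      block_label = "none", video_id = NA_integer_, cycle = NA_integer_,
      stringsAsFactors = FALSE)
    ev <- do.call(rbind, events)
    rownames(ev) <- NULL
    list(run_index = r, videos = sort(vids), events = ev)
  })
}

# Cyclic 4x4 Latin square over a permuted label set: row i, col j holds
# labels[((i + j - 2) %% 4) + 1].
latin_square_4 <- function(labels) {
  outer(0:3, 0:3, function(i, j) labels[((i + j) %% 4L) + 1L])
}

#' Number of TRs spanned by a run schedule
#' @param schedule One run schedule from [build_session()].
#' @return Integer number of TRs.
#' @export
schedule_n_tr <- function(schedule) {
  ev <- schedule$events
  as.integer(round((max(ev$onset + ev$duration)) / TR_SECONDS))
}

#' Write a run schedule as a BIDS-style events file
#'
#' Tab-delimited with columns `onset`, `duration`, `trial_type`,
#' `video_id`, `block_label`; onsets and durations in seconds.
#'
#' @param schedule One run schedule from [build_session()].
#' @param path Output file path.
#' @export
export_events <- function(schedule, path) {
  ev <- schedule$events
  out <- data.frame(onset = ev$onset, duration = ev$duration,
                    trial_type = ev$kind, video_id = ev$video_id,
                    block_label = ev$block_label)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events file written by [export_events()]
#' @param path Events TSV path.
#' @param run_index Run index to attach to the reconstructed schedule.
#' @return A run schedule list as produced by [build_session()] (without
#'   cycle bookkeeping).
#' @export
read_events <- function(path, run_index = NA_integer_) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  ev <- data.frame(onset = tab$onset, duration = tab$duration,
                   kind = tab$trial_type, block_label = tab$block_label,
                   video_id = tab$video_id, stringsAsFactors = FALSE)
  vids <- sort(unique(ev$video_id[!is.na(ev$video_id)]))
  list(run_index = run_index, videos = vids, events = ev)
}
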