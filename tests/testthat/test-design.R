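test_that("the full factorial enumerates 144 balanced videos", {
  v <- enumerate_videos()
  expect_equal(nrow(v), 144L)
  expect_equal(anyDuplicated(v$video_id), 0L)

  # fixing both order variants leaves the 2^4 binary crossing
  expect_equal(nrow(v[v$action_order_variant == 1 & v$ball_order_variant == 1, ]),
               16L)

  # full factorial balance: binary levels in half the rows, variants in a third
  for (f in c("actor_gender", "action_majority", "ball_majority",
              "actor_position"))
    expect_true(all(table(v[[f]]) == 72L))
  for (f in c("action_order_variant", "ball_order_variant"))
    expect_true(all(table(v[[f]]) == 48L))

  # each label tuple holds one minority and three majority events
  counts <- sapply(strsplit(v$action_labels, ","), function(x) table(factor(x, c("push", "flick"))))
  expect_true(all(sort(unique(as.vector(counts))) == c(1L, 3L)))
})

test_that("the balanced subset keeps every binary marginal at half, for any seed", {
  v <- enumerate_videos()
  for (seed in 1:5) {
    s <- select_balanced_subset(v, seed = seed)
    expect_equal(nrow(s), 72L)
    for (f in c("actor_gender", "action_majority", "ball_majority",
                "actor_position"))
      expect_true(all(table(s[[f]]) == 36L), label = paste(f, "seed", seed))
  }
  # seeds matter but balance never breaks
  s1 <- select_balanced_subset(v, seed = 1)
  s2 <- select_balanced_subset(v, seed = 2)
  expect_false(identical(s1$video_id, s2$video_id))

  expect_error(select_balanced_subset(v, seed = 1, size = 70),
               "unsatisfiable")
  expect_error(select_balanced_subset(v[1:100, ], seed = 1), "144")
})

test_that("session schedules satisfy the block-design invariants", {
  sess <- fixture_session()
  expect_length(sess, 9L)

  all_video_trials <- list()
  labels4 <- c("1-action", "3-actions", "1-ball", "3-balls")
  pos_counts <- matrix(0L, 4L, 4L, dimnames = list(labels4, NULL))
  for (run in sess) {
    ev <- run$events
    vids <- ev[ev$kind == "video", ]
    # 32 discrimination trials, 8 per block label, 4 fixation trials
    expect_equal(nrow(vids), 32L)
    expect_true(all(table(vids$block_label) == 8L))
    expect_equal(sum(ev$kind == "fixation" & ev$block_label == "fixation"), 4L)

    # every video appears once under each block label: identical stimuli
    # across attention conditions
    tab <- table(vids$video_id, vids$block_label)
    expect_true(all(tab == 1L))

    # TR grid alignment and contiguity
    expect_true(all(abs(round(ev$onset / 2.7) * 2.7 - ev$onset) < 1e-9))
    expect_true(all(abs(round(ev$duration / 2.7) * 2.7 - ev$duration) < 1e-9))
    o <- order(ev$onset)
    ends <- ev$onset[o] + ev$duration[o]
    expect_true(all(abs(ev$onset[o][-1] - ends[-length(ends)]) < 1e-9))
    expect_equal(ev$onset[o][1], 0)

    # within-cycle block positions for counterbalancing bookkeeping
    instr <- ev[ev$kind == "instruction" & ev$block_label != "fixation", ]
    for (cy in 1:4) {
      labs <- instr$block_label[instr$cycle == cy][order(instr$onset[instr$cycle == cy])]
      pos_counts[cbind(match(labs, rownames(pos_counts)), seq_along(labs))] <-
        pos_counts[cbind(match(labs, rownames(pos_counts)), seq_along(labs))] + 1L
    }
    all_video_trials[[run$run_index]] <- vids
  }

  # across the session: 72 trials per sub-condition
  all_vids <- do.call(rbind, all_video_trials)
  expect_true(all(table(all_vids$block_label) == 72L))
  # counterbalancing: each label occupies each within-cycle position
  # near-equally over the 9 runs
  expect_true(max(pos_counts) - min(pos_counts) <= 1L)

  expect_error(build_session(enumerate_videos()[1:10, ], seed = 1), "72")
})

test_that("events files round-trip through the BIDS-style TSV", {
  sess <- fixture_session()
  path <- withr::local_tempfile(fileext = ".tsv")
  export_events(sess[[3]], path)
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_setequal(header,
                  c("onset", "duration", "trial_type", "video_id", "block_label"))
  back <- read_events(path, run_index = 3L)
  expect_equal(back$events$onset, sess[[3]]$events$onset)
  expect_equal(back$events$kind, sess[[3]]$events$kind)
  expect_equal(back$events$block_label, sess[[3]]$events$block_label)
  expect_equal(back$events$video_id, sess[[3]]$events$video_id)
  expect_equal(back$videos, sess[[3]]$videos)
  expect_equal(back$events$onset[1], 0)
})
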