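# Shared fixtures, built once per test run. The session is the expensive
# shared object; everything else is cheap enough to build inline.

.fixtures <- new.env()

fixture_session <- function() {
  if (is.null(.fixtures$session)) {
    v72 <- select_balanced_subset(enumerate_videos(), seed = 11L)
    .fixtures$session <- build_session(v72, seed = 12L)
  }
  .fixtures$session
}

# A voxels x runs x 4 PSC array of pure noise (the null for the recoding).
null_psc <- function(n_vox, n_runs = 9L, sd = 1, seed = 1L) {
  set.seed(seed)
  array(rnorm(n_vox * n_runs * 4L, 0, sd), c(n_vox, n_runs, 4L),
        dimnames = list(NULL, NULL,
                        c("1-action", "3-actions", "1-ball", "3-balls")))
}

# Recoded matrices (voxels x 4) of pure noise for a set of subjects.
null_recoded <- function(n_vox, n_subjects, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n_subjects), function(s)
    matrix(rnorm(n_vox * 4L), n_vox, 4L,
           dimnames = list(NULL, c("PA", "nPA", "PB", "nPB"))))
}

# Small config for pipeline tests: 2 ROIs, few subjects, light nulls.
tiny_config <- function(seed = 5L) {
  cfg <- default_config(seed)
  cfg$n_subjects <- 4L
  cfg$n_shuffles <- 200L
  cfg$rois <- list(
    NPC3_L = list(n_voxels = 24L, mixture = c(0.6, 0.1, 0.15, 0.15)),
    phAIP_L = list(n_voxels = 20L, mixture = c(0.25, 0.25, 0.25, 0.25))
  )
  cfg
}
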