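# Shared scene fixtures, built in code. The "easy" regime (high contrast,
# calm sea, no glare) is the precondition for the detector tests; "hard"
# adds heavy wave texture and glare.

easy_scene <- function(seed, n_birds = 5, size = 512, gsd = 0.5) {
  skyfilter::generate_scene(skyfilter::scene_spec(
    size, size, gsd_cm = gsd, n_birds = n_birds, bird_contrast = 0.5,
    sea_state = 0.2, glare_fraction = 0, seed = seed))
}

hard_scene <- function(seed, n_birds = 5, size = 512, gsd = 0.5) {
  skyfilter::generate_scene(skyfilter::scene_spec(
    size, size, gsd_cm = gsd, n_birds = n_birds, bird_contrast = 0.5,
    sea_state = 1, glare_fraction = 0.1, seed = seed))
}

# A detector trained once and shared across tests (training is the slow
# part; memoised per test run). The training mix includes rough-water
# scenes so the classifier sees clutter negatives as well as birds, the
# way survey training sets include empty water patches.
shared_easy_classifier <- local({
  clf <- NULL
  function() {
    if (is.null(clf)) {
      train <- c(lapply(1:6, function(s) easy_scene(s, n_birds = 6)),
                 lapply(7:10, function(s) hard_scene(s, n_birds = 2)))
      clf <<- skyfilter::train_blob_detector(
        lapply(train, `[[`, "image"), lapply(train, `[[`, "gt_boxes"))
    }
    clf
  }
})
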