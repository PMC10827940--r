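# Small fixture builders shared across the suite. Everything is generated
# in code; nothing is read from disk.

tiny_caption_sets <- function() {
  list(
    caption_set("img1", c("this bird has a blue wing and a red head",
                          "a bird with a blue wing",
                          "the bird shows a red head"),
                true_class_id = "spA"),
    caption_set("img2", c("this bird has a white belly and a black tail",
                          "a bird with a black tail"),
                true_class_id = "spB")
  )
}

tiny_corpus <- function() {
  corpus(list(
    document("spA", c("the wing is blue.", "the head is red.",
                      "it forages at dawn and rests during midday.")),
    document("spB", c("the belly is white.", "the tail is black.",
                      "populations remain stable throughout the range."))
  ))
}

# Planted-token world: captions of one image share two unique tokens, so
# pair classification is Bayes-separable (accuracy 1 is attainable); used
# to test that stage-1 training actually learns.
planted_world <- function(n_images = 40L, captions_per_image = 5L,
                          seed = 1L) {
  withr::with_seed(seed, {
    lapply(seq_len(n_images), function(i) {
      tok <- sprintf("marker%03d", i)
      tok2 <- sprintf("ring%03d", i)
      caps <- vapply(seq_len(captions_per_image), function(j) {
        filler <- paste(sample(c("small", "plain", "quiet", "bright",
                                 "slender", "round", "pale", "gentle"),
                               2L), collapse = " ")
        sprintf("a %s bird with the %s mark and the %s band",
                filler, tok, tok2)
      }, character(1))
      caption_set(sprintf("img%03d", i), unique(caps))
    })
  })
}

# Fast low-dimensional configs so training-based tests stay quick.
fast_spec <- function(dim = 128L) encoder_spec(dim = dim)

fast_stage1_config <- function(epochs = 12L, seed = 0L)
  comparator_config(stage = 1L, phi_dims = c(64L, 32L), lr = 1e-3,
                    epochs = epochs, seed = seed)

fast_stage2_config <- function(epochs = 10L, seed = 0L, lambda_reg = 10)
  comparator_config(stage = 2L, phi_dims = c(64L, 32L, 16L), lr = 1e-3,
                    lambda_reg = lambda_reg, epochs = epochs, seed = seed)
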