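# Synthetic attribute worlds. Each species is a latent signature assigning
# one color to each body part; layperson captions render a noisy subset of
# the signature through fixed templates, and expert documents mix reworded
# visual sentences (optionally in jargon vocabulary) with non-visual filler
# about habitat and behavior. The generator emulates the conditions the
# matching pipeline faces on real data -- multiple noisy captions per image,
# a domain gap between caption and document style, maskable species names --
# while staying a deterministic string grammar, so every stage of the
# pipeline is testable offline and reproducible from a seed.

.part_jargon <- c(wing = "remiges", belly = "abdomen", head = "cranium",
                  beak = "mandible", tail = "rectrices")
.color_jargon <- c(red = "crimson", blue = "azure", yellow = "ochre",
                   green = "viridian", black = "ebony", white = "ivory",
                   brown = "umber", orange = "rufous")

.caption_templates <- c("this bird has %s.", "a bird with %s.",
                        "the bird shows %s.", "it has %s.",
                        "you can see %s here.")
.filler_templates <- c(
  "it nests in dense shrubland near quiet rivers.",
  "the species migrates across open plains in autumn.",
  "populations remain stable throughout the range.",
  "it forages at dawn and rests during midday.",
  "breeding occurs in late spring in sheltered meadows.",
  "it prefers wetlands and mixed woodland in winter.",
  "pairs defend a small territory around the nest.",
  "it is most vocal in the early morning."
)

.genus_syllables <- c("Lar", "Cor", "Pas", "Tur", "Sit", "Mer", "Cya",
                      "Pica", "Falco", "Strix", "Plu", "Mona", "Rega",
                      "Tanga", "Vire")
.genus_suffixes <- c("us", "a", "or", "ix", "on", "ella")
.epithets <- c("montana", "sylvatica", "borealis", "australis", "minor",
               "major", "elegans", "punctata", "striata", "palustris",
               "littoralis", "vulgaris", "cristata", "modesta", "serena")

#' Synthetic world configuration
#'
#' Defaults describe the standard benchmark world: 5 body parts x 8 colors
#' (so up to `8^5` distinct species signatures), 5 images per species with 5
#' captions each mentioning 2 parts, 10% attribute dropout, a mild
#' blue/black color confusion (the classic layperson confusion), documents
#' of 12 sentences with 40% non-visual filler, and jargon vocabulary on 25%
#' of visual document sentences.
#'
#' @param K number of species.
#' @param parts part nouns.
#' @param colors color adjectives (must have jargon synonyms when
#'   `jargon_rate > 0`; the built-in palette does).
#' @param images_per_species,captions_per_image,parts_per_caption caption
#'   generation sizes.
#' @param attribute_dropout probability a mentioned part is dropped from a
#'   caption.
#' @param color_confusion named list: `color -> named probabilities` of
#'   swapping to another color (e.g. `list(blue = c(black = 0.15))`).
#'   `list()` means no confusion.
#' @param jargon_rate probability a visual document sentence uses the
#'   jargon lexicon instead of the caption vocabulary.
#' @param filler_fraction fraction of document sentences that are
#'   non-visual filler, in `[0, 1)`.
#' @param doc_sentences sentences per document.
#' @param seed master seed; every generated artifact is a pure function of
#'   the config including this seed.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(K = 10L,
                         parts = c("wing", "belly", "head", "beak", "tail"),
                         colors = c("red", "blue", "yellow", "green",
                                    "black", "white", "brown", "orange"),
                         images_per_species = 5L, captions_per_image = 5L,
                         parts_per_caption = 2L, attribute_dropout = 0.1,
                         color_confusion = list(blue = c(black = 0.15),
                                                black = c(blue = 0.15)),
                         jargon_rate = 0.25, filler_fraction = 0.4,
                         doc_sentences = 12L, seed = 0L) {
  K <- as.integer(K)
  if (K > length(colors)^length(parts))
    stop_sm("K = ", K, " exceeds the number of distinct signatures ",
            length(colors)^length(parts))
  stopifnot(attribute_dropout >= 0, attribute_dropout <= 1,
            jargon_rate >= 0, jargon_rate <= 1,
            filler_fraction >= 0, filler_fraction < 1,
            parts_per_caption >= 1L, parts_per_caption <= length(parts))
  for (probs in color_confusion)
    stopifnot(all(probs >= 0), sum(probs) <= 1)
  structure(list(K = K, parts = parts, colors = colors,
                 images_per_species = as.integer(images_per_species),
                 captions_per_image = as.integer(captions_per_image),
                 parts_per_caption = as.integer(parts_per_caption),
                 attribute_dropout = attribute_dropout,
                 color_confusion = color_confusion,
                 jargon_rate = jargon_rate,
                 filler_fraction = filler_fraction,
                 doc_sentences = as.integer(doc_sentences),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate the latent species of a world
#'
#' Samples `K` distinct part -> color signatures without replacement and a
#' unique binomial-style display name per species (used to exercise
#' class-name masking).
#'
#' @param config a [synth_config()].
#' @return list of `species_spec` objects with fields `class_id`,
#'   `signature` (named character: part -> color) and `name`.
#' @export
generate_species <- function(config) {
  np <- length(config$parts); ncol_ <- length(config$colors)
  with_seed(config$seed, {
    idx <- sample.int(ncol_^np, config$K) - 1L
    names_pool <- character(0)
    lapply(seq_len(config$K), function(i) {
      digits <- integer(np)
      v <- idx[i]
      for (p in seq_len(np)) {
        digits[p] <- v %% ncol_
        v <- v %/% ncol_
      }
      sig <- config$colors[digits + 1L]
      names(sig) <- config$parts
      repeat {
        nm <- paste0(sample(.genus_syllables, 1L),
                     sample(.genus_suffixes, 1L), " ",
                     sample(.epithets, 1L))
        if (!nm %in% names_pool) break
      }
      names_pool <<- c(names_pool, nm)
      structure(list(class_id = sprintf("sp%03d", i), signature = sig,
                     name = nm),
                class = "species_spec")
    })
  })
}

.render_listing <- function(colors, parts) {
  paste(paste0("a ", colors, " ", parts), collapse = " and ")
}

.confuse_color <- function(color, confusion) {
  probs <- confusion[[color]]
  if (is.null(probs) || !length(probs)) return(color)
  u <- stats::runif(1)
  acc <- 0
  for (j in seq_along(probs)) {
    acc <- acc + probs[[j]]
    if (u < acc) return(names(probs)[j])
  }
  color
}

#' Generate layperson caption sets
#'
#' Per image, `captions_per_image` template sentences each mentioning
#' `parts_per_caption` parts of the species signature; with probability
#' `attribute_dropout` a mentioned part is dropped (at least one always
#' survives), and colors are swapped per the confusion matrix. With zero
#' noise every (part, color) mention is signature-consistent.
#'
#' @param species list from [generate_species()].
#' @param config a [synth_config()].
#' @return list of [caption_set()] with `true_class_id` filled in.
#' @export
generate_captions <- function(species, config) {
  with_seed(config$seed + 1L, {
    out <- list()
    for (sp in species) {
      for (img in seq_len(config$images_per_species)) {
        image_id <- sprintf("%s_img%02d", sp$class_id, img)
        caps <- vapply(seq_len(config$captions_per_image), function(ci) {
          chosen <- sample(config$parts, config$parts_per_caption)
          keep <- stats::runif(length(chosen)) >= config$attribute_dropout
          if (!any(keep)) keep[1L] <- TRUE
          chosen <- chosen[keep]
          cols <- vapply(sp$signature[chosen], .confuse_color, character(1),
                         confusion = config$color_confusion)
          tmpl <- sample(.caption_templates, 1L)
          sprintf(tmpl, .render_listing(cols, chosen))
        }, character(1))
        out[[length(out) + 1L]] <- caption_set(image_id, caps,
                                               true_class_id = sp$class_id)
      }
    }
    out
  })
}

#' Generate the expert document corpus (unmasked)
#'
#' Per species, `doc_sentences` sentences: `round(filler_fraction *
#' doc_sentences)` non-visual filler sentences (habitat/behavior templates
#' containing neither part nouns nor colors) and the rest visual sentences
#' rendering the signature, each with probability `jargon_rate` using the
#' injective jargon lexicon (e.g. "remiges" for wing, "crimson" for red).
#' The species name appears in the first visual sentence; masking it is the
#' caller's job (see [generate_benchmark()] and [mask_corpus()]).
#'
#' @inheritParams generate_captions
#' @return a [corpus()] with section labels `visual` / `filler`.
#' @export
generate_documents <- function(species, config) {
  n_fill <- round(config$filler_fraction * config$doc_sentences)
  n_vis <- config$doc_sentences - n_fill
  if (n_vis < 1L) stop_sm("doc_sentences too small for filler_fraction")
  jargon_missing <- setdiff(config$colors, names(.color_jargon))
  if (config$jargon_rate > 0 && length(jargon_missing))
    stop_sm("no jargon synonym for color(s): ",
            paste(jargon_missing, collapse = ", "))
  with_seed(config$seed + 2L, {
    docs <- lapply(species, function(sp) {
      parts_cycle <- config$parts[(seq_len(n_vis) - 1L) %%
                                    length(config$parts) + 1L]
      vis <- vapply(seq_len(n_vis), function(k) {
        part <- parts_cycle[k]
        color <- sp$signature[[part]]
        jargon <- stats::runif(1) < config$jargon_rate
        if (k == 1L) {           # name sentence, always plain vocabulary
          sprintf("the %s of the %s is %s.", part, sp$name, color)
        } else if (jargon) {
          part_w <- if (part %in% names(.part_jargon)) .part_jargon[[part]]
                    else part
          color_w <- unname(.color_jargon[color])
          sprintf("the %s of this species are %s.", part_w, color_w)
        } else {
          sprintf("the %s is %s.", part, color)
        }
      }, character(1))
      fill <- sample(.filler_templates, n_fill, replace = TRUE)
      sents <- c(vis, fill)
      labels <- c(rep("visual", n_vis), rep("filler", n_fill))
      ord <- c(1L, sample(seq_along(sents)[-1L]))  # name sentence first
      document(sp$class_id, sents[ord], title = sp$name,
               section_labels = labels[ord])
    })
    corpus(docs, mask_token = "a bird")
  })
}

#' Generate a complete benchmark world
#'
#' Species, caption sets, masked corpus and ground truth in one call; the
#' attached manifest records the full config so a world is reproducible
#' byte-for-byte from its seed. In separable mode (`attribute_dropout = 0`,
#' `color_confusion = list()`, `jargon_rate = 0`) each image's caption set
#' identifies its species' document uniquely by attribute overlap.
#'
#' @param config a [synth_config()].
#' @param mask mask species names in the corpus (default TRUE)?
#' @return list with elements `caption_sets`, `corpus` (masked), `truth`
#'   (named character image_id -> class_id), `species`, `config`.
#' @export
generate_benchmark <- function(config = synth_config(), mask = TRUE) {
  species <- generate_species(config)
  caption_sets <- generate_captions(species, config)
  corp <- generate_documents(species, config)
  if (mask)
    corp <- mask_corpus(corp, vapply(species, `[[`, character(1), "name"))
  truth <- vapply(caption_sets, `[[`, character(1), "true_class_id")
  names(truth) <- vapply(caption_sets, `[[`, character(1), "image_id")
  structure(list(caption_sets = caption_sets, corpus = corp, truth = truth,
                 species = species, config = config),
            class = "synth_world")
}

#' @export
print.synth_world <- function(x, ...) {
  cat(sprintf("<synth_world: K=%d, %d images, %d captions, seed=%d>\n",
              x$config$K, length(x$caption_sets),
              sum(vapply(x$caption_sets, function(s) length(s$captions),
                         integer(1))),
              x$config$seed))
  invisible(x)
}

#' Write a benchmark world to a directory
#'
#' Emits `captions.jsonl`, `corpus.json`, `truth.tsv`, `mask_list.txt` and
#' `manifest.json`.
#'
#' @param world a [generate_benchmark()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_benchmark <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_captions(world$caption_sets, file.path(dir, "captions.jsonl"))
  save_corpus(world$corpus, file.path(dir, "corpus.json"))
  utils::write.table(
    data.frame(image_id = names(world$truth), class_id = world$truth),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeLines(vapply(world$species, `[[`, character(1), "name"),
             file.path(dir, "mask_list.txt"), useBytes = TRUE)
  writeLines(jsonlite::toJSON(unclass(world$config), auto_unbox = TRUE,
                              pretty = TRUE),
             file.path(dir, "manifest.json"), useBytes = TRUE)
  invisible(dir)
}
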