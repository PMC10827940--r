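# Reading, normalizing, segmenting and masking caption sets and expert
# corpora, plus the noun extraction the neutral-pair miner depends on.

.abbreviations <- c(
  "mr", "mrs", "ms", "dr", "prof", "st", "no", "fig", "figs", "approx",
  "ca", "cf", "vs", "etc", "al", "sp", "spp", "subsp", "var", "in", "cm",
  "mm", "ft", "oz", "lb", "e.g", "i.e"
)

#' Split text into sentences
#'
#' Rule-based segmentation: a sentence boundary is terminal punctuation
#' (`.`, `!`, `?`, optionally followed by closing quotes/brackets) plus
#' whitespace, unless the preceding word is a known abbreviation or a single
#' letter (an initial), or the next character is lowercase (mid-sentence
#' period). The abbreviation list covers titles, measurement units and the
#' usual Latin shorthands, so strings like `"approx. 10 cm long"` stay one
#' sentence. The segmenter is deterministic; fixtures that depend on its
#' behavior pin it through this single implementation.
#'
#' @param text a character scalar.
#' @return character vector of non-empty sentences whose concatenation
#'   (modulo separating whitespace) covers the input.
#' @export
split_sentences <- function(text) {
  text <- normalize_text(text)
  if (!nzchar(text)) return(character(0))
  m <- stringi::stri_locate_all_regex(text, "[.!?]+[\"')\\]]*\\s+")[[1]]
  cuts <- integer(0)
  if (!is.na(m[1L, 1L])) {
    for (r in seq_len(nrow(m))) {
      boundary_end <- m[r, 2L]
      prev <- substr(text, 1L, m[r, 1L] - 1L)
      word <- stringi::stri_extract_last_regex(prev, "[A-Za-z0-9.]+")
      nxt <- substr(text, boundary_end + 1L, boundary_end + 1L)
      if (!is.na(word)) {
        w <- tolower(sub("\\.+$", "", word))
        if (w %in% .abbreviations) next
        if (nchar(w) == 1L && grepl("[a-z]", w)) next
      }
      if (grepl("[a-z]", nxt)) next
      cuts <- c(cuts, boundary_end)
    }
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, nchar(text))
  out <- trimws(substring(text, starts, ends))
  out[nzchar(out)]
}

#' Mask class-name mentions in text
#'
#' Replaces every case-insensitive whole-word occurrence of any class name
#' with `mask_token`, so a retrieval model cannot read the expert label off
#' the document. When names overlap (e.g. "Downy Woodpecker" and
#' "Woodpecker"), the longest name wins and the span is replaced once. The
#' operation is idempotent provided `mask_token` does not itself contain a
#' class name.
#'
#' @param text character vector.
#' @param class_names non-empty character vector of names to mask.
#' @param mask_token replacement string, e.g. `"a bird"`.
#' @return character vector with mentions replaced.
#' @export
mask_class_names <- function(text, class_names, mask_token) {
  if (length(class_names) == 0L) stop_sm("`class_names` must be non-empty")
  names_sorted <- class_names[order(-nchar(class_names), class_names)]
  esc <- gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", names_sorted)
  pat <- paste0(
    "(?i)(?<![A-Za-z0-9])(?:", paste(esc, collapse = "|"),
    ")(?![A-Za-z0-9])"
  )
  gsub(pat, mask_token, text, perl = TRUE)
}

# ---- noun extraction ------------------------------------------------------

# Closed noun lexicon for the offline dictionary tagger: bird and flower
# anatomy (plain + expert jargon), habitat/behavior vocabulary, and common
# concrete nouns seen in layperson captions. Singular forms; plural-only
# jargon (remiges, rectrices) listed as-is.
sentmatch_noun_lexicon <- c(
  # creatures and anatomy
  "bird", "flower", "plant", "animal", "wing", "belly", "head", "beak",
  "tail", "breast", "crown", "throat", "chest", "neck", "nape", "rump",
  "back", "face", "cheek", "chin", "eye", "leg", "foot", "claw", "bill",
  "feather", "plumage", "crest", "body", "petal", "stem", "leaf", "stamen",
  "bloom", "bud",
  # jargon (injective counterparts used by the synthetic documents)
  "remiges", "rectrices", "abdomen", "cranium", "mandible", "underparts",
  "upperparts",
  # markings
  "patch", "stripe", "spot", "bar", "ring", "band", "tip", "side", "edge",
  "pattern", "color", "colour", "shade", "size", "shape",
  # habitat / behavior / filler vocabulary
  "habitat", "forest", "woodland", "shrubland", "meadow", "field", "marsh",
  "wetland", "river", "lake", "coast", "mountain", "plain", "range",
  "region", "area", "ground", "tree", "branch", "bush", "grass", "seed",
  "insect", "berry", "fruit", "nectar", "worm", "fish", "nest", "egg",
  "song", "call", "flight", "distance", "population", "species", "pair",
  "group", "flock", "season", "spring", "summer", "autumn", "winter",
  "dawn", "dusk", "midday", "morning", "evening", "migration", "male",
  "female", "adult", "juvenile", "year", "day", "time", "food", "water",
  "sky", "sun", "rain", "snow", "picture", "image", "photo"
)

.irregular_plurals <- c(
  feet = "foot", geese = "goose", leaves = "leaf", calves = "calf",
  wolves = "wolf", mice = "mouse"
)

# Lemma of a lowercase token under the closed lexicon: identity if listed,
# else irregular-plural lookup, else simple plural stripping checked
# against the lexicon. Returns NA when no noun reading exists.
.dict_lemma <- function(tok, lexicon, irregular) {
  if (tok %in% lexicon) return(tok)
  if (tok %in% names(irregular)) {
    lem <- irregular[[tok]]
    return(if (lem %in% lexicon) lem else NA_character_)
  }
  cands <- character(0)
  if (grepl("ies$", tok)) cands <- c(cands, sub("ies$", "y", tok))
  if (grepl("(ses|xes|zes|ches|shes)$", tok)) cands <- c(cands, sub("es$", "", tok))
  if (grepl("[^s]s$", tok)) cands <- c(cands, sub("s$", "", tok))
  hit <- cands[cands %in% lexicon]
  if (length(hit)) hit[1L] else NA_character_
}

#' Dictionary noun tagger
#'
#' Builds a tagger function (text -> character vector of lowercased noun
#' lemmas) from a closed noun lexicon with plural lemmatization. This is the
#' default tagger: it is fully deterministic and needs no model files, which
#' keeps the noun-overlap logic exact and offline. Any function with the
#' same signature can replace it (see [extract_nouns()]), e.g. an adapter
#' around a statistical POS tagger.
#'
#' @param lexicon character vector of singular noun forms.
#' @param irregular named character vector mapping irregular plurals to
#'   their singulars.
#' @return a function `function(text) -> character` returning the sorted set
#'   of noun lemmas found in `text`.
#' @export
dictionary_noun_tagger <- function(lexicon = sentmatch_noun_lexicon,
                                   irregular = .irregular_plurals) {
  force(lexicon); force(irregular)
  function(text) {
    toks <- tokenize_words(text)
    if (!length(toks)) return(character(0))
    lems <- vapply(unique(toks), .dict_lemma, character(1),
                   lexicon = lexicon, irregular = irregular)
    sort(unique(lems[!is.na(lems)]))
  }
}

.default_tagger <- dictionary_noun_tagger()

default_noun_tagger <- function() {
  getOption("sentmatch.noun_tagger", .default_tagger)
}

#' Extract the noun set of a text
#'
#' Returns the set of lowercased noun lemmas occurring in `text`, as decided
#' by the configured tagger (default: the dictionary tagger). This is the
#' single source of truth for the no-common-noun predicate used when mining
#' neutral sentence pairs.
#'
#' @param text character scalar.
#' @param tagger optional tagger function; defaults to
#'   `getOption("sentmatch.noun_tagger")` or [dictionary_noun_tagger()].
#' @return sorted character vector (a set) of noun lemmas.
#' @export
extract_nouns <- function(text, tagger = NULL) {
  tagger <- tagger %||% default_noun_tagger()
  tagger(text)
}

#' Are two texts neutral-eligible?
#'
#' TRUE when the two texts share no nouns, the criterion under which a
#' caption-sentence pair is labelled neutral: without a common noun the
#' sentences describe different parts or topics and carry neither entailing
#' nor contradicting information.
#'
#' @param a,b character scalars.
#' @inheritParams extract_nouns
#' @return logical scalar.
#' @export
neutral_eligible <- function(a, b, tagger = NULL) {
  tagger <- tagger %||% default_noun_tagger()
  length(intersect(tagger(a), tagger(b))) == 0L
}

# ---- containers -----------------------------------------------------------

#' Caption set: all layperson descriptions of one image
#'
#' @param image_id opaque identifier.
#' @param captions character vector (length >= 1) of free-text descriptions;
#'   normalized and required non-empty.
#' @param true_class_id optional class identifier, carried for evaluation
#'   only and never consulted during training.
#' @return an object of class `caption_set`.
#' @export
caption_set <- function(image_id, captions, true_class_id = NULL) {
  captions <- normalize_text(captions)
  if (length(captions) < 1L || any(!nzchar(captions)))
    stop_sm("caption set '", image_id, "': captions must be non-empty text")
  structure(
    list(image_id = as.character(image_id), captions = captions,
         true_class_id = if (is.null(true_class_id)) NULL else as.character(true_class_id)),
    class = "caption_set"
  )
}

#' @export
print.caption_set <- function(x, ...) {
  cat(sprintf("<caption_set '%s': %d caption(s)%s>\n", x$image_id,
              length(x$captions),
              if (is.null(x$true_class_id)) "" else paste0(", class ", x$true_class_id)))
  invisible(x)
}

#' Expert document for one class
#'
#' @param class_id unique class identifier.
#' @param sentences character vector (length >= 1) of sentence strings.
#' @param title display title (defaults to `class_id`).
#' @param section_labels optional character vector parallel to `sentences`.
#' @return an object of class `document`.
#' @export
document <- function(class_id, sentences, title = class_id,
                     section_labels = NULL) {
  sentences <- normalize_text(sentences)
  sentences_keep <- nzchar(sentences)
  if (!is.null(section_labels)) {
    if (length(section_labels) != length(sentences))
      stop_sm("document '", class_id, "': section_labels length mismatch")
    section_labels <- as.character(section_labels)[sentences_keep]
  }
  sentences <- sentences[sentences_keep]
  if (length(sentences) < 1L)
    stop_sm("document '", class_id, "' has no sentences")
  structure(
    list(class_id = as.character(class_id), title = as.character(title),
         sentences = sentences, section_labels = section_labels),
    class = "document"
  )
}

#' Expert corpus: one document per class
#'
#' @param documents list of [document()] objects, unique class ids, K >= 2.
#' @param mask_token the class-name mask in force for this corpus.
#' @return an object of class `corpus`.
#' @export
corpus <- function(documents, mask_token = "a bird") {
  ids <- vapply(documents, `[[`, character(1), "class_id")
  if (anyDuplicated(ids))
    stop_sm("duplicate class_id in corpus: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(documents) < 2L) stop_sm("a corpus needs at least 2 documents")
  structure(list(documents = documents, mask_token = mask_token),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  ns <- vapply(x$documents, function(d) length(d$sentences), integer(1))
  cat(sprintf("<corpus: K=%d documents, %d sentences, mask '%s'>\n",
              length(x$documents), sum(ns), x$mask_token))
  invisible(x)
}

#' @export
length.corpus <- function(x) length(x$documents)

corpus_class_ids <- function(corp) {
  vapply(corp$documents, `[[`, character(1), "class_id")
}

#' Apply class-name masking to every sentence of a corpus
#'
#' @param corp a [corpus()].
#' @param class_names names to mask (e.g. all species names).
#' @param mask_token replacement; defaults to the corpus mask token.
#' @return the corpus with all sentences and titles masked.
#' @export
mask_corpus <- function(corp, class_names, mask_token = corp$mask_token) {
  corp$documents <- lapply(corp$documents, function(d) {
    d$sentences <- mask_class_names(d$sentences, class_names, mask_token)
    d$title <- mask_class_names(d$title, class_names, mask_token)
    d
  })
  corp$mask_token <- mask_token
  corp
}

# ---- file I/O -------------------------------------------------------------

#' Load caption sets from a JSONL file
#'
#' One JSON record per line with fields `image_id`, `text` and optionally
#' `class_id`. Records are grouped by `image_id` (first-appearance order,
#' caption order preserved within image).
#'
#' @param path file path.
#' @return list of [caption_set()] objects.
#' @export
load_captions <- function(path) {
  if (!file.exists(path)) stop_sm("caption file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop_sm("caption file is empty: ", path)
  recs <- vector("list", length(lines))
  for (i in which(keep)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$image_id) || is.null(rec$text) ||
        !nzchar(trimws(rec$text)))
      stop_sm("malformed caption record at line ", i, " of ", path)
    recs[[i]] <- rec
  }
  recs <- recs[keep]
  ids <- vapply(recs, function(r) as.character(r$image_id), character(1))
  out <- lapply(unique(ids), function(id) {
    sub <- recs[ids == id]
    cls <- unique(unlist(lapply(sub, function(r) r$class_id)))
    if (length(cls) > 1L)
      stop_sm("conflicting class_id for image ", id)
    caption_set(id, vapply(sub, function(r) as.character(r$text), character(1)),
                true_class_id = if (length(cls)) cls else NULL)
  })
  out
}

#' Save caption sets to JSONL
#'
#' @param caption_sets list of [caption_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_captions <- function(caption_sets, path) {
  lines <- unlist(lapply(caption_sets, function(cs) {
    vapply(cs$captions, function(txt) {
      rec <- list(image_id = cs$image_id, text = txt)
      if (!is.null(cs$true_class_id)) rec$class_id <- cs$true_class_id
      jsonlite::toJSON(rec, auto_unbox = TRUE)
    }, character(1))
  }))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Load an expert corpus
#'
#' Two on-disk layouts are supported. `"json"`: a JSON array (or an object
#' with fields `mask_token` and `documents`) of records with `class_id`,
#' optional `title`, and either `sections` (a map label -> text, segmented
#' here) or pre-segmented `sentences` (+ optional `section_labels`).
#' `"dir"`: a directory of `<class_id>.txt` files, one document each.
#'
#' @param path file or directory path.
#' @param format `"auto"` (default: directory vs file), `"json"` or `"dir"`.
#' @param mask_token mask token recorded on the corpus (a JSON corpus may
#'   carry its own, which wins).
#' @return a [corpus()].
#' @export
load_corpus <- function(path, format = c("auto", "json", "dir"),
                        mask_token = "a bird") {
  format <- match.arg(format)
  if (format == "auto") format <- if (dir.exists(path)) "dir" else "json"
  if (format == "dir") {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (!length(files)) stop_sm("no .txt documents in ", path)
    docs <- lapply(files, function(f) {
      id <- sub("\\.txt$", "", basename(f))
      txt <- paste(readLines(f, warn = FALSE, encoding = "UTF-8"),
                   collapse = " ")
      sents <- split_sentences(txt)
      if (!length(sents)) stop_sm("empty document: ", f)
      document(id, sents)
    })
    return(corpus(docs, mask_token = mask_token))
  }
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(obj$documents)) {
    mask_token <- obj$mask_token %||% mask_token
    obj <- obj$documents
  }
  docs <- lapply(obj, function(rec) {
    if (is.null(rec$class_id)) stop_sm("corpus record without class_id")
    id <- as.character(rec$class_id)
    title <- as.character(rec$title %||% id)
    if (!is.null(rec$sentences)) {
      document(id, unlist(rec$sentences), title = title,
               section_labels = if (is.null(rec$section_labels)) NULL
                                else unlist(rec$section_labels))
    } else if (!is.null(rec$sections)) {
      sents <- lapply(rec$sections, function(txt) split_sentences(txt))
      labels <- rep(names(rec$sections), vapply(sents, length, integer(1)))
      sents <- unlist(sents, use.names = FALSE)
      if (!length(sents)) stop_sm("empty document: ", id)
      document(id, sents, title = title, section_labels = labels)
    } else stop_sm("corpus record '", id, "' has neither sections nor sentences")
  })
  corpus(docs, mask_token = mask_token)
}

#' Save a corpus as JSON (round-trips through [load_corpus()])
#'
#' @param corp a [corpus()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_corpus <- function(corp, path) {
  obj <- list(
    mask_token = corp$mask_token,
    documents = lapply(corp$documents, function(d) {
      rec <- list(class_id = d$class_id, title = d$title,
                  sentences = as.list(d$sentences))
      if (!is.null(d$section_labels))
        rec$section_labels <- as.list(d$section_labels)
      rec
    })
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE), path,
             useBytes = TRUE)
  invisible(path)
}

#' Read a class-name mask list (one name per line)
#'
#' @param path plain-text file, one class name per line.
#' @return character vector of names.
#' @export
load_mask_list <- function(path) {
  nm <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
  nm[nzchar(nm)]
}
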