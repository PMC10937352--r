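## Mandarin articulatory phonetics: the place-voice-manner consonant
## chart, tone categories, syllable labeling, and chance levels.

#' Articulatory category vocabularies
#'
#' Mandarin consonants occupy 7 places of articulation and 8 manners
#' (aspiration and voicing contrasts counted as separate manners);
#' syllables carry one of 4 lexical tones. These fixed vocabularies
#' define the decoding label spaces, so their sizes also fix the chance
#' levels (1/7, 1/8, 1/4).
#'
#' @return character (or integer, for tones) vector of category names in
#'   canonical order.
#' @seealso [chanceLevel()], [consonantInventory()]
#' @export
#' @examples
#' placeCategories()
#' length(mannerCategories())
placeCategories <- function() {
  c("bilabial", "labiodental", "dental", "alveolar",
    "post-alveolar", "palatal", "velar")
}

#' @rdname placeCategories
#' @export
mannerCategories <- function() {
  c("plosive-unaspirated", "plosive-aspirated",
    "affricate-unaspirated", "affricate-aspirated",
    "fricative-voiceless", "fricative-voiced",
    "nasal", "lateral")
}

#' @rdname placeCategories
#' @export
toneCategories <- function() 1:4

#' The Mandarin place-voice-manner consonant inventory
#'
#' The 21 syllable-initial consonants of Standard Mandarin, each with its
#' pinyin symbol, IPA transcription, place of articulation and manner of
#' articulation. Every occupied (place, manner) cell of the standard
#' chart appears exactly once; pinyin symbols are unique.
#'
#' @return data.frame with columns `pinyin`, `ipa`, `place`, `manner`
#'   (place and manner as factors over [placeCategories()] and
#'   [mannerCategories()]).
#' @export
#' @examples
#' inv <- consonantInventory()
#' nrow(inv)                       # 21
#' subset(inv, manner == "fricative-voiceless")$pinyin
consonantInventory <- function() {
  asp <- "\u02b0"  # aspiration diacritic
  rows <- list(
    c("b",  "p",                     "bilabial",      "plosive-unaspirated"),
    c("p",  paste0("p", asp),        "bilabial",      "plosive-aspirated"),
    c("m",  "m",                     "bilabial",      "nasal"),
    c("f",  "f",                     "labiodental",   "fricative-voiceless"),
    c("z",  "ts",                    "dental",        "affricate-unaspirated"),
    c("c",  paste0("ts", asp),       "dental",        "affricate-aspirated"),
    c("s",  "s",                     "dental",        "fricative-voiceless"),
    c("d",  "t",                     "alveolar",      "plosive-unaspirated"),
    c("t",  paste0("t", asp),        "alveolar",      "plosive-aspirated"),
    c("n",  "n",                     "alveolar",      "nasal"),
    c("l",  "l",                     "alveolar",      "lateral"),
    c("zh", "t\u0282",               "post-alveolar", "affricate-unaspirated"),
    c("ch", paste0("t\u0282", asp),  "post-alveolar", "affricate-aspirated"),
    c("sh", "\u0282",                "post-alveolar", "fricative-voiceless"),
    c("r",  "\u0290",                "post-alveolar", "fricative-voiced"),
    c("j",  "t\u0255",               "palatal",       "affricate-unaspirated"),
    c("q",  paste0("t\u0255", asp),  "palatal",       "affricate-aspirated"),
    c("x",  "\u0255",                "palatal",       "fricative-voiceless"),
    c("g",  "k",                     "velar",         "plosive-unaspirated"),
    c("k",  paste0("k", asp),        "velar",         "plosive-aspirated"),
    c("h",  "x",                     "velar",         "fricative-voiceless")
  )
  m <- do.call(rbind, rows)
  data.frame(
    pinyin = m[, 1],
    ipa = m[, 2],
    place = factor(m[, 3], levels = placeCategories()),
    manner = factor(m[, 4], levels = mannerCategories()),
    stringsAsFactors = FALSE
  )
}

## Initials sorted longest-first so "zh"/"ch"/"sh" win over "z"/"c"/"s".
pinyinInitial <- function(pinyin) {
  assertThat(is.character(pinyin) && length(pinyin) == 1L && nzchar(pinyin),
             "pinyin must be a single non-empty string")
  s <- tolower(pinyin)
  inits <- consonantInventory()$pinyin
  inits <- inits[order(-nchar(inits))]
  for (ini in inits) {
    if (startsWith(s, ini)) return(ini)
  }
  # zero-initial spellings: bare finals plus the glide letters w/y
  if (grepl("^[aeiouwy]", s)) return(NA_character_)
  stop(sprintf("unknown pinyin initial in syllable '%s'", pinyin),
       call. = FALSE)
}

#' Label a pinyin syllable with its articulatory categories
#'
#' Maps a romanized Mandarin syllable and tone number to the decoding
#' target: place and manner of the initial consonant (from
#' [consonantInventory()]) plus the tone. Zero-initial syllables (e.g.
#' "an", "er", and the glide spellings "wu"/"yi") have no consonant, so
#' place and manner are `NA`; they remain usable for the tone task. The
#' neutral tone (0/5) is outside the 4-class tone space and is rejected.
#'
#' @param pinyin single syllable romanization, e.g. `"zhang"`.
#' @param tone integer tone in 1..4.
#' @return list with components `pinyin`, `initial`, `place`, `manner`
#'   (factors, `NA` for zero-initial syllables) and `tone`, of class
#'   `"ArticulatoryLabel"`.
#' @export
#' @examples
#' labelSyllable("zhang", 1)
#' labelSyllable("an", 4)$place   # NA: zero-initial
labelSyllable <- function(pinyin, tone) {
  assertThat(length(tone) == 1L && !is.na(tone) && tone == as.integer(tone),
             "tone must be a single integer")
  tone <- as.integer(tone)
  assertThat(tone %in% toneCategories(),
             "tone %d is outside the 4-tone space {1,2,3,4}", tone)
  ini <- pinyinInitial(pinyin)
  inv <- consonantInventory()
  if (is.na(ini)) {
    place <- factor(NA_character_, levels = placeCategories())
    manner <- factor(NA_character_, levels = mannerCategories())
  } else {
    row <- inv[inv$pinyin == ini, ]
    place <- row$place
    manner <- row$manner
  }
  structure(
    list(pinyin = pinyin, initial = ini, place = place, manner = manner,
         tone = tone),
    class = "ArticulatoryLabel"
  )
}

#' @export
print.ArticulatoryLabel <- function(x, ...) {
  cat(sprintf("<ArticulatoryLabel> %s  initial=%s place=%s manner=%s tone=%d\n",
              x$pinyin,
              ifelse(is.na(x$initial), "-", x$initial),
              ifelse(is.na(x$place), "-", as.character(x$place)),
              ifelse(is.na(x$manner), "-", as.character(x$manner)),
              x$tone))
  invisible(x)
}

#' Chance level of a decoding task
#'
#' Uniform-guessing accuracy 1/K for the task's K balanced categories:
#' 1/7 for articulatory place, 1/8 for manner, 1/4 for tone.
#'
#' @param task one of `"place"`, `"manner"`, `"tone"`.
#' @return fraction in (0, 1].
#' @export
#' @examples
#' chanceLevel("place")   # 1/7
chanceLevel <- function(task) {
  1 / length(taskLevels(task))
}

## Category levels for a task; validates the task name.
taskLevels <- function(task) {
  assertThat(is.character(task) && length(task) == 1L,
             "task must be a single string")
  switch(task,
    place = placeCategories(),
    manner = mannerCategories(),
    tone = as.character(toneCategories()),
    stop(sprintf("unknown task '%s' (expected place, manner or tone)", task),
         call. = FALSE)
  )
}

## Integer class index (1..K) of a label under a task; NA for
## zero-initial syllables on the consonant tasks.
taskClassIndex <- function(label, task) {
  lv <- taskLevels(task)
  val <- switch(task,
    place = as.character(label$place),
    manner = as.character(label$manner),
    tone = as.character(label$tone)
  )
  match(val, lv)
}

#' Export the consonant inventory as a tab-separated table
#'
#' Writes columns pinyin, ipa, place, manner in inventory order. The
#' output is byte-stable across runs so snapshots can be diffed.
#'
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
writeInventory <- function(path) {
  inv <- consonantInventory()
  inv$place <- as.character(inv$place)
  inv$manner <- as.character(inv$manner)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("pinyin\tipa\tplace\tmanner",
               sprintf("%s\t%s\t%s\t%s", inv$pinyin, inv$ipa,
                       inv$place, inv$manner)),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
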