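#' Annotation vocabulary for telecare call corpora
#'
#' The vocabulary fixes the closed label sets used throughout the package:
#' conversation topics, speaker roles, dialogue acts (grouped into high-level
#' categories), utterance attributes (symptom, lifestyle, and vitals
#' attributes), expert concern areas, and follow-up levels. The default
#' vocabulary shipped with the package covers the annotation scheme of
#' nurse-led heart-failure telesupport calls: 13 topics, 4 speaker roles, and
#' 18 dialogue acts in 7 categories.
#'
#' @param path Path to a YAML vocabulary file. The default reads the
#'   vocabulary shipped in `inst/extdata/vocabulary.yaml`.
#' @return An object of class `telecare_vocabulary`: a list with elements
#'   `topics`, `speakers`, `symptoms`, `attributes` (named list of attribute
#'   groups), `dialogue_acts` (named list mapping category to acts),
#'   `concern_areas`, and `follow_up_levels`.
#' @examples
#' voc <- read_vocabulary()
#' length(voc$topics)          # 13
#' names(voc$dialogue_acts)    # the 7 dialogue-act categories
#' @export
read_vocabulary <- function(path = default_vocabulary_path()) {
  v <- yaml::read_yaml(path)
  required <- c("topics", "speakers", "attributes", "dialogue_acts",
                "concern_areas", "follow_up_levels")
  missing <- setdiff(required, names(v))
  if (length(missing))
    stop("vocabulary file is missing sections: ", paste(missing, collapse = ", "))
  v$topics <- as.character(v$topics)
  v$speakers <- as.character(v$speakers)
  if (anyDuplicated(v$topics)) stop("duplicate topic labels in vocabulary")
  class(v) <- "telecare_vocabulary"
  v
}

#' @rdname read_vocabulary
#' @export
default_vocabulary_path <- function() {
  system.file("extdata", "vocabulary.yaml", package = "telefocus", mustWork = TRUE)
}

#' @export
print.telecare_vocabulary <- function(x, ...) {
  cat("Telecare annotation vocabulary\n")
  cat("  topics:         ", length(x$topics), "\n")
  cat("  speakers:       ", length(x$speakers), "\n")
  cat("  dialogue acts:  ", length(unlist(x$dialogue_acts)),
      "in", length(x$dialogue_acts), "categories\n")
  cat("  attributes:     ", length(unlist(x$attributes)), "\n")
  cat("  concern areas:  ", length(x$concern_areas), "\n")
  invisible(x)
}

# Flat act inventory and act -> category lookup.
vocab_acts <- function(vocab) unname(unlist(vocab$dialogue_acts))

vocab_act_category <- function(vocab) {
  cats <- rep(names(vocab$dialogue_acts), lengths(vocab$dialogue_acts))
  stats::setNames(cats, unlist(vocab$dialogue_acts))
}

vocab_attributes <- function(vocab) unname(unlist(vocab$attributes))

#' @rdname read_vocabulary
#' @export
symptom_attributes <- function(vocab = read_vocabulary()) {
  as.character(vocab$attributes$symptom)
}
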