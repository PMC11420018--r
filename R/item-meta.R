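#' Default item layout for the RESS, PHQ-9, and GAD-7
#'
#' The instrument battery behind the analysis: 38 RESS emotion-regulation
#' items on a 1-5 Likert scale spread over six subscales (suppression,
#' engagement, reappraisal: 8 items each; rumination: 6; arousal control,
#' distraction: 4 each, so subscale sum-scores range over 8-40, 6-30, and
#' 4-20 respectively), 9 PHQ-9 depression items and 7 GAD-7 anxiety items
#' coded 0-3. Item identifiers are synthetic ("sup1".."sup8", ...); the
#' published RESS item-to-subscale list is not public, but only labels would
#' change, not sum-score ranges.
#'
#' @return A data.frame with one row per item: `item_id`, `instrument`
#'   (RESS/PHQ9/GAD7), `subscale`, `label`, `min_code`, `max_code`.
#' @export
default_item_meta <- function() {
  subscales <- c(suppression = 8L, engagement = 8L, reappraisal = 8L,
                 rumination = 6L, arousal_control = 4L, distraction = 4L)
  prefix <- c(suppression = "sup", engagement = "eng", reappraisal = "rea",
              rumination = "rum", arousal_control = "aro", distraction = "dis")
  ress <- do.call(rbind, lapply(names(subscales), function(s) {
    k <- subscales[[s]]
    data.frame(item_id = paste0(prefix[[s]], seq_len(k)),
               instrument = "RESS", subscale = s,
               label = paste0(s, " item ", seq_len(k)),
               min_code = 1L, max_code = 5L,
               stringsAsFactors = FALSE)
  }))
  phq_labels <- c("loss of interest", "depressed mood / hopelessness",
                  "sleep problems", "fatigue", "appetite changes",
                  "low self-esteem", "concentration problems",
                  "psychomotor changes", "suicidal ideation")
  gad_labels <- c("nervousness", "uncontrollable worry", "excessive worry",
                  "trouble relaxing", "restlessness", "irritability",
                  "feeling afraid")
  sym <- rbind(
    data.frame(item_id = paste0("phq", 1:9), instrument = "PHQ9",
               subscale = "PHQ9", label = phq_labels,
               min_code = 0L, max_code = 3L, stringsAsFactors = FALSE),
    data.frame(item_id = paste0("gad", 1:7), instrument = "GAD7",
               subscale = "GAD7", label = gad_labels,
               min_code = 0L, max_code = 3L, stringsAsFactors = FALSE)
  )
  rbind(ress, sym)
}

#' Strategy sum-score ranges implied by the item layout
#'
#' @param items item metadata, as from [default_item_meta()].
#' @return Named list of `c(min, max)` integer sum-score ranges, one per
#'   emotion-regulation strategy.
#' @export
strategy_ranges <- function(items = default_item_meta()) {
  ress <- items[items$instrument == "RESS", ]
  sapply(split(ress, ress$subscale), function(d) {
    c(sum(d$min_code), sum(d$max_code))
  }, simplify = FALSE)
}

strategy_names <- function() {
  c("suppression", "engagement", "reappraisal",
    "rumination", "arousal_control", "distraction")
}

symptom_ids <- function(items = default_item_meta()) {
  items$item_id[items$instrument %in% c("PHQ9", "GAD7")]
}
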