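# Channel/condition vocabulary shared by every module.

#' Muscle channels recorded by the pipeline
#'
#' The four facial muscles monitored by the experiment, in canonical channel
#' order: corrugator supercilii (brow-knitting), zygomatic major
#' (lip-corner-pulling), masseter (jaw-closing) and suprahyoid (jaw-opening /
#' floor of mouth).
#'
#' @return Character vector of length 4.
#' @export
muscle_names <- function() {
  c("corrugator", "zygomatic", "masseter", "suprahyoid")
}

#' Facial-action condition labels
#'
#' The eight instructed facial actions: four simple actions and the four
#' frown/smile x speak/chew combinations.
#'
#' @return Character vector of length 8.
#' @export
condition_labels <- function() {
  c("frown", "smile", "chew", "speak",
    "frown_speak", "smile_speak", "frown_chew", "smile_chew")
}

# Elementary actions making up a condition label.
condition_parts <- function(condition) {
  strsplit(condition, "_", fixed = TRUE)[[1]]
}

assert_condition <- function(condition) {
  bad <- setdiff(condition, condition_labels())
  if (length(bad) > 0) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(condition_labels(), collapse = ", "),
         call. = FALSE)
  }
  invisible(condition)
}
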