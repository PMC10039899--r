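#' Ordered stage model
#'
#' Describes the ordered histopathological (sub)stages of a progression
#' cohort, optionally with a named partition of the stages into contiguous
#' phases (e.g. normal tissue / intraepithelial neoplasia / advanced
#' carcinoma).
#'
#' @param stages Character vector of unique stage labels, in progression
#'   order.
#' @param phases Optional named list of integer vectors; each element must
#'   be a contiguous run of stage indices, the elements must be ordered and
#'   together cover every stage exactly once.
#' @return An object of class `stage_model`.
#' @examples
#' stage_model(c("NT", "HYP", "Tis", "T2"),
#'             phases = list(NT = 1:2, IEN = 3, ADV = 4))
#' @export
stage_model <- function(stages, phases = NULL) {
  stages <- as.character(stages)
  if (anyDuplicated(stages)) stopf("stage labels must be unique")
  if (length(stages) < 1L) stopf("at least one stage required")
  if (!is.null(phases)) {
    idx <- unlist(phases, use.names = FALSE)
    if (!identical(sort(idx), seq_along(stages)))
      stopf("phases must cover all stages exactly once")
    for (b in phases)
      if (!identical(as.integer(b), seq(min(b), max(b))))
        stopf("each phase must be a contiguous block of stage indices")
    if (is.null(names(phases)) || anyDuplicated(names(phases)))
      stopf("phases must be uniquely named")
    starts <- vapply(phases, min, 0L)
    if (is.unsorted(starts)) stopf("phases must be in stage order")
  }
  structure(list(stages = stages, phases = phases), class = "stage_model")
}

#' @export
print.stage_model <- function(x, ...) {
  cat("<stage_model> ", length(x$stages), " stages: ",
      paste(x$stages, collapse = " > "), "\n", sep = "")
  if (!is.null(x$phases)) {
    for (nm in names(x$phases))
      cat("  phase ", nm, ": ",
          paste(x$stages[x$phases[[nm]]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Map stage labels to their phase name (NA if no partition set).
stage_phase <- function(model, stage) {
  if (is.null(model$phases)) return(rep(NA_character_, length(stage)))
  idx <- match(stage, model$stages)
  lut <- rep(NA_character_, length(model$stages))
  for (nm in names(model$phases)) lut[model$phases[[nm]]] <- nm
  lut[idx]
}

#' Default nine-stage esophageal progression model
#'
#' The ordered stages used throughout the synthetic cohort generator:
#' normal tissue, hyperplasia, carcinoma in situ (Tis), lamina propria
#' cancer, muscularis mucosa cancer, two submucosal invasion stages, T2
#' and T3.
#'
#' @return A `stage_model` with nine stages.
#' @export
default_stage_model <- function() {
  stage_model(c("NT", "HYP", "Tis", "LPC", "MMC", "SM1", "SM2", "T2", "T3"))
}
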