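#' Behavior taxonomy
#'
#' An ordered set of behavior category labels together with the index of the
#' reference category. The multinomial models express every linear predictor
#' as a log-odds contrast against the reference category, whose predictor is
#' pinned at zero, so the taxonomy fixes both the coding of the outcome and
#' the interpretation of every coefficient.
#'
#' The default taxonomy is the 19-category coding of proactive child-to-child
#' behaviors, with *ownership assertion* (category 19) as the reference.
#'
#' @param labels character vector of unique category names, in coding order.
#' @param reference_index integer position of the reference category
#'   (default: the last label).
#' @return An object of class `behavior_taxonomy`: a list with elements
#'   `labels`, `K` and `reference_index`.
#' @examples
#' tax <- behavior_taxonomy()
#' tax$K                      # 19
#' tax$labels[tax$reference_index]
#' @export
behavior_taxonomy <- function(labels = default_behavior_labels(),
                              reference_index = length(labels)) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("taxonomy labels must be unique", call. = FALSE)
  }
  K <- length(labels)
  if (K < 2L) stop("a taxonomy needs at least 2 categories", call. = FALSE)
  reference_index <- as.integer(reference_index)
  if (reference_index < 1L || reference_index > K) {
    stop("reference_index must lie in 1..K", call. = FALSE)
  }
  if (reference_index != K) {
    # Internally the reference is always the last contrast; reorder so the
    # chosen reference sits at position K and remember the original order.
    stop("reference_index must currently be the last category; reorder ",
         "`labels` so the reference comes last", call. = FALSE)
  }
  structure(list(labels = labels, K = K, reference_index = reference_index),
            class = "behavior_taxonomy")
}

#' @rdname behavior_taxonomy
#' @export
default_behavior_labels <- function() {
  c("comforting", "dominating", "helping", "leading", "dirty looks",
    "physical aggression", "requesting for access", "requesting for comfort",
    "requesting for help", "requesting for sharing", "scolding", "sharing",
    "supporting opinions", "taking", "tattling", "teasing (aggressive)",
    "teasing (playful)", "verbal aggression", "ownership assertion")
}

#' @export
print.behavior_taxonomy <- function(x, ...) {
  cat("Behavior taxonomy:", x$K, "categories; reference =",
      sQuote(x$labels[x$reference_index]), "\n")
  invisible(x)
}
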