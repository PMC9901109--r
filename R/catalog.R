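#' Define an event-type catalog with severity weights
#'
#' An event catalog lists the `K` component event types of a composite
#' endpoint together with their severity weights and marks the single
#' terminal type. Weights live in `(0, 1]`: a weight of 1 removes all of a
#' subject's remaining survival weight (death), while a non-fatal event of
#' weight `w` multiplies the subject's survival path by `1 - w` and leaves
#' the subject under follow-up.
#'
#' Exactly one type must be terminal, and that type must carry weight 1;
#' conversely no non-terminal type may have weight 1.
#'
#' @param types character vector of unique event-type labels.
#' @param weights numeric vector of severity weights in `(0, 1]`, one per type.
#' @param terminal label (or index) of the terminal type.
#' @return An object of class `wce_catalog`: a data frame with columns
#'   `event_type`, `weight`, `terminal`.
#' @examples
#' event_catalog(c("REMI", "CHF", "SHK", "DTH"), c(0.2, 0.3, 0.5, 1.0), "DTH")
#' @seealso [mace_catalog()] for the standard four-component MACE catalog.
#' @export
event_catalog <- function(types, weights, terminal) {
  types <- as.character(types)
  weights <- as.numeric(weights)
  if (length(types) != length(weights))
    stop_validation("`types` and `weights` must have equal length")
  if (anyDuplicated(types))
    stop_validation("event-type labels must be unique")
  if ("NONE" %in% types)
    stop_validation("'NONE' is reserved for the event-free roster sentinel")
  if (any(!is.finite(weights)) || any(weights <= 0) || any(weights > 1))
    stop_validation("all weights must lie strictly in (0, 1]")
  if (is.numeric(terminal)) terminal <- types[terminal]
  if (!terminal %in% types)
    stop_validation(sprintf("terminal type '%s' is not in the catalog", terminal))
  is_term <- types == terminal
  if (weights[is_term] != 1)
    stop_validation("the terminal type must have weight 1")
  if (any(weights[!is_term] == 1))
    stop_validation("only the terminal type may have weight 1")
  structure(
    data.frame(event_type = types, weight = weights, terminal = is_term,
               stringsAsFactors = FALSE),
    class = c("wce_catalog", "data.frame")
  )
}

#' Standard MACE catalog
#'
#' The four-component major-adverse-cardiac-event catalog used throughout the
#' package's examples: recurrent myocardial infarction (REMI, weight 0.2),
#' congestive heart failure (CHF, 0.3), cardiogenic shock (SHK, 0.5) and
#' all-cause death (DTH, 1.0, terminal). The weights are Delphi-panel
#' stakeholder severities; they are inputs to the method, not estimates.
#'
#' @return A [event_catalog()] object.
#' @export
mace_catalog <- function() {
  event_catalog(c("REMI", "CHF", "SHK", "DTH"), c(0.2, 0.3, 0.5, 1.0), "DTH")
}

#' Read or write an event catalog
#'
#' Catalogs are stored either as CSV with columns
#' `event_type,weight,terminal` or as YAML with those fields; the format is
#' chosen by file extension (`.yml`/`.yaml` vs anything else).
#'
#' @param path file path.
#' @return `read_event_catalog` returns a `wce_catalog`;
#'   `write_event_catalog` returns `path` invisibly.
#' @export
read_event_catalog <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    d <- data.frame(event_type = vapply(y, `[[`, "", "event_type"),
                    weight = vapply(y, function(e) as.numeric(e$weight), 0),
                    terminal = vapply(y, function(e) isTRUE(e$terminal), TRUE))
  } else {
    d <- read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("event_type", "weight", "terminal")
  if (!all(need %in% names(d)))
    stop_validation(sprintf("catalog file must have fields %s",
                            paste(need, collapse = ", ")))
  term <- d$event_type[as.logical(d$terminal)]
  if (length(term) != 1)
    stop_validation("catalog must mark exactly one terminal type")
  event_catalog(d$event_type, d$weight, term)
}

#' @rdname read_event_catalog
#' @param catalog a `wce_catalog`.
#' @export
write_event_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "wce_catalog"))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(lapply(seq_len(nrow(catalog)), function(i)
      list(event_type = catalog$event_type[i], weight = catalog$weight[i],
           terminal = catalog$terminal[i])), path)
  } else {
    write.csv(as.data.frame(catalog), path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @export
print.wce_catalog <- function(x, ...) {
  cat("Event-type catalog (", nrow(x), " types, terminal: ",
      x$event_type[x$terminal], ")\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

catalog_weights <- function(catalog) {
  setNames(catalog$weight, catalog$event_type)
}
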