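# Variant/attribute search, the change-detection engine over attribute
# histories (the reinterpretation trigger), and classification summaries.

norm_value <- function(x, ignore_case) {
  x <- trimws(as.character(x))
  if (ignore_case) tolower(x) else x
}

#' Define a change-detection query
#'
#' Predicates over current and previous attribute values, used to surface
#' reclassified variants — e.g. ClinVar changed from "benign" or
#' "uncertain significance" to "pathogenic". By default any strictly-prior
#' historical value may satisfy `previous_in` (the clinical question is
#' "was this ever called benign/VUS?"); `strict_previous` restricts the
#' match to the immediately preceding value.
#'
#' @param attribute attribute name (non-empty).
#' @param previous_in optional set of values matched against prior history
#'   entries.
#' @param current_equals optional value or value set the current entry must
#'   match.
#' @param since optional ISO-8601 timestamp; the current value must have
#'   been imported at or after it.
#' @param strict_previous match only the immediately preceding value?
#' @param ignore_case case-insensitive value matching? (ClinVar exports
#'   vary in capitalization.)
#' @return an object of class `change_query`.
#' @export
change_query <- function(attribute, previous_in = NULL,
                         current_equals = NULL, since = NULL,
                         strict_previous = FALSE, ignore_case = FALSE) {
  attribute <- as.character(attribute)
  if (length(attribute) != 1L || !nzchar(attribute)) {
    stop("change query: 'attribute' must be a single non-empty name",
         call. = FALSE)
  }
  if (is.null(previous_in) && is.null(current_equals)) {
    stop("change query: at least one of previous_in / current_equals ",
         "must be set", call. = FALSE)
  }
  structure(
    list(attribute = attribute,
         previous_in = if (is.null(previous_in)) NULL else
           as.character(previous_in),
         current_equals = if (is.null(current_equals)) NULL else
           as.character(current_equals),
         since = since,
         strict_previous = isTRUE(strict_previous),
         ignore_case = isTRUE(ignore_case)),
    class = "change_query"
  )
}

#' Search attribute histories for changes
#'
#' Returns exactly those variants whose named attribute currently satisfies
#' `current_equals`, has some qualifying prior entry in `previous_in` (any
#' strictly-prior value, or only the immediate predecessor under strict
#' mode), and — if `since` is set — whose current value was imported at or
#' after it. Results are in canonical variant order. An unknown attribute
#' yields an empty result.
#'
#' @param store a `variant_store`.
#' @param query a [change_query()].
#' @return data.frame with columns `variant`, `previous_value` (`NA` when
#'   `previous_in` is unset), `current_value`, `changed_at`.
#' @export
search_changes <- function(store, query) {
  stopifnot(inherits(store, "variant_store"),
            inherits(query, "change_query"))
  hits <- list()
  for (id in variant_ids(store)) {
    h <- attribute_history(store, id, query$attribute)
    n <- nrow(h)
    if (n == 0L) next
    cur <- norm_value(h$value[n], query$ignore_case)
    if (!is.null(query$current_equals) &&
        !cur %in% norm_value(query$current_equals, query$ignore_case)) {
      next
    }
    prev_match <- NA_character_
    if (!is.null(query$previous_in)) {
      if (n < 2L) next
      prior_idx <- if (query$strict_previous) n - 1L else seq_len(n - 1L)
      wanted <- norm_value(query$previous_in, query$ignore_case)
      ok <- norm_value(h$value[prior_idx], query$ignore_case) %in% wanted
      if (!any(ok)) next
      prev_match <- h$value[prior_idx[max(which(ok))]]
    }
    if (!is.null(query$since) && h$imported_at[n] < query$since) next
    hits[[length(hits) + 1L]] <- data.frame(
      variant = id, previous_value = prev_match,
      current_value = h$value[n], changed_at = h$imported_at[n],
      stringsAsFactors = FALSE
    )
  }
  if (length(hits) == 0L) {
    return(data.frame(variant = character(0),
                      previous_value = character(0),
                      current_value = character(0),
                      changed_at = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Search variants by current attribute values
#'
#' @param store a `variant_store`.
#' @param criteria named character vector of `attribute = value` pairs; a
#'   variant matches if every named attribute's current value equals the
#'   given value. Empty criteria match all variants.
#' @param ignore_case case-insensitive value comparison?
#' @return data.frame with column `variant` plus one column per criterion
#'   attribute holding the current values, in canonical variant order.
#' @export
search_variants <- function(store, criteria = character(0),
                            ignore_case = FALSE) {
  stopifnot(inherits(store, "variant_store"))
  criteria <- as_named_chr(criteria)
  ids <- variant_ids(store)
  keep <- character(0)
  vals <- list()
  for (id in ids) {
    ok <- TRUE
    cur <- character(0)
    for (nm in names(criteria)) {
      v <- current_attribute(store, id, nm)
      if (is.na(v) ||
          !identical(norm_value(v, ignore_case),
                     norm_value(criteria[[nm]], ignore_case))) {
        ok <- FALSE
        break
      }
      cur[nm] <- v
    }
    if (ok) {
      keep <- c(keep, id)
      vals[[id]] <- cur
    }
  }
  out <- data.frame(variant = keep, stringsAsFactors = FALSE)
  for (nm in names(criteria)) {
    out[[nm]] <- vapply(vals, `[[`, "", nm, USE.NAMES = FALSE)
  }
  out
}

# Half-up rounding to reproduce printed-percentage arithmetic (base R's
# round() is round-half-even).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Summary of classified variants by pathogenicity tier
#'
#' Counts variants whose current `"classification"` attribute is set, per
#' IARC tier, with percentages of the classified total rounded half-up to
#' one decimal. Unclassified variants are excluded from the denominator.
#'
#' @param store a `variant_store`.
#' @return data.frame with columns `code`, `label`, `count`, `percent`
#'   (tiers C5 down to C1; zero rows if nothing is classified), with the
#'   classified total in attribute `"total"`.
#' @export
classification_summary <- function(store) {
  stopifnot(inherits(store, "variant_store"))
  tiers <- classification_tiers()
  counts <- stats::setNames(integer(nrow(tiers)), tiers$code)
  for (id in ls(store$attrs, all.names = TRUE)) {
    hist <- get(id, envir = store$attrs)[["classification"]]
    if (is.null(hist) || length(hist) == 0L) next
    cur <- hist[[length(hist)]]$value
    if (cur %in% names(counts)) counts[cur] <- counts[cur] + 1L
  }
  total <- sum(counts)
  if (total == 0L) {
    out <- data.frame(code = character(0), label = character(0),
                      count = integer(0), percent = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "total") <- 0L
    return(out)
  }
  out <- data.frame(
    code = rev(tiers$code), label = rev(tiers$label),
    count = unname(counts[rev(tiers$code)]),
    percent = round_half_up(100 * unname(counts[rev(tiers$code)]) / total),
    stringsAsFactors = FALSE
  )
  attr(out, "total") <- total
  out
}
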