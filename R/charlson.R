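#' Charlson comorbidity index from diagnosis codes
#'
#' Scores a multiset of diagnosis codes against a condition/weight map. Each
#' condition counts once regardless of how many of its codes appear, so the
#' score is permutation-invariant and monotone non-decreasing in the code set.
#' Codes matching `exclude` are removed before scoring, which is how the
#' COPD-free variant of the index is computed.
#'
#' @param codes Character vector of diagnosis codes (duplicates allowed).
#' @param weight_map Tibble with columns `condition`, `weight`, `pattern`
#'   (prefix or exact match), as returned by [default_charlson_map()].
#' @param exclude Optional character vector of code patterns to drop before
#'   scoring (e.g. the COPD set).
#' @return A single non-negative integer score. Unmatched codes score 0.
#' @export
#' @examples
#' charlson(c("I21.4", "I50.9", "I50.1"))  # MI + CHF = 2
charlson <- function(codes, weight_map = default_charlson_map(), exclude = NULL) {
  if (length(codes) == 0L) return(0L)
  codes <- codes[!is.na(codes) & nzchar(codes)]
  if (!is.null(exclude)) codes <- codes[!match_codes(codes, exclude)]
  if (length(codes) == 0L) return(0L)
  hit <- weight_map |>
    group_by(.data$condition, .data$weight) |>
    summarise(matched = any(match_codes(.env$codes, .data$pattern)),
              .groups = "drop") |>
    filter(.data$matched)
  as.integer(sum(hit$weight))
}

# vectorised scorer over a long (patient_id, code) table; returns one row per
# patient present in `dx_long`
charlson_scores <- function(dx_long, weight_map = default_charlson_map(),
                            exclude = NULL) {
  if (nrow(dx_long) == 0L) {
    return(tibble(patient_id = character(), cci = integer()))
  }
  codes <- dx_long$code
  if (!is.null(exclude)) {
    keep <- !match_codes(codes, exclude)
    dx_long <- dx_long[keep, , drop = FALSE]
    codes <- dx_long$code
  }
  pieces <- lapply(seq_len(nrow(weight_map)), function(i) {
    hit <- startsWith(codes, weight_map$pattern[i])
    if (!any(hit)) return(NULL)
    tibble(patient_id = dx_long$patient_id[hit],
           condition = weight_map$condition[i],
           weight = weight_map$weight[i])
  })
  out <- bind_rows(pieces)
  if (nrow(out) == 0L) {
    return(tibble(patient_id = character(), cci = integer()))
  }
  out <- out |> distinct(.data$patient_id, .data$condition, .data$weight)
  agg <- rowsum(out$weight, out$patient_id)
  tibble(patient_id = rownames(agg), cci = as.integer(agg[, 1]))
}
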