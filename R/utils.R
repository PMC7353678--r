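#' @importFrom rlang %||% abort warn .data .env
#' @importFrom stats plogis rbinom rgamma rgeom rexp rpois runif quantile
#'   model.matrix glm binomial quasibinomial Gamma coef vcov predict
#'   weighted.mean as.formula pnorm qnorm setNames
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows bind_cols n n_distinct lag lead
#'   first last row_number if_else case_when distinct pull rename relocate
#'   across all_of any_of cummean coalesce slice_min slice rename_with
#' @importFrom tidyr uncount replace_na pivot_longer separate_rows
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom data.table as.data.table data.table setorder := .N
NULL

.datatable.aware <- TRUE

# prefix/exact matcher used for all diagnosis, procedure and drug code sets
match_codes <- function(codes, patterns) {
  out <- rep(FALSE, length(codes))
  if (length(patterns) == 0L || length(codes) == 0L) return(out)
  codes <- as.character(codes)
  for (p in patterns) out <- out | startsWith(codes, p)
  out & !is.na(codes)
}

# diagnosis fields carry an ordered ';'-separated code list; position 1 is primary
split_dx <- function(dx) strsplit(ifelse(is.na(dx), "", dx), ";", fixed = TRUE)

first_dx <- function(dx) {
  out <- sub(";.*$", "", dx)
  out[is.na(dx)] <- NA_character_
  out
}

# does any code in a ';'-separated diagnosis list match a pattern set?
# vectorised: a pattern matches at the string start or right after a ';'
dx_match_any <- function(dx, patterns) {
  out <- rep(FALSE, length(dx))
  if (length(patterns) == 0L || length(dx) == 0L) return(out)
  dx_chr <- ifelse(is.na(dx), "", dx)
  for (p in patterns) {
    out <- out | startsWith(dx_chr, p) |
      grepl(paste0(";", p), dx_chr, fixed = TRUE)
  }
  out
}

wmean <- function(x, w) sum(w * x) / sum(w)

# weighted sample variance; reduces to var(x) at unit weights
wvar <- function(x, w) {
  m <- wmean(x, w)
  sum(w * (x - m)^2) / (sum(w) - 1)
}

# independent sub-seed per RNG stream, kept inside 32-bit integer range
stream_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) * 48271 + 1103 * k) %% 2147483629)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("configuration error: `%s` must be a single positive number", name))
  }
  invisible(x)
}

year_of <- function(date) as.integer(format(date, "%Y"))
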