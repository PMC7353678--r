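# Brute-force day-marking oracles for coverage, PDC and gap detection.
# A fill adds its supply to a pill bank on its service date; each day with a
# positive bank is covered and consumes one day of supply. This reproduces
# overlap appending one day at a time, independent of the interval algebra
# used by the package.

oracle_covered <- function(dates, supplies, horizon) {
  covered <- logical(horizon + 1)
  bank <- 0L
  for (d in 0:horizon) {
    bank <- bank + sum(supplies[dates == d])
    if (bank > 0L) {
      covered[d + 1] <- TRUE
      bank <- bank - 1L
    }
  }
  covered
}

oracle_pdc <- function(dates, supplies, window_end) {
  covered <- oracle_covered(dates, supplies, window_end)
  min(sum(covered) / (window_end + 1), 1.0)
}

# last covered day before the first run of >= gap_days uncovered days that
# starts after the first covered day and ends by follow_up_end; NA if none
oracle_disc <- function(dates, supplies, follow_up_end, gap_days = 60) {
  covered <- oracle_covered(dates, supplies, follow_up_end)
  first_cov <- which(covered)[1]
  if (is.na(first_cov)) return(NA_integer_)
  run <- 0L
  last_cov <- first_cov - 1L  # 0-based day of last covered day seen
  for (d in (first_cov - 1L):follow_up_end) {
    if (covered[d + 1]) {
      run <- 0L
      last_cov <- d
    } else {
      run <- run + 1L
      if (run >= gap_days) return(as.integer(last_cov))
    }
  }
  NA_integer_
}

random_fill_pattern <- function() {
  k <- sample(1:6, 1)
  list(dates = sort(sample(0:300, k)),
       supplies = sample(1:40, k, replace = TRUE),
       fu = sample(150:400, 1))
}
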