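# Synthetic CDM-shaped EHR generator ----------------------------------------
#
# Emulates the data-generating structure the analysis assumes: era-dependent
# first-line drug choice, a per-line switching process over distinct drugs,
# per-year Poisson repeat-injection counts, diagnosis timing relative to
# index, exclusion-diagnosis contamination and right-censoring. Every drug in
# a patient's line sequence receives its line-opening injection plus
# Poisson(year1_rate - 1) further year-1 injections, so the expected year-1
# count per line drug is exactly year1_rate and every line is visible in the
# exposure table.

#' Simulation configuration
#'
#' Defaults emulate the published multi-hospital cohort: era weights from the
#' per-era patient counts (118 / 790 / 2378 of 3286), per-era first-line
#' choice probabilities anchored to the reported first-line shares
#' (triamcinolone-dominated before 2006, bevacizumab-dominated after),
#' `switch_prob` 0.19 (the reported level-1 switch fraction), switch targets
#' favoring steroids after anti-VEGF and bevacizumab after steroids (with no
#' steroid-to-steroid switching), per-drug year-1/year-2 injection rates
#' anchored to the published intensity tables, and a censoring mixture
#' putting mass below one year, between one and two years, and beyond two
#' years of follow-up.
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer RNG seed; `simulate_cdm()` is reproducible given it.
#' @param era_weights Named probabilities over eras `P1`, `P2`, `P3`.
#' @param first_line_probs Matrix (era x ingredient) of first-line choice
#'   probabilities; rows must sum to 1.
#' @param switch_prob Per-line probability that a further line is ever
#'   started.
#' @param switch_target_probs Matrix (current ingredient x target ingredient)
#'   with zero diagonal and rows summing to 1; at draw time the row is
#'   renormalized over drugs not yet used (if no unused drug has positive
#'   probability the sequence stops).
#' @param year1_rate,year2_rate Named per-drug mean injection counts for the
#'   first and second post-index years; `year1_rate` must be at least 1
#'   (it includes the line-opening injection).
#' @param interval_days_mean Mean gap in days between successive line starts.
#' @param dx_within_window_prob Probability that the RVO diagnosis falls in
#'   `[index, index + 180)` (otherwise it falls after the window and the
#'   patient must be filtered out by the cohort builder).
#' @param exclusion_dx_prob Probability of carrying an exclusion diagnosis.
#' @param censor_followup_days Censoring mixture: list with `probs` and
#'   `ranges` (list of integer `c(lo, hi)` day ranges, sampled uniformly).
#' @param sites Character vector of site labels; patients are assigned
#'   uniformly at random.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 1000L,
                              seed = 20260921L,
                              era_weights = c(P1 = 118, P2 = 790,
                                              P3 = 2378) / 3286,
                              first_line_probs = default_first_line_probs(),
                              switch_prob = 0.19,
                              switch_target_probs = default_switch_targets(),
                              year1_rate = c(bevacizumab = 2.63,
                                             ranibizumab = 2.05,
                                             aflibercept = 1.50,
                                             triamcinolone = 1.29,
                                             dexamethasone = 1.30),
                              year2_rate = c(bevacizumab = 0.80,
                                             ranibizumab = 0.59,
                                             aflibercept = 0.25,
                                             triamcinolone = 0.51,
                                             dexamethasone = 0.63),
                              interval_days_mean = 60,
                              dx_within_window_prob = 1.0,
                              exclusion_dx_prob = 0.05,
                              censor_followup_days = default_censoring(),
                              sites = "S1") {
  stopifnot(n_patients >= 0, switch_prob >= 0, switch_prob <= 1,
            dx_within_window_prob >= 0, dx_within_window_prob <= 1,
            exclusion_dx_prob >= 0, exclusion_dx_prob <= 1,
            interval_days_mean > 0, length(sites) >= 1)
  eras <- c("P1", "P2", "P3")
  if (is.null(names(era_weights))) names(era_weights) <- eras
  era_weights <- era_weights[eras]
  check_probs(era_weights, "era_weights")
  first_line_probs <- as.matrix(first_line_probs)[eras, .ingredients]
  for (e in eras) check_probs(first_line_probs[e, ],
                              paste0("first_line_probs[", e, ",]"))
  switch_target_probs <- as.matrix(switch_target_probs)[.ingredients,
                                                        .ingredients]
  if (any(diag(switch_target_probs) != 0)) {
    stop("switch_target_probs must have a zero diagonal", call. = FALSE)
  }
  for (d in .ingredients) check_probs(switch_target_probs[d, ],
                                      paste0("switch_target_probs[", d, ",]"))
  year1_rate <- year1_rate[.ingredients]
  year2_rate <- year2_rate[.ingredients]
  if (any(is.na(year1_rate)) || any(year1_rate < 1)) {
    stop("year1_rate must be defined and >= 1 for every drug ",
         "(it includes the line-opening injection)", call. = FALSE)
  }
  if (any(is.na(year2_rate)) || any(year2_rate < 0)) {
    stop("year2_rate must be defined and >= 0 for every drug", call. = FALSE)
  }
  cf <- censor_followup_days
  stopifnot(is.list(cf), !is.null(cf$probs), !is.null(cf$ranges),
            length(cf$probs) == length(cf$ranges))
  check_probs(cf$probs, "censor_followup_days$probs")
  for (r in cf$ranges) stopifnot(length(r) == 2, r[1] >= 1, r[1] <= r[2])
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 era_weights = era_weights,
                 first_line_probs = first_line_probs,
                 switch_prob = switch_prob,
                 switch_target_probs = switch_target_probs,
                 year1_rate = year1_rate, year2_rate = year2_rate,
                 interval_days_mean = interval_days_mean,
                 dx_within_window_prob = dx_within_window_prob,
                 exclusion_dx_prob = exclusion_dx_prob,
                 censor_followup_days = cf, sites = sites),
            class = "simulation_config")
}

check_probs <- function(p, what) {
  if (any(is.na(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop(what, " must be non-negative and sum to 1", call. = FALSE)
  }
  invisible(p)
}

#' @rdname simulation_config
#' @export
default_first_line_probs <- function() {
  m <- rbind(
    P1 = c(0.0100, 0.0000, 0.0000, 0.9900, 0.0000),
    P2 = c(0.7380, 0.0080, 0.0000, 0.2520, 0.0020),
    P3 = c(0.8730, 0.0190, 0.0016, 0.0749, 0.0315)
  )
  colnames(m) <- .ingredients
  m
}

#' @rdname simulation_config
#' @export
default_switch_targets <- function() {
  m <- rbind(
    bevacizumab   = c(0.00, 0.17, 0.05, 0.45, 0.33),
    ranibizumab   = c(0.60, 0.00, 0.05, 0.20, 0.15),
    aflibercept   = c(0.60, 0.10, 0.00, 0.15, 0.15),
    triamcinolone = c(0.85, 0.10, 0.05, 0.00, 0.00),
    dexamethasone = c(0.85, 0.10, 0.05, 0.00, 0.00)
  )
  colnames(m) <- .ingredients
  m
}

#' @rdname simulation_config
#' @export
default_censoring <- function() {
  list(probs = c(0.20, 0.25, 0.55),
       ranges = list(c(60L, 364L), c(365L, 729L), c(730L, 1460L)))
}

# sample one followup length per mixture component assignment
draw_followup <- function(n, cf) {
  comp <- sample.int(length(cf$probs), n, replace = TRUE, prob = cf$probs)
  vapply(comp, function(k) {
    r <- cf$ranges[[k]]
    if (r[1] == r[2]) as.integer(r[1]) else
      as.integer(sample(seq.int(r[1], r[2]), 1))
  }, integer(1))
}

#' Generate a synthetic CDM-shaped dataset
#'
#' Draws patients under `config`, writes their events into the four raw
#' tables and resolves them through the same path as a file load. Patients
#' whose diagnosis falls outside the inclusion window or who carry an
#' exclusion diagnosis are emitted anyway (the cohort builder must filter
#' them) and flagged in the ground truth. Exposures after the observation
#' end are truncated, exactly as a source database would not contain them;
#' `observed_lines` and the per-year counts in the ground truth describe the
#' emitted (post-truncation) data, `true_lines` the underlying sequence.
#'
#' Sets the RNG seed from `config$seed`; identical configs produce identical
#' tables.
#'
#' @param config A [simulation_config()].
#' @param registry Concept registry used to emit codes and resolve tables.
#' @return List with `tables` (a `cdm_tables`) and `ground_truth` (tibble:
#'   `person_id`, `site_id`, `era`, `index_date`, `followup_days`,
#'   `eligible`, `ineligible_reason`, `first_drug`, `true_lines`,
#'   `observed_lines`, `yr1_injections`, `yr2_injections`).
#' @export
simulate_cdm <- function(config = simulation_config(),
                         registry = default_concept_registry()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_patients
  eras <- c("P1", "P2", "P3")
  era_bounds <- default_era_bounds()

  if (n == 0) {
    empty <- empty_raw_tables()
    return(list(
      tables = cdm_tables(empty$person, empty$drug_exposure,
                          empty$condition_occurrence,
                          empty$observation_period, registry = registry),
      ground_truth = tibble::tibble(
        person_id = character(), site_id = character(), era = character(),
        index_date = as.Date(character()), followup_days = integer(),
        eligible = logical(), ineligible_reason = character(),
        first_drug = character(), true_lines = character(),
        observed_lines = character(), yr1_injections = integer(),
        yr2_injections = integer())))
  }

  person_id <- sprintf("sim%06d", seq_len(n))
  era <- eras[sample.int(3, n, replace = TRUE, prob = config$era_weights)]
  index_date <- as.Date(vapply(era, function(e) {
    i <- match(e, era_bounds$era)
    sample(seq.int(as.integer(era_bounds$start[i]),
                   as.integer(era_bounds$end[i])), 1)
  }, numeric(1)), origin = "1970-01-01")
  site_id <- sample(config$sites, n, replace = TRUE)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  age <- pmin(pmax(round(stats::rnorm(n, 62.9, 12)), 30), 95)
  birth_year <- as.integer(format(index_date, "%Y")) - as.integer(age)

  first_drug <- character(n)
  for (e in eras) {
    idx <- which(era == e)
    if (length(idx) > 0) {
      first_drug[idx] <- .ingredients[
        sample.int(5, length(idx), replace = TRUE,
                   prob = config$first_line_probs[e, ])]
    }
  }

  followup <- draw_followup(n, config$censor_followup_days)
  dx_ok <- stats::runif(n) < config$dx_within_window_prob
  has_excl <- stats::runif(n) < config$exclusion_dx_prob

  rvo_codes <- registry[["rvo"]]$codes
  excl_codes <- registry[["exclusion"]]$codes
  drug_code_of <- vapply(.ingredients,
                         function(d) registry[[d]]$codes$code[1], character(1))
  drug_vocab_of <- vapply(.ingredients,
                          function(d) registry[[d]]$codes$vocabulary[1],
                          character(1))

  exp_pid <- exp_ing <- character(0)
  exp_day <- integer(0)
  cond_pid <- cond_code <- cond_vocab <- character(0)
  cond_day <- integer(0)
  true_lines <- observed_lines <- character(n)
  yr1_obs <- yr2_obs <- integer(n)
  reason <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    # line sequence
    lines <- first_drug[i]
    repeat {
      if (length(lines) >= 5) break
      if (stats::runif(1) >= config$switch_prob) break
      w <- config$switch_target_probs[lines[length(lines)], ]
      w[lines] <- 0
      if (sum(w) <= 0) break
      lines <- c(lines, sample(.ingredients, 1, prob = w))
    }
    true_lines[i] <- seq_string(lines)

    # line start days, strictly increasing and comfortably inside year 1
    starts <- integer(length(lines))
    for (j in seq_along(lines)[-1]) {
      gap <- round(config$interval_days_mean * stats::runif(1, 0.5, 1.5))
      starts[j] <- min(starts[j - 1] + max(gap, 1), 300L + j)
    }

    # injections per line drug: year 1 = line start + Poisson extras, year 2
    # plain Poisson; distinct days per drug so no same-day self-duplicates
    days <- list()
    for (j in seq_along(lines)) {
      d <- lines[j]
      n1_extra <- stats::rpois(1, config$year1_rate[d] - 1)
      avail1 <- seq.int(starts[j] + 1L, 364L)
      extras <- if (n1_extra > 0) {
        sort(sample(avail1, min(n1_extra, length(avail1))))
      } else integer(0)
      n2 <- stats::rpois(1, config$year2_rate[d])
      days2 <- if (n2 > 0) sort(sample(365:729, min(n2, 365))) else integer(0)
      days[[d]] <- c(starts[j], extras, days2)
    }
    # right-censoring: the database only contains events under observation
    days <- lapply(days, function(x) x[x <= followup[i]])
    all_days <- unlist(days, use.names = FALSE)
    all_ing <- rep(names(days), lengths(days))
    ord <- order(all_days, ingredient_rank(all_ing))
    observed_lines[i] <- seq_string(unique(all_ing[ord]))
    yr1_obs[i] <- sum(all_days < 365L)
    yr2_obs[i] <- sum(all_days >= 365L & all_days < 730L)
    exp_pid <- c(exp_pid, rep(person_id[i], length(all_days)))
    exp_ing <- c(exp_ing, all_ing)
    exp_day <- c(exp_day, all_days)

    # RVO diagnosis
    if (dx_ok[i]) {
      dx_day <- sample(seq.int(0L, min(179L, followup[i])), 1)
      emit_dx <- TRUE
    } else {
      dx_day <- sample(181:400, 1)
      emit_dx <- dx_day <= followup[i]
      reason[i] <- "no_rvo_dx_in_window"
    }
    if (emit_dx) {
      k <- sample.int(nrow(rvo_codes), 1)
      cond_pid <- c(cond_pid, person_id[i])
      cond_code <- c(cond_code, rvo_codes$code[k])
      cond_vocab <- c(cond_vocab, rvo_codes$vocabulary[k])
      cond_day <- c(cond_day, dx_day)
    }

    # exclusion diagnosis (before or shortly after index, always observable)
    if (has_excl[i]) {
      hi <- min(60L, followup[i])
      pool <- c(seq.int(-180L, -1L), if (hi >= 10L) seq.int(10L, hi))
      ex_day <- sample(pool, 1)
      k <- sample.int(nrow(excl_codes), 1)
      cond_pid <- c(cond_pid, person_id[i])
      cond_code <- c(cond_code, excl_codes$code[k])
      cond_vocab <- c(cond_vocab, excl_codes$vocabulary[k])
      cond_day <- c(cond_day, ex_day)
      if (is.na(reason[i])) reason[i] <- "exclusion_dx"
    }
  }

  eligible <- dx_ok & !has_excl

  person <- tibble::tibble(person_id = person_id, birth_year = birth_year,
                           sex = sex, site_id = site_id)
  exp_dates <- index_date[match(exp_pid, person_id)] + exp_day
  cond_dates <- index_date[match(cond_pid, person_id)] + cond_day
  drug_exposure <- tibble::tibble(
    person_id = exp_pid,
    drug_code = unname(drug_code_of[exp_ing]),
    vocabulary = unname(drug_vocab_of[exp_ing]),
    exposure_date = exp_dates)
  condition_occurrence <- tibble::tibble(
    person_id = cond_pid, condition_code = cond_code,
    vocabulary = cond_vocab,
    condition_date = cond_dates)
  observation_period <- tibble::tibble(
    person_id = person_id, start_date = index_date,
    end_date = index_date + followup)

  tables <- cdm_tables(person, drug_exposure, condition_occurrence,
                       observation_period, registry = registry)
  ground_truth <- tibble::tibble(
    person_id = person_id, site_id = site_id, era = era,
    index_date = index_date, followup_days = followup,
    eligible = eligible, ineligible_reason = reason,
    first_drug = first_drug, true_lines = true_lines,
    observed_lines = observed_lines,
    yr1_injections = yr1_obs, yr2_injections = yr2_obs)
  list(tables = tables, ground_truth = ground_truth)
}

# Closed-form expectations ---------------------------------------------------

# exhaustive enumeration of the line-switching process: list of
# (sequence, probability) pairs for a given first drug
enumerate_sequences <- function(first, switch_prob, targets) {
  out <- list()
  recurse <- function(seq, q) {
    if (length(seq) == 5) {
      out[[length(out) + 1]] <<- list(seq = seq, p = q)
      return(invisible())
    }
    w <- targets[seq[length(seq)], ]
    w[seq] <- 0
    s <- sum(w)
    if (s <= 0 || switch_prob == 0) {
      out[[length(out) + 1]] <<- list(seq = seq, p = q)
      return(invisible())
    }
    out[[length(out) + 1]] <<- list(seq = seq, p = q * (1 - switch_prob))
    for (d in .ingredients[w > 0]) {
      recurse(c(seq, d), q * switch_prob * w[d] / s)
    }
  }
  recurse(first, 1)
  out
}

#' Closed-form expected summaries for a simulation configuration
#'
#' Exact expectations (via exhaustive enumeration of the at-most-five-line
#' switching process) of the quantities the analysis pipeline estimates,
#' with standard errors at the configured sample size. The estimands are
#' defined on subsets right-censoring cannot distort: first-line shares over
#' all included patients, the level-1 switch fraction over members followed
#' at least one year, and the year-1 mean over members followed at least two
#' years (the sensitivity-analysis denominator).
#'
#' The headline estimands carry standard errors at the configured
#' `n_patients` (cohort level, eras pooled); per-era breakdowns are also
#' returned for finer-grained inspection.
#'
#' @param config A [simulation_config()].
#' @return List with `inclusion_prob`, `p_followup_1y`, `p_followup_2y`,
#'   `first_line_shares` (cohort-level tibble `ingredient`, `share`, `se`,
#'   `n_expected`), `switch_level1` (tibble `switched_fraction`, `se`,
#'   `n_expected`), `year1_mean` (one-row tibble `mean`, `se`, `n_expected`),
#'   and per-era breakdowns `first_line_shares_by_era` and
#'   `year1_mean_by_era`.
#' @export
expected_summaries <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  eras <- c("P1", "P2", "P3")
  p_inc <- config$dx_within_window_prob * (1 - config$exclusion_dx_prob)
  cf <- config$censor_followup_days
  p_fu_at_least <- function(days) {
    sum(vapply(seq_along(cf$probs), function(k) {
      r <- cf$ranges[[k]]
      cf$probs[k] * max(0, min(r[2], Inf) - max(r[1], days) + 1) /
        (r[2] - r[1] + 1)
    }, numeric(1)))
  }
  p_fu1 <- p_fu_at_least(365)
  p_fu2 <- p_fu_at_least(730)

  n_inc <- config$n_patients * config$era_weights * p_inc
  n_all <- config$n_patients * p_inc

  share_tbl <- function(p, n) {
    tibble::tibble(ingredient = .ingredients, share = unname(p),
                   se = sqrt(unname(p) * (1 - unname(p)) / max(n, 1)),
                   n_expected = n)
  }
  first_line_shares_by_era <- dplyr::bind_rows(lapply(eras, function(e) {
    dplyr::mutate(share_tbl(config$first_line_probs[e, ], n_inc[[e]]),
                  era = e, .before = 1)
  }))
  # cohort-level shares: eras pooled with their weights
  p_pooled <- drop(config$era_weights %*% config$first_line_probs)
  first_line_shares <- share_tbl(p_pooled, n_all)

  n_sw <- config$n_patients * p_inc * p_fu1
  switch_level1 <- tibble::tibble(
    switched_fraction = config$switch_prob,
    se = sqrt(config$switch_prob * (1 - config$switch_prob) / max(n_sw, 1)),
    n_expected = n_sw)

  # mean/variance of the total year-1 injection count given first-line
  # choice probabilities p0 over drugs (exact enumeration of the switching
  # process; the count for each line drug is 1 + Poisson(year1_rate - 1))
  year1_moments <- function(p0) {
    seqs <- list()
    for (d in .ingredients) {
      if (p0[[d]] > 0) {
        sub <- enumerate_sequences(d, config$switch_prob,
                                   config$switch_target_probs)
        seqs <- c(seqs, lapply(sub, function(s) {
          list(seq = s$seq, p = s$p * p0[[d]])
        }))
      }
    }
    m_s <- vapply(seqs, function(s) sum(config$year1_rate[s$seq]), numeric(1))
    v_s <- vapply(seqs, function(s) sum(config$year1_rate[s$seq] - 1),
                  numeric(1))
    p_s <- vapply(seqs, function(s) s$p, numeric(1))
    mu <- sum(p_s * m_s)
    c(mean = mu, var = sum(p_s * (v_s + m_s^2)) - mu^2)
  }
  year1_mean_by_era <- dplyr::bind_rows(lapply(eras, function(e) {
    mm <- year1_moments(config$first_line_probs[e, ])
    n_e <- n_inc[[e]] * p_fu2
    tibble::tibble(era = e, mean = mm[["mean"]],
                   se = sqrt(mm[["var"]] / max(n_e, 1)), n_expected = n_e)
  }))
  mm <- year1_moments(p_pooled)
  n_y1 <- n_all * p_fu2
  year1_mean <- tibble::tibble(mean = mm[["mean"]],
                               se = sqrt(mm[["var"]] / max(n_y1, 1)),
                               n_expected = n_y1)

  list(inclusion_prob = p_inc, p_followup_1y = p_fu1, p_followup_2y = p_fu2,
       first_line_shares = first_line_shares,
       switch_level1 = switch_level1,
       year1_mean = year1_mean,
       first_line_shares_by_era = first_line_shares_by_era,
       year1_mean_by_era = year1_mean_by_era)
}
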