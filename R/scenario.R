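#' Per-arm dropout rates for a named dropout pattern
#'
#' The three patterns used throughout the simulation grid: `equal` deletes 30%
#' of final-visit observations in each arm; `unequal1` deletes 20% in control
#' and 40% in treatment; `unequal2` deletes 40% in control and 20% in
#' treatment.
#'
#' @param pattern one of `"equal"`, `"unequal1"`, `"unequal2"`.
#' @return named numeric vector with elements `control` and `treatment`.
#' @export
#' @examples
#' dropout_rates("unequal1")
dropout_rates <- function(pattern = c("equal", "unequal1", "unequal2")) {
  pattern <- match.arg(pattern)
  switch(pattern,
    equal    = c(control = 0.30, treatment = 0.30),
    unequal1 = c(control = 0.20, treatment = 0.40),
    unequal2 = c(control = 0.40, treatment = 0.20)
  )
}

#' Describe one simulation scenario cell
#'
#' A scenario fixes everything needed to generate and analyze replicates of a
#' two-arm longitudinal binary trial: the baseline event probability
#' (prevalence), the within-subject outcome correlation `rho` (induced by a
#' Beta-distributed subject-level event probability), the total sample size,
#' the hypothesis under which data are generated, the per-visit treatment
#' probability increment `delta`, the dropout mechanism and per-arm rates, the
#' number of Monte Carlo replicates and the root seed.
#'
#' If `n_total` is omitted it is computed from the two-proportion sample-size
#' formula ([required_sample_size()]) for 80% power at two-sided alpha 0.05 to
#' detect the end-of-study risk difference `delta * (n_visits - 1)`, which
#' gives 398 for prevalence 0.1 and 776 for prevalence 0.5 at the defaults.
#'
#' @param prevalence baseline (visit 1) event probability, in (0,1).
#' @param rho within-subject correlation of repeated outcomes, in (0,1).
#' @param n_total total number of subjects (even; 1:1 allocation). Computed
#'   from `prevalence`, `delta` and `n_visits` when `NULL`.
#' @param hypothesis `"alternative"` (treatment-arm probability rises by
#'   `delta` per visit) or `"null"` (constant probability in both arms).
#' @param delta per-visit increment of the treatment-arm event probability.
#' @param n_visits number of repeated measurements per subject (>= 2).
#' @param mechanism dropout mechanism at the final visit: `"none"`, `"MCAR"`,
#'   `"MAR1"` (prior responders more likely missing, gamma2 = +1.5) or
#'   `"MAR2"` (prior responders less likely missing, gamma2 = -1.5).
#' @param dropout_pattern per-arm rate pattern, see [dropout_rates()]. Ignored
#'   when `mechanism = "none"`.
#' @param n_reps number of Monte Carlo replicates.
#' @param seed integer root seed for the scenario; per-replicate seeds are
#'   derived from it so individual replicates are reproducible.
#' @return an object of class `scenario_config` (a validated list).
#' @export
#' @examples
#' scenario_config(prevalence = 0.1, rho = 0.3)
scenario_config <- function(prevalence, rho, n_total = NULL,
                            hypothesis = c("alternative", "null"),
                            delta = 0.05, n_visits = 3L,
                            mechanism = c("none", "MCAR", "MAR1", "MAR2"),
                            dropout_pattern = c("equal", "unequal1", "unequal2"),
                            n_reps = 1000L, seed = 1L) {
  hypothesis <- match.arg(hypothesis)
  mechanism <- match.arg(mechanism)
  dropout_pattern <- match.arg(dropout_pattern)
  stopifnot(
    is.numeric(prevalence), length(prevalence) == 1L,
    prevalence > 0, prevalence < 1,
    is.numeric(rho), length(rho) == 1L, rho > 0, rho < 1,
    is.numeric(delta), length(delta) == 1L, delta >= 0,
    is.numeric(n_visits), length(n_visits) == 1L, n_visits >= 2,
    is.numeric(n_reps), length(n_reps) == 1L, n_reps >= 1,
    is.numeric(seed), length(seed) == 1L
  )
  n_visits <- as.integer(n_visits)
  if (is.null(n_total)) {
    n_total <- required_sample_size(prevalence,
                                    prevalence + delta * (n_visits - 1L))
  }
  n_total <- as.integer(n_total)
  if (n_total <= 0L || n_total %% 2L != 0L)
    stop("`n_total` must be a positive even integer (1:1 allocation)")
  if (hypothesis == "alternative" &&
      prevalence + delta * (n_visits - 1L) > 1 + 1e-12)
    stop("mean treatment-arm probability exceeds 1 at the final visit; ",
         "reduce `delta`, `n_visits` or `prevalence`")
  structure(
    list(prevalence = prevalence, rho = rho, n_total = n_total,
         hypothesis = hypothesis, delta = delta, n_visits = n_visits,
         mechanism = mechanism, dropout_pattern = dropout_pattern,
         n_reps = as.integer(n_reps), seed = as.integer(seed)),
    class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario: prevalence", x$prevalence, "rho", x$rho,
      "N", x$n_total, paste0("(", x$hypothesis, ")"), "\n")
  cat("  visits", x$n_visits, "delta", x$delta,
      "mechanism", x$mechanism,
      if (x$mechanism != "none") paste0("[", x$dropout_pattern, "]") else "",
      "\n")
  cat("  replicates", x$n_reps, "seed", x$seed, "\n")
  invisible(x)
}

#' Read a scenario grid from a plain-text config file
#'
#' The file uses Debian-control (DCF) syntax: one `key: value` pair per line,
#' scenarios separated by blank lines. Recognised keys are the arguments of
#' [scenario_config()]; omitted keys take that function's defaults.
#'
#' @param path path to the config file.
#' @return list of `scenario_config` objects.
#' @export
#' @examples
#' cfg_file <- system.file("extdata", "example_scenarios.dcf",
#'                         package = "dropoutsim")
#' read_scenario_grid(cfg_file)
read_scenario_grid <- function(path) {
  blocks <- read.dcf(path)
  num_keys <- c("prevalence", "rho", "n_total", "delta", "n_visits",
                "n_reps", "seed")
  chr_keys <- c("hypothesis", "mechanism", "dropout_pattern")
  lapply(seq_len(nrow(blocks)), function(i) {
    row <- blocks[i, ]
    args <- list()
    for (k in intersect(names(row), num_keys))
      if (!is.na(row[[k]])) args[[k]] <- as.numeric(row[[k]])
    for (k in intersect(names(row), chr_keys))
      if (!is.na(row[[k]])) args[[k]] <- trimws(row[[k]])
    do.call(scenario_config, args)
  })
}

#' Full factorial scenario grid
#'
#' Builds the complete grid of the simulation study: 2 prevalences (0.1, 0.5,
#' each with its own sample size) x 2 correlations (0.3, 0.7) x 2 hypotheses x
#' (no missingness + MCAR with 3 dropout patterns + MAR1 and MAR2 each with 3
#' patterns) = 80 scenario cells.
#'
#' @param n_reps replicates per cell.
#' @param seed base seed; each cell receives `seed + cell index`.
#' @return list of `scenario_config` objects.
#' @export
full_scenario_grid <- function(n_reps = 1000L, seed = 1L) {
  cells <- expand.grid(
    prevalence = c(0.1, 0.5), rho = c(0.3, 0.7),
    hypothesis = c("alternative", "null"),
    mech_pat = c("none", paste0(rep(c("MCAR", "MAR1", "MAR2"), each = 3),
                                ".", c("equal", "unequal1", "unequal2"))),
    stringsAsFactors = FALSE)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    mp <- strsplit(cells$mech_pat[i], ".", fixed = TRUE)[[1]]
    out[[i]] <- scenario_config(
      prevalence = cells$prevalence[i], rho = cells$rho[i],
      hypothesis = cells$hypothesis[i],
      mechanism = mp[1],
      dropout_pattern = if (length(mp) > 1) mp[2] else "equal",
      n_reps = n_reps, seed = seed + i)
  }
  out
}
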