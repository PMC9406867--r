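effective_k2 <- function(anatomy, limits) {
  if (identical(anatomy, "knee")) limits$K2 * limits$K2_knee_multiplier
  else limits$K2
}

gc_threshold <- function(anatomy, limits) {
  if (identical(anatomy, "knee")) limits$gc_threshold_limb
  else limits$gc_threshold_trunk
}

#' RF risk tier of a scenario
#'
#' Applies the four SAR limit inequalities.  With TR-averaged metrics
#' \eqn{S_{wb} = \psi\,\xi_{wb}} and \eqn{S_{10g} = \psi\,\xi_{10g}} and
#' 6-minute averages scaled by \eqn{\min(1, T_S/T_{IEC})}:
#' tier 3 (attention) when any of
#' \eqn{S^{TIEC}_{wb} > K_1}, \eqn{S_{wb} > 2K_1},
#' \eqn{S^{TIEC}_{10g} > K_2^{eff}}, \eqn{S_{10g} > 2K_2^{eff}} holds;
#' tier 2 (warning) when instead \eqn{S_{wb} > K_1} or \eqn{S_{10g} >
#' K_2^{eff}} (a repetition or extension could reach tier 3); tier 1 (safe)
#' otherwise.  Equality with a limit is compliant (strict inequalities
#' escalate).  Knee implants use a doubled `K2`.
#'
#' @param scenario List or one-row data frame with `psi`, `TS`, `xi_wb`,
#'   `xi_10g` and `anatomy`.
#' @param limits An [iec_limits()].
#' @return Integer tier in `1:3`; attribute `metrics` carries the four
#'   inequality values.
#' @export
rf_tier <- function(scenario, limits = iec_limits()) {
  need <- c("psi", "TS", "xi_wb", "xi_10g", "anatomy")
  miss <- need[!need %in% names(scenario)]
  if (length(miss))
    stop("missing RF metric(s): ", paste(miss, collapse = ", "))
  if (anyNA(scenario[c("psi", "TS", "xi_wb", "xi_10g")]))
    stop("missing RF metric value")
  k2e <- effective_k2(scenario$anatomy, limits)
  wb <- temporal_averages(scenario$psi, scenario$xi_wb, scenario$TS, limits)
  lc <- temporal_averages(scenario$psi, scenario$xi_10g, scenario$TS, limits)
  tier <-
    if (wb$tiec > limits$K1 || wb$tr > 2 * limits$K1 ||
        lc$tiec > k2e || lc$tr > 2 * k2e) 3L
    else if (wb$tr > limits$K1 || lc$tr > k2e) 2L
    else 1L
  structure(tier, metrics = c(sar_wb_tiec = wb$tiec, sar_wb_tr = wb$tr,
                              sar_10g_tiec = lc$tiec, sar_10g_tr = lc$tr,
                              K2_eff = k2e))
}

#' GC risk tier of a scenario
#'
#' Temperature-rise based classification: tier 3 when the end-of-sequence
#' maximum rise \eqn{\vartheta} exceeds the threshold (2 degC for hip and
#' shoulder, reflecting 39 degC max local tissue temperature over a 37 degC
#' trunk baseline; 3 degC for the knee over a 36 degC limb baseline);
#' tier 2 when \eqn{\vartheta} is compliant but the steady-state rise
#' \eqn{\vartheta_\infty} exceeds it; tier 1 otherwise.
#'
#' @param scenario List or one-row data frame with `theta_end_max`,
#'   `theta_inf_max` and `anatomy`.
#' @param limits An [iec_limits()].
#' @return Integer tier in `1:3`; attribute `threshold` carries the degC
#'   threshold used.
#' @export
gc_tier <- function(scenario, limits = iec_limits()) {
  need <- c("theta_end_max", "theta_inf_max", "anatomy")
  miss <- need[!need %in% names(scenario)]
  if (length(miss))
    stop("missing GC metric(s): ", paste(miss, collapse = ", "))
  th <- scenario$theta_end_max
  thi <- scenario$theta_inf_max
  if (anyNA(c(th, thi))) stop("missing GC metric value")
  if (thi < th - 1e-12)
    stop("inconsistent metrics: theta_inf_max < theta_end_max")
  thr <- gc_threshold(scenario$anatomy, limits)
  tier <- if (th > thr) 3L else if (thi > thr) 2L else 1L
  structure(tier, threshold = thr)
}

#' Classify a scenario matrix
#'
#' Applies [rf_tier()] and/or [gc_tier()] to every scenario row and returns
#' the per-scenario report plus aggregate tier counts, ordered by (anatomy,
#' region, field strength, sequence).
#'
#' @param scenarios Data frame with columns `id`, `anatomy`, and the metric
#'   columns consumed by the tier functions (`psi`, `TS`, `xi_wb`, `xi_10g`
#'   for RF; `theta_end_max`, `theta_inf_max` for GC).  Optional `region`,
#'   `field_strength`, `sequence` columns are used for ordering.  Missing
#'   metric groups yield `NA` tiers for that channel.
#' @param limits An [iec_limits()].
#' @return An object of class `tier_report`: list with `report` (data
#'   frame including `rf_tier` / `gc_tier`) and `counts`.
#' @export
classify_matrix <- function(scenarios, limits = iec_limits()) {
  if (!nrow(scenarios)) {
    return(structure(list(report = scenarios,
                          counts = list(rf = integer(0), gc = integer(0))),
                     class = "tier_report"))
  }
  if (!"id" %in% names(scenarios))
    scenarios$id <- seq_len(nrow(scenarios))
  if (anyDuplicated(scenarios$id)) stop("duplicate scenario ids")
  ordcols <- intersect(c("anatomy", "region", "field_strength", "sequence"),
                       names(scenarios))
  if (length(ordcols))
    scenarios <- scenarios[do.call(order, scenarios[ordcols]), , drop = FALSE]
  has_rf <- all(c("psi", "TS", "xi_wb", "xi_10g") %in% names(scenarios))
  has_gc <- all(c("theta_end_max", "theta_inf_max") %in% names(scenarios))
  n <- nrow(scenarios)
  scenarios$rf_tier <- if (has_rf)
    vapply(seq_len(n), function(i)
      as.integer(rf_tier(as.list(scenarios[i, ]), limits)), integer(1))
  else NA_integer_
  scenarios$gc_tier <- if (has_gc)
    vapply(seq_len(n), function(i)
      as.integer(gc_tier(as.list(scenarios[i, ]), limits)), integer(1))
  else NA_integer_
  counts <- list(
    rf = if (has_rf) table(factor(scenarios$rf_tier, levels = 1:3)) else NULL,
    gc = if (has_gc) table(factor(scenarios$gc_tier, levels = 1:3)) else NULL
  )
  rownames(scenarios) <- NULL
  structure(list(report = scenarios, counts = counts), class = "tier_report")
}

#' @export
print.tier_report <- function(x, ...) {
  cat(sprintf("<tier_report> %d scenario(s)\n", nrow(x$report)))
  for (ch in c("rf", "gc")) {
    if (!is.null(x$counts[[ch]]))
      cat(sprintf("  %s tiers 1/2/3: %s\n", toupper(ch),
                  paste(as.integer(x$counts[[ch]]), collapse = "/")))
  }
  invisible(x)
}

#' Colour-coded text matrix of a tier report
#'
#' One line per scenario with tier-coloured markers (green/yellow/red
#' convention), suitable for terminal or log inspection.
#'
#' @param x A [classify_matrix()] result.
#' @return Character vector (invisibly); printed to the console.
#' @export
tier_matrix_text <- function(x) {
  sym <- c("1" = "[G]", "2" = "[Y]", "3" = "[R]", "NA" = "[ ]")
  rep <- x$report
  lines <- vapply(seq_len(nrow(rep)), function(i) {
    r <- rep[i, ]
    sprintf("%-12s RF %s GC %s", as.character(r$id),
            sym[as.character(r$rf_tier)], sym[as.character(r$gc_tier)])
  }, character(1))
  cat(lines, sep = "\n")
  invisible(lines)
}

round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Percentage tabulation of exam-category counts
#'
#' Converts labelled nonnegative counts into percentages of their total,
#' rounded half-up to one decimal (registry-table convention).
#'
#' @param counts Named nonnegative integer vector.
#' @return Named numeric vector of percentages (one decimal).
#' @export
#' @examples
#' category_percentages(c(head = 777, rest = 3986 - 777))[["head"]]  # 19.5
category_percentages <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  total <- sum(counts)
  if (total == 0) stop("total count is zero")
  out <- round_half_up(100 * counts / total, 1)
  stats::setNames(as.numeric(out), names(counts))
}
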