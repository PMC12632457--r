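#' Per-cell event rate from a fluctuation-assay plating
#'
#' Both colony counts are scaled back to the undiluted culture and the rate
#' is their ratio:
#' `rate = (colonies_selective / dilution_selective) /
#'         (colonies_permissive / dilution_permissive)`.
#' This is the per-cell frequency of resistant colony formation as the
#' plating assays report it, not a Luria-Delbruck mutation-rate estimate.
#' A culture with zero selective colonies gets rate 0 with `censored = TRUE`
#' (censored at one event); zero permissive colonies make the culture size
#' unestimable and raise an error.
#'
#' @param colonies_selective,colonies_permissive non-negative colony counts.
#' @param dilution_selective,dilution_permissive dilutions in (0, 1] (e.g.
#'   1e-2 for a 1:100 plating).
#' @return Data frame with `rate` and `censored`, one row per culture.
#' @export
rate_from_plating <- function(colonies_selective, dilution_selective,
                              colonies_permissive, dilution_permissive) {
  if (any(colonies_selective < 0) || any(colonies_permissive < 0))
    stop("colony counts must be non-negative")
  if (any(dilution_selective <= 0) || any(dilution_selective > 1) ||
      any(dilution_permissive <= 0) || any(dilution_permissive > 1))
    stop("dilutions must lie in (0, 1]")
  if (any(colonies_permissive == 0))
    stop("cannot estimate culture size: zero permissive colonies")
  rate <- (colonies_selective / dilution_selective) /
    (colonies_permissive / dilution_permissive)
  data.frame(rate = rate, censored = colonies_selective == 0)
}

#' Rates for a whole plating table
#'
#' @param counts a `count_table` (see [make_colony_fixture()]) with columns
#'   `sample_id`, `genotype`, `colonies_selective`, `colonies_permissive`,
#'   `dilution_selective`, `dilution_permissive`.
#' @return The table with `rate` and `censored` columns appended.
#' @export
rate_table <- function(counts) {
  need <- c("sample_id", "genotype", "colonies_selective",
            "colonies_permissive", "dilution_selective", "dilution_permissive")
  if (!all(need %in% names(counts)))
    stop("missing columns: ", paste(setdiff(need, names(counts)), collapse = ", "))
  r <- rate_from_plating(counts$colonies_selective, counts$dilution_selective,
                         counts$colonies_permissive, counts$dilution_permissive)
  cbind(as.data.frame(counts), r)
}

#' Fold change versus the wild-type mean rate, and its natural log
#'
#' Divides every sample's rate (wild-type samples included) by the mean rate
#' of the wild-type group: `fold_change_i = rate_i / mean(rate[WT])`,
#' `ln_fold_i = log(fold_change_i)`. Zero-rate samples have no defined log
#' fold change; they are kept in the table with `ln_fold = NA` and flagged,
#' with a warning.
#'
#' @param rates data frame with at least `rate` and `genotype` (e.g. from
#'   [rate_table()]).
#' @param wt_label genotype label of the wild-type group.
#' @return The input with `fold_change`, `ln_fold` and `ln_defined`
#'   appended; attribute `wt_mean_rate`.
#' @export
fold_change_ln <- function(rates, wt_label = "WT") {
  stopifnot(all(c("rate", "genotype") %in% names(rates)))
  wt <- rates$rate[rates$genotype == wt_label]
  if (length(wt) == 0) stop("no samples with wild-type label '", wt_label, "'")
  wt_mean <- mean(wt)
  if (wt_mean <= 0) stop("wild-type mean rate must be positive")
  out <- as.data.frame(rates)
  out$fold_change <- out$rate / wt_mean
  out$ln_defined <- out$rate > 0
  if (any(!out$ln_defined))
    warning(sum(!out$ln_defined),
            " zero-rate sample(s): ln fold change undefined, flagged NA")
  out$ln_fold <- ifelse(out$ln_defined, log(out$fold_change), NA_real_)
  attr(out, "wt_mean_rate") <- wt_mean
  out
}
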