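# ChIP-qPCR relative occupancy: delta-delta-Cq with a quadruplex-free
# control region, 100% amplification efficiency (base 2) as the formula
# fixes. Technical replicates are averaged on the Cq (log) scale; biological
# replicates are summarized after the fold change is formed.

#' Delta-Cq: site relative to the control region
#'
#' `delta_cq = cq_site - cq_control`, vectorized.
#'
#' @param cq_site,cq_control Quantification cycles.
#' @return Numeric vector of cycle differences.
#' @examples
#' delta_cq(25, 24)
#' @export
delta_cq <- function(cq_site, cq_control) {
  cq_site - cq_control
}

#' Delta-delta-Cq fold change
#'
#' `ddcq = 2^(-delta_sample) / 2^(-delta_input) = 2^(delta_input -
#' delta_sample)`: the fold enrichment of immunoprecipitated DNA at a site
#' over the control site, normalized to input.
#'
#' @param delta_sample Delta-Cq in the immunoprecipitated sample.
#' @param delta_input Delta-Cq in the input.
#' @return Positive fold change (vectorized).
#' @examples
#' ddcq(2, 1)   # 0.5
#' @export
ddcq <- function(delta_sample, delta_input) {
  2^(delta_input - delta_sample)
}

#' Summarize ChIP-qPCR occupancy per site and condition
#'
#' Technical replicates are averaged on the Cq scale within each biological
#' replicate; delta-Cq against the control site is formed separately for the
#' IP and input samples of each biological replicate; per-replicate
#' delta-delta-Cq values are then summarized (mean, SD, min-max). A single
#' biological replicate yields an undefined spread, which is flagged.
#'
#' @param table A Cq tibble with columns `sample` (`"IP"` / `"input"`),
#'   `condition`, `site`, `bio_rep`, optional `tech_rep`, and `cq`.
#' @param control_site Name of the control site (defaults to the table's
#'   `control_site` attribute).
#' @return Tibble per (`condition`, `site`): `ddcq_mean`, `ddcq_sd`,
#'   `ddcq_min`, `ddcq_max`, `n_bio_reps`, `spread_defined`.
#' @export
summarize_occupancy <- function(table, control_site = NULL) {
  control_site <- control_site %||% attr(table, "control_site")
  if (is.null(control_site)) abort("control_site must be given")
  need <- c("sample", "condition", "site", "bio_rep", "cq")
  miss <- setdiff(need, names(table))
  if (length(miss)) abort(paste0("Cq table missing column(s): ",
                                 paste(miss, collapse = ", ")))
  if (!control_site %in% table$site) {
    abort(paste0("control site '", control_site, "' absent from the Cq table"))
  }
  # technical replicates -> one Cq per (sample, condition, site, bio_rep)
  cq <- table |>
    dplyr::group_by(.data$sample, .data$condition, .data$site, .data$bio_rep) |>
    dplyr::summarise(cq = mean(.data$cq), .groups = "drop")
  ctrl <- cq |>
    dplyr::filter(.data$site == control_site) |>
    dplyr::select("sample", "condition", "bio_rep", cq_control = "cq")
  per_rep <- cq |>
    dplyr::filter(.data$site != control_site) |>
    dplyr::inner_join(ctrl, by = c("sample", "condition", "bio_rep")) |>
    dplyr::mutate(dcq = delta_cq(.data$cq, .data$cq_control)) |>
    dplyr::select("sample", "condition", "site", "bio_rep", "dcq") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "dcq") |>
    dplyr::filter(!is.na(.data$IP) & !is.na(.data$input)) |>
    dplyr::mutate(ddcq = ddcq(.data$IP, .data$input))
  out <- per_rep |>
    dplyr::group_by(.data$condition, .data$site) |>
    dplyr::summarise(
      ddcq_mean = mean(.data$ddcq),
      ddcq_sd = sd(.data$ddcq),
      ddcq_min = min(.data$ddcq),
      ddcq_max = max(.data$ddcq),
      n_bio_reps = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(spread_defined = .data$n_bio_reps > 1L)
  if (any(!out$spread_defined)) {
    warn("single biological replicate for some site(s): replicate spread undefined")
  }
  out
}
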