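# TF activity from signed regulon enrichment.  The logFC signature is
# converted to fractional ranks and probit scores; a regulon's normalised
# enrichment score is the mode-weighted mean of its targets' scores times
# sqrt(regulon size), standard normal under the permutation null.

#' Score one regulon against a logFC signature
#'
#' Signature values become fractional ranks `r = (rank - 0.5) / n` (average
#' ranks on ties) and probit scores `z = qnorm(r)`; then
#' `NES = sum(mode * z) / sqrt(m)` over the `m` measured targets, with a
#' two-sided standard normal p-value.
#'
#' @param signature a `sample_signature` tibble (or any data frame with
#'   `gene` and `log_fc`).
#' @param targets character vector of regulon target genes.
#' @param modes integer vector of regulation modes (+1/-1) parallel to
#'   `targets`.
#' @param min_targets minimum measured targets (default 5); below it the
#'   regulon is not scorable and `NA`s are returned.
#' @return A one-row tibble: `nes`, `p_value`, `n_targets`.
#' @export
score_regulon <- function(signature, targets, modes, min_targets = 5) {
  stopifnot(length(targets) == length(modes), all(modes %in% c(-1, 1)))
  z <- qnorm((rank(signature$log_fc) - 0.5) / nrow(signature))
  names(z) <- signature$gene
  present <- targets %in% signature$gene
  m <- sum(present)
  if (m < min_targets)
    return(tibble::tibble(nes = NA_real_, p_value = NA_real_,
                          n_targets = m))
  nes <- sum(modes[present] * z[targets[present]]) / sqrt(m)
  tibble::tibble(nes = nes, p_value = 2 * pnorm(-abs(nes)), n_targets = m)
}

#' Score every regulon against every sample signature
#'
#' @param signatures named list of `sample_signature` tibbles (one per
#'   tumour sample), e.g. `deg_matrix()$signatures`.
#' @param regulons a [regulon_set()].
#' @param min_targets minimum measured targets per regulon (default 5).
#' @return A tibble with columns `sample`, `tf`, `nes`, `p_value`,
#'   `n_targets`; unscorable TFs appear with `NA` and a message.
#' @export
score_regulons <- function(signatures, regulons, min_targets = 5) {
  reg <- split(regulons, regulons$tf)
  out <- purrr::imap(signatures, function(sig, sample) {
    z <- qnorm((rank(sig$log_fc) - 0.5) / nrow(sig)) |>
      setNames(sig$gene)
    purrr::imap(reg, function(r, tf) {
      present <- r$target %in% names(z)
      m <- sum(present)
      if (m < min_targets)
        return(tibble::tibble(sample = sample, tf = tf, nes = NA_real_,
                              p_value = NA_real_, n_targets = m))
      nes <- sum(r$mode[present] * z[r$target[present]]) / sqrt(m)
      tibble::tibble(sample = sample, tf = tf, nes = nes,
                     p_value = 2 * pnorm(-abs(nes)), n_targets = m)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  skipped <- unique(out$tf[is.na(out$nes)])
  if (length(skipped))
    message(sprintf("skipped %d TF(s) with fewer than %d measured targets: %s",
                    length(skipped), min_targets,
                    paste(head(skipped, 5), collapse = ", ")))
  out
}

#' Binarise TF activity scores into a state matrix
#'
#' Within each sample, p-values are BH-adjusted across TFs; a TF is active
#' (+1) when `NES > 0` and the adjusted p is below `alpha`, inactive (-1)
#' when `NES < 0` under the same cutoff, else 0.
#'
#' @param scores tibble from [score_regulons()].
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return A list: `states` (a `state_matrix` with provenance `"TF"`) and
#'   `calls` (the scores tibble with `p_adjusted` and `state` columns).
#' @export
call_tf_states <- function(scores, alpha = 0.05) {
  stopifnot(nrow(scores) > 0)
  bh_na <- function(p) {
    out <- rep(NA_real_, length(p))
    out[!is.na(p)] <- bh_adjust(p[!is.na(p)])
    out
  }
  calls <- scores |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(p_adjusted = bh_na(.data$p_value)) |>
    dplyr::ungroup() |>
    dplyr::mutate(state = dplyr::case_when(
      is.na(.data$nes) | is.na(.data$p_adjusted) ~ 0L,
      .data$nes > 0 & .data$p_adjusted < alpha ~ 1L,
      .data$nes < 0 & .data$p_adjusted < alpha ~ -1L,
      TRUE ~ 0L))
  wide <- calls |>
    dplyr::select("tf", "sample", "state") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "state",
                       values_fill = 0L)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$tf
  list(states = state_matrix(m, "TF"), calls = calls)
}
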