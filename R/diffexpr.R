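# Per-sample differential expression: one tumour sample against the
# reference group.  The per-gene test asks whether the observed tumour count
# is an outlier under a negative binomial null fitted to the reference
# samples; logFC, BH adjustment and the {-1, 0, +1} discretisation follow.

#' Differential-expression configuration
#'
#' @param lfc_threshold absolute log2 fold-change cutoff for a nonzero call
#'   (strict inequality; default 1).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param pseudocount added to both numerator and denominator of the fold
#'   change to avoid infinities (default 0.5).
#' @param dispersion_shrink weight in `[0, 1]` pulling each gene's
#'   method-of-moments dispersion towards the common (mean) dispersion
#'   (default 0.7); with few reference samples the per-gene estimate is
#'   noisy and strong shrinkage keeps the test calibrated.
#' @return A list of class `de_config`.
#' @export
de_config <- function(lfc_threshold = 1, alpha = 0.05, pseudocount = 0.5,
                      dispersion_shrink = 0.7) {
  stopifnot(lfc_threshold > 0, alpha > 0, alpha < 1, pseudocount > 0,
            dispersion_shrink >= 0, dispersion_shrink <= 1)
  structure(list(lfc_threshold = lfc_threshold, alpha = alpha,
                 pseudocount = pseudocount,
                 dispersion_shrink = dispersion_shrink),
            class = "de_config")
}

#' Remove genes below the lower quartile of mean expression
#'
#' Genes whose mean normalised count falls strictly below the 25th
#' percentile (linear-interpolation convention) of all gene means are
#' removed; survivor order is preserved.
#'
#' @param counts a [count_matrix()].
#' @return A filtered [count_matrix()].
#' @export
filter_low_expression <- function(counts) {
  if (nrow(counts$counts) < 4)
    format_error("need at least 4 genes to estimate the lower quartile")
  sf <- estimate_size_factors(counts)
  norm <- sweep(counts$counts, 2, sf, "/")
  means <- rowMeans(norm)
  q1 <- quantile(means, 0.25, type = 7, names = FALSE)
  keep <- means >= q1   # strict "below" removes; ties at the quartile stay
  if (!any(keep)) format_error("all genes filtered out")
  count_matrix(counts$counts[keep, , drop = FALSE], counts$roles)
}

#' Median-of-ratios size factors
#'
#' Factors against the geometric-mean pseudo-reference computed on genes
#' positive in all samples, normalised to geometric mean 1.  When no gene is
#' positive everywhere the function falls back to library-size factors with
#' a warning.
#'
#' @param counts a [count_matrix()].
#' @return Named positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(counts) {
  m <- counts$counts
  all_pos <- rowSums(m == 0) == 0
  if (!any(all_pos)) {
    warning("no gene positive in all samples; using library-size factors",
            call. = FALSE)
    sf <- counts$library_sizes
  } else {
    logref <- rowMeans(log(m[all_pos, , drop = FALSE]))
    sf <- apply(m[all_pos, , drop = FALSE], 2, function(col)
      exp(median(log(col) - logref)))
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(m))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone and capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return The adjusted values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    format_error("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# internal: two-sided NB outlier p-value including the observed point mass.
# The null predictive variance for the tumour count combines the reference
# NB variance with the sampling variance of the estimated reference mean
# ((1 + 1/n_ref) moment inflation); without it a 1-vs-n test is
# anti-conservative.
nb_two_sided_p <- function(x, mu, phi_eff) {
  lower <- numeric(length(x))
  upper <- numeric(length(x))
  nb <- phi_eff > 0
  lower[!nb] <- ppois(x[!nb], mu[!nb])
  upper[!nb] <- ppois(x[!nb] - 1, mu[!nb], lower.tail = FALSE)
  size <- 1 / phi_eff[nb]
  lower[nb] <- pnbinom(x[nb], size = size, mu = mu[nb])
  upper[nb] <- pnbinom(x[nb] - 1, size = size, mu = mu[nb],
                       lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Call differentially expressed genes for one tumour sample
#'
#' Per gene, `logFC = log2((x_s / f_s + c) / (mean_ref + c))` with
#' normalised counts and pseudocount `c`; the p-value is a two-sided
#' negative-binomial outlier test of the tumour count against the reference
#' prediction, with a per-gene method-of-moments dispersion shrunk towards
#' the common dispersion and inflated for reference-mean uncertainty.
#' P-values are BH-adjusted across genes and calls are discretised: +1/-1
#' when `|logFC|` exceeds the threshold and the adjusted p is below `alpha`.
#'
#' @param counts a [count_matrix()] (filtered).
#' @param sample_id a tumour sample id.
#' @param config a [de_config()].
#' @param size_factors optional precomputed factors (else estimated).
#' @return A tibble of class `sample_signature` with columns `gene`,
#'   `log_fc`, `p_value`, `p_adjusted`, `call`.
#' @export
call_degs <- function(counts, sample_id, config = de_config(),
                      size_factors = NULL) {
  if (!sample_id %in% tumor_ids(counts))
    format_error("'%s' is not a tumour sample", sample_id)
  refs <- reference_ids(counts)
  if (length(refs) < 2)
    format_error("need at least 2 reference samples")
  sf <- size_factors %||% estimate_size_factors(counts)
  ref_norm <- sweep(counts$counts[, refs, drop = FALSE], 2, sf[refs], "/")
  mu_ref <- rowMeans(ref_norm)
  var_ref <- apply(ref_norm, 1, var)
  n_ref <- length(refs)
  phi_gene <- pmax(0, (var_ref - mu_ref) / mu_ref^2)
  phi_gene[!is.finite(phi_gene)] <- 0
  phi_common <- mean(phi_gene[mu_ref > 0])
  w <- config$dispersion_shrink
  phi <- pmax(1e-8, w * phi_common + (1 - w) * phi_gene)
  x <- counts$counts[, sample_id]
  f_s <- sf[[sample_id]]
  c0 <- config$pseudocount
  log_fc <- log2((x / f_s + c0) / (mu_ref + c0))
  # predictive mean and moment-inflated variance on the tumour count scale
  m_s <- mu_ref * f_s
  v_s <- m_s + phi * m_s^2 + f_s^2 * (mu_ref + phi * mu_ref^2) / n_ref
  phi_eff <- ifelse(m_s > 0, pmax(0, (v_s - m_s) / m_s^2), 0)
  p <- ifelse(m_s > 0, nb_two_sided_p(x, m_s, phi_eff),
              as.numeric(x == 0))
  p[m_s == 0 & x > 0] <- 0
  p_adj <- bh_adjust(p)
  call <- ifelse(abs(log_fc) > config$lfc_threshold &
                   p_adj < config$alpha, sign(log_fc), 0)
  out <- tibble::tibble(gene = gene_ids(counts), log_fc = unname(log_fc),
                        p_value = unname(p), p_adjusted = unname(p_adj),
                        call = as.integer(unname(call)))
  structure(out, sample_id = sample_id, config = config,
            class = c("sample_signature", class(out)))
}

#' @export
glance.sample_signature <- function(x, ...) {
  tibble::tibble(sample = attr(x, "sample_id"), n_genes = nrow(x),
                 n_up = sum(x$call == 1), n_down = sum(x$call == -1))
}

#' Per-sample DEG signatures for every tumour sample
#'
#' @param counts a [count_matrix()].
#' @param config a [de_config()].
#' @return A list with `signatures` (named list of `sample_signature`
#'   tibbles), `log_fc` (genes x tumour samples matrix) and `calls` (the
#'   discrete genes x tumour samples \{-1, 0, 1\} matrix).
#' @export
deg_matrix <- function(counts, config = de_config()) {
  sf <- estimate_size_factors(counts)
  tumors <- tumor_ids(counts)
  sigs <- lapply(setNames(tumors, tumors), function(s)
    call_degs(counts, s, config, size_factors = sf))
  lfc <- vapply(sigs, function(s) s$log_fc, numeric(nrow(counts$counts)))
  calls <- vapply(sigs, function(s) s$call, integer(nrow(counts$counts)))
  rownames(lfc) <- rownames(calls) <- gene_ids(counts)
  list(signatures = sigs, log_fc = lfc, calls = calls)
}
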