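# Positive-feedback selection and discrete-score biclustering.  A protein's
# per-sample state profile and its encoding gene's DEG-call profile are
# compared by cosine similarity with a bootstrap confidence interval; a
# regulator whose gene moves concordantly with its state closes a positive
# feedback loop and is retained.

#' Cosine similarity of two discrete vectors
#'
#' `u . v / (||u|| ||v||)`, defined as 0 when either norm is zero.
#'
#' @param u,v equal-length numeric vectors.
#' @return The cosine in `[-1, 1]`.
#' @export
#' @examples
#' cosine(c(1, 0, 1, -1), c(1, 1, 0, -1))
cosine <- function(u, v) {
  if (length(u) != length(v)) format_error("vectors differ in length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

#' Percentile bootstrap confidence interval for the cosine
#'
#' Positions are resampled with replacement (jointly in both vectors) `B`
#' times; the cosine of each resample uses the zero-norm convention of
#' [cosine()].
#'
#' @param u,v equal-length vectors (length >= 2).
#' @param B bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(u, v, B = 1000, level = 0.95, seed = 1) {
  if (length(u) != length(v)) format_error("vectors differ in length")
  n <- length(u)
  stopifnot(n >= 2, B >= 1)
  idx <- with_seed(seed, matrix(sample.int(n, n * B, replace = TRUE), B, n))
  um <- matrix(u[idx], B, n); vm <- matrix(v[idx], B, n)
  dots <- rowSums(um * vm)
  norms <- sqrt(rowSums(um^2)) * sqrt(rowSums(vm^2))
  cosines <- ifelse(norms == 0, 0, dots / norms)
  q <- quantile(cosines, c((1 - level) / 2, 1 - (1 - level) / 2),
                names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

#' Select feedback-loop master regulators
#'
#' For every protein with a row in the state matrix, the cosine similarity
#' between its state profile and its encoding gene's DEG-call profile is
#' computed with a bootstrap CI; the protein is selected when the cosine
#' exceeds `cos_threshold` and the CI's lower limit is positive.  Proteins
#' whose encoding gene is not measured are retained as unselected records.
#'
#' @param mr_states a [state_matrix()] (proteins x samples).
#' @param deg_calls integer matrix of DEG calls (genes x samples,
#'   \{-1, 0, 1\}) sharing the sample set.
#' @param cos_threshold cosine cutoff (default 0.3).
#' @param B,level,seed bootstrap parameters (see [bootstrap_ci()]).
#' @return A tibble of class `feedback_records`: `protein`, `cosine`,
#'   `ci_low`, `ci_high`, `gene_measured`, `selected`.
#' @export
select_feedback_mrs <- function(mr_states, deg_calls, cos_threshold = 0.3,
                                B = 1000, level = 0.95, seed = 1) {
  samples <- intersect(colnames(mr_states), colnames(deg_calls))
  if (!length(samples)) format_error("no shared samples")
  unmeasured <- setdiff(rownames(mr_states), rownames(deg_calls))
  if (length(unmeasured))
    message(sprintf("%d protein(s) without a measured encoding gene: %s",
                    length(unmeasured),
                    paste(head(unmeasured, 5), collapse = ", ")))
  rows <- lapply(rownames(mr_states), function(p) {
    if (!p %in% rownames(deg_calls))
      return(tibble::tibble(protein = p, cosine = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            gene_measured = FALSE, selected = FALSE))
    u <- as.numeric(mr_states[p, samples])
    v <- as.numeric(deg_calls[p, samples])
    cs <- cosine(u, v)
    ci <- bootstrap_ci(u, v, B = B, level = level,
                       seed = sub_seed(seed, p))
    tibble::tibble(protein = p, cosine = cs, ci_low = ci[["low"]],
                   ci_high = ci[["high"]], gene_measured = TRUE,
                   selected = cs > cos_threshold && ci[["low"]] > 0)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, cos_threshold = cos_threshold,
            class = c("feedback_records", class(out)))
}

#' Merge regulator states and DEG calls into -3..3 scores
#'
#' The score encodes agreement between a protein's state and its gene's
#' expression call: `|3|` state and call agree in sign; `|2|` nonzero state,
#' call 0; `|1|` state 0, nonzero call; 0 otherwise (including sign
#' conflicts).
#'
#' @param mr_states a [state_matrix()].
#' @param deg_calls DEG call matrix (genes x samples); proteins without a
#'   measured gene contribute call 0.
#' @return An integer matrix of class `merged_scores` (proteins x shared
#'   samples).
#' @export
merged_scores <- function(mr_states, deg_calls) {
  samples <- intersect(colnames(mr_states), colnames(deg_calls))
  if (!length(samples)) format_error("no shared samples")
  s <- unclass(mr_states)[, samples, drop = FALSE]
  d <- matrix(0L, nrow(s), length(samples),
              dimnames = list(rownames(s), samples))
  measured <- intersect(rownames(s), rownames(deg_calls))
  d[measured, ] <- deg_calls[measured, samples]
  score <- matrix(0L, nrow(s), ncol(s), dimnames = dimnames(s))
  score[s != 0 & d == s] <- 3L
  score[s != 0 & d == 0] <- 2L
  score[s == 0 & d != 0] <- 1L
  score <- score * ifelse(s != 0, s, d)    # sign from state, else from call
  storage.mode(score) <- "integer"
  structure(score, class = c("merged_scores", "matrix", "array"))
}

#' @export
print.merged_scores <- function(x, ...) {
  cat(sprintf("<merged_scores> %d proteins x %d samples, values %d..%d\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' @export
tidy.merged_scores <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "protein") |>
    tidyr::pivot_longer(-"protein", names_to = "sample",
                        values_to = "score")
}

# internal: pairwise 1 - cosine distances between rows of a matrix
cosine_distance <- function(m) {
  norms <- sqrt(rowSums(m^2))
  dots <- tcrossprod(m)
  denom <- outer(norms, norms)
  cs <- ifelse(denom == 0, 0, dots / denom)
  cs[cs > 1] <- 1; cs[cs < -1] <- -1
  d <- 1 - cs
  diag(d) <- 0
  as.dist(d)
}

#' Bicluster a merged score matrix
#'
#' Rows (proteins) and columns (samples) are clustered independently with
#' Ward linkage (the `ward.D2` Lance-Williams convention on squared
#' distances) over 1 - cosine distances.
#'
#' @param m a [merged_scores()] matrix (>= 2 rows and columns).
#' @return A list of class `mr_biclustering`: `row_hclust`, `col_hclust`,
#'   `row_order`, `col_order`, `matrix`.
#' @export
bicluster <- function(m) {
  if (nrow(m) < 2 || ncol(m) < 2)
    format_error("need at least 2 rows and 2 columns")
  if (all(m == 0))
    format_error("all-zero matrix: cosine distances are degenerate")
  mm <- unclass(m)
  row_h <- hclust(cosine_distance(mm), method = "ward.D2")
  col_h <- hclust(cosine_distance(t(mm)), method = "ward.D2")
  structure(list(row_hclust = row_h, col_hclust = col_h,
                 row_order = rownames(m)[row_h$order],
                 col_order = colnames(m)[col_h$order],
                 matrix = structure(mm, class = c("merged_scores",
                                                  "matrix", "array"))),
            class = "mr_biclustering")
}

#' @export
print.mr_biclustering <- function(x, ...) {
  cat(sprintf("<mr_biclustering> %d proteins x %d samples (Ward, 1-cosine)\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Write the two dendrograms of a biclustering as Newick trees
#'
#' @param x an `mr_biclustering`.
#' @param row_path,col_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_dendrograms <- function(x, row_path, col_path) {
  ape::write.tree(ape::as.phylo(x$row_hclust), row_path)
  ape::write.tree(ape::as.phylo(x$col_hclust), col_path)
  invisible(c(row_path, col_path))
}

#' Containment of per-subtype master regulator sets
#'
#' For each ordered pair of subtypes (A, B): the fraction of proteins
#' present (nonzero in >= 1 sample) in A that are also present in B.
#' Quantifies nested subtype structure.
#'
#' @param mr_presence logical or \{-1, 0, 1\} matrix, proteins x samples.
#' @param subtypes character vector of subtype labels, one per sample.
#' @return A tibble: `from`, `to`, `n_from`, `containment`.
#' @export
subtype_containment <- function(mr_presence, subtypes) {
  stopifnot(ncol(mr_presence) == length(subtypes))
  present <- lapply(split(seq_along(subtypes), subtypes), function(j)
    rownames(mr_presence)[rowSums(mr_presence[, j, drop = FALSE] != 0) > 0])
  pairs <- expand.grid(from = names(present), to = names(present),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  tibble::tibble(
    from = pairs$from, to = pairs$to,
    n_from = vapply(pairs$from, function(a) length(present[[a]]), 0L),
    containment = unname(mapply(function(a, b) {
      if (!length(present[[a]])) return(NA_real_)
      mean(present[[a]] %in% present[[b]])
    }, pairs$from, pairs$to)))
}
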