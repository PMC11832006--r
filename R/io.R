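# Readers and writers for every external format the pipeline touches.
# All tables are UTF-8, tab-separated, with a header row; identifiers are
# opaque case-sensitive strings and no mapping is performed.

read_tsv_strict <- function(path, col_types = NULL) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  readr::read_tsv(path, col_types = col_types, progress = FALSE,
                  show_col_types = FALSE)
}

#' Read and write a count matrix
#'
#' The counts file is a TSV whose header row holds sample ids and whose first
#' column holds gene ids.  Sample roles come either from the `roles` argument
#' (named character vector) or from a sidecar metadata TSV with columns
#' `sample` and `role`.
#'
#' @param path counts TSV.
#' @param roles named character vector of `"tumor"`/`"reference"`.
#' @param metadata path to a sidecar TSV with columns `sample`, `role`
#'   (ignored when `roles` is given).
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, roles = NULL, metadata = NULL) {
  tbl <- read_tsv_strict(path)
  if (ncol(tbl) < 2) format_error("counts file needs gene ids plus samples")
  genes <- as.character(tbl[[1]])
  m <- as.matrix(tbl[, -1])
  if (!is.numeric(m)) format_error("non-numeric count in %s", path)
  if (anyNA(m)) format_error("missing count value in %s", path)
  rownames(m) <- genes
  if (is.null(roles)) {
    if (is.null(metadata))
      format_error("sample roles required (roles= or metadata=)")
    md <- read_tsv_strict(metadata)
    if (!all(c("sample", "role") %in% names(md)))
      format_error("metadata needs columns 'sample' and 'role'")
    roles <- setNames(md$role, md$sample)
  }
  count_matrix(m, roles)
}

#' @rdname read_count_matrix
#' @param x a `count_matrix`.
#' @param metadata_path optional path for the roles sidecar TSV.
#' @export
write_count_matrix <- function(x, path, metadata_path = NULL) {
  tbl <- tibble::as_tibble(x$counts, rownames = "gene")
  readr::write_tsv(tbl, path, progress = FALSE)
  if (!is.null(metadata_path))
    readr::write_tsv(tibble::tibble(sample = sample_ids(x),
                                    role = unname(x$roles)),
                     metadata_path, progress = FALSE)
  invisible(path)
}

# sign vocabulary accepted in network and regulon files
.sign_tokens <- c("1" = 1, "+1" = 1, "-1" = -1, "−1" = -1,
                  "activates" = 1, "inhibits" = -1,
                  "activation" = 1, "inhibition" = -1,
                  "stimulation" = 1, "repression" = -1)

parse_sign <- function(x, path) {
  s <- .sign_tokens[trimws(as.character(x))]
  if (anyNA(s)) {
    bad <- which(is.na(s))[1]
    format_error("unknown sign token '%s' (line %d of %s)",
                 trimws(as.character(x))[bad], bad + 1L, path)
  }
  as.integer(unname(s))
}

#' Read and write a directed signed network
#'
#' Accepts a three-column TSV (`source`, `sign`, `target` in SIF order, or
#' headered `from`/`sign`/`to`).  Sign tokens: `+1`/`-1`/`1`,
#' `activates`/`inhibits`, `stimulation`/`repression`.
#'
#' @param path network TSV/SIF.
#' @return A [signed_network()].
#' @export
read_signed_network <- function(path) {
  tbl <- read_tsv_strict(path, col_types = readr::cols(.default = "c"))
  if (ncol(tbl) < 3) format_error("network file needs 3 columns: %s", path)
  nm <- tolower(names(tbl))
  if (all(c("from", "to", "sign") %in% nm)) {
    from <- tbl[[which(nm == "from")]]
    to <- tbl[[which(nm == "to")]]
    sgn <- tbl[[which(nm == "sign")]]
  } else {           # SIF order: source, interaction, target
    from <- tbl[[1]]; sgn <- tbl[[2]]; to <- tbl[[3]]
  }
  signed_network(data.frame(from = from, to = to,
                            sign = parse_sign(sgn, path)))
}

#' @rdname read_signed_network
#' @param x a `signed_network`.
#' @export
write_signed_network <- function(x, path) {
  readr::write_tsv(tibble::tibble(from = x$from, sign = x$sign, to = x$to),
                   path, progress = FALSE)
  invisible(path)
}

#' Read and write a signed regulon table
#'
#' TSV with columns `tf`, `target`, `mode` (CollecTRI-style export); mode
#' tokens as in [read_signed_network()].
#'
#' @param path regulon TSV.
#' @return A [regulon_set()].
#' @export
read_regulons <- function(path) {
  tbl <- read_tsv_strict(path, col_types = readr::cols(.default = "c"))
  nm <- tolower(names(tbl))
  if (!all(c("tf", "target", "mode") %in% nm))
    format_error("regulon file needs columns tf, target, mode: %s", path)
  regulon_set(data.frame(tf = tbl[[which(nm == "tf")]],
                         target = tbl[[which(nm == "target")]],
                         mode = parse_sign(tbl[[which(nm == "mode")]], path)))
}

#' @rdname read_regulons
#' @param x a `regulon_set`.
#' @export
write_regulons <- function(x, path) {
  readr::write_tsv(tibble::tibble(tf = x$tf, target = x$target,
                                  mode = x$mode),
                   path, progress = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members.  Lines with fewer than three fields are rejected.
#'
#' @param path GMT file.
#' @return A [gene_sets()] collection.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) format_error("empty GMT file: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    format_error("malformed GMT line %d (<3 fields) in %s", short[1], path)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1)
  gene_sets(sets, vapply(fields, `[[`, "", 2))
}

#' @rdname read_gene_sets
#' @param x a `gene_sets` collection.
#' @export
write_gene_sets <- function(x, path) {
  sets <- gene_set_list(x)
  desc <- vapply(split(x$description, x$set), `[[`, "", 1)
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read and write a discrete state matrix
#'
#' TSV round-trip for proteins-by-samples matrices over \{-1, 0, 1\}; the
#' provenance tag travels in the `#provenance:` comment on the first line.
#'
#' @param path state matrix TSV.
#' @return A [state_matrix()].
#' @export
read_state_matrix <- function(path) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  first <- readLines(path, n = 1)
  prov <- if (grepl("^#provenance:", first))
    sub("^#provenance:\\s*", "", first) else "merged"
  tbl <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         show_col_types = FALSE)
  m <- as.matrix(tbl[, -1])
  rownames(m) <- as.character(tbl[[1]])
  state_matrix(m, provenance = prov)
}

#' @rdname read_state_matrix
#' @param x a `state_matrix`.
#' @export
write_state_matrix <- function(x, path) {
  m <- unclass(x)
  attr(m, "provenance") <- NULL
  tbl <- tibble::as_tibble(m, rownames = "protein")
  writeLines(c(sprintf("#provenance: %s", attr(x, "provenance")),
               sub("\n$", "", readr::format_tsv(tbl))),
             path, useBytes = TRUE)
  invisible(path)
}

#' Write a result table as TSV
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}
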