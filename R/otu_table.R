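#' Construct an OTU count table
#'
#' An `otu_table` is the universal input container of the package: an
#' integer matrix of non-negative counts with samples in rows and OTUs in
#' columns, per-sample total read counts, and (optionally) a class label per
#' sample.
#'
#' Totals need not equal the row sums: they may come from raw sequencing
#' depth before OTU filtering. When `totals` is `NULL` they default to the
#' row sums of `counts`.
#'
#' @param counts numeric matrix of non-negative integer counts, samples in
#'   rows, OTUs in columns. Dimnames, if present, provide the IDs.
#' @param sample_ids,otu_ids character vectors of IDs; default to the
#'   dimnames of `counts` or generated `S1..`/`OTU1..` IDs.
#' @param totals per-sample total aligned reads \eqn{N_i}; defaults to row
#'   sums.
#' @param labels optional per-sample class labels (coerced to factor).
#' @return An object of class `otu_table`: a list with elements `counts`,
#'   `totals` and `labels`.
#' @examples
#' x <- otu_table(matrix(c(1, 2, 3, 4), 2, 2))
#' x$totals
#' @export
otu_table <- function(counts, sample_ids = NULL, otu_ids = NULL,
                      totals = NULL, labels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L) stop("an otu_table needs at least 2 samples")
  if (ncol(counts) < 1L) stop("an otu_table needs at least 1 OTU")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(counts))
    stop(sprintf(
      "counts must be non-negative integers; offending entry [%d, %d] = %s",
      ij[1L], ij[2L], format(counts[bad[1L]])
    ))
  }
  storage.mode(counts) <- "double"
  if (is.null(sample_ids)) {
    sample_ids <- rownames(counts)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(counts)))
  }
  if (is.null(otu_ids)) {
    otu_ids <- colnames(counts)
    if (is.null(otu_ids)) otu_ids <- paste0("OTU", seq_len(ncol(counts)))
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  if (anyDuplicated(otu_ids)) stop("duplicate OTU IDs")
  if (length(sample_ids) != nrow(counts) || length(otu_ids) != ncol(counts))
    stop("ID lengths do not match the count matrix")
  dimnames(counts) <- list(sample_ids, otu_ids)
  if (is.null(totals)) totals <- rowSums(counts)
  totals <- as.numeric(totals)
  if (length(totals) != nrow(counts) || any(!is.finite(totals)) || any(totals < 0))
    stop("totals must be non-negative, one per sample")
  names(totals) <- sample_ids
  if (!is.null(labels)) {
    if (length(labels) != nrow(counts)) stop("labels must have one entry per sample")
    labels <- factor(labels)
    names(labels) <- sample_ids
  }
  structure(list(counts = counts, totals = totals, labels = labels),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs\n", nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  total reads: median %s (range %s-%s)\n",
              format(stats::median(x$totals)), format(min(x$totals)),
              format(max(x$totals))))
  zp <- mean(x$counts == 0)
  cat(sprintf("  overall zero proportion: %.3f\n", zp))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Read an OTU count table from delimited text
#'
#' Reads a TSV/CSV count table with a header row of IDs. Both orientations
#' are supported; `orientation = "otus-in-rows"` transposes on read so the
#' returned table always has samples in rows.
#'
#' @param path file path to a delimited text file (delimiter inferred from
#'   the extension, `.csv` = comma, otherwise tab; override with `sep`).
#' @param orientation `"samples-in-rows"` (default) or `"otus-in-rows"`.
#' @param label_column optional name of a column (in sample orientation)
#'   holding class labels.
#' @param totals_column optional name of a column holding per-sample total
#'   reads. By default a column named `"total"` (as written by
#'   [write_otu_table()]) is used when present; otherwise totals are the
#'   row sums over the count columns. Pass `NA` to force row sums.
#' @param label_file optional two-column delimited file (sample_id, label);
#'   ignored when `label_column` is given.
#' @param drop_columns metadata columns to discard (samples-in-rows only).
#' @param sep field delimiter; `NULL` to infer from the extension.
#' @return An [otu_table].
#' @export
read_otu_table <- function(path, orientation = c("samples-in-rows", "otus-in-rows"),
                           label_column = NULL, totals_column = NULL,
                           label_file = NULL, drop_columns = NULL, sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (orientation == "otus-in-rows") {
    if (!is.null(label_column) || !is.null(totals_column))
      stop("label/totals columns are only supported with samples-in-rows")
    mat <- t(as.matrix(df))
    return(otu_table(check_numeric_cells(mat)))
  }
  labels <- NULL
  totals <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% colnames(df)) stop("label column not found: ", label_column)
    labels <- df[[label_column]]
    df <- df[, setdiff(colnames(df), label_column), drop = FALSE]
  }
  if (is.null(totals_column) && "total" %in% colnames(df))
    totals_column <- "total"
  if (!is.null(totals_column) && !is.na(totals_column)) {
    if (!totals_column %in% colnames(df)) stop("totals column not found: ", totals_column)
    totals <- as.numeric(df[[totals_column]])
    df <- df[, setdiff(colnames(df), totals_column), drop = FALSE]
  }
  if (!is.null(drop_columns))
    df <- df[, setdiff(colnames(df), drop_columns), drop = FALSE]
  mat <- check_numeric_cells(as.matrix(df))
  if (is.null(labels) && !is.null(label_file)) {
    lab <- utils::read.table(label_file, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
    idx <- match(rownames(mat), lab[[1L]])
    if (anyNA(idx)) stop("label file is missing some sample IDs")
    labels <- lab[[2L]][idx]
  }
  otu_table(mat, totals = totals, labels = labels)
}

# read.table silently keeps character columns; surface the offending cell
check_numeric_cells <- function(mat) {
  num <- suppressWarnings(apply(mat, 2L, as.numeric))
  bad <- which(is.na(num) & !is.na(mat))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(mat))
    stop(sprintf("non-numeric entry at row '%s', column '%s': %s",
                 rownames(mat)[ij[1L]], colnames(mat)[ij[2L]], mat[bad[1L]]))
  }
  dimnames(num) <- dimnames(mat)
  num
}

#' Write an OTU table as TSV
#'
#' @param x an [otu_table].
#' @param path output file path.
#' @param labels if `TRUE` and the table is labelled, append a `label`
#'   column.
#' @export
write_otu_table <- function(x, path, labels = !is.null(x$labels)) {
  df <- as.data.frame(x$counts, check.names = FALSE)
  df <- cbind(sample_id = rownames(x$counts), df, total = x$totals)
  if (labels && !is.null(x$labels)) df$label <- as.character(x$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset an OTU table
#'
#' `[` keeps the container semantics: totals and labels follow the sample
#' subset; totals are NOT recomputed from the retained OTUs.
#'
#' @param x an [otu_table].
#' @param i,j sample and OTU indices.
#' @param ... ignored.
#' @export
`[.otu_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  otu_table(x$counts[i, j, drop = FALSE],
            totals = x$totals[i],
            labels = if (!is.null(x$labels)) x$labels[i])
}

#' Drop low-depth samples
#'
#' Retains samples whose total read count is at least `min_reads`; samples
#' with fewer reads are dropped. Order is preserved.
#'
#' @param x an [otu_table].
#' @param min_reads minimum total read count (samples with
#'   `totals < min_reads` are removed).
#' @return A filtered [otu_table].
#' @export
filter_samples_by_depth <- function(x, min_reads) {
  stopifnot(inherits(x, "otu_table"), min_reads >= 0)
  keep <- x$totals >= min_reads
  if (!any(keep)) stop("depth filter removed every sample")
  if (sum(keep) < 2L) stop("depth filter left fewer than 2 samples")
  x[which(keep), ]
}

#' Filter OTUs by mean relative abundance and zero proportion
#'
#' Retains OTUs whose mean relative abundance \eqn{mean_i(n_{ij}/N_i)} is at
#' least `min_mean_rel_abundance` and whose proportion of zero counts is
#' strictly below `max_zero_proportion`. Pass `0` / `1` to disable either
#' filter.
#'
#' @param x an [otu_table] with positive totals.
#' @param min_mean_rel_abundance minimum mean relative abundance in `[0, 1]`.
#' @param max_zero_proportion strict upper bound on the per-OTU zero
#'   proportion, in `[0, 1]`.
#' @return A filtered [otu_table].
#' @export
filter_otus <- function(x, min_mean_rel_abundance = 0, max_zero_proportion = 1) {
  stopifnot(inherits(x, "otu_table"),
            min_mean_rel_abundance >= 0, min_mean_rel_abundance <= 1,
            max_zero_proportion >= 0, max_zero_proportion <= 1)
  if (any(x$totals <= 0)) stop("relative abundance undefined: zero sample total")
  rel <- sweep(x$counts, 1L, x$totals, "/")
  zp <- colMeans(x$counts == 0)
  keep <- colMeans(rel) >= min_mean_rel_abundance &
    (max_zero_proportion == 1 | zp < max_zero_proportion)
  if (!any(keep)) stop("OTU filter removed every OTU")
  x[, which(keep)]
}

#' Per-sample resolutions
#'
#' The resolution of sample \eqn{i} is its sequencing depth normalized by
#' the cohort mean depth, \eqn{t_i = N_i / \bar N}. Resolutions scale the
#' Poisson rates of the count model so that samples sequenced at different
#' depths are treated on a common scale; by construction `mean(t) == 1`.
#'
#' @param x an [otu_table] with strictly positive totals, or a numeric
#'   vector of totals.
#' @return A list of class `resolutions` with elements `t` (per-sample
#'   resolution) and `nbar` (mean total).
#' @export
compute_resolutions <- function(x) {
  totals <- if (inherits(x, "otu_table")) x$totals else as.numeric(x)
  if (any(totals <= 0)) stop("all totals must be positive to define resolutions")
  nbar <- mean(totals)
  structure(list(t = totals / nbar, nbar = nbar), class = "resolutions")
}

#' Univariate OTU screening (Mann-Whitney U + Benjamini-Hochberg)
#'
#' Screens OTUs for association with a binary class label using a two-sided
#' Mann-Whitney U (Wilcoxon rank-sum) test on per-sample relative
#' abundances, adjusts p-values with the Benjamini-Hochberg step-up
#' procedure, and retains OTUs with q-value strictly below `alpha_q`.
#' Intended to be run on the training set only.
#'
#' @param x a labelled [otu_table] with exactly two classes.
#' @param alpha_q q-value threshold in `(0, 1]`; OTUs with `q < alpha_q` are
#'   retained (`alpha_q = 1` retains everything).
#' @param exact use the exact null distribution when both groups have fewer
#'   than 30 samples and there are no ties; otherwise the normal
#'   approximation with tie correction is used.
#' @return A list with `retained` (character vector of OTU ids) and
#'   `report` (data.frame with columns otu_id, U, p, q, retained).
#' @export
screen_otus <- function(x, alpha_q = 0.05, exact = FALSE) {
  stopifnot(inherits(x, "otu_table"), alpha_q > 0, alpha_q <= 1)
  if (is.null(x$labels) || nlevels(x$labels) != 2L)
    stop("screening requires a binary class label")
  if (any(x$totals <= 0)) stop("relative abundance undefined: zero sample total")
  rel <- sweep(x$counts, 1L, x$totals, "/")
  g1 <- x$labels == levels(x$labels)[1L]
  res <- apply(rel, 2L, function(v) {
    wt <- suppressWarnings(
      stats::wilcox.test(v[g1], v[!g1], alternative = "two.sided",
                         exact = exact, correct = TRUE)
    )
    c(U = unname(wt$statistic), p = wt$p.value)
  })
  p <- res["p", ]
  p[is.na(p)] <- 1 # constant OTU in both groups
  q <- stats::p.adjust(p, method = "BH")
  retained <- q < alpha_q | alpha_q == 1
  report <- data.frame(otu_id = colnames(x$counts), U = res["U", ], p = p,
                       q = q, retained = retained, row.names = NULL)
  list(retained = report$otu_id[report$retained], report = report)
}

#' Write an OTU screening report as TSV
#'
#' @param screening result of [screen_otus()].
#' @param path output file path.
#' @export
write_screening_report <- function(screening, path) {
  utils::write.table(screening$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
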