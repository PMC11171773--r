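#' Construct a time-series expression set
#'
#' @param values numeric matrix of log2 expression, genes in rows (rownames =
#'   gene ids), samples in columns (colnames = sample ids).
#' @param sample_groups named character vector mapping sample id to timepoint
#'   label (e.g. `"T1"`). Timepoints are ordered by their numeric suffix.
#' @return Object of class `expression_series` with components `values`,
#'   `sample_groups`, `timepoints` (ordered labels) and `genes`.
#' @export
expression_series <- function(values, sample_groups) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("expression matrix needs gene rownames")
  if (is.null(colnames(values))) stop("expression matrix needs sample colnames")
  if (anyDuplicated(rownames(values))) {
    stop("duplicated gene id: ",
         rownames(values)[duplicated(rownames(values))][1L])
  }
  if (!is.numeric(values) || anyNA(values)) {
    stop("expression matrix must be numeric with no missing values")
  }
  missing <- setdiff(colnames(values), names(sample_groups))
  if (length(missing) > 0L) {
    stop("sample(s) without timepoint group: ", paste(missing, collapse = ", "))
  }
  sample_groups <- sample_groups[colnames(values)]
  tp <- unique(unname(sample_groups))
  suffix <- suppressWarnings(as.numeric(sub("^[^0-9]*", "", tp)))
  tp <- if (anyNA(suffix)) sort(tp) else tp[order(suffix)]
  structure(list(values = values, sample_groups = sample_groups,
                 timepoints = tp, genes = rownames(values)),
            class = "expression_series")
}

#' @export
print.expression_series <- function(x, ...) {
  cat(sprintf("expression_series: %d genes x %d samples over %d timepoints (%s ... %s)\n",
              nrow(x$values), ncol(x$values), length(x$timepoints),
              x$timepoints[1L], x$timepoints[length(x$timepoints)]))
  invisible(x)
}

#' Read a time-series expression matrix
#'
#' The expression TSV has gene ids in the first column and one column per
#' sample; the group-map TSV has two columns, `sample` and `timepoint`.
#'
#' @param path expression matrix TSV.
#' @param group_map sample-to-timepoint TSV.
#' @return An [expression_series()].
#' @export
read_expression <- function(path, group_map) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1L]]
  if (anyDuplicated(genes)) {
    stop("duplicated gene id: ", genes[duplicated(genes)][1L])
  }
  mat <- df[, -1L, drop = FALSE]
  for (j in seq_along(mat)) {
    v <- suppressWarnings(as.numeric(mat[[j]]))
    if (anyNA(v)) {
      stop(sprintf("non-numeric expression value at row %d, column '%s'",
                   which(is.na(v))[1L], names(mat)[j]))
    }
    mat[[j]] <- v
  }
  mat <- as.matrix(mat)
  rownames(mat) <- genes
  gm <- utils::read.delim(group_map, stringsAsFactors = FALSE)
  if (ncol(gm) < 2L) stop("group map needs columns: sample, timepoint")
  groups <- stats::setNames(as.character(gm[[2L]]), as.character(gm[[1L]]))
  expression_series(mat, groups)
}

#' Write an expression series and its group map as TSVs
#'
#' @param series an [expression_series()].
#' @param path expression matrix output TSV.
#' @param group_path group map output TSV.
#' @export
write_expression <- function(series, path, group_path) {
  df <- data.frame(gene = rownames(series$values),
                   apply(series$values, 2L, function(v) sprintf("%.17g", v)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gm <- data.frame(sample = names(series$sample_groups),
                   timepoint = unname(series$sample_groups))
  utils::write.table(gm, group_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Align the grand mean expression to a target value
#'
#' Applies a single additive shift so the grand mean over all cells equals
#' `target` (default 10, the conventional log2 anchor for the arrays this
#' model was developed on). Relative differences between cells — hence fold
#' changes and t statistics — are preserved exactly. With
#' `per_sample = TRUE` each sample (array) is shifted independently instead.
#'
#' @param series an [expression_series()].
#' @param target grand mean after shifting (default 10).
#' @param per_sample shift each sample column separately.
#' @return The shifted series.
#' @export
normalize_global_mean <- function(series, target = 10, per_sample = FALSE) {
  stopifnot(inherits(series, "expression_series"),
            length(series$values) > 0L)
  if (per_sample) {
    shift <- target - colMeans(series$values)
    series$values <- sweep(series$values, 2L, shift, "+")
  } else {
    series$values <- series$values + (target - mean(series$values))
  }
  series
}

#' Samples belonging to one timepoint
#' @keywords internal
timepoint_samples <- function(series, timepoint) {
  if (!timepoint %in% series$timepoints) {
    stop("unknown timepoint label: ", timepoint)
  }
  names(series$sample_groups)[series$sample_groups == timepoint]
}

#' Adjacent timepoint pairs of a series
#'
#' @param series an [expression_series()].
#' @return List of length-2 character vectors, one per segment.
#' @export
segments_of <- function(series) {
  tp <- series$timepoints
  lapply(seq_len(length(tp) - 1L), function(i) c(tp[i], tp[i + 1L]))
}

segment_label <- function(segment) paste(segment, collapse = ":")

#' Call differentially expressed genes between adjacent timepoints
#'
#' Per-gene Welch t-test between the replicate groups of the two timepoints
#' with Benjamini-Hochberg FDR control. A gene is up-regulated iff
#' `log2fc >= log2(fc_threshold)` and `fdr <= fdr_threshold` (thresholds
#' inclusive); down-regulation is symmetric. With fewer than two replicates
#' on either side p-values are undefined and the call falls back to
#' fold-change-only mode (`p` and `fdr` set to `NA`, membership by fold
#' change alone).
#'
#' @param series an [expression_series()].
#' @param segment length-2 character vector of adjacent timepoint labels.
#' @param fdr_threshold FDR ceiling (default 0.1).
#' @param fc_threshold linear fold-change floor (default 1.5).
#' @return Object of class `deg_set`: `segment`, `up`, `down` (gene id
#'   vectors) and `stats` (per-gene `log2fc`, `p`, `fdr`).
#' @export
call_degs <- function(series, segment, fdr_threshold = 0.1,
                      fc_threshold = 1.5) {
  stopifnot(inherits(series, "expression_series"), length(segment) == 2L)
  s1 <- timepoint_samples(series, segment[1L])
  s2 <- timepoint_samples(series, segment[2L])
  x1 <- series$values[, s1, drop = FALSE]
  x2 <- series$values[, s2, drop = FALSE]
  log2fc <- rowMeans(x2) - rowMeans(x1)
  fc_only <- length(s1) < 2L || length(s2) < 2L
  if (fc_only) {
    p <- rep(NA_real_, nrow(x1))
    fdr <- p
  } else {
    p <- vapply(seq_len(nrow(x1)), function(i) {
      a <- x1[i, ]; b <- x2[i, ]
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        if (mean(a) == mean(b)) 1 else 0
      } else {
        stats::t.test(b, a)$p.value
      }
    }, numeric(1L))
    fdr <- stats::p.adjust(p, method = "BH")
  }
  lfc_min <- log2(fc_threshold)
  pass_fdr <- if (fc_only) rep(TRUE, length(p)) else fdr <= fdr_threshold
  up <- series$genes[log2fc >= lfc_min & pass_fdr]
  down <- series$genes[log2fc <= -lfc_min & pass_fdr]
  structure(list(segment = segment,
                 up = up, down = down,
                 stats = data.frame(gene = series$genes, log2fc = log2fc,
                                    p = p, fdr = fdr,
                                    stringsAsFactors = FALSE)),
            class = "deg_set")
}

#' @export
print.deg_set <- function(x, ...) {
  cat(sprintf("deg_set %s: %d up, %d down (of %d genes)\n",
              segment_label(x$segment), length(x$up), length(x$down),
              nrow(x$stats)))
  invisible(x)
}
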